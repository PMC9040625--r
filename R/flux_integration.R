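# Integration of protein concentrations with specific metabolic flux rates:
# apparent in vivo catalytic rates (k_app), gene-protein-reaction (GPR)
# resolution for isoenzymes and complexes, and flux-proteome correlations.

#' Concentration of a protein complex from its subunits
#'
#' The complex concentration is the mean of quantified subunit
#' concentrations; its standard deviation follows from error propagation of
#' the mean, `sqrt(sum(sd^2)) / m` for `m` subunits.
#'
#' @param means,sds Numeric vectors of subunit means and standard
#'   deviations (`NA` sds treated as 0).
#' @return List with `mean` and `sd`.
#' @export
complex_concentration <- function(means, sds = rep(0, length(means))) {
  ok <- is.finite(means)
  stopifnot(any(ok))
  m <- sum(ok)
  s <- sds[ok]
  s[is.na(s)] <- 0
  list(mean = mean(means[ok]), sd = sqrt(sum(s^2)) / m)
}

#' Select the in vivo relevant isoenzyme for a reaction
#'
#' Within each condition the alternative enzymes (single proteins or
#' complexes, by their combined concentration) are ranked by concentration
#' (1 = highest); the alternative with the smallest mean rank across
#' conditions is assumed to carry the whole flux. Ties are broken by higher
#' overall mean concentration, then lexicographically.
#'
#' @param alternatives Named list; each element is a character vector of
#'   subunit protein ids (length 1 for a single enzyme).
#' @param concentrations `data.frame` with `protein_id`, `condition`,
#'   `mean`, `sd`.
#' @return List with `chosen` (name of the selected alternative),
#'   `subunits`, and `conc` (`data.frame` of per-condition `mean`, `sd` for
#'   the chosen enzyme), or `NULL` when no alternative is quantified under
#'   all conditions.
#' @export
select_isoenzyme <- function(alternatives, concentrations) {
  stopifnot(length(alternatives) >= 1L)
  if (is.null(names(alternatives)) || any(!nzchar(names(alternatives))))
    names(alternatives) <- vapply(alternatives, paste, character(1),
                                  collapse = "+")
  cc <- data.table::as.data.table(concentrations)
  conditions <- unique(cc$condition)
  per_alt <- lapply(alternatives, function(subs) {
    sub <- cc[protein_id %in% subs]
    out <- sub[, {
      cx <- complex_concentration(mean, sd)
      .(mean = cx$mean, sd = cx$sd)
    }, by = condition]
    if (nrow(out) < length(conditions)) NULL else out
  })
  measured <- !vapply(per_alt, is.null, logical(1))
  if (!any(measured)) return(NULL)
  per_alt <- per_alt[measured]
  # rank alternatives within each condition (1 = most concentrated)
  tall <- data.table::rbindlist(per_alt, idcol = "alt")
  tall[, rank := rank(-mean, ties.method = "min"), by = condition]
  score <- tall[, .(mean_rank = mean(rank), overall = mean(mean)), by = alt]
  score <- score[order(mean_rank, -overall, alt)]
  chosen <- score$alt[1]
  list(chosen = chosen, subunits = alternatives[[chosen]],
       conc = as.data.frame(per_alt[[chosen]]))
}

#' Split a shared enzyme's concentration between reactions
#'
#' When one enzyme carries several reactions, its concentration is divided
#' proportionally to the flux each reaction carries; the split conserves the
#' total.
#'
#' @param total_conc Total enzyme concentration.
#' @param fluxes Named nonnegative numeric vector of fluxes per reaction.
#' @return Named vector of per-reaction concentrations summing to
#'   `total_conc`.
#' @export
split_shared_enzyme <- function(total_conc, fluxes) {
  stopifnot(all(fluxes >= 0))
  s <- sum(fluxes)
  if (s == 0) stop("cannot split by flux: all fluxes are zero")
  total_conc * fluxes / s
}

#' Apparent in vivo catalytic rate
#'
#' `k_app` is the specific flux rate divided by the concentration of the
#' catalyzing enzyme, converted to per-second units: flux in mmol/gDCW/h
#' over concentration in nmol/gDCW gives
#' `k_app = flux * 1e6 / (conc * 3600)` in 1/s, assuming every protein
#' chain is catalytically active. The standard deviation follows first-order
#' propagation for a ratio.
#'
#' @param flux Specific flux rate (mmol/gDCW/h); the magnitude is used.
#' @param conc Enzyme concentration (nmol/gDCW), positive.
#' @param flux_sd,conc_sd Optional standard deviations.
#' @return List with `kapp` (1/s) and `sd`.
#' @export
compute_kapp <- function(flux, conc, flux_sd = NA_real_, conc_sd = NA_real_) {
  if (is.na(conc) || conc <= 0) stop("enzyme concentration must be positive")
  k <- abs(flux) * 1e6 / (conc * 3600)
  s <- NA_real_
  if (!is.na(flux_sd) && !is.na(conc_sd)) {
    s <- if (flux == 0) 0 else
      k * sqrt((flux_sd / flux)^2 + (conc_sd / conc)^2)
  }
  list(kapp = k, sd = s)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a two-sided
#' normal-approximation p value.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `tau`, `p`, `n`.
#' @export
kendall_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Kendall correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Filter reactions eligible for k_app calculation
#'
#' Keeps reactions with (i) a nonzero flux under at least one condition,
#' (ii) a flux magnitude above `flux_fraction_min` of the reference (CO
#' fixation) reaction's flux under at least one condition, (iii) a chosen
#' enzyme with measured concentrations under all conditions, and (iv) no
#' membrane-flagged subunit in the chosen enzyme (membrane proteins are
#' excluded because their extraction is potentially incomplete).
#'
#' @param flux_means `data.frame`: `reaction_id`, `condition`, `mean`
#'   (mmol/gDCW/h).
#' @param reference_reaction Reaction id of the reference (CO fixation)
#'   flux.
#' @param gpr `data.frame`: `reaction_id`, `alternative_index`,
#'   `protein_id`, `membrane_flag` (logical).
#' @param concentrations `data.frame`: `protein_id`, `condition`, `mean`,
#'   `sd`.
#' @param flux_fraction_min Minimum fraction of the reference flux.
#' @return `data.frame` of eligible reactions with their chosen enzyme
#'   (`reaction_id`, `chosen`, comma-separated `subunits`).
#' @export
filter_kapp_reactions <- function(flux_means, reference_reaction, gpr,
                                  concentrations,
                                  flux_fraction_min = 0.001) {
  fm <- data.table::as.data.table(flux_means)
  if (!reference_reaction %in% fm$reaction_id)
    stop("reference reaction not in flux table: ", reference_reaction)
  ref <- fm[reaction_id == reference_reaction,
            .(ref_flux = abs(mean)), by = condition]
  x <- ref[fm, on = "condition"]
  keep_flux <- x[, .(nonzero = any(abs(mean) > 0),
                     above = any(abs(mean) > flux_fraction_min * ref_flux)),
                 by = reaction_id]
  keep_flux <- keep_flux[nonzero & above, reaction_id]
  gp <- data.table::as.data.table(gpr)
  rows <- list()
  for (rxn in intersect(unique(gp$reaction_id), keep_flux)) {
    g <- gp[reaction_id == rxn]
    alts <- split(g$protein_id, g$alternative_index)
    sel <- select_isoenzyme(alts, concentrations)
    if (is.null(sel)) next
    memb <- g[protein_id %in% sel$subunits, any(as.logical(membrane_flag))]
    if (isTRUE(memb)) next
    rows[[rxn]] <- data.frame(reaction_id = rxn, chosen = sel$chosen,
                              subunits = paste(sel$subunits, collapse = ","),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(reaction_id = character(), chosen = character(),
                      subunits = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' k_app table across reactions and conditions
#'
#' Resolves GPR associations (isoenzyme selection and complex averaging),
#' applies the flux and membrane eligibility filters, optionally splits a
#' shared enzyme's concentration between its reactions proportionally to
#' flux, and computes `k_app` with propagated uncertainty for every eligible
#' reaction and condition.
#'
#' @param fluxes Replicate flux table: `reaction_id`, `condition`,
#'   `replicate`, `value` (mmol/gDCW/h).
#' @param gpr GPR table (see [filter_kapp_reactions()]).
#' @param concentrations Condition-level concentrations (`protein_id`,
#'   `condition`, `mean`, `sd`).
#' @param reference_reaction Reference reaction id for the flux filter.
#' @param shared_splits Optional named list: for each shared enzyme, the
#'   character vector of reaction ids sharing it; the enzyme's
#'   concentration is split between them proportionally to flux within each
#'   condition.
#' @param config [pipeline_config()] list.
#' @return `data.frame`: `reaction_id`, `condition`, `chosen`,
#'   `flux_mean`, `flux_sd`, `enzyme_conc`, `enzyme_sd`, `kapp`, `kapp_sd`,
#'   `direction`.
#' @export
kapp_table <- function(fluxes, gpr, concentrations, reference_reaction,
                       shared_splits = NULL, config = pipeline_config()) {
  fx <- data.table::as.data.table(fluxes)
  fm <- fx[, .(mean = mean(value), sd = sd(value)),
           by = .(reaction_id, condition)]
  eligible <- filter_kapp_reactions(fm, reference_reaction, gpr,
                                    concentrations,
                                    flux_fraction_min = config$flux_fraction_min)
  if (nrow(eligible) == 0) return(data.frame())
  gp <- data.table::as.data.table(gpr)
  cc <- data.table::as.data.table(concentrations)
  rows <- list()
  for (i in seq_len(nrow(eligible))) {
    rxn <- eligible$reaction_id[i]
    subs <- strsplit(eligible$subunits[i], ",", fixed = TRUE)[[1]]
    for (cond in unique(fm$condition)) {
      f <- fm[reaction_id == rxn & condition == cond]
      if (nrow(f) == 0) next
      sub <- cc[protein_id %in% subs & condition == cond]
      if (nrow(sub) == 0) next
      cx <- complex_concentration(sub$mean, sub$sd)
      econc <- cx$mean; esd <- cx$sd
      # split a shared enzyme's pool between its reactions by flux
      if (!is.null(shared_splits)) {
        for (grp in shared_splits) {
          if (rxn %in% grp) {
            vv <- fm[reaction_id %in% grp & condition == cond]
            v <- abs(setNames(vv$mean, vv$reaction_id))
            if (sum(v) > 0) {
              frac <- split_shared_enzyme(1, v)[[rxn]]
              econc <- econc * frac
              esd <- esd * frac
            }
          }
        }
      }
      if (econc <= 0) next
      k <- compute_kapp(f$mean, econc, f$sd, esd)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = rxn, condition = cond, chosen = eligible$chosen[i],
        flux_mean = f$mean, flux_sd = f$sd, enzyme_conc = econc,
        enzyme_sd = esd, kapp = k$kapp, kapp_sd = k$sd,
        direction = sign(f$mean), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flux-proteome correlation summary
#'
#' Kendall tau-b correlations between flux magnitude and enzyme
#' concentration and between flux magnitude and k_app, pooled over
#' reaction-by-condition pairs (per-condition correlations reported as
#' well).
#'
#' @param kapp k_app table from [kapp_table()].
#' @return List with `flux_conc`, `flux_kapp` (each `tau`, `p`, `n`) and
#'   `per_condition` (`data.frame`).
#' @export
flux_proteome_correlations <- function(kapp) {
  kt <- data.table::as.data.table(kapp)
  fc <- kendall_correlation(abs(kt$flux_mean), kt$enzyme_conc)
  fk <- kendall_correlation(abs(kt$flux_mean), kt$kapp)
  per <- kt[, {
    a <- kendall_correlation(abs(flux_mean), enzyme_conc)
    b <- kendall_correlation(abs(flux_mean), kapp)
    .(tau_flux_conc = a$tau, p_flux_conc = a$p,
      tau_flux_kapp = b$tau, p_flux_kapp = b$p, n = a$n)
  }, by = condition]
  list(flux_conc = fc, flux_kapp = fk, per_condition = as.data.frame(per))
}
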