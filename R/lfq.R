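# Label-free estimation of proteome-wide absolute concentrations: candidate
# protein-intensity models (TopN, iBAQ, summed peptides) are fitted to the
# SIL-quantified anchors by log-log regression and the best model is chosen
# by bootstrapped cross-validation (cross-validated mean fold error).

#' In silico proteolytic digestion
#'
#' Cleaves C-terminal to lysine or arginine, by default not before proline
#' (trypsin rule), generates peptides with up to `missed_cleavages` internal
#' sites, and filters by length. Peptides are returned N-terminal first.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavages Maximum internal cleavage sites per peptide.
#' @param length_range Inclusive `[min, max]` peptide length filter.
#' @param cut_before_proline If `TRUE`, cleave K/R-P bonds too.
#' @return Character vector of peptides.
#' @export
digest_protein <- function(sequence, missed_cleavages = 0L,
                           length_range = c(1L, 1000L),
                           cut_before_proline = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n]
  if (!cut_before_proline) sites <- sites[aa[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  starts <- head(bounds, -1L) + 1L
  ends <- tail(bounds, -1L)
  n_frag <- length(starts)
  out <- character(0)
  for (i in seq_len(n_frag)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > n_frag) break
      len <- ends[j] - starts[i] + 1L
      if (len >= length_range[1] && len <= length_range[2])
        out <- c(out, substr(sequence, starts[i], ends[j]))
    }
  }
  out
}

#' Count theoretically observable peptides for iBAQ
#'
#' The iBAQ denominator: the number of fully tryptic peptides (no missed
#' cleavages) within the observable length range.
#'
#' @inheritParams digest_protein
#' @return Integer count.
#' @export
count_observable_peptides <- function(sequence, missed_cleavages = 0L,
                                      length_range = c(7L, 30L)) {
  length(digest_protein(sequence, missed_cleavages = missed_cleavages,
                        length_range = length_range))
}

#' Peptide intensity from its fragment ions
#'
#' Sum of the `top_fragments` most intense fragment ion areas (all of them
#' when the peptide has fewer).
#'
#' @param fragment_intensities Numeric vector of fragment ion areas.
#' @param top_fragments How many of the most intense fragments to sum.
#' @return Peptide intensity.
#' @export
peptide_intensity <- function(fragment_intensities, top_fragments = 5L) {
  stopifnot(length(fragment_intensities) > 0, all(fragment_intensities >= 0,
                                                  na.rm = TRUE))
  v <- sort(fragment_intensities[!is.na(fragment_intensities)],
            decreasing = TRUE)
  sum(head(v, top_fragments))
}

#' Protein intensity under a label-free model
#'
#' `topN` sums the N most intense peptides, `iBAQ` divides the summed
#' peptide intensity by the count of theoretically observable peptides, and
#' `all_pep_sum` is the plain sum. At least `min_peptides` distinct
#' quantified peptides are required.
#'
#' @param peptide_intensities Numeric vector, one value per quantified
#'   peptide of the protein in one sample.
#' @param method `"topN"`, `"iBAQ"`, or `"all_pep_sum"`.
#' @param top_n N for `topN`.
#' @param observable_count iBAQ denominator (see
#'   [count_observable_peptides()]).
#' @param min_peptides Minimum quantified peptides required.
#' @return Protein intensity, or `NA` (with a warning suppressed upstream)
#'   when fewer than `min_peptides` peptides are available.
#' @export
protein_intensity <- function(peptide_intensities,
                              method = c("topN", "iBAQ", "all_pep_sum"),
                              top_n = 3L, observable_count = NULL,
                              min_peptides = 2L) {
  method <- match.arg(method)
  v <- peptide_intensities[!is.na(peptide_intensities)]
  if (length(v) < min_peptides) return(NA_real_)
  switch(method,
         topN = sum(head(sort(v, decreasing = TRUE), top_n)),
         iBAQ = {
           if (is.null(observable_count) || is.na(observable_count) ||
               observable_count == 0)
             stop("iBAQ requires a positive observable peptide count")
           sum(v) / observable_count
         },
         all_pep_sum = sum(v))
}

# Expand a model name from the grid ("top1", ..., "iBAQ", "all_pep_sum")
# into a method/top_n pair.
parse_model_spec <- function(model) {
  if (grepl("^top[0-9]+$", model))
    list(method = "topN", top_n = as.integer(sub("^top", "", model)))
  else if (model %in% c("iBAQ", "all_pep_sum"))
    list(method = model, top_n = NA_integer_)
  else stop("unknown label-free model: ", model)
}

#' Protein intensities for all proteins and samples under one model
#'
#' @param features Long fragment table: `protein_id`, `peptide`,
#'   `sample_id`, `fragment_index`, `intensity`.
#' @param model Model name from the grid, e.g. `"top1"`, `"top3"`,
#'   `"iBAQ"`, `"all_pep_sum"`.
#' @param observable_counts Named integer vector (by `protein_id`) of
#'   observable peptide counts; required for iBAQ.
#' @param top_fragments,min_peptides See [peptide_intensity()] and
#'   [protein_intensity()].
#' @return `data.frame`: `protein_id`, `sample_id`, `intensity` (proteins
#'   with too few peptides omitted).
#' @export
build_protein_intensities <- function(features, model,
                                      observable_counts = NULL,
                                      top_fragments = 5L,
                                      min_peptides = 2L) {
  spec <- parse_model_spec(model)
  ft <- data.table::as.data.table(features)
  pep <- ft[!is.na(intensity),
            .(pep_int = peptide_intensity(intensity, top_fragments)),
            by = .(protein_id, peptide, sample_id)]
  prot <- pep[, .(intensity = {
    oc <- if (spec$method == "iBAQ") observable_counts[[protein_id[1]]] else NULL
    protein_intensity(pep_int, method = spec$method, top_n = spec$top_n,
                      observable_count = oc, min_peptides = min_peptides)
  }), by = .(protein_id, sample_id)]
  as.data.frame(prot[!is.na(intensity)])
}

#' Log-log anchor regression
#'
#' Ordinary least squares of log10 concentration on log10 intensity across
#' the anchor proteins; the fitted line converts label-free intensities into
#' absolute concentrations.
#'
#' @param concentration,intensity Paired positive vectors over anchors.
#' @return List with `slope`, `intercept`, `r`, `n`.
#' @export
fit_anchor_regression <- function(concentration, intensity) {
  stopifnot(length(concentration) == length(intensity))
  ok <- is.finite(concentration) & is.finite(intensity) &
    concentration > 0 & intensity > 0
  if (any(!ok)) warning("excluding ", sum(!ok),
                        " anchor(s) with nonpositive or missing values")
  x <- log10(intensity[ok]); y <- log10(concentration[ok])
  if (length(x) < 3L) stop("need at least 3 anchors with positive values")
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  r <- if (sd(y) == 0 || sd(x) == 0) NA_real_ else cor(x, y)
  list(slope = b[2], intercept = b[1], r = r, n = length(x))
}

#' Cross-validated mean fold error by bootstrapping
#'
#' For each bootstrap iteration the anchors are resampled with replacement,
#' the log-log regression refit, and the out-of-bag anchors predicted. Each
#' prediction contributes a fold error `FE = 10^|log10(pred) - log10(obs)|`;
#' the CV-MFE is the mean FE pooled over all out-of-bag predictions of all
#' iterations (geometric-mean aggregation available via `fe_aggregate`).
#' `ci95` is the half-width of the normal-approximation 95% interval of the
#' FE distribution.
#'
#' @param concentration,intensity Anchor pairs (positive).
#' @param n_boot Number of bootstrap iterations.
#' @param seed Random seed (mandatory for reproducibility).
#' @param fe_aggregate `"arithmetic"` or `"geometric"` mean of fold errors.
#' @return List with `cv_mfe`, `ci95`, `n_boot`, `n_oob`, and the pooled
#'   fold errors `fe`.
#' @export
cv_mfe_bootstrap <- function(concentration, intensity, n_boot = 100L,
                             seed = 1L, fe_aggregate = "arithmetic") {
  stopifnot(n_boot >= 1L, length(concentration) == length(intensity))
  ok <- is.finite(concentration) & is.finite(intensity) &
    concentration > 0 & intensity > 0
  conc <- concentration[ok]; int <- intensity[ok]
  n <- length(conc)
  if (n < 3L) stop("need at least 3 anchors")
  set.seed(seed)
  fe <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(unique(int[idx])) >= 3L && length(oob) > 0L) break
      if (try == 100) stop("could not draw a usable bootstrap sample")
    }
    fit <- lm(log10(conc[idx]) ~ log10(int[idx]))
    bcf <- unname(coef(fit))
    pred <- bcf[1] + bcf[2] * log10(int[oob])
    fe[[b]] <- 10^abs(pred - log10(conc[oob]))
  }
  fe <- unlist(fe)
  cv_mfe <- if (identical(fe_aggregate, "geometric")) exp(mean(log(fe)))
            else mean(fe)
  list(cv_mfe = cv_mfe, ci95 = qnorm(0.975) * sd(fe), n_boot = n_boot,
       n_oob = length(fe), fe = fe)
}

#' Select the label-free model with the smallest CV-MFE
#'
#' Builds protein intensities under every model of the grid, fits the anchor
#' regression, scores each model by [cv_mfe_bootstrap()], and returns the
#' fits sorted by CV-MFE (best first). Calibration is per sample, as
#' intensity scales differ between runs.
#'
#' @param features Fragment table (see [build_protein_intensities()]).
#' @param anchor_conc `data.frame` with `protein_id`, `sample_id`, `conc`
#'   (SIL-derived anchor concentrations, nmol/gDCW).
#' @param sample_id Sample to calibrate.
#' @param observable_counts Named vector for iBAQ.
#' @param config [pipeline_config()] list (`model_grid`, `n_boot`, `seed`,
#'   `top_fragments`, `min_peptides`, `fe_aggregate`).
#' @return List with `fits` (`data.frame`: `model`, `slope`, `intercept`,
#'   `r`, `cv_mfe`, `ci95`, `n_anchors`), `best` (model name), and
#'   `intensities` (protein intensities under the best model).
#' @export
select_lfq_model <- function(features, anchor_conc, sample_id,
                             observable_counts = NULL,
                             config = pipeline_config()) {
  sid <- sample_id
  ac <- data.table::as.data.table(anchor_conc)[sample_id == sid]
  if (nrow(ac) < 3L) stop("need at least 3 anchors for sample ", sid)
  rows <- list(); best_int <- NULL
  for (model in config$model_grid) {
    pi_all <- build_protein_intensities(
      features[features$sample_id == sid, ], model,
      observable_counts = observable_counts,
      top_fragments = config$top_fragments,
      min_peptides = config$min_peptides)
    m <- merge(ac, pi_all, by = c("protein_id", "sample_id"))
    if (nrow(m) < 3L) next
    reg <- fit_anchor_regression(m$conc, m$intensity)
    bt <- cv_mfe_bootstrap(m$conc, m$intensity, n_boot = config$n_boot,
                           seed = config$seed,
                           fe_aggregate = config$fe_aggregate)
    rows[[model]] <- data.frame(
      model = model, slope = reg$slope, intercept = reg$intercept,
      r = reg$r, cv_mfe = bt$cv_mfe, ci95 = bt$ci95, n_anchors = reg$n,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no label-free model could be fit for sample ",
                              sid)
  fits <- do.call(rbind, rows)
  fits <- fits[order(fits$cv_mfe), ]
  rownames(fits) <- NULL
  best <- fits$model[1]
  intensities <- build_protein_intensities(
    features[features$sample_id == sid, ], best,
    observable_counts = observable_counts,
    top_fragments = config$top_fragments,
    min_peptides = config$min_peptides)
  list(fits = fits, best = best, intensities = intensities)
}

#' Estimate proteome-wide concentrations from a fitted model
#'
#' Applies `conc = 10^(intercept + slope * log10(intensity))` to every
#' protein intensity. Anchors can optionally be reported with their
#' SIL-derived values instead of label-free estimates.
#'
#' @param fit List or one-row `data.frame` with `slope` and `intercept`.
#' @param intensities `data.frame` with `protein_id`, `sample_id`,
#'   `intensity`.
#' @param anchor_conc Optional SIL anchor concentrations (`protein_id`,
#'   `sample_id`, `conc`) substituted for the label-free estimate when
#'   `report_anchor_sil` is `TRUE`.
#' @param report_anchor_sil Report anchors at their SIL values.
#' @return `data.frame`: `protein_id`, `sample_id`, `conc` (nmol/gDCW),
#'   `source` (`"label-free"` or `"SIL"`).
#' @export
estimate_proteome <- function(fit, intensities, anchor_conc = NULL,
                              report_anchor_sil = TRUE) {
  x <- data.table::as.data.table(intensities)
  x <- x[!is.na(intensity) & intensity > 0]
  x[, conc := 10^(fit$intercept + fit$slope * log10(intensity))]
  x[, source := "label-free"]
  out <- x[, .(protein_id, sample_id, conc, source)]
  if (report_anchor_sil && !is.null(anchor_conc) && nrow(anchor_conc) > 0) {
    ac <- data.table::as.data.table(anchor_conc)[
      , .(protein_id, sample_id, sil_conc = conc)]
    out <- ac[out, on = c("protein_id", "sample_id")]
    out[!is.na(sil_conc), `:=`(conc = sil_conc, source = "SIL")]
    out[, sil_conc := NULL]
  }
  as.data.frame(out)
}

#' Total proteome mass per sample
#'
#' Sum of concentration times molecular weight over quantified proteins, in
#' grams of protein per gram dry cell weight; optionally also expressed as
#' the microgram equivalent of a loaded peptide amount.
#'
#' @param concentrations `data.frame`: `protein_id`, `sample_id`, `conc`
#'   (nmol/gDCW).
#' @param sequences `data.frame` with `protein_id` and `molecular_weight`
#'   (g/mol).
#' @param biomass Optional `data.frame` with `sample_id`, `gdcw`; when
#'   given, `mass_ug` is the mass equivalent of the aliquot.
#' @return `data.frame`: `sample_id`, `mass_g_per_gdcw`, `n_proteins`, and
#'   `mass_ug` when `biomass` is supplied.
#' @export
total_proteome_mass <- function(concentrations, sequences, biomass = NULL) {
  cc <- data.table::as.data.table(concentrations)
  sq <- data.table::as.data.table(sequences)[, .(protein_id,
                                                 molecular_weight)]
  x <- sq[cc, on = "protein_id"]
  n_missing <- sum(is.na(x$molecular_weight))
  if (n_missing > 0)
    warning(n_missing, " protein(s) without molecular weight excluded ",
            "from the mass sum")
  x <- x[!is.na(molecular_weight)]
  out <- x[, .(mass_g_per_gdcw = sum(conc * molecular_weight) * 1e-9,
               n_proteins = .N), by = sample_id]
  if (!is.null(biomass)) {
    bio <- data.table::as.data.table(biomass)
    out <- bio[out, on = "sample_id"]
    out[, mass_ug := mass_g_per_gdcw * gdcw * 1e6]
    out[, gdcw := NULL]
  }
  as.data.frame(out)
}
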