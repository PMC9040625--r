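# Synthetic-data generator with known ground truth. Emulates the study
# design the pipeline targets: steady-state chemostat cultures under three
# gas mixtures with four biological replicates, a set of SIL anchor
# proteins spanning three orders of magnitude of concentration, DIA-like
# peptide intensities with peptide-specific response factors and lognormal
# noise, a 10-point 2-fold spike-in dilution series with an additive
# background that breaks linearity at low spike levels, and replicate flux
# plus relative enzyme-expression tables with planted regulation scenarios.

AA_FREQ <- c(
  A = 0.089, R = 0.042, N = 0.043, D = 0.058, C = 0.011, E = 0.072,
  Q = 0.035, G = 0.072, H = 0.018, I = 0.076, L = 0.096, K = 0.078,
  M = 0.027, F = 0.043, P = 0.037, S = 0.055, T = 0.053, W = 0.009,
  Y = 0.035, V = 0.066)

#' Generate a ground-truth proteome
#'
#' Draws log-uniform true concentrations spanning `conc_range`, random
#' protein sequences (digestible by the label-free module), a
#' concentration-stratified anchor subset (every concentration decade
#' contains at least one anchor), fixed peptide response factors, and fixed
#' per-peptide fragment profiles. Per-condition true concentrations deviate
#' from the base by a lognormal condition effect. Fully deterministic under
#' `seed`.
#'
#' @param n_proteins Number of proteins.
#' @param conc_range Concentration range in nmol/gDCW (log-uniform).
#' @param n_anchors Number of anchor proteins.
#' @param conditions Condition labels.
#' @param n_replicates Biological replicates per condition.
#' @param n_peptides_mean Mean number of measured peptides per protein.
#' @param sigma_condition Log10 sd of the per-condition concentration
#'   effect.
#' @param sigma_peptide Log10 sd of peptide response factors ("flyability").
#' @param n_fragments Fragment ions per peptide (with the default 6, the
#'   top-5 fragment sum covers most but not all of a peptide's signal, as
#'   in real DIA data).
#' @param length_range Protein sequence length range.
#' @param total_mass_g When not `NULL`, rescale concentrations so the
#'   condition-average proteome mass equals this many g/gDCW.
#' @param seed Random seed.
#' @return Object of class `anchorlfq_truth`: list with `proteins`
#'   (`protein_id`, `sequence`, `molecular_weight`, `is_anchor`,
#'   `base_conc`), `concentrations` (`protein_id`, `condition`, `conc`),
#'   `peptides` (`protein_id`, `peptide`, `phi`), `fragment_profiles`
#'   (`peptide`, `fragment_index`, `weight`), `conditions`,
#'   `n_replicates`, `gdcw`, `seed`.
#' @export
generate_ground_truth <- function(n_proteins = 1000L,
                                  conc_range = c(0.1, 1000),
                                  n_anchors = 16L,
                                  conditions = c("CO", "syngas", "highH2CO"),
                                  n_replicates = 4L,
                                  n_peptides_mean = 6,
                                  sigma_condition = 0.1,
                                  sigma_peptide = 0.4,
                                  n_fragments = 6L,
                                  length_range = c(100L, 800L),
                                  total_mass_g = NULL,
                                  seed = 1L) {
  if (n_anchors > n_proteins) stop("invalid config: n_anchors > n_proteins")
  if (any(conc_range <= 0) || conc_range[2] <= conc_range[1])
    stop("invalid config: conc_range must be positive and increasing")
  set.seed(seed)
  ids <- sprintf("PROT%04d", seq_len(n_proteins))
  base_conc <- 10^runif(n_proteins, log10(conc_range[1]),
                        log10(conc_range[2]))
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  sequences <- vapply(lens, function(L)
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = ""), character(1))
  mw <- vapply(sequences, protein_mw, numeric(1), USE.NAMES = FALSE)

  if (!is.null(total_mass_g)) {
    base_conc <- base_conc * total_mass_g / (sum(base_conc * mw) * 1e-9)
  }

  # stratified anchor draw: at least one anchor per concentration decade
  decade <- floor(log10(base_conc))
  anchors <- integer(0)
  for (d in unique(decade)) {
    pool <- which(decade == d)
    anchors <- c(anchors, pool[sample.int(length(pool), 1L)])
  }
  remaining <- setdiff(seq_len(n_proteins), anchors)
  extra <- n_anchors - length(anchors)
  if (extra > 0)
    anchors <- c(anchors, sample(remaining, extra))
  anchors <- sort(anchors[seq_len(min(n_anchors, length(anchors)))])

  proteins <- data.frame(protein_id = ids, sequence = sequences,
                         molecular_weight = mw,
                         is_anchor = seq_len(n_proteins) %in% anchors,
                         base_conc = base_conc, stringsAsFactors = FALSE)

  conc <- data.table::CJ(protein_id = ids, condition = conditions,
                         sorted = FALSE)
  conc[, conc := base_conc[match(protein_id, ids)] *
         10^rnorm(.N, 0, sigma_condition)]

  # measured peptide set per protein: a draw from its tryptic digest
  pep_rows <- lapply(seq_len(n_proteins), function(i) {
    peps <- unique(digest_protein(sequences[i], missed_cleavages = 0L,
                                  length_range = c(7L, 25L)))
    if (length(peps) < 2L) return(NULL)
    k <- min(length(peps), max(2L, rpois(1L, n_peptides_mean)))
    data.frame(protein_id = ids[i],
               peptide = sample(peps, k), stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, pep_rows)
  peptides$phi <- 10^rnorm(nrow(peptides), 0, sigma_peptide)

  n_frag <- as.integer(n_fragments)
  fw <- matrix(rexp(nrow(peptides) * n_frag), ncol = n_frag)
  fw <- fw / rowSums(fw)
  fragment_profiles <- data.frame(
    peptide = rep(peptides$peptide, each = n_frag),
    protein_id = rep(peptides$protein_id, each = n_frag),
    fragment_index = rep(seq_len(n_frag), nrow(peptides)),
    weight = as.vector(t(fw)), stringsAsFactors = FALSE)

  structure(list(proteins = proteins,
                 concentrations = as.data.frame(conc),
                 peptides = peptides,
                 fragment_profiles = fragment_profiles,
                 conditions = conditions, n_replicates = n_replicates,
                 gdcw = 1e-4, seed = seed),
            class = "anchorlfq_truth")
}

#' Default DIA simulation design
#'
#' Noise parameters of the intensity model. `sigma_noise` (log10) is set so
#' the CV of a light/heavy ratio, `sqrt(2) * sigma_noise * ln(10)`, is about
#' 22% — the inter-peptide variability reported for DIA anchor
#' quantification; `sigma_bio` is set so replicate-level protein
#' concentrations (averaging the ratio noise over roughly six peptides) have
#' a CV of about 11%.
#'
#' @param ... Named overrides.
#' @return List of design parameters.
#' @export
dia_design <- function(...) {
  d <- list(sigma_noise = 0.068,   # log10; peptide-level measurement noise
            sigma_bio = 0.028,     # log10; biological replicate variation
            sigma_sample = 0.05,   # log10; per-sample global intensity factor
            response_per_nmol = 1e12,
            detection_floor = 1e6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(d))
  if (length(unknown) > 0)
    stop("unknown design parameter(s): ", paste(unknown, collapse = ", "))
  d[names(dots)] <- dots
  d
}

#' Simulate DIA-like peptide intensities
#'
#' Light peptide intensity is `conc * gdcw * response * phi_p * kappa_s *
#' eps` with the peptide response factor `phi_p` fixed per peptide, a
#' per-sample factor `kappa_s`, and lognormal measurement noise `eps`.
#' Heavy intensities of anchor peptides derive from the spiked SIL amounts
#' with the same peptide response factor and independent noise. Fragment
#' intensities split each peptide's light intensity by its fixed fragment
#' profile. Intensities below the detection floor are censored to missing.
#'
#' @param truth [generate_ground_truth()] object.
#' @param design [dia_design()] list.
#' @param seed Random seed.
#' @return List with `measurements` (anchor light/heavy table), `features`
#'   (proteome-wide fragment table), `samples`, `spikes`, `biomass`.
#' @export
simulate_dia_intensities <- function(truth, design = dia_design(),
                                     seed = truth$seed + 1L) {
  set.seed(seed)
  samples <- data.table::CJ(condition = truth$conditions,
                            replicate = seq_len(truth$n_replicates),
                            sorted = FALSE)
  samples[, sample_id := paste0(condition, "_r", replicate)]
  samples[, kappa := 10^rnorm(.N, 0, design$sigma_sample)]

  anchors <- truth$proteins$protein_id[truth$proteins$is_anchor]
  spikes <- data.table::CJ(protein_id = anchors,
                           sample_id = samples$sample_id, sorted = FALSE)
  spikes[, amount := truth$proteins$base_conc[
    match(protein_id, truth$proteins$protein_id)] * truth$gdcw]

  pep <- data.table::as.data.table(truth$peptides)
  conc <- data.table::as.data.table(truth$concentrations)
  smp <- samples[, .(sample_id, condition, replicate, kappa)]
  grid <- pep[, .(protein_id, peptide, phi)][
    , data.table::copy(smp), by = .(protein_id, peptide, phi)]
  grid <- conc[grid, on = c("protein_id", "condition")]
  # biological replicate effect, shared by all peptides of a protein
  bio <- grid[, .(protein_id, sample_id)]
  bio <- unique(bio)
  bio[, bio_eff := 10^rnorm(.N, 0, design$sigma_bio)]
  grid <- bio[grid, on = c("protein_id", "sample_id")]
  grid[, conc_rep := conc * bio_eff]
  grid[, light := conc_rep * truth$gdcw * design$response_per_nmol *
         phi * kappa * 10^rnorm(.N, 0, design$sigma_noise)]

  # heavy channel for anchor peptides from spiked SIL amounts
  grid <- spikes[grid, on = c("protein_id", "sample_id")]
  grid[, heavy := ifelse(is.na(amount), NA_real_,
                         amount * design$response_per_nmol * phi * kappa *
                           10^rnorm(.N, 0, design$sigma_noise))]
  grid[light < design$detection_floor, light := NA_real_]
  grid[!is.na(heavy) & heavy < design$detection_floor, heavy := NA_real_]

  measurements <- grid[!is.na(amount),
                       .(protein_id, peptide, precursor_charge = 2L,
                         sample_id, condition, replicate,
                         light_intensity = light, heavy_intensity = heavy)]

  fp <- data.table::as.data.table(truth$fragment_profiles)
  features <- fp[grid[!is.na(light),
                      .(protein_id, peptide, sample_id, light)],
                 on = c("protein_id", "peptide"), allow.cartesian = TRUE]
  features[, intensity := light * weight]
  features[intensity < design$detection_floor / 10, intensity := NA_real_]
  features <- features[, .(protein_id, peptide, sample_id, fragment_index,
                           intensity)]

  list(measurements = as.data.frame(measurements),
       features = as.data.frame(features),
       samples = as.data.frame(samples[, .(sample_id, condition, replicate)]),
       spikes = as.data.frame(spikes),
       biomass = data.frame(sample_id = samples$sample_id,
                            gdcw = truth$gdcw, stringsAsFactors = FALSE))
}

#' Simulate a spike-in dilution series
#'
#' Heavy spike amounts start at twice the endogenous level (level 0, DS01)
#' and halve per level over `n_levels` samples; the light (lysate
#' background) channel is constant. An additive instrument background on
#' both channels makes the measured light/heavy ratio deviate from
#' linearity once the heavy signal approaches the background, which is the
#' mechanism generating a lower limit of quantification. The planted LLOQ
#' level per peptide is the calibration outcome on the noise-free curve.
#'
#' @param truth [generate_ground_truth()] object.
#' @param design [dia_design()] list.
#' @param n_levels Number of dilution levels (level 0 highest spike).
#' @param background Additive background intensity on both channels.
#' @param sigma_noise Log10 measurement noise. The series is a single
#'   technical injection sequence, so its scatter is technical only and far
#'   smaller than between-sample noise.
#' @param seed Random seed.
#' @return List with `dilution` (`protein_id`, `peptide`,
#'   `precursor_charge`, `level`, `expected_ratio`, `light_intensity`,
#'   `heavy_intensity`) and `planted` (`peptide`, `planted_lloq_level`).
#' @export
simulate_dilution_series <- function(truth, design = dia_design(),
                                     n_levels = 10L, background = 2e4,
                                     sigma_noise = 0.01,
                                     seed = truth$seed + 2L) {
  set.seed(seed)
  pep <- data.table::as.data.table(truth$peptides)
  anchors <- truth$proteins$protein_id[truth$proteins$is_anchor]
  pep <- pep[protein_id %in% anchors]
  base <- truth$proteins$base_conc[match(pep$protein_id,
                                         truth$proteins$protein_id)]
  resp <- truth$gdcw * design$response_per_nmol
  light0 <- base * resp * pep$phi          # constant lysate background
  heavy0 <- 2 * base * resp * pep$phi      # DS01: twice endogenous

  rows <- vector("list", n_levels)
  for (k in seq_len(n_levels) - 1L) {
    eps_l <- 10^rnorm(nrow(pep), 0, sigma_noise)
    eps_h <- 10^rnorm(nrow(pep), 0, sigma_noise)
    rows[[k + 1L]] <- data.table::data.table(
      protein_id = pep$protein_id, peptide = pep$peptide,
      precursor_charge = 2L, level = k, expected_ratio = 2^k,
      light_intensity = light0 * eps_l + background,
      heavy_intensity = heavy0 / 2^k * eps_h + background)
  }
  dilution <- data.table::rbindlist(rows)

  # planted LLOQ: the calibration outcome on the noise-free curve. A
  # peptide whose noise-free fit sits within noise reach of a pass
  # criterion (margins of two standard errors under sigma_noise) has no
  # stable truth level and is recorded as indeterminate (NA).
  se_ratio <- sqrt(2) * sigma_noise * log2(10)
  slope_margin <- 2 * se_ratio / sqrt(30)      # Sxx >= 30 for usable fits
  int_margin <- 2 * se_ratio * 0.6             # sqrt(1/n + xbar^2/Sxx)
  planted <- vapply(seq_len(nrow(pep)), function(i) {
    nf <- data.frame(level = seq_len(n_levels) - 1L,
                     light_intensity = light0[i] + background,
                     heavy_intensity = heavy0[i] / 2^(seq_len(n_levels) - 1L) +
                       background)
    fit <- fit_dilution_series(nf)
    tight <- fit_dilution_series(
      nf, slope_range = c(0.95 + slope_margin, 1.05 - slope_margin),
      intercept_range = c(-0.1 + int_margin, 0.1 - int_margin))
    loose <- fit_dilution_series(
      nf, slope_range = c(0.95 - slope_margin, 1.05 + slope_margin),
      intercept_range = c(-0.1 - int_margin, 0.1 + int_margin))
    stable <- isTRUE(fit$pass) && isTRUE(tight$pass) &&
      isTRUE(loose$pass) && fit$lloq_level == tight$lloq_level &&
      fit$lloq_level == loose$lloq_level
    if (stable) fit$lloq_level else NA_integer_
  }, integer(1))

  list(dilution = as.data.frame(dilution),
       planted = data.frame(protein_id = pep$protein_id,
                            peptide = pep$peptide,
                            planted_lloq_level = planted,
                            stringsAsFactors = FALSE))
}

#' Simulate flux and enzyme-expression tables with planted regulation
#'
#' Each reaction is assigned one enzyme and a scenario: `null` (no flux
#' change between conditions), `translational` (the flux changes and the
#' enzyme expression follows with the same fold change), or
#' `posttranslational` (the flux changes while expression stays flat).
#' Changed reactions get the fold change `flux_fc` in the second condition.
#' Replicate fluxes are normal with a fixed relative spread; expression
#' replicates are lognormal. Planted apparent catalytic rates increase with
#' flux (high-flux reactions get both more enzyme and faster enzymes), and
#' enzyme concentrations are derived from them, so the flux-concentration
#' and flux-k_app rank correlations of real metabolism are reproduced. A
#' high-flux reference (carbon fixation) reaction anchors the flux filter.
#'
#' @param truth [generate_ground_truth()] object (supplies condition labels
#'   and protein ids).
#' @param n_null,n_translational,n_posttranslational Scenario counts.
#' @param flux_fc Fold change planted in changed reactions.
#' @param rep_cv Relative replicate spread of fluxes and expression.
#' @param seed Random seed.
#' @return List with `fluxes`, `expression`, `gpr`, `concentrations`
#'   (condition-level `protein_id`, `condition`, `mean`, `sd`), `truth`
#'   (`reaction_id`, `scenario`, `kapp_true` per condition), and
#'   `reference_reaction`.
#' @export
simulate_fluxes_and_expression <- function(truth,
                                           n_null = 20L,
                                           n_translational = 2L,
                                           n_posttranslational = 18L,
                                           flux_fc = 3,
                                           rep_cv = 0.1,
                                           seed = truth$seed + 3L) {
  set.seed(seed)
  conditions <- truth$conditions
  n_rep <- truth$n_replicates
  scen <- c(rep("null", n_null), rep("translational", n_translational),
            rep("posttranslational", n_posttranslational))
  # small proteomes carry proportionally fewer reactions (one distinct
  # enzyme per reaction plus the reference)
  avail <- nrow(truth$proteins) - 1L
  if (length(scen) > avail)
    scen <- scen[sort(sample.int(length(scen), avail))]
  scen <- sample(scen)
  n_rxn <- length(scen)
  rxn <- sprintf("rxn%03d", seq_len(n_rxn))
  prot <- sample(truth$proteins$protein_id, n_rxn + 1L)
  base_flux <- 10^runif(n_rxn, log10(0.05), log10(5))

  flux_mean <- matrix(base_flux, n_rxn, length(conditions))
  expr_mean <- matrix(1000, n_rxn, length(conditions))
  changed <- scen != "null"
  flux_mean[changed, 2] <- base_flux[changed] * flux_fc
  expr_mean[scen == "translational", 2] <- 1000 * flux_fc

  # planted k_app grows with flux so concentration and rate both track flux
  kapp_true <- 3 * (flux_mean / 0.5)^0.5 * 10^rnorm(n_rxn, 0, 0.25)
  conc_mean <- flux_mean * 1e6 / (kapp_true * 3600)

  ref <- "rxn_co_fix"
  rows_f <- list(); rows_e <- list()
  for (i in seq_len(n_rxn)) {
    for (j in seq_along(conditions)) {
      rows_f[[length(rows_f) + 1L]] <- data.table::data.table(
        reaction_id = rxn[i], condition = conditions[j],
        replicate = seq_len(n_rep),
        value = rnorm(n_rep, flux_mean[i, j], rep_cv * flux_mean[i, j]))
      rows_e[[length(rows_e) + 1L]] <- data.table::data.table(
        reaction_id = rxn[i], condition = conditions[j],
        replicate = seq_len(n_rep),
        relative_intensity = expr_mean[i, j] *
          10^rnorm(n_rep, 0, rep_cv / log(10)))
    }
  }
  for (j in seq_along(conditions))
    rows_f[[length(rows_f) + 1L]] <- data.table::data.table(
      reaction_id = ref, condition = conditions[j],
      replicate = seq_len(n_rep), value = rnorm(n_rep, 10, rep_cv * 10))
  fluxes <- as.data.frame(data.table::rbindlist(rows_f))
  expression <- as.data.frame(data.table::rbindlist(rows_e))

  gpr <- data.frame(reaction_id = c(rxn, ref),
                    alternative_index = 1L,
                    protein_id = prot,
                    membrane_flag = FALSE, stringsAsFactors = FALSE)
  conc_rows <- list()
  for (i in seq_len(n_rxn))
    conc_rows[[i]] <- data.table::data.table(
      protein_id = prot[i], condition = conditions,
      mean = conc_mean[i, ], sd = rep_cv * conc_mean[i, ])
  # the reference reaction's enzyme, scaled like the others
  conc_rows[[n_rxn + 1L]] <- data.table::data.table(
    protein_id = prot[n_rxn + 1L], condition = conditions,
    mean = 10 * 1e6 / (3 * (10 / 0.5)^0.5 * 3600), sd = 0)
  concentrations <- as.data.frame(data.table::rbindlist(conc_rows))

  truth_tab <- data.frame(reaction_id = rxn, scenario = scen,
                          stringsAsFactors = FALSE)
  for (j in seq_along(conditions))
    truth_tab[[paste0("kapp_", conditions[j])]] <- kapp_true[, j]

  list(fluxes = fluxes, expression = expression, gpr = gpr,
       concentrations = concentrations, truth = truth_tab,
       reference_reaction = ref)
}
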