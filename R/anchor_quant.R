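# Anchor protein quantification from light/heavy peptide ratios against
# SIL-protein spike-in standards, with dilution-series calibration of the
# linear range and LLOQ, and stringent peptide-level filtering.

#' Quantify a SIL-protein stock from its quantification tag
#'
#' SIL-protein stocks carry an N-terminal quantification tag; the stock
#' concentration follows from the heavy/light intensity ratio of the tag
#' peptide against a known amount of unlabeled reference (Aqua) peptide
#' spiked into the digested aliquot.
#'
#' @param heavy_tag_intensity MS intensity of the heavy (SIL-protein) tag.
#' @param light_tag_intensity MS intensity of the light (Aqua reference) tag.
#' @param aqua_amount_pmol Amount of reference peptide spiked in (pmol).
#' @param aliquot_volume_ul Volume of stock digested (microliters).
#' @return Stock concentration in pmol per microliter.
#' @export
quantify_sil_stock <- function(heavy_tag_intensity, light_tag_intensity,
                               aqua_amount_pmol = 2, aliquot_volume_ul = 4) {
  if (is.na(light_tag_intensity) || light_tag_intensity <= 0)
    stop("no reference signal: light tag intensity missing or zero")
  stopifnot(heavy_tag_intensity >= 0, aqua_amount_pmol > 0,
            aliquot_volume_ul > 0)
  (heavy_tag_intensity / light_tag_intensity) * aqua_amount_pmol /
    aliquot_volume_ul
}

#' Fit the dilution-series calibration for one peptide
#'
#' A spike-in dilution series (level 0 = highest heavy spike, halving per
#' level) validates the linear quantification range of each peptide. The
#' measured light/heavy ratio, expressed in doublings relative to the
#' highest-spike sample (DS01), is regressed on the expected number of
#' doublings: a perfectly linear peptide has slope 1 and intercept 0 in this
#' space. Points are used only when both intensities are present. While the
#' acceptance criteria (`r2 > r2_min`, slope and intercept within their
#' bands, at least `min_points` points) are not met, the lowest-spike
#' (highest-level) point is dropped and the model refit. The heavy intensity
#' at the lowest retained level is the smallest signal inside the validated
#' linear range and serves as the peptide's LLOQ intensity for both
#' channels (the light channel is roughly constant across the series, so it
#' carries no quantification floor of its own).
#'
#' @param points `data.frame` with columns `level` (integer, 0 = highest
#'   spike), `light_intensity`, `heavy_intensity`; one peptide.
#' @param r2_min,slope_range,intercept_range,min_points Acceptance criteria
#'   for the linear range (defaults are the standard stringent values).
#' @return One-row `data.frame`: `r2`, `slope`, `intercept`, `lloq`
#'   (intensity floor), `lloq_level`, `n_points_used`, `pass`, `reason`.
#' @export
fit_dilution_series <- function(points, r2_min = 0.95,
                                slope_range = c(0.95, 1.05),
                                intercept_range = c(-0.1, 0.1),
                                min_points = 3L) {
  fail <- function(reason) {
    data.frame(r2 = NA_real_, slope = NA_real_, intercept = NA_real_,
               lloq = NA_real_, lloq_level = NA_integer_,
               n_points_used = 0L, pass = FALSE, reason = reason,
               stringsAsFactors = FALSE)
  }
  pts <- points[!is.na(points$light_intensity) &
                  !is.na(points$heavy_intensity) &
                  points$light_intensity > 0 & points$heavy_intensity > 0, ]
  pts <- pts[order(pts$level), ]
  if (nrow(pts) < min_points) return(fail("fewer than min_points usable points"))
  if (pts$level[1] != 0L) return(fail("no usable measurement at level 0"))

  ratio <- pts$light_intensity / pts$heavy_intensity
  # doublings of the measured ratio relative to DS01, against expected level
  y <- log2(ratio / ratio[1])
  x <- as.numeric(pts$level)

  keep <- seq_len(nrow(pts))
  repeat {
    fit <- lm(y[keep] ~ x[keep])
    b <- unname(coef(fit))
    sst <- sum((y[keep] - mean(y[keep]))^2)
    r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
    ok <- is.finite(r2) && r2 > r2_min &&
      b[2] > slope_range[1] && b[2] < slope_range[2] &&
      b[1] > intercept_range[1] && b[1] < intercept_range[2]
    if (ok || length(keep) - 1L < min_points) break
    keep <- keep[-length(keep)]
  }
  low <- keep[length(keep)]
  data.frame(r2 = r2, slope = b[2], intercept = b[1],
             lloq = pts$heavy_intensity[low],
             lloq_level = as.integer(pts$level[low]),
             n_points_used = length(keep),
             pass = ok, reason = if (ok) "" else "criteria not met",
             stringsAsFactors = FALSE)
}

#' Calibrate all peptides of a dilution-series table
#'
#' Applies [fit_dilution_series()] per peptide.
#'
#' @param dilution `data.frame` with columns `peptide`, `level`,
#'   `light_intensity`, `heavy_intensity` (optionally `protein_id`,
#'   `precursor_charge`).
#' @param config [pipeline_config()] list.
#' @return `data.frame` of calibrations, one row per peptide.
#' @export
calibrate_dilution_series <- function(dilution, config = pipeline_config()) {
  dt <- data.table::as.data.table(dilution)
  out <- dt[, fit_dilution_series(.SD, r2_min = config$r2_min,
                                  slope_range = config$slope_range,
                                  intercept_range = config$intercept_range,
                                  min_points = config$min_points),
            by = peptide]
  as.data.frame(out)
}

#' Filter anchor peptides with the stringent quantification rules
#'
#' Applies, in order: (1) per peptide, keep only the precursor charge with
#' the highest heavy intensity in the highest-spike dilution sample (DS01;
#' ties broken by lower charge); (2) remove peptides quantified in fewer
#' than `min_replicates` biological replicates within any condition;
#' (3) remove peptides without a heavy DS01 signal; (4) remove peptides
#' without heavy signals for at least `min_points` consecutive dilution
#' levels starting at level 0; (5) remove peptides failing the
#' dilution-series calibration; (6) mask individual sample measurements
#' whose light or heavy signal is below the peptide's LLOQ; (7) re-apply the
#' replicate-presence rule to the masked data (at least `min_replicates`
#' L/H ratios per condition); (8) remove outlier peptides whose light/heavy
#' ratio deviates from the all-peptide mean ratio of the protein by more
#' than `outlier_pct_max` percent on average, either across all samples or
#' within any condition's replicates. Every removal and mask is logged with
#' its rule identifier.
#'
#' @param measurements Peptide measurement `data.frame`: `protein_id`,
#'   `peptide`, `precursor_charge`, `sample_id`, `condition`, `replicate`,
#'   `light_intensity`, `heavy_intensity`.
#' @param dilution Dilution-series `data.frame` as in
#'   [calibrate_dilution_series()] (with `precursor_charge` if precursors
#'   must be resolved).
#' @param calibrations Output of [calibrate_dilution_series()]; computed
#'   from `dilution` when `NULL`.
#' @param config [pipeline_config()] list.
#' @return List with `measurements` (retained, masked rows dropped),
#'   `removal_log` (`data.frame` of `rule`, `peptide`, `detail`), and
#'   `calibrations`.
#' @export
filter_anchor_peptides <- function(measurements, dilution,
                                   calibrations = NULL,
                                   config = pipeline_config()) {
  meas <- data.table::as.data.table(measurements)
  dil <- data.table::as.data.table(dilution)
  log_entries <- list()
  note <- function(rule, peptide, detail) {
    log_entries[[length(log_entries) + 1L]] <<-
      data.table::data.table(rule = rule, peptide = peptide, detail = detail)
  }

  # rule 1: one precursor per peptide, highest heavy at DS01
  if ("precursor_charge" %in% names(dil) &&
      length(unique(meas$precursor_charge)) > 1L) {
    ds01 <- dil[level == 0L & !is.na(heavy_intensity)]
    best <- ds01[order(-heavy_intensity, precursor_charge, peptide),
                 .SD[1L], by = peptide][, .(peptide, precursor_charge)]
    dropped <- meas[!best, on = c("peptide", "precursor_charge")]
    if (nrow(dropped) > 0)
      for (p in unique(dropped$peptide))
        note("rule1_precursor", p, "lower-heavy precursor removed")
    meas <- meas[best, on = c("peptide", "precursor_charge"), nomatch = NULL]
    dil <- dil[best, on = c("peptide", "precursor_charge"), nomatch = NULL]
  }

  quantified <- !is.na(meas$light_intensity) & !is.na(meas$heavy_intensity) &
    meas$light_intensity > 0 & meas$heavy_intensity > 0
  meas <- meas[quantified]

  # rule 2: >= min_replicates quantified bioreplicates in every condition
  conditions <- unique(meas$condition)
  reps <- meas[, .(n = data.table::uniqueN(replicate)),
               by = .(peptide, condition)]
  reps <- reps[n >= config$min_replicates]
  ok2 <- reps[, .(n_cond = .N), by = peptide][n_cond == length(conditions),
                                              peptide]
  for (p in setdiff(unique(meas$peptide), ok2))
    note("rule2_replicates", p, "quantified in < min replicates in a condition")
  meas <- meas[peptide %in% ok2]

  # rule 3: heavy signal at DS01
  ds01_ok <- dil[level == 0L & !is.na(heavy_intensity) & heavy_intensity > 0,
                 unique(peptide)]
  for (p in setdiff(unique(meas$peptide), ds01_ok))
    note("rule3_ds01_heavy", p, "no heavy signal at DS01")
  meas <- meas[peptide %in% ds01_ok]

  # rule 4: >= min_points consecutive dilution levels with heavy signal,
  # starting at level 0
  runlen <- dil[!is.na(heavy_intensity) & heavy_intensity > 0,
                .(run = {
                  lv <- sort(unique(level))
                  # length of the consecutive prefix 0, 1, 2, ...
                  pre <- lv == seq_along(lv) - 1L
                  if (!pre[1]) 0L else match(FALSE, pre,
                                             nomatch = length(lv) + 1L) - 1L
                }), by = peptide]
  ok4 <- runlen[run >= config$min_points, peptide]
  for (p in setdiff(unique(meas$peptide), ok4))
    note("rule4_continuous_series", p,
         "< min consecutive dilution levels with heavy signal")
  meas <- meas[peptide %in% ok4]

  # rule 5: dilution calibration must pass
  if (is.null(calibrations))
    calibrations <- calibrate_dilution_series(dil, config)
  cal <- data.table::as.data.table(calibrations)
  ok5 <- cal[pass == TRUE, peptide]
  for (p in setdiff(unique(meas$peptide), ok5))
    note("rule5_calibration", p, "dilution-series calibration failed")
  meas <- meas[peptide %in% ok5]

  # rule 6: mask sample signals below the peptide's validated LLOQ
  meas <- cal[, .(peptide, lloq)][meas, on = "peptide"]
  below <- meas$light_intensity < meas$lloq |
    meas$heavy_intensity < meas$lloq
  if (any(below))
    for (p in unique(meas$peptide[below]))
      note("rule6_lloq_mask", p,
           paste0(sum(below & meas$peptide == p), " sample(s) below LLOQ"))
  meas <- meas[!below]
  meas[, lloq := NULL]

  # rule 7: >= min_replicates ratios per condition after masking
  reps7 <- meas[, .(n = data.table::uniqueN(replicate)),
                by = .(peptide, condition)]
  reps7 <- reps7[n >= config$min_replicates]
  ok7 <- reps7[, .(n_cond = .N), by = peptide][n_cond == length(conditions),
                                               peptide]
  for (p in setdiff(unique(meas$peptide), ok7))
    note("rule7_replicates_postmask", p,
         "< min replicate ratios in a condition after LLOQ masking")
  meas <- meas[peptide %in% ok7]

  # rule 8: outlier peptides vs the protein's all-peptide mean ratio
  if (nrow(meas) > 0) {
    meas[, ratio := light_intensity / heavy_intensity]
    meas[, prot_mean := mean(ratio), by = .(protein_id, sample_id)]
    meas[, pct_diff := abs(ratio - prot_mean) / prot_mean * 100]
    overall <- meas[, .(d = mean(pct_diff)), by = peptide]
    within <- meas[, .(d = mean(pct_diff)), by = .(peptide, condition)]
    out8 <- union(overall[d > config$outlier_pct_max, peptide],
                  within[d > config$outlier_pct_max, peptide])
    for (p in out8)
      note("rule8_outlier", p, "mean deviation from protein mean ratio > max")
    meas <- meas[!peptide %in% out8]
    meas[, c("ratio", "prot_mean", "pct_diff") := NULL]
  }

  removal_log <- if (length(log_entries) > 0)
    as.data.frame(data.table::rbindlist(log_entries))
  else
    data.frame(rule = character(), peptide = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(measurements = as.data.frame(meas), removal_log = removal_log,
       calibrations = as.data.frame(cal))
}

#' Compute anchor protein concentrations
#'
#' Per sample, a peptide's concentration estimate is its light/heavy ratio
#' times the spiked SIL-protein amount, divided by the biomass (gDCW)
#' represented by the digested aliquot; the protein's sample concentration
#' is the mean over its peptides. Condition-level statistics (mean, sd, CV)
#' are taken over biological replicates; a condition whose replicate CV
#' exceeds `cv_max` is flagged `NQ` (not quantified).
#'
#' @param measurements Retained peptide measurements (see
#'   [filter_anchor_peptides()]).
#' @param spikes `data.frame` with `protein_id`, `sample_id`, `amount`
#'   (nmol spiked into the aliquot).
#' @param biomass `data.frame` with `sample_id`, `gdcw` (grams dry cell
#'   weight represented by the aliquot).
#' @param cv_max Replicate-CV threshold above which a condition is `NQ`.
#' @return List with `peptide_level` (per peptide x sample concentrations),
#'   `sample_level` (per protein x sample), and `condition_level`
#'   (`protein_id`, `condition`, `mean`, `sd`, `cv`, `n_replicates`,
#'   `n_peptides`, `status`).
#' @export
compute_anchor_concentrations <- function(measurements, spikes, biomass,
                                          cv_max = 0.5) {
  meas <- data.table::as.data.table(measurements)
  spk <- data.table::as.data.table(spikes)
  bio <- data.table::as.data.table(biomass)

  missing_spk <- unique(meas[!spk, on = c("protein_id", "sample_id"),
                             .(protein_id, sample_id)])
  if (nrow(missing_spk) > 0)
    stop("missing spike-in amount for protein ", missing_spk$protein_id[1],
         " in sample ", missing_spk$sample_id[1])
  missing_bio <- setdiff(unique(meas$sample_id), bio$sample_id)
  if (length(missing_bio) > 0)
    stop("missing biomass equivalent for sample ", missing_bio[1])

  x <- spk[meas, on = c("protein_id", "sample_id")]
  x <- bio[x, on = "sample_id"]
  x[, conc := light_intensity / heavy_intensity * amount / gdcw]
  peptide_level <- x[, .(protein_id, peptide, sample_id, condition,
                         replicate, conc)]
  sample_level <- peptide_level[, .(conc = mean(conc), n_peptides = .N),
                                by = .(protein_id, sample_id, condition,
                                       replicate)]
  condition_level <- sample_level[, .(
    mean = mean(conc), sd = sd(conc), n_replicates = .N,
    n_peptides = max(n_peptides)), by = .(protein_id, condition)]
  condition_level[, cv := ifelse(mean > 0, sd / mean, NA_real_)]
  condition_level[, status := ifelse(!is.na(cv) & cv > cv_max,
                                     "NQ", "quantified")]
  list(peptide_level = as.data.frame(peptide_level),
       sample_level = as.data.frame(sample_level),
       condition_level = as.data.frame(condition_level))
}

#' Summarize anchor quantification quality
#'
#' The inter-replicate CV is averaged over quantified protein-by-condition
#' entries; the inter-peptide CV is the CV across peptide-level
#' concentration estimates within a protein and sample, averaged over all
#' protein-by-sample entries with at least two peptides.
#'
#' @param condition_level,peptide_level As returned by
#'   [compute_anchor_concentrations()].
#' @return List with `mean_replicate_cv` and `mean_peptide_cv` (fractions,
#'   not percent).
#' @export
summarize_anchor_quality <- function(condition_level, peptide_level = NULL) {
  cl <- data.table::as.data.table(condition_level)
  rep_cv <- cl[status == "quantified" & is.finite(cv), cv]
  mean_rep <- if (length(rep_cv) > 0) mean(rep_cv) else NA_real_
  mean_pep <- NA_real_
  if (!is.null(peptide_level) && nrow(peptide_level) > 0) {
    pl <- data.table::as.data.table(peptide_level)
    per <- pl[, .(cv = if (.N >= 2L) sd(conc) / mean(conc) else NA_real_),
              by = .(protein_id, sample_id)]
    pep_cv <- per[is.finite(cv), cv]
    if (length(pep_cv) > 0) mean_pep <- mean(pep_cv)
  }
  list(mean_replicate_cv = mean_rep, mean_peptide_cv = mean_pep)
}
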