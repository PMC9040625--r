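# Proteome allocation over a functional hierarchy and protein-complex
# stoichiometry checks.

#' Aggregate proteome allocation over a functional hierarchy
#'
#' Computes per-category fractions of the proteome at a chosen level of a
#' tree-like functional hierarchy. By default categories are weighted by
#' mass (concentration times molecular weight), as tile areas of a proteome
#' map are; molar weighting (concentration only) is available. Proteins
#' without a hierarchy entry are binned under a fallback category so that
#' fractions always sum to 1.
#'
#' @param concentrations `data.frame`: `protein_id`, `conc` (a single
#'   sample or condition average).
#' @param sequences `data.frame` with `protein_id`, `molecular_weight`
#'   (ignored for molar weighting).
#' @param hierarchy `data.frame`: `protein_id`, `level1`, `level2`,
#'   `level3`.
#' @param level Hierarchy level to aggregate at (1, 2, or 3).
#' @param weight `"mass"` or `"molar"`.
#' @param fallback Category label for unmapped proteins.
#' @return `data.frame`: `category`, `fraction`, `n_proteins`, sorted by
#'   decreasing fraction.
#' @export
aggregate_allocation <- function(concentrations, sequences = NULL, hierarchy,
                                 level = 1L, weight = c("mass", "molar"),
                                 fallback = "not included in pathway") {
  weight <- match.arg(weight)
  stopifnot(level %in% 1:3)
  cc <- data.table::as.data.table(concentrations)
  if (nrow(cc) == 0) stop("empty concentration table")
  if (weight == "mass") {
    sq <- data.table::as.data.table(sequences)[, .(protein_id,
                                                   molecular_weight)]
    cc <- sq[cc, on = "protein_id"]
    if (anyNA(cc$molecular_weight))
      stop("molecular weight missing for mass weighting: ",
           cc[is.na(molecular_weight), protein_id][1])
    cc[, w := conc * molecular_weight]
  } else cc[, w := conc]
  hz <- data.table::as.data.table(hierarchy)
  lev <- paste0("level", level)
  hz <- hz[, .(protein_id, category = get(lev))]
  cc <- hz[cc, on = "protein_id"]
  cc[is.na(category), category := fallback]
  out <- cc[, .(fraction = sum(w), n_proteins = .N), by = category]
  out[, fraction := fraction / sum(fraction)]
  out <- out[order(-fraction)]
  as.data.frame(out)
}

#' Check observed protein-complex stoichiometry against expectation
#'
#' Concentration ratios of complex members to the reference member (the
#' first member of the definition) are compared with the expected
#' stoichiometry; a member is within tolerance when the fold deviation
#' `max(observed/expected, expected/observed)` of its ratio does not exceed
#' `tolerance_fold` (defaulting to the 1.5-fold calibration error band of
#' the label-free estimates).
#'
#' @param concentrations `data.frame`: `protein_id`, `conc`.
#' @param complex_def `data.frame`: `complex_id`, `protein_id`,
#'   `stoichiometry` (first row is the reference member).
#' @param tolerance_fold Maximum tolerated fold deviation.
#' @return `data.frame` per member: `complex_id`, `protein_id`,
#'   `observed_ratio`, `expected_ratio`, `fold_deviation`, `status`
#'   (`within`, `outside`, `missing`, or `reference`).
#' @export
stoichiometry_check <- function(concentrations, complex_def,
                                tolerance_fold = 1.5) {
  stopifnot(nrow(complex_def) >= 2L)
  cc <- data.table::as.data.table(concentrations)
  conc_of <- setNames(cc$conc, cc$protein_id)
  ref_id <- complex_def$protein_id[1]
  ref_st <- complex_def$stoichiometry[1]
  if (!ref_id %in% names(conc_of) || is.na(conc_of[[ref_id]]))
    stop("reference member not quantified: ", ref_id)
  ref_conc <- conc_of[[ref_id]]
  rows <- lapply(seq_len(nrow(complex_def)), function(i) {
    pid <- complex_def$protein_id[i]
    exp_ratio <- complex_def$stoichiometry[i] / ref_st
    if (i == 1L)
      return(data.frame(complex_id = complex_def$complex_id[i],
                        protein_id = pid, observed_ratio = 1,
                        expected_ratio = 1, fold_deviation = 1,
                        status = "reference", stringsAsFactors = FALSE))
    if (!pid %in% names(conc_of) || is.na(conc_of[[pid]]))
      return(data.frame(complex_id = complex_def$complex_id[i],
                        protein_id = pid, observed_ratio = NA_real_,
                        expected_ratio = exp_ratio,
                        fold_deviation = NA_real_, status = "missing",
                        stringsAsFactors = FALSE))
    obs_ratio <- conc_of[[pid]] / ref_conc
    dev <- max(obs_ratio / exp_ratio, exp_ratio / obs_ratio)
    data.frame(complex_id = complex_def$complex_id[i], protein_id = pid,
               observed_ratio = obs_ratio, expected_ratio = exp_ratio,
               fold_deviation = dev,
               status = if (dev <= tolerance_fold) "within" else "outside",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
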