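# Classification of metabolic flux changes as translational (carried by a
# matching enzyme-concentration change) or posttranslational (flux changes
# while the enzyme concentration does not follow), via a two-stage test:
# first significant flux changes (two-sided t test, BH-FDR), then a
# left-tailed comparison of the enzyme change against the flux change.

#' Two-sample equal-variance t test for a flux change
#'
#' Pooled-variance two-sided Student's t test between replicate flux values
#' of two conditions. Degenerate zero-variance inputs return p = 1 when the
#' means agree and p = 0 when they differ.
#'
#' @param replicates_a,replicates_b Numeric replicate vectors (length >= 2).
#' @return List with `t`, `p`, `df`.
#' @export
flux_change_test <- function(replicates_a, replicates_b) {
  a <- replicates_a[is.finite(replicates_a)]
  b <- replicates_b[is.finite(replicates_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 replicates per group")
  df <- length(a) + length(b) - 2L
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(list(t = if (p == 1) 0 else Inf * sign(mean(a) - mean(b)),
                p = p, df = df))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

# One-sided (left-tailed) two-sample equal-variance t test of
# H0: mean(x) >= mean(y) against mean(x) < mean(y).
left_tail_t <- function(x, y) {
  df <- length(x) + length(y) - 2L
  if (sd(x) == 0 && sd(y) == 0) {
    p <- if (mean(x) >= mean(y)) 1 else 0
    return(list(t = 0, p = p, df = df))
  }
  tt <- t.test(x, y, var.equal = TRUE, alternative = "less")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Classify flux regulation for condition pairs
#'
#' Stage one: for every reaction and unordered condition pair, a two-sided
#' equal-variance t test on replicate fluxes with BH-FDR across all tested
#' pairs identifies significant flux changes (`flux_q < alpha`). Stage two:
#' each significant pair is oriented so the flux log2 fold change is
#' positive, replicate-level log2 fold changes are formed for the flux and
#' for the relative enzyme expression (each replicate of the high condition
#' against the low condition's mean), and a left-tailed two-sample
#' equal-variance t test asks whether the enzyme change falls short of the
#' flux change. BH-FDR across the stage-two tests; `regulation_q < alpha`
#' is called `posttranslational`, otherwise `translational`. Reactions
#' without enzyme expression data are `no_enzyme_data`; nonsignificant flux
#' changes are `not_significant`.
#'
#' @param fluxes Replicate flux table: `reaction_id`, `condition`,
#'   `replicate`, `value`.
#' @param expression Relative enzyme expression table keyed by reaction:
#'   `reaction_id`, `condition`, `replicate`, `relative_intensity`
#'   (positive, relative scale).
#' @param alpha Significance level for both stages.
#' @return `data.frame`: `reaction_id`, `condition_a`, `condition_b`,
#'   `flux_log2fc`, `enzyme_log2fc`, `flux_p`, `flux_q`, `regulation_p`,
#'   `regulation_q`, `call`.
#' @export
classify_regulation <- function(fluxes, expression, alpha = 0.05) {
  fx <- data.table::as.data.table(fluxes)
  ex <- data.table::as.data.table(expression)
  conditions <- sort(unique(fx$condition))
  pairs <- utils::combn(conditions, 2, simplify = FALSE)

  rows <- list()
  for (rxn in unique(fx$reaction_id)) {
    for (pr in pairs) {
      va <- fx[reaction_id == rxn & condition == pr[1], value]
      vb <- fx[reaction_id == rxn & condition == pr[2], value]
      if (length(va) < 2L || length(vb) < 2L) next
      # reactions must carry flux under both conditions to be comparable
      if (all(va == 0) || all(vb == 0)) next
      st1 <- flux_change_test(va, vb)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        reaction_id = rxn, condition_a = pr[1], condition_b = pr[2],
        flux_p = st1$p)
    }
  }
  if (length(rows) == 0)
    return(data.frame(reaction_id = character(), condition_a = character(),
                      condition_b = character(), flux_log2fc = numeric(),
                      enzyme_log2fc = numeric(), flux_p = numeric(),
                      flux_q = numeric(), regulation_p = numeric(),
                      regulation_q = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  res <- data.table::rbindlist(rows)
  res[, flux_q := bh_fdr(flux_p)]
  res[, `:=`(flux_log2fc = NA_real_, enzyme_log2fc = NA_real_,
             regulation_p = NA_real_, regulation_q = NA_real_,
             call = "not_significant")]

  sig <- which(res$flux_q < alpha)
  for (i in sig) {
    rxn <- res$reaction_id[i]
    a <- res$condition_a[i]; b <- res$condition_b[i]
    va <- abs(fx[reaction_id == rxn & condition == a, value])
    vb <- abs(fx[reaction_id == rxn & condition == b, value])
    # orient the pair so the flux fold change is positive (b = high)
    if (mean(vb) < mean(va)) { tmp <- a; a <- b; b <- tmp
                               tmp <- va; va <- vb; vb <- tmp }
    flux_fc <- log2(vb / mean(va))
    data.table::set(res, i, "flux_log2fc", mean(flux_fc))
    ea <- ex[reaction_id == rxn & condition == a, relative_intensity]
    eb <- ex[reaction_id == rxn & condition == b, relative_intensity]
    if (length(ea) < 2L || length(eb) < 2L ||
        any(c(ea, eb) <= 0, na.rm = TRUE)) {
      data.table::set(res, i, "call", "no_enzyme_data")
      next
    }
    enz_fc <- log2(eb / mean(ea))
    data.table::set(res, i, "enzyme_log2fc", mean(enz_fc))
    st2 <- left_tail_t(enz_fc, flux_fc)
    data.table::set(res, i, "regulation_p", st2$p)
  }
  tested <- which(!is.na(res$regulation_p))
  if (length(tested) > 0) {
    res$regulation_q[tested] <- bh_fdr(res$regulation_p[tested])
    res$call[tested] <- ifelse(res$regulation_q[tested] < alpha,
                               "posttranslational", "translational")
  }
  data.table::setcolorder(res, c("reaction_id", "condition_a", "condition_b",
                                 "flux_log2fc", "enzyme_log2fc", "flux_p",
                                 "flux_q", "regulation_p", "regulation_q",
                                 "call"))
  as.data.frame(res)
}

#' Fraction of significant flux changes called posttranslational
#'
#' @param calls Output of [classify_regulation()].
#' @return Fraction in `[0, 1]` of classified (posttranslational or
#'   translational) flux changes that are posttranslational.
#' @export
regulation_summary <- function(calls) {
  n_post <- sum(calls$call == "posttranslational")
  n_trans <- sum(calls$call == "translational")
  stopifnot(n_post + n_trans >= 1L)
  n_post / (n_post + n_trans)
}
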