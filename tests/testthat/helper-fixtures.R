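# Small hand-built fixtures for the anchor-quantification tests.

# A perfectly linear dilution series for one peptide: heavy halves per
# level, light constant; optional additive background on both channels.
make_dilution <- function(peptide = "PEPTIDEK", protein_id = "P1",
                          light = 1e8, heavy0 = 2e8, n_levels = 10L,
                          background = 0) {
  data.frame(protein_id = protein_id, peptide = peptide,
             precursor_charge = 2L,
             level = seq_len(n_levels) - 1L,
             expected_ratio = 2^(seq_len(n_levels) - 1L),
             light_intensity = light + background,
             heavy_intensity = heavy0 / 2^(seq_len(n_levels) - 1L) +
               background,
             stringsAsFactors = FALSE)
}

# Anchor measurements for one protein: every peptide has the given L/H
# ratio in every sample (3 conditions x 4 replicates by default).
make_measurements <- function(peptides, ratios = rep(1, length(peptides)),
                              protein_id = "P1",
                              conditions = c("A", "B", "C"),
                              n_replicates = 4L,
                              heavy = 1e7) {
  rows <- list()
  for (i in seq_along(peptides)) {
    for (cond in conditions) {
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = protein_id, peptide = peptides[i],
          precursor_charge = 2L,
          sample_id = paste0(cond, "_r", r), condition = cond,
          replicate = r, light_intensity = ratios[i] * heavy,
          heavy_intensity = heavy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Spike and biomass tables covering every (protein, sample) in a
# measurement table.
make_spikes <- function(measurements, amount = 1e-3) {
  u <- unique(measurements[, c("protein_id", "sample_id")])
  u$amount <- amount
  u
}

make_biomass <- function(measurements, gdcw = 1e-4) {
  data.frame(sample_id = unique(measurements$sample_id), gdcw = gdcw,
             stringsAsFactors = FALSE)
}

# Brute-force oracle for the dilution calibration: refit over every
# "drop the k lowest-spike points" suffix and return the smallest k whose
# fit passes all criteria.
oracle_dilution_fit <- function(points, r2_min = 0.95,
                                slope_range = c(0.95, 1.05),
                                intercept_range = c(-0.1, 0.1),
                                min_points = 3L) {
  pts <- points[!is.na(points$light_intensity) &
                  !is.na(points$heavy_intensity) &
                  points$light_intensity > 0 & points$heavy_intensity > 0, ]
  pts <- pts[order(pts$level), ]
  ratio <- pts$light_intensity / pts$heavy_intensity
  y <- log2(ratio / ratio[1])
  x <- as.numeric(pts$level)
  for (k in 0:(nrow(pts) - min_points)) {
    idx <- seq_len(nrow(pts) - k)
    fit <- lm(y[idx] ~ x[idx])
    b <- unname(coef(fit))
    sst <- sum((y[idx] - mean(y[idx]))^2)
    r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
    if (is.finite(r2) && r2 > r2_min && b[2] > slope_range[1] &&
        b[2] < slope_range[2] && b[1] > intercept_range[1] &&
        b[1] < intercept_range[2])
      return(list(pass = TRUE, n_points_used = length(idx),
                  lloq_level = pts$level[length(idx)]))
  }
  list(pass = FALSE, n_points_used = min_points,
       lloq_level = pts$level[min_points])
}

# Brute-force Kendall tau-b over all pairs, with tie correction.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Brute-force Benjamini-Hochberg step-up with monotonicity enforcement.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  for (i in (m - 1):1) q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  pmin(q, 1)
}
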