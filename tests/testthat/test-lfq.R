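test_that("tryptic digestion respects cleavage and missed-cleavage rules", {
  expect_equal(digest_protein("AKRPK"), c("AK", "RPK"))
  expect_equal(digest_protein("AAAA"), "AAAA")
  expect_setequal(digest_protein("AKCK", missed_cleavages = 1L),
                  c("AK", "CK", "AKCK"))
  expect_equal(digest_protein("AKRPK", cut_before_proline = TRUE),
               c("AK", "R", "PK"))
  expect_error(digest_protein(""), "empty sequence")
})

test_that("observable peptide counting applies the iBAQ length window", {
  expect_equal(count_observable_peptides("AKRPK", length_range = c(2, 30)), 2L)
  expect_equal(count_observable_peptides("AKRPK"), 0L)  # all shorter than 7
  s <- paste0(paste(rep("AAAAAAAK", 12), collapse = ""))
  expect_equal(count_observable_peptides(s), 12L)
})

test_that("peptide intensity sums the top fragments", {
  expect_equal(peptide_intensity(c(10, 9, 8, 7, 6, 5, 4)), 40)
  expect_equal(peptide_intensity(3), 3)
  expect_equal(peptide_intensity(c(0, 0, 0)), 0)
})

test_that("protein intensity models agree with hand-computed values", {
  v <- c(100, 50, 10)
  expect_equal(protein_intensity(v, "topN", top_n = 1), 100)
  expect_equal(protein_intensity(v, "topN", top_n = 3), 160)
  expect_equal(protein_intensity(v, "iBAQ", observable_count = 16), 10)
  expect_equal(protein_intensity(v, "all_pep_sum"), 160)
  expect_true(is.na(protein_intensity(c(5), "topN")))   # < 2 peptides
  expect_error(protein_intensity(v, "iBAQ", observable_count = 0),
               "observable")
})

test_that("iBAQ equals m*u/n for m equal peptides and n observable", {
  for (m in c(2, 4, 7)) for (n in c(5, 16)) {
    u <- 123.4
    expect_equal(protein_intensity(rep(u, m), "iBAQ", observable_count = n),
                 m * u / n)
  }
})

test_that("anchor regression recovers exact and planted slopes", {
  intensity <- 10^seq(4, 8, length.out = 8)
  reg <- fit_anchor_regression(intensity / 1000, intensity)
  expect_equal(reg$slope, 1, tolerance = 1e-10)
  expect_equal(reg$intercept, -3, tolerance = 1e-10)
  expect_equal(reg$r, 1, tolerance = 1e-10)

  set.seed(8)
  li <- runif(16, 4, 8)
  conc <- 10^(0.9 * li - 4 + rnorm(16, 0, 0.1))
  reg2 <- fit_anchor_regression(conc, 10^li)
  expect_equal(reg2$slope, 0.9, tolerance = 0.1)
  expect_error(fit_anchor_regression(1:2, 1:2), "at least 3")
})

test_that("CV-MFE is exactly 1 for noise-free anchors and is deterministic", {
  li <- seq(4, 8, length.out = 16)
  bt <- cv_mfe_bootstrap(10^(li - 3), 10^li, n_boot = 50, seed = 1)
  expect_equal(bt$cv_mfe, 1)
  b1 <- cv_mfe_bootstrap(10^(li - 3 + 0.1 * sin(li)), 10^li, n_boot = 50,
                         seed = 9)
  b2 <- cv_mfe_bootstrap(10^(li - 3 + 0.1 * sin(li)), 10^li, n_boot = 50,
                         seed = 9)
  expect_identical(b1$cv_mfe, b2$cv_mfe)
  expect_identical(b1$fe, b2$fe)
  expect_true(all(b1$fe >= 1))
})

test_that("bootstrap CV-MFE matches the Monte-Carlo fold-error oracle under
           planted lognormal noise", {
  set.seed(101)
  n <- 16
  li <- runif(n, 5, 9)
  conc <- 10^(li - 6 + rnorm(n, 0, 0.17))
  bt <- cv_mfe_bootstrap(conc, 10^li, n_boot = 1000, seed = 101)
  # oracle: E[10^|e|], e ~ N(0, 0.17 * sqrt(1 + 1/n)) -- a first-order
  # approximation that ignores out-of-bag fit uncertainty, hence a slight
  # underestimate of the bootstrap value
  s <- 0.17 * sqrt(1 + 1 / n)
  oracle <- 2 * exp((s * log(10))^2 / 2) * pnorm(s * log(10))
  expect_gt(bt$cv_mfe, 0.95 * oracle)
  expect_lt(bt$cv_mfe, 1.35 * oracle)
  # the regime of a ~1.5-fold average calibration error
  expect_gt(bt$cv_mfe, 1.3)
  expect_lt(bt$cv_mfe, 1.8)
})

test_that("model selection recovers the generating summarization", {
  # intensities generated as the top-3 peptide sum: top3 must beat top1
  set.seed(21)
  n <- 16
  conc <- 10^runif(n, 0, 3)
  anchors <- sprintf("A%02d", seq_len(n))
  feats <- list()
  for (i in seq_len(n)) {
    n_pep <- 6
    pep_int <- conc[i] * 1e6 * 10^rnorm(n_pep, 0, 0.3)
    # top-1 summaries are noisier than top-3 sums by construction
    for (p in seq_len(n_pep))
      feats[[length(feats) + 1L]] <- data.frame(
        protein_id = anchors[i], peptide = paste0(anchors[i], "pep", p),
        sample_id = "s1", fragment_index = 1:5,
        intensity = pep_int[p] * c(0.4, 0.25, 0.15, 0.12, 0.08),
        stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, feats)
  top3 <- build_protein_intensities(feats, "top3")
  conc_tab <- data.frame(protein_id = anchors, sample_id = "s1",
                         conc = 10^(log10(
                           top3$intensity[match(anchors,
                                                top3$protein_id)]) - 6))
  cfg <- pipeline_config(model_grid = c("top1", "top3"), n_boot = 60,
                         seed = 4)
  sel <- select_lfq_model(feats, conc_tab, "s1", config = cfg)
  expect_equal(sel$best, "top3")
  expect_equal(sel$fits$cv_mfe[sel$fits$model == "top3"], 1,
               tolerance = 1e-10)
})

test_that("rescaling intensities shifts the intercept but not predictions", {
  set.seed(31)
  li <- runif(12, 4, 8)
  conc <- 10^(li - 3 + rnorm(12, 0, 0.1))
  r1 <- fit_anchor_regression(conc, 10^li)
  r2 <- fit_anchor_regression(conc, 10^li * 50)
  expect_equal(r2$slope, r1$slope, tolerance = 1e-9)
  expect_equal(r2$intercept, r1$intercept - r1$slope * log10(50),
               tolerance = 1e-9)
  pred1 <- 10^(r1$intercept + r1$slope * log10(10^li))
  pred2 <- 10^(r2$intercept + r2$slope * log10(10^li * 50))
  expect_equal(pred2, pred1, tolerance = 1e-9)
})

test_that("proteome estimation applies the fitted line and is monotone", {
  fit <- list(slope = 1, intercept = -3)
  ints <- data.frame(protein_id = c("P1", "P2"), sample_id = "s1",
                     intensity = c(1e6, 1e5))
  est <- estimate_proteome(fit, ints)
  expect_equal(est$conc[est$protein_id == "P1"], 1000)
  expect_true(est$conc[est$protein_id == "P1"] >
                est$conc[est$protein_id == "P2"])
})

test_that("anchors can be reported at their SIL values", {
  fit <- list(slope = 1, intercept = -3)
  ints <- data.frame(protein_id = c("P1", "P2"), sample_id = "s1",
                     intensity = c(1e6, 1e5))
  sil <- data.frame(protein_id = "P1", sample_id = "s1", conc = 1234)
  est <- estimate_proteome(fit, ints, anchor_conc = sil)
  expect_equal(est$conc[est$protein_id == "P1"], 1234)
  expect_equal(est$source[est$protein_id == "P1"], "SIL")
  expect_equal(est$source[est$protein_id == "P2"], "label-free")
})

test_that("most label-free estimates fall within 2-fold of the truth", {
  truth <- generate_ground_truth(n_proteins = 150, seed = 6)
  dia <- simulate_dia_intensities(truth)
  dil <- simulate_dilution_series(truth)
  filt <- filter_anchor_peptides(dia$measurements, dil$dilution)
  anch <- compute_anchor_concentrations(filt$measurements, dia$spikes,
                                        dia$biomass)
  cfg <- pipeline_config(model_grid = c("top1", "top3"), n_boot = 40,
                         seed = 2)
  sel <- select_lfq_model(dia$features,
                          anch$sample_level[, c("protein_id", "sample_id",
                                                "conc")],
                          "CO_r1", config = cfg)
  est <- estimate_proteome(sel$fits[1, ], sel$intensities,
                           report_anchor_sil = FALSE)
  m <- merge(est, truth$concentrations[truth$concentrations$condition ==
                                         "CO", ], by = "protein_id")
  fe <- pmax(m$conc.x / m$conc.y, m$conc.y / m$conc.x)
  expect_gt(mean(fe < 2), 0.7)
})

test_that("total proteome mass is the conc * MW sum and is linear", {
  conc <- data.frame(protein_id = "P1", sample_id = "s1", conc = 1000)
  seqs <- data.frame(protein_id = "P1", molecular_weight = 50000)
  m <- total_proteome_mass(conc, seqs)
  expect_equal(m$mass_g_per_gdcw, 0.05)
  conc2 <- conc; conc2$conc <- 2 * conc2$conc
  expect_equal(total_proteome_mass(conc2, seqs)$mass_g_per_gdcw, 0.1)
  bio <- data.frame(sample_id = "s1", gdcw = 2e-6)
  m2 <- total_proteome_mass(conc, seqs, bio)
  expect_equal(m2$mass_ug, 0.05 * 2e-6 * 1e6)
})

test_that("a proteome built to a target mass is recovered within the
           calibration error band", {
  truth <- generate_ground_truth(n_proteins = 150, total_mass_g = 0.5,
                                 sigma_condition = 0, seed = 7)
  expect_equal(sum(truth$proteins$base_conc *
                     truth$proteins$molecular_weight) * 1e-9, 0.5,
               tolerance = 1e-9)
  dia <- simulate_dia_intensities(truth)
  dil <- simulate_dilution_series(truth)
  filt <- filter_anchor_peptides(dia$measurements, dil$dilution)
  anch <- compute_anchor_concentrations(filt$measurements, dia$spikes,
                                        dia$biomass)
  cfg <- pipeline_config(model_grid = c("top3"), n_boot = 30, seed = 2)
  sel <- select_lfq_model(dia$features,
                          anch$sample_level[, c("protein_id", "sample_id",
                                                "conc")],
                          "CO_r1", config = cfg)
  est <- estimate_proteome(sel$fits[1, ], sel$intensities,
                           report_anchor_sil = FALSE)
  m <- total_proteome_mass(est, truth$proteins)
  expect_gt(m$mass_g_per_gdcw, 0.5 / sel$fits$cv_mfe[1])
  expect_lt(m$mass_g_per_gdcw, 0.5 * sel$fits$cv_mfe[1])
})
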