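test_that("SIL stock quantification follows the heavy/light tag ratio", {
  expect_equal(quantify_sil_stock(5e6, 5e6, 2, 4), 0.5)
  expect_equal(quantify_sil_stock(1e7, 5e6, 2, 4), 1.0)
  expect_error(quantify_sil_stock(3e6, 0), "no reference signal")
  expect_error(quantify_sil_stock(3e6, NA), "no reference signal")
})

test_that("a noise-free 2-fold series calibrates perfectly", {
  fit <- fit_dilution_series(make_dilution())
  expect_true(fit$pass)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_points_used, 10L)
  expect_equal(fit$lloq_level, 9L)
  # LLOQ is the heavy signal at the lowest retained level
  expect_equal(fit$lloq, 2e8 / 2^9)
})

test_that("a series with a wrong slope fails calibration", {
  d <- make_dilution()
  # compress the measured ratio: slope 0.8 in doubling space
  r0 <- d$light_intensity[1] / d$heavy_intensity[1]
  d$heavy_intensity <- d$light_intensity / (r0 * 2^(0.8 * d$level))
  fit <- fit_dilution_series(d)
  expect_false(fit$pass)
  expect_equal(fit$slope, 0.8, tolerance = 1e-6)
})

test_that("too few usable points fail with a reason", {
  d <- make_dilution(n_levels = 4L)
  d$heavy_intensity[c(2, 3)] <- NA
  fit <- fit_dilution_series(d)
  expect_false(fit$pass)
  expect_match(fit$reason, "fewer than")
})

test_that("iterative low-spike dropping matches the brute-force
           drop-suffix oracle", {
  set.seed(11)
  for (i in 1:25) {
    bg <- 10^runif(1, 3, 7.5)
    noise <- 10^rnorm(10, 0, 0.015)
    d <- make_dilution(background = 0)
    d$heavy_intensity <- d$heavy_intensity * noise + bg
    d$light_intensity <- d$light_intensity + bg
    fit <- fit_dilution_series(d)
    orc <- oracle_dilution_fit(d)
    expect_equal(fit$pass, orc$pass)
    if (orc$pass) {
      expect_equal(fit$n_points_used, orc$n_points_used)
      expect_equal(fit$lloq_level, orc$lloq_level)
    }
  }
})

test_that("peptides quantified in too few replicates are removed", {
  peps <- c("AAAK", "CCCK")
  meas <- make_measurements(peps)
  # AAAK missing in 2 of 4 replicates of condition A
  drop <- meas$peptide == "AAAK" & meas$condition == "A" &
    meas$replicate %in% c(3, 4)
  meas$light_intensity[drop] <- NA
  dil <- rbind(make_dilution("AAAK"), make_dilution("CCCK"))
  filt <- filter_anchor_peptides(meas, dil)
  expect_false("AAAK" %in% filt$measurements$peptide)
  expect_true("CCCK" %in% filt$measurements$peptide)
  expect_true("rule2_replicates" %in%
                filt$removal_log$rule[filt$removal_log$peptide == "AAAK"])
})

test_that("an offset peptide is removed by the 50% outlier rule", {
  peps <- paste0(c("AAA", "CCC", "DDD", "EEE", "FFF"), "K")
  meas <- make_measurements(peps, ratios = c(1, 1, 1, 1, 2))
  dil <- do.call(rbind, lapply(peps, make_dilution))
  filt <- filter_anchor_peptides(meas, dil)
  kept <- unique(filt$measurements$peptide)
  expect_false("FFFK" %in% kept)
  expect_setequal(kept, paste0(c("AAA", "CCC", "DDD", "EEE"), "K"))
  expect_true(all(filt$removal_log$rule == "rule8_outlier"))
})

test_that("concordant peptides above the LLOQ pass unfiltered", {
  peps <- paste0(c("AAA", "CCC", "DDD"), "K")
  meas <- make_measurements(peps)
  dil <- do.call(rbind, lapply(peps, make_dilution))
  filt <- filter_anchor_peptides(meas, dil)
  expect_equal(nrow(filt$measurements), nrow(meas))
  expect_equal(nrow(filt$removal_log), 0L)
})

test_that("peptides without DS01 heavy signal or a continuous series are
           removed", {
  peps <- c("AAAK", "CCCK", "DDDK")
  meas <- make_measurements(peps)
  d1 <- make_dilution("AAAK")
  d2 <- make_dilution("CCCK"); d2$heavy_intensity[1] <- NA   # no DS01
  d3 <- make_dilution("DDDK"); d3$heavy_intensity[2:3] <- NA # broken run
  filt <- filter_anchor_peptides(meas, rbind(d1, d2, d3))
  expect_setequal(unique(filt$measurements$peptide), "AAAK")
  rules <- setNames(filt$removal_log$rule, filt$removal_log$peptide)
  expect_equal(unname(rules["CCCK"]), "rule3_ds01_heavy")
  expect_equal(unname(rules["DDDK"]), "rule4_continuous_series")
})

test_that("concentration arithmetic and the NQ rule are correct", {
  # one peptide, L/H = 1, spike 10 nmol, 1 gDCW -> 10 nmol/gDCW
  meas <- make_measurements("AAAK", conditions = "A", n_replicates = 4L)
  spikes <- make_spikes(meas, amount = 10)
  biomass <- make_biomass(meas, gdcw = 1)
  res <- compute_anchor_concentrations(meas, spikes, biomass)
  expect_equal(res$condition_level$mean, 10)
  expect_equal(res$condition_level$status, "quantified")

  # replicate concentrations (100, 100, 100, 260): CV = 0.571 > 0.5 -> NQ
  meas2 <- make_measurements("AAAK", conditions = "A", n_replicates = 4L)
  meas2$light_intensity <- 1e7 * c(100, 100, 100, 260)[meas2$replicate] / 100
  res2 <- compute_anchor_concentrations(meas2, make_spikes(meas2, 100 * 1e-4),
                                        make_biomass(meas2))
  expect_equal(res2$condition_level$mean, 140)
  expect_equal(res2$condition_level$cv, sd(c(100, 100, 100, 260)) / 140)
  expect_equal(res2$condition_level$status, "NQ")

  # mean 270, sd 15 -> CV ~ 5.6%
  expect_equal(15 / 270, 0.0556, tolerance = 1e-2)
})

test_that("missing spike or biomass records are hard errors", {
  meas <- make_measurements("AAAK", conditions = "A")
  spikes <- make_spikes(meas)[-1, ]
  expect_error(compute_anchor_concentrations(meas, spikes,
                                             make_biomass(meas)),
               "missing spike-in")
  expect_error(compute_anchor_concentrations(meas, make_spikes(meas),
                                             make_biomass(meas)[0, ]),
               "missing biomass")
})

test_that("quality summary reproduces hand-computed CVs", {
  # identical replicates -> zero replicate CV
  meas <- make_measurements(c("AAAK", "CCCK"))
  res <- compute_anchor_concentrations(meas, make_spikes(meas),
                                       make_biomass(meas))
  q <- summarize_anchor_quality(res$condition_level, res$peptide_level)
  expect_equal(q$mean_replicate_cv, 0)

  # two peptides at 90 and 110 nmol/gDCW -> inter-peptide CV ~ 14.1%
  meas2 <- make_measurements(c("AAAK", "CCCK"), ratios = c(0.9, 1.1),
                             conditions = "A", n_replicates = 3L)
  res2 <- compute_anchor_concentrations(meas2, make_spikes(meas2, 1e-2),
                                        make_biomass(meas2))
  q2 <- summarize_anchor_quality(res2$condition_level, res2$peptide_level)
  expect_equal(q2$mean_peptide_cv, sd(c(90, 110)) / 100)
})

test_that("concentrations scale with the spike amounts", {
  meas <- make_measurements(c("AAAK", "CCCK"), ratios = c(0.8, 1.2))
  b <- make_biomass(meas)
  r1 <- compute_anchor_concentrations(meas, make_spikes(meas, 1e-3), b)
  r3 <- compute_anchor_concentrations(meas, make_spikes(meas, 3e-3), b)
  expect_equal(r3$condition_level$mean, 3 * r1$condition_level$mean)
})

test_that("tightening the r2 threshold never enlarges the retained set", {
  truth <- generate_ground_truth(n_proteins = 60, n_anchors = 8, seed = 3)
  dia <- simulate_dia_intensities(truth)
  dil <- simulate_dilution_series(truth, sigma_noise = 0.03)
  prev <- NULL
  for (r2 in c(0.95, 0.99, 0.999, 0.99999)) {
    cfg <- pipeline_config(r2_min = r2)
    kept <- unique(filter_anchor_peptides(dia$measurements, dil$dilution,
                                          config = cfg)$measurements$peptide)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("zero-noise synthetic data is recovered exactly", {
  truth <- generate_ground_truth(n_proteins = 40, n_anchors = 6,
                                 sigma_condition = 0, seed = 5)
  design <- dia_design(sigma_noise = 0, sigma_bio = 0, sigma_sample = 0,
                       detection_floor = 0)
  dia <- simulate_dia_intensities(truth, design)
  dil <- simulate_dilution_series(truth, design, background = 0,
                                  sigma_noise = 0)
  filt <- filter_anchor_peptides(dia$measurements, dil$dilution)
  res <- compute_anchor_concentrations(filt$measurements, dia$spikes,
                                       dia$biomass)
  m <- merge(res$condition_level, truth$concentrations,
             by = c("protein_id", "condition"))
  expect_gt(nrow(m), 0)
  expect_equal(m$mean, m$conc, tolerance = 1e-9)
  expect_true(all(m$status == "quantified"))
})
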