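conc_table <- function(ids, means, conditions = c("CO", "syn", "h2"),
                       sd_frac = 0.1) {
  # means: matrix ids x conditions
  do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(protein_id = ids[i], condition = conditions,
               mean = means[i, ], sd = sd_frac * means[i, ],
               stringsAsFactors = FALSE)))
}

test_that("complex concentration propagates subunit uncertainty", {
  cx <- complex_concentration(c(10, 20), c(2, 2))
  expect_equal(cx$mean, 15)
  expect_equal(cx$sd, sqrt(8) / 2)
  one <- complex_concentration(5, 1.5)
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 1.5)
  # m identical subunits each +-s -> s / sqrt(m)
  for (m in c(2, 4, 9))
    expect_equal(complex_concentration(rep(7, m), rep(3, m))$sd, 3 / sqrt(m))
})

test_that("isoenzyme selection follows the mean concentration ranking", {
  cc <- conc_table(c("A", "B"), rbind(c(10, 10, 10), c(5, 5, 5)))
  sel <- select_isoenzyme(list(A = "A", B = "B"), cc)
  expect_equal(sel$chosen, "A")

  # A ranks (1,2,2), B ranks (2,1,1) -> B wins on mean rank
  cc2 <- conc_table(c("A", "B"), rbind(c(10, 5, 5), c(8, 9, 9)))
  sel2 <- select_isoenzyme(list(A = "A", B = "B"), cc2)
  expect_equal(sel2$chosen, "B")

  single <- select_isoenzyme(list(A = "A"), cc)
  expect_equal(single$chosen, "A")
})

test_that("isoenzyme selection is invariant to alternative order and
           handles unmeasured alternatives", {
  cc <- conc_table(c("A", "B"), rbind(c(10, 5, 5), c(8, 9, 9)))
  s1 <- select_isoenzyme(list(A = "A", B = "B"), cc)
  s2 <- select_isoenzyme(list(B = "B", A = "A"), cc)
  expect_equal(s1$chosen, s2$chosen)
  # an alternative missing one condition cannot be chosen
  cc3 <- cc[!(cc$protein_id == "B" & cc$condition == "h2"), ]
  s3 <- select_isoenzyme(list(A = "A", B = "B"), cc3)
  expect_equal(s3$chosen, "A")
  expect_null(select_isoenzyme(list(B = "B"), cc3))
})

test_that("complexes compete by their combined concentration", {
  cc <- conc_table(c("A1", "A2", "B"),
                   rbind(c(6, 6, 6), c(8, 8, 8), c(10, 10, 10)))
  sel <- select_isoenzyme(list(cplx = c("A1", "A2"), B = "B"), cc)
  # complex mean (6+8)/2 = 7 < 10 -> B wins
  expect_equal(sel$chosen, "B")
})

test_that("shared-enzyme splitting is proportional and conservative", {
  expect_equal(split_shared_enzyme(100, c(a = 3, b = 1)),
               c(a = 75, b = 25))
  expect_equal(split_shared_enzyme(100, c(a = 5, b = 0)),
               c(a = 100, b = 0))
  s <- split_shared_enzyme(42, c(a = 1, b = 2, c = 7))
  expect_equal(sum(s), 42)
  expect_error(split_shared_enzyme(10, c(a = 0, b = 0)), "zero")
})

test_that("k_app unit conversion and scaling are exact", {
  expect_equal(compute_kapp(1, 1e6 / 3600)$kapp, 1)
  expect_equal(compute_kapp(0, 100)$kapp, 0)
  expect_equal(compute_kapp(6.7, 62)$kapp, 30.017921, tolerance = 1e-6)
  k <- compute_kapp(2, 50)$kapp
  expect_equal(compute_kapp(4, 50)$kapp, 2 * k)
  expect_equal(compute_kapp(2, 100)$kapp, k / 2)
  expect_error(compute_kapp(1, 0), "positive")
  # ratio error propagation
  k2 <- compute_kapp(10, 100, 1, 20)
  expect_equal(k2$sd, k2$kapp * sqrt(0.01 + 0.04))
})

test_that("flux filters remove small, zero, and membrane-bound reactions", {
  fm <- data.frame(
    reaction_id = rep(c("ref", "small", "zero", "ok", "memb"), each = 2),
    condition = rep(c("CO", "syn"), 5),
    mean = c(1, 1, 5e-4, 5e-4, 0, 0, 0.5, 0.5, 0.5, 0.5))
  gpr <- data.frame(reaction_id = c("small", "zero", "ok", "memb"),
                    alternative_index = 1L,
                    protein_id = c("P1", "P2", "P3", "P4"),
                    membrane_flag = c(FALSE, FALSE, FALSE, TRUE))
  cc <- conc_table(paste0("P", 1:4),
                   matrix(10, 4, 3)[, 1:2], conditions = c("CO", "syn"))
  el <- filter_kapp_reactions(fm, "ref", gpr, cc)
  expect_equal(el$reaction_id, "ok")
  expect_error(filter_kapp_reactions(fm, "nope", gpr, cc),
               "reference reaction")
})

test_that("kendall correlation matches the brute-force pair-count oracle", {
  expect_equal(kendall_correlation(1:5, 2 * (1:5))$tau, 1)
  expect_equal(kendall_correlation(1:3, 3:1)$tau, -1)
  set.seed(13)
  for (i in 1:20) {
    n <- 8
    x <- sample(1:5, n, replace = TRUE)  # ties on purpose
    y <- x + sample(0:3, n, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(kendall_correlation(x, y)$tau, oracle_kendall(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_correlation(rep(1, 5), 1:5), "constant")
})

test_that("planted k_app values are recovered exactly without noise", {
  truth <- generate_ground_truth(n_proteins = 80, seed = 9)
  flx <- simulate_fluxes_and_expression(truth, rep_cv = 1e-9)
  kt <- kapp_table(flx$fluxes, flx$gpr, flx$concentrations,
                   flx$reference_reaction)
  expect_gt(nrow(kt), 0)
  m <- merge(kt, flx$truth, by = "reaction_id")
  for (cond in truth$conditions) {
    sub <- m[m$condition == cond, ]
    expect_equal(sub$kapp, sub[[paste0("kapp_", cond)]], tolerance = 1e-4)
  }
})

test_that("flux, concentration, and k_app are rank-correlated in the
           synthetic study", {
  truth <- generate_ground_truth(n_proteins = 80, seed = 10)
  flx <- simulate_fluxes_and_expression(truth)
  kt <- kapp_table(flx$fluxes, flx$gpr, flx$concentrations,
                   flx$reference_reaction)
  co <- flux_proteome_correlations(kt)
  expect_gt(co$flux_conc$tau, 0.2)
  expect_lt(co$flux_conc$p, 0.01)
  expect_gt(co$flux_kapp$tau, 0.2)
  expect_lt(co$flux_kapp$p, 0.01)
})
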