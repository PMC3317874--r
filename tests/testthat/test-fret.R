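test_that("bleed-through coefficients are per-ROI ratio means with rejection rules", {
  co <- estimate_bleedthrough(roi_table(30, 100, 0), roi_table(10, 0, 100))
  expect_equal(co$co_a, 0.30)
  expect_equal(co$co_b, 0.10)
  # zero-signal donor controls: no bleed-through
  co0 <- estimate_bleedthrough(roi_table(c(0, 0), c(100, 50), 0),
                               roi_table(5, 0, 100))
  expect_equal(co0$co_a, 0)
  # an ROI with a zero denominator is excluded with a warning
  expect_warning(
    coz <- estimate_bleedthrough(roi_table(c(30, 7), c(100, 0), 0),
                                 roi_table(10, 0, 100)),
    "excluded")
  expect_equal(coz$co_a, 0.30)
  expect_equal(coz$n_a, 1L)
  # all rejected -> error
  expect_warning(expect_error(
    estimate_bleedthrough(roi_table(30, 0, 0), roi_table(10, 0, 100)),
    "rejected"))
  expect_error(estimate_bleedthrough(roi_table(30, 100, 0)[0, ],
                                     roi_table(10, 0, 100)), "non-empty")
})

test_that("normalized net FRET matches hand arithmetic and its invariances", {
  co <- bleedthrough_coefficients(0.5, 0.2)
  expect_equal(normalized_net_fret(roi_table(120, 100, 100), co), 0.50)
  # pure bleed-through gives exactly zero net transfer
  expect_equal(normalized_net_fret(roi_table(70, 100, 100), co), 0)
  # invariance under uniform intensity rescaling
  set.seed(2)
  base <- roi_table(runif(20, 50, 200), runif(20, 50, 200), runif(20, 50, 200))
  for (c_scale in c(0.1, 3, 1000)) {
    scaled <- base
    scaled[, c("i_fret", "i_cfp", "i_yfp")] <-
      scaled[, c("i_fret", "i_cfp", "i_yfp")] * c_scale
    expect_equal(normalized_net_fret(scaled, co),
                 normalized_net_fret(base, co), tolerance = 1e-12)
  }
  expect_error(normalized_net_fret(roi_table(10, 0, 100), co), "positive")
})

test_that("the literal printed formula variant is available for audit", {
  co <- bleedthrough_coefficients(0.5, 0.2)
  # (CoA*I_CFP - CoB*I_YFP)/sqrt(I_CFP*I_YFP): no I_FRET term at all
  expect_equal(normalized_net_fret(roi_table(999, 100, 100), co,
                                   variant = "printed"), 0.30)
  expect_equal(normalized_net_fret(roi_table(0, 100, 100), co,
                                   variant = "printed"), 0.30)
})

test_that("summaries aggregate over cells/ROIs and flag sparse sampling", {
  co <- bleedthrough_coefficients(0.5, 0.2)
  rois <- do.call(rbind, lapply(1:12, function(c_id)
    roi_table(rep(120, 20), rep(100, 20), rep(100, 20),
              cell_id = sprintf("c%02d", c_id))))
  s <- summarize_fret(rois, co, condition = "wt")
  expect_equal(s$mean_nfret, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(s$n_cells, 12L)
  expect_true(s$valid)
  # five cells only: produced, but flagged
  expect_warning(s5 <- summarize_fret(rois[rois$cell_id <= "c05", ], co),
                 "thresholds")
  expect_false(s5$valid)
  expect_equal(s5$n_cells, 5L)
})

test_that("full pipeline recovers zero and nonzero ground-truth NFRET", {
  # recovery is assessed on the mean over replicate synthetic experiments,
  # against the single-experiment (240-ROI) standard error: the target of
  # the check is systematic bias of the estimator, not per-draw luck
  run_once <- function(mu, seed) {
    g <- make_fret_rois(true_nfret = mu, seed = seed)
    co <- estimate_bleedthrough(g$donor_only, g$acceptor_only)
    summarize_fret(g$experimental, co)
  }
  # zero net transfer through the full pipeline
  s0 <- lapply(1:5, function(k) run_once(0, 10 + k))
  expect_lt(abs(mean(sapply(s0, `[[`, "mean_nfret"))),
            2 * mean(sapply(s0, `[[`, "se_nfret")))
  # noiseless generator is exact
  gex <- make_fret_rois(true_nfret = 0.25, noise_cv = 0, seed = 11)
  coe <- estimate_bleedthrough(gex$donor_only, gex$acceptor_only)
  expect_equal(mean(normalized_net_fret(gex$experimental, coe)), 0.25,
               tolerance = 1e-9)
  # the four reported dimer conditions at 12 x 20 ROIs
  for (mu in c(0.07, 0.27, 0.30, 0.49)) {
    ss <- lapply(1:5, function(k) run_once(mu, round(1000 * mu) + k))
    expect_lt(abs(mean(sapply(ss, `[[`, "mean_nfret")) - mu),
              2 * mean(sapply(ss, `[[`, "se_nfret")))
  }
})

test_that("colocalization index matches hand values and its bounds", {
  expect_equal(colocalization_index(100, 100, 100), 1.0)
  expect_equal(colocalization_index(100, 100, 0), 0.0)
  expect_equal(colocalization_index(150, 50, 40), 0.40)
  expect_error(colocalization_index(0, 0, 0), "zero")
  expect_error(colocalization_index(10, 10, 11), "exceeds")
  expect_error(colocalization_index(-1, 10, 0), ">= 0")
  # property: within [0, 1] whenever counts are consistent
  set.seed(3)
  for (k in 1:50) {
    nr <- sample(1:500, 1); ng <- sample(1:500, 1)
    ny <- sample(0:min(nr, ng), 1)
    idx <- colocalization_index(nr, ng, ny)
    expect_gte(idx, 0); expect_lte(idx, 1)
  }
})
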