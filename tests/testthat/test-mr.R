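# cis-MR: instrument selection, GLS combination of Wald ratios, HEIDI
# outlier filtering, FDR and robustness verdicts.

test_that("instrument selection enforces count, clumping and frequency filters", {
  panel <- ar1_panel(m = 30, rho = 0.85, seed = 71)
  set.seed(61)
  z <- draw_region_z(panel, setNames(0.2, panel$variants$id[15]), n = 14824)
  st <- stats_from_z(panel, z)
  # a single causal variant in tight LD yields < 3 independent instruments
  expect_identical(select_instruments(st, panel$ld), "insufficient")
  # two variants at r2 = 0.25: only the stronger survives clumping
  panel2 <- ar1_panel(m = 10, rho = sqrt(0.25), seed = 72)
  st2 <- stats_from_z(panel2, c(9, 10, rep(0, 8)))
  sel2 <- prune_signals(st2[1:2, ], panel2$ld, r2_max = 0.1)
  expect_equal(nrow(sel2), 1)
  expect_equal(sel2$id, st2$id[2])
  # frequency mismatch with the reference drops the variant
  panel3 <- ar1_panel(m = 12, rho = 0, seed = 73)
  set.seed(62)
  z3 <- draw_region_z(panel3,
                      setNames(rep(0.2, 4), panel3$variants$id[c(2, 5, 8, 11)]),
                      n = 14824)
  st3 <- stats_from_z(panel3, z3)
  st3$eaf[2] <- min(0.99, panel3$ld$variants$eaf[2] + 0.6)
  sel3 <- select_instruments(st3, panel3$ld)
  expect_false(st3$id[2] %in% sel3$id)
})

test_that("GSMR with identical Wald ratios returns them exactly; diagonal case equals IVW", {
  est <- gsmr_estimate(b_zx = c(0.2, 0.4, 0.3), se_zx = c(0.02, 0.02, 0.02),
                       b_zy = 0.5 * c(0.2, 0.4, 0.3),
                       se_zy = c(0.01, 0.01, 0.01))
  expect_equal(est$b_xy, 0.5, tolerance = 1e-12)
  # independent instruments: must equal inverse-variance weighting of
  # the Wald ratios computed by hand
  set.seed(71)
  b_zx <- runif(6, 0.1, 0.4) * sample(c(-1, 1), 6, TRUE)
  se_zx <- runif(6, 0.01, 0.03)
  b_zy <- 0.3 * b_zx + rnorm(6, 0, 0.01)
  se_zy <- runif(6, 0.01, 0.03)
  est2 <- gsmr_estimate(b_zx, se_zx, b_zy, se_zy)
  ratio <- b_zy / b_zx
  v <- (se_zy^2 + ratio^2 * se_zx^2) / b_zx^2
  expect_equal(est2$b_xy, sum(ratio / v) / sum(1 / v), tolerance = 1e-10)
  expect_equal(est2$se_xy, sqrt(1 / sum(1 / v)), tolerance = 1e-10)
})

test_that("the GSMR estimator recovers a planted causal effect from 13 correlated instruments", {
  cfg <- sim_config(n_cohorts = 1, cohort_ns = 14824, n_blocks = 4,
                    block_size = 25, rho = 0.8, seed = 74,
                    maf_range = c(0.15, 0.5))
  panel <- simulate_ld_panel(cfg)
  causal_ids <- panel$variants$id[c(2, 9, 16, 23, 27, 34, 41, 48, 52,
                                    59, 66, 77, 84)]
  beta_exp <- rep(0.12, 13)
  theta <- 0.3
  hits <- 0L; n_ok <- 0L; chain_hits <- 0L; chain_ok <- 0L
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    set.seed(4000 + i)
    zx <- draw_region_z(panel, setNames(beta_exp, causal_ids), n = 14824)
    expo <- stats_from_z(panel, zx)
    n_eff <- 40000 * 0.25 * 0.75
    zy <- draw_region_z(panel, setNames(theta * beta_exp, causal_ids),
                        n = n_eff)
    outc <- stats_from_z(panel, zy, n = n_eff)
    inst <- select_instruments(expo, panel$ld)
    if (!identical(inst, "insufficient")) {
      n_ok <- n_ok + 1L
      oi <- match(inst$id, outc$id)
      R <- ld_subset(panel$ld, inst$id)$r
      est <- gsmr_estimate(inst$beta, inst$se, outc$beta[oi],
                           outc$se[oi], R)
      hits <- hits + (abs(est$b_xy - theta) <= 3 * est$se_xy)
    }
    res <- mr_protein_disease(expo, outc, panel$ld)
    if (res$status == "ok") {
      chain_ok <- chain_ok + 1L
      chain_hits <- chain_hits + (abs(res$b_xy - theta) <= 3 * res$se_xy)
    }
  }
  expect_gte(n_ok / n_rep, 0.95)
  expect_gte(hits / n_ok, 0.99)
  # the full chain (with HEIDI trimming of valid instruments) pays a
  # small, documented coverage cost but stays close
  expect_gte(chain_hits / chain_ok, 0.95)
})

test_that("HEIDI removes a planted pleiotropic instrument and is ~calibrated under the null", {
  set.seed(81)
  k <- 10
  b_zx <- runif(k, 0.15, 0.35)
  se_zx <- rep(0.01, k)
  removed_outlier <- 0L
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    set.seed(5000 + i)
    ratio_true <- rep(0.3, k)
    se_zy <- rep(0.015, k)
    b_zy <- ratio_true * b_zx + rnorm(k, 0, se_zy)
    # instrument 4 carries an independent outcome effect 5 SD off
    b_zy[4] <- b_zy[4] + 5 * se_zy[4]
    hd <- heidi_outlier(b_zx, se_zx, b_zy, se_zy)
    if (4 %in% hd$removed) removed_outlier <- removed_outlier + 1L
  }
  expect_gte(removed_outlier / n_rep, 0.8)
  # null calibration: consistent instruments removed at roughly the
  # filter's nominal 5% rate
  set.seed(82)
  rates <- replicate(200, {
    b_zy <- 0.3 * b_zx + rnorm(k, 0, 0.015)
    hd <- heidi_outlier(b_zx, se_zx, b_zy, rep(0.015, k))
    length(hd$removed) / (k - 1)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.04)
  # the reference instrument is never removed
  hd <- heidi_outlier(c(0.5, 0.2), c(0.01, 0.01), c(10, 0.06), c(0.01, 0.01))
  expect_false(hd$ref %in% hd$removed)
})

test_that("BH q-values match the step-up oracle and drive the verdicts", {
  p <- c(0.001, 0.02, 0.03, 0.04)
  res <- data.frame(p_xy = p, disease_min_p = 1e-6,
                    r2_sentinel_disease = 0.9, max_pp4 = 0.9)
  out <- fdr_and_robustness(res, q_max = 0.05)
  expect_equal(out$fdr_q, c(0.004, 0.04, 0.04, 0.04), tolerance = 1e-12)
  # brute-force step-up oracle
  m <- length(p)
  o <- order(p)
  q_raw <- p[o] * m / seq_len(m)
  q_oracle <- rev(cummin(rev(q_raw)))[order(o)]
  expect_equal(out$fdr_q, q_oracle, tolerance = 1e-12)
  expect_true(all(out$verdict == "robust"))
})

test_that("robustness filters demote weak-disease-signal and non-colocalizing pairs", {
  res <- data.frame(
    p_xy = c(1e-6, 1e-6, 1e-6, 0.5, NA),
    disease_min_p = c(1e-8, 0.01, 1e-8, 1e-8, NA),
    r2_sentinel_disease = c(0.9, 0.9, 0.5, 0.9, NA),
    max_pp4 = c(0.95, 0.95, 0.95, 0.95, NA))
  out <- fdr_and_robustness(res)
  expect_equal(out$verdict,
               c("robust", "eliminated_weak_disease_signal",
                 "significant_not_robust", "not_significant",
                 "insufficient_instruments"))
})

test_that("a null causal effect keeps the GSMR false-positive rate near nominal", {
  cfg <- sim_config(n_cohorts = 1, cohort_ns = 14824, n_blocks = 2,
                    block_size = 20, rho = 0.6, seed = 75,
                    maf_range = c(0.15, 0.5))
  panel <- simulate_ld_panel(cfg)
  causal_ids <- panel$variants$id[c(3, 11, 19, 23, 31, 39)]
  rejections <- 0L; n_ok <- 0L
  for (i in 1:400) {
    set.seed(6000 + i)
    zx <- draw_region_z(panel, setNames(rep(0.15, 6), causal_ids), n = 14824)
    zy <- draw_region_z(panel, NULL, n = 20000)
    expo <- stats_from_z(panel, zx)
    outc <- stats_from_z(panel, zy, n = 20000)
    inst <- select_instruments(expo, panel$ld)
    if (identical(inst, "insufficient")) next
    oi <- match(inst$id, outc$id)
    est <- gsmr_estimate(inst$beta, inst$se, outc$beta[oi], outc$se[oi],
                         ld_subset(panel$ld, inst$id)$r)
    n_ok <- n_ok + 1L
    rejections <- rejections + (est$p_xy < 0.05)
  }
  expect_gt(n_ok, 300)
  expect_gt(rejections / n_ok, 0.02)
  expect_lt(rejections / n_ok, 0.08)
})

test_that("MR results report the odds-ratio transform consistently", {
  panel <- ar1_panel(m = 40, rho = 0.5, seed = 76, maf_range = c(0.15, 0.5))
  causal_ids <- panel$variants$id[c(5, 15, 25, 35)]
  set.seed(91)
  zx <- draw_region_z(panel, setNames(rep(0.15, 4), causal_ids), n = 14824)
  zy <- draw_region_z(panel, setNames(rep(-0.045, 4), causal_ids), n = 20000)
  res <- mr_protein_disease(stats_from_z(panel, zx),
                            stats_from_z(panel, zy, n = 20000), panel$ld)
  expect_equal(res$status, "ok")
  expect_equal(res$or_, exp(res$b_xy), tolerance = 1e-12)
  expect_true(res$or_lo < res$or_ && res$or_ < res$or_hi)
  expect_equal(res$n_instruments_used +
                 (nchar(res$heidi_removed) > 0) *
                 length(strsplit(res$heidi_removed, ";")[[1]]),
               res$n_instruments_selected)
})
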