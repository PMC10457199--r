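# Bayesian colocalization: ABFs, hypothesis posteriors, conditioning,
# and the conditional-then-colocalize extension.

test_that("log ABF matches the closed form, including the worked case", {
  # null z favors no association
  expect_lt(log_abf(0, 0.1), 0)
  # uninformative limit: huge SE -> log ABF -> 0
  expect_equal(log_abf(0.5, 1e6), 0, tolerance = 1e-9)
  # beta = 0.1, se = 0.01, W = 0.15^2: r = 0.995575..., z = 10
  lab <- log_abf(0.1, 0.01, prior_sd = 0.15)
  r <- 0.0225 / (1e-4 + 0.0225)
  expect_equal(lab, 0.5 * (log(1 - r) + r * 100), tolerance = 1e-12)
  expect_equal(lab, 47.07, tolerance = 0.01)
  # default prior SDs: 0.15 quantitative, 0.2 case-control
  expect_equal(log_abf(0.1, 0.01, "case_control"),
               log_abf(0.1, 0.01, prior_sd = 0.2))
})

test_that("posteriors sum to one, favor PP0 under the global null", {
  set.seed(11)
  panel <- ar1_panel(m = 100, rho = 0.5, seed = 61)
  z1 <- draw_region_z(panel, NULL, n = 5000)
  z2 <- draw_region_z(panel, NULL, n = 5000)
  set.seed(12)
  t1 <- stats_from_z(panel, rnorm(100, 0, 1), n = 5000)
  t2 <- stats_from_z(panel, rnorm(100, 0, 1), n = 5000)
  res <- coloc_pair(t1, t2)
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  expect_gt(res$pp["PP0"], 0.99)
  expect_false(res$colocalized)
  expect_equal(res$n_variants, 100)
})

test_that("shared causal variants give high PP4; distinct unlinked ones high PP3", {
  panel <- ar1_panel(m = 200, rho = 0.8, seed = 62, maf_range = c(0.2, 0.5))
  causal <- panel$variants$id[100]
  pp4 <- pp3 <- numeric(10)
  for (i in 1:10) {
    set.seed(700 + i)
    b <- 10 / sqrt(14824) / sqrt(2 * 0.3 * 0.7)   # z ~ 10 at the causal variant
    z1 <- draw_region_z(panel, setNames(b, causal), n = 14824)
    z2 <- draw_region_z(panel, setNames(b, causal), n = 14824)
    r <- coloc_pair(stats_from_z(panel, z1), stats_from_z(panel, z2))
    pp4[i] <- r$pp["PP4"]
    # distinct: second trait's causal variant in a different LD block
    other <- panel$variants$id[5]
    z3 <- draw_region_z(panel, setNames(b, other), n = 14824)
    r3 <- coloc_pair(stats_from_z(panel, z1), stats_from_z(panel, z3))
    pp3[i] <- r3$pp["PP3"]
  }
  expect_gt(mean(pp4 > 0.95), 0.9)
  expect_gt(mean(pp3 > 0.95), 0.9)
})

test_that("coloc is symmetric up to exchanging PP1 and PP2, monotone in p12", {
  panel <- ar1_panel(m = 50, rho = 0.6, seed = 63)
  set.seed(21)
  z1 <- draw_region_z(panel, setNames(0.1, panel$variants$id[25]), n = 10000)
  z2 <- draw_region_z(panel, NULL, n = 10000)
  t1 <- stats_from_z(panel, z1, n = 10000)
  t2 <- stats_from_z(panel, z2, n = 10000)
  a <- coloc_pair(t1, t2)
  b <- coloc_pair(t2, t1)
  expect_equal(unname(a$pp[c("PP0", "PP2", "PP1", "PP3", "PP4")]),
               unname(b$pp), tolerance = 1e-12)
  pp4 <- sapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(p12)
    coloc_pair(t1, t2, p12 = p12)$pp["PP4"])
  expect_true(all(diff(pp4) > 0))
})

test_that("log-sum-exp keeps posteriors finite for extreme signals", {
  panel <- ar1_panel(m = 10, rho = 0.3, seed = 64)
  se <- 0.01
  t1 <- stats_from_z(panel, rep(0, 10), n = 1000)
  t1$beta <- c(2, rep(0, 9)); t1$se <- se      # z = 200
  t2 <- t1
  res <- coloc_pair(t1, t2)
  expect_true(all(is.finite(res$pp)))
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  expect_gt(res$pp["PP4"], 0.99)
  # independent max-shift oracle on the 10-variant toy: recompute the
  # five hypothesis weights and posteriors from scratch
  l1 <- log_abf(t1$beta, t1$se)
  l2 <- log_abf(t2$beta, t2$se)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  s1 <- lse(l1); s2 <- lse(l2); s12 <- lse(l1 + l2)
  lh <- c(0, log(1e-4) + s1, log(1e-4) + s2,
          log(1e-4) + log(1e-4) + s1 + s2 + log1p(-exp(s12 - s1 - s2)),
          log(1e-5) + s12)
  pp_oracle <- exp(lh - lse(lh))
  expect_equal(unname(res$pp), pp_oracle, tolerance = 1e-9)
  expect_error(coloc_pair(t1, transform(t2, id = paste0(id, "_x"))),
               "harmonize")
})

test_that("conditioning on the empty set or an orthogonal variant changes nothing", {
  panel <- ar1_panel(m = 30, rho = 0, seed = 65)
  set.seed(31)
  z <- draw_region_z(panel, setNames(0.2, panel$variants$id[15]), n = 8000)
  st <- stats_from_z(panel, z, n = 8000)
  expect_identical(conditioned_sumstats(st, panel$ld, character()), st)
  cond <- conditioned_sumstats(st, panel$ld, panel$variants$id[1])
  keep <- st$id != panel$variants$id[1]
  expect_equal(cond$beta[keep], st$beta[keep], tolerance = 1e-6)
  expect_equal(cond$beta[!keep], 0)
  expect_error(conditioned_sumstats(st, panel$ld, "nope"), "absent")
})

test_that("conditioning a shadow signal on its driver collapses it", {
  panel <- ar1_panel(m = 40, rho = 0.9, seed = 66)
  driver <- panel$variants$id[20]
  shadow_i <- 21
  collapsed <- 0L
  for (i in 1:40) {
    set.seed(800 + i)
    z <- draw_region_z(panel, setNames(0.15, driver), n = 14824)
    st <- stats_from_z(panel, z, n = 14824)
    cond <- conditioned_sumstats(st, panel$ld, driver)
    if (abs(cond$beta[shadow_i] / cond$se[shadow_i]) < 2) collapsed <- collapsed + 1L
  }
  expect_gte(collapsed / 40, 0.95)
})

test_that("single-signal traits reduce pwcoco to plain coloc", {
  panel <- ar1_panel(m = 60, rho = 0.8, seed = 67)
  causal <- panel$variants$id[30]
  set.seed(41)
  z1 <- draw_region_z(panel, setNames(0.15, causal), n = 14824)
  z2 <- draw_region_z(panel, setNames(0.12, causal), n = 14824)
  t1 <- stats_from_z(panel, z1)
  t2 <- stats_from_z(panel, z2)
  pw <- pwcoco(t1, t2, panel$ld)
  expect_equal(dim(pw$pp4), c(1, 1))
  plain <- coloc_pair(t1, t2)
  expect_equal(pw$pp4[1, 1], unname(plain$pp["PP4"]), tolerance = 1e-9)
})

test_that("pwcoco resolves a two-signal locus: shared pair colocalizes, other does not", {
  panel <- ar1_panel(m = 100, rho = 0.8, seed = 68, maf_range = c(0.2, 0.5))
  s_shared <- panel$variants$id[25]
  s_only1 <- panel$variants$id[75]
  got <- 0L
  for (i in 1:10) {
    set.seed(900 + i)
    z1 <- draw_region_z(panel, setNames(c(0.15, 0.15), c(s_shared, s_only1)),
                        n = 14824)
    z2 <- draw_region_z(panel, setNames(0.12, s_shared), n = 14824)
    pw <- pwcoco(stats_from_z(panel, z1), stats_from_z(panel, z2), panel$ld)
    ok_max <- pw$max_pp4 > 0.8
    other <- pw$pp4[rownames(pw$pp4) == s_only1, , drop = TRUE]
    ok_other <- length(other) == 0 || all(other < 0.2)
    if (ok_max && ok_other) got <- got + 1L
  }
  expect_gte(got / 10, 0.8)
})

test_that("conditioning on an orthogonal secondary signal leaves primary coloc unchanged", {
  cfg <- sim_config(n_cohorts = 1, cohort_ns = 14824, n_blocks = 2,
                    block_size = 30, rho = 0.8, seed = 69)
  panel <- simulate_ld_panel(cfg)
  a <- panel$variants$id[15]    # block 1
  b <- panel$variants$id[45]    # block 2 (r = 0 with block 1)
  set.seed(51)
  z1 <- draw_region_z(panel, setNames(c(0.15, 0.15), c(a, b)), n = 14824)
  z2 <- draw_region_z(panel, setNames(0.12, a), n = 14824)
  t1 <- stats_from_z(panel, z1)
  t2 <- stats_from_z(panel, z2)
  cond <- conditioned_sumstats(t1, panel$ld, b)
  r_cond <- coloc_pair(cond[cond$id != b, ], t2[t2$id != b, ])
  r_raw <- coloc_pair(t1[t1$id != b & panel$variants$block == 1, ],
                      t2[t2$id != b & panel$variants$block == 1, ])
  expect_equal(unname(r_cond$pp["PP4"]), unname(r_raw$pp["PP4"]),
               tolerance = 1e-3)
})
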