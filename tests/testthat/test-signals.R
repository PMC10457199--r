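# Locus definition: region merging with sentinels, cis/trans labels,
# stepwise conditional analysis, pruning, and variance explained.

test_that("two flanked variants merge into one clipped region; distant ones split", {
  x <- data.frame(chrom = "1", pos = c(1000000, 2500000),
                  mlog10p = c(12, 15))
  r <- define_regions(x, flank = 1e6)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1)
  expect_equal(r$end, 3500000)
  expect_equal(r$sentinel_pos, 2500000)
  x2 <- data.frame(chrom = "1", pos = c(1e6, 4e6), mlog10p = c(12, 15))
  r2 <- define_regions(x2, flank = 1e6)
  expect_equal(nrow(r2), 2)
  # exactly-touching intervals merge (closed-interval semantics)
  x3 <- data.frame(chrom = "1", pos = c(1e6, 3e6), mlog10p = c(12, 15))
  expect_equal(nrow(define_regions(x3, flank = 1e6)), 1)
  expect_equal(nrow(define_regions(x3[0, ], flank = 1e6)), 0)
})

test_that("region merging equals the interval-union oracle, is idempotent and order-invariant", {
  set.seed(101)
  for (rep in 1:5) {
    pos <- sort(sample.int(5e7, 100))
    x <- data.frame(chrom = "1", pos = pos, mlog10p = runif(100, 10, 40))
    r <- define_regions(x, flank = 1e6)
    oracle <- interval_union(pmax(1, pos - 1e6), pos + 1e6)
    expect_equal(r$start, oracle$start)
    expect_equal(r$end, oracle$end)
    # every variant in exactly one region
    n_hit <- sapply(pos, function(p) sum(p >= r$start & p <= r$end))
    expect_true(all(n_hit == 1))
    # permutation invariance
    perm <- sample.int(100)
    r_perm <- define_regions(x[perm, ], flank = 1e6)
    expect_equal(r_perm, r)
    # idempotence: regions of the sentinels reproduce containing regions
    sent <- data.frame(chrom = "1", pos = r$sentinel_pos,
                       mlog10p = r$sentinel_mlog10p)
    r2 <- define_regions(sent, flank = 1e6)
    expect_true(all(r2$sentinel_pos == r$sentinel_pos))
  }
  skip_if_not_installed("IRanges")
  pos <- sort(sample.int(3e7, 60))
  x <- data.frame(chrom = "1", pos = pos, mlog10p = runif(60, 10, 30))
  r <- define_regions(x, flank = 1e6)
  ir <- IRanges::reduce(IRanges::IRanges(pmax(1, pos - 1e6), pos + 1e6))
  expect_equal(r$start, IRanges::start(ir))
  expect_equal(r$end, IRanges::end(ir))
})

test_that("sentinel tie-break is lowest p, then largest |z|, then smallest position", {
  x <- data.frame(chrom = "1", pos = c(100, 200, 300),
                  mlog10p = c(15, 15, 15), z_meta = c(8, -9, 9))
  r <- define_regions(x, flank = 1e6)
  expect_equal(r$sentinel_pos, 200)  # |z| = 9 first at pos 200
})

test_that("cis/trans labels follow the 1 Mb TSS rule", {
  reg <- data.frame(chrom = "1", sentinel_pos = 5e6)
  expect_equal(classify_cis_trans(reg, tss = 5.5e6, tss_chrom = "1"), "cis")
  expect_equal(classify_cis_trans(reg, tss = 6e6, tss_chrom = "1"), "cis")   # exactly 1 Mb
  expect_equal(classify_cis_trans(reg, tss = 1e7, tss_chrom = "1"), "trans")
  expect_equal(classify_cis_trans(reg, tss = 5e6, tss_chrom = "2"), "trans")
  expect_equal(classify_cis_trans(reg, tss = NA, tss_chrom = "1"), "unclassified")
})

test_that("with orthogonal LD the stepwise fit reduces to marginal per-variant tests", {
  panel <- ar1_panel(m = 12, rho = 0, seed = 51)
  ids <- panel$variants$id
  beta_true <- setNames(c(0.25, 0.2, 0.15), ids[c(2, 6, 10)])
  set.seed(4)
  z <- draw_region_z(panel, beta_true, n = 14824)
  st <- stats_from_z(panel, z, n = 14824)
  sel <- conditional_stepwise(st, panel$ld)
  # all three planted variants selected, joint == marginal
  expect_setequal(sel$id, ids[c(2, 6, 10)])
  expect_equal(sel$beta_joint, sel$beta_marginal, tolerance = 1e-10)
  i <- match(sel$id, st$id)
  expect_equal(sel$beta_joint / sel$se_joint, st$beta[i] / st$se[i],
               tolerance = 1e-8)
  # selection order follows marginal significance
  expect_equal(sel$id, st$id[i][order(-st$mlog10p[i])])
})

test_that("two weakly linked causal variants are both found; a pure-LD shadow adds no extra signal", {
  panel <- ar1_panel(m = 50, rho = 0.8, seed = 52)
  ids <- panel$variants$id
  causal <- ids[c(15, 29)]          # 14 steps apart: r^2 ~ 0.002
  f2 <- panel$variants$eaf[c(15, 29)]
  b2 <- c(9, 8.5) / sqrt(14824 * 2 * f2 * (1 - f2))   # marginal z ~ 9, 8.5
  hits2 <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    set.seed(600 + i)
    z <- draw_region_z(panel, setNames(b2, causal), n = 14824)
    st <- stats_from_z(panel, z, n = 14824)
    sel <- conditional_stepwise(st, panel$ld)
    if (nrow(sel) == 2) hits2 <- hits2 + 1L
  }
  expect_gte(hits2 / n_rep, 0.9)

  # near-perfect shadow (r^2 ~ 0.95 with the causal variant, no effect
  # of its own): the procedure must never report it as an additional
  # signal alongside the causal variant it tags
  panel_hi <- ar1_panel(m = 30, rho = 0.975, seed = 55)
  ids_hi <- panel_hi$variants$id
  b_hi <- 9 / sqrt(14824 * 2 * panel_hi$variants$eaf[10] *
                     (1 - panel_hi$variants$eaf[10]))
  double_counts <- 0L
  for (i in seq_len(n_rep)) {
    set.seed(660 + i)
    z <- draw_region_z(panel_hi, setNames(b_hi, ids_hi[10]), n = 14824)
    sel <- conditional_stepwise(stats_from_z(panel_hi, z), panel_hi$ld)
    if (all(ids_hi[c(10, 11)] %in% sel$id)) double_counts <- double_counts + 1L
  }
  expect_equal(double_counts, 0L)
})

test_that("one causal variant among 49 LD proxies yields exactly one signal", {
  panel <- ar1_panel(m = 50, rho = 0.9, seed = 53)
  b1 <- 10 / sqrt(14824 * 2 * panel$variants$eaf[25] *
                    (1 - panel$variants$eaf[25]))   # marginal z ~ 10
  one <- 0L
  for (i in 1:30) {
    set.seed(900 + i)
    z <- draw_region_z(panel, setNames(b1, panel$variants$id[25]), n = 14824)
    st <- stats_from_z(panel, z, n = 14824)
    sel <- conditional_stepwise(st, panel$ld)
    if (nrow(sel) == 1) one <- one + 1L
  }
  expect_gte(one / 30, 0.9)
})

test_that("pruning keeps the lower-p member of linked pairs and forces sentinels", {
  panel <- ar1_panel(m = 10, rho = 0.5, seed = 54)
  ids <- panel$variants$id
  x <- data.frame(id = ids[c(1, 2, 8)], mlog10p = c(20, 30, 15))
  # r(1,2) = 0.5 (r2 = 0.25 > 0.1): keep the stronger (id 2);
  # r(2,8) = 0.5^6 (r2 ~ 2e-4): id 8 independent
  pruned <- prune_signals(x, panel$ld, r2_max = 0.1)
  expect_setequal(pruned$id, ids[c(2, 8)])
  # forcing the weaker one as sentinel inverts the outcome
  pruned2 <- prune_signals(x, panel$ld, r2_max = 0.1, forced = ids[1])
  expect_true(ids[1] %in% pruned2$id)
  expect_false(ids[2] %in% pruned2$id)
  # mutually independent set unchanged (max r2 = 0.5^8 ~ 0.004)
  y <- data.frame(id = ids[c(1, 5, 10)], mlog10p = c(12, 11, 10))
  expect_equal(nrow(prune_signals(y, panel$ld, r2_max = 0.1)), 3)
})

test_that("variance explained follows the chi-square formula and is additive", {
  expect_equal(compute_pve(0, 0.1, 1000)$pve, 0)
  # chi2 = 100, N = 1000 -> 100/1098
  one <- compute_pve(1, 0.1, 1000)
  expect_equal(one$pve, 100 / 1098, tolerance = 1e-12)
  expect_equal(one$pve, 0.09107, tolerance = 1e-4)
  many <- compute_pve(c(1, 0.5), c(0.1, 0.1), c(1000, 2000))
  expect_equal(many$pve,
               compute_pve(1, 0.1, 1000)$pve + compute_pve(0.5, 0.1, 2000)$pve,
               tolerance = 1e-12)
  expect_true(all(many$terms >= 0 & many$terms < 1))
  expect_error(compute_pve(1, 0.1, 2), "exceed 2")
})
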