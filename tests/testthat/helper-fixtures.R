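# Shared fixture builders: small AR(1) panels, summary statistics drawn
# from the sampling distribution of marginal z-scores, and brute-force
# oracles used against the package implementations.

# one-block AR(1) panel of m variants
ar1_panel <- function(m = 50, rho = 0.8, seed = 1, n_blocks = 1,
                      maf_range = c(0.1, 0.5)) {
  cfg <- sim_config(n_cohorts = 1, cohort_ns = 1000, n_blocks = n_blocks,
                    block_size = m, rho = rho, maf_range = maf_range,
                    seed = seed)
  simulate_ld_panel(cfg)
}

# draw a marginal z vector for the panel given per-allele true effects
# (named by variant id), using the same sampling theory as the
# generator but standalone so tests control every input
draw_region_z <- function(panel, beta_true = NULL, n = 14824) {
  v <- panel$variants
  b <- numeric(nrow(v))
  if (!is.null(beta_true))
    b[match(names(beta_true), v$id)] <- beta_true
  b_std <- b * sqrt(2 * v$eaf * (1 - v$eaf))
  ch <- chol(panel$ld$r + diag(1e-8, nrow(panel$ld$r)))
  mu <- sqrt(n) * drop(panel$ld$r %*% b_std)
  mu + drop(crossprod(ch, rnorm(nrow(v))))
}

# wrap a z vector as a canonical summary-statistics table for the panel
stats_from_z <- function(panel, z, n = 14824) {
  v <- panel$variants
  se <- 1 / sqrt(2 * v$eaf * (1 - v$eaf) * n)
  sumstats(chrom = v$chrom, pos = v$pos, ea = v$ea, oa = v$oa,
           eaf = v$eaf, beta = z * se, se = se, n = n,
           info = 1, hwe_p = 0.5, id = v$id)
}

# exhaustive hypergeometric two-sided Fisher p for a 2x2 table
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n0 <- c + d; k <- a + c
  x <- max(0, k - n0):min(k, m)
  probs <- dhyper(x, m, n0, k)
  obs <- dhyper(a, m, n0, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force closed-interval union on one chromosome
interval_union <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  if (length(start) > 1) for (i in 2:length(start)) {
    if (start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[i])
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}
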