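# Synthetic multi-cohort GWAS summary statistics with known ground truth.
#
# The fast path draws marginal effect estimates directly from their
# sampling distribution given the LD structure (for a standardized trait
# and standardized genotypes, E[z_j] = sqrt(N) * sum_k r_jk * beta_std_k
# and cov(z) = R), which is orders of magnitude faster than simulating
# individuals and regressing. A slow individual-level path is kept for
# cross-validation of the fast path.

#' Default per-cohort sample sizes
#'
#' Unequal sizes emulating an 11-cohort consortium of general-population
#' cohorts totalling ~14,800 participants; recycled for other cohort
#' counts.
#'
#' @param n_cohorts Number of cohorts.
#' @return Numeric vector of sample sizes.
#' @export
default_cohort_ns <- function(n_cohorts = 11) {
  base <- c(3200, 2400, 1900, 1500, 1300, 1100, 1000, 900, 700, 500, 300)
  rep_len(base, n_cohorts)
}

#' Simulation configuration
#'
#' Defines the multi-cohort design the generator emulates: several
#' European-ancestry-style cohorts of unequal size contributing
#' summary statistics over a panel of LD blocks.
#'
#' @param n_cohorts Number of cohorts (default 11, the multi-cohort
#'   design the pipeline targets).
#' @param cohort_ns Per-cohort sample sizes; defaults to sizes summing to
#'   ~14,800 across 11 cohorts.
#' @param n_blocks Number of mutually uncorrelated LD blocks.
#' @param block_size Variants per block.
#' @param rho Within-block AR(1) dosage correlation, in \[0, 1).
#' @param maf_range Interval from which minor-allele frequencies are
#'   drawn, subset of (0, 0.5\].
#' @param seed Integer random seed; all generator output is a
#'   deterministic function of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 11,
                       cohort_ns = NULL,
                       n_blocks = 4,
                       block_size = 50,
                       rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  if (is.null(cohort_ns)) cohort_ns <- default_cohort_ns(n_cohorts)
  stopifnot(length(cohort_ns) == n_cohorts, all(cohort_ns >= 2),
            rho >= 0, rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  structure(list(n_cohorts = n_cohorts, cohort_ns = as.numeric(cohort_ns),
                 n_blocks = n_blocks, block_size = block_size, rho = rho,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth table for planted signals
#'
#' @param trait Trait identifier each planted signal acts on (protein,
#'   transcript or disease name).
#' @param variant_id Causal variant id (must exist in the panel).
#' @param beta_true True per-allele effect on the standardized trait
#'   (liability/log-odds for disease).
#' @param shared_with Optional character vector (one `;`-separated string
#'   per row) of other traits sharing this causal variant.
#' @param tau Between-cohort heterogeneity SD of the true effect.
#' @return A `data.frame` of class `truth_table`.
#' @export
truth_table <- function(trait, variant_id, beta_true,
                        shared_with = "", tau = 0) {
  out <- data.frame(trait = as.character(trait),
                    variant_id = as.character(variant_id),
                    beta_true = as.numeric(beta_true),
                    shared_with = rep_len(shared_with, length(trait)),
                    tau = rep_len(tau, length(trait)),
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", class(out))
  out
}

#' Simulate a variant panel with block-diagonal AR(1) LD
#'
#' Generates `n_blocks * block_size` variants laid out on a synthetic
#' chromosome (5 kb spacing within blocks, 10 Mb gaps between blocks so
#' blocks never fall in one merged locus) with within-block allelic
#' correlation \eqn{r_{ij} = \rho^{|i-j|}} and independence across blocks.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome label for the panel.
#' @return A list with `variants` (panel table with MAFs) and `ld`
#'   (an [ld_reference()] holding the analytic correlation matrix).
#' @export
simulate_ld_panel <- function(config, chrom = "1") {
  set.seed(config$seed)
  m <- config$n_blocks * config$block_size
  block <- rep(seq_len(config$n_blocks), each = config$block_size)
  within <- sequence(rep(config$block_size, config$n_blocks))
  pos <- (block - 1) * 1e7 + within * 5000L
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # avoid strand-ambiguous (A/T, C/G) pairs, as a QC'd imputation panel would
  alleles <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, c(a, comp[a])), 1), "")
  variants <- data.frame(
    chrom = chrom, pos = as.integer(pos), ea = ea, oa = oa,
    eaf = maf, block = block, stringsAsFactors = FALSE
  )
  variants$id <- paste(variants$chrom, variants$pos, variants$ea,
                       variants$oa, sep = ":")
  r <- matrix(0, m, m)
  for (b in seq_len(config$n_blocks)) {
    i <- which(block == b)
    r[i, i] <- config$rho^abs(outer(within[i], within[i], "-"))
  }
  list(variants = variants, ld = ld_reference(variants, r, n_ref = 10000L))
}

# beta (per-allele, standardized trait) -> standardized-genotype scale
.beta_std <- function(beta, f) beta * sqrt(2 * f * (1 - f))

# Draw one cohort's marginal z-vector given true standardized effects.
# z ~ MVN(sqrt(n_eff) * R %*% beta_std, R); chol_r is chol(R + ridge).
.draw_marginal_z <- function(chol_r, r, beta_std, n_eff) {
  mu <- sqrt(n_eff) * drop(r %*% beta_std)
  mu + drop(crossprod(chol_r, stats::rnorm(nrow(r))))
}

.panel_chol <- function(ld) {
  chol(ld$r + diag(1e-8, nrow(ld$r)))
}

#' Simulate per-cohort quantitative-trait GWAS summary statistics
#'
#' Emulates additive linear-model association scans of an inverse-rank
#' normalized trait (variance 1) in each cohort: marginal estimates are
#' drawn from their sampling distribution given the LD panel, with the
#' per-cohort true effect perturbed by `N(0, tau^2)` heterogeneity.
#'
#' @param panel Output of [simulate_ld_panel()].
#' @param truth A [truth_table()] restricted to one trait.
#' @param config A [sim_config()].
#' @param trait Trait name; only `truth` rows for this trait are planted.
#' @param seed_offset Integer added to `config$seed` so different traits
#'   get independent draws under one config.
#' @return A list of canonical summary-statistics tables, one per cohort.
#' @export
simulate_protein_gwas <- function(panel, truth, config, trait = NULL,
                                  seed_offset = 0L) {
  tr <- truth
  if (!is.null(trait)) tr <- truth[truth$trait == trait, , drop = FALSE]
  miss <- setdiff(tr$variant_id, panel$variants$id)
  if (length(miss))
    stop("planted causal variant(s) absent from panel: ",
         paste(miss, collapse = ", "))
  v <- panel$variants
  m <- nrow(v)
  chol_r <- .panel_chol(panel$ld)
  idx <- match(tr$variant_id, v$id)
  cohorts <- vector("list", config$n_cohorts)
  for (cix in seq_len(config$n_cohorts)) {
    # single independent stream per cohort
    set.seed(config$seed + seed_offset + 1000L * cix)
    n_c <- config$cohort_ns[cix]
    b_true <- numeric(m)
    if (length(idx))
      b_true[idx] <- tr$beta_true + stats::rnorm(length(idx), 0, tr$tau)
    z <- .draw_marginal_z(chol_r, panel$ld$r, .beta_std(b_true, v$eaf), n_c)
    se <- 1 / sqrt(2 * v$eaf * (1 - v$eaf) * n_c)
    cohorts[[cix]] <- sumstats(
      chrom = v$chrom, pos = v$pos, ea = v$ea, oa = v$oa, eaf = v$eaf,
      beta = z * se, se = se, n = n_c,
      info = 1, hwe_p = 0.5, id = v$id
    )
  }
  names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
  cohorts
}

#' Simulate a case-control disease GWAS under a protein-liability model
#'
#' Disease log-odds effects at the protein's causal variants are
#' `theta * beta_protein` (vertical pleiotropy: the protein causes the
#' disease). Under `confounder_mode = "ld_confounded"` the disease effect
#' is instead carried by a distinct variant in LD with the protein signal
#' — the scenario HEIDI filtering and conditional colocalization must
#' flag.
#'
#' @param panel Output of [simulate_ld_panel()].
#' @param protein_truth [truth_table()] rows for the exposure protein.
#' @param theta Causal effect of 1 SD of protein on disease log-odds.
#' @param confounder_mode `"none"` or `"ld_confounded"`.
#' @param config A [sim_config()].
#' @param n_cases,n_controls Case/control counts of the disease GWAS.
#' @param confounder_r2 Target LD r² between each protein causal variant
#'   and its confounding neighbour (nearest panel variant achieving it).
#' @param confounder_beta Log-odds effect of each confounding variant.
#' @param seed_offset Stream offset, as in [simulate_protein_gwas()].
#' @return One canonical summary-statistics table (log-odds scale) with
#'   attribute `disease_truth` describing the planted disease effects.
#' @export
simulate_disease_gwas <- function(panel, protein_truth, theta,
                                  confounder_mode = c("none", "ld_confounded"),
                                  config,
                                  n_cases = 10000, n_controls = 30000,
                                  confounder_r2 = 0.3,
                                  confounder_beta = 0.15,
                                  seed_offset = 500L) {
  confounder_mode <- match.arg(confounder_mode)
  stopifnot(is.finite(theta))
  v <- panel$variants
  m <- nrow(v)
  idx <- match(protein_truth$variant_id, v$id)
  if (anyNA(idx)) stop("protein causal variant absent from panel")
  gamma <- numeric(m)
  if (confounder_mode == "none") {
    gamma[idx] <- theta * protein_truth$beta_true
  } else {
    for (i in idx) {
      r2 <- panel$ld$r[i, ]^2
      cand <- which(abs(r2 - confounder_r2) < 0.15 & seq_len(m) != i)
      if (!length(cand)) cand <- setdiff(order(abs(r2 - confounder_r2)), i)[1]
      j <- cand[which.min(abs(r2[cand] - confounder_r2))]
      gamma[j] <- gamma[j] + confounder_beta
    }
  }
  n_total <- n_cases + n_controls
  phi <- n_cases / n_total
  n_eff <- n_total * phi * (1 - phi)    # effective N on the log-odds scale
  set.seed(config$seed + seed_offset)
  chol_r <- .panel_chol(panel$ld)
  z <- .draw_marginal_z(chol_r, panel$ld$r, .beta_std(gamma, v$eaf), n_eff)
  se <- 1 / sqrt(2 * v$eaf * (1 - v$eaf) * n_eff)
  out <- sumstats(
    chrom = v$chrom, pos = v$pos, ea = v$ea, oa = v$oa, eaf = v$eaf,
    beta = z * se, se = se, n = n_total,
    info = 1, hwe_p = 0.5, id = v$id
  )
  attr(out, "disease_truth") <- data.frame(
    variant_id = v$id[gamma != 0], gamma = gamma[gamma != 0],
    mode = rep_len(confounder_mode, sum(gamma != 0)),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulate imputed genotype dosages for a panel
#'
#' Draws continuous (imputation-style) allele dosages with mean \eqn{2f},
#' variance \eqn{2f(1-f)} and pairwise correlation equal to the panel's
#' analytic LD matrix, so the empirical correlation of a large dosage
#' table converges to the analytic `r` of the panel.
#'
#' @param panel Output of [simulate_ld_panel()].
#' @param n Number of simulated genomes (rows).
#' @param seed Random seed.
#' @return An `n x m` dosage matrix with variant ids as column names.
#' @export
simulate_dosages <- function(panel, n, seed = 1L) {
  set.seed(seed)
  v <- panel$variants
  m <- nrow(v)
  chol_r <- .panel_chol(panel$ld)
  lat <- matrix(stats::rnorm(n * m), n, m) %*% chol_r
  g <- sweep(lat, 2, sqrt(2 * v$eaf * (1 - v$eaf)), "*")
  g <- sweep(g, 2, 2 * v$eaf, "+")
  colnames(g) <- v$id
  g
}

#' Individual-level cross-validation path
#'
#' Simulates genotype dosages and the quantitative trait explicitly and
#' runs per-variant linear regressions. Slow; used only to validate the
#' sampling-theory fast path on small panels.
#'
#' @inheritParams simulate_protein_gwas
#' @param n Sample size for the single simulated cohort.
#' @return A canonical summary-statistics table.
#' @export
simulate_individual_gwas <- function(panel, truth, config, n = 2000) {
  v <- panel$variants
  m <- nrow(v)
  g <- simulate_dosages(panel, n, seed = config$seed + 77L)
  idx <- match(truth$variant_id, v$id)
  b_std <- numeric(m)
  b_std[idx] <- .beta_std(truth$beta_true, v$eaf[idx])
  y_g <- drop(scale(g) %*% b_std)
  y <- y_g + stats::rnorm(n, 0, sqrt(max(1e-8, 1 - stats::var(y_g))))
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    fit <- stats::lm.fit(cbind(1, g[, j]), y)
    s2 <- sum(fit$residuals^2) / (n - 2)
    xx <- sum((g[, j] - mean(g[, j]))^2)
    beta[j] <- fit$coefficients[2]
    se[j] <- sqrt(s2 / xx)
  }
  sumstats(chrom = v$chrom, pos = v$pos, ea = v$ea, oa = v$oa, eaf = v$eaf,
           beta = beta, se = se, n = n, info = 1, hwe_p = 0.5, id = v$id)
}
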