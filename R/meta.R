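# Fixed-effects inverse-variance meta-analysis of cohort-level pQTL
# summary statistics, with the presence / significance / heterogeneity
# filters applied to every variant.

#' Cohort-level quality control
#'
#' Keeps a record iff its minor-allele frequency, Hardy-Weinberg p-value
#' and imputation quality pass the configured floors. Missing optional
#' fields (`hwe_p`, `info`) do not cause exclusion.
#'
#' @param x Canonical summary-statistics table.
#' @param maf_min Minimum minor-allele frequency (default 0.001),
#'   boundary inclusive.
#' @param hwe_min Hardy-Weinberg exclusion threshold: kept iff
#'   `hwe_p > hwe_min` (default 1e-6).
#' @param info_min Minimum imputation quality (default 0.3), boundary
#'   inclusive.
#' @return The filtered table with attribute `qc_drops` counting
#'   exclusions per filter.
#' @export
cohort_qc <- function(x, maf_min = 0.001, hwe_min = 1e-6, info_min = 0.3) {
  maf <- pmin(x$eaf, 1 - x$eaf)
  ok_maf <- !is.na(maf) & maf >= maf_min
  ok_hwe <- is.na(x$hwe_p) | x$hwe_p > hwe_min
  ok_info <- is.na(x$info) | x$info >= info_min
  keep <- ok_maf & ok_hwe & ok_info
  out <- x[keep, , drop = FALSE]
  attr(out, "qc_drops") <- c(maf = sum(!ok_maf),
                             hwe = sum(ok_maf & !ok_hwe),
                             info = sum(ok_maf & ok_hwe & !ok_info))
  out
}

#' Fixed-effects inverse-variance pooling for one variant
#'
#' @param beta Per-cohort effect estimates (common effect allele).
#' @param se Per-cohort standard errors, all > 0.
#' @return A list with `beta_meta`, `se_meta`, `z_meta`, `p_meta`,
#'   `mlog10p`, `Q` (Cochran's statistic), `I2` (percent), `k_studies`.
#' @export
meta_fixed <- function(beta, se) {
  if (any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sm <- 1 / sqrt(sum(w))
  z <- bm / sm
  k <- length(beta)
  Q <- sum(w * (beta - bm)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(beta_meta = bm, se_meta = sm, z_meta = z,
       p_meta = p_from_z(z), mlog10p = mlog10p_from_z(z),
       Q = Q, I2 = I2, k_studies = k)
}

#' Meta-analyse a set of cohorts across all variants
#'
#' Harmonizes every cohort to the allele orientation of the first cohort
#' in which each variant appears, pools with fixed-effects
#' inverse-variance weights, and records per-variant heterogeneity and
#' per-cohort support needed by the significance filters.
#'
#' @param cohorts Named list of canonical summary-statistics tables.
#' @param support_p Per-cohort p-value defining a "supporting" cohort for
#'   the heterogeneity consistency rule (default 0.05).
#' @return A `data.frame` with one row per variant: identity columns,
#'   `eaf` (weighted mean), `beta_meta, se_meta, z_meta, p_meta, mlog10p,
#'   Q, I2, k_studies, n_total`, `directions` (one `+`/`-`/`?` per cohort
#'   in input order) and `n_support` (cohorts with p < `support_p` and
#'   sign agreeing with the pooled effect).
#' @export
meta_analyse <- function(cohorts, support_p = 0.05) {
  stopifnot(length(cohorts) >= 1)
  # reference orientation: first appearance of each site
  ref <- NULL
  for (ch in cohorts) {
    add <- ch[!paste(ch$chrom, ch$pos) %in%
                if (is.null(ref)) character() else paste(ref$chrom, ref$pos),
              c("chrom", "pos", "ea", "oa", "eaf", "id")]
    ref <- rbind(ref, add)
  }
  ref <- ref[order(ref$chrom, ref$pos), , drop = FALSE]
  m <- nrow(ref)
  k <- length(cohorts)
  B <- S <- P <- matrix(NA_real_, m, k)
  Nm <- matrix(0, m, k)
  key_ref <- paste(ref$chrom, ref$pos)
  for (cix in seq_len(k)) {
    h <- harmonize(cohorts[[cix]], ref)
    h <- h[h$match != "unmatchable", , drop = FALSE]
    i <- match(paste(h$chrom, h$pos), key_ref)
    B[i, cix] <- h$beta
    S[i, cix] <- h$se
    P[i, cix] <- h$p
    Nm[i, cix] <- h$n
  }
  W <- 1 / S^2
  W[is.na(W)] <- 0
  Bz <- B; Bz[is.na(Bz)] <- 0
  sw <- rowSums(W)
  bm <- rowSums(W * Bz) / sw
  sm <- 1 / sqrt(sw)
  z <- bm / sm
  kk <- rowSums(!is.na(B))
  Q <- rowSums(W * (Bz - bm)^2)
  I2 <- ifelse(Q > 0, pmax(0, (Q - (kk - 1)) / Q) * 100, 0)
  dirs <- matrix("?", m, k)
  dirs[!is.na(B) & B > 0] <- "+"
  dirs[!is.na(B) & B <= 0] <- "-"
  support <- rowSums(!is.na(P) & P < support_p &
                       sign(B) == rep(sign(bm), k), na.rm = TRUE)
  data.frame(
    ref[, c("chrom", "pos", "ea", "oa", "id")],
    eaf = ref$eaf,
    beta_meta = bm, se_meta = sm, z_meta = z,
    p_meta = p_from_z(z), mlog10p = mlog10p_from_z(z),
    Q = Q, I2 = I2, k_studies = kk, n_total = rowSums(Nm * !is.na(B)),
    directions = apply(dirs, 1, paste, collapse = ""),
    n_support = support,
    stringsAsFactors = FALSE
  )
}

#' Apply the presence / significance / heterogeneity filters
#'
#' Assigns each meta-analysed variant one of four verdicts:
#' * `excluded` — present in fewer than `min_studies` cohorts or fewer
#'   than `min_n` participants;
#' * `not_significant` — pooled p above `p_sig`;
#' * `filtered_heterogeneous` — pooled p at or below `p_sig` but
#'   heterogeneity `I2 > i2_max` without at least `min_consistent`
#'   cohorts individually supporting the effect (p < 0.05, direction
#'   matching the pooled estimate);
#' * `significant` — everything else.
#'
#' Threshold conventions: p compared with `<=`, I² with strict `>`.
#' The p comparison is done in -log10 space so extreme signals never
#' underflow.
#'
#' @param meta Output of [meta_analyse()].
#' @param p_sig Study-wide significance threshold (default 5e-10).
#' @param i2_max Heterogeneity tolerance in percent (default 30).
#' @param min_studies,min_n Presence floors (defaults 3 studies,
#'   3,500 participants).
#' @param min_consistent Supporting-cohort count required when
#'   heterogeneous (default 3).
#' @return `meta` with an added `verdict` factor column.
#' @export
apply_meta_filters <- function(meta, p_sig = 5e-10, i2_max = 30,
                               min_studies = 3, min_n = 3500,
                               min_consistent = 3) {
  ml_sig <- -log10(p_sig)
  verdict <- rep("significant", nrow(meta))
  verdict[meta$mlog10p < ml_sig] <- "not_significant"
  het <- meta$mlog10p >= ml_sig & meta$I2 > i2_max &
    meta$n_support < min_consistent
  verdict[het] <- "filtered_heterogeneous"
  verdict[meta$k_studies < min_studies | meta$n_total < min_n] <- "excluded"
  meta$verdict <- factor(verdict, levels = c("excluded", "not_significant",
                                             "significant",
                                             "filtered_heterogeneous"))
  meta
}

#' Study-wide significance threshold
#'
#' Bonferroni correction of the conventional genome-wide threshold for
#' the number of (approximately independent) protein GWAS analysed.
#'
#' @param genome_wide Base genome-wide threshold (default 5e-8).
#' @param n_traits Number of traits tested (default 100).
#' @return `genome_wide / n_traits` (5e-10 at the defaults).
#' @export
study_wide_threshold <- function(genome_wide = 5e-8, n_traits = 100) {
  genome_wide / n_traits
}

#' Bonferroni replication threshold
#'
#' @param alpha Family-wise error target (default 0.05).
#' @param n_signals Number of discovery signals taken to replication.
#' @return `alpha / n_signals`.
#' @export
replication_threshold <- function(alpha = 0.05, n_signals) {
  alpha / n_signals
}

#' Genomic-control inflation factor
#'
#' Median-based lambda of a vector of two-sided p-values (or z-scores).
#' Reported per protein for diagnostics; never used to rescale results.
#'
#' @param p Two-sided p-values (ignored if `z` given).
#' @param z Optional z-scores.
#' @return Lambda (1 under the null).
#' @export
genomic_lambda <- function(p = NULL, z = NULL) {
  chisq <- if (!is.null(z)) z^2 else stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Compare discovery signals with a replication cohort
#'
#' Harmonizes the replication records to the discovery orientation and
#' reports testability, directional concordance, the Pearson correlation
#' of effect estimates and replication counts at the study-wide and a
#' Bonferroni-corrected threshold.
#'
#' @param discovery Meta-analysis rows for the discovery signals
#'   (columns `chrom, pos, ea, oa, beta_meta, mlog10p`).
#' @param replication Canonical summary-statistics table from the
#'   replication cohort.
#' @param p_strict Strict replication threshold (default 5e-10).
#' @param alpha Family-wise error rate for the Bonferroni threshold
#'   (default 0.05 over the number of discovery signals).
#' @return A list: `n_signals`, `n_testable`, `n_concordant`,
#'   `pearson_r`, `p_bonferroni`, `n_rep_strict`, `n_rep_bonferroni`,
#'   and the merged per-signal table. Empty overlap is flagged via
#'   `n_testable = 0`.
#' @export
compare_replication <- function(discovery, replication,
                                p_strict = 5e-10, alpha = 0.05) {
  n_signals <- nrow(discovery)
  h <- harmonize(replication, discovery)
  h <- h[h$match != "unmatchable", , drop = FALSE]
  i <- match(paste(h$chrom, h$pos), paste(discovery$chrom, discovery$pos))
  merged <- data.frame(
    discovery[i, c("chrom", "pos", "ea", "oa")],
    beta_disc = discovery$beta_meta[i],
    beta_rep = h$beta, se_rep = h$se,
    mlog10p_rep = h$mlog10p,
    stringsAsFactors = FALSE
  )
  n_testable <- nrow(merged)
  if (n_testable == 0)
    warning("no overlapping variants between discovery and replication")
  conc <- sum(sign(merged$beta_disc) == sign(merged$beta_rep))
  r <- if (n_testable >= 3) stats::cor(merged$beta_disc, merged$beta_rep)
       else NA_real_
  p_bonf <- replication_threshold(alpha, n_signals)
  list(
    n_signals = n_signals,
    n_testable = n_testable,
    n_concordant = conc,
    pearson_r = r,
    p_bonferroni = p_bonf,
    n_rep_strict = sum(merged$mlog10p_rep >= -log10(p_strict)),
    n_rep_bonferroni = sum(merged$mlog10p_rep >= -log10(p_bonf)),
    table = merged
  )
}
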