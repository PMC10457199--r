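# Locus-level signal definition: region merging, sentinel selection,
# cis/trans classification, approximate stepwise conditional analysis
# from summary statistics plus an LD reference, LD pruning, and the
# proportion of protein variance explained.

#' Merge significant variants into locus regions and pick sentinels
#'
#' Each significant variant contributes a closed interval of
#' `pos - flank` to `pos + flank` (left-clipped at 1); overlapping or
#' exactly touching intervals on one chromosome are merged transitively
#' until no overlap remains. The sentinel of each merged region is the
#' variant with the lowest p (ties: largest |z|, then smallest
#' position).
#'
#' @param x Data frame of significant variants with columns
#'   `chrom, pos, mlog10p` (or `p`) and optionally `z_meta`, `id`.
#' @param flank Flank size in bp (default 1,000,000).
#' @return A `data.frame` of regions: `chrom, start, end, n_variants`,
#'   sentinel columns (`sentinel_id, sentinel_pos, sentinel_mlog10p`).
#'   Empty input gives an empty frame.
#' @export
define_regions <- function(x, flank = 1e6) {
  cols <- c("chrom", "start", "end", "n_variants",
            "sentinel_id", "sentinel_pos", "sentinel_mlog10p")
  if (nrow(x) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  if (!"mlog10p" %in% names(x)) x$mlog10p <- -log10(x$p)
  if (!"id" %in% names(x)) x$id <- paste(x$chrom, x$pos, sep = ":")
  if (!"z_meta" %in% names(x)) x$z_meta <- NA_real_
  out <- NULL
  for (ch in unique(x$chrom)) {
    v <- x[x$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    start <- pmax(1, v$pos - flank)
    end <- v$pos + flank
    # sweep over position-sorted intervals; touching counts as overlap
    grp <- cumsum(c(1, as.integer(start[-1] > cummax(end[-length(end)]))))
    for (g in unique(grp)) {
      i <- which(grp == g)
      vi <- v[i, , drop = FALSE]
      ord <- order(-vi$mlog10p, -abs(vi$z_meta), vi$pos)
      s <- vi[ord[1], ]
      out <- rbind(out, data.frame(
        chrom = ch, start = min(start[i]), end = max(end[i]),
        n_variants = length(i),
        sentinel_id = s$id, sentinel_pos = s$pos,
        sentinel_mlog10p = s$mlog10p,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify a pQTL region as cis or trans
#'
#' A signal is cis iff its sentinel lies on the chromosome of the gene
#' encoding the target protein and within 1 Mb of its transcription
#' start site; otherwise trans. Unknown genes give `"unclassified"`.
#'
#' @param region One row of [define_regions()] output (needs `chrom`,
#'   `sentinel_pos`).
#' @param tss TSS position of the encoding gene (NA if unknown).
#' @param tss_chrom Chromosome of the encoding gene.
#' @param cis_window Distance defining cis (default 1,000,000 bp),
#'   boundary inclusive.
#' @return `"cis"`, `"trans"` or `"unclassified"`.
#' @export
classify_cis_trans <- function(region, tss, tss_chrom, cis_window = 1e6) {
  if (is.na(tss) || is.na(tss_chrom)) return("unclassified")
  if (region$chrom == tss_chrom &&
      abs(region$sentinel_pos - tss) <= cis_window) "cis" else "trans"
}

# Joint (multiple-regression) fit of selected variants from marginal
# stats and LD, GCTA-COJO style. D_j = 2 f_j (1-f_j) N_j approximates
# the diagonal of X'X. The phenotypic (and residual) variance is fixed
# at 1 — the trait is inverse-rank normalized and planted signals
# explain a small fraction of it — which makes the orthogonal-LD case
# reduce exactly to the marginal per-variant tests.
.cojo_joint <- function(beta, se, eaf, n, R, ridge = 0) {
  D <- 2 * eaf * (1 - eaf) * n
  A <- sqrt(D) * t(sqrt(D) * t(R))       # sqrt(D) R sqrt(D)
  if (ridge > 0) diag(A) <- diag(A) + ridge * diag(A)
  xy <- D * beta
  bj <- tryCatch(solve(A, xy), error = function(e) {
    warning("singular LD submatrix; ridge-stabilizing")
    solve(A + diag(1e-6 * mean(diag(A)), nrow(A)), xy)
  })
  sigma2 <- 1
  Ainv <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-6 * mean(diag(A)), nrow(A))))
  list(beta_joint = bj, se_joint = sqrt(sigma2 * diag(Ainv)),
       sigma2 = sigma2, D = D)
}

#' Approximate stepwise conditional analysis (COJO-style)
#'
#' Selects conditionally independent association signals in a region
#' from marginal meta-analysis statistics and an LD reference. Starting
#' from the sentinel, each step computes the approximate conditional
#' z-score of every remaining eligible candidate given the currently
#' selected set (multiple-regression algebra with per-variant diagonal
#' scaling \eqn{2 f (1-f) N} and phenotypic variance 1) and admits the
#' most significant candidate while its conditional p passes `p_enter`
#' and its LD with the selected set stays below the collinearity cap.
#'
#' @param stats Region summary statistics (canonical columns plus `id`),
#'   typically [meta_analyse()] rows renamed to `beta`/`se` or a cohort
#'   table; needs `id, beta, se, eaf, n, mlog10p`.
#' @param ld An [ld_reference()] covering the region variants.
#' @param p_enter Entry threshold (default 5e-10; eligibility also
#'   requires the marginal p to pass it).
#' @param maf_floor Minimum MAF for non-sentinel candidates
#'   (default 0.01).
#' @param collinearity Maximum r² allowed between a candidate and any
#'   selected variant (default 0.9).
#' @param sentinel Id of the forced first signal (default: lowest
#'   marginal p).
#' @return A `data.frame` of selected signals in selection order:
#'   `id, beta_marginal, beta_joint, se_joint, z_joint, mlog10p_joint`.
#'   Zero rows if no variant passes `p_enter`.
#' @export
conditional_stepwise <- function(stats, ld, p_enter = 5e-10,
                                 maf_floor = 0.01, collinearity = 0.9,
                                 sentinel = NULL) {
  stopifnot(all(stats$id %in% ld$variants$id))
  if (!"mlog10p" %in% names(stats))
    stats$mlog10p <- mlog10p_from_z(stats$beta / stats$se)
  ml_enter <- -log10(p_enter)
  if (is.null(sentinel)) sentinel <- stats$id[which.max(stats$mlog10p)]
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  eligible <- (stats$mlog10p >= ml_enter) &
    (maf >= maf_floor | stats$id == sentinel)
  if (!eligible[stats$id == sentinel] &&
      stats$mlog10p[stats$id == sentinel] < ml_enter) {
    return(data.frame(id = character(), beta_marginal = numeric(),
                      beta_joint = numeric(), se_joint = numeric(),
                      z_joint = numeric(), mlog10p_joint = numeric()))
  }
  R_all <- ld_subset(ld, stats$id)$r
  sel <- match(sentinel, stats$id)
  repeat {
    cand <- setdiff(which(eligible), sel)
    if (!length(cand)) break
    fit <- .cojo_joint(stats$beta[sel], stats$se[sel], stats$eaf[sel],
                       stats$n[sel], R_all[sel, sel, drop = FALSE])
    Rss_inv <- tryCatch(solve(R_all[sel, sel, drop = FALSE]),
                        error = function(e)
                          solve(R_all[sel, sel, drop = FALSE] +
                                  diag(1e-6, length(sel))))
    best <- NULL
    for (j in cand) {
      r_js <- R_all[j, sel]
      if (max(r_js^2) > collinearity) next
      q <- drop(r_js %*% Rss_inv %*% r_js)
      if (q >= 0.999) next
      D_j <- 2 * stats$eaf[j] * (1 - stats$eaf[j]) * stats$n[j]
      b_cond <- stats$beta[j] -
        sum(r_js * sqrt(fit$D / D_j) * fit$beta_joint)
      se_cond <- sqrt(fit$sigma2 / (D_j * (1 - q)))
      z_cond <- b_cond / se_cond
      ml <- mlog10p_from_z(z_cond)
      if (is.null(best) || ml > best$ml)
        best <- list(j = j, ml = ml)
    }
    if (is.null(best) || best$ml < ml_enter) break
    sel <- c(sel, best$j)
  }
  fit <- .cojo_joint(stats$beta[sel], stats$se[sel], stats$eaf[sel],
                     stats$n[sel], R_all[sel, sel, drop = FALSE])
  z_joint <- fit$beta_joint / fit$se_joint
  data.frame(
    id = stats$id[sel],
    beta_marginal = stats$beta[sel],
    beta_joint = fit$beta_joint,
    se_joint = fit$se_joint,
    z_joint = z_joint,
    mlog10p_joint = mlog10p_from_z(z_joint),
    stringsAsFactors = FALSE
  )
}

#' Greedy LD pruning with forced sentinels
#'
#' Keeps sentinels first, then walks remaining variants by ascending p
#' and keeps each one iff its r² with every already-kept variant is at
#' most `r2_max`.
#'
#' @param x Data frame with `id` and `mlog10p` (or `p`).
#' @param ld An [ld_reference()] covering the variants.
#' @param r2_max Independence threshold (default 0.1), boundary
#'   inclusive.
#' @param forced Ids always kept (sentinels), in priority order.
#' @return The kept subset of `x`, sentinels first.
#' @export
prune_signals <- function(x, ld, r2_max = 0.1, forced = character()) {
  if (!"mlog10p" %in% names(x)) x$mlog10p <- -log10(x$p)
  R <- ld_subset(ld, x$id)$r
  keep <- match(forced, x$id)
  keep <- keep[!is.na(keep)]
  rest <- setdiff(order(-x$mlog10p), keep)
  for (j in rest) {
    if (!length(keep) || all(R[j, keep]^2 <= r2_max)) keep <- c(keep, j)
  }
  x[keep, , drop = FALSE]
}

#' Proportion of protein variance explained by pQTL sentinels
#'
#' \deqn{\mathrm{PVE} = \sum_{i=1}^{T} \frac{\chi_i^2}{\chi_i^2 + N_i - 2}}
#' where \eqn{\chi_i^2 = (\beta_i / \mathrm{s.e.}_i)^2} and \eqn{N_i} the
#' variant's sample size.
#'
#' @param beta,se Sentinel effect estimates and standard errors.
#' @param n Per-sentinel sample sizes, > 2.
#' @return A list: `terms` (per-sentinel contributions, each in
#'   \[0, 1)), `pve` (their sum; warned about if >= 1).
#' @export
compute_pve <- function(beta, se, n) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(n <= 2)) stop("n must exceed 2")
  chi2 <- (beta / se)^2
  terms <- chi2 / (chi2 + n - 2)
  pve <- sum(terms)
  if (pve >= 1) warning("total PVE >= 1; sentinel set is not independent")
  list(terms = terms, pve = pve)
}
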