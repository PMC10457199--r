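# cis Mendelian randomization of protein exposures on disease outcomes:
# correlated-instrument selection, generalized-least-squares combination
# of Wald ratios, HEIDI outlier removal, BH FDR and the post-hoc
# robustness filters.

#' Select cis instruments for a protein exposure
#'
#' Greedy LD clumping of the exposure region by ascending p at
#' `r2 <= clump_r2`, restricted to variants at or below the selection
#' p-value threshold and with an effect-allele frequency within
#' `freq_diff_max` of the LD reference panel. Returns `"insufficient"`
#' when fewer than `min_instruments` survive.
#'
#' @param exposure Canonical summary-statistics table for the cis region
#'   (encoding gene +/- 1 Mb), with `id` matching the LD reference.
#' @param ld An [ld_reference()] whose `variants` carry reference
#'   `eaf` values.
#' @param p_thresh Selection threshold (default 5e-8).
#' @param clump_r2 Maximum pairwise r² among instruments (default 0.1).
#' @param freq_diff_max Maximum |eaf - eaf_reference| (default 0.4).
#' @param min_instruments Minimum surviving instruments (default 3).
#' @return A `data.frame` of instruments (rows of `exposure`, clump
#'   order) or the string `"insufficient"`.
#' @export
select_instruments <- function(exposure, ld, p_thresh = 5e-8,
                               clump_r2 = 0.1, freq_diff_max = 0.4,
                               min_instruments = 3) {
  x <- exposure[exposure$mlog10p >= -log10(p_thresh), , drop = FALSE]
  if (nrow(x)) {
    ref_eaf <- ld$variants$eaf[match(x$id, ld$variants$id)]
    ok <- is.na(ref_eaf) | abs(x$eaf - ref_eaf) <= freq_diff_max
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) >= 1) {
    x <- prune_signals(x, ld, r2_max = clump_r2)
  }
  if (nrow(x) < min_instruments) return("insufficient")
  x
}

#' GSMR-style causal-effect estimate with correlated instruments
#'
#' Combines per-instrument Wald ratios
#' \eqn{\hat\beta_i = b_{zy,i} / b_{zx,i}} with approximate variances
#' \eqn{v_i = (se_{zy,i}^2 + \hat\beta_i^2 se_{zx,i}^2) / b_{zx,i}^2}
#' by generalized least squares under the instrument correlation
#' structure \eqn{V_{ij} = r_{ij} \sqrt{v_i v_j}}:
#' \deqn{\hat b_{xy} = \frac{\mathbf 1^\top V^{-1} \hat\beta}
#'   {\mathbf 1^\top V^{-1} \mathbf 1}, \qquad
#'   se = \sqrt{1 / (\mathbf 1^\top V^{-1} \mathbf 1)}.}
#' With uncorrelated instruments this reduces to inverse-variance
#' weighting of the Wald ratios.
#'
#' @param b_zx,se_zx Instrument-exposure effects and SEs.
#' @param b_zy,se_zy Instrument-outcome effects and SEs (harmonized to
#'   the same effect alleles).
#' @param r Instrument correlation matrix (identity if `NULL`).
#' @return A list: `b_xy`, `se_xy`, `z_xy`, `p_xy`, `wald` (per-
#'   instrument ratios and variances).
#' @export
gsmr_estimate <- function(b_zx, se_zx, b_zy, se_zy, r = NULL) {
  k <- length(b_zx)
  stopifnot(k >= 1, length(b_zy) == k)
  if (is.null(r)) r <- diag(k)
  ratio <- b_zy / b_zx
  v <- (se_zy^2 + ratio^2 * se_zx^2) / b_zx^2
  V <- r * sqrt(outer(v, v))
  Vinv <- tryCatch(solve(V), error = function(e) {
    warning("instrument covariance not invertible; ridge-stabilizing")
    solve(V + diag(1e-6 * mean(diag(V)), k))
  })
  one <- rep(1, k)
  denom <- drop(one %*% Vinv %*% one)
  b_xy <- drop(one %*% Vinv %*% ratio) / denom
  se_xy <- sqrt(1 / denom)
  z <- b_xy / se_xy
  list(b_xy = b_xy, se_xy = se_xy, z_xy = z, p_xy = p_from_z(z),
       wald = data.frame(ratio = ratio, v = v))
}

#' HEIDI outlier filtering of instruments
#'
#' Tests every instrument's Wald ratio against the reference
#' instrument's (the one with the smallest exposure p): the difference
#' \eqn{d_i = \hat\beta_i - \hat\beta_{ref}} has delta-method variance
#' \eqn{v_i + v_{ref} - 2 r_{i,ref}\sqrt{v_i v_{ref}}} including the
#' LD-induced covariance. Instruments with two-sided `p(d) < p_heidi`
#' are removed as probable LD-confounded/pleiotropic outliers; the
#' reference itself is never removed.
#'
#' @param b_zx,se_zx,b_zy,se_zy Instrument effects as in
#'   [gsmr_estimate()].
#' @param r Instrument correlation matrix (identity if `NULL`).
#' @param exposure_p Per-instrument exposure p-values (pick the
#'   reference); defaults to p from `b_zx / se_zx`.
#' @param p_heidi Removal threshold (default 0.05).
#' @return A list: `keep` (logical), `removed` (indices), `ref` (index
#'   of the reference instrument), `p_d` (per-instrument deviation p;
#'   NA for the reference).
#' @export
heidi_outlier <- function(b_zx, se_zx, b_zy, se_zy, r = NULL,
                          exposure_p = NULL, p_heidi = 0.05) {
  k <- length(b_zx)
  if (is.null(r)) r <- diag(k)
  if (is.null(exposure_p)) exposure_p <- p_from_z(b_zx / se_zx)
  ref <- which.min(exposure_p)
  ratio <- b_zy / b_zx
  v <- (se_zy^2 + ratio^2 * se_zx^2) / b_zx^2
  d <- ratio - ratio[ref]
  var_d <- v + v[ref] - 2 * r[, ref] * sqrt(v * v[ref])
  var_d <- pmax(var_d, 1e-12)
  p_d <- p_from_z(d / sqrt(var_d))
  p_d[ref] <- NA_real_
  keep <- is.na(p_d) | p_d >= p_heidi
  list(keep = keep, removed = which(!keep), ref = ref, p_d = p_d)
}

#' Full cis-MR of one protein on one disease
#'
#' Chains instrument selection, exposure/outcome harmonization, HEIDI
#' outlier removal and the GSMR-style estimate, and reports the result
#' on the odds-ratio scale (outcome effects are log-odds; the OR is per
#' 1 SD of inverse-rank-normalized protein).
#'
#' @param exposure Cis-region exposure summary statistics.
#' @param outcome Disease GWAS summary statistics (log-odds scale).
#' @param ld An [ld_reference()] covering the region.
#' @param p_thresh,clump_r2,freq_diff_max,min_instruments Instrument
#'   selection parameters (see [select_instruments()]).
#' @param p_heidi HEIDI removal threshold (default 0.05).
#' @return A one-row `data.frame`: `status` (`"ok"` or
#'   `"insufficient"`), `b_xy, se_xy, p_xy, or_, or_lo, or_hi`,
#'   `n_instruments_selected`, `n_instruments_used`, `heidi_removed`
#'   (`;`-separated ids), `sentinel_id`.
#' @export
mr_protein_disease <- function(exposure, outcome, ld,
                               p_thresh = 5e-8, clump_r2 = 0.1,
                               freq_diff_max = 0.4, min_instruments = 3,
                               p_heidi = 0.05) {
  empty <- data.frame(
    status = "insufficient", b_xy = NA_real_, se_xy = NA_real_,
    p_xy = NA_real_, or_ = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
    n_instruments_selected = 0L, n_instruments_used = 0L,
    heidi_removed = "", sentinel_id = NA_character_,
    stringsAsFactors = FALSE
  )
  inst <- select_instruments(exposure, ld, p_thresh, clump_r2,
                             freq_diff_max, min_instruments)
  if (identical(inst, "insufficient")) return(empty)
  out_h <- harmonize(outcome, inst)
  out_h <- out_h[out_h$match != "unmatchable", , drop = FALSE]
  i <- match(paste(out_h$chrom, out_h$pos), paste(inst$chrom, inst$pos))
  inst <- inst[i[!is.na(i)], , drop = FALSE]
  out_h <- out_h[!is.na(i), , drop = FALSE]
  if (nrow(inst) < min_instruments) return(empty)
  R <- ld_subset(ld, inst$id)$r
  hd <- heidi_outlier(inst$beta, inst$se, out_h$beta, out_h$se, R,
                      exposure_p = inst$p, p_heidi = p_heidi)
  removed_ids <- inst$id[hd$removed]
  keep <- hd$keep
  if (sum(keep) < min_instruments) return(empty)
  est <- gsmr_estimate(inst$beta[keep], inst$se[keep],
                       out_h$beta[keep], out_h$se[keep],
                       R[keep, keep, drop = FALSE])
  ci <- est$b_xy + c(-1, 1) * stats::qnorm(0.975) * est$se_xy
  data.frame(
    status = "ok", b_xy = est$b_xy, se_xy = est$se_xy, p_xy = est$p_xy,
    or_ = exp(est$b_xy), or_lo = exp(ci[1]), or_hi = exp(ci[2]),
    n_instruments_selected = nrow(inst),
    n_instruments_used = sum(keep),
    heidi_removed = paste(removed_ids, collapse = ";"),
    sentinel_id = inst$id[which.max(inst$mlog10p)],
    stringsAsFactors = FALSE
  )
}

#' FDR control and post-hoc robustness filters across MR results
#'
#' Benjamini-Hochberg q-values are computed jointly across all tested
#' protein-disease models; FDR-significant pairs are then audited for
#' (a) a convincing disease association at the locus (smallest disease
#' p at or below `locus_p_max`), (b) tight LD between the sentinel
#' exposure variant and the best disease variant (`r2 > r2_min`), and
#' (c) colocalization support (maximum PP4 at or above `pp4_min`).
#' Pairs failing (a) are `"eliminated_weak_disease_signal"`; passing
#' everything is `"robust"`; passing FDR but failing (b) or (c) is
#' `"significant_not_robust"`.
#'
#' @param results Data frame of MR results, one row per tested model,
#'   with columns `p_xy` (NA for insufficient models), and per-locus
#'   audit columns `disease_min_p`, `r2_sentinel_disease`, `max_pp4`
#'   (NAs allowed; a missing audit value fails that check).
#' @param q_max FDR threshold (default 0.01).
#' @param locus_p_max Disease-signal floor (default 1e-4).
#' @param r2_min Sentinel-disease LD requirement (default 0.8,
#'   strict >).
#' @param pp4_min Colocalization requirement (default 0.8).
#' @return `results` with added `fdr_q`, flag columns
#'   (`disease_signal_ok`, `ld_ok`, `pwcoco_pass`) and `verdict`.
#' @export
fdr_and_robustness <- function(results, q_max = 0.01, locus_p_max = 1e-4,
                               r2_min = 0.8, pp4_min = 0.8) {
  q <- rep(NA_real_, nrow(results))
  tested <- !is.na(results$p_xy)
  q[tested] <- stats::p.adjust(results$p_xy[tested], method = "BH")
  results$fdr_q <- q
  sig <- tested & q < q_max
  results$disease_signal_ok <- !is.na(results$disease_min_p) &
    results$disease_min_p <= locus_p_max
  results$ld_ok <- !is.na(results$r2_sentinel_disease) &
    results$r2_sentinel_disease > r2_min
  results$pwcoco_pass <- !is.na(results$max_pp4) &
    results$max_pp4 >= pp4_min
  verdict <- rep("not_significant", nrow(results))
  verdict[!tested] <- "insufficient_instruments"
  verdict[sig] <- ifelse(
    !results$disease_signal_ok[sig], "eliminated_weak_disease_signal",
    ifelse(results$ld_ok[sig] & results$pwcoco_pass[sig],
           "robust", "significant_not_robust"))
  results$verdict <- verdict
  results
}
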