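# Pairwise Bayesian colocalization under the single-causal-variant
# assumption, with a conditional-then-colocalize extension for loci
# carrying multiple independent signals.

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield log approximate Bayes factor
#'
#' Per-variant evidence of association from an effect estimate and its
#' standard error under a normal prior on the true effect:
#' with \eqn{V = \mathrm{s.e.}^2}, \eqn{W} the prior variance and
#' \eqn{r = W / (V + W)},
#' \deqn{\log \mathrm{ABF} = \tfrac12\left(\log(1 - r) + r z^2\right).}
#'
#' @param beta,se Effect estimates and standard errors (se > 0).
#' @param trait_type `"quantitative"` (prior SD 0.15, trait-SD scale) or
#'   `"case_control"` (prior SD 0.2, log-odds scale).
#' @param prior_sd Override of the prior effect SD.
#' @return Vector of log ABFs.
#' @export
log_abf <- function(beta, se,
                    trait_type = c("quantitative", "case_control"),
                    prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(prior_sd))
    prior_sd <- if (trait_type == "quantitative") 0.15 else 0.2
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Pairwise colocalization over a region
#'
#' Evaluates the five single-causal-variant hypotheses for two traits
#' over their shared harmonized variants: no association (H0), trait 1
#' only (H1), trait 2 only (H2), both with distinct causal variants
#' (H3), both with a shared causal variant (H4). Sums are taken in log
#' space so arbitrarily strong signals stay finite.
#'
#' @param trait1,trait2 Canonical summary-statistics tables already
#'   harmonized to common effect alleles; only variants present in both
#'   (matched on `id`) are used.
#' @param p1,p2 Per-variant prior probabilities of association with
#'   trait 1 / trait 2 (defaults 1e-4).
#' @param p12 Per-variant prior probability of association with both
#'   (default 1e-5).
#' @param type1,type2 Trait types passed to [log_abf()].
#' @param pp4_rule PP4 at or above this is called colocalized
#'   (default 0.8).
#' @return An object of class `coloc_result`: `pp` (named PP0..PP4
#'   summing to 1), `n_variants`, `priors`, `colocalized`, and the
#'   per-variant log-ABF table.
#' @export
coloc_pair <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       type1 = "quantitative", type2 = "quantitative",
                       pp4_rule = 0.8) {
  shared <- intersect(trait1$id, trait2$id)
  if (!length(shared))
    stop("no shared variants between traits; harmonize and intersect ",
         "the two datasets before colocalization")
  t1 <- trait1[match(shared, trait1$id), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$id), , drop = FALSE]
  l1 <- log_abf(t1$beta, t1$se, type1)
  l2 <- log_abf(t2$beta, t2$se, type2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    # distinct causal variants: sum over ordered pairs j != k
    h3 = log(p1) + log(p2) + .logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(
    pp = pp, n_variants = length(shared),
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    colocalized = unname(pp["PP4"] >= pp4_rule),
    abf = data.frame(id = shared, labf1 = l1, labf2 = l2,
                     stringsAsFactors = FALSE)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  cat(if (x$colocalized) "-> colocalized (PP4 rule)\n" else
    "-> not colocalized\n")
  invisible(x)
}

#' Condition summary statistics on a set of variants
#'
#' Produces approximate conditional association statistics for every
#' variant in a region given the joint effects of a conditioning set,
#' using the same multiple-regression algebra as the stepwise
#' conditional analysis: for variant j and conditioning set K,
#' \deqn{b_{c,j} = b_j - \sum_{k \in K} r_{jk} (s_j / s_k)\, b_{joint,k}}
#' with \eqn{s = \sqrt{1 / (2 f (1-f) N)}}, and the standard error
#' inflated by the conditional-variance factor \eqn{1 - q_j} where
#' \eqn{q_j = r_{jK} R_{KK}^{-1} r_{Kj}}. Conditioned variants get
#' `beta = 0`.
#'
#' @param stats Canonical summary-statistics table for the region.
#' @param ld An [ld_reference()] covering the region.
#' @param condition_on Character vector of variant ids to condition on;
#'   empty set returns `stats` unchanged.
#' @return A table with `beta`, `se`, `p`, `mlog10p` replaced by their
#'   conditional counterparts.
#' @export
conditioned_sumstats <- function(stats, ld, condition_on) {
  if (!length(condition_on)) return(stats)
  if (!all(condition_on %in% ld$variants$id))
    stop("conditioning variant(s) absent from LD reference")
  if (!all(condition_on %in% stats$id))
    stop("conditioning variant(s) absent from region statistics")
  R <- ld_subset(ld, stats$id)$r
  kix <- match(condition_on, stats$id)
  fit <- .cojo_joint(stats$beta[kix], stats$se[kix], stats$eaf[kix],
                     stats$n[kix], R[kix, kix, drop = FALSE])
  Rkk_inv <- tryCatch(solve(R[kix, kix, drop = FALSE]),
                      error = function(e)
                        solve(R[kix, kix, drop = FALSE] +
                                diag(1e-6, length(kix))))
  out <- stats
  for (j in seq_len(nrow(stats))) {
    if (j %in% kix) {
      out$beta[j] <- 0
      next
    }
    r_jk <- R[j, kix]
    q <- drop(r_jk %*% Rkk_inv %*% r_jk)
    D_j <- 2 * stats$eaf[j] * (1 - stats$eaf[j]) * stats$n[j]
    out$beta[j] <- stats$beta[j] -
      sum(r_jk * sqrt(fit$D / D_j) * fit$beta_joint)
    out$se[j] <- sqrt(fit$sigma2 / (D_j * max(1 - q, 1e-6)))
  }
  z <- out$beta / out$se
  out$p <- p_from_z(z)
  out$p[match(condition_on, out$id)] <- 1
  out$mlog10p <- mlog10p_from_z(z)
  out$mlog10p[match(condition_on, out$id)] <- 0
  out
}

#' Conditional-then-pairwise colocalization (multi-signal loci)
#'
#' Runs the stepwise conditional analysis on each trait to find its
#' independent signals, forms for each signal the summary statistics
#' conditioned on the trait's other signals, and colocalizes every
#' signal pair across traits (plus the unconditioned pair). With one
#' signal per trait this reduces exactly to [coloc_pair()].
#'
#' @param trait1,trait2 Region summary-statistics tables (harmonized).
#' @param ld An [ld_reference()] covering the region.
#' @param p_cutoff Stepwise-selection entry threshold (default 5e-8).
#' @param collinearity Collinearity cap for the stepwise selection
#'   (default 0.9 on r²).
#' @param p1,p2,p12 Colocalization priors (defaults 1e-4, 1e-4, 1e-5).
#' @param type1,type2 Trait types passed to [log_abf()].
#' @param pp4_rule Colocalization call threshold on PP4 (default 0.8).
#' @return A list: `pp4` matrix (signals of trait 1 x signals of
#'   trait 2), `max_pp4`, `colocalized`, `results` (all pairwise
#'   `coloc_result`s including `unconditioned`), and the per-trait
#'   signal tables.
#' @export
pwcoco <- function(trait1, trait2, ld, p_cutoff = 5e-8,
                   collinearity = 0.9, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                   type1 = "quantitative", type2 = "quantitative",
                   pp4_rule = 0.8) {
  sig <- function(tr) {
    tryCatch(
      conditional_stepwise(tr, ld, p_enter = p_cutoff, maf_floor = 0,
                           collinearity = collinearity),
      error = function(e) {
        warning("conditional analysis failed (", conditionMessage(e),
                "); falling back to the marginal signal")
        data.frame(id = tr$id[which.max(tr$mlog10p)])
      })
  }
  sig1 <- sig(trait1)
  sig2 <- sig(trait2)
  # no selectable signal: treat the trait as single-signal, unconditioned
  ids1 <- if (nrow(sig1)) sig1$id else trait1$id[which.max(trait1$mlog10p)]
  ids2 <- if (nrow(sig2)) sig2$id else trait2$id[which.max(trait2$mlog10p)]
  results <- list(
    unconditioned = coloc_pair(trait1, trait2, p1, p2, p12,
                               type1, type2, pp4_rule)
  )
  pp4 <- matrix(NA_real_, length(ids1), length(ids2),
                dimnames = list(ids1, ids2))
  for (i in seq_along(ids1)) {
    c1 <- if (length(ids1) > 1)
      conditioned_sumstats(trait1, ld, setdiff(ids1, ids1[i])) else trait1
    for (j in seq_along(ids2)) {
      c2 <- if (length(ids2) > 1)
        conditioned_sumstats(trait2, ld, setdiff(ids2, ids2[j])) else trait2
      res <- coloc_pair(c1, c2, p1, p2, p12, type1, type2, pp4_rule)
      pp4[i, j] <- res$pp["PP4"]
      results[[paste(ids1[i], ids2[j], sep = " x ")]] <- res
    }
  }
  max_pp4 <- max(pp4)
  list(pp4 = pp4, max_pp4 = max_pp4,
       colocalized = max_pp4 >= pp4_rule,
       results = results, signals1 = sig1, signals2 = sig2)
}
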