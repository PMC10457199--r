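# Candidate-mediator prioritization at trans-pQTLs: positional
# ("bottom-up") evidence around the sentinel and functional-overlap
# ("top-down") testing of annotation terms, combined into evidence
# tiers.

#' Genes local to a trans-pQTL sentinel
#'
#' @param sentinel_chrom,sentinel_pos Sentinel variant location.
#' @param genes Gene annotation table with columns `gene, chrom, tss`
#'   (optionally `terms`, `partners` as `;`-separated strings).
#' @param window Half-width of the local window in bp (default
#'   500,000), boundary inclusive.
#' @return Local genes ordered by distance to the sentinel (ties by
#'   gene id), with `distance`, `distance_rank` and `nearest3` columns.
#'   Zero rows when no gene falls in the window.
#' @export
local_genes <- function(sentinel_chrom, sentinel_pos, genes,
                        window = 5e5) {
  g <- genes[genes$chrom == sentinel_chrom &
               abs(genes$tss - sentinel_pos) <= window, , drop = FALSE]
  if (!nrow(g)) {
    g$distance <- numeric(0); g$distance_rank <- integer(0)
    g$nearest3 <- logical(0)
    return(g)
  }
  g$distance <- abs(g$tss - sentinel_pos)
  g <- g[order(g$distance, g$gene), , drop = FALSE]
  g$distance_rank <- seq_len(nrow(g))
  g$nearest3 <- g$distance_rank <= 3
  rownames(g) <- NULL
  g
}

#' Annotation-term overlap test for one local gene
#'
#' Two-sided Fisher's exact test on the 2x2 classification of the
#' background term universe (all terms carried by any local gene at the
#' locus) by membership in the local gene's terms and in the
#' trans-affected protein's terms, Bonferroni-corrected for the number
#' of local genes at the locus.
#'
#' @param gene_terms Character vector of the local gene's terms.
#' @param target_terms Character vector of the trans-affected protein's
#'   terms.
#' @param background Character vector: union of all local genes' terms
#'   at the locus.
#' @param n_local Number of local genes (Bonferroni factor).
#' @return A list: `shared` (count), `p` (raw two-sided Fisher p),
#'   `p_adjusted` (`min(1, p * n_local)`), `table` (the 2x2 matrix).
#'   Empty background returns `p = NA` with a `skipped` reason.
#' @export
term_overlap_test <- function(gene_terms, target_terms, background,
                              n_local = 1) {
  background <- unique(background)
  if (!length(background))
    return(list(shared = 0L, p = NA_real_, p_adjusted = NA_real_,
                table = NULL, skipped = "empty background term set"))
  in_gene <- background %in% gene_terms
  in_target <- background %in% target_terms
  tab <- matrix(c(sum(in_gene & in_target), sum(in_gene & !in_target),
                  sum(!in_gene & in_target), sum(!in_gene & !in_target)),
                nrow = 2,
                dimnames = list(gene = c("in", "out"),
                                target = c("in", "out")))
  p <- stats::fisher.test(tab)$p.value
  list(shared = tab[1, 1], p = p,
       p_adjusted = min(1, p * n_local), table = tab)
}

#' Combine evidence classes into a candidate tier
#'
#' Tier = number of satisfied evidence classes: top-3 proximity,
#' cis-eQTL support of the sentinel, protein-protein interaction with
#' the trans-affected target, and adjusted term-overlap p < 0.05.
#'
#' @param nearest3,cis_eqtl_overlap,ppi_with_target Logical flags.
#' @param term_p_adjusted Bonferroni-adjusted Fisher p (NA counts as no
#'   evidence).
#' @return Integer tier in 0..4.
#' @export
combine_evidence <- function(nearest3, cis_eqtl_overlap, ppi_with_target,
                             term_p_adjusted) {
  as.integer(nearest3) + as.integer(cis_eqtl_overlap) +
    as.integer(ppi_with_target) +
    as.integer(!is.na(term_p_adjusted) & term_p_adjusted < 0.05)
}

# ";"-separated string -> character vector
.split_terms <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Prioritize candidate mediating genes at a trans-pQTL
#'
#' Runs the full per-locus report: local genes within the window,
#' bottom-up flags (3-nearest, cis-eQTL support of the sentinel, PPI
#' with the target protein) and the top-down term-overlap test, then
#' ranks candidates by evidence tier, adjusted p and distance.
#'
#' cis-eQTL support of a local gene holds when the trans-pQTL sentinel
#' is that gene's local eQTL sentinel, is in LD `r2 >= eqtl_r2` with
#' it, or is a member of a supplied credible set.
#'
#' @param sentinel_chrom,sentinel_pos Trans-pQTL sentinel location.
#' @param sentinel_id Sentinel variant id.
#' @param target_gene Gene encoding the trans-affected protein (its
#'   `terms`/`partners` are looked up in `genes`).
#' @param genes Gene annotation table (`gene, chrom, tss, terms,
#'   partners`; terms and partners `;`-separated).
#' @param eqtl Optional named list mapping local gene ids to their
#'   cis-eQTL summary-statistics tables (canonical columns; used to
#'   find each gene's eQTL sentinel in the window).
#' @param ld Optional [ld_reference()] used for the sentinel-eQTL LD
#'   check.
#' @param credible_sets Optional named list mapping gene ids to
#'   character vectors of credible-set variant ids.
#' @param window Local window half-width (default 500,000 bp).
#' @param eqtl_r2 LD threshold for sentinel-eQTL support (default 0.8).
#' @return A `data.frame` (one row per local gene, ranked): distance
#'   columns, evidence flags, Fisher p columns, `tier`, `rank`. Empty
#'   when no local genes; attribute `note` explains empty output.
#' @export
prioritize_mediators <- function(sentinel_chrom, sentinel_pos, sentinel_id,
                                 target_gene, genes,
                                 eqtl = NULL, ld = NULL,
                                 credible_sets = NULL,
                                 window = 5e5, eqtl_r2 = 0.8) {
  loc <- local_genes(sentinel_chrom, sentinel_pos, genes, window)
  if (!nrow(loc)) {
    out <- loc
    attr(out, "note") <- "no local candidates in window"
    return(out)
  }
  target_terms <- .split_terms(
    genes$terms[match(target_gene, genes$gene)])
  target_partners <- .split_terms(
    genes$partners[match(target_gene, genes$gene)])
  background <- unique(unlist(lapply(loc$terms, .split_terms)))
  n_local <- nrow(loc)
  res <- lapply(seq_len(n_local), function(i) {
    gt <- .split_terms(loc$terms[i])
    tt <- term_overlap_test(gt, target_terms, background, n_local)
    eq <- .sentinel_eqtl_support(loc$gene[i], sentinel_id, sentinel_pos,
                                 eqtl, ld, credible_sets, window, eqtl_r2)
    ppi <- loc$gene[i] %in% target_partners ||
      target_gene %in% .split_terms(loc$partners[i])
    data.frame(shared_terms = tt$shared, term_p = tt$p,
               term_p_adjusted = tt$p_adjusted,
               cis_eqtl_overlap = eq, ppi_with_target = ppi,
               stringsAsFactors = FALSE)
  })
  out <- cbind(loc, do.call(rbind, res))
  out$tier <- combine_evidence(out$nearest3, out$cis_eqtl_overlap,
                               out$ppi_with_target, out$term_p_adjusted)
  ord <- order(-out$tier,
               ifelse(is.na(out$term_p_adjusted), 2, out$term_p_adjusted),
               out$distance)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Bottom-up cis-eQTL evidence for one local gene.
.sentinel_eqtl_support <- function(gene, sentinel_id, sentinel_pos,
                                   eqtl, ld, credible_sets,
                                   window, eqtl_r2) {
  if (!is.null(credible_sets) && gene %in% names(credible_sets) &&
      sentinel_id %in% credible_sets[[gene]]) return(TRUE)
  if (is.null(eqtl) || !gene %in% names(eqtl)) return(FALSE)
  e <- eqtl[[gene]]
  e <- e[abs(e$pos - sentinel_pos) <= window, , drop = FALSE]
  if (!nrow(e)) return(FALSE)
  eqtl_sentinel <- e$id[which.max(e$mlog10p)]
  if (identical(eqtl_sentinel, sentinel_id)) return(TRUE)
  if (!is.null(ld) &&
      all(c(eqtl_sentinel, sentinel_id) %in% ld$variants$id)) {
    r <- ld$r[match(sentinel_id, ld$variants$id),
              match(eqtl_sentinel, ld$variants$id)]
    return(r^2 >= eqtl_r2)
  }
  FALSE
}
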