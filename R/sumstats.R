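#' @keywords internal
"_PACKAGE"

# Canonical column set exchanged by every stage. A summary-statistics table
# is a plain data.frame with (at least) these columns; optional columns may
# be absent or NA.
.SUMSTAT_COLS <- c("chrom", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
.SUMSTAT_OPT <- c("info", "hwe_p", "id")

#' Construct a canonical summary-statistics table
#'
#' Builds and validates the variant-level association table used throughout
#' the pipeline: one row per variant with alleles, effect-allele frequency,
#' additive effect estimate (trait-SD units for quantitative traits,
#' log-odds for case-control), its standard error, two-sided p-value and
#' sample size.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based base-pair positions (>= 1).
#' @param ea,oa Effect and other allele (A/C/G/T strings); `ea != oa` rowwise.
#' @param eaf Effect-allele frequencies in (0, 1).
#' @param beta Additive per-allele effect estimates.
#' @param se Standard errors, > 0.
#' @param p Two-sided p-values in (0, 1]; if `NULL`, computed from
#'   `beta / se` under the normal approximation.
#' @param n Per-variant sample sizes (>= 1).
#' @param info Optional imputation quality in \[0, 1\].
#' @param hwe_p Optional Hardy-Weinberg equilibrium p-values.
#' @param id Optional variant names; defaults to `chrom:pos:ea:oa`.
#'
#' @return A `data.frame` sorted by (chrom, pos) with columns
#'   `chrom, pos, ea, oa, eaf, beta, se, p, n, info, hwe_p, id` and a
#'   `mlog10p` column holding \eqn{-\log_{10} p} computed from the z-score
#'   (robust far beyond double-precision underflow of `p`).
#' @export
sumstats <- function(chrom, pos, ea, oa, eaf, beta, se, p = NULL, n,
                     info = NA_real_, hwe_p = NA_real_, id = NULL) {
  chrom <- as.character(chrom)
  ea <- toupper(as.character(ea)); oa <- toupper(as.character(oa))
  if (any(pos < 1, na.rm = TRUE)) stop("pos must be >= 1")
  if (any(ea == oa, na.rm = TRUE)) stop("effect and other allele must differ")
  if (any(se <= 0, na.rm = TRUE)) stop("se must be > 0")
  if (any(eaf <= 0 | eaf >= 1, na.rm = TRUE)) stop("eaf must lie in (0, 1)")
  if (any(n < 1, na.rm = TRUE)) stop("n must be >= 1")
  z <- beta / se
  if (is.null(p)) p <- p_from_z(z)
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p must lie in (0, 1]")
  if (is.null(id)) id <- paste(chrom, pos, ea, oa, sep = ":")
  out <- data.frame(
    chrom = chrom, pos = as.integer(pos), ea = ea, oa = oa,
    eaf = eaf, beta = beta, se = se, p = p, n = n,
    info = info, hwe_p = hwe_p, id = id,
    mlog10p = mlog10p_from_z(z),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out[, c("chrom", "pos", "ea", "oa")]))
    stop("duplicate (chrom, pos, ea, oa) records")
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Default TSV header -> canonical name map (the METAL-style dialect).
.DEFAULT_DIALECT <- c(
  CHR = "chrom", POS = "pos", EA = "ea", OA = "oa", EAF = "eaf",
  BETA = "beta", SE = "se", P = "p", N = "n", INFO = "info",
  HWE_P = "hwe_p", ID = "id"
)

#' Read a summary-statistics TSV
#'
#' Reads a tab-separated file with a header (gzip-transparent), renames
#' columns through a dialect map, drops rows whose mandatory numeric fields
#' do not parse, and returns a canonical table sorted by position.
#'
#' @param path File path (plain or gzip-compressed TSV).
#' @param dialect Named character vector mapping file column names to
#'   canonical names (`chrom, pos, ea, oa, eaf, beta, se, p, n, info,
#'   hwe_p, id`). Defaults to the upper-case dialect `CHR, POS, EA, OA,
#'   EAF, BETA, SE, P, N, INFO, HWE_P`.
#'
#' @return A canonical summary-statistics `data.frame` (see [sumstats()])
#'   with attribute `n_dropped` counting rows removed for unparsable
#'   numerics.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  if (is.null(dialect)) dialect <- .DEFAULT_DIALECT
  con <- gzfile(path, "rt")
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  names(raw) <- ifelse(names(raw) %in% names(dialect),
                       dialect[names(raw)], names(raw))
  need <- c("chrom", "pos", "ea", "oa", "beta", "se", "p", "n")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  num_cols <- intersect(c("pos", "eaf", "beta", "se", "p", "n", "info", "hwe_p"),
                        names(raw))
  parsed <- raw
  for (cl in num_cols) parsed[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
  mandatory_num <- intersect(c("pos", "beta", "se", "p", "n"), num_cols)
  ok <- rowSums(is.na(parsed[, mandatory_num, drop = FALSE])) == 0
  n_dropped <- sum(!ok)
  parsed <- parsed[ok, , drop = FALSE]
  out <- sumstats(
    chrom = parsed$chrom, pos = parsed$pos, ea = parsed$ea, oa = parsed$oa,
    eaf = if ("eaf" %in% names(parsed)) parsed$eaf else NA_real_,
    beta = parsed$beta, se = parsed$se, p = parsed$p, n = parsed$n,
    info = if ("info" %in% names(parsed)) parsed$info else NA_real_,
    hwe_p = if ("hwe_p" %in% names(parsed)) parsed$hwe_p else NA_real_,
    id = if ("id" %in% names(parsed)) parsed$id else NULL
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a summary-statistics TSV
#'
#' Inverse of [read_sumstats()]: writes the canonical columns under the
#' default upper-case dialect. Numeric fields are written with full
#' precision (17 significant digits) so a read/write round trip preserves
#' values to machine accuracy.
#'
#' @param x Canonical summary-statistics table.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  inv <- names(.DEFAULT_DIALECT)
  names(inv) <- .DEFAULT_DIALECT
  cols <- c("chrom", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n",
            "info", "hwe_p", "id")
  out <- x[, cols, drop = FALSE]
  for (cl in c("eaf", "beta", "se", "p", "hwe_p", "info"))
    out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
  names(out) <- inv[cols]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize records to target allele orientation
#'
#' Aligns each record's effect allele to a target orientation at the same
#' site: matching alleles pass through, swapped alleles flip the effect
#' sign and frequency, anything else (including unresolvable
#' strand-ambiguous pairs) is marked unmatchable. Strand-ambiguous pairs
#' (A/T or C/G) are accepted only when the effect-allele frequencies
#' discriminate the two orientations by more than `freq_gap`; this is a
#' deliberately conservative policy since a wrong call silently flips
#' effect signs.
#'
#' @param x Canonical summary-statistics table.
#' @param target Data frame with columns `chrom, pos, ea, oa` (and
#'   optionally `eaf`, used to resolve strand-ambiguous pairs).
#' @param freq_gap Minimum separation between
#'   \eqn{|f - f_t|} and \eqn{|f - (1 - f_t)|} required to orient a
#'   strand-ambiguous pair (default 0.1).
#'
#' @return `x` with `beta`, `eaf` flipped where needed and an added
#'   `match` column: `"match"`, `"flip"` or `"unmatchable"`. Rows with no
#'   target site are `"unmatchable"`.
#' @export
harmonize <- function(x, target, freq_gap = 0.1) {
  key_x <- paste(x$chrom, x$pos)
  key_t <- paste(target$chrom, target$pos)
  idx <- match(key_x, key_t)
  status <- rep("unmatchable", nrow(x))
  out <- x
  has <- !is.na(idx)
  t_ea <- target$ea[idx]; t_oa <- target$oa[idx]
  t_eaf <- if ("eaf" %in% names(target)) target$eaf[idx] else rep(NA_real_, nrow(x))
  ambiguous <- .is_ambiguous(x$ea, x$oa)
  same <- has & x$ea == t_ea & x$oa == t_oa
  swap <- has & x$ea == t_oa & x$oa == t_ea
  # ambiguous pairs: both orientations are sequence-compatible, use EAF
  amb <- has & ambiguous & (same | swap)
  if (any(amb)) {
    d_same <- abs(x$eaf - t_eaf)
    d_flip <- abs(x$eaf - (1 - t_eaf))
    resolvable <- amb & !is.na(t_eaf) & abs(d_same - d_flip) > freq_gap
    same[amb] <- FALSE; swap[amb] <- FALSE
    same[resolvable & d_same < d_flip] <- TRUE
    swap[resolvable & d_flip < d_same] <- TRUE
  }
  status[same] <- "match"
  status[swap] <- "flip"
  out$beta[swap] <- -out$beta[swap]
  out$eaf[swap] <- 1 - out$eaf[swap]
  tmp <- out$ea[swap]; out$ea[swap] <- out$oa[swap]; out$oa[swap] <- tmp
  out$match <- status
  out
}

.is_ambiguous <- function(ea, oa) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(ea) & !is.na(oa) & comp[ea] == oa
}

#' Reconstruct effect size and standard error from a z-score
#'
#' Converts a z-score, allele frequency and sample size into an effect
#' estimate and standard error on the standardized-trait scale via
#' \deqn{d = \sqrt{2 f (1 - f)(z^2 + N)}, \quad b = z / d, \quad
#'   \mathrm{s.e.} = 1 / d,}
#' the standard reconstruction used when an association resource reports
#' only z and frequency.
#'
#' @param z Z-scores.
#' @param f Effect-allele frequencies in (0, 1).
#' @param n Sample sizes, > 0.
#' @return A list with vectors `beta` and `se`; `beta / se` recovers `z`
#'   exactly up to floating round-off.
#' @export
z_to_beta_se <- function(z, f, n) {
  if (any(f <= 0 | f >= 1)) stop("allele frequency must lie in (0, 1)")
  if (any(n <= 0)) stop("n must be > 0")
  d <- sqrt(2 * f * (1 - f) * (z^2 + n))
  list(beta = z / d, se = 1 / d)
}

#' Two-sided normal p-value from a z-score
#'
#' Uses the survival-function formulation `2 * pnorm(|z|, lower = FALSE)`
#' so that extreme scores (|z| up to ~37) keep nonzero representable
#' p-values.
#'
#' @param z Z-scores.
#' @return Two-sided p-values.
#' @export
p_from_z <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Z-score magnitude (optionally signed) from a two-sided p-value
#'
#' @param p Two-sided p-values in (0, 1].
#' @param sign Optional effect signs applied to the magnitude.
#' @return Z-scores.
#' @export
z_from_p <- function(p, sign = 1) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  sign * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' -log10 two-sided p-value directly from a z-score
#'
#' Computed in log space so association strength can be compared far below
#' the double-precision underflow point of the p-value itself; the
#' pipeline's threshold comparisons are done on this scale.
#'
#' @param z Z-scores.
#' @return \eqn{-\log_{10} p} values.
#' @export
mlog10p_from_z <- function(z) {
  -(stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

#' Build an LD reference object
#'
#' @param variants Data frame with columns `chrom, pos, ea, oa` (and
#'   optionally `id`, `eaf`) ordered as the rows/columns of `r`.
#' @param r Square allelic correlation matrix (symmetric, unit diagonal,
#'   entries in \[-1, 1\]).
#' @param n_ref Reference panel sample count.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(variants, r, n_ref = NA_integer_) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("r must be square")
  if (nrow(r) != nrow(variants)) stop("variants and r dimensions differ")
  if (max(abs(r - t(r))) > 1e-8) stop("r must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("r must have unit diagonal")
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) stop("r entries must lie in [-1, 1]")
  r <- (r + t(r)) / 2
  if (!"id" %in% names(variants))
    variants$id <- paste(variants$chrom, variants$pos, variants$ea,
                         variants$oa, sep = ":")
  dimnames(r) <- list(variants$id, variants$id)
  structure(list(variants = variants, r = r, n_ref = n_ref),
            class = "ld_reference")
}

#' Compute an LD reference from a genotype dosage matrix
#'
#' @param dosage Numeric matrix, samples x variants (columns in the order
#'   of `variants`).
#' @param variants Variant table as in [ld_reference()].
#' @return An `ld_reference` with `r = cor(dosage)` and
#'   `n_ref = nrow(dosage)`.
#' @export
ld_from_dosage <- function(dosage, variants) {
  r <- stats::cor(dosage)
  # monomorphic columns yield NA correlations; treat as unlinked
  r[is.na(r)] <- 0
  diag(r) <- 1
  ld_reference(variants, r, n_ref = nrow(dosage))
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("LD reference:", nrow(x$r), "variants, n_ref =", x$n_ref, "\n")
  invisible(x)
}

#' Subset an LD reference to a set of variant ids
#'
#' @param ld An [ld_reference()].
#' @param ids Variant ids; the result keeps this order.
#' @return An `ld_reference` over `ids`.
#' @export
ld_subset <- function(ld, ids) {
  idx <- match(ids, ld$variants$id)
  if (anyNA(idx)) stop("variant(s) absent from LD reference: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  ld_reference(ld$variants[idx, , drop = FALSE],
               ld$r[idx, idx, drop = FALSE], ld$n_ref)
}
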