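#' Estimate allele frequencies from a genotype matrix
#'
#' Frequency of the counted (A1) allele per SNP, estimated from the pooled
#' analysis sample (cases and controls together) over non-missing genotypes.
#'
#' @param g a [genotype_matrix()].
#' @return A tibble with columns `snp_id`, `chrom`, `p` (A1 frequency) and
#'   `n_obs` (non-missing genotype count).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_obs <- colSums(!is.na(g$dosages))
  if (any(n_obs == 0))
    stop("SNP(s) with all genotypes missing: ",
         paste(head(g$snps$id[n_obs == 0], 5), collapse = ", "),
         call. = FALSE)
  tibble::tibble(snp_id = g$snps$id, chrom = g$snps$chrom,
                 p = colMeans(g$dosages, na.rm = TRUE) / 2,
                 n_obs = as.integer(n_obs))
}

#' Compute the genetic relationship matrix
#'
#' Realised-relatedness estimator over genome-wide SNPs.  With dosage
#' \eqn{x_{ij}} of SNP *i* in individual *j* and sample allele frequency
#' \eqn{p_i}, the off-diagonal entries are
#' \deqn{A_{jk} = \frac{1}{N_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1 - p_i)}}
#' over the \eqn{N_{jk}} SNPs non-missing in both individuals, and the
#' diagonal uses the less noisy estimator
#' \deqn{A_{jj} = 1 + \frac{1}{N_{jj}} \sum_i
#'   \frac{x_{ij}^2 - (1 + 2p_i)x_{ij} + 2p_i^2}{2p_i(1 - p_i)},}
#' the form used by the GCTA tool (so written GRM files interoperate).
#' SNPs that are monomorphic or below the minor-allele-frequency cutoff are
#' excluded; missing genotypes are handled by the per-pair denominators, never
#' imputed.  The result is invariant to which allele is counted.
#'
#' @param g a [genotype_matrix()].
#' @param freqs optional allele-frequency tibble from [allele_frequencies()]
#'   (must cover every SNP id in `g`); defaults to frequencies estimated from
#'   `g` itself.
#' @param maf_min minor-allele-frequency cutoff; SNPs with
#'   `min(p, 1 - p) < maf_min` are excluded.  Default 0.01 ("common" SNPs).
#' @param chr,exclude_chr optional chromosome restriction, passed to
#'   [subset_snps()] (e.g. `chr = "6"` for an MHC-only GRM, or
#'   `exclude_chr = "6"` for the complement).
#' @return A [new_grm()] object.
#' @export
compute_grm <- function(g, freqs = NULL, maf_min = 0.01,
                        chr = NULL, exclude_chr = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(chr) || !is.null(exclude_chr))
    g <- subset_snps(g, chr = chr, exclude_chr = exclude_chr)
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  p <- freqs$p[match(g$snps$id, freqs$snp_id)]
  if (anyNA(p))
    stop("allele frequencies missing for ", sum(is.na(p)), " SNP(s)",
         call. = FALSE)

  keep <- pmin(p, 1 - p) >= maf_min & p > 0 & p < 1
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(n_excl, " SNP(s) excluded (monomorphic or MAF < ", maf_min, "); ",
            sum(keep), " retained")
  if (!any(keep))
    stop("no SNPs left after the MAF filter", call. = FALSE)

  x <- g$dosages[, keep, drop = FALSE]
  p <- p[keep]
  het <- 2 * p * (1 - p)

  w <- sweep(sweep(x, 2, 2 * p, "-"), 2, sqrt(het), "/")
  has_missing <- anyNA(x)
  if (has_missing) {
    obs <- !is.na(x)
    w[!obs] <- 0
    storage.mode(obs) <- "double"
    n_pairs <- tcrossprod(obs)
  } else {
    n_pairs <- matrix(as.numeric(ncol(x)), nrow(x), nrow(x))
  }
  num <- tcrossprod(w)               # sum_i w_ij w_ik over shared SNPs
  if (any(n_pairs == 0))
    stop("some individual pair shares no non-missing SNPs (N_jk = 0)",
         call. = FALSE)
  a <- num / n_pairs

  # GCTA diagonal: 1 + mean over non-missing SNPs of
  # (x^2 - (1 + 2p) x + 2 p^2) / (2p(1-p))
  dterm <- x * x - sweep(x, 2, 1 + 2 * p, "*")
  dterm <- sweep(dterm, 2, 2 * p^2, "+")
  dterm <- sweep(dterm, 2, het, "/")
  dterm[is.na(x)] <- 0
  diag(a) <- 1 + rowSums(dterm) / diag(n_pairs)

  new_grm(a, n_pairs, g$samples, n_snps = sum(keep))
}

#' Shrink a GRM for prediction error due to imperfect linkage disequilibrium
#'
#' Genotyped SNPs tag causal variants imperfectly, which inflates the sampling
#' noise of the off-diagonal relatedness estimates.  This applies the
#' regression-style shrinkage used by the GCTA `--grm-adj` option:
#' \eqn{\beta = 1 - (c + 1/N) / \mathrm{Var}(A_{jk})} computed from the
#' empirical variance of the off-diagonal entries and the number of SNPs
#' \eqn{N}, then \eqn{A^*_{jk} = \beta A_{jk}} off the diagonal and
#' \eqn{A^*_{jj} = 1 + \beta (A_{jj} - 1)}.  The adjustment is not idempotent:
#' re-applying it shrinks again.
#'
#' @param grm a [new_grm()] object.
#' @param c expected genetic-variance loss parameter of the adjustment;
#'   default 0 (the usual tool setting, where only the \eqn{1/N} sampling
#'   term is removed).
#' @return The adjusted [new_grm()] object, with the shrinkage factor in
#'   attribute `"ld_beta"`.
#' @export
adjust_grm_ld <- function(grm, c = 0) {
  stopifnot(inherits(grm, "grm"), c >= 0)
  off <- grm$values[upper.tri(grm$values)]
  v <- stats::var(off)
  if (!is.finite(v) || v <= c + 1 / grm$n_snps)
    stop("off-diagonal variance (", signif(v, 4),
         ") does not exceed c + 1/N = ", signif(c + 1 / grm$n_snps, 4),
         "; LD adjustment undefined", call. = FALSE)
  beta <- 1 - (c + 1 / grm$n_snps) / v
  a <- beta * grm$values
  diag(a) <- 1 + beta * (diag(grm$values) - 1)
  out <- new_grm(a, grm$n_pairs, grm$samples, grm$n_snps)
  attr(out, "ld_beta") <- beta
  out
}

#' Principal components of a GRM
#'
#' Top-*k* eigenvectors of the relatedness matrix, the standard covariates for
#' adjusting a mixed model for global population structure.  Eigenvectors are
#' unit-norm with a deterministic sign convention (the largest-magnitude
#' loading is positive).
#'
#' @param grm a [new_grm()] object.
#' @param k number of components, `1 <= k < n`.
#' @return A covariate tibble with columns `fid`, `iid`, `PC1` ... `PCk`;
#'   eigenvalues in attribute `"eigenvalues"`.
#' @export
grm_pca <- function(grm, k) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$samples)
  if (k < 1 || k >= n) stop("need 1 <= k < n", call. = FALSE)
  if (any(!is.finite(grm$values)))
    stop("GRM contains non-finite entries", call. = FALSE)
  e <- eigen(grm$values, symmetric = TRUE)
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  out <- tibble::as_tibble(as.data.frame(vecs))
  names(out) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(grm$samples[, c("fid", "iid")], out)
  attr(out, "eigenvalues") <- e$values[seq_len(k)]
  out
}
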