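#' Construct a genotype matrix
#'
#' Container for an individuals-by-SNPs dosage matrix plus SNP and sample
#' metadata.  Dosages count copies of the A1 allele (PLINK convention) and are
#' 0, 1, 2 or `NA` for a missing genotype; missingness is never imputed here,
#' downstream code handles it per pair of individuals.
#'
#' @param dosages integer matrix, individuals in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param snps data frame with one row per SNP and columns `chrom` (character
#'   chromosome label), `id` (unique SNP id), `pos` (base-pair position),
#'   `a1`, `a2` (alleles; `a1` is the counted allele).
#' @param samples data frame with one row per individual and columns `fid`
#'   (family id) and `iid` (individual id); pairs must be unique.
#'
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `snps` (tibble) and `samples` (tibble).
#' @export
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   snps = data.frame(chrom = "1", id = c("s1", "s2"), pos = c(1, 2),
#'                     a1 = "A", a2 = "B"),
#'   samples = data.frame(fid = c("F1", "F2"), iid = c("I1", "I2"))
#' )
#' n_samples(g)
genotype_matrix <- function(dosages, snps, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  snps <- tibble::as_tibble(snps)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("chrom", "id", "pos", "a1", "a2") %in% names(snps)),
            all(c("fid", "iid") %in% names(samples)))
  snps$chrom <- as.character(snps$chrom)
  if (nrow(snps) != ncol(dosages))
    stop("snps has ", nrow(snps), " rows but dosages has ", ncol(dosages),
         " columns", call. = FALSE)
  if (nrow(samples) != nrow(dosages))
    stop("samples has ", nrow(samples), " rows but dosages has ",
         nrow(dosages), " rows", call. = FALSE)
  bad <- setdiff(unique(dosages[!is.na(dosages)]), 0:2)
  if (length(bad))
    stop("dosage values outside {0, 1, 2, NA}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(snps$id))
    stop("duplicate SNP ids", call. = FALSE)
  if (anyDuplicated(paste(samples$fid, samples$iid)))
    stop("duplicate (fid, iid) sample pairs", call. = FALSE)
  structure(list(dosages = dosages, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat("<genotype_matrix> ", n_samples(x), " individuals x ", n_snps(x),
      " SNPs (", length(unique(x$snps$chrom)), " chromosomes, ",
      sprintf("%.1f%%", 100 * miss), " missing)\n", sep = "")
  invisible(x)
}

#' Dimensions of genotype containers
#'
#' @param x a `genotype_matrix`.
#' @return Number of individuals (`n_samples`) or SNPs (`n_snps`).
#' @export
n_samples <- function(x) nrow(x$dosages)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$dosages)

#' Subset a genotype matrix by chromosome or by individuals
#'
#' `subset_snps()` keeps SNPs on the chromosomes in `chr`, or drops those in
#' `exclude_chr` (exactly one of the two may be given; neither returns `x`
#' unchanged).  `subset_samples()` keeps the individuals at row indices `idx`,
#' in the order given.
#'
#' @param x a `genotype_matrix`.
#' @param chr,exclude_chr character vectors of chromosome labels.
#' @param idx integer vector of row indices.
#' @return A `genotype_matrix`.
#' @export
subset_snps <- function(x, chr = NULL, exclude_chr = NULL) {
  if (!is.null(chr) && !is.null(exclude_chr))
    stop("give either `chr` or `exclude_chr`, not both", call. = FALSE)
  keep <- rep(TRUE, n_snps(x))
  if (!is.null(chr)) keep <- x$snps$chrom %in% as.character(chr)
  if (!is.null(exclude_chr)) keep <- !(x$snps$chrom %in% as.character(exclude_chr))
  if (!any(keep))
    stop("no SNPs left after chromosome subsetting", call. = FALSE)
  genotype_matrix(x$dosages[, keep, drop = FALSE], x$snps[keep, ], x$samples)
}

#' @rdname subset_snps
#' @export
subset_samples <- function(x, idx) {
  genotype_matrix(x$dosages[idx, , drop = FALSE], x$snps, x$samples[idx, ])
}

#' Construct a genetic relationship matrix object
#'
#' Container for a symmetric n-by-n relatedness matrix together with the
#' per-pair counts of SNPs that were non-missing in both individuals.
#'
#' @param values symmetric numeric matrix of relatedness coefficients.
#' @param n_pairs symmetric matrix of per-pair non-missing SNP counts.
#' @param samples data frame with columns `fid`, `iid` (one row per
#'   individual, unique pairs).
#' @param n_snps number of SNPs the matrix was computed from.
#' @return An object of class `grm`.
#' @export
new_grm <- function(values, n_pairs, samples, n_snps) {
  values <- as.matrix(values)
  n_pairs <- as.matrix(n_pairs)
  samples <- tibble::as_tibble(samples)
  n <- nrow(samples)
  stopifnot(all(dim(values) == n), all(dim(n_pairs) == n))
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8)))
    stop("GRM values are not symmetric", call. = FALSE)
  if (any(!is.finite(values)))
    stop("GRM contains non-finite entries", call. = FALSE)
  if (any(n_pairs > n_snps))
    stop("pair counts exceed the number of SNPs", call. = FALSE)
  structure(list(values = (values + t(values)) / 2, n_pairs = n_pairs,
                 samples = samples, n_snps = as.integer(n_snps)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$samples)
  off <- x$values[upper.tri(x$values)]
  cat("<grm> ", n, " individuals, ", x$n_snps, " SNPs; mean diag ",
      sprintf("%.4f", mean(diag(x$values))), ", var offdiag ",
      sprintf("%.3g", stats::var(off)), "\n", sep = "")
  invisible(x)
}
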