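# PLINK v1 .bed 2-bit codes (SNP-major): 00 = hom A1 (dosage 2), 01 = missing,
# 10 = het, 11 = hom A2 (dosage 0).  Bit pairs fill each byte from the low bits.
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)   # index by code + 1
.dosage_to_code <- c(3L, 2L, 0L)                # index by dosage + 1; NA -> 1

#' Read a PLINK v1 binary genotype triple
#'
#' Decodes a SNP-major `.bed` file with its `.bim`/`.fam` companions into a
#' [genotype_matrix()].  Dosages count the A1 allele of the `.bim` file; the
#' missing genotype code becomes `NA`.
#'
#' @param bed,bim,fam file paths.  If `bim`/`fam` are missing, they are derived
#'   from `bed` by swapping the extension, so `read_plink("x.bed")` works.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(bed, bim = NULL, fam = NULL) {
  if (is.null(bim)) bim <- sub("\\.bed$", ".bim", bed)
  if (is.null(fam)) fam <- sub("\\.bed$", ".fam", bed)
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)

  if (length(readLines(bim, n = 1)) == 0) {          # zero-SNP file
    bim_df <- data.frame(chrom = character(), id = character(),
                         cm = character(), pos = character(),
                         a1 = character(), a2 = character())
  } else {
    bim_df <- read.table(bim, header = FALSE, colClasses = "character")
    if (ncol(bim_df) != 6)
      stop(".bim must have 6 columns, found ", ncol(bim_df), call. = FALSE)
    names(bim_df) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  }
  fam_df <- read.table(fam, header = FALSE, colClasses = "character")
  if (ncol(fam_df) < 2)
    stop(".fam must have at least 2 columns", call. = FALSE)

  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("not a PLINK v1 SNP-major .bed file (bad magic bytes): ", bed,
         call. = FALSE)
  bpv <- ceiling(n / 4)                      # bytes per SNP
  if (length(raw) != 3L + bpv * m)
    stop(".bed size (", length(raw), " bytes) inconsistent with ", n,
         " individuals x ", m, " SNPs (expected ", 3L + bpv * m, ")",
         call. = FALSE)

  if (m == 0L) {
    dos <- matrix(integer(0), nrow = n, ncol = 0)
  } else {
    bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
    dos <- matrix(NA_integer_, nrow = 4L * bpv, ncol = m)
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(bytes, 2L * k), 3L)
      dos[seq(k + 1L, by = 4L, length.out = bpv), ] <- .code_to_dosage[code + 1L]
    }
    dos <- dos[seq_len(n), , drop = FALSE]
  }
  genotype_matrix(
    dos,
    snps = data.frame(chrom = bim_df$chrom, id = bim_df$id,
                      pos = as.numeric(bim_df$pos),
                      a1 = bim_df$a1, a2 = bim_df$a2),
    samples = data.frame(fid = fam_df[[1]], iid = fam_df[[2]])
  )
}

#' Write a PLINK v1 binary genotype triple
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix; writes `prefix.bed`, `prefix.bim`,
#'   `prefix.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- n_samples(g)
  m <- n_snps(g)
  bpv <- ceiling(n / 4)

  codes <- matrix(0L, nrow = 4L * bpv, ncol = m)   # pad codes are 0
  if (m > 0L && n > 0L) {
    cc <- .dosage_to_code[g$dosages + 1L]
    cc[is.na(cc)] <- 1L
    codes[seq_len(n), ] <- cc
  }
  if (m > 0L) {
    i0 <- seq(1L, by = 4L, length.out = bpv)
    bytes <- codes[i0, , drop = FALSE] +
      4L  * codes[i0 + 1L, , drop = FALSE] +
      16L * codes[i0 + 2L, , drop = FALSE] +
      64L * codes[i0 + 3L, , drop = FALSE]
    body <- as.raw(as.vector(bytes))
  } else {
    body <- raw(0)
  }
  writeBin(c(.bed_magic, body), paste0(prefix, ".bed"))

  bim <- data.frame(g$snps$chrom, g$snps$id, rep(0L, m),
                    format(g$snps$pos, scientific = FALSE, trim = TRUE),
                    g$snps$a1, g$snps$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$samples$fid, g$samples$iid, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read or write a GRM in GCTA binary format
#'
#' The GCTA format stores the lower triangle with diagonal of the relatedness
#' matrix as 4-byte little-endian floats, ordered by individual then by pair
#' (`(1,1), (2,1), (2,2), (3,1), ...`), in `prefix.grm.bin`; per-pair
#' non-missing SNP counts analogously in `prefix.grm.N.bin`; and sample ids as
#' two whitespace-separated columns in `prefix.grm.id`.
#'
#' @param prefix path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triple.
#' @return `read_grm_gcta()` returns a [new_grm()] object; `write_grm_gcta()`
#'   returns `prefix` invisibly.
#' @export
read_grm_gcta <- function(prefix) {
  files <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
  for (f in files)
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  ids <- read.table(files[3], header = FALSE, colClasses = "character")
  n <- nrow(ids)
  ntri <- n * (n + 1) / 2
  read_tri <- function(path) {
    if (file.size(path) != 4 * ntri)
      stop(path, " has ", file.size(path), " bytes; expected ", 4 * ntri,
           " for ", n, " individuals", call. = FALSE)
    v <- readBin(path, "numeric", n = ntri, size = 4, endian = "little")
    m <- matrix(0, n, n)
    m[upper.tri(m, diag = TRUE)] <- v   # column-major upper == GCTA pair order
    m + t(m) - diag(diag(m))
  }
  vals <- read_tri(files[1])
  counts <- read_tri(files[2])
  new_grm(vals, counts, data.frame(fid = ids[[1]], iid = ids[[2]]),
          n_snps = max(counts))
}

#' @param grm a [new_grm()] object.
#' @rdname read_grm_gcta
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  ut <- upper.tri(grm$values, diag = TRUE)
  writeBin(as.numeric(grm$values[ut]), paste0(prefix, ".grm.bin"),
           size = 4, endian = "little")
  writeBin(as.numeric(grm$n_pairs[ut]), paste0(prefix, ".grm.N.bin"),
           size = 4, endian = "little")
  write.table(grm$samples[, c("fid", "iid")], paste0(prefix, ".grm.id"),
              quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

.read_id_value_table <- function(path, min_cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(parts)
  if (any(ncols < min_cols))
    stop(path, ": line ", which(ncols < min_cols)[1], " has fewer than ",
         min_cols, " columns", call. = FALSE)
  list(parts = parts, lines = lines)
}

.parse_numeric_col <- function(values, path, col) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) & !(values %in% c("NA", "-9")))
  if (length(bad))
    stop(path, ": non-numeric value '", values[bad[1]], "' in column ", col,
         ", line ", bad[1], call. = FALSE)
  out[values == "-9"] <- NA_real_
  out
}

#' Read a GCTA-style phenotype file
#'
#' Whitespace-delimited `FID IID value` text.  Case/control status may be coded
#' `{0,1}` (0 = control) or `{1,2}` (1 = control); a `{1,2}` coding is
#' normalised to `{0,1}` with a message.  `-9`/`NA` become missing.
#'
#' @param path file path.
#' @return A tibble with columns `fid`, `iid`, `status` (0 control / 1 case).
#' @export
read_phenotype <- function(path) {
  tab <- .read_id_value_table(path, 3L)
  fid <- vapply(tab$parts, `[[`, "", 1L)
  iid <- vapply(tab$parts, `[[`, "", 2L)
  val <- .parse_numeric_col(vapply(tab$parts, `[[`, "", 3L), path, 3L)
  obs <- sort(unique(val[!is.na(val)]))
  if (all(obs %in% c(1, 2)) && length(obs) > 0 && any(obs == 2)) {
    message("phenotype in ", path, " is {1,2}-coded; recoding to {0,1}")
    val <- val - 1
  } else if (!all(obs %in% c(0, 1))) {
    stop(path, ": phenotype values must be coded {0,1} or {1,2}; saw ",
         paste(obs, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(fid = fid, iid = iid, status = val)
}

#' Read a GCTA-style quantitative covariate file
#'
#' Whitespace-delimited `FID IID cov1 [cov2 ...]` text; all covariate values
#' must be present and numeric.
#'
#' @param path file path.
#' @return A tibble with columns `fid`, `iid` and one numeric column per
#'   covariate (`C1`, `C2`, ...).
#' @export
read_covariates <- function(path) {
  tab <- .read_id_value_table(path, 3L)
  k <- min(lengths(tab$parts)) - 2L
  out <- tibble::tibble(
    fid = vapply(tab$parts, `[[`, "", 1L),
    iid = vapply(tab$parts, `[[`, "", 2L)
  )
  for (j in seq_len(k)) {
    v <- .parse_numeric_col(vapply(tab$parts, `[[`, "", 2L + j), path, 2L + j)
    if (anyNA(v))
      stop(path, ": missing covariate value in column ", 2L + j, ", line ",
           which(is.na(v))[1], call. = FALSE)
    out[[paste0("C", j)]] <- v
  }
  out
}
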