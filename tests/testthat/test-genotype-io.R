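test_that("hand-encoded PLINK bed bytes decode to the documented dosages", {
  # 2 individuals, 1 SNP: hom-A1 (code 00) and hom-A2 (code 11) pack into one
  # byte 0b00001100 = 0x0c; A1 dosages must come out [2, 0]
  prefix <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x0c)), paste0(prefix, ".bed"))
  writeLines("1\trs1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines(c("F1 I1 0 0 0 -9", "F2 I2 0 0 0 -9"), paste0(prefix, ".fam"))
  g <- read_plink(paste0(prefix, ".bed"))
  expect_equal(as.vector(g$dosages), c(2L, 0L))
  expect_equal(g$snps$a1, "A")

  # 4 individuals, 1 SNP, all four codes in one byte:
  # (00, 01, 10, 11) -> 0 + 1*4 + 2*16 + 3*64 = 228 -> dosages 2, NA, 1, 0
  prefix2 <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 228)), paste0(prefix2, ".bed"))
  writeLines("2\trs2\t0\t5\tC\tT", paste0(prefix2, ".bim"))
  writeLines(paste0("F", 1:4, " I", 1:4, " 0 0 0 -9"), paste0(prefix2, ".fam"))
  g2 <- read_plink(paste0(prefix2, ".bed"))
  expect_equal(as.vector(g2$dosages), c(2L, NA, 1L, 0L))
})

test_that("PLINK triples round-trip and obey the 2-bit packing rule", {
  g <- rand_geno(5, 7, missing_rate = 0.15, seed = 42)
  prefix <- tempfile()
  write_plink(g, prefix)
  # n = 5 individuals -> ceil(5/4) = 2 bytes per SNP
  expect_equal(file.size(paste0(prefix, ".bed")), 3 + 2 * 7)
  g2 <- read_plink(paste0(prefix, ".bed"))
  expect_identical(g2$dosages, g$dosages)
  expect_equal(g2$snps$chrom, g$snps$chrom)
  expect_equal(g2$snps$id, g$snps$id)
  expect_equal(g2$samples, g$samples)

  # empty SNP set -> valid bed of exactly the 3 header bytes
  g0 <- genotype_matrix(matrix(integer(0), nrow = 3, ncol = 0),
                        snps = data.frame(chrom = character(), id = character(),
                                          pos = numeric(), a1 = character(),
                                          a2 = character()),
                        samples = data.frame(fid = c("A", "B", "C"),
                                             iid = c("1", "2", "3")))
  p0 <- tempfile()
  write_plink(g0, p0)
  expect_equal(file.size(paste0(p0, ".bed")), 3)
  expect_equal(n_snps(read_plink(paste0(p0, ".bed"))), 0L)
})

test_that("corrupt or inconsistent PLINK files raise format errors", {
  g <- rand_geno(2, 3, seed = 7)
  prefix <- tempfile()
  write_plink(g, prefix)
  # enough extra fam individuals to change the per-SNP byte count
  cat(paste0("F", 9:11, " I", 9:11, " 0 0 0 -9\n", collapse = ""),
      file = paste0(prefix, ".fam"), append = TRUE)
  expect_error(read_plink(paste0(prefix, ".bed")), "inconsistent")
  # wrong magic bytes
  bad <- tempfile()
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x0c)), paste0(bad, ".bed"))
  file.copy(paste0(prefix, ".bim"), paste0(bad, ".bim"))
  writeLines(c("F1 I1 0 0 0 -9"), paste0(bad, ".fam"))
  expect_error(read_plink(paste0(bad, ".bed")), "magic")
})

test_that("an independent python decoder agrees with read_plink", {
  g <- rand_geno(9, 6, missing_rate = 0.1, seed = 11)
  prefix <- tempfile()
  write_plink(g, prefix)
  out <- run_python("
import sys
import numpy as np
path, n, m = sys.argv[1], int(sys.argv[2]), int(sys.argv[3])
b = np.fromfile(path, dtype=np.uint8)
assert b[0] == 0x6C and b[1] == 0x1B and b[2] == 0x01
bpv = (n + 3) // 4
body = b[3:].reshape(m, bpv)
lut = {0: 2, 1: -1, 2: 1, 3: 0}
for j in range(m):
    row = []
    for i in range(n):
        byte = body[j, i // 4]
        code = (byte >> (2 * (i % 4))) & 3
        row.append(lut[code])
    print(' '.join(map(str, row)))
", args = c(paste0(prefix, ".bed"), "9", "6"))
  ref <- do.call(cbind, lapply(strsplit(out, " "), as.integer))
  ref[ref == -1L] <- NA_integer_
  expect_identical(ref, g$dosages)
})

test_that("GCTA GRM binaries round-trip bit-exactly with the documented layout", {
  set.seed(5)
  n <- 6
  A <- crossprod(matrix(rnorm(n * n), n)) / n
  A <- A - mean(A[upper.tri(A)])          # force negative off-diagonals
  N <- matrix(120L, n, n)
  samples <- data.frame(fid = paste0("F", 1:n), iid = paste0("I", 1:n))
  grm <- new_grm(A, N, samples, n_snps = 150)

  prefix <- tempfile()
  write_grm_gcta(grm, prefix)
  # n(n+1)/2 stored float32 values
  expect_equal(file.size(paste0(prefix, ".grm.bin")), 4 * n * (n + 1) / 2)
  back <- read_grm_gcta(prefix)
  expect_identical(back$values, t(back$values))          # symmetry exact
  expect_lt(max(abs(back$values - grm$values)), 1e-6)    # float32 storage
  expect_equal(back$n_pairs, grm$n_pairs)
  expect_equal(back$samples$iid, samples$iid)

  # second write of the re-read object reproduces the bytes exactly
  prefix2 <- tempfile()
  write_grm_gcta(back, prefix2)
  expect_identical(readBin(paste0(prefix, ".grm.bin"), "raw", 1000),
                   readBin(paste0(prefix2, ".grm.bin"), "raw", 1000))

  # n = 2 -> 3 stored values = 12 bytes
  g2 <- new_grm(diag(2), matrix(10L, 2, 2), samples[1:2, ], n_snps = 10)
  p2 <- tempfile()
  write_grm_gcta(g2, p2)
  expect_equal(file.size(paste0(p2, ".grm.bin")), 12)

  # truncated binary -> consistency error
  trunc <- readBin(paste0(prefix, ".grm.bin"), "raw", 8)
  writeBin(trunc, paste0(prefix, ".grm.bin"))
  expect_error(read_grm_gcta(prefix), "expected")
})

test_that("an independent python parser reads our GRM files", {
  set.seed(9)
  n <- 5
  A <- crossprod(matrix(rnorm(n * 8), ncol = n)) / 8
  grm <- new_grm(A, matrix(40L, n, n),
                 data.frame(fid = paste0("F", 1:n), iid = paste0("I", 1:n)),
                 n_snps = 40)
  prefix <- tempfile()
  write_grm_gcta(grm, prefix)
  out <- run_python("
import sys
import numpy as np
prefix, n = sys.argv[1], int(sys.argv[2])
v = np.fromfile(prefix + '.grm.bin', dtype='<f4')
assert v.size == n * (n + 1) // 2
k = 0
for i in range(n):
    for j in range(i + 1):
        print(i, j, repr(float(v[k])))
        k += 1
", args = c(prefix, as.character(n)))
  for (line in out) {
    f <- strsplit(line, " ")[[1]]
    i <- as.integer(f[1]) + 1L
    j <- as.integer(f[2]) + 1L
    expect_equal(as.numeric(f[3]), grm$values[i, j], tolerance = 1e-6)
  }
})

test_that("phenotype files parse with both codings and report bad lines", {
  f <- tempfile()
  writeLines(c("F1 I1 1", "F2 I2 0"), f)
  ph <- read_phenotype(f)
  expect_equal(ph$status, c(1, 0))
  expect_equal(ph$fid, c("F1", "F2"))

  # {1,2} coding normalises to the {0,1} twin, with a notice
  f12 <- tempfile()
  writeLines(c("F1 I1 2", "F2 I2 1"), f12)
  expect_message(ph12 <- read_phenotype(f12), "recoding")
  expect_equal(ph12$status, ph$status)

  fbad <- tempfile()
  writeLines(c("F1 I1 1", "F2 I2 ??"), fbad)
  expect_error(read_phenotype(fbad), "line 2")

  fshort <- tempfile()
  writeLines("F1 I1", fshort)
  expect_error(read_phenotype(fshort), "fewer than 3")
})

test_that("covariate files parse into the expected number of PC columns", {
  f <- tempfile()
  writeLines(c("F1 I1 0.12 -0.5", "F2 I2 -0.03 0.7"), f)
  cv <- read_covariates(f)
  expect_equal(ncol(cv), 4)          # fid, iid + two principal components
  expect_equal(cv$C2, c(-0.5, 0.7))
  fbad <- tempfile()
  writeLines(c("F1 I1 0.1", "F2 I2 NA"), fbad)
  expect_error(read_covariates(fbad), "missing covariate")
})

test_that("randomised round trips hold for every reader/writer pair", {
  for (seed in 1:3) {
    g <- rand_geno(10, 20, missing_rate = 0.08, seed = seed)
    p <- tempfile()
    write_plink(g, p)
    expect_identical(read_plink(paste0(p, ".bed"))$dosages, g$dosages)

    grm <- compute_grm(g, maf_min = 0)
    pg <- tempfile()
    write_grm_gcta(grm, pg)
    back <- read_grm_gcta(pg)
    expect_identical(back$values, t(back$values))
    expect_lt(max(abs(back$values - grm$values)), 1e-6)
  }
})
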