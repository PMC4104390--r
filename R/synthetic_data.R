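# Synthetic cohorts with the statistical structure the estimator assumes:
# independent biallelic SNPs (optionally two Balding-Nichols subpopulations),
# a liability-threshold binary trait with chosen liability-scale h2 and
# per-chromosome causal placement, and low-prevalence ascertained case-control
# sampling by rejection.

# Named RNG streams derived from one integer seed, so that e.g. toggling
# missingness does not perturb the genotype draws.
.stream_names <- c("freq", "effects", "geno", "residual", "missing")

.make_streams <- function(seed) {
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, length(.stream_names)))
  env <- new.env(parent = emptyenv())
  for (i in seq_along(.stream_names)) {
    withr::with_seed(seeds[i], assign(.stream_names[i], get(".Random.seed", globalenv()), envir = env))
  }
  env
}

.with_stream <- function(streams, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Configure a synthetic cohort simulation
#'
#' Defines the generative model for [simulate_cohort()]: ancestral allele
#' frequencies uniform on `maf_range`; genotypes binomial(2, p) per SNP
#' (per-subpopulation frequencies from a Balding-Nichols model when
#' `fst > 0`); liability equal to a genetic component from standardised causal
#' dosages plus normal residual noise with total unit variance; case status by
#' thresholding liability at the quantile of the population prevalence; and
#' ascertained sampling of `n_cases` cases with `case_control_ratio` times as
#' many controls.
#'
#' @param n_snps_per_chrom named integer vector: chromosome label -> number of
#'   SNPs.
#' @param causal data frame with columns `chrom`, `n_causal`, `h2_share`
#'   giving, per chromosome, how many causal SNPs to place there and how much
#'   liability variance they jointly explain.  `NULL` (with `h2_true = 0`)
#'   means no genetic signal.
#' @param h2_true liability-scale heritability; must equal the sum of
#'   `h2_share` (default: that sum).
#' @param prevalence population prevalence K of the trait, in (0, 0.5).
#' @param n_cases number of cases to ascertain.
#' @param case_control_ratio controls per case (default 3, the 1:3 design).
#' @param maf_range range for ancestral allele frequencies (default
#'   `c(0.05, 0.5)`).
#' @param fst Wright's fixation index for an optional two-subpopulation
#'   structure model; 0 (default) gives one homogeneous population.
#' @param missing_rate fraction of dosages set missing uniformly at random.
#' @param seed integer seed; every stream of randomness derives from it.
#' @param max_draws cap on the number of individuals simulated while waiting
#'   for `n_cases` cases to accrue (default 1e7); guards runaway rejection
#'   sampling at very low prevalence.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps_per_chrom, causal = NULL, h2_true = NULL,
                              prevalence, n_cases, case_control_ratio = 3,
                              maf_range = c(0.05, 0.5), fst = 0,
                              missing_rate = 0, seed = 1, max_draws = 1e7) {
  n_snps_per_chrom <- stats::setNames(as.integer(n_snps_per_chrom),
                                      names(n_snps_per_chrom))
  if (is.null(names(n_snps_per_chrom)) || any(!nzchar(names(n_snps_per_chrom))))
    stop("n_snps_per_chrom must be named by chromosome label", call. = FALSE)
  if (any(n_snps_per_chrom <= 0)) stop("SNP counts must be positive", call. = FALSE)
  if (!is.null(causal)) {
    causal <- tibble::as_tibble(causal)
    stopifnot(all(c("chrom", "n_causal", "h2_share") %in% names(causal)))
    causal$chrom <- as.character(causal$chrom)
    if (!all(causal$chrom %in% names(n_snps_per_chrom)))
      stop("causal chromosomes absent from n_snps_per_chrom", call. = FALSE)
    if (any(causal$n_causal <= 0) || any(causal$h2_share < 0))
      stop("invalid causal specification", call. = FALSE)
    if (any(causal$n_causal > n_snps_per_chrom[causal$chrom]))
      stop("more causal SNPs requested than SNPs on the chromosome",
           call. = FALSE)
  }
  share_sum <- if (is.null(causal)) 0 else sum(causal$h2_share)
  if (is.null(h2_true)) h2_true <- share_sum
  if (abs(h2_true - share_sum) > 1e-8)
    stop("h2_true (", h2_true, ") must equal the sum of h2_share (",
         share_sum, ")", call. = FALSE)
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 0.5)
    stop("prevalence must be in (0, 0.5)", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (n_cases <= 0 || case_control_ratio <= 0)
    stop("n_cases and case_control_ratio must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(
    n_snps_per_chrom = n_snps_per_chrom, causal = causal, h2_true = h2_true,
    prevalence = prevalence, n_cases = as.integer(n_cases),
    case_control_ratio = case_control_ratio, maf_range = maf_range,
    fst = fst, missing_rate = missing_rate, seed = as.integer(seed),
    max_draws = max_draws
  ), class = "simulation_config")
}

.snp_table <- function(n_snps_per_chrom) {
  chroms <- rep(names(n_snps_per_chrom), n_snps_per_chrom)
  within <- unlist(lapply(n_snps_per_chrom, seq_len), use.names = FALSE)
  tibble::tibble(chrom = chroms,
                 id = paste0("chr", chroms, "_snp", within),
                 pos = within * 1000, a1 = "A", a2 = "B")
}

.draw_freqs <- function(m, maf_range, fst) {
  p_anc <- runif(m, maf_range[1], maf_range[2])
  if (fst > 0) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    p_sub <- cbind(rbeta(m, a, b), rbeta(m, a, b))
    p_sub[] <- pmin(pmax(p_sub, 1e-4), 1 - 1e-4)
  } else p_sub <- NULL
  list(anc = p_anc, sub = p_sub)
}

# genotypes for `n` individuals at the SNPs indexed by `cols`; `pop` is the
# subpopulation index per individual (all 1 when there is no structure)
.draw_genotypes <- function(n, cols, freqs, pop) {
  m <- length(cols)
  if (is.null(freqs$sub)) {
    p <- freqs$anc[cols]
    matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  } else {
    out <- matrix(0L, n, m)
    for (s in unique(pop)) {
      rows <- pop == s
      p <- freqs$sub[cols, s]
      out[rows, ] <- rbinom(sum(rows) * m, 2L, rep(p, each = sum(rows)))
    }
    out
  }
}

#' Simulate an ascertained liability-threshold case-control cohort
#'
#' Runs the generative model of [simulation_config()].  Causal effects are
#' drawn i.i.d. normal per chromosome and rescaled so the genetic liability
#' variance from each chromosome equals its `h2_share` exactly (effects apply
#' to dosages standardised at the generating ancestral frequency); residual
#' liability is normal with variance `1 - h2_true`, so liabilities have unit
#' population variance.  Ascertainment is by rejection: individuals are
#' simulated in batches until `n_cases` liabilities exceed the threshold
#' `qnorm(1 - prevalence)`, and the first `round(ratio * n_cases)` simulated
#' controls are retained.  Because non-causal SNPs are independent of
#' liability, only causal genotypes are drawn during the rejection loop;
#' non-causal genotypes are filled in for the retained individuals afterwards
#' (an exact shortcut, not an approximation).  Missingness, if requested, is
#' applied uniformly at random from its own RNG stream.
#'
#' @param config a [simulation_config()].
#' @return A list of class `simulated_cohort`: `genotypes`
#'   ([genotype_matrix()]), `phenotype` (tibble `fid`, `iid`, `status`),
#'   `liabilities`, `true_effects` (tibble `snp_id`, `chrom`, `beta`, on the
#'   standardised-dosage scale), `subpop` (when `fst > 0`), `n_simulated` and
#'   `n_cases_seen` (pre-ascertainment totals), and the `config` echo.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  streams <- .make_streams(config$seed)
  snps <- .snp_table(config$n_snps_per_chrom)
  m <- nrow(snps)

  freqs <- .with_stream(streams, "freq",
                        .draw_freqs(m, config$maf_range, config$fst))

  causal_idx <- integer(0)
  beta <- numeric(0)
  if (!is.null(config$causal)) {
    picks <- .with_stream(streams, "effects", {
      lapply(seq_len(nrow(config$causal)), function(r) {
        on_chr <- which(snps$chrom == config$causal$chrom[r])
        idx <- sort(sample(on_chr, config$causal$n_causal[r]))
        u <- rnorm(length(idx))
        list(idx = idx, beta = u * sqrt(config$causal$h2_share[r] / sum(u^2)))
      })
    })
    causal_idx <- unlist(lapply(picks, `[[`, "idx"))
    beta <- unlist(lapply(picks, `[[`, "beta"))
  }

  t_thr <- qnorm(config$prevalence, lower.tail = FALSE)
  n_controls <- round(config$case_control_ratio * config$n_cases)
  sd_resid <- sqrt(1 - config$h2_true)
  p_c <- freqs$anc[causal_idx]
  scale_c <- sqrt(2 * p_c * (1 - p_c))

  batch <- max(1000L, min(20000L, ceiling(config$n_cases / config$prevalence / 10)))
  kept_geno <- list(); kept_liab <- list(); kept_case <- list(); kept_pop <- list()
  n_cases_got <- 0L; n_controls_got <- 0L
  n_simulated <- 0; n_cases_seen <- 0
  while (n_cases_got < config$n_cases || n_controls_got < n_controls) {
    if (n_simulated >= config$max_draws)
      stop("simulated ", n_simulated, " individuals without accruing ",
           config$n_cases, " cases at prevalence ", config$prevalence,
           "; raise max_draws or the prevalence", call. = FALSE)
    pop <- if (config$fst > 0)
      .with_stream(streams, "geno", sample(1:2, batch, replace = TRUE))
    else rep(1L, batch)
    gc_mat <- if (length(causal_idx))
      .with_stream(streams, "geno", .draw_genotypes(batch, causal_idx, freqs, pop))
    else matrix(0L, batch, 0)
    gliab <- if (length(causal_idx))
      drop(sweep(gc_mat, 2, 2 * p_c, "-") %*% (beta / scale_c))
    else numeric(batch)
    liab <- gliab + .with_stream(streams, "residual", rnorm(batch, 0, sd_resid))
    is_case <- liab > t_thr
    n_simulated <- n_simulated + batch
    n_cases_seen <- n_cases_seen + sum(is_case)

    take_case <- which(is_case)[seq_len(min(sum(is_case),
                                            config$n_cases - n_cases_got))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case),
                                             n_controls - n_controls_got))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take)) {
      kept_geno[[length(kept_geno) + 1L]] <- gc_mat[take, , drop = FALSE]
      kept_liab[[length(kept_liab) + 1L]] <- liab[take]
      kept_case[[length(kept_case) + 1L]] <- is_case[take]
      kept_pop[[length(kept_pop) + 1L]] <- pop[take]
    }
    n_cases_got <- n_cases_got + length(take_case)
    n_controls_got <- n_controls_got + length(take_ctrl)
  }

  liab <- unlist(kept_liab)
  status <- as.integer(unlist(kept_case))
  pop <- unlist(kept_pop)
  n <- length(liab)
  dos <- matrix(0L, n, m)
  if (length(causal_idx)) dos[, causal_idx] <- do.call(rbind, kept_geno)
  noncausal <- setdiff(seq_len(m), causal_idx)
  if (length(noncausal))
    dos[, noncausal] <- .with_stream(streams, "geno",
                                     .draw_genotypes(n, noncausal, freqs, pop))
  if (config$missing_rate > 0) {
    drop_mask <- .with_stream(streams, "missing",
                              runif(n * m) < config$missing_rate)
    dos[drop_mask] <- NA_integer_
  }

  g <- genotype_matrix(
    dos, snps,
    samples = data.frame(fid = paste0("F", seq_len(n)),
                         iid = paste0("I", seq_len(n)))
  )
  structure(list(
    genotypes = g,
    phenotype = tibble::tibble(fid = g$samples$fid, iid = g$samples$iid,
                               status = status),
    liabilities = liab,
    true_effects = tibble::tibble(snp_id = snps$id[causal_idx],
                                  chrom = snps$chrom[causal_idx], beta = beta),
    subpop = if (config$fst > 0) pop else NULL,
    n_simulated = n_simulated, n_cases_seen = n_cases_seen,
    config = config
  ), class = "simulated_cohort")
}

#' Simulate a genotype-independent (null) case-control cohort
#'
#' Emulates the controls-coded-as-cases negative control: genotypes are drawn
#' for `n_groupA + n_groupB` individuals and the case/control labels are
#' assigned purely by group membership (group A = "cases"), independent of
#' genotype, so the true SNP heritability of the label is zero.  With
#' `fst > 0` the two groups are drawn from two Balding-Nichols
#' subpopulations, giving a structure-confounded null for exercising
#' principal-component adjustment.
#'
#' @param n_groupA,n_groupB group sizes; group A is labelled case.
#' @param n_snps_per_chrom named integer vector, as in [simulation_config()].
#' @param maf_range,fst,missing_rate,seed as in [simulation_config()].
#' @return A `simulated_cohort` with empty `true_effects` and no liabilities.
#' @export
simulate_null_cohort <- function(n_groupA, n_groupB, n_snps_per_chrom,
                                 maf_range = c(0.05, 0.5), fst = 0,
                                 missing_rate = 0, seed = 1) {
  stopifnot(n_groupA > 0, n_groupB > 0)
  streams <- .make_streams(seed)
  snps <- .snp_table(stats::setNames(as.integer(n_snps_per_chrom),
                                     names(n_snps_per_chrom)))
  m <- nrow(snps)
  n <- n_groupA + n_groupB
  freqs <- .with_stream(streams, "freq", .draw_freqs(m, maf_range, fst))
  pop <- if (fst > 0) rep(1:2, c(n_groupA, n_groupB)) else rep(1L, n)
  dos <- .with_stream(streams, "geno", .draw_genotypes(n, seq_len(m), freqs, pop))
  if (missing_rate > 0) {
    drop_mask <- .with_stream(streams, "missing", runif(n * m) < missing_rate)
    dos[drop_mask] <- NA_integer_
  }
  g <- genotype_matrix(
    dos, snps,
    samples = data.frame(fid = paste0("F", seq_len(n)),
                         iid = paste0("I", seq_len(n)))
  )
  structure(list(
    genotypes = g,
    phenotype = tibble::tibble(fid = g$samples$fid, iid = g$samples$iid,
                               status = rep(c(1L, 0L), c(n_groupA, n_groupB))),
    liabilities = NULL,
    true_effects = tibble::tibble(snp_id = character(), chrom = character(),
                                  beta = numeric()),
    subpop = if (fst > 0) pop else NULL,
    n_simulated = n, n_cases_seen = n_groupA,
    config = list(n_groupA = n_groupA, n_groupB = n_groupB,
                  n_snps_per_chrom = n_snps_per_chrom, maf_range = maf_range,
                  fst = fst, missing_rate = missing_rate, seed = seed)
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", sum(x$phenotype$status == 1), " cases / ",
      sum(x$phenotype$status == 0), " controls, ", n_snps(x$genotypes),
      " SNPs, ", nrow(x$true_effects), " causal\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to PLINK + phenotype files
#'
#' Emits the cohort through the standard writers: a PLINK `.bed/.bim/.fam`
#' triple, a GCTA-style `.phen` file, and a JSON sidecar `prefix.truth.json`
#' with the true simulation parameters for parameter-recovery work.
#'
#' @param cohort a `simulated_cohort`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  write_plink(cohort$genotypes, prefix)
  write.table(cohort$phenotype, paste0(prefix, ".phen"), quote = FALSE,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  truth <- list(
    true_effects = cohort$true_effects,
    n_simulated = cohort$n_simulated,
    n_cases_seen = cohort$n_cases_seen,
    config = cohort$config[setdiff(names(cohort$config), "causal")],
    causal = if (!is.null(cohort$config$causal)) cohort$config$causal
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    saveRDS(truth, paste0(prefix, ".truth.rds"))
  }
  invisible(prefix)
}
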