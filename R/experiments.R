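# End-to-end experiment drivers: partitioned heritability at one or more
# prevalences, subsampling robustness at moderate sample sizes, and the
# controls-coded-as-cases negative control.

.new_report <- function(design, rows, summary, seeds, config) {
  structure(list(design = design, rows = rows, summary = summary,
                 seeds = seeds, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> design:", x$design, "\n")
  print(x$summary)
  invisible(x)
}

.snp_set_grms <- function(g, snp_sets, focal_chrom, maf_min, adj_ld) {
  grms <- lapply(snp_sets, function(set) {
    grm <- switch(set,
                  all = compute_grm(g, maf_min = maf_min),
                  focal = compute_grm(g, maf_min = maf_min, chr = focal_chrom),
                  rest = compute_grm(g, maf_min = maf_min,
                                     exclude_chr = focal_chrom))
    if (!is.null(adj_ld)) grm <- adjust_grm_ld(grm, c = adj_ld)
    grm
  })
  names(grms) <- snp_sets
  grms
}

.set_label <- function(set, focal_chrom) {
  switch(set, all = "all", focal = paste0("chr", focal_chrom),
         rest = paste0("NOchr", focal_chrom))
}

# single-component fit + liability transform for one SNP set
.fit_and_transform <- function(grm, phen, covs, prevalences, constrain = TRUE) {
  fit <- fit_reml(phen, grm, covariates = covs, constrain = constrain)
  tot <- fit$h2_obs[fit$h2_obs$component == "total", ]
  purrr::map_dfr(prevalences, function(K) {
    li <- observed_to_liability(tot$estimate, tot$se, K = K,
                                P = fit$case_proportion)
    tibble::tibble(prevalence = K, h2_obs = tot$estimate, se_obs = tot$se,
                   h2_liability = li$h2_liability,
                   se_liability = li$se_liability,
                   converged = fit$converged, boundary = tot$boundary)
  })
}

#' Partitioned heritability across SNP sets and prevalences
#'
#' Fits single-component GREML models on the all-SNP GRM, the focal-chromosome
#' GRM, and the complement GRM, then transforms each observed-scale estimate
#' to the liability scale at every requested prevalence.  Mirrors the
#' genome-wide / chromosome-6 / without-chromosome-6 partition used to ask how
#' much of the SNP heritability the MHC region carries.  Principal components
#' of the all-SNP GRM may be included as fixed covariates to adjust for global
#' population structure.
#'
#' @param cohort a `simulated_cohort`, or any list with elements `genotypes`
#'   ([genotype_matrix()]) and `phenotype` (tibble `fid`, `iid`, `status`).
#' @param prevalences numeric vector of population prevalences K.
#' @param focal_chrom chromosome label to partition on (default `"6"`).
#' @param pcs number of principal components of the all-SNP GRM to include as
#'   covariates (default 2; use 0 for a homogeneous cohort).
#' @param adj_ld `NULL` for no LD adjustment (default), or the `c` parameter
#'   passed to [adjust_grm_ld()] (0 for the usual tool setting).
#' @param maf_min minor-allele-frequency cutoff for [compute_grm()].
#' @return An `experiment_report` whose `rows` have one row per
#'   (snp_set, prevalence) with observed- and liability-scale estimates and
#'   model SEs.
#' @export
run_partitioned <- function(cohort, prevalences, focal_chrom = "6", pcs = 2,
                            adj_ld = NULL, maf_min = 0.01) {
  g <- cohort$genotypes
  if (!focal_chrom %in% g$snps$chrom)
    stop("focal chromosome '", focal_chrom, "' absent from the genotypes",
         call. = FALSE)
  grms <- .snp_set_grms(g, c("all", "focal", "rest"), focal_chrom, maf_min,
                        adj_ld)
  covs <- if (pcs > 0) grm_pca(grms$all, pcs) else NULL
  rows <- purrr::map_dfr(names(grms), function(set) {
    dplyr::mutate(
      .fit_and_transform(grms[[set]], cohort$phenotype, covs, prevalences),
      snp_set = .set_label(set, focal_chrom), replicate = 1L,
      .before = 1
    )
  })
  summary <- dplyr::summarise(
    dplyr::group_by(rows, .data$snp_set, .data$prevalence),
    mean_h2_liability = mean(.data$h2_liability),
    sd_h2_liability = NA_real_,
    mean_se_model = mean(.data$se_liability),
    n_replicates = dplyr::n(), .groups = "drop"
  )
  .new_report("partitioned", rows, summary, seeds = NULL,
              config = list(prevalences = prevalences,
                            focal_chrom = focal_chrom, pcs = pcs,
                            adj_ld = adj_ld, maf_min = maf_min))
}

#' Subsampling stability of heritability estimates at moderate sample sizes
#'
#' Repeatedly draws `n_cases` cases and `ratio * n_cases` controls (without
#' replacement within a draw; draws may overlap across replicates) from a
#' large case-control pool, runs the full GRM + REML + liability pipeline on
#' each draw, and summarises the replicate estimates by their mean and
#' standard deviation — the convention of reporting "mean (SD over twenty
#' random selections)" used to probe estimator stability at sample sizes
#' typical of pharmacogenetic cohorts.
#'
#' @param pool a `simulated_cohort` (or compatible list) holding more cases
#'   and controls than one draw needs.
#' @param n_cases cases per draw.
#' @param ratio controls per case (default 3).
#' @param reps number of random selections (default 20).
#' @param prevalence population prevalence K for the liability transform.
#' @param seed integer seed for the draws.
#' @param snp_sets subset of `c("all", "focal", "rest")` to fit per draw.
#' @param pcs principal components per draw (default 0: the intended pool is
#'   homogeneous).
#' @inheritParams run_partitioned
#' @return An `experiment_report`; `summary` holds the mean and (for
#'   `reps > 1`) SD of the liability-scale estimates per SNP set.
#' @export
run_subsample <- function(pool, n_cases, ratio = 3, reps = 20, prevalence,
                          seed = 1, snp_sets = c("all", "focal", "rest"),
                          focal_chrom = "6", pcs = 0, adj_ld = NULL,
                          maf_min = 0.01) {
  snp_sets <- match.arg(snp_sets, several.ok = TRUE)
  phen <- pool$phenotype
  case_idx <- which(phen$status == 1)
  ctrl_idx <- which(phen$status == 0)
  n_ctrl <- round(ratio * n_cases)
  if (length(case_idx) < n_cases || length(ctrl_idx) < n_ctrl)
    stop("pool too small: need >= ", n_cases, " cases and >= ", n_ctrl,
         " controls, have ", length(case_idx), " / ", length(ctrl_idx),
         call. = FALSE)
  draws <- withr::with_seed(as.integer(seed), lapply(seq_len(reps), function(r) {
    sort(c(sample(case_idx, n_cases), sample(ctrl_idx, n_ctrl)))
  }))
  rows <- purrr::map_dfr(seq_len(reps), function(r) {
    g_r <- subset_samples(pool$genotypes, draws[[r]])
    phen_r <- phen[draws[[r]], ]
    grms <- .snp_set_grms(g_r, snp_sets, focal_chrom, maf_min, adj_ld)
    covs <- if (pcs > 0) grm_pca(grms[["all"]], pcs) else NULL
    purrr::map_dfr(names(grms), function(set) {
      dplyr::mutate(
        .fit_and_transform(grms[[set]], phen_r, covs, prevalence),
        snp_set = .set_label(set, focal_chrom), replicate = r, .before = 1
      )
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(rows, .data$snp_set, .data$prevalence),
    mean_h2_liability = mean(.data$h2_liability),
    sd_h2_liability = if (reps > 1) sd(.data$h2_liability) else NA_real_,
    mean_se_model = mean(.data$se_liability),
    n_replicates = dplyr::n(), .groups = "drop"
  )
  .new_report("subsample", rows, summary, seeds = seed,
              config = list(n_cases = n_cases, ratio = ratio, reps = reps,
                            prevalence = prevalence, snp_sets = snp_sets,
                            focal_chrom = focal_chrom, pcs = pcs,
                            adj_ld = adj_ld, maf_min = maf_min))
}

#' Negative control: heritability of genotype-independent labels
#'
#' Runs the all-SNP pipeline on a cohort whose case/control labels were
#' assigned independently of genotype (e.g. two control sets relabelled as
#' pseudo-cases and pseudo-controls, from [simulate_null_cohort()]).  A
#' constrained estimate near zero indicates no substantial measurement or
#' batch artefact; systematically positive estimates would.
#'
#' @param null_cohort a `simulated_cohort` (or compatible list) with
#'   genotype-independent labels.
#' @param prevalence population prevalence K used for the liability transform
#'   (default 0.0005, the rare-trait setting of the original control).
#' @param pcs principal components to include (default 0).
#' @inheritParams run_partitioned
#' @return An `experiment_report` with a single all-SNP row.
#' @export
run_negative_control <- function(null_cohort, prevalence = 0.0005, pcs = 0,
                                 maf_min = 0.01, adj_ld = NULL) {
  grm_all <- compute_grm(null_cohort$genotypes, maf_min = maf_min)
  if (!is.null(adj_ld)) grm_all <- adjust_grm_ld(grm_all, c = adj_ld)
  covs <- if (pcs > 0) grm_pca(grm_all, pcs) else NULL
  rows <- dplyr::mutate(
    .fit_and_transform(grm_all, null_cohort$phenotype, covs, prevalence),
    snp_set = "all", replicate = 1L, .before = 1
  )
  summary <- dplyr::summarise(
    dplyr::group_by(rows, .data$snp_set, .data$prevalence),
    mean_h2_liability = mean(.data$h2_liability),
    sd_h2_liability = NA_real_,
    mean_se_model = mean(.data$se_liability),
    n_replicates = dplyr::n(), .groups = "drop"
  )
  .new_report("negative_control", rows, summary, seeds = NULL,
              config = list(prevalence = prevalence, pcs = pcs,
                            maf_min = maf_min, adj_ld = adj_ld))
}

#' Plot an experiment report
#'
#' Liability-scale estimates per SNP set, with error bars: the replicate SD
#' for multi-replicate designs (subsampling), otherwise the model SE.
#'
#' @param object an `experiment_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.experiment_report <- function(object, ...) {
  s <- object$summary
  s$err <- ifelse(is.na(s$sd_h2_liability), s$mean_se_model, s$sd_h2_liability)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$snp_set, y = .data$mean_h2_liability,
                                  colour = factor(.data$prevalence))) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4), size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_h2_liability - .data$err,
                   ymax = .data$mean_h2_liability + .data$err),
      position = ggplot2::position_dodge(0.4), width = 0.2
    ) +
    ggplot2::labs(x = "SNP set", y = expression(h^2 ~ "(liability scale)"),
                  colour = "prevalence K",
                  title = paste0(object$design, " experiment")) +
    ggplot2::theme_minimal()
}
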