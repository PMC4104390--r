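# GREML: restricted maximum likelihood for y = X beta + sum_r g_r + e with
# g_r ~ N(0, sigma2_g[r] * A_r), e ~ N(0, sigma2_e * I).  The binary trait
# enters as 0/1 on the observed scale; liability conversion is post hoc.

#' Restricted log-likelihood of a variance-component mixed model
#'
#' Direct dense evaluation of
#' \deqn{\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right]}
#' with \eqn{V = \sum_r \sigma^2_{g_r} A_r + \sigma^2_e I} and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}} (additive constants
#' dropped).  Exposed so that an external maximiser — e.g. a grid search — can
#' serve as an independent check on [fit_reml()].
#'
#' @param y numeric response vector (0/1 disease status in the intended use).
#' @param X fixed-effect design: `NULL` for intercept only, or a numeric
#'   matrix/data frame of covariates.  An intercept column is always included.
#' @param grms a [new_grm()] object, a list of them, or a plain symmetric
#'   matrix / list of matrices, aligned with `y`.
#' @param sigma2_g numeric vector of genetic variance(s), one per GRM.
#' @param sigma2_e residual variance.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_log_likelihood <- function(y, X = NULL, grms, sigma2_g, sigma2_e) {
  a_list <- .as_grm_matrices(grms)
  n <- length(y)
  stopifnot(length(sigma2_g) == length(a_list))
  for (a in a_list) stopifnot(all(dim(a) == n))
  X <- .design_matrix(X, n)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design X is rank deficient", call. = FALSE)

  V <- diag(sigma2_e, n)
  for (r in seq_along(a_list)) V <- V + sigma2_g[r] * a_list[[r]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R))
    stop("V is not positive definite at these variance components",
         call. = FALSE)
  ldV <- 2 * sum(log(diag(R)))
  Vinv <- chol2inv(R)
  ViX <- Vinv %*% X
  C <- crossprod(X, ViX)
  Rc <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Rc))
    stop("X'V^{-1}X is singular", call. = FALSE)
  ldC <- 2 * sum(log(diag(Rc)))
  Viy <- Vinv %*% y
  b <- crossprod(X, Viy)
  beta <- backsolve(Rc, forwardsolve(t(Rc), b))
  yPy <- sum(y * Viy) - sum(b * beta)
  -0.5 * (ldV + ldC + yPy)
}

.as_grm_matrices <- function(grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  if (is.matrix(grms)) grms <- list(grms)
  lapply(grms, function(g) if (inherits(g, "grm")) g$values else as.matrix(g))
}

.design_matrix <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("X has ", nrow(X), " rows; expected ", n, call. = FALSE)
  has_const <- any(apply(X, 2, function(col) sd(col) == 0 & col[1] != 0))
  if (!has_const) X <- cbind(`(Intercept)` = 1, X)
  X
}

# Engines return, for a parameter vector theta = c(sigma2_g..., sigma2_e):
# ll, grad, AI matrix, trPA, yPAPy, beta — or NULL when V (or X'VinvX) fails.

.engine_fast <- function(A, y, X) {
  ed <- eigen(A, symmetric = TRUE)
  d <- ed$values
  yt <- drop(crossprod(ed$vectors, y))
  Xt <- crossprod(ed$vectors, X)
  function(theta) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 0)) return(NULL)
    w <- 1 / v
    Xw <- Xt * w
    C <- crossprod(Xt, Xw)
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Cinv <- chol2inv(R)
    b <- crossprod(Xw, yt)
    beta <- drop(Cinv %*% b)
    Py <- drop(w * yt - Xw %*% beta)
    yPy <- sum(yt * Py)
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(R))) + yPy)
    Pv <- function(x) drop(w * x - Xw %*% (Cinv %*% crossprod(Xw, x)))
    trPA <- c(sum(w * d) - sum(Cinv * crossprod(Xt, Xt * (d * w^2))),
              sum(w)     - sum(Cinv * crossprod(Xt, Xt * w^2)))
    APy <- d * Py
    yPAPy <- c(sum(d * Py^2), sum(Py^2))
    PAPy <- Pv(APy)
    PPy <- Pv(Py)
    AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                         sum(APy * PPy),  sum(Py * PPy)), 2, 2)
    list(ll = ll, grad = -0.5 * (trPA - yPAPy), AI = AI,
         trPA = trPA, yPAPy = yPAPy, beta = beta)
  }
}

.engine_dense <- function(a_list, y, X) {
  n <- length(y)
  comps <- c(a_list, list(diag(1, n)))   # residual component last
  function(theta) {
    V <- matrix(0, n, n)
    for (r in seq_along(comps)) V <- V + theta[r] * comps[[r]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vinv <- chol2inv(R)
    ViX <- Vinv %*% X
    C <- crossprod(X, ViX)
    Rc <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Rc)) return(NULL)
    Cinv <- chol2inv(Rc)
    Viy <- drop(Vinv %*% y)
    b <- drop(crossprod(X, Viy))
    beta <- drop(Cinv %*% b)
    Py <- Viy - drop(ViX %*% beta)
    yPy <- sum(y * Py)
    ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rc))) + yPy)
    Pv <- function(x) drop(Vinv %*% x - ViX %*% (Cinv %*% crossprod(ViX, x)))
    ViXC <- ViX %*% Cinv
    k1 <- length(comps)
    trPA <- yPAPy <- numeric(k1)
    APy <- vector("list", k1)
    for (r in seq_len(k1)) {
      Ar <- comps[[r]]
      trPA[r] <- sum(Vinv * Ar) - sum(ViXC * (Ar %*% ViX))
      APy[[r]] <- drop(Ar %*% Py)
      yPAPy[r] <- sum(Py * APy[[r]])
    }
    AI <- matrix(0, k1, k1)
    PAPy <- lapply(APy, Pv)
    for (r in seq_len(k1))
      for (s in r:k1)
        AI[r, s] <- AI[s, r] <- 0.5 * sum(APy[[r]] * PAPy[[s]])
    list(ll = ll, grad = -0.5 * (trPA - yPAPy), AI = AI,
         trPA = trPA, yPAPy = yPAPy, beta = beta)
  }
}

#' Fit a GREML mixed model by AI-REML
#'
#' Estimates variance components of
#' `y = X beta + sum_r g_r + e`, `g_r ~ N(0, sigma2_g[r] A_r)`, by restricted
#' maximum likelihood: one EM step from equal-split starting values, then
#' average-information (AI) updates with step-halving whenever a proposed move
#' decreases the restricted likelihood, falling back to an EM step when the AI
#' matrix is singular or the AI move cannot improve.  With `constrain = TRUE`
#' (default) variance components are clamped at a small positive floor, which
#' bounds the observed-scale heritability to `[0, 1]`; estimates sitting on
#' the floor are flagged as boundary estimates and their standard errors
#' (from the inverse AI matrix) are unreliable.
#'
#' Single-GRM fits are computed in the eigenbasis of the GRM (one
#' decomposition, then O(n) per iteration); multi-component fits use dense
#' algebra.  Both maximise exactly the function exposed by
#' [restricted_log_likelihood()].
#'
#' @param phenotype tibble with columns `fid`, `iid` and a third numeric
#'   column (0/1 status), e.g. from [read_phenotype()]; or a bare numeric
#'   vector already aligned with the GRM.
#' @param grms a [new_grm()] object or a (optionally named) list of them; all
#'   must cover the same individuals.
#' @param covariates optional covariate tibble (`fid`, `iid`, numeric columns),
#'   e.g. from [grm_pca()] or [read_covariates()]; or an aligned numeric
#'   matrix.  An intercept is always added.
#' @param max_iter maximum REML iterations (default 100).
#' @param tol convergence tolerance on the change in restricted log-likelihood
#'   (default 1e-8).
#' @param algorithm `"ai"` (EM first step, then average information; default)
#'   or `"em"` (EM throughout; slower, derivative-free in the AI sense).
#' @param constrain clamp variance components to be non-negative (default
#'   `TRUE`).
#' @param allow_subset if `TRUE`, individuals missing from the phenotype or
#'   covariates are dropped from the GRM instead of raising an error.
#' @return An object of class `greml_fit`: variance components `sigma2`
#'   (named, residual last), `se_sigma2`, sampling covariance `cov_sigma2`,
#'   `loglik`, fixed effects `beta`, heritability table `h2_obs` (see
#'   [h2_observed()]), `converged`, `n_iter`, `boundary` flags, sample counts.
#' @seealso [h2_observed()], [observed_to_liability()], [tidy.greml_fit()]
#' @export
fit_reml <- function(phenotype, grms, covariates = NULL,
                     max_iter = 100, tol = 1e-8,
                     algorithm = c("ai", "em"), constrain = TRUE,
                     allow_subset = FALSE) {
  algorithm <- match.arg(algorithm)
  al <- .align_inputs(phenotype, grms, covariates, allow_subset)
  y <- al$y
  X <- al$X
  a_list <- al$a_list
  n <- length(y)
  k <- length(a_list)
  if (n <= ncol(X) + k)
    stop("need n > ", ncol(X) + k, " individuals for ", k,
         " component(s) and ", ncol(X), " fixed effect(s)", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design X is rank deficient", call. = FALSE)

  engine <- if (k == 1) .engine_fast(a_list[[1]], y, X)
            else .engine_dense(a_list, y, X)

  vary <- var(y)
  if (vary == 0) stop("phenotype has zero variance", call. = FALSE)
  floor_v <- 1e-6 * vary
  theta <- rep(vary / (k + 1), k + 1)
  q <- engine(theta)
  if (is.null(q))
    stop("V is not positive definite at the starting values", call. = FALSE)

  clamp <- function(th) if (constrain) pmax(th, floor_v) else th
  try_step <- function(theta, delta, q) {
    # move with step-halving until the restricted likelihood does not decrease
    for (h in 0:30) {
      prop <- clamp(theta + delta / 2^h)
      qn <- engine(prop)
      if (!is.null(qn) && qn$ll >= q$ll - 1e-12)
        return(list(theta = prop, q = qn))
    }
    NULL
  }

  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    delta <- NULL
    if (it > 1 && algorithm == "ai") {
      delta <- tryCatch(solve(q$AI, q$grad), error = function(e) NULL)
    }
    if (is.null(delta))                              # first step, EM mode,
      delta <- theta^2 * (q$yPAPy - q$trPA) / n      # or singular AI fallback
    moved <- try_step(theta, delta, q)
    if (is.null(moved) && algorithm == "ai") {
      delta <- theta^2 * (q$yPAPy - q$trPA) / n
      moved <- try_step(theta, delta, q)
    }
    if (is.null(moved)) { converged <- TRUE; break }  # no ascent direction left
    dll <- moved$q$ll - q$ll
    theta <- moved$theta
    q <- moved$q
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  comp_names <- c(al$comp_names, "e")
  names(theta) <- comp_names
  boundary <- constrain & theta <= 1.5 * floor_v
  cov_sigma2 <- tryCatch(solve(q$AI), error = function(e) {
    matrix(NA_real_, k + 1, k + 1)
  })
  dimnames(cov_sigma2) <- list(comp_names, comp_names)
  se <- sqrt(pmax(diag(cov_sigma2), 0))

  is_binary <- all(y %in% c(0, 1))
  fit <- structure(list(
    sigma2 = theta, se_sigma2 = se, cov_sigma2 = cov_sigma2,
    loglik = q$ll, beta = setNames(q$beta, colnames(X)),
    converged = converged, n_iter = it, boundary = boundary,
    n = n,
    n_cases = if (is_binary) sum(y == 1) else NA_integer_,
    n_controls = if (is_binary) sum(y == 0) else NA_integer_,
    case_proportion = if (is_binary) mean(y) else NA_real_
  ), class = "greml_fit")
  fit$h2_obs <- h2_observed(fit)
  fit
}

.align_inputs <- function(phenotype, grms, covariates, allow_subset) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1)
  comp_names <- names(grms)
  if (is.null(comp_names))
    comp_names <- if (length(grms) == 1) "g" else paste0("g", seq_along(grms))

  if (all(vapply(grms, inherits, TRUE, "grm"))) {
    base <- grms[[1]]$samples
    key <- paste(base$fid, base$iid)
    a_list <- vector("list", length(grms))
    a_list[[1]] <- grms[[1]]$values
    for (r in seq_along(grms)[-1]) {
      kr <- paste(grms[[r]]$samples$fid, grms[[r]]$samples$iid)
      idx <- match(key, kr)
      if (anyNA(idx))
        stop("GRM ", r, " does not cover all individuals of GRM 1",
             call. = FALSE)
      a_list[[r]] <- grms[[r]]$values[idx, idx]
    }
    keep <- seq_along(key)
    if (is.data.frame(phenotype)) {
      kp <- paste(phenotype$fid, phenotype$iid)
      idx <- match(key, kp)
      if (anyNA(idx)) {
        if (!allow_subset)
          stop(sum(is.na(idx)), " GRM individual(s) missing from the ",
               "phenotype; use allow_subset = TRUE to drop them",
               call. = FALSE)
        keep <- which(!is.na(idx))
      }
      y <- phenotype[[3]][idx[keep]]
    } else {
      y <- as.numeric(phenotype)
      if (length(y) != length(key))
        stop("phenotype length ", length(y), " != GRM size ", length(key),
             call. = FALSE)
    }
    if (anyNA(y)) {
      keep2 <- which(!is.na(phenotype[[3]][match(key, paste(phenotype$fid, phenotype$iid))]))
      if (!allow_subset)
        stop("missing phenotype values; use allow_subset = TRUE to drop them",
             call. = FALSE)
      keep <- intersect(keep, keep2)
      y <- phenotype[[3]][match(key, paste(phenotype$fid, phenotype$iid))][keep]
    }
    if (is.data.frame(covariates)) {
      kc <- paste(covariates$fid, covariates$iid)
      idx <- match(key[keep], kc)
      if (anyNA(idx))
        stop("covariates missing for ", sum(is.na(idx)), " individual(s)",
             call. = FALSE)
      Xc <- as.matrix(covariates[idx, setdiff(names(covariates), c("fid", "iid")),
                                 drop = FALSE])
    } else if (!is.null(covariates)) {
      Xc <- as.matrix(covariates)
      Xc <- Xc[keep, , drop = FALSE]
    } else Xc <- NULL
    a_list <- lapply(a_list, function(a) a[keep, keep])
    X <- .design_matrix(Xc, length(keep))
    return(list(y = y, X = X, a_list = a_list, comp_names = comp_names))
  }

  # plain matrices: phenotype must be a vector aligned with them
  a_list <- .as_grm_matrices(grms)
  y <- if (is.data.frame(phenotype)) phenotype[[3]] else as.numeric(phenotype)
  X <- .design_matrix(covariates, length(y))
  list(y = y, X = X, a_list = a_list, comp_names = comp_names)
}

#' Observed-scale heritability from a fitted model
#'
#' Per-component and total proportions of phenotypic variance,
#' \eqn{h^2_{obs,r} = \sigma^2_{g_r} / (\sum_s \sigma^2_{g_s} + \sigma^2_e)},
#' with standard errors by the delta method on the inverse-AI sampling
#' covariance of the variance components.
#'
#' @param fit a `greml_fit` from [fit_reml()].
#' @return A tibble with columns `component` (the genetic components, then
#'   `"total"`), `estimate`, `se`, `boundary`.
#' @export
h2_observed <- function(fit) {
  stopifnot(inherits(fit, "greml_fit"))
  theta <- fit$sigma2
  k1 <- length(theta)
  vp <- sum(theta)
  if (vp <= 0) stop("total phenotypic variance is zero", call. = FALSE)
  S <- fit$cov_sigma2
  gnames <- names(theta)[-k1]
  rows <- lapply(seq_len(k1 - 1), function(r) {
    gvec <- (-theta[r] / vp^2) * rep(1, k1)
    gvec[r] <- gvec[r] + 1 / vp
    se <- if (anyNA(S)) NA_real_ else sqrt(max(drop(gvec %*% S %*% gvec), 0))
    tibble::tibble(component = gnames[r], estimate = unname(theta[r] / vp),
                   se = se, boundary = unname(fit$boundary[r]))
  })
  gsum <- sum(theta[-k1])
  gvec <- c(rep(theta[k1] / vp^2, k1 - 1), -gsum / vp^2)
  se_tot <- if (anyNA(S)) NA_real_ else sqrt(max(drop(gvec %*% S %*% gvec), 0))
  dplyr::bind_rows(rows,
                   tibble::tibble(component = "total",
                                  estimate = unname(gsum / vp), se = se_tot,
                                  boundary = any(fit$boundary[-k1])))
}

#' @export
print.greml_fit <- function(x, ...) {
  cat("GREML fit (", x$n, " individuals", sep = "")
  if (!is.na(x$n_cases)) cat(": ", x$n_cases, " cases / ", x$n_controls,
                             " controls", sep = "")
  cat(")\n")
  for (nm in names(x$sigma2))
    cat(sprintf("  V(%s)\t%.6f\t(SE %.6f)%s\n", nm, x$sigma2[nm],
                x$se_sigma2[nm], if (x$boundary[nm]) " [boundary]" else ""))
  tot <- x$h2_obs[x$h2_obs$component == "total", ]
  cat(sprintf("  h2 (observed scale)\t%.6f\t(SE %.6f)\n", tot$estimate, tot$se))
  cat(sprintf("  logL\t%.6f\n  converged\t%s after %d iterations\n",
              x$loglik, x$converged, x$n_iter))
  invisible(x)
}

#' Tidy a GREML fit
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity
#' (variance components and heritabilities), `glance()` a one-row model
#' summary.
#'
#' @param x a `greml_fit`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.greml_fit <- function(x, ...) {
  vc <- tibble::tibble(term = paste0("V(", names(x$sigma2), ")"),
                       estimate = unname(x$sigma2),
                       std.error = unname(x$se_sigma2),
                       boundary = unname(x$boundary))
  h2 <- dplyr::transmute(x$h2_obs,
                         term = paste0("h2_obs(", .data$component, ")"),
                         estimate = .data$estimate, std.error = .data$se,
                         boundary = .data$boundary)
  dplyr::bind_rows(vc, h2)
}

#' @rdname tidy.greml_fit
#' @exportS3Method generics::glance
glance.greml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_cases = x$n_cases,
                 n_controls = x$n_controls, n_iter = x$n_iter,
                 converged = x$converged)
}
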