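# Liability-threshold conversion: the binary trait is modelled as a latent
# standard-normal liability; individuals whose liability exceeds the threshold
# set by population prevalence K are cases.  REML estimates made on the 0/1
# observed scale are mapped to the liability scale, with a correction for
# case-control ascertainment (sample case proportion P >> K).

#' Liability threshold and normal density at a prevalence
#'
#' @param K population prevalence, in (0, 1).
#' @return Named numeric vector with `t = qnorm(1 - K)` (the liability
#'   threshold) and `z = dnorm(t)` (the standard-normal density at it).
#' @export
#' @examples
#' liability_threshold(0.5)    # t = 0, z = 1/sqrt(2*pi)
#' liability_threshold(0.008)
liability_threshold <- function(K) {
  if (!is.numeric(K) || any(K <= 0) || any(K >= 1))
    stop("prevalence K must lie in (0, 1)", call. = FALSE)
  t <- qnorm(K, lower.tail = FALSE)
  c(t = t, z = dnorm(t))
}

.liability_factor <- function(K, P, ascertained) {
  z <- liability_threshold(K)[["z"]]
  base <- K * (1 - K) / z^2
  if (ascertained) base * K * (1 - K) / (P * (1 - P)) else base
}

#' Transform heritability from the observed to the liability scale
#'
#' Applies the case-control ascertainment-corrected transformation
#' \deqn{h^2_l = h^2_{obs} \times \frac{K(1-K)}{z^2}
#'       \times \frac{K(1-K)}{P(1-P)},}
#' where `K` is the population prevalence, `P` the case proportion in the
#' analysed sample and `z` the standard-normal density at the liability
#' threshold.  Standard errors transform by the same factor (delta method on
#' a linear map).  With `ascertained = FALSE` (or `P = K`) the simpler
#' no-ascertainment factor `K(1-K)/z^2` is used.
#'
#' @param h2_obs,se_obs observed-scale heritability estimate(s) and standard
#'   error(s); vectors are transformed elementwise.
#' @param K population prevalence, in (0, 1).
#' @param P sample case proportion, in (0, 1).  Pass the value computed from
#'   the analysed phenotype (e.g. `fit$case_proportion`); defaults to `K`,
#'   i.e. no ascertainment.
#' @param ascertained apply the ascertainment correction (default `TRUE`).
#' @return A tibble of class `liability_estimate`, one row per input, with
#'   columns `h2_liability`, `se_liability`, `h2_observed`, `se_observed`,
#'   `K`, `P`, `t`, `z`, `factor`.
#' @export
#' @examples
#' observed_to_liability(0.2, 0.05, K = 0.5, P = 0.5)  # factor is exactly pi/2
observed_to_liability <- function(h2_obs, se_obs = NA_real_, K, P = K,
                                  ascertained = TRUE) {
  if (any(h2_obs < 0, na.rm = TRUE))
    stop("h2_obs must be >= 0", call. = FALSE)
  if (!is.numeric(P) || any(P <= 0) || any(P >= 1))
    stop("case proportion P must lie in (0, 1)", call. = FALSE)
  tz <- liability_threshold(K)
  f <- .liability_factor(K, P, ascertained)
  out <- tibble::tibble(
    h2_liability = f * h2_obs, se_liability = f * se_obs,
    h2_observed = h2_obs, se_observed = se_obs,
    K = K, P = if (ascertained) P else K,
    t = tz[["t"]], z = tz[["z"]], factor = f
  )
  class(out) <- c("liability_estimate", class(out))
  out
}

#' Invert the liability transformation
#'
#' Maps a liability-scale estimate back to the observed scale; the exact
#' inverse of [observed_to_liability()] with the same arguments (provided for
#' checking round trips).
#'
#' @inheritParams observed_to_liability
#' @param h2_liability,se_liability liability-scale estimate and SE.
#' @return A tibble with columns `h2_observed`, `se_observed`.
#' @export
liability_to_observed <- function(h2_liability, se_liability = NA_real_, K,
                                  P = K, ascertained = TRUE) {
  f <- .liability_factor(K, P, ascertained)
  tibble::tibble(h2_observed = h2_liability / f,
                 se_observed = se_liability / f)
}
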