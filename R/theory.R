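#' Harmonic number
#'
#' `H_n = sum_{k=1}^{n} 1/k`, the coupon-collector factor that governs the
#' zero-lifespan renewal time of the unbiased uncoupled model.
#'
#' @param n positive integer.
#' @return `H_n` as a double.
#' @examples
#' harmonic_number(100) # 5.187378
#' @export
harmonic_number <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a positive integer", call. = FALSE)
  sum(1 / seq_len(n))
}

#' Minimal replicative lifespan under ideal centripetal bias (coupled model)
#'
#' With removal always drawn from the inward sector of radius `m`, a lineage
#' advances at most `m` cells per division, so complete renewal of a cornea of
#' radius `R` needs at least `ceiling(R / m)` divisions.
#'
#' @param R corneal radius in cells (`R > m`).
#' @param m local interaction radius in cells (`>= 1`).
#' @return Integer lower bound on the replicative lifespan.
#' @examples
#' min_rls_ideal_bias(100, 5) # 20
#' @export
min_rls_ideal_bias <- function(R, m) {
  stopifnot(R >= m, m >= 1)
  as.integer(ceiling(R / m))
}

#' Lower limit on the renewal time of the coupled model
#'
#' Under ideal bias the renewal front advances, per corneal replication time,
#' by the mean removal distance `(m + 1) / 2`, giving a renewal-time limit of
#' `2 R / (m + 1)` normalized replications.
#'
#' @inheritParams min_rls_ideal_bias
#' @return Renewal-time bound in corneal replication times.
#' @examples
#' renewal_time_limit_coupled(100, 5) # 33.33
#' @export
renewal_time_limit_coupled <- function(R, m) {
  stopifnot(R >= m, m >= 1)
  2 * R / (m + 1)
}

#' Zero-lifespan renewal time of the uncoupled model
#'
#' Closed-form renewal times for the limit RLS = 0 in which only limbal stem
#' cells divide (asymmetrically, at rate `lambda_s * a`), and each division
#' pushes one cell into the cornea. With perfect centripetal bias the removed
#' cell is always at the centre and
#' `t_withbias = (lambda_p / (2 * lambda_s * a)) * (R + 1)`;
#' without bias the removal site is uniform and a first-passage
#' (coupon-collector) argument gives
#' `t_nobias = (lambda_p / (lambda_s * a)) * H_R * R`,
#' with `H_R` the R-th harmonic number. Both are expressed in corneal
#' replication times (multiples of `1 / lambda_p`).
#'
#' @param R corneal radius in cells.
#' @param lambda_s stem-cell division rate.
#' @param lambda_p progenitor division rate (sets the time unit).
#' @param a fraction of stem divisions that are asymmetric, in (0, 1].
#' @param bias `"ideal"` or `"none"`.
#' @return Renewal time in corneal replication times.
#' @examples
#' renewal_time_uncoupled_rls0(100, 0.1, 1, 0.85, "ideal") # ~594
#' @export
renewal_time_uncoupled_rls0 <- function(R, lambda_s = 0.1, lambda_p = 1,
                                        a = 0.85, bias = c("ideal", "none")) {
  bias <- match.arg(bias)
  stopifnot(R >= 1, lambda_s > 0, lambda_p > 0, a > 0, a <= 1)
  if (bias == "ideal") {
    (lambda_p / (2 * lambda_s * a)) * (R + 1)
  } else {
    (lambda_p / (lambda_s * a)) * harmonic_number(R) * R
  }
}

#' No-bias to ideal-bias renewal-time ratio (uncoupled, RLS = 0)
#'
#' The ratio `t_nobias / t_withbias = 2 * H_R * R / (R + 1)` is parameter-free
#' (the rates cancel) and depends only on the corneal radius.
#'
#' @param R corneal radius in cells.
#' @return The fold-increase in renewal time when the bias is removed.
#' @examples
#' uncoupled_bias_ratio(100) # 10.27
#' @export
uncoupled_bias_ratio <- function(R) {
  2 * harmonic_number(R) * R / (R + 1)
}

#' Minimal renewal time of the uncoupled model (ideal bias, high RLS)
#'
#' With perfect centripetal bias and unconstrained lifespan, a labeled stripe
#' doubles its length every corneal replication time, so the whole cornea is
#' renewed after `log2(R)` replications.
#'
#' @param R corneal radius in cells (`>= 2`).
#' @param integer_valued if `TRUE`, return the conservative `ceiling`.
#' @return Renewal time in corneal replication times.
#' @examples
#' min_renewal_time_uncoupled(100)                       # 6.64
#' min_renewal_time_uncoupled(100, integer_valued = TRUE) # 7
#' @export
min_renewal_time_uncoupled <- function(R, integer_valued = FALSE) {
  stopifnot(R >= 2)
  t <- log2(R)
  if (integer_valued) ceiling(t) else t
}

#' One-step binomial model of the renewal front (coupled, no bias)
#'
#' Reduced description of the unbiased coupled dynamics: after the first
#' progenitor lifespan the renewal front sits at depth `m`; each additional
#' lifespan advances it by one cell with probability `p_advance` (about 3/8
#' for the circular front geometry, see [front_advance_probability()]). The
#' steady-state front depth is therefore `m + Binomial(RLS - 1, p_advance)`,
#' capped at the corneal radius, and the implied renewed area fraction is
#' `1 - ((R - depth) / R)^2`.
#'
#' @param R corneal radius in cells.
#' @param m local interaction radius in cells.
#' @param RLS progenitor replicative lifespan (`>= 1`).
#' @param p_advance per-lifespan front-advance probability in (0, 1].
#' @param n_samples Monte-Carlo sample size for the front-depth distribution.
#' @param seed integer seed for the sampling.
#' @return A list with `mean_depth` (exact binomial mean, capped at `R`),
#'   `renewed_fraction` (exact expectation over the binomial), and `depths`
#'   (the Monte-Carlo sample).
#' @examples
#' one_step_front_model(100, 5, 1)$mean_depth # 5: RLS = 1 fills the m-disk
#' @export
one_step_front_model <- function(R, m, RLS, p_advance = 3 / 8,
                                 n_samples = 1e4, seed = 1) {
  stopifnot(R > m, m >= 1, RLS >= 1, p_advance > 0, p_advance <= 1)
  k <- 0:(RLS - 1)
  pk <- stats::dbinom(k, size = RLS - 1, prob = p_advance)
  depth <- pmin(m + k, R)
  mean_depth <- sum(pk * depth)
  renewed <- sum(pk * (1 - ((R - depth) / R)^2))
  draws <- NULL
  if (n_samples > 0) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    draws <- pmin(m + stats::rbinom(n_samples, size = RLS - 1, p = p_advance), R)
  }
  list(mean_depth = mean_depth, renewed_fraction = renewed, depths = draws)
}

#' Monte-Carlo estimate of the front-advance probability
#'
#' Probability that a single replication at the renewal front advances the
#' front, when the removed cell is drawn uniformly from the local sector
#' around the dividing cell. The front is taken as a circle of radius
#' `front_radius` (default `R - m`, the unbiased steady-state front of an
#' RLS = 1 tissue); the removal point is drawn uniformly from the annulus
#' `1 <= d <= m` around a front cell (a removed cell is a distinct cell at
#' least one spacing away), restricted to the sector of angle `alpha` facing
#' the centre; the front advances when the removal lies at least one full
#' cell spacing closer to the centre than the front. With `alpha = 2*pi`
#' (no bias) and `m = 5` the estimate is about 3/8; under ideal bias
#' (small `alpha`) every removal is inward and the probability is 1.
#'
#' @param R corneal radius in cells.
#' @param m local interaction radius in cells.
#' @param n_samples number of Monte-Carlo draws.
#' @param seed integer seed.
#' @param alpha sector angle in radians (`2*pi` = no bias).
#' @param front_radius radius of the circular front (default `R - m`).
#' @return Estimated advance probability.
#' @examples
#' front_advance_probability(100, 5, n_samples = 2e4) # ~0.38
#' @export
front_advance_probability <- function(R, m, n_samples = 1e5, seed = 1,
                                      alpha = 2 * pi, front_radius = R - m) {
  stopifnot(R > m, m >= 1, front_radius > m, n_samples >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # front cell at (front_radius, 0); inward direction is -x
  k <- sqrt(1 + stats::runif(n_samples) * (m^2 - 1))        # uniform on annulus
  th <- pi + stats::runif(n_samples, -alpha / 2, alpha / 2) # around inward
  qx <- front_radius + k * cos(th)
  qy <- k * sin(th)
  mean(sqrt(qx^2 + qy^2) <= front_radius - 1)
}

#' Closed-form benchmark table
#'
#' Evaluates every closed-form benchmark for one parameter set; used by the
#' `theory` CLI subcommand.
#'
#' @inheritParams renewal_time_uncoupled_rls0
#' @param m local interaction radius in cells.
#' @return A data.frame with columns `quantity`, `value`, `units`.
#' @export
theory_table <- function(R = 100, m = 5, lambda_s = 0.1, lambda_p = 1,
                         a = 0.85) {
  data.frame(
    quantity = c(
      "harmonic_number(R)",
      "min_rls_ideal_bias",
      "renewal_time_limit_coupled",
      "renewal_time_uncoupled_rls0_ideal",
      "renewal_time_uncoupled_rls0_none",
      "uncoupled_bias_ratio",
      "min_renewal_time_uncoupled",
      "min_renewal_time_uncoupled_ceil"
    ),
    value = c(
      harmonic_number(R),
      min_rls_ideal_bias(R, m),
      renewal_time_limit_coupled(R, m),
      renewal_time_uncoupled_rls0(R, lambda_s, lambda_p, a, "ideal"),
      renewal_time_uncoupled_rls0(R, lambda_s, lambda_p, a, "none"),
      uncoupled_bias_ratio(R),
      min_renewal_time_uncoupled(R),
      min_renewal_time_uncoupled(R, integer_valued = TRUE)
    ),
    units = c(
      "dimensionless", "replications", "replication times",
      "replication times", "replication times", "fold",
      "replication times", "replication times"
    ),
    stringsAsFactors = FALSE
  )
}
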