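#' Diffusion parameters
#'
#' Container for the fixed parameters of the two-boundary Wiener
#' diffusion used as the response stage: boundary separation `alpha`
#' (evidence units), relative starting point `beta` (so the process
#' starts at `beta * alpha` between the absorbing boundaries 0 and
#' `alpha`), and non-decision time `tau` (seconds).  The within-trial
#' diffusion coefficient is fixed at 1.  Under accuracy coding the upper
#' boundary codes a correct response and the lower boundary an error.
#'
#' @param alpha Boundary separation (> 0), default 1.5.
#' @param beta Relative starting point in (0, 1), default 0.2.
#' @param tau Non-decision time in seconds (>= 0), default 0.3.
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(alpha = 1.5, beta = 0.2, tau = 0.3) {
  stopifnot(alpha > 0, beta > 0, beta < 1, tau >= 0)
  structure(list(alpha = alpha, beta = beta, tau = tau),
            class = "diffusion_params")
}

#' Closed-form upper-boundary absorption probability
#'
#' For a Wiener process with unit diffusion coefficient, drift `drift`,
#' absorbing boundaries at 0 and `alpha`, started at `beta * alpha`:
#' `P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a))` for nonzero drift
#' `v`, and `beta` for zero drift.
#'
#' @param alpha,beta Boundary separation and relative start.
#' @param drift Drift rate (vectorised).
#' @return Probability of absorption at the upper boundary.
#' @export
wiener_upper_prob <- function(alpha, beta, drift) {
  z <- beta * alpha
  p <- numeric(length(drift))
  for (i in seq_along(drift)) {
    v <- drift[i]
    if (v == 0) {
      p[i] <- beta
    } else if (v > 0) {
      p[i] <- expm1(-2 * v * z) / expm1(-2 * v * alpha)
    } else {
      # reflect to keep the exponentials bounded
      p[i] <- 1 - expm1(2 * v * (alpha - z)) / expm1(2 * v * alpha)
    }
  }
  p
}

# ---- exact first-passage time distribution -------------------------------
#
# Defective CDF of absorption at the LOWER boundary (0) by time t, for a
# process started at z in (0, a) with drift mu and unit diffusion.  Uses
# the spectral (large-time) series: the first-passage density is
#   f0(t) = (pi / a^2) exp(-mu z - mu^2 t / 2)
#           * sum_k k sin(k pi z / a) exp(-k^2 pi^2 t / (2 a^2)),
# which integrates (term by term) to
#   F0(t) = P0 - (pi / a^2) exp(-mu z)
#           * sum_k k sin(k pi z / a) exp(-lambda_k t) / lambda_k,
# with lambda_k = (mu^2 + k^2 pi^2 / a^2) / 2 and P0 the total
# lower-boundary absorption probability.  The number of retained terms is
# chosen from the smallest evaluated t so the truncated tail is below
# ~1e-15 of a term's scale.

.fpt_nterms <- function(a, t_min) {
  k <- ceiling((a / pi) * sqrt(2 * 36 / t_min))
  min(max(8L, as.integer(k)), 20000L)
}

# Series terms for a given (a, z, mu), valid down to t_min.
.fpt_series <- function(a, z, mu, t_min) {
  K <- .fpt_nterms(a, t_min)
  k <- seq_len(K)
  lam <- (mu^2 + (k * pi / a)^2) / 2
  list(lam = lam,
       coef = (pi / a^2) * exp(-z * mu) * k * sin(k * pi * z / a) / lam)
}

# vectorised over t; scalar a, z, mu
.fpt_lower_cdf <- function(t, a, z, mu, p_lower = NULL) {
  if (is.null(p_lower)) p_lower <- 1 - wiener_upper_prob(a, z / a, mu)
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  ser <- .fpt_series(a, z, mu, min(tp))
  tail <- drop(exp(-outer(tp, ser$lam)) %*% ser$coef)
  out[pos] <- pmin(pmax(p_lower - tail, 0), p_lower)
  out
}

# Smallest time below which total absorption probability is < ~2e-15, so
# the quantile search can safely start there (the spectral series is slow
# to converge for very small t, but no probability mass lives there).
.fpt_t_floor <- function(a, z, mu) {
  d <- min(z, a - z)
  d^2 / (2 * (36 + d * abs(mu)))
}

# Conditional quantile of the lower-boundary first-passage time:
# solves F0(t) = u * P0 by bisection on the spectral-series CDF, with the
# series terms computed once per parameter set.  u in (0, 1).
.fpt_lower_quantile <- function(u, a, z, mu) {
  p_lower <- 1 - wiener_upper_prob(a, z / a, mu)
  target <- u * p_lower
  n <- length(u)
  t_floor <- .fpt_t_floor(a, z, mu)
  ser <- .fpt_series(a, z, mu, t_floor)
  lam <- ser$lam
  coef <- ser$coef
  K_max <- length(lam)
  cdf <- function(t) {
    # terms beyond the convergence requirement at the smallest t evaluated
    # are negligible (lam is increasing), so truncate adaptively
    Kt <- min(K_max, .fpt_nterms(a, min(t)))
    if (n == 1L) {
      p_lower - sum(exp(-t * lam[seq_len(Kt)]) * coef[seq_len(Kt)])
    } else {
      p_lower - drop(exp(-outer(t, lam[seq_len(Kt)])) %*% coef[seq_len(Kt)])
    }
  }
  lo <- rep(t_floor, n)
  hi <- rep(1, n)
  for (i in 1:60) {
    need <- cdf(hi) < target
    if (!any(need)) break
    hi[need] <- hi[need] * 2
  }
  for (i in 1:52) {
    mid <- (lo + hi) / 2
    below <- cdf(mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-9 * (1 + max(hi))) break
  }
  (lo + hi) / 2
}

#' Sample first-passage events of the Wiener diffusion
#'
#' Draws exact first-passage (boundary, time) pairs of a drift-diffusion
#' process with unit diffusion coefficient between absorbing boundaries 0
#' and `alpha`, started at `beta * alpha`.  The boundary is drawn from
#' the closed-form absorption probability and the decision time from the
#' exact conditional first-passage distribution by series-based
#' inverse-CDF sampling (no time-stepping approximation).  The reported
#' `rt` adds the non-decision time `tau`.
#'
#' First-passage times exceeding `censor_at` seconds of process time are
#' resampled once; if the resample also exceeds the deadline the draw is
#' kept and flagged `censored` (with the default drift floor of 3 this is
#' practically impossible).
#'
#' @param n Number of draws.
#' @param params A [diffusion_params()] object.
#' @param drift Drift rate (scalar).
#' @param censor_at Process-time deadline in seconds (default 10).
#' @return A list with `upper` (logical), `rt` (seconds, `> tau`) and
#'   `censored` (logical).
#' @examples
#' set.seed(1)
#' s <- sample_wiener(5, diffusion_params(), drift = 3)
#' s$rt
#' @export
sample_wiener <- function(n, params = diffusion_params(), drift,
                          censor_at = 10) {
  stopifnot(inherits(params, "diffusion_params"), length(drift) == 1L,
            is.finite(drift))
  a <- params$alpha
  z <- params$beta * a
  p_up <- wiener_upper_prob(a, params$beta, drift)
  upper <- stats::runif(n) < p_up
  t_dec <- numeric(n)
  n_lo <- sum(!upper)
  n_up <- sum(upper)
  # lower-boundary draws as-is; upper-boundary draws via the reflection
  # (a - z, -drift) so both reduce to lower-boundary quantiles
  if (n_lo > 0L) {
    t_dec[!upper] <- .fpt_lower_quantile(stats::runif(n_lo), a, z, drift)
  }
  if (n_up > 0L) {
    t_dec[upper] <- .fpt_lower_quantile(stats::runif(n_up), a, a - z, -drift)
  }
  censored <- t_dec > censor_at
  if (any(censored)) {
    for (i in which(censored)) {
      zz <- if (upper[i]) a - z else z
      vv <- if (upper[i]) -drift else drift
      t2 <- .fpt_lower_quantile(stats::runif(1L), a, zz, vv)
      if (t2 <= censor_at) {
        t_dec[i] <- t2
        censored[i] <- FALSE
      }
    }
  }
  list(upper = upper, rt = t_dec + params$tau, censored = censored)
}

#' Euler-path simulation of the diffusion (validation oracle)
#'
#' Direct stochastic simulation of the diffusion path with time step
#' `step`, used only to cross-validate [sample_wiener()]; coarse
#' time-stepping biases first-passage times upward by O(sqrt(step)), so
#' this is never the production sampler.
#'
#' @inheritParams sample_wiener
#' @param step Euler time step in seconds (1e-4 or smaller recommended).
#' @param max_time Give up on paths still unabsorbed after this process
#'   time (counted as censored).
#' @return A list with `upper`, `rt` and `censored` as in
#'   [sample_wiener()].
#' @export
euler_oracle <- function(n, params = diffusion_params(), drift,
                         step = 1e-4, max_time = 30) {
  a <- params$alpha
  x <- rep(params$beta * a, n)
  t_abs <- rep(NA_real_, n)
  upper <- rep(NA, n)
  active <- seq_len(n)
  sd_step <- sqrt(step)
  n_steps <- ceiling(max_time / step)
  for (s in seq_len(n_steps)) {
    x[active] <- x[active] + drift * step + sd_step * stats::rnorm(length(active))
    hit_up <- x[active] >= a
    hit_lo <- x[active] <= 0
    hit <- hit_up | hit_lo
    if (any(hit)) {
      idx <- active[hit]
      t_abs[idx] <- s * step
      upper[idx] <- hit_up[hit]
      active <- active[!hit]
    }
    if (length(active) == 0L) break
  }
  censored <- is.na(t_abs)
  t_abs[censored] <- max_time
  upper[censored] <- FALSE
  list(upper = upper, rt = t_abs + params$tau, censored = censored)
}

#' Select the physical response key
#'
#' Under accuracy coding an upper-boundary absorption maps to the
#' required response; a lower-boundary absorption maps to one of the
#' remaining keys, chosen uniformly at random.
#'
#' @param upper Logical: did the process hit the upper boundary?
#' @param required_response Index of the to-be-pressed response.
#' @param n_responses Number of response alternatives (default 6).
#' @return The index of the response actually given.
#' @export
select_response <- function(upper, required_response, n_responses = 6L) {
  if (upper) return(required_response)
  pool <- seq_len(n_responses)[-required_response]
  pool[sample.int(length(pool), 1L)]
}
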