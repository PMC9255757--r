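#' The LATER response-time model
#'
#' Response times arise by a linear rise to threshold at an ergodic rate:
#' `RT = theta0 + (-log p) / r` with `r ~ Normal(mu, sigma)` truncated to
#' `r > 0`, where `p` is the subjective probability of the upcoming
#' stimulus. More strongly expected stimuli (larger `p`) are answered
#' faster; the reciprocal of the centred response time is normally
#' distributed. Truncating the rate at zero keeps all response times above
#' `theta0`, i.e. no probability is assigned to negative durations.
#'
#' All parameters are in seconds (`theta0`) and reciprocal seconds (`mu`,
#' `sigma`); file I/O converts from/to milliseconds.
#'
#' @name later
NULL

#' Probability floor applied to predictive probabilities before taking logs
#' (keeps predicted response times finite for near-impossible stimuli).
#' @export
P_FLOOR <- 1e-6

#' Construct LATER parameters
#'
#' @param theta0 non-negative time offset in seconds.
#' @param mu mean of the rise rate, in 1/seconds, positive.
#' @param sigma standard deviation of the rise rate, in 1/seconds, positive.
#' @return Object of class `later_params`.
#' @export
later_params <- function(theta0, mu, sigma) {
  vals <- c(theta0 = theta0, mu = mu, sigma = sigma)
  if (any(!is.finite(vals)) || theta0 < 0 || mu <= 0 || sigma <= 0) {
    stop("require finite theta0 >= 0, mu > 0, sigma > 0", call. = FALSE)
  }
  structure(list(theta0 = theta0, mu = mu, sigma = sigma),
            class = "later_params")
}

#' @export
print.later_params <- function(x, ...) {
  cat(sprintf("LATER: theta0 = %.4g s, mu = %.4g 1/s, sigma = %.4g 1/s\n",
              x$theta0, x$mu, x$sigma))
  invisible(x)
}

check_p <- function(p) {
  if (any(p <= 0 | p > 1)) {
    stop("subjective probability must lie in (0, 1]", call. = FALSE)
  }
}

#' LATER response-time density
#'
#' Density of `RT = theta0 + (-log p) / r`, `r ~ Normal(mu, sigma)`
#' truncated to `r > 0`; includes the change-of-variables factor
#' `(-log p) / (rt - theta0)^2`. Zero for `rt <= theta0`. For `p = 1` the
#' distribution is a point mass at `theta0` and has no density.
#'
#' @param rt response time(s) in seconds.
#' @param p subjective probability in (0, 1); recycled against `rt`.
#' @param params a [later_params()].
#' @param log return the log density.
#' @return Density values, same length as `rt`.
#' @export
rt_density <- function(rt, p, params, log = FALSE) {
  check_p(p)
  if (any(p == 1)) {
    stop("p = 1 gives a degenerate response time (point mass at theta0); ",
         "use sample_rt()/map_rt() for the point-mass case", call. = FALSE)
  }
  n <- max(length(rt), length(p))
  rt <- rep_len(rt, n)
  p <- rep_len(p, n)
  x <- -log(p)
  d <- rt - params$theta0
  lp <- rep(-Inf, n)
  pos <- d > 0
  if (any(pos)) {
    z <- (x[pos] / d[pos] - params$mu) / params$sigma
    lp[pos] <- stats::dnorm(z, log = TRUE) - log(params$sigma) -
      stats::pnorm(params$mu / params$sigma, log.p = TRUE) +
      log(x[pos]) - 2 * log(d[pos])
  }
  if (log) lp else exp(lp)
}

#' Sample LATER response times
#'
#' Draws the rate from the positive-truncated `Normal(mu, sigma)` by
#' inverse-CDF and returns `theta0 + (-log p) / r`; `p = 1` returns
#' `theta0` exactly.
#'
#' @param p subjective probabilities in (0, 1].
#' @param params a [later_params()].
#' @param seed optional integer seed.
#' @return Response times in seconds, one per element of `p`.
#' @export
sample_rt <- function(p, params, seed = NULL) {
  check_p(p)
  if (!is.null(seed)) set.seed(seed)
  n <- length(p)
  lo <- stats::pnorm(0, params$mu, params$sigma)
  u <- stats::runif(n, lo, 1)
  r <- stats::qnorm(u, params$mu, params$sigma)
  out <- params$theta0 + ifelse(p == 1, 0, -log(p) / r)
  out
}

#' Point prediction of the response time
#'
#' The trial-by-trial prediction conditioned on the subjective probability
#' and the response-time parameters: by default the plug-in value
#' `theta0 + (-log p) / mu` (the response time at the mean rate); with
#' `exact_mode = TRUE` the mode of [rt_density()] is located numerically.
#' Probabilities are floored at `P_FLOOR` to keep the prediction finite.
#'
#' @param p subjective probabilities in (0, 1].
#' @param params a [later_params()].
#' @param exact_mode locate the density mode by 1-D optimization.
#' @return Predicted response times in seconds.
#' @export
map_rt <- function(p, params, exact_mode = FALSE) {
  check_p(p)
  p <- pmax(p, P_FLOOR)
  plug <- params$theta0 + (-log(p)) / params$mu
  if (!exact_mode) return(plug)
  vapply(seq_along(p), function(i) {
    if (p[i] == 1) return(params$theta0)
    opt <- stats::optimize(function(rt) rt_density(rt, p[i], params, log = TRUE),
                           lower = params$theta0 + 1e-9,
                           upper = params$theta0 + 5 * (plug[i] - params$theta0) + 1,
                           maximum = TRUE, tol = 1e-9)
    opt$maximum
  }, numeric(1))
}

#' QQ diagnostics of the LATER rate residuals
#'
#' Inverts the model on observed response times, `r_n = (-log p_n) /
#' (rt_n - theta0)`, z-scores the implied rates and pairs their empirical
#' quantiles with standard-normal quantiles. Under a well-specified model
#' the points lie on the identity line.
#'
#' @param rts observed response times in seconds, all `> theta0`.
#' @param ps subjective probabilities, same length.
#' @param params a [later_params()].
#' @return A data.frame with columns `theoretical` and `empirical` (sorted
#'   z-scored rates), one row per trial.
#' @export
residual_qq <- function(rts, ps, params) {
  if (length(rts) != length(ps)) stop("length mismatch", call. = FALSE)
  check_p(ps)
  bad <- which(rts <= params$theta0)
  if (length(bad) > 0) {
    stop("response times at trials ", paste(utils::head(bad, 5), collapse = ", "),
         " are <= theta0; rate undefined", call. = FALSE)
  }
  r <- (-log(pmax(ps, P_FLOOR))) / (rts - params$theta0)
  if (stats::sd(r) < 1e-12) {
    stop("implied rates have zero variance; QQ undefined", call. = FALSE)
  }
  z <- (r - mean(r)) / stats::sd(r)
  n <- length(z)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             empirical = sort(z))
}
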