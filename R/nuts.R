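# No-U-Turn sampler (Hoffman & Gelman 2014, Algorithm 3) with dual-averaging
# step-size adaptation and a diagonal mass matrix, over an arbitrary
# differentiable log density. fn(theta) must return list(lp = scalar,
# grad = vector). inv_mass is the estimated posterior variance per
# coordinate (the inverse metric); momenta are drawn with sd 1/sqrt(inv_mass).

MAX_TREE_DEPTH <- 8L
DIVERGENCE_GAP <- 1000

leapfrog <- function(fn, theta, rho, step, grad, inv_mass) {
  rho <- rho + 0.5 * step * grad
  theta <- theta + step * inv_mass * rho
  ev <- fn(theta)
  if (!is.finite(ev$lp)) {
    return(list(theta = theta, rho = rho, lp = -Inf,
                grad = rep(0, length(theta))))
  }
  rho <- rho + 0.5 * step * ev$grad
  list(theta = theta, rho = rho, lp = ev$lp, grad = ev$grad)
}

kinetic <- function(rho, inv_mass) 0.5 * sum(inv_mass * rho^2)

no_uturn <- function(theta_plus, theta_minus, rho_plus, rho_minus, inv_mass) {
  dt <- theta_plus - theta_minus
  (sum(dt * inv_mass * rho_minus) >= 0) && (sum(dt * inv_mass * rho_plus) >= 0)
}

build_tree <- function(fn, theta, rho, grad, logu, v, j, step, H0, inv_mass) {
  if (j == 0L) {
    st <- leapfrog(fn, theta, rho, v * step, grad, inv_mass)
    H <- st$lp - kinetic(st$rho, inv_mass)
    n_ok <- as.integer(logu <= H)
    s_ok <- (logu < H + DIVERGENCE_GAP) && is.finite(H)
    alpha <- min(1, exp(min(0, H - H0)))
    list(theta_minus = st$theta, rho_minus = st$rho, grad_minus = st$grad,
         theta_plus = st$theta, rho_plus = st$rho, grad_plus = st$grad,
         theta_prop = st$theta, lp_prop = st$lp, grad_prop = st$grad,
         n = n_ok, s = s_ok, alpha = alpha, n_alpha = 1L)
  } else {
    t1 <- build_tree(fn, theta, rho, grad, logu, v, j - 1L, step, H0, inv_mass)
    if (!t1$s) return(t1)
    if (v == -1) {
      t2 <- build_tree(fn, t1$theta_minus, t1$rho_minus, t1$grad_minus,
                       logu, v, j - 1L, step, H0, inv_mass)
      t1$theta_minus <- t2$theta_minus; t1$rho_minus <- t2$rho_minus
      t1$grad_minus <- t2$grad_minus
    } else {
      t2 <- build_tree(fn, t1$theta_plus, t1$rho_plus, t1$grad_plus,
                       logu, v, j - 1L, step, H0, inv_mass)
      t1$theta_plus <- t2$theta_plus; t1$rho_plus <- t2$rho_plus
      t1$grad_plus <- t2$grad_plus
    }
    if (t2$n > 0L && stats::runif(1) < t2$n / max(1L, t1$n + t2$n)) {
      t1$theta_prop <- t2$theta_prop
      t1$lp_prop <- t2$lp_prop
      t1$grad_prop <- t2$grad_prop
    }
    t1$alpha <- t1$alpha + t2$alpha
    t1$n_alpha <- t1$n_alpha + t2$n_alpha
    t1$n <- t1$n + t2$n
    t1$s <- t2$s && no_uturn(t1$theta_plus, t1$theta_minus,
                             t1$rho_plus, t1$rho_minus, inv_mass)
    t1
  }
}

nuts_step <- function(fn, theta, lp, grad, step, inv_mass = NULL,
                      max_depth = MAX_TREE_DEPTH) {
  if (is.null(inv_mass)) inv_mass <- rep(1, length(theta))
  rho0 <- stats::rnorm(length(theta), sd = 1 / sqrt(inv_mass))
  H0 <- lp - kinetic(rho0, inv_mass)
  logu <- H0 - stats::rexp(1)
  theta_minus <- theta_plus <- theta
  rho_minus <- rho_plus <- rho0
  grad_minus <- grad_plus <- grad
  prop <- list(theta = theta, lp = lp, grad = grad)
  n <- 1L; s <- TRUE; j <- 0L
  alpha_sum <- 0; n_alpha <- 0L
  while (s && j < max_depth) {
    v <- sample(c(-1, 1), 1L)
    if (v == -1) {
      tr <- build_tree(fn, theta_minus, rho_minus, grad_minus, logu, v, j,
                       step, H0, inv_mass)
      theta_minus <- tr$theta_minus; rho_minus <- tr$rho_minus
      grad_minus <- tr$grad_minus
    } else {
      tr <- build_tree(fn, theta_plus, rho_plus, grad_plus, logu, v, j,
                       step, H0, inv_mass)
      theta_plus <- tr$theta_plus; rho_plus <- tr$rho_plus
      grad_plus <- tr$grad_plus
    }
    if (tr$s && tr$n > 0L && stats::runif(1) < tr$n / n) {
      prop <- list(theta = tr$theta_prop, lp = tr$lp_prop, grad = tr$grad_prop)
    }
    n <- n + tr$n
    alpha_sum <- alpha_sum + tr$alpha
    n_alpha <- n_alpha + tr$n_alpha
    s <- tr$s && no_uturn(theta_plus, theta_minus, rho_plus, rho_minus,
                          inv_mass)
    j <- j + 1L
  }
  list(theta = prop$theta, lp = prop$lp, grad = prop$grad,
       accept_stat = if (n_alpha > 0L) alpha_sum / n_alpha else 0,
       depth = j)
}

# crude initial step size: double/halve until the one-step acceptance
# probability crosses 1/2
find_step_size <- function(fn, theta, lp, grad, inv_mass = NULL) {
  if (is.null(inv_mass)) inv_mass <- rep(1, length(theta))
  step <- 0.1
  rho <- stats::rnorm(length(theta), sd = 1 / sqrt(inv_mass))
  H0 <- lp - kinetic(rho, inv_mass)
  one <- function(step) {
    st <- leapfrog(fn, theta, rho, step, grad, inv_mass)
    st$lp - kinetic(st$rho, inv_mass) - H0
  }
  dH <- one(step)
  if (!is.finite(dH)) {
    while (!is.finite(dH) && step > 1e-10) { step <- step / 2; dH <- one(step) }
    return(max(step, 1e-10))
  }
  a <- if (dH > log(0.5)) 1 else -1
  for (i in 1:50) {
    step <- step * 2^a
    dH <- one(step)
    if (!is.finite(dH)) dH <- -Inf
    if (a * dH <= a * log(0.5)) break
  }
  step
}

new_dual_avg <- function(step0, target_accept = 0.8) {
  list(mu = log(10 * step0), log_step = log(step0), log_step_bar = log(step0),
       Hbar = 0, m = 0L, gamma = 0.05, t0 = 10, kappa = 0.75,
       delta = target_accept)
}

dual_avg_update <- function(da, accept_stat) {
  da$m <- da$m + 1L
  frac <- 1 / (da$m + da$t0)
  da$Hbar <- (1 - frac) * da$Hbar + frac * (da$delta - accept_stat)
  da$log_step <- da$mu - sqrt(da$m) / da$gamma * da$Hbar
  w <- da$m^(-da$kappa)
  da$log_step_bar <- w * da$log_step + (1 - w) * da$log_step_bar
  da
}

# Generic adaptive NUTS chain used by all fitting front-ends.
#
# make_target(outer) returns list(fn, tag): the (possibly outer-step
# dependent) log density and an opaque tag recorded with the sample.
# record(theta, lp, outer, tag) maps the final state of an outer step to a
# stored sample. Warmup = first half of the outer steps: dual averaging
# throughout, with the diagonal metric re-estimated from the accumulated
# draws at the midpoint of warmup (step size is then re-adapted).
nuts_chain <- function(make_target, theta, n_outer, n_inner, record,
                       max_depth = MAX_TREE_DEPTH) {
  tgt <- make_target(1L)
  ev <- tgt$fn(theta)
  if (!is.finite(ev$lp)) stop("initial point has non-finite density")
  inv_mass <- rep(1, length(theta))
  step0 <- find_step_size(tgt$fn, theta, ev$lp, ev$grad, inv_mass)
  da <- new_dual_avg(step0)
  n_warm <- max(1L, n_outer %/% 2L)
  metric_at <- max(1L, n_warm %/% 2L)
  warm_draws <- matrix(NA_real_, metric_at * n_inner, length(theta))
  draw_i <- 0L
  out <- vector("list", n_outer)
  for (outer in seq_len(n_outer)) {
    if (outer > 1L) {
      tgt <- make_target(outer)
      ev <- tgt$fn(theta)
      if (!is.finite(ev$lp)) stop("divergent log joint at outer step ", outer)
    }
    adapting <- outer <= n_warm
    for (inner in seq_len(n_inner)) {
      step <- exp(if (adapting) da$log_step else da$log_step_bar)
      st <- nuts_step(tgt$fn, theta, ev$lp, ev$grad, step, inv_mass,
                      max_depth)
      theta <- st$theta
      ev <- list(lp = st$lp, grad = st$grad)
      if (adapting) {
        da <- dual_avg_update(da, st$accept_stat)
        if (draw_i < nrow(warm_draws)) {
          draw_i <- draw_i + 1L
          warm_draws[draw_i, ] <- theta
        }
      }
    }
    if (outer == metric_at && draw_i >= 20L) {
      # estimate from the later half of the collected draws, past the
      # initial transient
      use <- warm_draws[seq.int(draw_i %/% 2L + 1L, draw_i), , drop = FALSE]
      v <- apply(use, 2, stats::var)
      n_est <- nrow(use)
      inv_mass <- pmax(v * n_est / (n_est + 5) + 1e-3 * 5 / (n_est + 5), 1e-8)
      step0 <- find_step_size(tgt$fn, theta, ev$lp, ev$grad, inv_mass)
      da <- new_dual_avg(step0)
    }
    out[[outer]] <- record(theta, ev$lp, outer, tgt$tag)
  }
  out
}
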