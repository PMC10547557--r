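# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# windowed diagonal mass-matrix adaptation (Stan-like warm-up schedule).
# Internal: used by fit_dirichlet(method = "mcmc").

leapfrog <- function(theta, p, eps, L, gr, mass) {
  g <- gr(theta)
  if (any(!is.finite(g))) {
    return(NULL)
  }
  p <- p + 0.5 * eps * g
  for (l in seq_len(L)) {
    theta <- theta + eps * p / mass
    g <- gr(theta)
    if (any(!is.finite(g))) {
      return(NULL)
    }
    if (l < L) p <- p + eps * g
  }
  p <- p + 0.5 * eps * g
  list(theta = theta, p = p)
}

# energy = -lp + kinetic (mass is the momentum variance)
hmc_energy <- function(lp_val, p, mass) -lp_val + 0.5 * sum(p^2 / mass)

find_initial_eps <- function(theta, lp, gr, mass, eps = 0.1) {
  p0 <- rnorm(length(theta), 0, sqrt(mass))
  h0 <- hmc_energy(lp(theta), p0, mass)
  ratio_at <- function(e) {
    step <- leapfrog(theta, p0, e, 1L, gr, mass)
    if (is.null(step)) {
      return(0)
    }
    r <- exp(h0 - hmc_energy(lp(step$theta), step$p, mass))
    if (is.finite(r)) r else 0
  }
  dir <- if (ratio_at(eps) > 0.5) 1 else -1
  for (i in 1:30) {
    eps_new <- eps * 2^dir
    r <- ratio_at(eps_new)
    if ((dir == 1 && r < 0.5) || (dir == -1 && r > 0.5)) break
    eps <- eps_new
  }
  eps
}

new_dual_avg <- function(eps) {
  list(
    mu = log(10 * eps), log_eps_bar = log(eps), h_bar = 0, m = 0,
    gamma = 0.05, t0 = 10, kappa = 0.75
  )
}

update_dual_avg <- function(da, accept_prob, target) {
  da$m <- da$m + 1
  da$h_bar <- (1 - 1 / (da$m + da$t0)) * da$h_bar +
    (target - accept_prob) / (da$m + da$t0)
  log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
  w <- da$m^(-da$kappa)
  da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
  da$eps <- exp(log_eps)
  da
}

hmc_chain <- function(start, lp, gr, mass, iter, warmup,
                      target_accept = 0.85, L_range = c(12L, 24L),
                      div_threshold = 1000) {
  npar <- length(start)
  theta <- start
  lp_cur <- lp(theta)
  draws <- matrix(NA_real_, iter - warmup, npar)
  divergences <- 0L
  accepts <- 0

  # warm-up schedule: eps-only opening, two mass-estimation windows, eps-only
  # closing (fractions of warmup)
  w1 <- max(20L, floor(0.15 * warmup))
  w4 <- max(20L, floor(0.10 * warmup))
  mid <- warmup - w1 - w4
  win_ends <- unique(c(w1 + floor(mid / 2), w1 + mid))
  win_start <- w1 + 1L

  eps <- find_initial_eps(theta, lp, gr, mass)
  da <- new_dual_avg(eps)
  win_sum <- numeric(npar)
  win_sq <- numeric(npar)
  win_n <- 0L

  for (it in seq_len(iter)) {
    p0 <- rnorm(npar, 0, sqrt(mass))
    h0 <- hmc_energy(lp_cur, p0, mass)
    L <- sample(seq(L_range[1], L_range[2]), 1)
    step <- leapfrog(theta, p0, eps, L, gr, mass)
    if (is.null(step)) {
      accept_prob <- 0
      diverged <- TRUE
    } else {
      h1 <- hmc_energy(lp(step$theta), step$p, mass)
      delta_h <- h1 - h0
      diverged <- !is.finite(delta_h) || delta_h > div_threshold
      accept_prob <- if (diverged) 0 else min(1, exp(-delta_h))
      if (!diverged && runif(1) < accept_prob) {
        theta <- step$theta
        lp_cur <- lp(theta)
      }
    }
    if (it <= warmup) {
      da <- update_dual_avg(da, accept_prob, target_accept)
      eps <- da$eps
      if (it >= win_start && it <= max(win_ends)) {
        win_sum <- win_sum + theta
        win_sq <- win_sq + theta^2
        win_n <- win_n + 1L
        if (it %in% win_ends && win_n >= 10L) {
          v <- (win_sq - win_sum^2 / win_n) / (win_n - 1)
          # regularize towards unit scale as Stan does for short windows
          v <- (win_n / (win_n + 5)) * v + (5 / (win_n + 5)) * 1e-3
          mass <- 1 / pmax(v, 1e-10)
          win_sum[] <- 0
          win_sq[] <- 0
          win_n <- 0L
          eps <- find_initial_eps(theta, lp, gr, mass, eps = eps)
          da <- new_dual_avg(eps)
        }
      }
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      if (diverged) divergences <- divergences + 1L
      accepts <- accepts + accept_prob
      draws[it - warmup, ] <- theta
    }
  }
  list(
    draws = draws, divergences = divergences, step_size = eps,
    accept_rate = accepts / (iter - warmup)
  )
}

# split-Rhat (potential scale reduction) over a list of per-chain draw
# matrices (post-warmup)
split_rhat <- function(chain_list) {
  halves <- list()
  for (m in chain_list) {
    n <- nrow(m)
    h <- floor(n / 2)
    halves <- c(
      halves,
      list(m[1:h, , drop = FALSE], m[(h + 1):(2 * h), , drop = FALSE])
    )
  }
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(
    halves, function(m) apply(m, 2, var),
    numeric(ncol(halves[[1]]))
  )
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  b <- n * apply(means, 1, var)
  w <- rowMeans(vars)
  sqrt(((n - 1) / n * w + b / n) / w)
}
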