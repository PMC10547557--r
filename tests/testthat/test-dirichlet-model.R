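test_that("dirichlet log density matches direct log-gamma arithmetic", {
  # uniform Dirichlet has constant density Gamma(3) = 2 on the 3-simplex
  expect_equal(ddirichlet_log(c(1 / 3, 1 / 3, 1 / 3), c(1, 1, 1)), log(2))
  set.seed(61)
  for (i in 1:10) {
    y <- drop(rdirichlet(1, c(1, 1, 1)))
    expect_equal(ddirichlet_log(y, c(1, 1, 1)), log(2))
  }
  y <- c(0.5, 0.3, 0.2)
  a <- c(2, 3, 4)
  manual <- lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(y))
  expect_equal(ddirichlet_log(y, a), manual)

  expect_error(ddirichlet_log(c(1, 0, 0), c(1, 1, 1)), "interior")
  expect_error(ddirichlet_log(y, c(-1, 1, 1)), "positive")
})

test_that("softmax link produces valid mean simplexes", {
  out <- dirichlet_mean(c(0, 0, 0), phi = 9)
  expect_equal(out$mu, matrix(1 / 3, 1, 3))
  expect_equal(out$alpha, matrix(3, 1, 3))
  # saturation
  big <- dirichlet_mean(c(50, 0, 0), phi = 10)
  expect_gte(big$mu[1, 1], 1 - 1e-15)
  # hand-computed softmax for a fixed parameter set
  eta <- c(0.4, 0, -0.3)
  expect_equal(
    drop(dirichlet_mean(eta, 5)$mu), exp(eta) / sum(exp(eta))
  )
  m <- dirichlet_mean(matrix(rnorm(30), 10, 3), phi = 20)$mu
  expect_equal(rowSums(m), rep(1, 10))
})

test_that("standardization centres, scales and stores constants", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$mean, 2)
  expect_error(standardize(rep(4, 10)), "zero variance")
  set.seed(62)
  x <- rlnorm(300, 3, 1)
  z <- standardize(x)
  expect_lt(abs(mean(z$values)), 1e-12)
  expect_equal(sd(z$values), 1, tolerance = 1e-12)
  expect_equal(z$values * z$sd + z$mean, x)
})

test_that("relabelling the reference category leaves fitted compositions
           unchanged under flat priors", {
  cfg <- sim_config(seed = 71, n_countries = 1, sites_per_country = 120)
  rec <- simulate_composition_records(cfg)$records
  flat <- dirichlet_priors(beta_scale = Inf)
  f1 <- fit_dirichlet(rec,
    covariates = c("biomass", "coral", "depth"),
    reference = "mobile_invertivore", method = "map", priors = flat,
    varying_slope = FALSE, group_intercept = FALSE, seed = 1,
    laplace_draws = 100
  )
  f2 <- fit_dirichlet(rec,
    covariates = c("biomass", "coral", "depth"),
    reference = "piscivore", method = "map", priors = flat,
    varying_slope = FALSE, group_intercept = FALSE, seed = 1,
    laplace_draws = 100
  )
  expect_lt(max(abs(fitted_composition(f1) - fitted_composition(f2))), 1e-6)
})

test_that("posterior intervals cover true coefficients at the nominal rate", {
  # 5 replicates x 16 coefficients, 90% Laplace intervals: pooled coverage
  # should be near 0.9 (bounded below at 0.8 to absorb sampling noise)
  hits <- 0
  total <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 300 + s, n_countries = 3, sites_per_country = 100)
    sim <- simulate_composition_records(cfg)
    fit <- fit_dirichlet(sim$records, method = "map", seed = s)
    truth <- as.vector(sim$truth$beta)
    hit <- truth >= fit$coef$conf_low & truth <= fit$coef$conf_high
    hits <- hits + sum(hit)
    total <- total + length(hit)
  }
  expect_gte(hits / total, 0.8)
})

test_that("zero-signal simulations keep zero inside most intervals", {
  beta0 <- default_true_beta() * 0
  hits <- 0
  total <- 0
  for (s in 1:5) {
    cfg <- sim_config(
      seed = 400 + s, n_countries = 3, sites_per_country = 100,
      true_beta = beta0
    )
    sim <- simulate_composition_records(cfg)
    fit <- fit_dirichlet(sim$records, method = "map", seed = s)
    hit <- fit$coef$conf_low <= 0 & fit$coef$conf_high >= 0
    hits <- hits + sum(hit)
    total <- total + length(hit)
  }
  expect_gte(hits / total, 0.8)
})

test_that("single-country data collapse the hierarchy without breaking the
           fixed effects", {
  cfg <- sim_config(seed = 77, n_countries = 1, sites_per_country = 150)
  sim <- simulate_composition_records(cfg)
  f_h <- fit_dirichlet(sim$records, method = "map", seed = 1)
  f_0 <- fit_dirichlet(sim$records,
    method = "map", seed = 1,
    varying_slope = FALSE, group_intercept = FALSE
  )
  # slopes agree with the no-hierarchy fit (intercept/slope can shift by the
  # single country-level effect, which the prior shrinks towards zero)
  slopes <- function(f) {
    m <- matrix(f$coef$estimate, ncol = 2)
    m[-1, ] # drop intercepts
  }
  expect_lt(max(abs(slopes(f_h) - slopes(f_0))), 0.1)
  expect_lt(max(abs(matrix(f_h$coef$estimate, ncol = 2) - sim$truth$beta)), 0.3)
})

test_that("biomass-gradient predictions are coherent simplex paths", {
  cfg <- sim_config(seed = 88, n_countries = 2, sites_per_country = 75)
  sim <- simulate_composition_records(cfg)
  fit <- fit_dirichlet(sim$records, method = "map", seed = 3)
  pr <- predict_along_biomass(fit, "country_01", n_grid = 15)
  expect_equal(nrow(pr), 45)
  expect_true(all(pr$median > 0 & pr$median < 1))
  expect_true(all(pr$lower <= pr$median & pr$median <= pr$upper))
  # each draw closes to 1, so the posterior means close exactly
  mn <- matrix(pr$mean, ncol = 3)
  expect_equal(rowSums(mn), rep(1, 15), tolerance = 1e-9)
  # true piscivore biomass slope is positive: predicted share must rise
  pisc <- pr$median[pr$category == "piscivore"]
  expect_gt(cor(pisc, seq_along(pisc), method = "spearman"), 0.9)
  # guard rails
  expect_error(predict_along_biomass(fit, "atlantis"), "unknown country")
  rng <- fit$data$biomass_raw_range
  expect_error(
    predict_along_biomass(fit, "country_01", grid = rng[2] * 2),
    "beyond"
  )
})

test_that("zero-parameter model predicts uniform thirds at the mean", {
  beta0 <- default_true_beta() * 0
  cfg <- sim_config(
    seed = 99, n_countries = 2, sites_per_country = 100, true_beta = beta0,
    sigma_mgmt = 1e-6, sigma_slope = 1e-6
  )
  sim <- simulate_composition_records(cfg)
  fit <- fit_dirichlet(sim$records,
    method = "map", seed = 4,
    varying_slope = FALSE, group_intercept = FALSE
  )
  grid <- mean(sim$records$fishable_biomass_kg_ha)
  pr <- predict_along_biomass(fit, "country_01", grid = grid)
  expect_equal(unname(pr$median), rep(1 / 3, 3), tolerance = 0.05)
})

test_that("posterior means are invariant to affine covariate rescaling", {
  cfg <- sim_config(seed = 111, n_countries = 2, sites_per_country = 75)
  sim <- simulate_composition_records(cfg)
  f1 <- fit_dirichlet(sim$records, method = "map", seed = 5)
  rec2 <- sim$records
  rec2$depth_m <- rec2$depth_m * 3.28 + 10 # feet with an offset
  rec2$coral_pct <- rec2$coral_pct / 100 # fractions
  f2 <- fit_dirichlet(rec2, method = "map", seed = 5)
  expect_equal(f1$coef$estimate, f2$coef$estimate, tolerance = 1e-5)
  expect_lt(max(abs(fitted_composition(f1) - fitted_composition(f2))), 1e-5)
})
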