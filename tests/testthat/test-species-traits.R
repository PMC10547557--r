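test_that("nutrient density handles zero, cap-boundary and capped profiles", {
  rni <- make_rni()
  zero <- tibble::tibble(
    ca_mg = 0, fe_mg = 0, zn_mg = 0, se_ug = 0, vita_ug = 0, om3_g = 0
  )
  expect_equal(nutrient_density(zero, rni), 0)

  # each concentration exactly at its reference intake: six capped nutrients
  at_rni <- tibble::tibble(
    ca_mg = 1000, fe_mg = 10, zn_mg = 5, se_ug = 50, vita_ug = 500, om3_g = 1
  )
  expect_equal(nutrient_density(at_rni, rni), 600)

  # calcium alone at 250% of its intake: cap binds at exactly 100
  capped <- tibble::tibble(
    ca_mg = 2500, fe_mg = 0, zn_mg = 0, se_ug = 0, vita_ug = 0, om3_g = 0
  )
  expect_equal(nutrient_density(capped, rni), 100)
})

test_that("uncapped nutrient density equals the closed-form linear sum", {
  rni <- make_rni()
  set.seed(11)
  for (i in 1:20) {
    pr <- tibble::tibble(
      ca_mg = runif(1, 0, 3000), fe_mg = runif(1, 0, 30),
      zn_mg = runif(1, 0, 15), se_ug = runif(1, 0, 200),
      vita_ug = runif(1, 0, 2000), om3_g = runif(1, 0, 3)
    )
    manual <- 100 * (pr$ca_mg / 1000 + pr$fe_mg / 10 + pr$zn_mg / 5 +
      pr$se_ug / 50 + pr$vita_ug / 500 + pr$om3_g / 1)
    expect_equal(nutrient_density(pr, rni, cap = Inf), manual)
  }
})

test_that("nutrient density is monotone in each concentration below the cap", {
  rni <- make_rni()
  set.seed(12)
  cols <- c("ca_mg", "fe_mg", "zn_mg", "se_ug", "vita_ug", "om3_g")
  caps <- c(1000, 10, 5, 50, 500, 1) # concentration at which cap binds
  for (rep in 1:10) {
    base <- tibble::tibble(
      ca_mg = runif(1, 0, 500), fe_mg = runif(1, 0, 5),
      zn_mg = runif(1, 0, 2.5), se_ug = runif(1, 0, 25),
      vita_ug = runif(1, 0, 250), om3_g = runif(1, 0, 0.5)
    )
    d0 <- nutrient_density(base, rni)
    for (j in seq_along(cols)) {
      up <- base
      up[[cols[j]]] <- up[[cols[j]]] * 1.5 # still below cap
      expect_gt(nutrient_density(up, rni), d0)
      over <- base
      over[[cols[j]]] <- caps[j] * 3 # far above cap: contribution fixed at 100
      over2 <- base
      over2[[cols[j]]] <- caps[j] * 5
      expect_equal(nutrient_density(over, rni), nutrient_density(over2, rni))
    }
  }
})

test_that("missing nutrient in the reference table is a configuration error", {
  rni <- make_rni()[-3, ] # drop zinc
  expect_error(nutrient_density(make_traits(), rni), "zinc")
})

test_that("portion scaling is linear below the cap", {
  rni <- make_rni()
  pr <- tibble::tibble(
    ca_mg = 100, fe_mg = 1, zn_mg = 0.5, se_ug = 5, vita_ug = 50, om3_g = 0.1
  )
  expect_equal(
    nutrient_density(pr, rni, portion = 50),
    nutrient_density(pr, rni, portion = 100) / 2
  )
})

test_that("growth-nutrient association matches direct correlation and flags
           degenerate input", {
  set.seed(21)
  tr <- make_traits()[rep(1:6, 4), ]
  tr$species_id <- paste0(tr$species_id, seq_len(nrow(tr)))
  tr$k_max <- tr$k_max * exp(rnorm(nrow(tr), 0, 0.3))
  rni <- make_rni()
  out <- growth_nutrient_association(tr, rni)
  expect_equal(
    out$r[out$variable == "nutrient_density"],
    cor(nutrient_density(tr, rni), log10(tr$k_max))
  )
  expect_equal(
    out$r[out$variable == "iron"], cor(tr$fe_mg, log10(tr$k_max))
  )
  expect_true(all(out$r >= -1 & out$r <= 1, na.rm = TRUE))

  # zero k_max variance -> undefined correlation
  tr_const <- tr
  tr_const$k_max <- 0.5
  expect_error(growth_nutrient_association(tr_const, rni), "zero variance")

  # density exactly proportional to log k_max -> r = 1
  tr2 <- tr
  tr2$ca_mg <- 0
  tr2$fe_mg <- 0
  tr2$zn_mg <- 0
  tr2$se_ug <- 0
  tr2$vita_ug <- 0
  tr2$om3_g <- (log10(tr2$k_max) - min(log10(tr2$k_max)) + 0.1) / 100
  out2 <- growth_nutrient_association(tr2, rni)
  expect_equal(out2$r[out2$variable == "nutrient_density"], 1)
})

test_that("species order does not change association output", {
  set.seed(22)
  tr <- make_traits()[rep(1:6, 3), ]
  tr$species_id <- paste0("s", seq_len(nrow(tr)))
  tr$k_max <- tr$k_max * exp(rnorm(nrow(tr), 0, 0.2))
  rni <- make_rni()
  a <- growth_nutrient_association(tr, rni)
  b <- growth_nutrient_association(tr[sample(nrow(tr)), ], rni)
  expect_equal(a, b)
})

test_that("trait validation applies aliases and rejects unknown labels", {
  tr <- make_traits()
  tr$trophic_group[1] <- "herbivore (scraper)"
  expect_error(validate_traits(tr), "herbivore \\(scraper\\)")
  ok <- validate_traits(
    tr,
    aliases = c("herbivore (scraper)" = "herbivore_scraper_detritivore")
  )
  expect_equal(ok$trophic_group[1], "herbivore_scraper_detritivore")

  bad <- make_traits()
  bad$k_max[2] <- 20 # above the admissible growth-coefficient range
  expect_error(validate_traits(bad), "k_max")
  bad2 <- make_traits()
  bad2$lw_b[1] <- 5
  expect_error(validate_traits(bad2), "lw_b")
})

test_that("default reference-intake table loads with provenance", {
  rni <- default_rni()
  expect_setequal(rni$nutrient, names(nutrient_units()))
  expect_true(all(rni$intake > 0))
  expect_match(attr(rni, "population"), "women")
})
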