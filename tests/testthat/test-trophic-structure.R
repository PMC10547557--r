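test_that("herbivore merge sums every service column", {
  study <- small_study()
  ing <- ingest_survey(study$survey, study$sites, study$traits)
  sserv <- site_services(transect_services(ing$observations, ing$traits))
  merged <- merge_herbivores(sserv)

  site <- sserv$site_id[1]
  scr <- sserv[sserv$site_id == site &
    sserv$trophic_group == "herbivore_scraper_detritivore", ]
  brw <- sserv[sserv$site_id == site &
    sserv$trophic_group == "herbivore_browser", ]
  h <- merged[merged$site_id == site & merged$trophic_group == "herbivore", ]
  expect_equal(
    h$standing_biomass_kg_ha, scr$standing_biomass_kg_ha +
      brw$standing_biomass_kg_ha
  )
  for (n in names(nutrient_units())) {
    expect_equal(h[[n]], scr[[n]] + brw[[n]])
  }
  # turnover is recomputed from merged production and biomass, not summed
  expect_equal(
    h$turnover_pct,
    turnover(h$production_g_ha_d, h$standing_biomass_kg_ha)
  )
  # other groups untouched
  p0 <- sserv[sserv$site_id == site & sserv$trophic_group == "piscivore", ]
  p1 <- merged[merged$site_id == site & merged$trophic_group == "piscivore", ]
  expect_equal(p1$standing_biomass_kg_ha, p0$standing_biomass_kg_ha)
})

test_that("merging zero herbivore groups yields a zero herbivore row", {
  tt <- tidyr::crossing(
    tibble::tibble(site_id = "s1", transect_id = "t1", area_m2 = 250),
    trophic_group = trophic_groups()
  )
  for (cl in c(
    "standing_biomass_kg_ha", "production_g_ha_d", "turnover_pct",
    names(nutrient_units())
  )) {
    tt[[cl]] <- 0
  }
  tt$standing_biomass_kg_ha[tt$trophic_group == "piscivore"] <- 5
  m <- merge_herbivores(tt)
  expect_equal(
    m$standing_biomass_kg_ha[m$trophic_group == "herbivore"], 0
  )
})

test_that("simplex closure normalizes, zero-adjusts and errors on all-zero", {
  expect_equal(to_simplex(c(50, 30, 20)), c(0.5, 0.3, 0.2))
  z <- to_simplex(c(1, 0, 0), zero_adjust = 1e-4)
  expect_true(all(z > 0))
  expect_equal(sum(z), 1)
  expect_error(to_simplex(c(0, 0, 0)), "all-zero")
  expect_error(to_simplex(c(-1, 1, 1)), "non-negative")

  # renormalization moves each part by at most 2x the adjustment
  set.seed(51)
  for (i in 1:50) {
    v <- runif(3)
    v[sample(3, sample(0:2, 1))] <- 0
    if (sum(v) == 0) next
    raw <- v / sum(v)
    adj <- to_simplex(v, zero_adjust = 1e-4)
    expect_true(all(abs(adj - raw) <= 2e-4 + 1e-12))
    expect_equal(sum(adj), 1)
  }
})

test_that("pyramid rules classify the documented example cases", {
  expect_equal(classify_pyramid(c(0.6, 0.3, 0.1)), "bottom_heavy")
  expect_equal(
    classify_pyramid(c(0.6, 0.3, 0.1), rule = "herbivore_majority"),
    "bottom_heavy"
  )
  # rule divergence: no herbivore majority but herbivores tie piscivores
  expect_equal(
    classify_pyramid(c(0.4, 0.2, 0.4), rule = "herbivore_majority"),
    "top_heavy"
  )
  expect_equal(classify_pyramid(c(0.4, 0.2, 0.4)), "tie")
  # invertivore-dominated but herbivores exceed piscivores
  expect_equal(classify_pyramid(c(0.45, 0.5, 0.05)), "bottom_heavy")
  # exact 50% herbivores is not a majority
  expect_equal(
    classify_pyramid(c(0.5, 0.3, 0.2), rule = "herbivore_majority"),
    "top_heavy"
  )
})

test_that("classification is invariant to rescaling raw values", {
  set.seed(52)
  for (i in 1:30) {
    v <- runif(3)
    p1 <- classify_pyramid(to_simplex(v))
    p2 <- classify_pyramid(to_simplex(v * runif(1, 0.01, 100)))
    expect_equal(p1, p2)
  }
})

test_that("composition records close site shares onto the simplex with
           covariates attached", {
  study <- small_study()
  ing <- ingest_survey(study$survey, study$sites, study$traits)
  sserv <- site_services(transect_services(ing$observations, ing$traits))
  rec <- composition_records(sserv, study$sites, "standing_biomass_kg_ha")

  p <- as.matrix(rec[, c(
    "prop_herbivore", "prop_mobile_invertivore", "prop_piscivore"
  )])
  expect_true(all(p > 0))
  expect_equal(rowSums(p), rep(1, nrow(p)))
  expect_true(all(c(
    "fishable_biomass_kg_ha", "coral_pct", "depth_m", "country", "management"
  ) %in% names(rec)))
  # shares reproduce the merged service table
  merged <- merge_herbivores(sserv)
  site <- rec$site_id[1]
  m <- merged[merged$site_id == site & merged$trophic_group %in%
    c("herbivore", "mobile_invertivore", "piscivore"), ]
  v <- m$standing_biomass_kg_ha[match(
    c("herbivore", "mobile_invertivore", "piscivore"), m$trophic_group
  )]
  expect_equal(unname(p[rec$site_id == site, ]), v / sum(v))
})
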