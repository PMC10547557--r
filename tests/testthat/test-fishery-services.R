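test_that("nutrient production applies edible fraction and concentration", {
  pr <- tibble::tibble(
    ca_mg = 50, fe_mg = 1, zn_mg = 1, se_ug = 40, vita_ug = 30, om3_g = 0.2
  )
  out <- nutrient_production(100, pr)
  expect_equal(out$calcium, 100 * 0.87 * 50 / 100) # 43.5 mg/d/ha
  expect_equal(out$omega3, 100 * 0.87 * 0.2 / 100)
  # zero production gives zero everywhere
  z <- nutrient_production(0, pr)
  expect_true(all(as.numeric(z[1, ]) == 0))
  # linear in production and concentration
  expect_equal(nutrient_production(200, pr)$zinc, 2 * out$zinc)
  pr2 <- pr
  pr2$fe_mg <- 3
  expect_equal(nutrient_production(100, pr2)$iron, 3 * out$iron)
})

test_that("turnover arithmetic, basis, and degenerate cases", {
  expect_equal(turnover(10, 100), 3.65) # annual default
  expect_equal(turnover(10, 100, basis = "daily"), 0.01)
  expect_equal(turnover(0, 100), 0)
  expect_equal(turnover(0, 0), 0)
  expect_error(turnover(5, 0), "impossible")
  # invariant to scaling counts: production and biomass scale together
  expect_equal(turnover(10 * 7, 100 * 7), turnover(10, 100))
})

test_that("site services average transects and a single transect is identity", {
  study <- small_study()
  ing <- ingest_survey(study$survey, study$sites, study$traits)
  tserv <- transect_services(ing$observations, ing$traits)
  sserv <- site_services(tserv)

  # independent group-by mean
  manual <- aggregate(
    tserv[, c("standing_biomass_kg_ha", "production_g_ha_d")],
    by = list(site_id = tserv$site_id, trophic_group = tserv$trophic_group),
    FUN = mean
  )
  key <- paste(sserv$site_id, sserv$trophic_group)
  mkey <- paste(manual$site_id, manual$trophic_group)
  expect_equal(
    sserv$standing_biomass_kg_ha,
    manual$standing_biomass_kg_ha[match(key, mkey)]
  )
  expect_equal(
    sserv$production_g_ha_d,
    manual$production_g_ha_d[match(key, mkey)]
  )

  one <- tserv[tserv$transect_id == tserv$transect_id[1], ]
  s1 <- site_services(one)
  expect_equal(s1$standing_biomass_kg_ha, one$standing_biomass_kg_ha)
  expect_equal(s1$turnover_pct, one$turnover_pct)
})

test_that("two transects with biomass 100 and 300 average to 200", {
  tt <- tidyr::crossing(
    tibble::tibble(
      site_id = "s1", transect_id = c("t1", "t2"), area_m2 = 250
    ),
    trophic_group = trophic_groups()
  )
  tt$standing_biomass_kg_ha <- ifelse(tt$transect_id == "t1", 100, 300)
  tt$production_g_ha_d <- 0
  tt$turnover_pct <- 0
  for (n in names(reefnutro::nutrient_units())) tt[[n]] <- 0
  out <- site_services(tt)
  expect_true(all(out$standing_biomass_kg_ha == 200))
})

test_that("relative contributions are shares of the included-group total", {
  study <- small_study()
  ing <- ingest_survey(study$survey, study$sites, study$traits)
  sserv <- site_services(transect_services(ing$observations, ing$traits))
  rc <- relative_contributions(sserv, "standing_biomass_kg_ha")

  # sums to 100 per site and excludes sessile invertivores
  sums <- tapply(rc$share_pct, rc$site_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_false("sessile_invertivore" %in% rc$trophic_group)

  # matches a direct ratio
  incl <- sserv[sserv$trophic_group != "sessile_invertivore", ]
  site1 <- incl[incl$site_id == incl$site_id[1], ]
  expect_equal(
    rc$share_pct[rc$site_id == site1$site_id[1]],
    100 * site1$standing_biomass_kg_ha / sum(site1$standing_biomass_kg_ha)
  )

  # single nonzero group takes 100%
  toy <- sserv[sserv$site_id == sserv$site_id[1], ]
  toy$production_g_ha_d <- ifelse(
    toy$trophic_group == "piscivore", 5, 0
  )
  rc2 <- relative_contributions(toy, "production_g_ha_d")
  expect_equal(rc2$share_pct[rc2$trophic_group == "piscivore"], 100)
  expect_equal(sum(rc2$share_pct), 100)

  # equal values split evenly across the six included groups
  toy$production_g_ha_d <- 3
  rc3 <- relative_contributions(toy, "production_g_ha_d")
  expect_equal(rc3$share_pct, rep(100 / 6, 6))

  # all-zero totals are an error
  toy$production_g_ha_d <- 0
  expect_error(
    relative_contributions(toy, "production_g_ha_d"), "all-zero"
  )
})

test_that("nutrient service rates equal an individual-level recomputation", {
  study <- small_study()
  ing <- ingest_survey(study$survey, study$sites, study$traits)
  obs <- ing$observations
  tserv <- transect_services(obs, ing$traits)

  # recompute zinc production for one transect by looping over individuals
  tid <- obs$transect_id[1]
  sub <- obs[obs$transect_id == tid, ]
  zn <- 0
  for (r in seq_len(nrow(sub))) {
    tr <- ing$traits[ing$traits$species_id == sub$species_id[r], ]
    dl <- max(0, tr$l_max_cm - sub$length_resolved[r]) *
      (1 - exp(-tr$k_max / 365))
    dw <- tr$lw_a * (sub$length_resolved[r] + dl)^tr$lw_b -
      tr$lw_a * sub$length_resolved[r]^tr$lw_b
    zn <- zn + sub$count[r] * dw * 0.87 * tr$zn_mg / 100
  }
  got <- sum(tserv$zinc[tserv$transect_id == tid]) * sub$area_m2[1] / 10000
  expect_equal(got, zn, tolerance = 1e-10)
})
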