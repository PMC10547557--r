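# Fixtures built in code: a simple reference-intake table with round numbers,
# a small trait table, and a six-row toy survey exercising every exclusion
# rule.

make_rni <- function() {
  tibble::tibble(
    nutrient = c("calcium", "iron", "zinc", "selenium", "vitamin_a", "omega3"),
    intake = c(1000, 10, 5, 50, 500, 1),
    unit = c("mg", "mg", "mg", "ug", "ug", "g")
  )
}

make_traits <- function() {
  tibble::tibble(
    species_id = c(
      "sp_wrasse", "sp_dam", "sp_shark", "sp_parrot", "sp_grouper", "sp_goat"
    ),
    trophic_group = c(
      "mobile_invertivore", "planktivore", "piscivore",
      "herbivore_scraper_detritivore", "piscivore", "mobile_invertivore"
    ),
    l_max_cm = c(25, 10, 300, 45, 90, 30),
    k_max = c(0.8, 1.5, 0.08, 0.5, 0.2, 0.6),
    lw_a = c(0.012, 0.015, 0.005, 0.0135, 0.010, 0.011),
    lw_b = c(3.0, 3.1, 3.05, 3.05, 3.02, 2.98),
    ca_mg = c(40, 60, 10, 80, 15, 50),
    fe_mg = c(1.0, 2.0, 0.3, 1.5, 0.5, 1.2),
    zn_mg = c(1.5, 2.5, 0.5, 2.0, 0.8, 1.8),
    se_ug = c(40, 30, 80, 35, 60, 45),
    vita_ug = c(30, 50, 10, 60, 20, 40),
    om3_g = c(0.15, 0.30, 0.10, 0.20, 0.25, 0.18),
    is_damselfish = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_elasmobranch = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

# one row per exclusion rule plus three rows that survive
make_toy_survey <- function() {
  tibble::tibble(
    site_id = "s1",
    transect_id = "s1_t1",
    species_id = c(
      "sp_wrasse", "sp_dam", "sp_shark", "sp_parrot", "sp_grouper", "sp_goat"
    ),
    length_cm = c(4, 10, 80, 20, 35, 15),
    length_is_binned = FALSE,
    count = 1L,
    width_m = 5,
    length_m = 50
  )
}

make_sites <- function(site_ids = "s1") {
  tibble::tibble(
    site_id = site_ids,
    country = "country_01",
    management = "restricted",
    depth_m = 8,
    coral_pct = 30,
    turf_pct = 20,
    macroalgae_pct = 10,
    rubble_pct = 10,
    bare_pct = 10
  )
}

# small simulated study shared by several aggregate-level tests
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        seed = 42, n_countries = 2, sites_per_country = 10,
        species_pool_size = 80
      )
      cache <<- simulate_study(cfg)
    }
    cache
  }
})
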