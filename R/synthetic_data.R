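# Synthetic-study generator: trait tables, sites, transects and observations
# with known ground truth, so every pipeline stage is testable without any
# external download.

#' Configuration for a synthetic reef study
#'
#' Defaults emulate the survey design the package targets: four countries,
#' ~75 sites each, 1-8 belt transects per site (median 3) drawn from the
#' standard dimension set (5 x 50, 10 x 50, 2 x 30 m), a ~541-species trait
#' pool, and site fishable biomass spanning roughly 10-6000 kg ha^-1.
#' Compositions of the three fishery-target groups follow a hierarchical
#' Dirichlet model whose true parameters are part of the configuration, so
#' that model fits can be checked against ground truth.
#'
#' @param seed Master seed; all generator functions derive their RNG state
#'   from it.
#' @param n_countries,sites_per_country Survey extent.
#' @param transect_probs Probabilities of 1-8 transect replicates per site.
#' @param transect_dims List of `c(width, length)` metre pairs.
#' @param transect_dim_probs Sampling weights for `transect_dims`.
#' @param species_pool_size Number of species in the trait pool.
#' @param biomass_range Fishable-biomass gradient (kg ha^-1), sampled
#'   log-uniformly.
#' @param true_beta 8 x 2 matrix of fixed effects on the standardized scale
#'   (rows: intercept, biomass, coral, turf, macroalgae, rubble, bare, depth;
#'   columns: herbivore, piscivore — mobile invertivore is the reference).
#' @param sigma_mgmt,sigma_slope SDs of the management-in-country intercepts
#'   and the country biomass slopes.
#' @param phi True Dirichlet precision.
#' @param targeted_fraction Share of fishable biomass held by the three
#'   targeted groups (herbivores, mobile invertivores, piscivores); the rest
#'   is split among planktivores, omnivores and sessile invertivores.
#' @param browser_fraction Mean share of herbivore biomass held by browsers
#'   (vs scraping detritivores).
#' @param benthic_regime_probs Mixture over benthic regimes (coral, turf,
#'   macroalgae, rubble, bare) determining which cover dominates a site.
#' @param management_mix Per-country management probabilities; a matrix with
#'   one row per country and columns `open_access`, `restricted`, `no_take`,
#'   or a single vector recycled over countries.
#' @param contamination_rate Expected fraction of extra rows per transect that
#'   exercise the exclusion filters (damselfish, elasmobranchs, fish < 5 cm).
#' @param nutrient_size_links Whether calcium, iron, zinc (negative) and
#'   selenium (positive) concentrations are linked to body size, the realistic
#'   default; `FALSE` draws all nutrients independently of size and growth.
#' @param binned_countries Indices of countries recording lengths in 5 cm bins
#'   (up to 40 cm).
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_countries = 4,
                       sites_per_country = 75,
                       transect_probs = c(
                         0.10, 0.20, 0.35, 0.15, 0.08, 0.05, 0.04, 0.03
                       ),
                       transect_dims = list(c(5, 50), c(10, 50), c(2, 30)),
                       transect_dim_probs = c(0.79, 0.14, 0.07),
                       species_pool_size = 541,
                       biomass_range = c(10, 6000),
                       true_beta = default_true_beta(),
                       sigma_mgmt = 0.1,
                       sigma_slope = 0.1,
                       phi = 50,
                       targeted_fraction = 0.75,
                       browser_fraction = 0.35,
                       benthic_regime_probs = c(
                         hard_coral = 0.4, turf_algae = 0.2, macroalgae = 0.2,
                         rubble = 0.1, bare_substrate = 0.1
                       ),
                       management_mix = rbind(
                         c(open_access = 0.4, restricted = 0.4, no_take = 0.2),
                         c(open_access = 0, restricted = 0.6, no_take = 0.4)
                       ),
                       contamination_rate = 0.05,
                       nutrient_size_links = TRUE,
                       binned_countries = seq_len(n_countries) [
                         seq_len(n_countries) %% 2 == 0
                       ]) {
  stopifnot(
    n_countries >= 1, sites_per_country >= 1, species_pool_size >= 7,
    biomass_range[1] > 0, diff(biomass_range) > 0,
    targeted_fraction > 0, targeted_fraction <= 1, phi > 0
  )
  if (is.null(dim(management_mix))) {
    management_mix <- matrix(management_mix,
      nrow = 1,
      dimnames = list(NULL, names(management_mix))
    )
  }
  structure(
    list(
      seed = seed, n_countries = n_countries,
      sites_per_country = sites_per_country,
      transect_probs = transect_probs, transect_dims = transect_dims,
      transect_dim_probs = transect_dim_probs,
      species_pool_size = species_pool_size, biomass_range = biomass_range,
      true_beta = true_beta, sigma_mgmt = sigma_mgmt,
      sigma_slope = sigma_slope, phi = phi,
      targeted_fraction = targeted_fraction,
      browser_fraction = browser_fraction,
      benthic_regime_probs = benthic_regime_probs,
      management_mix = management_mix,
      contamination_rate = contamination_rate,
      nutrient_size_links = nutrient_size_links,
      binned_countries = binned_countries
    ),
    class = "sim_config"
  )
}

#' Default true fixed effects of the synthetic composition model
#'
#' Standardized-scale coefficients for the two non-reference categories
#' (herbivore, piscivore; mobile invertivore is the reference). The pattern
#' follows the qualitative structure of fished reef assemblages: herbivores
#' dominate on average, piscivore share rises with fishable biomass and depth,
#' herbivore share rises with coral and macroalgal cover and falls on rubble.
#'
#' @return An 8 x 2 named matrix.
#' @export
default_true_beta <- function() {
  m <- cbind(
    herbivore = c(0.8, -0.2, 0.3, 0.1, 0.3, -0.2, 0.0, -0.2),
    piscivore = c(-0.8, 0.5, 0.0, -0.1, 0.0, -0.1, -0.3, 0.3)
  )
  rownames(m) <- c(
    "(Intercept)", "biomass", "coral", "turf", "macroalgae", "rubble",
    "bare", "depth"
  )
  m
}

#' Simulate a species trait pool
#'
#' Emulates the trait structure of reef fish assemblages: log-normal maximum
#' lengths per trophic group; standardized growth coefficients declining with
#' maximum length (`k_max = c * l_max^gamma * noise`, gamma < 0, clipped to
#' the published range); calcium, iron and zinc concentrations declining with
#' body size, selenium increasing with it, vitamin A and omega-3 independent
#' of growth. A subset of small planktivores/omnivores is flagged as
#' damselfish and a few large piscivores as elasmobranchs so the ingest
#' filters can be exercised.
#'
#' @param config A [sim_config()].
#' @return A validated trait tibble (see [read_traits()]).
#' @export
simulate_species_pool <- function(config) {
  set.seed(config$seed)
  n <- config$species_pool_size
  groups <- trophic_groups()
  wts <- c(0.15, 0.08, 0.14, 0.10, 0.10, 0.25, 0.18)
  tg <- c(groups, sample(groups, n - length(groups), TRUE, prob = wts))
  meanlog <- c(
    herbivore_scraper_detritivore = log(28), herbivore_browser = log(38),
    planktivore = log(13), omnivore = log(20), sessile_invertivore = log(16),
    mobile_invertivore = log(25), piscivore = log(48)
  )
  l_max <- pmin(pmax(rlnorm(n, meanlog[tg], 0.4), 6), 200)
  # growth declines with maximum length and is structured by diet: grazers
  # and planktivores grow fast for their size, piscivores slowly
  k_mult <- c(
    herbivore_scraper_detritivore = 1.6, herbivore_browser = 1.2,
    planktivore = 1.3, omnivore = 1.0, sessile_invertivore = 1.0,
    mobile_invertivore = 0.9, piscivore = 0.6
  )
  k_max <- pmin(
    pmax(8.9 * unname(k_mult[tg]) * l_max^-0.9 * rlnorm(n, 0, 0.4), 0.011),
    16.43
  )
  lw_a <- pmin(pmax(rlnorm(n, log(0.012), 0.3), 0.003), 0.05)
  lw_b <- pmin(pmax(rnorm(n, 3.0, 0.1), 2.6), 3.4)
  # centred log size drives the mineral/selenium size links; a config switch
  # removes the links so null-association behaviour can be studied
  ll <- if (isTRUE(config$nutrient_size_links)) log(l_max) - 3 else 0
  traits <- tibble::tibble(
    species_id = sprintf("sp%04d", seq_len(n)),
    trophic_group = tg,
    l_max_cm = l_max,
    k_max = k_max,
    lw_a = lw_a,
    lw_b = lw_b,
    ca_mg = exp(3.7 - 0.5 * ll + rnorm(n, 0, 0.5)),
    fe_mg = exp(0.0 - 0.4 * ll + rnorm(n, 0, 0.4)),
    zn_mg = exp(0.5 - 0.4 * ll + rnorm(n, 0, 0.35)),
    se_ug = exp(3.7 + 0.3 * ll + rnorm(n, 0, 0.4)),
    vita_ug = exp(3.4 + rnorm(n, 0, 0.8)),
    om3_g = exp(-1.7 + rnorm(n, 0, 0.5)),
    is_damselfish = FALSE,
    is_elasmobranch = FALSE
  )
  small_plank <- which(
    traits$trophic_group %in% c("planktivore", "omnivore") &
      traits$l_max_cm < 15
  )
  if (length(small_plank) > 0) {
    flag <- small_plank[rbinom(length(small_plank), 1, 0.4) == 1]
    if (length(flag) == 0) flag <- small_plank[1]
    traits$is_damselfish[flag] <- TRUE
  }
  big_pisc <- which(traits$trophic_group == "piscivore" & traits$l_max_cm > 70)
  if (length(big_pisc) > 0) {
    flag <- big_pisc[rbinom(length(big_pisc), 1, 0.15) == 1]
    if (length(flag) == 0) flag <- big_pisc[1]
    traits$is_elasmobranch[flag] <- TRUE
  }
  validate_traits(traits)
}

# site covariates + true compositions from the Dirichlet model
simulate_sites_truth <- function(config) {
  set.seed(config$seed + 1L)
  n_c <- config$n_countries
  n_s <- config$sites_per_country
  n <- n_c * n_s
  country <- rep(sprintf("country_%02d", seq_len(n_c)), each = n_s)
  mgmt_levels <- management_levels()
  mix <- config$management_mix
  management <- character(n)
  for (ci in seq_len(n_c)) {
    row <- mix[(ci - 1) %% nrow(mix) + 1, mgmt_levels]
    management[country == country[(ci - 1) * n_s + 1]] <-
      sample(mgmt_levels, n_s, TRUE, prob = row)
  }
  depth <- pmin(pmax(rlnorm(n, log(8), 0.5), 2), 25)
  regimes <- sample(
    names(config$benthic_regime_probs), n, TRUE,
    prob = config$benthic_regime_probs
  )
  # five tracked groups plus an unclassified remainder (sand, soft corals,
  # sponges); the remainder varies substantially on real reefs, so the five
  # covers are not a closed composition
  cover_alpha <- matrix(1, n, 6)
  colnames(cover_alpha) <- c(benthic_groups(), "other")
  cover_alpha[, "other"] <- 3
  for (i in seq_len(n)) cover_alpha[i, regimes[i]] <- 6
  covers <- 100 * t(vapply(
    seq_len(n), function(i) drop(rdirichlet(1, cover_alpha[i, ])),
    numeric(6)
  ))
  colnames(covers) <- colnames(cover_alpha)
  biomass <- 10^runif(
    n, log10(config$biomass_range[1]), log10(config$biomass_range[2])
  )

  raw <- cbind(
    biomass = biomass,
    coral = covers[, "hard_coral"], turf = covers[, "turf_algae"],
    macroalgae = covers[, "macroalgae"], rubble = covers[, "rubble"],
    bare = covers[, "bare_substrate"], depth = depth
  )
  xs <- apply(raw, 2, function(x) (x - mean(x)) / sd(x))
  X <- cbind(`(Intercept)` = 1, xs)

  u_slope <- matrix(
    rnorm(n_c * 2, 0, config$sigma_slope), n_c, 2,
    dimnames = list(unique(country), c("herbivore", "piscivore"))
  )
  grp <- paste(country, management, sep = ":")
  grp_levels <- sort(unique(grp))
  u_mgmt <- matrix(
    rnorm(length(grp_levels) * 2, 0, config$sigma_mgmt),
    length(grp_levels), 2,
    dimnames = list(grp_levels, c("herbivore", "piscivore"))
  )

  eta <- matrix(0, n, 3)
  ci <- match(country, unique(country))
  gi <- match(grp, grp_levels)
  for (j in 1:2) {
    k <- c(1, 3)[j] # herbivore, piscivore columns; mobile invertivore = 2
    eta[, k] <- X %*% config$true_beta[, j] +
      u_mgmt[gi, j] +
      u_slope[ci, j] * xs[, "biomass"]
  }
  mu <- dirichlet_mean(eta, config$phi)$mu
  y <- t(vapply(
    seq_len(n), function(i) drop(rdirichlet(1, mu[i, ] * config$phi)),
    numeric(3)
  ))
  colnames(y) <- composition_categories()

  sites <- tibble::tibble(
    site_id = sprintf("site_%04d", seq_len(n)),
    country = country, management = management,
    depth_m = depth,
    coral_pct = covers[, "hard_coral"],
    turf_pct = covers[, "turf_algae"],
    macroalgae_pct = covers[, "macroalgae"],
    rubble_pct = covers[, "rubble"],
    bare_pct = covers[, "bare_substrate"]
  )
  list(
    sites = sites,
    truth = list(
      beta = config$true_beta, sigma_mgmt = config$sigma_mgmt,
      sigma_slope = config$sigma_slope, phi = config$phi,
      u_slope = u_slope, u_mgmt = u_mgmt,
      target_biomass = biomass, composition = y, mu = mu,
      standardization = list(
        mean = colMeans(raw), sd = apply(raw, 2, sd)
      )
    )
  )
}

#' Simulate model-ready composition records with known truth
#'
#' Draws site covariates and three-part compositions directly from the
#' hierarchical Dirichlet model (the well-specified case), bypassing the
#' survey layer. This is the generator used for parameter-recovery and
#' calibration studies of [fit_dirichlet()].
#'
#' @param config A [sim_config()].
#' @return List with `records` (ready for [fit_dirichlet()]) and `truth`
#'   (true coefficients on the standardized scale, group effects, `phi`, and
#'   the site compositions).
#' @export
simulate_composition_records <- function(config) {
  st <- simulate_sites_truth(config)
  records <- tibble::tibble(
    site_id = st$sites$site_id,
    prop_herbivore = st$truth$composition[, 1],
    prop_mobile_invertivore = st$truth$composition[, 2],
    prop_piscivore = st$truth$composition[, 3],
    service = "simulated",
    fishable_biomass_kg_ha = st$truth$target_biomass,
    country = st$sites$country,
    management = st$sites$management,
    depth_m = st$sites$depth_m,
    coral_pct = st$sites$coral_pct,
    turf_pct = st$sites$turf_pct,
    macroalgae_pct = st$sites$macroalgae_pct,
    rubble_pct = st$sites$rubble_pct,
    bare_pct = st$sites$bare_pct
  )
  list(records = records, truth = st$truth)
}

# Fill one transect's group budget (grams) with individual fish drawn from
# the group's unconditional size distribution. The fish that crosses the
# remaining budget is admitted with probability remaining/mass, keeping the
# expected realized biomass equal to the budget without biasing rare groups
# towards implausibly small individuals; overshoot_g bounds how far past the
# budget that crossing fish may land.
fill_group_budget <- function(budget_g, species, lmax, lwa, lwb,
                              overshoot_g = Inf, max_failures = 30) {
  out_sp <- character(0)
  out_len <- numeric(0)
  remaining <- budget_g
  failures <- 0
  while (remaining > 0.02 * budget_g && failures < max_failures) {
    i <- sample.int(length(species), 1)
    upper <- max(5.5, 0.95 * lmax[i])
    len <- 5 + (upper - 5) * stats::rbeta(1, 3, 2)
    mass <- lwa[i] * len^lwb[i]
    if (mass <= remaining) {
      out_sp <- c(out_sp, species[i])
      out_len <- c(out_len, len)
      remaining <- remaining - mass
      failures <- 0
    } else if (mass - remaining <= overshoot_g) {
      if (runif(1) < remaining / mass) {
        out_sp <- c(out_sp, species[i])
        out_len <- c(out_len, len)
      }
      break
    } else {
      failures <- failures + 1
    }
  }
  list(species = out_sp, length = out_len)
}

#' Simulate a UVC survey from site truth
#'
#' Generates per-transect observations whose fishable biomass and trophic
#' composition match each site's ground-truth targets: counts are drawn per
#' trophic group until the group's biomass budget on the transect is filled,
#' lengths come from truncated size distributions below each species' maximum
#' length, and (at a configurable rate) damselfish, elasmobranch and sub-5 cm
#' rows are added to exercise the exclusion filters. Countries configured as
#' binned record lengths as 5 cm bin lower edges up to 40 cm.
#'
#' @param config A [sim_config()].
#' @param traits Trait pool from [simulate_species_pool()].
#' @param sites_truth Output of the site generator (see [simulate_study()]).
#' @return A survey tibble (see [read_survey()]).
#' @export
simulate_survey <- function(config, traits, sites_truth) {
  set.seed(config$seed + 2L)
  sites <- sites_truth$sites
  truth <- sites_truth$truth
  n <- nrow(sites)
  cats <- composition_categories()

  pool <- traits[!traits$is_damselfish & !traits$is_elasmobranch, ]
  by_group <- split(seq_len(nrow(pool)), pool$trophic_group)
  dams <- traits[traits$is_damselfish, ]
  elas <- traits[traits$is_elasmobranch, ]

  country_idx <- match(sites$country, unique(sites$country))
  rows <- vector("list", n * 4L)
  ri <- 0L
  for (i in seq_len(n)) {
    n_tr <- sample(1:8, 1, prob = config$transect_probs)
    y <- unname(truth$composition[i, ])
    browser_share <- stats::rbeta(1, config$browser_fraction * 10,
      (1 - config$browser_fraction) * 10
    )
    other_split <- drop(rdirichlet(1, c(5, 3, 2))) # plank, omni, sessile
    group_share <- c(
      herbivore_scraper_detritivore =
        config$targeted_fraction * y[1] * (1 - browser_share),
      herbivore_browser = config$targeted_fraction * y[1] * browser_share,
      planktivore = (1 - config$targeted_fraction) * other_split[1],
      omnivore = (1 - config$targeted_fraction) * other_split[2],
      sessile_invertivore = (1 - config$targeted_fraction) * other_split[3],
      mobile_invertivore = config$targeted_fraction * y[2],
      piscivore = config$targeted_fraction * y[3]
    )
    binned <- country_idx[i] %in% config$binned_countries
    for (tr in seq_len(n_tr)) {
      dim_i <- config$transect_dims[[
        sample.int(length(config$transect_dims), 1,
          prob = config$transect_dim_probs
        )
      ]]
      area_ha <- dim_i[1] * dim_i[2] / 10000
      tid <- sprintf("%s_t%02d", sites$site_id[i], tr)
      transect_budget_g <- truth$target_biomass[i] * area_ha * 1000
      # one crossing fish per group may overshoot its budget; the allowance
      # is shared across groups so the transect total stays within ~10%
      overshoot_allow <- 0.1 * transect_budget_g
      sp_all <- character(0)
      len_all <- numeric(0)
      for (g in names(group_share)) {
        budget <- transect_budget_g * group_share[[g]]
        gi <- by_group[[g]]
        if (is.null(gi) || budget <= 0) next
        fill <- fill_group_budget(
          budget, pool$species_id[gi], pool$l_max_cm[gi],
          pool$lw_a[gi], pool$lw_b[gi],
          overshoot_g = overshoot_allow
        )
        mi <- match(fill$species, pool$species_id)
        realized <- sum(pool$lw_a[mi] * fill$length^pool$lw_b[mi])
        overshoot_allow <- max(0, overshoot_allow - max(0, realized - budget))
        sp_all <- c(sp_all, fill$species)
        len_all <- c(len_all, fill$length)
      }
      # contamination rows exercising the ingest filters
      if (config$contamination_rate > 0 && length(sp_all) > 0) {
        n_cont <- stats::rpois(
          3, config$contamination_rate * length(sp_all) / 3
        )
        if (n_cont[1] > 0 && nrow(dams) > 0) {
          j <- sample.int(nrow(dams), n_cont[1], TRUE)
          sp_all <- c(sp_all, dams$species_id[j])
          len_all <- c(len_all, runif(n_cont[1], 6, 12))
        }
        if (n_cont[2] > 0 && nrow(elas) > 0) {
          j <- sample.int(nrow(elas), n_cont[2], TRUE)
          sp_all <- c(sp_all, elas$species_id[j])
          len_all <- c(len_all, runif(n_cont[2], 60, 150))
        }
        if (n_cont[3] > 0) {
          j <- sample.int(nrow(pool), n_cont[3], TRUE)
          sp_all <- c(sp_all, pool$species_id[j])
          len_all <- c(len_all, runif(n_cont[3], 2, 4.5))
        }
      }
      if (length(sp_all) == 0) next
      is_small <- len_all < 5
      rec_len <- ifelse(
        binned & len_all <= 40 & !is_small,
        floor(len_all / 5) * 5,
        pmax(round(len_all), 1)
      )
      rec_bin <- binned & len_all <= 40 & !is_small
      tab <- tibble::tibble(
        site_id = sites$site_id[i], transect_id = tid,
        species_id = sp_all, length_cm = rec_len,
        length_is_binned = rec_bin,
        width_m = dim_i[1], length_m = dim_i[2]
      ) |>
        dplyr::count(
          .data$site_id, .data$transect_id, .data$species_id,
          .data$length_cm, .data$length_is_binned,
          .data$width_m, .data$length_m,
          name = "count"
        )
      ri <- ri + 1L
      rows[[ri]] <- tab
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(ri)])
  out[, c(
    "site_id", "transect_id", "species_id", "length_cm",
    "length_is_binned", "count", "width_m", "length_m"
  )]
}

#' Simulate a complete synthetic study
#'
#' Generates the trait pool, site table with true compositions, and a UVC
#' survey realizing those targets. The returned `truth` element carries every
#' ground-truth quantity (true coefficients, group effects, precision, target
#' biomass and compositions) for downstream validation.
#'
#' @param config A [sim_config()].
#' @return List with `traits`, `sites`, `survey`, and `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  traits <- simulate_species_pool(config)
  st <- simulate_sites_truth(config)
  survey <- simulate_survey(config, traits, st)
  list(traits = traits, sites = st$sites, survey = survey, truth = st$truth)
}
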