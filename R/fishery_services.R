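#' Nutrient production from biomass production
#'
#' Converts a biomass production rate into the production rates of six dietary
#' nutrients contained in the edible portion of that biomass:
#' `rate_n = production x edible_fraction x concentration_n / 100 g`.
#' Units follow the concentration units: mg d^-1 ha^-1 for calcium, iron and
#' zinc; ug d^-1 ha^-1 for selenium and vitamin A; g d^-1 ha^-1 for omega-3.
#'
#' @param production_g_ha_d Biomass production (g d^-1 ha^-1); vectorized.
#' @param profile Data frame (rows matching `production_g_ha_d`, or one row)
#'   with the six concentration columns `ca_mg, fe_mg, zn_mg, se_ug, vita_ug,
#'   om3_g` (per 100 g).
#' @param edible_fraction Edible portion of whole-fish mass; the finfish
#'   average 0.87 is the default.
#'
#' @return A tibble with columns `calcium, iron, zinc, selenium, vitamin_a,
#'   omega3`.
#' @export
#' @examples
#' nutrient_production(100, data.frame(
#'   ca_mg = 50, fe_mg = 1, zn_mg = 1, se_ug = 40, vita_ug = 30, om3_g = 0.2
#' ))
nutrient_production <- function(production_g_ha_d, profile,
                                edible_fraction = 0.87) {
  stopifnot(edible_fraction > 0, edible_fraction <= 1)
  cols <- nutrient_cols()
  out <- lapply(names(cols), function(n) {
    production_g_ha_d * edible_fraction * profile[[cols[[n]]]] / 100
  })
  names(out) <- names(cols)
  tibble::as_tibble(out)
}

#' Biomass turnover
#'
#' Production divided by standing biomass, expressed as a percentage. The
#' daily basis reports percent of standing stock produced per day; the annual
#' basis (default) multiplies by 365.
#'
#' @param production_g_ha_d Biomass production (g d^-1 ha^-1).
#' @param standing_biomass_kg_ha Standing biomass (kg ha^-1).
#' @param basis `"annual"` (default) or `"daily"`.
#' @return Turnover in percent. Zero biomass with zero production is defined
#'   as 0; zero biomass with positive production is an error.
#' @export
#' @examples
#' turnover(10, 100) # 3.65% per year
turnover <- function(production_g_ha_d, standing_biomass_kg_ha,
                     basis = c("annual", "daily")) {
  basis <- match.arg(basis)
  impossible <- standing_biomass_kg_ha <= 0 & production_g_ha_d > 0
  if (any(impossible)) {
    stop("positive production with zero standing biomass is impossible",
      call. = FALSE
    )
  }
  daily <- ifelse(
    standing_biomass_kg_ha == 0, 0,
    100 * (production_g_ha_d / 1000) / standing_biomass_kg_ha
  )
  if (basis == "annual") daily * 365 else daily
}

#' Per-transect fishery services by trophic group
#'
#' Computes, for every transect and trophic group, standing biomass
#' (kg ha^-1), biomass production (g d^-1 ha^-1), biomass turnover (%), and
#' the six nutrient-production rates. Nutrient rates are accumulated at the
#' individual-observation level (each fish's production times its own
#' species' concentrations) before scaling to per-hectare.
#'
#' @param observations Cleaned observations from [ingest_survey()].
#' @param traits Validated trait table.
#' @param edible_fraction Passed to [nutrient_production()].
#' @param basis Turnover basis, see [turnover()].
#' @param days_per_year Passed to [daily_growth()].
#'
#' @return Tibble: one row per site x transect x trophic group with service
#'   columns.
#' @export
transect_services <- function(observations, traits, edible_fraction = 0.87,
                              basis = c("annual", "daily"),
                              days_per_year = 365) {
  basis <- match.arg(basis)
  idx <- match(observations$species_id, traits$species_id)
  g <- daily_growth(
    observations$length_resolved,
    l_max = traits$l_max_cm[idx], k_max = traits$k_max[idx],
    lw_a = traits$lw_a[idx], lw_b = traits$lw_b[idx],
    days_per_year = days_per_year
  )
  obs <- observations
  obs$mass_total_g <- g$mass_g * obs$count
  obs$prod_total_g <- g$daily_mass_production_g * obs$count
  nut <- nutrient_production(
    obs$prod_total_g,
    traits[idx, unname(nutrient_cols()), drop = FALSE],
    edible_fraction = edible_fraction
  )
  obs <- dplyr::bind_cols(obs, nut)

  per_tr <- obs |>
    dplyr::group_by(.data$site_id, .data$transect_id, .data$trophic_group) |>
    dplyr::summarise(
      area_m2 = .data$area_m2[1],
      standing_biomass_kg_ha = to_per_hectare(
        sum(.data$mass_total_g), .data$area_m2[1]
      ) / 1000,
      production_g_ha_d = to_per_hectare(
        sum(.data$prod_total_g), .data$area_m2[1]
      ),
      dplyr::across(
        dplyr::all_of(names(nutrient_cols())),
        \(x) to_per_hectare(sum(x), .data$area_m2[1])
      ),
      .groups = "drop"
    )

  transects <- dplyr::distinct(
    obs, .data$site_id, .data$transect_id, .data$area_m2
  )
  grid <- tidyr::crossing(transects, trophic_group = trophic_groups())
  out <- grid |>
    dplyr::left_join(
      per_tr,
      by = c("site_id", "transect_id", "area_m2", "trophic_group")
    ) |>
    dplyr::mutate(dplyr::across(
      c(
        "standing_biomass_kg_ha", "production_g_ha_d",
        dplyr::all_of(names(nutrient_cols()))
      ),
      \(x) tidyr::replace_na(x, 0)
    ))
  out$turnover_pct <- turnover(
    out$production_g_ha_d, out$standing_biomass_kg_ha,
    basis = basis
  )
  attr(out, "turnover_basis") <- basis
  out
}

#' Site-level fishery services
#'
#' Averages transect-level service estimates (unweighted mean across a site's
#' transects) to give one row per site x trophic group. Averaging transects
#' before any normalization reduces sampling variability arising from the
#' number and size of transect replicates.
#'
#' @param transect_table Output of [transect_services()].
#' @return Tibble: one row per site x trophic group with the same service
#'   columns; carries the turnover basis as an attribute.
#' @export
site_services <- function(transect_table) {
  metric_cols <- c(
    "standing_biomass_kg_ha", "production_g_ha_d", "turnover_pct",
    names(nutrient_cols())
  )
  out <- transect_table |>
    dplyr::group_by(.data$site_id, .data$trophic_group) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols), mean),
      n_transects = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "turnover_basis") <- attr(transect_table, "turnover_basis")
  out
}

#' Relative contributions of trophic groups to a fishery service
#'
#' Converts site-level service values into each trophic group's percent share
#' of the site total across the included groups. Sessile invertivores are
#' excluded by default: they are not fishery targets and contribute little to
#' nutrient production.
#'
#' @param service_table Output of [site_services()] (or the transect table).
#' @param service Name of the service column, e.g. `"standing_biomass_kg_ha"`,
#'   `"turnover_pct"`, or a nutrient (`"zinc"`).
#' @param groups Trophic groups to include; shares are computed over these.
#'
#' @return Tibble: one row per site x included group with `share_pct`; shares
#'   sum to 100 within each site.
#' @export
relative_contributions <- function(service_table, service,
                                   groups = setdiff(
                                     trophic_groups(), "sessile_invertivore"
                                   )) {
  if (!service %in% names(service_table)) {
    stop("unknown service column: ", service, call. = FALSE)
  }
  tab <- service_table[service_table$trophic_group %in% groups, ]
  out <- tab |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(total = sum(.data[[service]])) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    stop("all-zero service total at some site; composition undefined",
      call. = FALSE
    )
  }
  out$share_pct <- 100 * out[[service]] / out$total
  out$service <- service
  dplyr::select(
    out, "site_id", "trophic_group", "service", "share_pct"
  )
}

#' Site-level covariates for the composition model
#'
#' Builds one row per site with total fishable biomass (standing biomass
#' summed over trophic groups after the ingest exclusions), benthic covers,
#' depth, country and management.
#'
#' @param service_table Output of [site_services()].
#' @param sites Validated site table.
#' @return Tibble of site covariates.
#' @export
site_covariates <- function(service_table, sites) {
  biomass <- service_table |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      fishable_biomass_kg_ha = sum(.data$standing_biomass_kg_ha),
      .groups = "drop"
    )
  dplyr::inner_join(biomass, sites, by = "site_id")
}
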