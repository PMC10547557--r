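#' Daily somatic growth of an individual fish
#'
#' Advances each fish one day along its species' von Bertalanffy growth
#' trajectory, parameterized by the standardized growth coefficient `k_max`
#' (per year) at the species' maximum length. With asymptotic length taken
#' equal to the maximum length `l_max`, the one-day length increment is
#'
#'   dL = (l_max - L) * (1 - exp(-k_max / 365))
#'
#' for L below `l_max`, and zero otherwise (fish recorded at or above their
#' species maximum — possible with binned lengths — are clamped to zero growth
#' rather than assigned a negative age). The increment is converted to a mass
#' increment with the species' length-weight relationship:
#'
#'   dW = lw_a * (L + dL)^lw_b - lw_a * L^lw_b.
#'
#' These are *potential* rates: natural and fishing mortality are excluded by
#' construction.
#'
#' @param length_cm Current body length (cm); vectorized.
#' @param l_max Species maximum length (cm), used as asymptotic length. The
#'   equivalence is isolated here: pass a corrected asymptotic length to use a
#'   different convention.
#' @param k_max Standardized growth coefficient (per year).
#' @param lw_a,lw_b Length-weight coefficients.
#' @param days_per_year Days used to convert the annual coefficient to a daily
#'   rate (default 365).
#'
#' @return A tibble with `mass_g`, `daily_length_growth_cm`, and
#'   `daily_mass_production_g`.
#' @export
#' @examples
#' daily_growth(10, 30, 0.5, 0.01, 3)
daily_growth <- function(length_cm, l_max, k_max, lw_a, lw_b,
                         days_per_year = 365) {
  stopifnot(all(length_cm > 0), all(l_max > 0), all(k_max > 0))
  dl <- pmax(0, (l_max - length_cm)) * (1 - exp(-k_max / days_per_year))
  w0 <- length_to_mass(length_cm, lw_a, lw_b)
  w1 <- length_to_mass(length_cm + dl, lw_a, lw_b)
  tibble::tibble(
    mass_g = w0,
    daily_length_growth_cm = dl,
    daily_mass_production_g = w1 - w0
  )
}

#' Per-transect biomass and production by trophic group
#'
#' Sums individual standing mass and daily production over all observations on
#' each transect, scales to per-hectare rates, and reports one row per
#' transect x trophic group. Groups absent from a transect get explicit zeros
#' so that downstream site averages are not biased towards transects where a
#' group happened to be seen.
#'
#' @param observations Cleaned observations from [ingest_survey()] (must carry
#'   `length_resolved`, `area_m2`, `trophic_group`).
#' @param traits Validated trait table.
#' @param days_per_year Passed to [daily_growth()].
#'
#' @return A tibble with one row per site x transect x trophic group:
#'   `standing_biomass_kg_ha` (kg ha^-1) and `production_g_ha_d`
#'   (g d^-1 ha^-1).
#' @export
transect_production <- function(observations, traits, days_per_year = 365) {
  idx <- match(observations$species_id, traits$species_id)
  if (any(is.na(idx))) {
    stop("observations contain species absent from the trait table",
      call. = FALSE
    )
  }
  g <- daily_growth(
    observations$length_resolved,
    l_max = traits$l_max_cm[idx],
    k_max = traits$k_max[idx],
    lw_a = traits$lw_a[idx],
    lw_b = traits$lw_b[idx],
    days_per_year = days_per_year
  )
  obs <- observations
  obs$mass_total_g <- g$mass_g * obs$count
  obs$prod_total_g <- g$daily_mass_production_g * obs$count

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
      .groups = "drop"
    )

  # complete the transect x group grid with zeros
  transects <- dplyr::distinct(
    obs, .data$site_id, .data$transect_id, .data$area_m2
  )
  grid <- tidyr::crossing(transects, trophic_group = trophic_groups())
  grid |>
    dplyr::left_join(
      per_tr,
      by = c("site_id", "transect_id", "area_m2", "trophic_group")
    ) |>
    dplyr::mutate(
      standing_biomass_kg_ha = tidyr::replace_na(
        .data$standing_biomass_kg_ha, 0
      ),
      production_g_ha_d = tidyr::replace_na(.data$production_g_ha_d, 0)
    )
}
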