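#' Merge the two herbivore groups
#'
#' Combines scraping/detritivorous and browsing herbivores into a single
#' `herbivore` group by summing every service column, leaving other groups
#' untouched. The composition model works with three fishery-target groups:
#' herbivores, mobile invertivores and piscivores.
#'
#' @param service_table Output of [site_services()] or [transect_services()].
#' @return The table with one `herbivore` row per site (and transect, if
#'   present) replacing the two herbivore rows.
#' @export
merge_herbivores <- function(service_table) {
  herb <- c("herbivore_scraper_detritivore", "herbivore_browser")
  if (!all(herb %in% unique(service_table$trophic_group)) &&
    !any(herb %in% unique(service_table$trophic_group))) {
    stop("no herbivore groups present in the service table", call. = FALSE)
  }
  keys <- intersect(c("site_id", "transect_id"), names(service_table))
  metric_cols <- setdiff(
    names(service_table)[vapply(service_table, is.numeric, logical(1))],
    c("n_transects", "area_m2")
  )
  tab <- service_table
  tab$trophic_group[tab$trophic_group %in% herb] <- "herbivore"
  out <- tab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "trophic_group")))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols), sum),
      .groups = "drop"
    )
  # turnover is a ratio, not additive: recompute for the merged herbivores
  if (all(c("production_g_ha_d", "standing_biomass_kg_ha", "turnover_pct")
  %in% names(out))) {
    basis <- attr(service_table, "turnover_basis")
    if (is.null(basis)) basis <- "annual"
    merged <- out$trophic_group == "herbivore"
    out$turnover_pct[merged] <- turnover(
      out$production_g_ha_d[merged], out$standing_biomass_kg_ha[merged],
      basis = basis
    )
    attr(out, "turnover_basis") <- basis
  }
  out
}

#' Close values onto the 3-part simplex
#'
#' Divides three non-negative values by their total, then replaces exact zero
#' components by a small positive fraction and renormalizes. Dirichlet support
#' requires strictly positive parts, and observed piscivore shares can be
#' exactly zero on heavily fished reefs.
#'
#' @param values Numeric vector of 3 non-negative values, or a 3-column matrix
#'   (rows are observations).
#' @param zero_adjust Replacement fraction for zero parts (default 1e-4).
#' @return Vector or matrix of strictly positive proportions summing to 1.
#' @export
#' @examples
#' to_simplex(c(50, 30, 20))
#' to_simplex(c(1, 0, 0))
to_simplex <- function(values, zero_adjust = 1e-4) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  if (any(m < 0)) stop("composition values must be non-negative", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("all-zero composition; simplex undefined", call. = FALSE)
  }
  p <- m / tot
  zero <- p == 0
  if (any(zero)) {
    p[zero] <- zero_adjust
    p <- p / rowSums(p)
  }
  if (vec) drop(p) else p
}

#' Classify trophic-pyramid shape
#'
#' Two definitions are in common use and both are implemented. Under
#' `herbivore_majority`, a site is bottom-heavy when herbivores contribute
#' more than 50% of the service (ties go to top-heavy). Under
#' `herbivore_vs_piscivore` (the default), a site is bottom-heavy when the
#' herbivore share exceeds the piscivore share, top-heavy when piscivores
#' dominate herbivores, and flagged `"tie"` when the two are exactly equal.
#' The rules agree whenever either herbivores or piscivores hold an outright
#' majority; they can disagree only when herbivores lack a majority yet still
#' exceed piscivores (e.g. invertivore-dominated reefs).
#'
#' @param proportions Numeric vector `c(herbivore, mobile_invertivore,
#'   piscivore)` or a 3-column matrix of simplex rows in that order.
#' @param rule `"herbivore_vs_piscivore"` (default) or `"herbivore_majority"`.
#' @return Character vector: `"bottom_heavy"`, `"top_heavy"`, or (rule 2 only)
#'   `"tie"`.
#' @export
#' @examples
#' classify_pyramid(c(0.6, 0.3, 0.1))
#' classify_pyramid(c(0.4, 0.2, 0.4), rule = "herbivore_majority")
classify_pyramid <- function(proportions,
                             rule = c(
                               "herbivore_vs_piscivore", "herbivore_majority"
                             )) {
  rule <- match.arg(rule)
  m <- if (is.null(dim(proportions))) {
    matrix(proportions, nrow = 1)
  } else {
    as.matrix(proportions)
  }
  if (ncol(m) != 3) stop("expected 3-part compositions", call. = FALSE)
  herb <- m[, 1]
  pisc <- m[, 3]
  if (rule == "herbivore_majority") {
    ifelse(herb > 0.5, "bottom_heavy", "top_heavy")
  } else {
    dplyr::case_when(
      herb > pisc ~ "bottom_heavy",
      herb < pisc ~ "top_heavy",
      TRUE ~ "tie"
    )
  }
}

#' Build model-ready composition records
#'
#' For one fishery service, computes each site's three-part trophic
#' composition (herbivore, mobile invertivore, piscivore) from the site
#' service table, closes it onto the simplex, and joins the site covariates.
#' This is the input to [fit_dirichlet()].
#'
#' @param service_table Output of [site_services()].
#' @param sites Validated site table.
#' @param service Service column to decompose (see
#'   [relative_contributions()]).
#' @param zero_adjust Passed to [to_simplex()].
#'
#' @return Tibble: one row per site with `prop_herbivore`,
#'   `prop_mobile_invertivore`, `prop_piscivore`, `fishable_biomass_kg_ha`,
#'   benthic covers, `depth_m`, `country`, `management`, and `service`.
#' @export
composition_records <- function(service_table, sites, service,
                                zero_adjust = 1e-4) {
  merged <- merge_herbivores(service_table)
  tab <- merged[
    merged$trophic_group %in% c("herbivore", "mobile_invertivore", "piscivore"),
    c("site_id", "trophic_group", service)
  ]
  wide <- tidyr::pivot_wider(
    tab,
    names_from = "trophic_group", values_from = dplyr::all_of(service)
  )
  m <- as.matrix(wide[, c("herbivore", "mobile_invertivore", "piscivore")])
  p <- to_simplex(m, zero_adjust = zero_adjust)
  covs <- site_covariates(service_table, sites)
  out <- tibble::tibble(
    site_id = wide$site_id,
    prop_herbivore = p[, 1],
    prop_mobile_invertivore = p[, 2],
    prop_piscivore = p[, 3],
    service = service
  )
  dplyr::inner_join(out, covs, by = "site_id")
}
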