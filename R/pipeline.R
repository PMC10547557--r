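#' Run the survey-to-services pipeline
#'
#' Convenience wrapper chaining [ingest_survey()], [transect_services()] and
#' [site_services()]; the pieces remain available individually.
#'
#' @inheritParams ingest_survey
#' @inheritParams transect_services
#' @return List with `site_services` (site x trophic group service table),
#'   `transect_services`, `covariates` (site-level model covariates),
#'   `exclusion_log`, `traits`, and `sites`.
#' @export
pipeline_services <- function(survey, sites, traits, edible_fraction = 0.87,
                              basis = c("annual", "daily"),
                              min_length_cm = 5) {
  basis <- match.arg(basis)
  ing <- ingest_survey(survey, sites, traits, min_length_cm = min_length_cm)
  tr <- transect_services(
    ing$observations, ing$traits,
    edible_fraction = edible_fraction, basis = basis
  )
  st <- site_services(tr)
  list(
    site_services = st,
    transect_services = tr,
    covariates = site_covariates(st, ing$sites),
    exclusion_log = ing$exclusion_log,
    traits = ing$traits,
    sites = ing$sites
  )
}
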