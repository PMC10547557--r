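#' Reference nutrient intakes
#'
#' Daily recommended nutrient intakes (RNI) used to express tissue
#' concentrations as percent contributions of a fillet portion. The default
#' table ships with the package (`inst/extdata/rni_women_18_65.csv`) and holds
#' intakes for adult women aged 18-65 drawn from WHO/FAO vitamin and mineral
#' requirement reports and the EFSA adequate intake for long-chain omega-3
#' fatty acids. These are configuration, not constants of the method: replace
#' the file (or pass your own table) to target a different reference
#' population. The provenance label travels with the table so downstream
#' outputs can record which reference was used.
#'
#' @param path Optional path to a replacement CSV (`nutrient,intake,unit`
#'   columns) or YAML file (nutrient: intake mapping).
#' @param population Label describing the reference population; stored as an
#'   attribute on the returned table.
#'
#' @return A tibble with columns `nutrient`, `intake`, `unit`, carrying a
#'   `population` attribute. Units match [nutrient_units()].
#' @export
#' @examples
#' default_rni()
default_rni <- function(path = NULL, population = "adult women 18-65") {
  if (is.null(path)) {
    path <- system.file("extdata", "rni_women_18_65.csv", package = "reefnutro")
  }
  rni <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML RNI table requires the 'yaml' package", call. = FALSE)
    }
    vals <- yaml::read_yaml(path)
    tibble::tibble(
      nutrient = names(vals),
      intake = vapply(vals, as.numeric, numeric(1)),
      unit = unname(nutrient_units()[names(vals)])
    )
  } else {
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  validate_rni(rni)
  attr(rni, "population") <- population
  rni
}

validate_rni <- function(rni) {
  need <- c("nutrient", "intake")
  if (!all(need %in% names(rni))) {
    stop("RNI table must have columns 'nutrient' and 'intake'", call. = FALSE)
  }
  if (any(!is.finite(rni$intake)) || any(rni$intake <= 0)) {
    stop("all RNI intakes must be positive and finite", call. = FALSE)
  }
  invisible(rni)
}

# look up intakes for the six tracked nutrients, erroring on any gap
rni_vector <- function(rni) {
  validate_rni(rni)
  missing <- setdiff(names(nutrient_units()), rni$nutrient)
  if (length(missing) > 0) {
    stop(
      "RNI table is missing nutrient(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  setNames(
    rni$intake[match(names(nutrient_units()), rni$nutrient)],
    names(nutrient_units())
  )
}
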