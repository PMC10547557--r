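#' Read a long-format UVC survey table
#'
#' One row per observation: a species seen on a transect at a site, with a
#' body length (point estimate or the lower edge of a length bin) and a count.
#'
#' @param path CSV with columns `site_id, transect_id, species_id, length_cm,
#'   length_is_binned, count`, plus transect dimensions `width_m, length_m`
#'   (constant within a transect).
#' @return A tibble of observations.
#' @export
read_survey <- function(path) {
  obs <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_survey(obs)
}

validate_survey <- function(obs) {
  need <- c(
    "site_id", "transect_id", "species_id", "length_cm",
    "length_is_binned", "count", "width_m", "length_m"
  )
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0) {
    stop("survey table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  obs$length_is_binned <- as.logical(obs$length_is_binned)
  if (any(obs$length_cm <= 0) || any(!is.finite(obs$length_cm))) {
    stop("all lengths must be positive", call. = FALSE)
  }
  if (any(obs$count < 1) || any(obs$count != round(obs$count))) {
    stop("counts must be integers >= 1", call. = FALSE)
  }
  if (any(obs$width_m <= 0) || any(obs$length_m <= 0)) {
    stop("transect dimensions must be positive", call. = FALSE)
  }
  tibble::as_tibble(obs)
}

#' Read a site table
#'
#' @param path CSV with columns `site_id, country, management, depth_m,
#'   coral_pct, turf_pct, macroalgae_pct, rubble_pct, bare_pct`.
#' @return A tibble of sites.
#' @export
read_sites <- function(path) {
  sites <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_sites(sites)
}

validate_sites <- function(sites) {
  need <- c(
    "site_id", "country", "management", "depth_m",
    "coral_pct", "turf_pct", "macroalgae_pct", "rubble_pct", "bare_pct"
  )
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    stop("site table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad_mgmt <- setdiff(unique(sites$management), management_levels())
  if (length(bad_mgmt) > 0) {
    stop("unknown management label(s): ", paste(bad_mgmt, collapse = ", "),
      call. = FALSE
    )
  }
  covers <- as.matrix(sites[, c(
    "coral_pct", "turf_pct", "macroalgae_pct",
    "rubble_pct", "bare_pct"
  )])
  if (any(covers < 0) || any(covers > 100)) {
    stop("benthic covers must lie in [0, 100]", call. = FALSE)
  }
  if (any(rowSums(covers) > 100 + 1e-8)) {
    stop("benthic covers sum to more than 100% at some sites", call. = FALSE)
  }
  if (any(sites$depth_m <= 0)) stop("depth must be positive", call. = FALSE)
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id in site table", call. = FALSE)
  }
  tibble::as_tibble(sites)
}

#' Resolve recorded lengths to point estimates
#'
#' Surveys in some countries record lengths in 5 cm bins up to 40 cm and to
#' the nearest cm above that. Binned records are mapped to the bin midpoint
#' (lower edge + half the bin width); point records, and binned records whose
#' lower edge exceeds the binning cut-off, pass through unchanged. The
#' bin-to-length rule is pluggable: supply `rule` to use e.g. the lower edge
#' or a geometric midpoint instead.
#'
#' @param length_cm Recorded length (point value or bin lower edge).
#' @param is_binned Logical; whether the record is a bin lower edge.
#' @param bin_width Bin width in cm (default 5).
#' @param bin_cutoff Lengths above this are recorded to the nearest cm even in
#'   binned surveys (default 40).
#' @param rule Function of `(lower, width)` returning the resolved length for
#'   binned records; default is the arithmetic midpoint.
#'
#' @return Numeric vector of resolved lengths (cm).
#' @export
#' @examples
#' resolve_length(c(23, 10, 45), c(FALSE, TRUE, TRUE))
resolve_length <- function(length_cm, is_binned, bin_width = 5,
                           bin_cutoff = 40,
                           rule = function(lower, width) lower + width / 2) {
  stopifnot(bin_width > 0)
  binned <- is_binned & length_cm <= bin_cutoff
  out <- length_cm
  out[binned] <- rule(length_cm[binned], bin_width)
  out
}

#' Allometric length-to-mass conversion
#'
#' Standard power-law conversion `W = a * L^b` with published length-weight
#' coefficients (`a` in g cm^-b, `b` dimensionless).
#'
#' @param length_cm Body length in cm.
#' @param lw_a,lw_b Length-weight coefficients.
#' @return Body mass in grams.
#' @export
#' @examples
#' length_to_mass(10, 0.01, 3) # 10 g
length_to_mass <- function(length_cm, lw_a, lw_b) {
  w <- lw_a * length_cm^lw_b
  if (any(!is.finite(w))) {
    stop("non-finite mass from length-weight conversion; check lw_a/lw_b",
      call. = FALSE
    )
  }
  w
}

#' Convert a per-transect quantity to a per-hectare rate
#'
#' @param value Quantity measured on the transect.
#' @param area_m2 Transect area in square metres.
#' @return The quantity per hectare.
#' @export
#' @examples
#' to_per_hectare(0.1, 250) # 4 per ha
to_per_hectare <- function(value, area_m2) {
  stopifnot(all(area_m2 > 0))
  value * 10000 / area_m2
}

#' Apply fishery-target exclusion filters
#'
#' Removes observations that are not fishery targets or cannot be surveyed
#' reliably: fish shorter than 5 cm (resolved length), damselfish species,
#' and highly mobile elasmobranchs. Species missing from the trait table
#' abort ingest (they would otherwise be silently dropped from production
#' estimates).
#'
#' @param obs Survey observations (see [read_survey()]); a `length_resolved`
#'   column is used if present, otherwise lengths are resolved with defaults.
#' @param traits Validated trait table.
#' @param min_length_cm Minimum retained length (default 5).
#'
#' @return A list with `observations` (the retained rows) and `log`, a named
#'   integer vector counting rows removed per rule
#'   (`small`, `damselfish`, `elasmobranch`).
#' @export
apply_exclusion_filters <- function(obs, traits, min_length_cm = 5) {
  unknown <- setdiff(unique(obs$species_id), traits$species_id)
  if (length(unknown) > 0) {
    stop(
      "species in survey but absent from trait table: ",
      paste(head(unknown, 10), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(obs) == 0) {
    return(list(
      observations = obs,
      log = c(small = 0L, damselfish = 0L, elasmobranch = 0L)
    ))
  }
  len <- if ("length_resolved" %in% names(obs)) {
    obs$length_resolved
  } else {
    resolve_length(obs$length_cm, obs$length_is_binned)
  }
  idx <- match(obs$species_id, traits$species_id)
  small <- len < min_length_cm
  dams <- !small & traits$is_damselfish[idx]
  elas <- !small & !dams & traits$is_elasmobranch[idx]
  drop <- small | dams | elas
  list(
    observations = obs[!drop, , drop = FALSE],
    log = c(
      small = sum(small), damselfish = sum(dams), elasmobranch = sum(elas)
    )
  )
}

#' Ingest and clean a UVC survey
#'
#' Validates the survey, site, and trait tables; resolves binned lengths;
#' applies the exclusion filters; converts lengths to mass; and attaches
#' transect area and species traits. This is the entry point of the pipeline.
#'
#' @param survey Survey observations (tibble or CSV path).
#' @param sites Site table (tibble or CSV path).
#' @param traits Trait table (tibble or CSV path).
#' @param bin_width,bin_cutoff,rule Passed to [resolve_length()].
#' @param min_length_cm Passed to [apply_exclusion_filters()].
#'
#' @return A list with `observations` (cleaned, with `length_resolved`,
#'   `mass_g`, `area_m2`, `trophic_group`), `sites`, `traits`, and
#'   `exclusion_log`.
#' @export
ingest_survey <- function(survey, sites, traits, bin_width = 5,
                          bin_cutoff = 40,
                          rule = function(lower, width) lower + width / 2,
                          min_length_cm = 5) {
  if (is.character(survey)) survey <- read_survey(survey) else survey <- validate_survey(survey)
  if (is.character(sites)) sites <- read_sites(sites) else sites <- validate_sites(sites)
  if (is.character(traits)) traits <- read_traits(traits) else traits <- validate_traits(traits)

  unknown_sites <- setdiff(unique(survey$site_id), sites$site_id)
  if (length(unknown_sites) > 0) {
    stop(
      "survey references site_id(s) absent from the site table: ",
      paste(head(unknown_sites, 10), collapse = ", "),
      call. = FALSE
    )
  }

  survey$length_resolved <- resolve_length(
    survey$length_cm, survey$length_is_binned,
    bin_width = bin_width, bin_cutoff = bin_cutoff, rule = rule
  )
  filtered <- apply_exclusion_filters(survey, traits,
    min_length_cm = min_length_cm
  )
  obs <- filtered$observations
  obs$area_m2 <- obs$width_m * obs$length_m
  idx <- match(obs$species_id, traits$species_id)
  obs$trophic_group <- traits$trophic_group[idx]
  obs$mass_g <- length_to_mass(
    obs$length_resolved, traits$lw_a[idx], traits$lw_b[idx]
  )
  list(
    observations = obs, sites = sites, traits = traits,
    exclusion_log = filtered$log
  )
}
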