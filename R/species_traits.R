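#' Read and validate a species trait table
#'
#' The trait table carries, per species, the biology needed to turn survey
#' observations into production estimates (maximum length, standardized von
#' Bertalanffy growth coefficient `k_max`, length-weight coefficients, trophic
#' group) plus six muscle-tissue nutrient concentrations per 100 g and flags
#' for non-target taxa (damselfishes, elasmobranchs).
#'
#' @param path CSV path with columns `species_id, trophic_group, l_max_cm,
#'   k_max, lw_a, lw_b, ca_mg, fe_mg, zn_mg, se_ug, vita_ug, om3_g,
#'   is_damselfish, is_elasmobranch`.
#' @param aliases Optional named character vector mapping non-canonical
#'   trophic-group labels to canonical ones, e.g.
#'   `c("herbivore (scraper)" = "herbivore_scraper_detritivore")`.
#' @param lw_b_bounds Sanity bounds for the length-weight exponent.
#'
#' @return A validated tibble of species traits.
#' @export
read_traits <- function(path, aliases = NULL, lw_b_bounds = c(2, 4)) {
  traits <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_traits(traits, aliases = aliases, lw_b_bounds = lw_b_bounds)
}

#' Validate a species trait table
#'
#' Applies the alias map to trophic-group labels, rejects unknown labels, and
#' enforces positivity/range invariants on growth and length-weight
#' parameters and nutrient concentrations.
#'
#' @inheritParams read_traits
#' @param traits A data frame shaped like the trait CSV (see [read_traits()]).
#' @param k_max_range Admissible range of the standardized growth coefficient;
#'   the default spans published reef-fish values.
#' @return The trait table as a tibble, with canonical trophic-group labels
#'   and logical flag columns.
#' @export
validate_traits <- function(traits, aliases = NULL, lw_b_bounds = c(2, 4),
                            k_max_range = c(0.011, 16.43)) {
  need <- c(
    "species_id", "trophic_group", "l_max_cm", "k_max", "lw_a", "lw_b",
    unname(nutrient_cols()), "is_damselfish", "is_elasmobranch"
  )
  missing <- setdiff(need, names(traits))
  if (length(missing) > 0) {
    stop("trait table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  traits <- tibble::as_tibble(traits)
  tg <- as.character(traits$trophic_group)
  if (!is.null(aliases)) {
    hit <- tg %in% names(aliases)
    tg[hit] <- unname(aliases[tg[hit]])
  }
  unknown <- setdiff(unique(tg), trophic_groups())
  if (length(unknown) > 0) {
    stop(
      "unknown trophic group label(s): ", paste(unknown, collapse = ", "),
      "; extend the alias map or correct the table",
      call. = FALSE
    )
  }
  traits$trophic_group <- tg
  traits$is_damselfish <- as.logical(traits$is_damselfish)
  traits$is_elasmobranch <- as.logical(traits$is_elasmobranch)

  stopifnot_all <- function(ok, what) {
    if (!all(ok, na.rm = FALSE)) {
      bad <- traits$species_id[!ok | is.na(ok)]
      stop(
        "invalid ", what, " for species: ",
        paste(head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  stopifnot_all(is.finite(traits$l_max_cm) & traits$l_max_cm > 0, "l_max_cm")
  stopifnot_all(
    is.finite(traits$k_max) & traits$k_max >= k_max_range[1] &
      traits$k_max <= k_max_range[2],
    "k_max (outside admissible range)"
  )
  stopifnot_all(is.finite(traits$lw_a) & traits$lw_a > 0, "lw_a")
  stopifnot_all(
    is.finite(traits$lw_b) & traits$lw_b >= lw_b_bounds[1] &
      traits$lw_b <= lw_b_bounds[2],
    "lw_b (outside sanity bounds)"
  )
  for (col in nutrient_cols()) {
    stopifnot_all(is.finite(traits[[col]]) & traits[[col]] >= 0, col)
  }
  if (anyDuplicated(traits$species_id)) {
    stop("duplicated species_id in trait table", call. = FALSE)
  }
  traits
}

#' Nutrient density of a 100 g fillet portion
#'
#' Sums, over six nutrients, the percent contribution of one portion of raw
#' muscle tissue to the recommended daily intake, capping each nutrient's
#' contribution (default 100%) before summation so that a single highly
#' concentrated nutrient (typically selenium) cannot dominate the score.
#' The result lies in [0, 6 x cap].
#'
#' @param traits Trait table (see [read_traits()]) or any data frame with the
#'   six nutrient concentration columns; a single row works.
#' @param rni Reference-intake table from [default_rni()].
#' @param portion Portion size in grams (default 100).
#' @param cap Per-nutrient cap in percent (default 100). Use `Inf` for the
#'   uncapped linear sum.
#'
#' @return Numeric vector of nutrient densities (percent), one per row.
#' @export
#' @examples
#' tr <- data.frame(
#'   ca_mg = 500, fe_mg = 2, zn_mg = 2.45, se_ug = 52,
#'   vita_ug = 50, om3_g = 0.55
#' )
#' nutrient_density(tr, default_rni())
nutrient_density <- function(traits, rni = default_rni(), portion = 100,
                             cap = 100) {
  stopifnot(portion > 0, cap > 0)
  intakes <- rni_vector(rni)
  cols <- nutrient_cols()
  dens <- rep(0, nrow(as.data.frame(traits)))
  for (n in names(cols)) {
    conc <- traits[[cols[[n]]]]
    if (any(!is.finite(conc)) || any(conc < 0)) {
      stop("non-finite or negative concentration in ", cols[[n]], call. = FALSE)
    }
    contrib <- 100 * conc * (portion / 100) / intakes[[n]]
    dens <- dens + pmin(cap, contrib)
  }
  unname(dens)
}

#' Species-level association between growth potential and nutrition
#'
#' Correlates nutrient density, and each of the six tissue concentrations,
#' with the growth coefficient `k_max` on a log10 scale (growth coefficients
#' span three orders of magnitude across reef fishes, so the log scale is the
#' natural axis).
#'
#' @inheritParams nutrient_density
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_k Correlate against `log10(k_max)` (default) rather than raw
#'   `k_max`.
#'
#' @return A tibble with columns `variable` (`nutrient_density` plus the six
#'   nutrients), `r`, and `n`.
#' @export
growth_nutrient_association <- function(traits, rni = default_rni(),
                                        method = c("pearson", "spearman"),
                                        log_k = TRUE) {
  method <- match.arg(method)
  cols <- nutrient_cols()
  keep <- complete.cases(traits[, c("k_max", unname(cols))])
  traits <- traits[keep, ]
  if (nrow(traits) < 3) {
    stop("need at least 3 species with complete traits", call. = FALSE)
  }
  k <- if (log_k) log10(traits$k_max) else traits$k_max
  if (var(k) == 0) {
    stop("k_max has zero variance; correlation undefined", call. = FALSE)
  }
  dens <- nutrient_density(traits, rni)
  if (var(dens) == 0) {
    stop("zero variance in nutrient density; correlation undefined",
      call. = FALSE
    )
  }
  vars <- c(
    nutrient_density = list(dens),
    lapply(cols, function(cl) traits[[cl]])
  )
  # a constant individual nutrient yields NA rather than an error: the
  # aggregate density correlation is still well defined
  r <- vapply(vars, function(v) {
    if (var(v) == 0) NA_real_ else cor(v, k, method = method)
  }, numeric(1))
  tibble::tibble(variable = names(vars), r = unname(r), n = nrow(traits))
}
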