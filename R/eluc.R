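#' Land-use-change emission subcomponents
#'
#' Bookkeeping models decompose net land-use-change emissions (E_LUC) into
#' five subcomponents: total deforestation, total forest (re-)growth, gross
#' sources from wood harvest, gross sinks from wood harvest, and other
#' transitions. The long layout used throughout this module is one row per
#' (model, density_mode, component, year) with `value` in GtC/yr; regrowth
#' and harvest sinks are stored as negative fluxes so the net E_LUC is the
#' plain sum over components.
#'
#' @name eluc-components
#' @keywords internal
NULL

eluc_component_names <- c(
  "deforestation", "regrowth", "harvest_src", "harvest_snk", "other"
)

check_eluc_components <- function(x) {
  x <- as_tibble(x)
  need <- c("model", "density_mode", "component", "year", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(x$component), eluc_component_names)
  if (length(bad)) {
    abort(paste0("Unknown E_LUC component(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(x$density_mode %in% c("static", "transient"))) {
    abort("`density_mode` must be \"static\" or \"transient\".")
  }
  x
}

#' Net E_LUC from subcomponents
#'
#' @param components long subcomponent tibble (see [eluc-components]).
#' @return Tibble with one row per (model, density_mode, year) and the net
#'   `value` = sum of the five subcomponents.
#' @export
eluc_net <- function(components) {
  components <- check_eluc_components(components)
  components |>
    group_by(.data$model, .data$density_mode, .data$year) |>
    summarise(value = sum(.data$value), .groups = "drop")
}

#' Transient-to-static emission ratios from reference model pairs
#'
#' Reference bookkeeping models that provide E_LUC under both static and
#' transient carbon densities define, per subcomponent and year, the ratio
#' transient/static. Ratios are formed per reference model and then averaged
#' across models; they are later applied to models that only ran with static
#' densities. Where a static subcomponent flux is essentially zero
#' (|flux| < `zero_tol`) the ratio carries no information and falls back
#' to 1 (no scaling).
#'
#' @param reference long subcomponent tibble containing both density modes
#'   for each reference model.
#' @param zero_tol static fluxes smaller than this (GtC/yr, absolute) are
#'   treated as zero for ratio formation.
#' @return Tibble with one row per (component, year): `ratio` averaged over
#'   reference models and `n_models` entering the average.
#' @export
eluc_component_ratios <- function(reference, zero_tol = 1e-6) {
  reference <- check_eluc_components(reference)
  wide <- reference |>
    tidyr::pivot_wider(
      id_cols = c("model", "component", "year"),
      names_from = "density_mode", values_from = "value"
    )
  if (!all(c("static", "transient") %in% names(wide))) {
    abort("Reference models must provide both static and transient runs.")
  }
  if (any(is.na(wide$static)) || any(is.na(wide$transient))) {
    abort("Static and transient runs must cover the same component-years.")
  }
  wide |>
    mutate(ratio = ifelse(
      abs(.data$static) < zero_tol, 1, .data$transient / .data$static
    )) |>
    group_by(.data$component, .data$year) |>
    summarise(
      ratio = mean(.data$ratio), n_models = dplyr::n(), .groups = "drop"
    )
}

#' Apply transient-density ratios to a static-density model
#'
#' Each subcomponent of the target model (run with static densities) is
#' multiplied by its averaged transient/static ratio for that year, and the
#' rescaled subcomponents are summed into the net E_LUC under transient
#' densities.
#'
#' @param target long subcomponent tibble for one or more models, all with
#'   `density_mode == "static"`.
#' @param ratios per-(component, year) ratios from [eluc_component_ratios()].
#' @param fallback_ratio if `NULL` (default) a component-year missing from
#'   `ratios` is an error; otherwise that value (typically 1) is used.
#' @return Tibble with one row per (model, year): net E_LUC under transient
#'   densities.
#' @export
eluc_apply_scaling <- function(target, ratios, fallback_ratio = NULL) {
  target <- check_eluc_components(target)
  if (any(target$density_mode != "static")) {
    abort("`target` must contain static-density runs only.")
  }
  joined <- left_join(
    target, ratios[, c("component", "year", "ratio")],
    by = c("component", "year")
  )
  if (any(is.na(joined$ratio))) {
    if (is.null(fallback_ratio)) {
      abort("Missing ratio for some component-years; supply `fallback_ratio` to allow.")
    }
    joined$ratio[is.na(joined$ratio)] <- fallback_ratio
  }
  joined |>
    group_by(.data$model, .data$year) |>
    summarise(value = sum(.data$value * .data$ratio), .groups = "drop")
}

# DerSimonian-Laird between-model variance for one year of delta-L estimates.
# y: per-model estimates, v: per-model within variances (sigma^2).
dl_tau2 <- function(y, v) {
  k <- length(y)
  if (k < 2L) return(0)
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Combine per-model transient-density corrections (delta-L)
#'
#' The delta-L correction is the difference (transient-density E_LUC minus
#' static-density E_LUC), available per bookkeeping model. The ensemble
#' annual value is the unweighted cross-model mean; its 1-sigma combines the
#' between-model variance (DerSimonian-Laird tau^2, computed from the
#' per-model estimates and their within-model sigmas) with the mean
#' within-model variance: sigma = sqrt(tau^2 + mean(sigma_i^2)). This keeps
#' the reported uncertainty at least as large as either source alone. The
#' cumulative correction is the running sum of annual values since
#' `base_year`.
#'
#' @param deltas tibble with one row per (model, year): columns `model`,
#'   `year`, `value` (GtC/yr) and `sigma` (per-model 1-sigma; required for
#'   the random-effects weights).
#' @param base_year first year of the cumulative sum (default: first covered
#'   year).
#' @return A list of class `"delta_l_result"` with elements `annual` (tibble
#'   `year`, `value`, `sigma`, `tau2`, `cumulative` in GtC), `members` (the
#'   input), `n_models`.
#' @export
delta_L <- function(deltas, base_year = NULL) {
  deltas <- as_tibble(deltas)
  need <- c("model", "year", "value", "sigma")
  miss <- setdiff(need, names(deltas))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  n_models <- length(unique(deltas$model))
  if (n_models < 2L) {
    warn("Single bookkeeping model: falling back to its own sigma (no between-model term).")
  }
  annual <- deltas |>
    group_by(.data$year) |>
    summarise(
      tau2 = dl_tau2(.data$value, .data$sigma^2),
      within_var = mean(.data$sigma^2),
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    mutate(sigma = sqrt(.data$tau2 + .data$within_var)) |>
    select("year", "value", "sigma", "tau2") |>
    arrange(.data$year)
  base_year <- base_year %||% min(annual$year)
  annual <- annual |>
    mutate(cumulative = cumsum(ifelse(.data$year >= base_year, .data$value, 0)))
  structure(
    list(annual = annual, members = deltas, n_models = n_models),
    class = "delta_l_result"
  )
}

#' @export
print.delta_l_result <- function(x, ...) {
  last <- x$annual[nrow(x$annual), ]
  cat(sprintf(
    "delta-L correction from %d bookkeeping models, %d-%d\n  final-year value %s GtC/yr, cumulative %s GtC\n",
    x$n_models, min(x$annual$year), max(x$annual$year),
    fmt_pm(last$value, last$sigma, 2), fmt_flux(last$cumulative, 1)
  ))
  invisible(x)
}

#' @rdname delta_L
#' @param x a `"delta_l_result"`.
#' @param ... unused.
#' @export
tidy.delta_l_result <- function(x, ...) x$annual

#' @rdname delta_L
#' @export
glance.delta_l_result <- function(x, ...) {
  tibble(
    n_models = x$n_models,
    n_years = nrow(x$annual),
    cumulative_gtc = x$annual$cumulative[nrow(x$annual)],
    mean_tau2 = mean(x$annual$tau2)
  )
}

#' Apply the delta-L correction to an E_LUC series
#'
#' Adds the annual delta-L correction to the stored E_LUC values and folds
#' the correction sigma into the series sigma in quadrature.
#'
#' @param e_luc flux-series tibble for E_LUC.
#' @param dl a `"delta_l_result"` from [delta_L()].
#' @return Corrected flux-series tibble (years restricted to the overlap).
#' @export
apply_delta_L <- function(e_luc, dl) {
  e_luc <- check_flux_series(e_luc)
  ann <- dl$annual
  joined <- inner_join(
    e_luc, rename(ann, dl_value = "value", dl_sigma = "sigma"),
    by = "year"
  )
  tibble(
    component = joined$component,
    year = joined$year,
    value = joined$value + joined$dl_value,
    sigma = sqrt(joined$sigma^2 + joined$dl_sigma^2)
  )
}
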