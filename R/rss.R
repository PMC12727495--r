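#' PFT grids for the replaced-sinks-and-sources correction
#'
#' Vegetation-model output enters the RSS correction in two long tibbles:
#'
#' * a cover grid, one row per (cell, pft, year) with `cover_fraction` in
#'   `[0, 1]`; per cell-year the fractions sum to at most 1 (the residual is
#'   bare ground, which carries no flux);
#' * a flux grid, one row per (cell, pft, year) with `nbp_density`, the net
#'   biome production per unit PFT area (sink positive), so that flux =
#'   density x fraction x cell area.
#'
#' Cell areas live in a separate tibble (`cell`, `area`); areas are explicit
#' inputs, no spherical geometry is computed.
#'
#' @name pft-grids
#' @keywords internal
NULL

check_pft_cover <- function(x) {
  x <- as_tibble(x)
  need <- c("cell", "pft", "year", "cover_fraction")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(x$cover_fraction < 0)) abort("Cover fractions must be >= 0.")
  tot <- x |>
    group_by(.data$cell, .data$year) |>
    summarise(total = sum(.data$cover_fraction), .groups = "drop")
  if (any(tot$total > 1 + 1e-9)) {
    abort("Cover fractions exceed 1 within a cell-year.")
  }
  x
}

check_pft_flux <- function(x) {
  x <- as_tibble(x)
  need <- c("cell", "pft", "year", "nbp_density")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(x$nbp_density))) abort("NBP densities must be finite.")
  x
}

#' Reconstruct the land sink under actual (transient) land cover
#'
#' The land sink in budget assessments comes from simulations run with
#' pre-industrial land cover held fixed (S2). Because forest area has
#' declined historically and forests take up more carbon than the systems
#' that replaced them, that setup overestimates the sink. This function
#' recombines the S2 per-PFT flux densities with the transient cover
#' fractions of the land-use run (S3):
#' S_corrected(t) = sum over cells and PFTs of
#' density_S2(cell, pft, t) x fraction_S3(cell, pft, t) x area(cell),
#' i.e. the sink the S2-simulated land system would have shown under the
#' actual, changing land cover (still excluding direct land-use fluxes).
#'
#' PFTs present in the cover grid but lacking an S2 flux density (newly
#' created anthropogenic types) are handled per `missing_pft`: `"proxy"`
#' substitutes the cell's cover-weighted mean S2 density over the PFTs that
#' do have one; `"exclude"` drops that area from the sum.
#'
#' @param nbp_s2 flux grid (see [pft-grids]).
#' @param cover cover grid to recombine with (S3 fractions for the
#'   correction; passing the S2 fractions reproduces the S2 global sum).
#' @param areas tibble (`cell`, `area`).
#' @param missing_pft `"proxy"` (default) or `"exclude"`.
#' @param component label for the output series.
#' @return Flux-series tibble of the global annual sink (GtC/yr).
#' @export
reconstruct_sland <- function(nbp_s2, cover, areas,
                              missing_pft = c("proxy", "exclude"),
                              component = "S_LAND") {
  missing_pft <- match.arg(missing_pft)
  nbp_s2 <- check_pft_flux(nbp_s2)
  cover <- check_pft_cover(cover)
  joined <- left_join(cover, nbp_s2, by = c("cell", "pft", "year"))
  if (any(is.na(joined$nbp_density))) {
    if (missing_pft == "exclude") {
      joined <- filter(joined, !is.na(.data$nbp_density))
    } else {
      proxy <- joined |>
        filter(!is.na(.data$nbp_density)) |>
        group_by(.data$cell, .data$year) |>
        summarise(
          proxy_density = sum(.data$nbp_density * .data$cover_fraction) /
            sum(.data$cover_fraction),
          .groups = "drop"
        )
      joined <- joined |>
        left_join(proxy, by = c("cell", "year")) |>
        mutate(nbp_density = dplyr::coalesce(
          .data$nbp_density, .data$proxy_density, 0
        )) |>
        select(-"proxy_density")
    }
  }
  joined <- left_join(joined, areas, by = "cell")
  if (any(is.na(joined$area))) abort("Every cell needs an `area` entry.")
  out <- joined |>
    group_by(.data$year) |>
    summarise(
      value = sum(.data$nbp_density * .data$cover_fraction * .data$area),
      .groups = "drop"
    ) |>
    arrange(.data$year)
  flux_series(component, out$year, out$value)
}

#' Replaced-sinks-and-sources bias of one model
#'
#' Difference between the land sink as simulated under fixed pre-industrial
#' cover (S2) and the land-cover-corrected reconstruction; positive when the
#' S2 setup overestimates the sink.
#'
#' @param sland_s2 flux-series tibble, the S2 global land sink.
#' @param sland_corrected flux-series tibble from [reconstruct_sland()].
#' @return Flux-series tibble with `component = "RSS"`.
#' @export
rss_bias <- function(sland_s2, sland_corrected) {
  sland_s2 <- check_flux_series(sland_s2)
  sland_corrected <- check_flux_series(sland_corrected)
  check_aligned(sland_s2, sland_corrected, c("S2 sink", "corrected sink"))
  flux_series("RSS", sland_s2$year, sland_s2$value - sland_corrected$value)
}

#' Aggregate per-model RSS biases into the ensemble correction
#'
#' Unweighted cross-model mean per year; uncertainty is the inter-model
#' sample (n-1) standard deviation; cumulative bias is the running sum since
#' `base_year`.
#'
#' @param members tibble with one row per (model, year): columns `model`,
#'   `year`, `value` (bias in GtC/yr).
#' @param base_year first year of the cumulative sum (default: first
#'   covered year).
#' @return A list of class `"rss_result"`: `annual` (tibble `year`, `value`,
#'   `sigma`, `cumulative`), `members`, `n_models`.
#' @export
aggregate_rss <- function(members, base_year = NULL) {
  members <- as_tibble(members)
  need <- c("model", "year", "value")
  miss <- setdiff(need, names(members))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  n_models <- length(unique(members$model))
  annual <- members |>
    group_by(.data$year) |>
    summarise(
      sigma = if (dplyr::n() >= 2) sd(.data$value) else NA_real_,
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    select("year", "value", "sigma") |>
    arrange(.data$year)
  base_year <- base_year %||% min(annual$year)
  annual <- mutate(
    annual,
    cumulative = cumsum(ifelse(.data$year >= base_year, .data$value, 0))
  )
  structure(
    list(annual = annual, members = members, n_models = n_models),
    class = "rss_result"
  )
}

#' @export
print.rss_result <- function(x, ...) {
  last <- x$annual[nrow(x$annual), ]
  cat(sprintf(
    "RSS bias from %d models, %d-%d\n  final-year bias %s GtC/yr, cumulative %s GtC\n",
    x$n_models, min(x$annual$year), max(x$annual$year),
    fmt_pm(last$value, last$sigma, 2), fmt_flux(last$cumulative, 1)
  ))
  invisible(x)
}

#' @rdname aggregate_rss
#' @param x an `"rss_result"`.
#' @param ... unused.
#' @export
tidy.rss_result <- function(x, ...) x$annual

#' @rdname aggregate_rss
#' @export
glance.rss_result <- function(x, ...) {
  tibble(
    n_models = x$n_models,
    n_years = nrow(x$annual),
    cumulative_gtc = x$annual$cumulative[nrow(x$annual)]
  )
}

#' Apply the RSS correction to a land-sink series
#'
#' Subtracts the ensemble-mean bias from the stored S_LAND values (the S2
#' setup overestimates the sink, so the correction reduces it) and folds the
#' inter-model sigma into the series sigma in quadrature.
#'
#' @param s_land flux-series tibble for S_LAND.
#' @param rss an `"rss_result"` from [aggregate_rss()].
#' @return Corrected flux-series tibble (years restricted to the overlap).
#' @export
apply_rss <- function(s_land, rss) {
  s_land <- check_flux_series(s_land)
  ann <- rss$annual
  joined <- inner_join(
    s_land, rename(ann, rss_value = "value", rss_sigma = "sigma"),
    by = "year"
  )
  tibble(
    component = joined$component,
    year = joined$year,
    value = joined$value - joined$rss_value,
    sigma = sqrt(joined$sigma^2 + dplyr::coalesce(joined$rss_sigma, 0)^2)
  )
}
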