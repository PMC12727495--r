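#' Annual flux series
#'
#' The package's atomic data structure is a tibble of annual fluxes with one
#' row per year: columns `component` (a label such as `"E_FOS"`, `"E_LUC"`,
#' `"S_LAND"`, `"S_OCEAN"`, `"G_ATM"`, `"B_IM"` or any free tag), `year`
#' (calendar years CE, strictly ascending and contiguous), `value` (GtC/yr;
#' sinks positive for the land and ocean sinks, sources positive for the
#' emission terms, atmospheric growth positive) and `sigma` (per-year 1-sigma
#' uncertainty in GtC/yr, `NA` when unknown -- never silently zero).
#'
#' @param component single label for the flux component.
#' @param year integer years, strictly ascending and contiguous.
#' @param value annual fluxes in GtC/yr, same length as `year`.
#' @param sigma optional per-year 1-sigma uncertainties (GtC/yr), recycled if
#'   scalar; `NULL` means unknown and is stored as `NA`.
#'
#' @return A tibble with columns `component`, `year`, `value`, `sigma`.
#' @examples
#' flux_series("E_FOS", 2014:2023, rep(9.7, 10), sigma = 0.5)
#' @export
flux_series <- function(component, year, value, sigma = NULL) {
  stopifnot(is.character(component), length(component) == 1L)
  year <- as.integer(year)
  if (length(value) == 1L) value <- rep(as.numeric(value), length(year))
  if (length(value) != length(year)) {
    abort("`value` must be scalar or have one entry per `year`.")
  }
  if (is.null(sigma)) {
    sigma <- rep(NA_real_, length(year))
  } else {
    if (length(sigma) == 1L) sigma <- rep(as.numeric(sigma), length(year))
    if (length(sigma) != length(year)) {
      abort("`sigma` must be scalar or one entry per `year`.")
    }
    if (any(sigma < 0, na.rm = TRUE)) abort("`sigma` must be non-negative.")
  }
  out <- tibble(
    component = component, year = year,
    value = as.numeric(value), sigma = as.numeric(sigma)
  )
  check_flux_series(out)
}

#' Validate a flux-series tibble
#'
#' Checks the invariants of the annual-series layout (see [flux_series()]):
#' required columns, strictly ascending contiguous years, non-negative sigma.
#' Returns its input (as a tibble) so it can sit inside a pipe.
#'
#' @param x a data frame with columns `component`, `year`, `value` and
#'   optionally `sigma`.
#' @return `x` as a tibble, with a `sigma` column added (all `NA`) if absent.
#' @export
check_flux_series <- function(x) {
  x <- as_tibble(x)
  need <- c("component", "year", "value")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"sigma" %in% names(x)) x$sigma <- NA_real_
  for (comp in unique(x$component)) {
    yrs <- x$year[x$component == comp]
    if (length(yrs) > 1L && !all(diff(yrs) == 1L)) {
      abort(paste0("Years for ", comp, " must be contiguous and ascending."))
    }
  }
  if (any(x$sigma < 0, na.rm = TRUE)) abort("`sigma` must be non-negative.")
  x
}

# Internal: assert two series cover identical year axes.
check_aligned <- function(a, b, what = c("series", "series")) {
  if (length(a$year) != length(b$year) || !all(a$year == b$year)) {
    abort(paste0(
      "Year axes of ", what[1], " and ", what[2], " are not aligned."
    ))
  }
  invisible(TRUE)
}

#' Read and write annual flux series as CSV
#'
#' The on-disk exchange format is one row per (component, member, year):
#' columns `component`, `member`, `year`, `value_gtc_per_yr`,
#' `sigma_gtc_per_yr`; UTF-8 with `.` decimal separator. `member` is empty
#' for consensus (non-ensemble) series.
#'
#' @param path file path.
#' @param x tibble with columns `component`, `year`, `value`, `sigma` and
#'   optionally `member`.
#' @return `read_flux_csv()` returns a tibble in the package's series layout
#'   (with a `member` column when any member labels are present);
#'   `write_flux_csv()` returns `x` invisibly.
#' @export
read_flux_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(
    component = as.character(raw$component),
    member = if ("member" %in% names(raw)) as.character(raw$member) else NA_character_,
    year = as.integer(raw$year),
    value = as.numeric(raw$value_gtc_per_yr),
    sigma = if ("sigma_gtc_per_yr" %in% names(raw)) {
      as.numeric(raw$sigma_gtc_per_yr)
    } else {
      NA_real_
    }
  )
  if (all(is.na(out$member) | out$member == "")) out$member <- NULL
  out
}

#' @rdname read_flux_csv
#' @export
write_flux_csv <- function(x, path) {
  x <- check_flux_series(x)
  out <- tibble(
    component = x$component,
    member = if ("member" %in% names(x)) x$member else "",
    year = x$year,
    value_gtc_per_yr = x$value,
    sigma_gtc_per_yr = x$sigma
  )
  readr::write_csv(out, path)
  invisible(x)
}
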