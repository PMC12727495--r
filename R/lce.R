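#' Anthropogenic lateral carbon export perturbation
#'
#' Constructor for the anthropogenic perturbation of the land-to-inland-water
#' carbon flux and its routing. `f_li` is the total perturbation of the
#' land-to-inland-water export (GtC/yr, 2014-2023 minus pre-industrial),
#' partitioned downstream into added aquatic CO2 evasion (`f_ia`), added
#' aquatic sediment storage (`f_is`) and added export to the open ocean
#' (`f_ie`). By origin, `f_li` splits into `dissolved_share` (displaced
#' dissolved soil CO2, which merely moves the outgassing point and does not
#' touch the land sink) and `organic_share` (terrestrial organic carbon, an
#' actual loss from land reservoirs). Defaults are the assessed decadal
#' values; `organic_sigma_alt` records the second printed uncertainty for
#' the organic share (the source prints two inconsistent values; both are
#' kept as metadata, neither is propagated).
#'
#' @param f_li,f_ia,f_is,f_ie partition fluxes in GtC/yr, all >= 0.
#' @param dissolved_share,organic_share origin split of `f_li` (GtC/yr).
#' @param sigmas named numeric vector of 1-sigma values for the six fluxes.
#' @param organic_sigma_alt alternative printed sigma for the organic share.
#' @return A list of class `"lce_perturbation"`.
#' @export
lateral_flux_perturbation <- function(f_li = 0.54, f_ia = 0.34, f_is = 0.09,
                                      f_ie = 0.11,
                                      dissolved_share = 0.27,
                                      organic_share = 0.27,
                                      sigmas = c(
                                        f_li = 0.44, f_ia = 0.26,
                                        f_is = 0.03, f_ie = 0.08,
                                        dissolved_share = 0.31,
                                        organic_share = 0.31
                                      ),
                                      organic_sigma_alt = 0.22) {
  vals <- c(
    f_li = f_li, f_ia = f_ia, f_is = f_is, f_ie = f_ie,
    dissolved_share = dissolved_share, organic_share = organic_share
  )
  if (any(vals < 0)) abort("All perturbation fluxes must be non-negative.")
  structure(
    list(
      f_li = f_li, f_ia = f_ia, f_is = f_is, f_ie = f_ie,
      dissolved_share = dissolved_share, organic_share = organic_share,
      sigmas = sigmas, organic_sigma_alt = organic_sigma_alt
    ),
    class = "lce_perturbation"
  )
}

#' @export
print.lce_perturbation <- function(x, ...) {
  cat(sprintf(
    "Lateral-export perturbation F'_LI = %.2f GtC/yr\n  -> evasion %.2f + burial %.2f + ocean export %.2f\n  origin: dissolved %.2f + organic %.2f\n",
    x$f_li, x$f_ia, x$f_is, x$f_ie, x$dissolved_share, x$organic_share
  ))
  invisible(x)
}

#' Validate the lateral-flux conservation identities
#'
#' Checks the two mass-conservation identities of the perturbation:
#' F'_LI = F'_IA + F'_IS + F'_IE (downstream partition) and
#' F'_LI = dissolved + organic (origin split), each to within `tol`.
#'
#' @param p an `"lce_perturbation"`.
#' @param tol tolerance in GtC/yr (default 0.005, i.e. printed-rounding
#'   agreement).
#' @return A one-row tibble: `pass`, `residual_partition`, `residual_origin`.
#'   With `strict = TRUE`, a violation raises an error naming the identity.
#' @param strict raise an error on failure instead of returning it.
#' @export
validate_partition <- function(p, tol = 0.005, strict = FALSE) {
  if (tol <= 0) abort("`tol` must be positive.")
  res_part <- p$f_li - (p$f_ia + p$f_is + p$f_ie)
  res_orig <- p$f_li - (p$dissolved_share + p$organic_share)
  pass <- abs(res_part) <= tol && abs(res_orig) <= tol
  if (strict && !pass) {
    which <- if (abs(res_part) > tol) "downstream partition" else "origin split"
    abort(sprintf(
      "Lateral-flux %s does not close: residual %.3f GtC/yr exceeds tol %.3f.",
      which, if (abs(res_part) > tol) res_part else res_orig, tol
    ))
  }
  tibble(
    pass = pass,
    residual_partition = res_part,
    residual_origin = res_orig
  )
}

#' Land-sink reduction from the lateral-export perturbation
#'
#' The dissolved share of the export is soil CO2 displaced laterally before
#' outgassing: the combined land-plus-aquatic exchange with the atmosphere is
#' unchanged, so it does not affect the land sink. Of the organic share, the
#' part buried in sediments (`f_is`) or exported to the ocean (`f_ie`) also
#' leaves the atmosphere untouched; only the remainder -- organic carbon
#' decomposed in inland waters and evaded as CO2 -- is a genuine loss of land
#' uptake. The correction is therefore organic_share - F'_IS - F'_IE,
#' returned as a positive reduction to apply to S_LAND. No correction is
#' ever produced for the ocean sink (exported carbon is assumed to stay
#' stored in the ocean).
#'
#' @param p an `"lce_perturbation"`.
#' @param sigma 1-sigma of the correction (GtC/yr); the assessed value 0.06
#'   is carried as given rather than re-derived.
#' @param tol tolerance forwarded to [validate_partition()].
#' @return One-row tibble: `value`, `sigma` (GtC/yr).
#' @examples
#' sland_lce_correction(lateral_flux_perturbation()) # 0.07 GtC/yr
#' @export
sland_lce_correction <- function(p, sigma = 0.06, tol = 0.005) {
  validate_partition(p, tol = tol, strict = TRUE)
  value <- p$organic_share - p$f_is - p$f_ie
  if (value < -tol) {
    abort("Inconsistent partition: organic share smaller than burial plus ocean export.")
  }
  tibble(value = max(value, 0), sigma = sigma)
}

#' Apply the lateral-export correction to a land-sink series
#'
#' The assessed correction is a single decadal value; its historical growth
#' is described by a per-year ramp weight in `[0, 1]`:
#' S_LAND(t) <- S_LAND(t) - correction x ramp(t). The correction sigma
#' (scaled by the ramp) folds into the series sigma in quadrature.
#'
#' @param s_land flux-series tibble for S_LAND.
#' @param correction one-row tibble (`value`, `sigma`) from
#'   [sland_lce_correction()], or a single number.
#' @param ramp per-year weights in `[0, 1]`, recycled if scalar; default 1
#'   (full correction every year). See [linear_ramp()] for the default
#'   historical shape.
#' @return Corrected flux-series tibble.
#' @export
apply_lce <- function(s_land, correction, ramp = 1) {
  s_land <- check_flux_series(s_land)
  if (is.data.frame(correction)) {
    corr_sigma <- correction$sigma[1]
    correction <- correction$value[1]
  } else {
    corr_sigma <- 0
  }
  if (length(ramp) == 1L) ramp <- rep(ramp, nrow(s_land))
  if (length(ramp) != nrow(s_land)) {
    abort("`ramp` must be scalar or one weight per year.")
  }
  if (any(ramp < 0 | ramp > 1)) abort("Ramp weights must lie in [0, 1].")
  tibble(
    component = s_land$component,
    year = s_land$year,
    value = s_land$value - correction * ramp,
    sigma = ifelse(
      is.na(s_land$sigma), NA_real_,
      sqrt(s_land$sigma^2 + (corr_sigma * ramp)^2)
    )
  )
}

#' Linear historical ramp
#'
#' Minimal-assumption growth shape for a perturbation known only as a recent
#' decadal mean: weights rise linearly from 0 in `from` to 1 in `to`.
#'
#' @param years integer years.
#' @param from year at which the ramp is 0 (clamped below).
#' @param to year at which the ramp reaches 1 (clamped above).
#' @return Numeric weights in `[0, 1]`, one per year.
#' @export
linear_ramp <- function(years, from = 1960, to = 2023) {
  pmin(pmax((years - from) / (to - from), 0), 1)
}

#' Read lateral-export configuration from YAML
#'
#' Flat key-value block with the six perturbation numbers (`f_li`, `f_ia`,
#' `f_is`, `f_ie`, `dissolved_share`, `organic_share`) and optional `sigmas`.
#'
#' @param path YAML file path.
#' @return An `"lce_perturbation"`.
#' @export
read_lce_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(
    names(cfg),
    c("f_li", "f_ia", "f_is", "f_ie", "dissolved_share", "organic_share")
  )]
  if (!is.null(cfg$sigmas)) args$sigmas <- unlist(cfg$sigmas)
  do.call(lateral_flux_perturbation, args)
}
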