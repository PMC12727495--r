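#' Ocean-sink correction parameters
#'
#' Bundle of the parameters for the two ocean-sink bias corrections. Global
#' ocean biogeochemical models (GOBMs) underestimate the sink by about 10%
#' (too-weak overturning, spin-up biases, interior-ocean constraints), so
#' their ensemble mean is scaled up multiplicatively. Observation-based fCO2
#' products miss the temperature gradient across the sub-millimetre surface
#' skin: the cool-skin effect strengthens uptake (+0.42 GtC/yr) and is
#' partly offset by the warm-layer measurement-depth effect (-0.24 GtC/yr),
#' a net additive adjustment of +0.18 GtC/yr. Uncertainties are calibrated
#' from stated confidences that each correction is positive (90% for the
#' GOBM scaling, 66% for the skin adjustment) via [confidence_sigma()].
#'
#' @param gobm_scale_fraction multiplicative scaling of the GOBM sink
#'   (default 0.10).
#' @param gobm_scale_sigma 1-sigma of the scaling fraction (default 0.08,
#'   the value implied by 90% confidence after rounding).
#' @param cool_skin cool-skin adjustment, GtC/yr, increases the sink.
#' @param warm_layer warm-layer adjustment, GtC/yr, decreases the sink.
#' @param fco2_sigma 1-sigma of the net skin adjustment, GtC/yr (default
#'   0.4, the value implied by 66% confidence after rounding).
#' @param p_positive_gobm,p_positive_fco2 stated confidences.
#' @return A list of class `"ocean_correction_spec"` (also carries the
#'   implied standard-normal scores `z_gobm`, `z_fco2`).
#' @export
ocean_correction_spec <- function(gobm_scale_fraction = 0.10,
                                  gobm_scale_sigma = 0.08,
                                  cool_skin = 0.42,
                                  warm_layer = 0.24,
                                  fco2_sigma = 0.4,
                                  p_positive_gobm = 0.90,
                                  p_positive_fco2 = 0.66) {
  if (cool_skin < 0 || warm_layer < 0) {
    abort("`cool_skin` and `warm_layer` must be non-negative magnitudes.")
  }
  for (p in c(p_positive_gobm, p_positive_fco2)) {
    if (p <= 0 || p >= 1) abort("Confidences must lie strictly in (0, 1).")
  }
  structure(
    list(
      gobm_scale_fraction = gobm_scale_fraction,
      gobm_scale_sigma = gobm_scale_sigma,
      cool_skin = cool_skin,
      warm_layer = warm_layer,
      fco2_sigma = fco2_sigma,
      p_positive_gobm = p_positive_gobm,
      p_positive_fco2 = p_positive_fco2,
      z_gobm = qnorm(1 - p_positive_gobm),
      z_fco2 = qnorm(1 - p_positive_fco2)
    ),
    class = "ocean_correction_spec"
  )
}

#' Read the ocean correction parameters from YAML
#'
#' Reads the `ocean:` section (or the whole file if no such key) of a YAML
#' configuration into an [ocean_correction_spec()].
#'
#' @param path YAML file path.
#' @return An `"ocean_correction_spec"`.
#' @export
read_ocean_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$ocean)) cfg <- cfg$ocean
  do.call(ocean_correction_spec, cfg[intersect(
    names(cfg),
    names(formals(ocean_correction_spec))
  )])
}

#' Scale the GOBM ocean-sink estimate upward
#'
#' Applies the multiplicative bias correction to each annual value:
#' corrected(t) = gobm(t) x (1 + fraction); the correction series is
#' gobm(t) x fraction with sigma(t) = gobm(t) x sigma_fraction.
#'
#' @param gobm flux-series tibble of the GOBM ensemble-mean sink.
#' @param spec an [ocean_correction_spec()].
#' @return List with `corrected` and `correction` flux-series tibbles.
#' @examples
#' g <- flux_series("S_OCEAN", 2014:2023, 2.6, 0.4)
#' scale_gobm(g)$correction$value[1] # 0.26
#' @export
scale_gobm <- function(gobm, spec = ocean_correction_spec()) {
  gobm <- check_flux_series(gobm)
  if (spec$gobm_scale_fraction < 0) {
    abort("`gobm_scale_fraction` must be non-negative.")
  }
  f <- spec$gobm_scale_fraction
  correction <- tibble(
    component = "S_OCEAN_gobm_scaling",
    year = gobm$year,
    value = gobm$value * f,
    sigma = gobm$value * spec$gobm_scale_sigma
  )
  corrected <- tibble(
    component = gobm$component,
    year = gobm$year,
    value = gobm$value * (1 + f),
    sigma = ifelse(
      is.na(gobm$sigma), NA_real_,
      sqrt(gobm$sigma^2 + correction$sigma^2)
    )
  )
  list(corrected = corrected, correction = correction)
}

#' Cool-skin / warm-layer adjustment of the fCO2-product sink
#'
#' Adds the net skin-temperature adjustment (cool-skin minus warm-layer,
#' +0.18 GtC/yr at defaults) uniformly to the fCO2-product sink series.
#' A negative net adjustment is allowed but flagged with a warning, since
#' the assessment places 66% confidence on a positive correction.
#'
#' @param fco2 flux-series tibble of the fCO2-product ensemble-mean sink.
#' @param spec an [ocean_correction_spec()].
#' @return List with `corrected` (flux-series tibble) and `correction`
#'   (one-row tibble `value`, `sigma`).
#' @export
skin_adjust <- function(fco2, spec = ocean_correction_spec()) {
  fco2 <- check_flux_series(fco2)
  net <- spec$cool_skin - spec$warm_layer
  if (net < 0) {
    warn("Net skin adjustment is negative (warm layer exceeds cool skin).")
  }
  correction <- tibble(value = net, sigma = spec$fco2_sigma)
  corrected <- tibble(
    component = fco2$component,
    year = fco2$year,
    value = fco2$value + net,
    sigma = ifelse(
      is.na(fco2$sigma), NA_real_,
      sqrt(fco2$sigma^2 + spec$fco2_sigma^2)
    )
  )
  list(corrected = corrected, correction = correction)
}

#' Calibrate a correction uncertainty from a sign confidence
#'
#' Given a positive correction and a stated probability `p_positive` that
#' its true value is positive, the implied Gaussian 1-sigma solves
#' P(N(correction, sigma) > 0) = p_positive, i.e. Z = qnorm(1 - p_positive)
#' (negative for p > 0.5) and sigma = correction / |Z|. The inverse normal
#' comes from R's `qnorm` (absolute accuracy well below 1e-8).
#'
#' @param correction positive correction magnitude (any unit).
#' @param p_positive confidence in (0.5, 1) that the correction is positive.
#' @return One-row tibble: `correction`, `p_positive`, `z` (negative),
#'   `sigma` (same unit as `correction`).
#' @examples
#' confidence_sigma(0.10, 0.90) # sigma ~ 0.078, adopted as 8%
#' confidence_sigma(0.18, 0.66) # sigma ~ 0.44, adopted as 0.4 GtC/yr
#' @export
confidence_sigma <- function(correction, p_positive) {
  if (correction <= 0) abort("`correction` must be positive.")
  if (p_positive <= 0.5 || p_positive >= 1) {
    abort("`p_positive` must lie strictly in (0.5, 1): at 0.5 the implied sigma is infinite.")
  }
  z <- qnorm(1 - p_positive)
  tibble(
    correction = correction,
    p_positive = p_positive,
    z = z,
    sigma = correction / abs(z)
  )
}

#' Combine the GOBM and fCO2-product streams into S_OCEAN
#'
#' The assessed ocean sink is the per-year unweighted mean of the two
#' corrected streams. The combined correction mean is the average of the two
#' correction means, with sigma = 1/2 x quadrature(sigma_gobm, sigma_fco2)
#' (the propagation rule for an average of two independent streams); the
#' total S_OCEAN sigma combines the baseline sigma with that correction
#' sigma in quadrature.
#'
#' @param gobm_corrected,fco2_corrected corrected flux-series tibbles from
#'   [scale_gobm()] and [skin_adjust()].
#' @param base_sigma per-year (or scalar) 1-sigma of the uncorrected ocean
#'   sink; default `NULL` leaves sigma as the half-quadrature of the two
#'   stream sigmas.
#' @param corrections optional list with the two correction objects, used to
#'   attach the combined-correction summary as attribute `"correction"`.
#' @return Flux-series tibble with `component = "S_OCEAN"`.
#' @export
combine_ocean <- function(gobm_corrected, fco2_corrected, base_sigma = NULL,
                          corrections = NULL) {
  gobm_corrected <- check_flux_series(gobm_corrected)
  fco2_corrected <- check_flux_series(fco2_corrected)
  check_aligned(gobm_corrected, fco2_corrected, c("GOBM stream", "fCO2 stream"))
  value <- (gobm_corrected$value + fco2_corrected$value) / 2
  out <- tibble(
    component = "S_OCEAN",
    year = gobm_corrected$year,
    value = value,
    sigma = NA_real_
  )
  if (!is.null(corrections)) {
    corr_mean <- (mean(corrections$gobm$value) + corrections$fco2$value[1]) / 2
    corr_sigma <- quadrature(
      c(mean(corrections$gobm$sigma), corrections$fco2$sigma[1])
    ) / 2
    attr(out, "correction") <- tibble(value = corr_mean, sigma = corr_sigma)
    if (!is.null(base_sigma)) {
      out$sigma <- sqrt(base_sigma^2 + corr_sigma^2)
    }
  } else if (!is.null(base_sigma)) {
    out$sigma <- base_sigma
  }
  out
}
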