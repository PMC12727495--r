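# Shared fixture builders; everything is generated in code at test time.

# Five-component budget with constant decadal values (Table-style row).
constant_budget <- function(values, sigmas = NULL, years = 2014:2023) {
  s <- function(k) if (is.null(sigmas)) NULL else sigmas[[k]]
  budget_table(
    flux_series("E_FOS", years, values[["E_FOS"]], s("E_FOS")),
    flux_series("E_LUC", years, values[["E_LUC"]], s("E_LUC")),
    flux_series("S_LAND", years, values[["S_LAND"]], s("S_LAND")),
    flux_series("S_OCEAN", years, values[["S_OCEAN"]], s("S_OCEAN")),
    flux_series("G_ATM", years, values[["G_ATM"]], s("G_ATM"))
  )
}

# Long subcomponent tibble for one bookkeeping model from named per-year
# component vectors.
eluc_table <- function(model, density_mode, years, ...) {
  comps <- list(...)
  dplyr::bind_rows(lapply(names(comps), function(nm) {
    tibble::tibble(
      model = model, density_mode = density_mode, component = nm,
      year = years, value = rep_len(comps[[nm]], length(years))
    )
  }))
}

# Noise-free, bias-free world configuration (members identical to truth);
# individual knobs can still be switched back on through `...`.
silent_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    iav_sigma = c(e_fos = 0, e_luc = 0, s_land = 0, s_ocean = 0),
    member_sigma = c(
      bookkeeping = 0, dgvm = 0, gobm = 0, fco2 = 0,
      dgvm_fixed = 0, gobm_fixed = 0
    ),
    spread = c(
      bookkeeping_ratio = 0, rss_member = 0, clim_land_member = 0,
      clim_ocean_member = 0, inversion_offset = 0, inversion_net = 0
    ),
    delta_l_decadal = 0, rss_decadal = 0, gobm_bias_fraction = 0,
    skin_deficit = 0, clim_land_decadal = 0, clim_ocean_decadal = 0,
    lce = lateral_flux_perturbation(0, 0, 0, 0, 0, 0)
  )
  args <- utils::modifyList(args, list(...))
  do.call(world_config, args)
}

# Identity-free ocean spec (no corrections at all).
null_ocean_spec <- function() {
  ocean_correction_spec(
    gobm_scale_fraction = 0, gobm_scale_sigma = 0,
    cool_skin = 0, warm_layer = 0, fco2_sigma = 0
  )
}
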