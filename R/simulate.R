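#' Configuration of the synthetic carbon-cycle world
#'
#' Defines the study conditions for the synthetic ensemble generator: a
#' "true" global budget that closes exactly, plus ensembles of biased,
#' noisy observations of each component in the shapes the consolidation
#' pipeline consumes. Trend anchors place the truth at the consolidated
#' decadal means (E_FOS 9.7, E_LUC 1.2, S_LAND 2.7, S_OCEAN 3.1 GtC/yr over
#' 2014-2023, G_ATM by closure); interannual variability is AR(1) with
#' phi = 0.5 and the largest innovation sigma on land. Bias knobs default
#' to the assessed magnitudes: bookkeeping models low on E_LUC by a
#' transient-density correction of 0.11 GtC/yr (decadal), fixed-cover land
#' sink high by an RSS bias of 0.5 GtC/yr, lateral-export land-sink excess
#' of 0.07 GtC/yr (linear ramp), ocean models low by 10/110 of the true
#' sink, fCO2 products low by a 0.18 GtC/yr skin deficit, and climate
#' change weakening the land and ocean sinks by 0.8 and 0.18 GtC/yr.
#' Bias trajectories grow linearly from the first year, normalised so their
#' 2014-2023 mean equals the knob (except the lateral-export term, which is
#' injected exactly as correction x linear ramp so the standard correction
#' closes it).
#'
#' @param seed integer master seed; each ensemble draws from its own
#'   deterministic sub-stream so changing one knob never reshuffles the
#'   noise of the others.
#' @param years simulated calendar years.
#' @param phi AR(1) coefficient of interannual variability.
#' @param iav_sigma named innovation sigmas (GtC/yr) for the truth
#'   trajectories.
#' @param n_bookkeeping,n_dgvm,n_gobm,n_fco2,n_inversions ensemble sizes.
#' @param member_sigma named AR(1) innovation sigmas for member-level noise.
#' @param delta_l_decadal,rss_decadal decadal-mean bias magnitudes, GtC/yr.
#' @param gobm_bias_fraction multiplicative low bias of the ocean models
#'   (the generated sink is truth / (1 + fraction)).
#' @param skin_deficit additive low bias of the fCO2 products, GtC/yr.
#' @param clim_land_decadal,clim_ocean_decadal decadal-mean climate-driven
#'   sink weakening, GtC/yr.
#' @param lce an [lateral_flux_perturbation()] describing the
#'   lateral-export knob.
#' @param decade two-year vector, the reporting decade.
#' @return A list of class `"world_config"`.
#' @export
world_config <- function(seed = 1,
                         years = 1960:2023,
                         phi = 0.5,
                         iav_sigma = c(
                           e_fos = 0.05, e_luc = 0.10,
                           s_land = 0.40, s_ocean = 0.12
                         ),
                         n_bookkeeping = 4,
                         n_dgvm = 7,
                         n_gobm = 10,
                         n_fco2 = 10,
                         n_inversions = 14,
                         member_sigma = c(
                           bookkeeping = 0.12, dgvm = 0.15,
                           gobm = 0.08, fco2 = 0.10,
                           dgvm_fixed = 0.05, gobm_fixed = 0.03
                         ),
                         spread = c(
                           bookkeeping_ratio = 0.15, rss_member = 0.25,
                           clim_land_member = 0.25, clim_ocean_member = 0.2,
                           inversion_offset = 0.5, inversion_net = 0.02
                         ),
                         delta_l_decadal = 0.11,
                         rss_decadal = 0.5,
                         gobm_bias_fraction = 0.10,
                         skin_deficit = 0.18,
                         clim_land_decadal = 0.8,
                         clim_ocean_decadal = 0.18,
                         lce = lateral_flux_perturbation(),
                         decade = c(2014, 2023)) {
  if (length(years) < 10) abort("Need at least a decade of years.")
  if (gobm_bias_fraction < 0 || skin_deficit < 0) {
    abort("Bias knobs must be non-negative.")
  }
  structure(
    as.list(environment()),
    class = "world_config"
  )
}

# CO2 mole-fraction trajectory (ppm): exponential approach anchored at
# 316 ppm in 1960 and 423 ppm in 2024 above a 277 ppm pre-industrial base.
co2_trajectory <- function(years) {
  b <- log((423 - 277) / (316 - 277)) / 64
  a <- (316 - 277) / exp(b * (1960 - 1700))
  277 + a * exp(b * (years - 1700))
}

# Linear bias ramp normalised so its mean over the reporting decade is 1.
norm_ramp <- function(years, decade) {
  r <- (years - years[1]) / (max(years) - years[1])
  r / mean(r[years >= decade[1] & years <= decade[2]])
}

#' Toy bookkeeping model of land-use-change emissions
#'
#' A deliberately small committed-flux accounting model used to exercise the
#' transient-density machinery with known truth. Land-cover transitions
#' (clearing, regrowth, wood harvest, other) create cohorts whose carbon
#' follows first-order kinetics: a cleared stock of area x equilibrium
#' density decays to the atmosphere with timescale `tau_clear` (the year-n
#' source is stock x (e^-((n-1)/tau) - e^-(n/tau))); regrowing cohorts take
#' up carbon toward area x equilibrium density with timescale `tau_regrow`;
#' wood harvest creates a paired source (fraction `harvest_intensity` of the
#' standing stock, decaying with `tau_harvest`) and regrowth sink cohort.
#' Equilibrium density is either static (`beta = 0`) or transient,
#' density(t) = density x (1 + beta x ln(CO2(t) / CO2(1700))).
#'
#' @param transitions tibble (`year`, `type`, `area`) with `type` in
#'   `clearing`, `regrowth`, `harvest`, `other`; areas in arbitrary units.
#' @param years simulation years.
#' @param density equilibrium carbon density, GtC per area unit.
#' @param beta CO2 sensitivity of the equilibrium density (0 = static).
#' @param tau_clear,tau_regrow,tau_harvest e-folding timescales in years.
#' @param harvest_intensity fraction of the standing stock removed by a
#'   harvest event.
#' @param initial_area available natural area; cumulative clearing plus
#'   harvest beyond it is a validation error.
#' @param model label for the output.
#' @return Long subcomponent tibble (see [eluc-components]) with
#'   `density_mode` set from `beta`.
#' @export
toy_bookkeeping <- function(transitions, years,
                            density = 1, beta = 0,
                            tau_clear = 10, tau_regrow = 25,
                            tau_harvest = 5, harvest_intensity = 0.3,
                            initial_area = Inf, model = "toy") {
  transitions <- as_tibble(transitions)
  need <- c("year", "type", "area")
  miss <- setdiff(need, names(transitions))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(transitions$type), c("clearing", "regrowth", "harvest", "other"))
  if (length(bad)) {
    abort(paste0("Unknown transition type(s): ", paste(bad, collapse = ", ")))
  }
  used <- transitions |>
    filter(.data$type %in% c("clearing", "harvest")) |>
    arrange(.data$year) |>
    mutate(total = cumsum(.data$area))
  if (nrow(used) && max(used$total) > initial_area + 1e-9) {
    abort("Transition areas exceed the available area.")
  }
  dens_t <- function(yr) {
    density * (1 + beta * log(co2_trajectory(yr) / co2_trajectory(1700)))
  }
  n <- length(years)
  comp <- matrix(
    0, n, 5,
    dimnames = list(NULL, eluc_component_names)
  )
  decay_flux <- function(stock, start_year, tau) {
    # flux in year index i (>= start) for a unit event at start_year
    age <- years - start_year + 1 # age 1 in the event year
    f <- ifelse(
      age >= 1, exp(-(age - 1) / tau) - exp(-age / tau), 0
    )
    stock * f
  }
  for (i in seq_len(nrow(transitions))) {
    tr <- transitions[i, ]
    if (!tr$year %in% years) next
    d0 <- dens_t(tr$year)
    if (tr$type == "clearing") {
      comp[, "deforestation"] <- comp[, "deforestation"] +
        decay_flux(tr$area * d0, tr$year, tau_clear)
    } else if (tr$type == "other") {
      comp[, "other"] <- comp[, "other"] +
        decay_flux(tr$area * d0, tr$year, tau_clear)
    } else if (tr$type == "regrowth") {
      # uptake toward the (possibly drifting) equilibrium stock
      stock <- 0
      uptake <- numeric(n)
      rate <- 1 - exp(-1 / tau_regrow)
      for (j in which(years >= tr$year)) {
        target <- tr$area * dens_t(years[j])
        uptake[j] <- (target - stock) * rate
        stock <- stock + uptake[j]
      }
      comp[, "regrowth"] <- comp[, "regrowth"] - uptake
    } else if (tr$type == "harvest") {
      removed <- tr$area * d0 * harvest_intensity
      comp[, "harvest_src"] <- comp[, "harvest_src"] +
        decay_flux(removed, tr$year, tau_harvest)
      stock <- 0
      uptake <- numeric(n)
      rate <- 1 - exp(-1 / tau_regrow)
      for (j in which(years >= tr$year)) {
        target <- tr$area * dens_t(years[j]) * harvest_intensity
        uptake[j] <- (target - stock) * rate
        stock <- stock + uptake[j]
      }
      comp[, "harvest_snk"] <- comp[, "harvest_snk"] - uptake
    }
  }
  tidyr::expand_grid(
    component = eluc_component_names, year = years
  ) |>
    mutate(
      model = model,
      density_mode = if (beta == 0) "static" else "transient",
      value = purrr::map2_dbl(
        .data$component, .data$year,
        ~ comp[match(.y, years), .x]
      )
    ) |>
    select("model", "density_mode", "component", "year", "value")
}

#' Build a toy PFT world with a closed-form RSS bias
#'
#' Constructs matching cover and flux grids for the replaced-sinks-and-
#' sources correction: constant pre-industrial cover (S2: forest 0.5, grass
#' 0.3, crop 0), transient cover (S3) in which a prescribed forest area is
#' converted to cropland, and per-PFT flux densities
#' density(pft, t) = mu(t) + base_density(pft), with the common offset
#' mu(t) chosen so the S2 global sum reproduces `sland_s2` exactly and the
#' forest-loss fraction chosen so the RSS bias of the reconstruction equals
#' `rss_bias` exactly (closed form: bias = sum_cells area x forest_loss x
#' (forest density - crop density), and the density gap is the constant
#' base gap). The additive form keeps the construction well defined even in
#' years when the target sink is weak or negative.
#'
#' @param years simulation years.
#' @param sland_s2 per-year S2 global land sink to reproduce (GtC/yr).
#' @param rss_bias per-year bias the world should produce (GtC/yr).
#' @param n_cells number of grid cells.
#' @param areas cell areas (recycled; default 1).
#' @param base_density named densities (relative units) for
#'   `forest`, `grass`, `crop`.
#' @return List with `cover_s2`, `cover_s3`, `nbp`, `areas` (tibbles in the
#'   [pft-grids] layout), `true_bias` and `sland_s2` flux series.
#' @export
make_pft_world <- function(years, sland_s2, rss_bias,
                           n_cells = 4, areas = 1,
                           base_density = c(forest = 2, grass = 0.5, crop = 0.2)) {
  n <- length(years)
  stopifnot(length(sland_s2) == n, length(rss_bias) == n)
  area_vec <- rep_len(areas, n_cells)
  cells <- paste0("cell", seq_len(n_cells))
  s2_frac <- c(forest = 0.5, grass = 0.3, crop = 0)
  # common density offset per year so the S2 sum matches sland_s2
  tot_area <- sum(area_vec)
  veg_frac <- as.numeric(s2_frac["forest"] + s2_frac["grass"])
  base_sum <- as.numeric(
    s2_frac["forest"] * base_density["forest"] +
      s2_frac["grass"] * base_density["grass"]
  )
  mu <- (sland_s2 / tot_area - base_sum) / veg_frac
  # forest loss per cell-year delivering the requested bias; the density
  # gap forest - crop is constant by construction
  d_gap <- as.numeric(base_density["forest"] - base_density["crop"])
  loss <- rss_bias / (d_gap * tot_area)
  if (any(!is.finite(loss)) || any(loss < -1e-9) ||
    any(loss > s2_frac["forest"])) {
    abort("Requested bias implies an invalid forest-loss fraction.")
  }
  grid <- tidyr::expand_grid(
    cell = cells, pft = names(base_density), year = years
  )
  yr_idx <- match(grid$year, years)
  cover_s2 <- mutate(grid, cover_fraction = as.numeric(s2_frac[grid$pft]))
  cover_s3 <- mutate(
    grid,
    cover_fraction = as.numeric(s2_frac[grid$pft]) +
      ifelse(grid$pft == "forest", -loss[yr_idx],
        ifelse(grid$pft == "crop", loss[yr_idx], 0)
      )
  )
  nbp <- mutate(
    grid,
    nbp_density = mu[yr_idx] + as.numeric(base_density[grid$pft])
  )
  list(
    cover_s2 = cover_s2,
    cover_s3 = cover_s3,
    nbp = nbp,
    areas = tibble(cell = cells, area = area_vec),
    true_bias = flux_series("RSS", years, rss_bias),
    sland_s2 = flux_series("S_LAND", years, sland_s2)
  )
}

#' Simulate the full synthetic input bundle
#'
#' Generates everything the consolidation pipeline consumes, with known
#' truth and exact internal mass balance: (a) a truth budget closing to
#' machine precision; (b) baseline (biased) observations of each component;
#' (c) bookkeeping subcomponent tables with static/transient reference
#' pairs for the transient-density correction; (d) per-model PFT worlds for
#' the RSS correction; (e) ocean model and fCO2-product ensembles carrying
#' the scaling and skin biases; (f) paired full/constant-climate sink runs
#' with a known weakening trajectory; (g) an inversion ensemble (net
#' atmospheric inputs plus monthly station mole fractions) consistent with
#' the reference conversion factor. Same seed, same output, bit for bit.
#'
#' @param config a [world_config()].
#' @param inversions generate the (comparatively bulky) inversion member
#'   mole fractions (default `TRUE`; switch off when only the flux budget
#'   is needed).
#' @return A list of class `"carbon_world"`; see Details in the vignette.
#' @export
simulate_world <- function(config = world_config(), inversions = TRUE) {
  stopifnot(inherits(config, "world_config"))
  years <- config$years
  n <- length(years)
  seed <- config$seed
  phi <- config$phi
  decade <- config$decade
  ramp <- norm_ramp(years, decade)
  lramp <- linear_ramp(years, years[1], max(years))

  # --- deterministic truth trajectories + AR(1) interannual variability
  fos_smooth <- 9.7 * exp(0.028 * (years - mean(decade)))
  rel <- fos_smooth / 9.7
  land_smooth <- 2.7 * rel^0.8
  ocean_smooth <- 3.1 * rel^0.9
  luc_smooth <- rep(1.2, n)
  noise <- with_stream(seed, 1L, list(
    e_fos = ar1_noise(n, phi, config$iav_sigma[["e_fos"]]),
    e_luc = ar1_noise(n, phi, config$iav_sigma[["e_luc"]]),
    s_land = ar1_noise(n, phi, config$iav_sigma[["s_land"]]),
    s_ocean = ar1_noise(n, phi, config$iav_sigma[["s_ocean"]])
  ))
  e_fos <- fos_smooth + noise$e_fos
  e_luc <- luc_smooth + noise$e_luc
  s_land <- land_smooth + noise$s_land
  s_ocean <- ocean_smooth + noise$s_ocean
  g_atm <- e_fos + e_luc - s_land - s_ocean # closure, exact
  if (any(land_smooth <= 0) || any(ocean_smooth <= 0)) {
    abort("Configured trends produce negative sink trajectories.")
  }
  truth <- budget_table(
    flux_series("E_FOS", years, e_fos),
    flux_series("E_LUC", years, e_luc),
    flux_series("S_LAND", years, s_land),
    flux_series("S_OCEAN", years, s_ocean),
    flux_series("G_ATM", years, g_atm)
  )

  # --- true bias trajectories
  delta_l_true <- config$delta_l_decadal * ramp
  rss_true <- config$rss_decadal * ramp
  lce_scalar <- sland_lce_correction(config$lce)
  lce_true <- lce_scalar$value * lramp
  clim_land_true <- config$clim_land_decadal * ramp
  clim_ocean_true <- config$clim_ocean_decadal * ramp

  # --- bookkeeping ensemble: static nets low by delta-L, carried entirely
  #     by the deforestation component so reference ratios recover it
  e_luc_static <- e_luc - delta_l_true
  fixed_parts <- c(
    regrowth = -0.35, harvest_src = 0.25, harvest_snk = -0.25, other = -0.20
  )
  bk <- with_stream(seed, 10L, {
    model_scale <- 1 + rnorm(config$n_bookkeeping, 0, config$member_sigma[["bookkeeping"]])
    ratio_noise <- rnorm(config$n_bookkeeping, 0, config$spread[["bookkeeping_ratio"]])
    purrr::map(seq_len(config$n_bookkeeping), function(m) {
      def_static <- (e_luc_static + 0.55) * model_scale[m]
      parts <- purrr::imap(
        fixed_parts, ~ tibble(
          component = .y, year = years, value = .x * model_scale[m]
        )
      )
      static <- bind_rows(
        tibble(component = "deforestation", year = years, value = def_static),
        bind_rows(parts)
      ) |>
        mutate(
          model = paste0("BK", m), density_mode = "static",
          .before = 1
        )
      # transient twin: deforestation scaled so net gains delta-L (with a
      # per-model perturbation on the reference models)
      def_transient <- def_static + delta_l_true * (1 + ratio_noise[m]) * model_scale[m]
      transient <- static |>
        mutate(
          density_mode = "transient",
          value = ifelse(
            .data$component == "deforestation", def_transient, .data$value
          )
        )
      list(static = static, transient = transient)
    })
  })
  bookkeeping_static <- bind_rows(purrr::map(bk, "static"))
  bookkeeping_transient_ref <- bind_rows(
    purrr::map(bk[1:2], "transient")
  )
  e_luc_obs <- eluc_net(bookkeeping_static) |>
    group_by(.data$year) |>
    summarise(value = mean(.data$value), .groups = "drop")

  # --- DGVM S2 ensemble (fixed pre-industrial cover): truth plus RSS bias
  #     plus the lateral-export excess plus member noise
  dgvm <- with_stream(seed, 20L, {
    kappa <- 1 + rnorm(config$n_dgvm, 0, config$spread[["rss_member"]])
    purrr::map(seq_len(config$n_dgvm), function(m) {
      iav <- ar1_noise(n, phi, config$member_sigma[["dgvm"]])
      bias_m <- rss_true * kappa[m]
      s2 <- s_land + bias_m + lce_true + iav
      list(member = paste0("DGVM", m), s2 = s2, rss_bias = bias_m)
    })
  })
  dgvm_s2 <- bind_rows(purrr::map(dgvm, ~ tibble(
    model = .x$member, year = years, value = .x$s2
  )))
  pft_worlds <- purrr::map(dgvm, function(d) {
    make_pft_world(years, sland_s2 = d$s2, rss_bias = d$rss_bias)
  })
  names(pft_worlds) <- purrr::map_chr(dgvm, "member")

  # --- paired constant-climate runs (climate effect = fixed - full)
  dgvm_fixed <- with_stream(seed, 25L, {
    zeta <- 1 + rnorm(config$n_dgvm, 0, config$spread[["clim_land_member"]])
    bind_rows(purrr::map(seq_len(config$n_dgvm), function(m) {
      tibble(
        model = paste0("DGVM", m), year = years,
        value = dgvm[[m]]$s2 + clim_land_true * zeta[m] +
          ar1_noise(n, phi, config$member_sigma[["dgvm_fixed"]])
      )
    }))
  })

  # --- ocean model ensemble: multiplicatively low, plus paired runs
  gobm <- with_stream(seed, 30L, {
    bind_rows(purrr::map(seq_len(config$n_gobm), function(m) {
      tibble(
        model = paste0("GOBM", m), year = years,
        value = s_ocean / (1 + config$gobm_bias_fraction) +
          ar1_noise(n, phi, config$member_sigma[["gobm"]])
      )
    }))
  })
  gobm_mean <- gobm |>
    group_by(.data$year) |>
    summarise(value = mean(.data$value), .groups = "drop")
  gobm_fixed <- with_stream(seed, 35L, {
    zeta <- 1 + rnorm(config$n_gobm, 0, config$spread[["clim_ocean_member"]])
    bind_rows(purrr::map(seq_len(config$n_gobm), function(m) {
      member <- filter(gobm, .data$model == paste0("GOBM", m))
      tibble(
        model = member$model, year = years,
        value = member$value + clim_ocean_true * zeta[m] +
          ar1_noise(n, phi, config$member_sigma[["gobm_fixed"]])
      )
    }))
  })

  # --- fCO2-product ensemble: additively low by the skin deficit
  fco2 <- with_stream(seed, 40L, {
    bind_rows(purrr::map(seq_len(config$n_fco2), function(m) {
      tibble(
        model = paste0("FCO2_", m), year = years,
        value = s_ocean - config$skin_deficit +
          ar1_noise(n, phi, config$member_sigma[["fco2"]])
      )
    }))
  })
  fco2_mean <- fco2 |>
    group_by(.data$year) |>
    summarise(value = mean(.data$value), .groups = "drop")

  # --- observed growth rate (exact mass, reference conversion factor)
  growth_true_ppm <- g_atm / 2.124
  growth_obs <- tibble(
    year = years, growth_ppm = growth_true_ppm, sigma_ppm = 0.02 / 2.124
  )

  # --- inversion ensemble: monthly station mole fractions plus net inputs
  inv <- NULL
  if (inversions) {
    boundary_ppm <- 316 + c(0, cumsum(growth_true_ppm))
    n_months <- n * 12 + 1
    dates <- as.Date(paste(
      rep(years[1]:(max(years) + 1), each = 12)[seq_len(n_months)],
      rep(1:12, length.out = n_months), 1,
      sep = "-"
    ))
    month_t <- decimal_year(dates)
    base_path <- approx(c(years, max(years) + 1), boundary_ppm, xout = month_t)$y
    seasonal <- 3 * sin(2 * pi * month_t) + 0.8 * cos(4 * pi * month_t)
    inv <- with_stream(seed, 50L, {
      start_years <- c(
        rep(years[1], ceiling(config$n_inversions * 0.6)),
        rep(
          max(years[1], 2001),
          config$n_inversions - ceiling(config$n_inversions * 0.6)
        )
      )
      offsets <- rnorm(config$n_inversions, 0, config$spread[["inversion_offset"]])
      members <- purrr::map(seq_len(config$n_inversions), function(m) {
        keep <- month_t >= start_years[m]
        mole <- tibble(
          member = sprintf("INV%02d", m),
          date = dates[keep],
          ppm = base_path[keep] + seasonal[keep] + offsets[m]
        )
        eps <- rnorm(n, 0, config$spread[["inversion_net"]])
        net <- tibble(
          member = sprintf("INV%02d", m),
          year = years,
          net_input_gtc = 2.124 * growth_true_ppm * (1 + eps)
        ) |>
          filter(.data$year >= start_years[m])
        list(mole = mole, net = net)
      })
      list(
        molefractions = bind_rows(purrr::map(members, "mole")),
        net_input = bind_rows(purrr::map(members, "net"))
      )
    })
  }

  # --- baseline (uncorrected) assessed budget with conventional sigmas
  baseline <- budget_table(
    flux_series("E_FOS", years, e_fos, 0.5),
    flux_series("E_LUC", years, e_luc_obs$value, 0.7),
    flux_series(
      "S_LAND", years,
      (dgvm_s2 |>
        group_by(.data$year) |>
        summarise(value = mean(.data$value), .groups = "drop"))$value,
      0.9
    ),
    flux_series(
      "S_OCEAN", years, (gobm_mean$value + fco2_mean$value) / 2, 0.4
    ),
    flux_series("G_ATM", years, g_atm, 0.02)
  )

  structure(
    list(
      config = config,
      years = years,
      truth = truth,
      truth_meta = list(
        delta_l = flux_series("delta_L", years, delta_l_true),
        rss = flux_series("RSS", years, rss_true),
        lce = flux_series("LCE", years, lce_true),
        clim_land = flux_series("S_LAND_clim", years, clim_land_true),
        clim_ocean = flux_series("S_OCEAN_clim", years, clim_ocean_true),
        growth_ppm = growth_true_ppm
      ),
      baseline = baseline,
      bookkeeping_static = bookkeeping_static,
      bookkeeping_transient_ref = bookkeeping_transient_ref,
      bookkeeping_delta_sigma = 0.03,
      dgvm_s2 = dgvm_s2,
      dgvm_fixed = dgvm_fixed,
      pft_worlds = pft_worlds,
      gobm = gobm,
      gobm_fixed = gobm_fixed,
      fco2 = fco2,
      growth_obs = growth_obs,
      inversions = inv
    ),
    class = "carbon_world"
  )
}

#' @export
print.carbon_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic carbon-cycle world, %d-%d (seed %d)\n  ensembles: %d bookkeeping, %d DGVM, %d GOBM, %d fCO2, %d inversions\n",
    min(x$years), max(x$years), x$config$seed,
    x$config$n_bookkeeping, x$config$n_dgvm, x$config$n_gobm,
    x$config$n_fco2, x$config$n_inversions
  ))
  invisible(x)
}

#' Write the synthetic bundle to CSV files
#'
#' Writes every reader-facing table of a simulated world into `dir` using
#' the exchange formats of the owning modules, with values at 17
#' significant digits so outputs are reproducible bit for bit across
#' platforms.
#'
#' @param world a `"carbon_world"` from [simulate_world()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_world_csv <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- options(digits = 17, scipen = 100)
  on.exit(options(old))
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
  }
  put(world$truth, "truth_budget.csv")
  put(world$baseline, "baseline_budget.csv")
  put(world$bookkeeping_static, "bookkeeping_static.csv")
  put(world$bookkeeping_transient_ref, "bookkeeping_transient_ref.csv")
  put(world$dgvm_s2, "dgvm_s2.csv")
  put(world$dgvm_fixed, "dgvm_fixed_climate.csv")
  put(world$gobm, "gobm.csv")
  put(world$gobm_fixed, "gobm_fixed_climate.csv")
  put(world$fco2, "fco2_products.csv")
  put(world$growth_obs, "growth_observed.csv")
  if (!is.null(world$inversions)) {
    put(world$inversions$net_input, "inversion_net_input.csv")
    put(world$inversions$molefractions, "inversion_molefractions.csv")
  }
  invisible(files)
}
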