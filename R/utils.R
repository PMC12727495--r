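#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n across all_of rename distinct pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats lm coef pt qnorm pnorm rnorm sd approx
NULL

# Half-up rounding to `digits` decimals (Table-1 style reporting; base R
# round() is half-even). Internal computation always stays at full precision.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_flux <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

fmt_pm <- function(value, sigma, digits = 1) {
  if (is.null(sigma) || all(is.na(sigma))) {
    fmt_flux(value, digits)
  } else {
    paste0(fmt_flux(value, digits), " ± ", fmt_flux(sigma, digits))
  }
}

# Deterministic per-ensemble RNG streams: changing one generator knob must not
# reshuffle the noise of unrelated ensembles, so each ensemble draws from its
# own sub-seed derived from the master seed and a fixed stream id.
stream_seed <- function(seed, stream_id) {
  (as.integer(seed) %% 94906265L) * 22L + as.integer(stream_id)
}

with_stream <- function(seed, stream_id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream_id))
  force(expr)
}

# Stationary AR(1) noise: x_t = phi x_{t-1} + e_t, e ~ N(0, sigma^2),
# initialised from the stationary distribution.
ar1_noise <- function(n, phi = 0.5, sigma = 1) {
  if (sigma == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma / sqrt(1 - phi^2))
  if (n > 1) {
    e <- rnorm(n - 1, 0, sigma)
    for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
  }
  x
}

# Calendar date -> decimal year with 1 January of year y mapping exactly to
# y (fraction = elapsed days / days in that year). Shared by the growth-rate
# algorithm and the synthetic mole-fraction generator so that year-boundary
# values are interpolation nodes, not extrapolations.
decimal_year <- function(dates) {
  lt <- as.POSIXlt(as.Date(dates))
  year <- lt$year + 1900
  days <- ifelse(
    (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366, 365
  )
  year + lt$yday / days
}
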