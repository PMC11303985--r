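#' Parameters of the synthetic seasonal forcing
#'
#' Independent sinusoidal annual cycles (365-day year, no leap days) for
#' water temperature, a dimensionless light factor, and external nutrient
#' load. The cycle is identical every year, so looped multi-year runs have
#' no interannual environmental variability. Each channel follows
#' `mean + amplitude * sin(2 * pi * (day - phase) / 365)`; at `day = phase`
#' the channel equals its mean and is rising.
#'
#' @param temperature List with `mean` (deg C), `amplitude` (deg C) and
#'   `phase` (day of year). The default peaks in late July.
#' @param light List with `mean`, `amplitude`, `phase`; clamped to \[0, 1\].
#' @param load List with `base` (g m^-3 d^-1), `amplitude` (g m^-3 d^-1)
#'   and `phase`; clamped at 0.
#' @param clamp_temperature If `TRUE`, temperature is floored at 0 deg C.
#' @return An object of class `"forcing_params"`.
#' @export
forcing_params <- function(temperature = list(mean = 10, amplitude = 9, phase = 112),
                           light = list(mean = 0.55, amplitude = 0.45, phase = 81),
                           load = list(base = 0.002, amplitude = 0, phase = 0),
                           clamp_temperature = FALSE) {
  chk <- function(x, nm, fields) {
    if (!is.list(x) || !all(fields %in% names(x)))
      stop(sprintf("`%s` must be a list with fields %s", nm,
                   paste(fields, collapse = ", ")), call. = FALSE)
    lapply(x[fields], as.numeric)
  }
  structure(list(
    temperature = chk(temperature, "temperature", c("mean", "amplitude", "phase")),
    light = chk(light, "light", c("mean", "amplitude", "phase")),
    load = chk(load, "load", c("base", "amplitude", "phase")),
    clamp_temperature = isTRUE(clamp_temperature)
  ), class = "forcing_params")
}

#' Seasonal forcing for a day of the year
#'
#' @param day Integer day(s) of the 365-day year, in \[1, 365\].
#' @param params A [forcing_params()].
#' @param load_scale Positive multiplier on the nutrient load; the scenario
#'   ladder uses 0.25, 0.5, 1, 2 and 4 times the baseline.
#' @return A data frame with columns `day`, `temperature` (deg C),
#'   `light_factor` in \[0, 1\] and `nutrient_load` (g m^-3 d^-1).
#' @examples
#' f <- forcing_params()
#' seasonal_forcing(c(1, 100, 200, 365), f)
#' @export
seasonal_forcing <- function(day, params = forcing_params(), load_scale = 1) {
  stopifnot(inherits(params, "forcing_params"))
  if (any(day < 1) || any(day > 365) || any(day != round(day)))
    stop("`day` must be an integer in [1, 365]", call. = FALSE)
  if (!is.numeric(load_scale) || load_scale <= 0)
    stop("`load_scale` must be > 0", call. = FALSE)
  ang <- function(phase) 2 * pi * (day - phase) / 365
  temp <- params$temperature$mean +
    params$temperature$amplitude * sin(ang(params$temperature$phase))
  if (params$clamp_temperature) temp <- pmax(temp, 0)
  light <- params$light$mean +
    params$light$amplitude * sin(ang(params$light$phase))
  light <- pmin(pmax(light, 0), 1)
  load <- pmax(params$load$base +
                 params$load$amplitude * sin(ang(params$load$phase)), 0) * load_scale
  data.frame(day = day, temperature = temp, light_factor = light,
             nutrient_load = load)
}

# Q10 temperature scaling of a reference rate (reference temperature 20 C)
.q10 <- function(temp, q10, t_ref = 20) q10^((temp - t_ref) / 10)

#' Temperature scaling of physiological rates
#'
#' Exponential Q10 scaling, `rate(T) = rate_ref * Q10^((T - T_ref) / 10)`,
#' with reference temperature 20 deg C.
#'
#' @param rate_ref Reference rate at 20 deg C.
#' @param temp Ambient temperature (deg C); vectorized.
#' @param q10 Q10 coefficient (default 2).
#' @return Scaled rate(s).
#' @export
temperature_scale <- function(rate_ref, temp, q10 = 2) {
  if (q10 <= 0) stop("`q10` must be > 0", call. = FALSE)
  rate_ref * .q10(temp, q10)
}
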