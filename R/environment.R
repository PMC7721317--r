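## Diel environment curves and the stomatal gas-exchange model.

#' Skewed diel curve
#'
#' A 24-h-periodic, continuous curve that attains `v_min` exactly at hour
#' `t_min` and `v_max` exactly at hour `t_max`, and is monotone on each arc
#' between the two extremes. Implemented as a sine of a phase-warped clock:
#' a piecewise-linear phase map sends `t_min` to -pi/2 and `t_max` to +pi/2,
#' so the two arcs (typically of unequal length, hence the skew) each carry
#' half a sine period. Used for diel temperature and relative-humidity
#' profiles.
#'
#' @param t hour of day in `[0, 24)`; vectorized.
#' @param v_min,v_max extreme values (`v_min <= v_max`).
#' @param t_min,t_max hours at which the extremes are attained.
#' @param skew shape exponent applied to the within-arc clock. `1` gives a
#'   plain (phase-warped) sine; values below 1 make the curve leave each
#'   extreme quickly and plateau before the next one - the shape of
#'   measured diel temperature records, which warm fast after sunrise and
#'   cool fast after the afternoon peak.
#' @return numeric vector of curve values.
#' @export
skewed_diel_curve <- function(t, v_min, v_max, t_min = 5, t_max = 15,
                              skew = 1) {
  if (v_min > v_max) stop("v_min must not exceed v_max")
  if (skew <= 0) stop("skew must be positive")
  if (v_min == v_max) return(rep(v_min, length(t)))
  if ((t_min %% 24) == (t_max %% 24)) stop("t_min and t_max must differ")
  d1 <- (t_max - t_min) %% 24       # rising arc length
  d2 <- 24 - d1                     # falling arc length
  dt <- (t - t_min) %% 24
  phase <- ifelse(dt <= d1,
                  -pi / 2 + pi * (dt / d1)^skew,
                  pi / 2 + pi * ((dt - d1) / d2)^skew)
  v_min + (v_max - v_min) * (1 + sin(phase)) / 2
}

#' Diel light curve
#'
#' Gaussian light curve centered at solar noon with peak intensity `i_max`,
#' clamped to zero below the light-compensation point (default 30
#' umol m-2 s-1): since a Gaussian reaches zero only asymptotically,
#' intensities below the compensation point count as darkness. The Gaussian
#' width is chosen so that the above-compensation window is exactly
#' `daylength` hours wide.
#'
#' @param t hour of day; vectorized.
#' @param i_max peak photon flux in umol m-2 s-1 (must exceed
#'   `compensation`).
#' @param daylength length of the above-compensation window in hours.
#' @param compensation light-compensation point in umol m-2 s-1.
#' @param noon hour of solar noon.
#' @return photon flux in umol m-2 s-1 (0 at night).
#' @export
light_curve <- function(t, i_max = 250, daylength = 12, compensation = 30,
                        noon = 12) {
  if (i_max <= compensation)
    stop("i_max must exceed the light-compensation point (no daytime exists)")
  if (daylength <= 0 || daylength >= 24)
    stop("daylength must lie strictly between 0 and 24 hours")
  sigma <- (daylength / 2) / sqrt(2 * log(i_max / compensation))
  dt <- pmin(abs(t - noon), 24 - abs(t - noon))
  i <- i_max * exp(-dt^2 / (2 * sigma^2))
  ifelse(i < compensation, 0, i)
}

#' Diel environment profile
#'
#' Builds per-step temperature, relative humidity, light intensity and
#' day/night flags for a closed 24-h cycle. Temperature follows a skewed
#' diel curve with its maximum mid-afternoon and its minimum one hour
#' before sunrise; relative humidity is anti-phased with temperature.
#' Values are evaluated at step midpoints.
#'
#' @param n_steps number of time intervals (must divide 24; 24, 12, 6 or 4).
#' @param t_min,t_max daily temperature extremes in degrees C.
#' @param rh_min,rh_max daily relative-humidity extremes in `[0, 1]`.
#' @param i_max peak light intensity in umol m-2 s-1.
#' @param daylength photoperiod in hours.
#' @param compensation light-compensation point in umol m-2 s-1.
#' @param hour_t_max hour at which temperature peaks (default 15:00).
#' @param skew arc-shape exponent of [skewed_diel_curve()]; the default 0.5
#'   reproduces the fast post-sunrise warm-up and post-peak cool-down of
#'   measured diel records.
#' @return object of class `environment_profile`: data.frame with columns
#'   `step`, `hour` (midpoint), `T`, `RH`, `I`, `is_day`, plus attributes
#'   `step_hours` and the generating parameters.
#' @export
diel_environment <- function(n_steps = 24, t_min = 20, t_max = 30,
                             rh_min = 0.4, rh_max = 0.8, i_max = 250,
                             daylength = 12, compensation = 30,
                             hour_t_max = 15, skew = 0.5) {
  if (24 %% n_steps != 0)
    stop("n_steps must divide 24 (use 24, 12, 8, 6, 4, 3, 2 or 1)")
  if (rh_min < 0 || rh_max > 1 || rh_min > rh_max)
    stop("relative humidity extremes must satisfy 0 <= rh_min <= rh_max <= 1")
  step_hours <- 24 / n_steps
  noon <- 12
  sunrise <- noon - daylength / 2
  hour_t_min <- (sunrise - 1) %% 24
  hour <- (seq_len(n_steps) - 0.5) * step_hours
  Tv <- skewed_diel_curve(hour, t_min, t_max, hour_t_min, hour_t_max, skew)
  ## RH anti-phased with T: driest when hottest
  RHv <- skewed_diel_curve(hour, -rh_max, -rh_min, hour_t_min, hour_t_max, skew)
  RHv <- -RHv
  Iv <- light_curve(hour, i_max, daylength, compensation, noon)
  out <- data.frame(step = seq_len(n_steps), hour = hour, T = Tv, RH = RHv,
                    I = Iv, is_day = Iv >= compensation)
  structure(out, class = c("environment_profile", "data.frame"),
            step_hours = step_hours,
            params = list(t_min = t_min, t_max = t_max, rh_min = rh_min,
                          rh_max = rh_max, i_max = i_max,
                          daylength = daylength, compensation = compensation,
                          hour_t_max = hour_t_max, skew = skew))
}

#' Gas-exchange parameters for the linearized stomatal diffusion model
#'
#' @param c_atm atmospheric CO2 mole fraction in umol mol-1.
#' @param ci_ratio ratio of internal to atmospheric CO2 concentration,
#'   strictly in (0, 1).
#' @param diff_ratio H2O:CO2 diffusivity ratio through the stomata.
#' @param pressure atmospheric pressure in kPa.
#' @return object of class `gas_exchange_params`.
#' @export
gas_exchange_params <- function(c_atm = 400, ci_ratio = 0.7,
                                diff_ratio = 1.6, pressure = 101.325) {
  if (ci_ratio <= 0 || ci_ratio >= 1)
    stop("ci_ratio must lie strictly between 0 and 1")
  if (diff_ratio <= 0) stop("diff_ratio must be positive")
  structure(list(c_atm = c_atm, ci_ratio = ci_ratio,
                 diff_ratio = diff_ratio, pressure = pressure),
            class = "gas_exchange_params")
}

#' Saturation vapor pressure of water (Buck equation)
#'
#' `0.61121 * exp((18.678 - T/234.5) * (T / (257.14 + T)))` kPa; accurate
#' over 0-50 degrees C.
#'
#' @param temp_c air temperature in degrees C.
#' @return saturation vapor pressure in kPa.
#' @export
esat_buck <- function(temp_c) {
  0.61121 * exp((18.678 - temp_c / 234.5) * (temp_c / (257.14 + temp_c)))
}

#' Water cost of CO2 uptake through the stomata
#'
#' The linearized diffusion model: water vapor and CO2 share the stomatal
#' path, so the ratio of their fluxes equals the diffusivity ratio times the
#' ratio of their mole-fraction gradients,
#' \deqn{r = D \cdot \frac{e_{sat}(T)(1 - RH)/P}{c_{atm}(1 - c_i/c_a)}.}
#' `r` is the number of moles of water transpired per mole of CO2 taken up;
#' it increases with temperature (steeper vapor gradient) and decreases with
#' relative humidity.
#'
#' @param temp_c leaf/air temperature in degrees C; vectorized.
#' @param rh relative humidity in `[0, 1]`; vectorized.
#' @param gas a [gas_exchange_params()].
#' @param esat_fun saturation vapor pressure function (kPa), default
#'   [esat_buck()].
#' @return mol H2O per mol CO2.
#' @export
water_per_co2 <- function(temp_c, rh, gas = gas_exchange_params(),
                          esat_fun = esat_buck) {
  if (any(rh > 1) || any(rh < 0)) stop("rh must lie in [0, 1]")
  vap_grad <- esat_fun(temp_c) / gas$pressure * (1 - rh)
  co2_grad <- gas$c_atm * 1e-6 * (1 - gas$ci_ratio)
  gas$diff_ratio * vap_grad / co2_grad
}

#' Total diel transpirational water loss
#'
#' Integrates the per-step water cost of the CO2 uptake flux over the diel
#' cycle: `sum_t r(T_t, RH_t) * u_t * dt`, converted to mol m-2 day-1.
#' Linear in the uptake vector.
#'
#' @param co2_uptake per-step CO2 uptake flux in umol m-2 s-1 (nonnegative;
#'   net efflux carries no transpiration cost and is modelled as a separate
#'   reaction).
#' @param env an [diel_environment()] profile with matching `n_steps`.
#' @param gas a [gas_exchange_params()].
#' @return total water loss in mol m-2 day-1.
#' @export
total_water_loss <- function(co2_uptake, env, gas = gas_exchange_params()) {
  if (length(co2_uptake) != nrow(env))
    stop("co2_uptake must have one entry per environment step")
  if (any(co2_uptake < 0))
    stop("co2_uptake must be nonnegative (net CO2 efflux carries no ",
         "transpiration cost in this model)")
  r <- water_per_co2(env$T, env$RH, gas)
  step_seconds <- attr(env, "step_hours") * 3600
  sum(r * co2_uptake * step_seconds) * 1e-6
}
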