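# Psychrometric conversions: temperature / relative humidity / pressure of a
# moist gas sample -> water mole fraction, humid<->dry molar factors, dew point.
#
# Saturation vapor pressure uses the Arden Buck (1981) over-liquid-water form.
# The enhancement factor for moist air is omitted: it is <= 0.5% of es, far
# below the +/-0.003 accuracy of the molar-ratio method this feeds.

.buck_a <- 6.1121    # hPa
.buck_b <- 18.678
.buck_c <- 234.5     # degC
.buck_d <- 257.14    # degC

#' Saturation vapor pressure of water over liquid
#'
#' Arden Buck (1981) over-water formula,
#' \eqn{e_s(T) = 6.1121 \exp[(18.678 - T/234.5)\, T/(T + 257.14)]} hPa.
#'
#' @param temp_c Gas temperature in degrees Celsius; must lie in the
#'   sensor-plausible open interval (-20, 60).
#' @return Saturation vapor pressure in hPa. Strictly increasing in `temp_c`.
#' @examples
#' saturation_vapor_pressure(22.5)
#' @export
saturation_vapor_pressure <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  if (any(temp_c <= -20 | temp_c >= 60)) {
    stop("temp_c outside sensor-plausible range (-20, 60) degC", call. = FALSE)
  }
  .buck_a * exp((.buck_b - temp_c / .buck_c) * temp_c / (temp_c + .buck_d))
}

#' Psychrometric state of a gas sample
#'
#' Bundles the temperature, relative humidity and total pressure of a moist
#' gas sample (e.g. the gasbag contents or the exhalation line). These three
#' numbers determine the water mole fraction and hence every humid/dry
#' conversion in the package.
#'
#' @param temp_c Gas temperature, degrees Celsius, in (-20, 60).
#' @param rh Relative humidity as a fraction in \[0, 1\]. Values read from
#'   measurement files are in percent and converted at parse time.
#' @param pressure_hpa Total pressure in hPa, > 0.
#' @return An object of class `psychro_state`.
#' @examples
#' psychro_state(22.5, 0.925, 1002)
#' @export
psychro_state <- function(temp_c, rh, pressure_hpa) {
  stopifnot(length(temp_c) == 1L, length(rh) == 1L, length(pressure_hpa) == 1L)
  if (!is.finite(temp_c) || temp_c <= -20 || temp_c >= 60) {
    stop("temp_c outside sensor-plausible range (-20, 60) degC", call. = FALSE)
  }
  if (!is.finite(rh) || rh < 0 || rh > 1) {
    stop("rh must be a fraction in [0, 1] (convert percent at parse time)",
         call. = FALSE)
  }
  if (!is.finite(pressure_hpa) || pressure_hpa <= 0) {
    stop("pressure_hpa must be positive", call. = FALSE)
  }
  structure(list(temp_c = temp_c, rh = rh, pressure_hpa = pressure_hpa),
            class = "psychro_state")
}

#' A dry-gas psychrometric marker
#'
#' Convenience constructor for a state with zero humidity, for which every
#' humid/dry conversion is the identity.
#'
#' @param temp_c Gas temperature in degrees Celsius.
#' @param pressure_hpa Total pressure in hPa.
#' @return A `psychro_state` with `rh = 0`.
#' @export
dry_state <- function(temp_c = 20, pressure_hpa = 1013.25) {
  psychro_state(temp_c, 0, pressure_hpa)
}

#' @export
print.psychro_state <- function(x, ...) {
  cat(sprintf("<psychro_state> %.2f degC, RH %.1f%%, %.1f hPa (x_w = %.6f)\n",
              x$temp_c, 100 * x$rh, x$pressure_hpa, water_mole_fraction(x)))
  invisible(x)
}

#' Water mole fraction of a moist gas
#'
#' \eqn{x_w = \mathrm{rh} \cdot e_s(T) / P}: the fraction of all molecules in
#' the sample that are water vapor. This is the quantity a vaporized water
#' drop adds to a gasbag and the quantity removed when converting humid
#' readings to a dry-gas basis.
#'
#' @param state A [psychro_state()].
#' @return Fraction in \[0, 1); zero iff `rh = 0`.
#' @examples
#' water_mole_fraction(psychro_state(22.5, 0.925, 1002))
#' @export
water_mole_fraction <- function(state) {
  stopifnot(inherits(state, "psychro_state"))
  pw <- state$rh * saturation_vapor_pressure(state$temp_c)
  if (pw >= state$pressure_hpa) {
    stop("invalid psychrometric state: rh * es(T) >= total pressure",
         call. = FALSE)
  }
  pw / state$pressure_hpa
}

#' Humid-to-dry molar conversion factor
#'
#' The factor by which a molar quantity measured on a humid basis must be
#' multiplied to express it on a dry basis: \eqn{1/(1 - x_w)}. Always
#' \eqn{\ge 1}, with equality iff the gas is dry.
#'
#' @inheritParams water_mole_fraction
#' @return Dimensionless ratio \eqn{\ge 1}.
#' @examples
#' humid_to_dry_factor(psychro_state(22.5, 0.925, 1002))
#' @export
humid_to_dry_factor <- function(state) {
  1 / (1 - water_mole_fraction(state))
}

#' Dew point of a moist gas
#'
#' The temperature at which the sample's water vapor pressure saturates,
#' i.e. the solution of \eqn{e_s(T_d) = \mathrm{rh}\, e_s(T)}. Solved in
#' closed form: with \eqn{y = \ln(p_w / a)} the Buck formula inverts to the
#' quadratic \eqn{T^2/c + (y - b) T + y d = 0}, whose physical root is
#' \eqn{T_d = \tfrac{c}{2}\left[(b - y) - \sqrt{(b - y)^2 - 4 y d / c}\right]}.
#'
#' @inheritParams water_mole_fraction
#' @return Dew-point temperature in degrees Celsius; \eqn{T_d \le T}, with
#'   equality iff `rh = 1`.
#' @examples
#' dew_point(psychro_state(22.5, 0.925, 1002))
#' @export
dew_point <- function(state) {
  stopifnot(inherits(state, "psychro_state"))
  if (state$rh <= 0) {
    stop("dew point undefined for a perfectly dry gas (rh = 0)", call. = FALSE)
  }
  pw <- state$rh * saturation_vapor_pressure(state$temp_c)
  y <- log(pw / .buck_a)
  disc <- (.buck_b - y)^2 - 4 * y * .buck_d / .buck_c
  .buck_c / 2 * ((.buck_b - y) - sqrt(disc))
}
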