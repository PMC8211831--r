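# Raw sensor readings -> physically meaningful dry gas fractions.
#
# Correction order (each step uses already-physical quantities):
#   1. pressure standardization (sensors calibrated at ambient, read in a
#      circuit 10-15 mmHg above ambient; partial-pressure sensors over-read
#      by p_circuit/p_calib)
#   2. CO2/O2 cross-sensitivity fix, using the pressure-standardized O2
#   3. humid -> dry conversion of the exhaled fractions

HPA_PER_MMHG <- 1.333224

#' One averaged gas-concentration record
#'
#' @param o2_frac O2 fraction (0-1) as read by the sensor.
#' @param co2_frac CO2 fraction (0-1) as read.
#' @param p_calib_hpa Pressure at sensor calibration, hPa.
#' @param p_circuit_hpa In-circuit pressure during the measurement, hPa.
#' @param psychro A [psychro_state()] of the sampled gas, or `"dry"` for a
#'   dry-gas line (e.g. inspiratory limb).
#' @param timestamp_s Seconds from record start.
#' @return An object of class `gas_reading`.
#' @export
gas_reading <- function(o2_frac, co2_frac, p_calib_hpa, p_circuit_hpa,
                        psychro = "dry", timestamp_s = 0) {
  # raw partial-pressure readings taken above the calibration pressure can
  # exceed 1 (e.g. 100% O2 in a circuit 10-15 mmHg over ambient); the strict
  # [0, 1] and sum-to-1 contracts apply to the corrected fractions and are
  # enforced in correct_reading()
  stopifnot(o2_frac >= 0, o2_frac <= 1.2, co2_frac >= 0, co2_frac <= 0.25)
  if (o2_frac + co2_frac > 1.2) {
    stop("o2_frac + co2_frac implausibly large", call. = FALSE)
  }
  if (p_calib_hpa <= 0 || p_circuit_hpa <= 0) {
    stop("pressures must be positive", call. = FALSE)
  }
  if (!identical(psychro, "dry") && !inherits(psychro, "psychro_state")) {
    stop("psychro must be a psychro_state or the \"dry\" marker", call. = FALSE)
  }
  structure(list(o2_frac = o2_frac, co2_frac = co2_frac,
                 p_calib_hpa = p_calib_hpa, p_circuit_hpa = p_circuit_hpa,
                 psychro = psychro, timestamp_s = timestamp_s),
            class = "gas_reading")
}

#' Correct CO2 reading for O2 cross-sensitivity
#'
#' Infrared CO2 sensors under-read linearly as the O2 concentration rises.
#' The empirical correction is
#' \deqn{CO2 = CO2_{meas} / (1 - 0.00072 \times O2_{meas})}
#' with both operands in percent (the coefficient gives a 7.2% effect at
#' 100% O2). The corrected value is never below the measured one, with
#' equality only at zero O2.
#'
#' @param co2_measured_pct Measured CO2 in percent, within the sensor range
#'   \[0, 20\].
#' @param o2_measured_pct Measured O2 in percent, \[0, 100\].
#' @return Corrected CO2 in percent.
#' @examples
#' correct_co2_cross_sensitivity(4.0, 100) # 4.3103
#' @export
correct_co2_cross_sensitivity <- function(co2_measured_pct, o2_measured_pct) {
  # 1e-6 slack: pressure-standardizing a 100% O2 reading can land a few
  # ulp above 100
  if (any(o2_measured_pct < 0 | o2_measured_pct > 100 + 1e-6)) {
    stop("o2_measured_pct must be in [0, 100]", call. = FALSE)
  }
  o2_measured_pct <- pmin(o2_measured_pct, 100)
  if (any(co2_measured_pct < 0 | co2_measured_pct > 20)) {
    stop("co2_measured_pct outside sensor range [0, 20]", call. = FALSE)
  }
  co2_measured_pct / (1 - 0.00072 * o2_measured_pct)
}

#' Standardize a fraction reading to its calibration pressure
#'
#' Both gas sensors respond to partial pressure: a sensor calibrated at
#' ambient pressure but reading inside a circuit held 10-15 mmHg above
#' ambient over-reports the fraction by `p_circuit / p_calib`. The
#' standardized fraction is `frac_read * p_calib / p_circuit`; the identity
#' when the two pressures agree.
#'
#' @param frac_read Fraction as read (0-1 scale or percent, preserved).
#' @param p_calib_hpa Calibration pressure, hPa.
#' @param p_circuit_hpa In-circuit pressure during the reading, hPa.
#' @return Standardized fraction, same scale as the input.
#' @export
standardize_pressure <- function(frac_read, p_calib_hpa, p_circuit_hpa) {
  if (any(p_calib_hpa <= 0) || any(p_circuit_hpa <= 0)) {
    stop("pressures must be positive", call. = FALSE)
  }
  frac_read * p_calib_hpa / p_circuit_hpa
}

#' Convert a humid-basis fraction to a dry-gas basis
#'
#' Exhaled gas is measured water-saturated; metabolic equations use dry
#' fractions. `frac_dry = frac_wet / (1 - x_w)` where `x_w` is the water
#' mole fraction of the sample.
#'
#' @param frac_wet Fraction on the humid basis (0-1).
#' @param psychro A [psychro_state()] of the measured gas.
#' @return Dry-basis fraction, \eqn{\ge} the wet one.
#' @examples
#' wet_to_dry_fraction(0.16, psychro_state(22.5, 0.925, 1002))
#' @export
wet_to_dry_fraction <- function(frac_wet, psychro) {
  out <- frac_wet * humid_to_dry_factor(psychro)
  if (any(out > 1)) {
    stop("inconsistent inputs: dry fraction exceeds 1", call. = FALSE)
  }
  out
}

#' Interpolate dry FIO2 between pre- and post-measurement values
#'
#' The inspired O2 fraction is recorded on a dry circuit before and after
#' the expired-gas measurement; its time series in between is taken as the
#' linear interpolation of the two.
#'
#' @param pre_value Dry FIO2 before the measurement block.
#' @param post_value Dry FIO2 after it.
#' @param t_frac Position in the block as a fraction in \[0, 1\].
#' @return Interpolated FIO2.
#' @export
interpolate_fio2 <- function(pre_value, post_value, t_frac) {
  if (any(t_frac < 0 | t_frac > 1)) {
    stop("t_frac must lie in [0, 1]", call. = FALSE)
  }
  pre_value + (post_value - pre_value) * t_frac
}

#' Average a window of 1-s gas readings
#'
#' Data are logged every second; analysis uses the arithmetic mean of a
#' 60-s window of fractions and pressures.
#'
#' @param readings A non-empty list of [gas_reading()]s.
#' @param window_s Window length in seconds; readings whose timestamps fall
#'   in `[min(timestamp), min(timestamp) + window_s]` are averaged.
#' @return A single [gas_reading()] holding the window means; the psychro
#'   context of the first reading is carried through.
#' @export
average_window <- function(readings, window_s = 60) {
  if (length(readings) == 0L) stop("empty window", call. = FALSE)
  stopifnot(all(vapply(readings, inherits, logical(1), "gas_reading")))
  ts <- vapply(readings, `[[`, numeric(1), "timestamp_s")
  keep <- ts <= min(ts) + window_s
  sel <- readings[keep]
  m <- function(f) mean(vapply(sel, `[[`, numeric(1), f))
  gas_reading(o2_frac = m("o2_frac"), co2_frac = m("co2_frac"),
              p_calib_hpa = m("p_calib_hpa"), p_circuit_hpa = m("p_circuit_hpa"),
              psychro = sel[[1]]$psychro, timestamp_s = m("timestamp_s"))
}

#' Apply the full correction chain to one gas reading
#'
#' Pressure standardization, then the CO2/O2 cross-sensitivity fix (using
#' the pressure-standardized O2, in percent), then the humid-to-dry
#' conversion if the reading carries a psychrometric state.
#'
#' @param reading A [gas_reading()].
#' @return A list with dry-basis `o2_frac` and `co2_frac`.
#' @export
correct_reading <- function(reading) {
  stopifnot(inherits(reading, "gas_reading"))
  o2 <- standardize_pressure(reading$o2_frac, reading$p_calib_hpa,
                             reading$p_circuit_hpa)
  co2 <- standardize_pressure(reading$co2_frac, reading$p_calib_hpa,
                              reading$p_circuit_hpa)
  co2 <- correct_co2_cross_sensitivity(co2 * 100, o2 * 100) / 100
  if (inherits(reading$psychro, "psychro_state")) {
    o2 <- wet_to_dry_fraction(o2, reading$psychro)
    co2 <- wet_to_dry_fraction(co2, reading$psychro)
  }
  # percent-level overshoot of the sum is expected from sensor noise at
  # FIO2 1.0 (true dry fractions already sum to 1); only gross violations
  # indicate corrupted inputs
  if (o2 > 1 + 1e-6 || o2 + co2 > 1.02) {
    stop("corrected fractions exceed 1: inconsistent reading", call. = FALSE)
  }
  list(o2_frac = min(o2, 1), co2_frac = co2)
}

#' Read a time series of gas records from delimited text
#'
#' Expected columns: `t_s, o2_pct, co2_pct, p_circuit_mmhg_gauge,
#' p_ambient_hpa, temp_c, rh_pct`. Gauge pressure (mmHg above ambient) is
#' added to the ambient pressure at parse time (1 mmHg = 1.333224 hPa);
#' percent columns become fractions.
#'
#' @param path Path to a CSV file.
#' @param p_calib_hpa Calibration pressure in hPa (defaults to each row's
#'   ambient pressure, matching calibration at ambient).
#' @return A list of [gas_reading()]s.
#' @export
read_gas_timeseries <- function(path, p_calib_hpa = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "o2_pct", "co2_pct", "p_circuit_mmhg_gauge",
            "p_ambient_hpa", "temp_c", "rh_pct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("gas time-series file lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    pcal <- if (is.null(p_calib_hpa)) row$p_ambient_hpa else p_calib_hpa
    psy <- if (row$rh_pct > 0) {
      psychro_state(row$temp_c, row$rh_pct / 100,
                    row$p_ambient_hpa + row$p_circuit_mmhg_gauge * HPA_PER_MMHG)
    } else "dry"
    gas_reading(o2_frac = row$o2_pct / 100, co2_frac = row$co2_pct / 100,
                p_calib_hpa = pcal,
                p_circuit_hpa = row$p_ambient_hpa +
                  row$p_circuit_mmhg_gauge * HPA_PER_MMHG,
                psychro = psy, timestamp_s = row$t_s)
  })
}
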