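# Metabolic rates from dry gas fractions and the measured molar ratio.
#
# With R = VI/VE measured directly (not assumed 1, not Haldane-estimated):
#   VO2  = (R * FIO2 - FEO2) * VE
#   VCO2 = FECO2 * VE                     (inspired gas carries no CO2)
#   RQ   = VCO2 / VO2
# All fractions are dry-basis after gas_corrections; VE is the dry expired
# minute volume at STPD (273.15 K, 1013.25 hPa, dry).

#' Ventilator settings for one subject
#'
#' @param mvv_ml_min Minute ventilation volume set on the ventilator, mL/min.
#' @param rr_per_min Respiratory rate, breaths/min.
#' @param peep_cmH2O Positive end-expiratory pressure, cmH2O.
#' @param mass_kg Subject mass, kg.
#' @return An object of class `ventilation_setting`.
#' @export
ventilation_setting <- function(mvv_ml_min = 180, rr_per_min = 45,
                                peep_cmH2O = 2, mass_kg = 0.45) {
  vals <- c(mvv_ml_min, rr_per_min, peep_cmH2O, mass_kg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ventilation settings must be positive", call. = FALSE)
  }
  structure(list(mvv_ml_min = mvv_ml_min, rr_per_min = rr_per_min,
                 peep_cmH2O = peep_cmH2O, mass_kg = mass_kg),
            class = "ventilation_setting")
}

#' Oxygen consumption from the measured molar ratio
#'
#' `VO2 = (R * FIO2 - FEO2) * VE`. Because R multiplies FIO2 directly, the
#' equation stays well-posed at FIO2 1.0, where the Haldane transformation
#' is singular.
#'
#' @param r Measured dry molar ratio VI/VE, physiologically in (0.9, 1.1).
#' @param fio2,feo2 Dry inspired/expired O2 fractions in \[0, 1\].
#' @param ve_stpd Dry expired minute volume at STPD (any volume unit).
#' @return VO2 in the units of `ve_stpd`.
#' @examples
#' vo2(1.0, 0.21, 0.16, 400)
#' @export
vo2 <- function(r, fio2, feo2, ve_stpd) {
  stopifnot(fio2 >= 0, fio2 <= 1, feo2 >= 0, feo2 <= 1)
  if (r <= 0.9 || r >= 1.1) {
    stop("molar ratio outside the physiological band (0.9, 1.1)",
         call. = FALSE)
  }
  if (r * fio2 <= feo2) {
    stop("nonpositive O2 uptake: r * fio2 <= feo2 (inconsistent inputs)",
         call. = FALSE)
  }
  (r * fio2 - feo2) * ve_stpd
}

#' Carbon dioxide production
#'
#' `VCO2 = VE * FECO2 - VI * FICO2`; with CO2-free inspired gas
#' (`fico2 = 0`) this is `FECO2 * VE`.
#'
#' @param feco2 Dry expired CO2 fraction.
#' @param ve_stpd Dry expired minute volume at STPD.
#' @param fico2 Dry inspired CO2 fraction (0 for CO2-free supply gas).
#' @param vi_stpd Dry inspired minute volume at STPD; only used when
#'   `fico2 > 0`.
#' @return VCO2 in the units of `ve_stpd`.
#' @export
vco2 <- function(feco2, ve_stpd, fico2 = 0, vi_stpd = NULL) {
  stopifnot(feco2 >= 0, feco2 <= 1, fico2 >= 0, fico2 <= 1)
  inspired <- if (fico2 > 0) {
    if (is.null(vi_stpd)) {
      stop("vi_stpd required when fico2 > 0", call. = FALSE)
    }
    vi_stpd * fico2
  } else 0
  out <- ve_stpd * feco2 - inspired
  if (out < 0) stop("negative VCO2: inconsistent inputs", call. = FALSE)
  out
}

#' Respiratory quotient
#'
#' @param vco2 CO2 production rate.
#' @param vo2 O2 consumption rate, > 0, same units.
#' @return Dimensionless RQ = VCO2/VO2.
#' @export
rq <- function(vco2, vo2) {
  if (any(vo2 <= 0)) stop("vo2 must be positive", call. = FALSE)
  vco2 / vo2
}

#' Haldane-transformation estimate of VI/VE
#'
#' Under nitrogen conservation, `VI/VE = FEN2/FIN2 =
#' (1 - FEO2 - FECO2)/(1 - FIO2)`. The denominator vanishes at FIO2 1.0 —
#' the singularity that motivates measuring R directly.
#'
#' @param fio2,feo2,feco2 Dry gas fractions; `fio2 < 1`.
#' @return Predicted dimensionless VI/VE.
#' @examples
#' haldane_ratio(0.21, 0.16, 0.045) # 1.006
#' @export
haldane_ratio <- function(fio2, feo2, feco2) {
  if (any(fio2 >= 1)) {
    stop("Haldane transformation undefined at fio2 >= 1 (denominator 0)",
         call. = FALSE)
  }
  (1 - feo2 - feco2) / (1 - fio2)
}

#' Convert a measured expired volume to dry STPD
#'
#' The water-displacement volume measurement is taken humid at ambient
#' temperature and pressure. Dry STPD volume is
#' `ve * (1 - x_w) * (P / 1013.25) * (273.15 / (273.15 + T))`.
#'
#' @param ve_measured_ml_min Expired minute volume as measured, mL/min.
#' @param psychro [psychro_state()] of the measured gas.
#' @return Dry STPD volume rate, mL/min.
#' @export
ve_to_stpd <- function(ve_measured_ml_min, psychro) {
  xw <- water_mole_fraction(psychro)
  ve_measured_ml_min * (1 - xw) * (psychro$pressure_hpa / 1013.25) *
    (273.15 / (273.15 + psychro$temp_c))
}

#' Normalize a rate by body mass
#'
#' @param rate_ml_min Rate in mL/min.
#' @param mass_kg Subject mass in kg, > 0.
#' @return Rate in mL/kg/min.
#' @export
per_kg <- function(rate_ml_min, mass_kg) {
  if (any(mass_kg <= 0)) stop("mass_kg must be positive", call. = FALSE)
  rate_ml_min / mass_kg
}

#' Full measurement-to-metabolism pipeline
#'
#' Runs the complete inversion chain on one measurement: sensor corrections
#' on the inspired and expired readings (pressure standardization, CO2
#' cross-sensitivity, humid-to-dry), bag timing to humid R to dry R,
#' measured VE to dry STPD, then VO2, VCO2, RQ with per-kg
#' normalization. Any stage failure aborts with the stage name.
#'
#' @param inhale [gas_reading()] of the inspired gas (dry line).
#' @param exhale [gas_reading()] of the expired gas with its exhalation-line
#'   psychrometric state.
#' @param timing [bag_timing()].
#' @param bag_psychro [psychro_state()] of the gasbag contents (for the
#'   humid-to-dry ratio correction).
#' @param ve_measured_ml_min Expired minute volume as measured by water
#'   displacement, mL/min.
#' @param ve_psychro [psychro_state()] of the gas during the volume
#'   measurement.
#' @param setting [ventilation_setting()] (mass for per-kg normalization).
#' @return An object of class `metabolic_result`: fields `r`,
#'   `ve_stpd_ml_min`, `vi_stpd_ml_min`, `vo2_ml_kg_min`, `vco2_ml_kg_min`,
#'   `rq`, plus the dry fractions used.
#' @export
full_pipeline <- function(inhale, exhale, timing, bag_psychro,
                          ve_measured_ml_min, ve_psychro, setting) {
  stopifnot(inherits(setting, "ventilation_setting"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  insp <- stage("gas_corrections", correct_reading(inhale))
  exp_ <- stage("gas_corrections", correct_reading(exhale))
  r_humid <- stage("molar_ratio", ratio_from_timing(timing))
  r_dry <- stage("molar_ratio", dry_ratio(r_humid, bag_psychro))
  ve_stpd <- stage("stpd", ve_to_stpd(ve_measured_ml_min, ve_psychro))
  vo2_abs <- stage("metabolism", vo2(r_dry, insp$o2_frac, exp_$o2_frac,
                                     ve_stpd))
  vco2_abs <- stage("metabolism", vco2(exp_$co2_frac, ve_stpd,
                                       fico2 = insp$co2_frac,
                                       vi_stpd = r_dry * ve_stpd))
  structure(list(
    r = r_dry,
    ve_stpd_ml_min = ve_stpd,
    vi_stpd_ml_min = r_dry * ve_stpd,
    vo2_ml_kg_min = per_kg(vo2_abs, setting$mass_kg),
    vco2_ml_kg_min = per_kg(vco2_abs, setting$mass_kg),
    rq = rq(vco2_abs, vo2_abs),
    fio2_dry = insp$o2_frac, feo2_dry = exp_$o2_frac,
    feco2_dry = exp_$co2_frac
  ), class = "metabolic_result")
}

#' @export
print.metabolic_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<metabolic_result>\n",
    "  R (VI/VE, dry)   %.5f\n",
    "  VE STPD          %.2f mL/min\n",
    "  VO2              %.2f mL/kg/min\n",
    "  VCO2             %.2f mL/kg/min\n",
    "  RQ               %.3f\n"),
    x$r, x$ve_stpd_ml_min, x$vo2_ml_kg_min, x$vco2_ml_kg_min, x$rq))
  invisible(x)
}
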