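# Mass-balance gas-exchange simulator for a ventilated subject.
#
# The forward model books molecules, not volumes: inspired dry gas VI (STPD
# mL/min) carries VI*FIO2 of O2; the subject removes vo2_total of O2 and adds
# vco2 of CO2; an optional net N2 flux dn2 closes or breaks the Haldane
# assumption. O2 uptake has a mitochondrial (CO2-producing) component plus
# two non-CO2-producing sinks: an enzymatic (cytochrome-P450-like) term
# proportional to FIO2 and a cutaneous-diffusion term proportional to
# max(0, FIO2 - 0.21). Both make VO2 rise with FIO2 while VCO2 stays put —
# the qualitative signature the method is built to detect.

#' Ground-truth parameters of a simulated ventilated subject
#'
#' @param mass_kg Body mass, kg.
#' @param fio2 Inspired dry O2 fraction, in \[0.21, 1\].
#' @param mvv_ml_min Inspired dry minute volume at STPD, mL/min.
#' @param vo2_mito_ml_kg_min Mitochondrial (CO2-producing) O2 uptake,
#'   mL/kg/min STPD.
#' @param rq_tissue Tissue respiratory quotient of the mitochondrial
#'   component; VCO2 = rq_tissue * vo2_mito.
#' @param k_p450_ml_kg_min Non-CO2-producing enzymatic O2 sink; consumes
#'   `k_p450 * fio2` mL/kg/min.
#' @param k_skin_ml_kg_min Cutaneous diffusive O2 loss; consumes
#'   `k_skin * max(0, fio2 - 0.21)` mL/kg/min.
#' @param dn2_ml_min Net N2 imbalance added to expiration (0 = the
#'   Haldane-consistent, N2-conserving world).
#' @param body_temp_c Core temperature, degC.
#' @param exhalation_rh Relative humidity of exhalation at the (ambient
#'   temperature) measurement points, fraction; circuits equilibrate to
#'   roughly 0.90-0.93 at room temperature.
#' @return An object of class `virtual_subject`.
#' @export
virtual_subject <- function(mass_kg = 0.45, fio2 = 0.3, mvv_ml_min = 180,
                            vo2_mito_ml_kg_min = 13, rq_tissue = 0.9,
                            k_p450_ml_kg_min = 0, k_skin_ml_kg_min = 0,
                            dn2_ml_min = 0, body_temp_c = 37,
                            exhalation_rh = 0.92) {
  if (fio2 < 0.21 || fio2 > 1) stop("fio2 must lie in [0.21, 1]",
                                    call. = FALSE)
  rates <- c(vo2_mito_ml_kg_min, k_p450_ml_kg_min, k_skin_ml_kg_min)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  stopifnot(mass_kg > 0, mvv_ml_min > 0, rq_tissue >= 0,
            exhalation_rh >= 0, exhalation_rh <= 1)
  structure(list(mass_kg = mass_kg, fio2 = fio2, mvv_ml_min = mvv_ml_min,
                 vo2_mito_ml_kg_min = vo2_mito_ml_kg_min,
                 rq_tissue = rq_tissue,
                 k_p450_ml_kg_min = k_p450_ml_kg_min,
                 k_skin_ml_kg_min = k_skin_ml_kg_min,
                 dn2_ml_min = dn2_ml_min, body_temp_c = body_temp_c,
                 exhalation_rh = exhalation_rh),
            class = "virtual_subject")
}

#' Noiseless gas state of a virtual subject
#'
#' Solves the dry STPD mass balance:
#' \preformatted{
#'   vo2_total = mass * (vo2_mito + k_p450*fio2 + k_skin*max(0, fio2-0.21))
#'   vco2      = mass * rq_tissue * vo2_mito
#'   VE        = VI - vo2_total + vco2 + dn2
#'   FEO2      = (VI*fio2 - vo2_total) / VE ;  FECO2 = vco2 / VE
#'   R_dry     = VI / VE
#' }
#' With `dn2 = 0` nitrogen is conserved and `R_dry` equals the Haldane
#' estimate from its own expired fractions.
#'
#' @param subject A [virtual_subject()].
#' @return A list: `vi_ml_min`, `ve_dry_ml_min`, `vo2_total_ml_min`,
#'   `vco2_ml_min`, `feo2_dry`, `feco2_dry`, `r_dry`, and per-kg
#'   `vo2_ml_kg_min`, `vco2_ml_kg_min`, `rq`.
#' @export
forward_model <- function(subject) {
  stopifnot(inherits(subject, "virtual_subject"))
  vi <- subject$mvv_ml_min
  vo2_total <- subject$mass_kg *
    (subject$vo2_mito_ml_kg_min +
     subject$k_p450_ml_kg_min * subject$fio2 +
     subject$k_skin_ml_kg_min * max(0, subject$fio2 - 0.21))
  vco2 <- subject$mass_kg * subject$rq_tissue * subject$vo2_mito_ml_kg_min
  ve <- vi - vo2_total + vco2 + subject$dn2_ml_min
  if (ve <= 0) stop("infeasible subject: VE_dry <= 0", call. = FALSE)
  feo2 <- (vi * subject$fio2 - vo2_total) / ve
  feco2 <- vco2 / ve
  # at fio2 = 1 with dn2 = 0 the expired dry gas is exactly O2 + CO2, so
  # the fractions legitimately sum to 1; only a physically negative N2
  # content (sum > 1) is infeasible
  if (feo2 <= 0 || feo2 > 1 || feco2 >= 1 || feo2 + feco2 > 1 + 1e-9) {
    stop("infeasible subject: expired fractions outside (0, 1)",
         call. = FALSE)
  }
  list(vi_ml_min = vi, ve_dry_ml_min = ve, vo2_total_ml_min = vo2_total,
       vco2_ml_min = vco2, feo2_dry = feo2, feco2_dry = feco2,
       r_dry = vi / ve,
       vo2_ml_kg_min = vo2_total / subject$mass_kg,
       vco2_ml_kg_min = vco2 / subject$mass_kg,
       rq = vco2 / vo2_total)
}

#' Simulate one full measurement of a virtual subject
#'
#' Applies the forward sensor distortions in exactly the order the analysis
#' pipeline inverts them: exhaled fractions humidified to the measurement
#' line's psychrometric state, CO2 reading distorted by the inverse
#' O2-cross-sensitivity law, both readings inflated by the in-circuit /
#' calibration pressure ratio, then independent multiplicative Gaussian
#' noise on the expired O2 reading and on the pump-out time ti (te is a
#' controlled 600 s). The expired volume is reported as the humid
#' ambient-condition reading of the true dry STPD VE.
#'
#' @param subject A [virtual_subject()].
#' @param model An [error_model()]; its sigmas set the noise (use zeros for
#'   a noiseless measurement). Its `seed` is ignored here — pass `seed`.
#' @param seed Integer RNG seed for this measurement.
#' @param ambient_temp_c,ambient_pressure_hpa Room conditions to which the
#'   gasbag equilibrates.
#' @param p_circuit_offset_mmhg In-circuit pressure above ambient, mmHg.
#' @param te_s Controlled gas-collection time, seconds.
#' @return An object of class `simulated_measurement`: the [gas_reading()]s,
#'   [bag_timing()], psychrometric states and measured VE that
#'   [full_pipeline()] consumes, plus `truth` (the [forward_model()] output)
#'   and `seed`.
#' @export
simulate_measurement <- function(subject, model = error_model(0, 0),
                                 seed = 1L,
                                 ambient_temp_c = 22.8,
                                 ambient_pressure_hpa = 1008,
                                 p_circuit_offset_mmhg = 12,
                                 te_s = 600) {
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(model, "error_model"))
  truth <- forward_model(subject)
  set.seed(as.integer(seed))

  line <- psychro_state(ambient_temp_c, subject$exhalation_rh,
                        ambient_pressure_hpa)
  xw <- water_mole_fraction(line)
  p_circ <- ambient_pressure_hpa + p_circuit_offset_mmhg * HPA_PER_MMHG

  # humid bag ratio and timing; noise enters through ti only
  r_humid <- truth$r_dry * (1 - xw)
  ti <- te_s / r_humid * (1 + stats::rnorm(1, 0, model$sigma_r_rel))
  timing <- bag_timing(te_s = te_s, ti_s = ti)

  # expired reading: humidify -> inverse cross-sensitivity -> pressure
  # inflation -> sensor noise (expired O2 only)
  feo2_wet <- truth$feo2_dry * (1 - xw)
  feco2_wet <- truth$feco2_dry * (1 - xw)
  o2_std_pct <- feo2_wet * 100
  feco2_meas <- (feco2_wet * (1 - 0.00072 * o2_std_pct))
  exhale <- gas_reading(
    o2_frac = feo2_wet * (p_circ / ambient_pressure_hpa) *
      (1 + stats::rnorm(1, 0, model$sigma_o2_rel)),
    co2_frac = feco2_meas * (p_circ / ambient_pressure_hpa),
    p_calib_hpa = ambient_pressure_hpa, p_circuit_hpa = p_circ,
    psychro = line)

  # inspired reading: dry calibrated supply, same pressure inflation
  inhale <- gas_reading(
    o2_frac = subject$fio2 * (p_circ / ambient_pressure_hpa),
    co2_frac = 0,
    p_calib_hpa = ambient_pressure_hpa, p_circuit_hpa = p_circ,
    psychro = "dry")

  # water-displacement VE: humid, at ambient conditions
  ve_measured <- truth$ve_dry_ml_min /
    ((1 - xw) * (ambient_pressure_hpa / 1013.25) *
     (273.15 / (273.15 + ambient_temp_c)))

  structure(list(inhale = inhale, exhale = exhale, timing = timing,
                 bag_psychro = line, ve_measured_ml_min = ve_measured,
                 ve_psychro = line,
                 setting = ventilation_setting(mvv_ml_min = subject$mvv_ml_min,
                                               mass_kg = subject$mass_kg),
                 truth = truth, subject = subject, seed = as.integer(seed)),
            class = "simulated_measurement")
}

#' Run the analysis pipeline on a simulated measurement
#'
#' Convenience wrapper passing the measurement's components to
#' [full_pipeline()].
#'
#' @param m A `simulated_measurement`.
#' @return A `metabolic_result`.
#' @export
recover_measurement <- function(m) {
  stopifnot(inherits(m, "simulated_measurement"))
  full_pipeline(m$inhale, m$exhale, m$timing, m$bag_psychro,
                m$ve_measured_ml_min, m$ve_psychro, m$setting)
}

#' Default 2x2 cohort configuration
#'
#' Four groups of six mirroring the anesthetic-by-FIO2 design: `a`/`b`
#' intravenous-anesthetic animals at FIO2 0.3/1.0 with the O2-dependent
#' uptake attributed to the enzymatic sink, `c`/`d` volatile-anesthetic
#' animals with it attributed to the cutaneous sink. Sink slopes and
#' mitochondrial rates are chosen so the group-mean recovered VO2 land at
#' 15.4/21.0 (groups a/b) and 15.4/17.2 (c/d) mL/kg/min with VCO2 near
#' 12.1-12.5, and per-animal dn2 places the dry molar ratio at the
#' reference group means (~1.007-1.011).
#'
#' @param n_per_group Animals per group.
#' @return A list of group configurations for [generate_cohort()].
#' @export
cohort_preset_2x2 <- function(n_per_group = 6) {
  base <- list(
    list(label = "a", fio2 = 0.3, vo2_mito = 13.0, rq_tissue = 0.946,
         k_p450 = 8.0, k_skin = 0, r_target_mean = 1.0072),
    list(label = "b", fio2 = 1.0, vo2_mito = 13.0, rq_tissue = 0.946,
         k_p450 = 8.0, k_skin = 0, r_target_mean = 1.0076),
    list(label = "c", fio2 = 0.3, vo2_mito = 15.17, rq_tissue = 0.801,
         k_p450 = 0, k_skin = 2.571, r_target_mean = 1.0089),
    list(label = "d", fio2 = 1.0, vo2_mito = 15.17, rq_tissue = 0.801,
         k_p450 = 0, k_skin = 2.571, r_target_mean = 1.0108)
  )
  lapply(base, function(g) {
    g$n <- n_per_group
    g$vo2_cv <- 0.07
    g$r_target_sd <- 0.0015
    g
  })
}

#' Generate a synthetic measurement cohort
#'
#' Draws per-animal parameters for each configured group, simulates each
#' measurement at the group's noise level, and tabulates the results in the
#' measurement-table schema extended with ground truth. Infeasible
#' parameter draws are resampled (configuration error after 1000
#' rejections).
#'
#' @param config List of group configurations (see [cohort_preset_2x2()]);
#'   each needs `label`, `n`, `fio2`, `vo2_mito`, `vo2_cv`, `rq_tissue`,
#'   `k_p450`, `k_skin`, and either `r_target_mean`/`r_target_sd` (dn2 set
#'   per animal to land the dry ratio there) or `dn2` (fixed, default 0).
#' @param seed Integer seed; the whole table is reproducible from it.
#' @param noise An [error_model()] giving per-measurement sensor noise.
#' @return A data.frame: `group, r_test_lung, r_humid, pressure_hpa, temp_c,
#'   rh_pct, true_vo2, true_vco2, true_rq, seed` plus recovered
#'   `vo2_ml_kg_min, vco2_ml_kg_min, rq, r_dry_recovered`.
#' @export
generate_cohort <- function(config = cohort_preset_2x2(), seed = 20210617,
                            noise = error_model(0.003, 0.002)) {
  set.seed(as.integer(seed))
  rows <- list()
  reject <- 0L
  for (g in config) {
    n <- g$n %||% 0L
    if (n == 0L) next
    for (i in seq_len(n)) {
      repeat {
        if (reject > 1000L) {
          stop("cohort config rejected > 1000 infeasible draws",
               call. = FALSE)
        }
        mass <- stats::runif(1, 0.40, 0.50)
        vo2_mito <- g$vo2_mito * (1 + stats::rnorm(1, 0, g$vo2_cv %||% 0))
        temp_c <- stats::runif(1, 22.4, 23.5)
        rh <- stats::runif(1, 0.895, 0.925)
        press <- stats::runif(1, 995, 1025)
        sub <- try(virtual_subject(
          mass_kg = mass, fio2 = g$fio2, mvv_ml_min = 180,
          vo2_mito_ml_kg_min = max(vo2_mito, 0.1),
          rq_tissue = g$rq_tissue,
          k_p450_ml_kg_min = g$k_p450, k_skin_ml_kg_min = g$k_skin,
          exhalation_rh = rh), silent = TRUE)
        if (!inherits(sub, "try-error")) {
          if (!is.null(g$r_target_mean)) {
            r_target <- stats::rnorm(1, g$r_target_mean,
                                     g$r_target_sd %||% 0)
            # dn2 solving VI/VE = r_target given the subject's vo2/vco2
            fm0 <- try(forward_model(sub), silent = TRUE)
            if (inherits(fm0, "try-error")) { reject <- reject + 1L; next }
            ve_target <- sub$mvv_ml_min / r_target
            sub$dn2_ml_min <- ve_target - sub$mvv_ml_min +
              fm0$vo2_total_ml_min - fm0$vco2_ml_min
          } else {
            sub$dn2_ml_min <- g$dn2 %||% 0
          }
          fm <- try(forward_model(sub), silent = TRUE)
          if (!inherits(fm, "try-error")) break
        }
        reject <- reject + 1L
      }
      mseed <- sample.int(.Machine$integer.max, 1)
      m <- simulate_measurement(sub, model = noise, seed = mseed,
                                ambient_temp_c = temp_c,
                                ambient_pressure_hpa = press)
      rec <- recover_measurement(m)
      r_test_lung <- 1 + stats::rnorm(1, 0, noise$sigma_r_rel)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$label, r_test_lung = r_test_lung,
        r_humid = ratio_from_timing(m$timing),
        pressure_hpa = press, temp_c = temp_c, rh_pct = 100 * rh,
        true_vo2 = fm$vo2_ml_kg_min, true_vco2 = fm$vco2_ml_kg_min,
        true_rq = fm$rq, seed = mseed,
        vo2_ml_kg_min = rec$vo2_ml_kg_min,
        vco2_ml_kg_min = rec$vco2_ml_kg_min,
        rq = rec$rq, r_dry_recovered = rec$r)
    }
  }
  if (!length(rows)) {
    return(data.frame(group = character(), r_test_lung = numeric(),
                      r_humid = numeric(), pressure_hpa = numeric(),
                      temp_c = numeric(), rh_pct = numeric(),
                      true_vo2 = numeric(), true_vco2 = numeric(),
                      true_rq = numeric(), seed = integer(),
                      vo2_ml_kg_min = numeric(), vco2_ml_kg_min = numeric(),
                      rq = numeric(), r_dry_recovered = numeric()))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
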