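# Propagation of independent sensor errors through the VO2 equation.
#
# The O2 sensor's random error (+/-0.2% of reading, 21-100% range) and the
# molar-ratio error (+/-0.3%) are independent. To first order, for
# VO2 = (R*FIO2 - FEO2)*VE with VE constant and FIO2 fixed by the calibrated
# supply gas, the relative VO2 error is
#   sqrt((sR * R*FIO2)^2 + (sO2 * FEO2)^2) / (R*FIO2 - FEO2)
# i.e. absolute errors of the two near-unity operands in quadrature over the
# small extraction difference. "+/- x%" is interpreted as a 1-sigma relative
# error; a Monte Carlo route checks the delta-method answer.

#' Sensor error model
#'
#' @param sigma_r_rel 1-sigma relative error of the molar ratio R
#'   (0.003 for the method's stated +/-0.3%).
#' @param sigma_o2_rel 1-sigma relative error of the expired O2 reading
#'   (0.002 for +/-0.2%).
#' @param n_draws Monte Carlo sample count.
#' @param seed RNG seed for the Monte Carlo route.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sigma_r_rel = 0.003, sigma_o2_rel = 0.002,
                        n_draws = 1e5, seed = 20210617) {
  if (sigma_r_rel < 0 || sigma_o2_rel < 0) {
    stop("sigmas must be non-negative", call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(sigma_r_rel = sigma_r_rel, sigma_o2_rel = sigma_o2_rel,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "error_model")
}

#' First-order relative error of VO2
#'
#' Delta-method quadrature of the independent R and expired-O2 errors:
#' `sqrt((sR * r * fio2)^2 + (sO2 * feo2)^2) / (r * fio2 - feo2)`.
#' The denominator is the O2 extraction; because both operands are near 1
#' while the extraction is ~0.04-0.05, percent-level sensor errors inflate
#' to several percent of VO2, and more so at high FIO2 where the `sR*r*fio2`
#' term is largest.
#'
#' @param r Molar ratio VI/VE.
#' @param fio2,feo2 Dry O2 fractions, with `r * fio2 > feo2`.
#' @param model An [error_model()].
#' @return Relative (fractional) 1-sigma error of VO2.
#' @examples
#' error_model(0.003, 0.002) |> analytic_vo2_relative_error(1.0092, 1.0, 1.0092 - 0.048)
#' @export
analytic_vo2_relative_error <- function(model, r, fio2, feo2) {
  stopifnot(inherits(model, "error_model"))
  extraction <- r * fio2 - feo2
  if (extraction <= 0) {
    stop("degenerate operating point: r * fio2 <= feo2", call. = FALSE)
  }
  sqrt((model$sigma_r_rel * r * fio2)^2 +
       (model$sigma_o2_rel * feo2)^2) / extraction
}

#' Monte Carlo relative error of VO2
#'
#' Draws independent multiplicative Gaussian perturbations of R and of the
#' expired O2 reading, recomputes `VO2 = (R*FIO2 - FEO2)*VE` for each draw,
#' and summarizes the relative spread. Reproducible for a given seed.
#'
#' @inheritParams analytic_vo2_relative_error
#' @param ve Expired minute volume (any unit; cancels in relative terms).
#' @return A list: `mean_rel` (mean relative deviation from the noiseless
#'   VO2), `sd_rel` (relative SD), `ci95_half_rel` (half-width of the
#'   central 95% interval, relative), `n_draws`, `seed`, and `low_n`
#'   (warning flag, TRUE when `n_draws < 100`).
#' @export
monte_carlo_vo2_error <- function(model, r, fio2, feo2, ve = 180) {
  stopifnot(inherits(model, "error_model"))
  v0 <- (r * fio2 - feo2) * ve
  if (v0 <= 0) stop("degenerate operating point", call. = FALSE)
  set.seed(model$seed)
  rs <- r * (1 + stats::rnorm(model$n_draws, 0, model$sigma_r_rel))
  fes <- feo2 * (1 + stats::rnorm(model$n_draws, 0, model$sigma_o2_rel))
  v <- (rs * fio2 - fes) * ve
  rel <- v / v0 - 1
  qs <- stats::quantile(rel, c(0.025, 0.975), names = FALSE)
  list(mean_rel = mean(rel), sd_rel = stats::sd(rel),
       ci95_half_rel = diff(qs) / 2,
       n_draws = model$n_draws, seed = model$seed,
       low_n = model$n_draws < 100)
}

#' Relative VO2 error across an FIO2 grid
#'
#' Evaluates the analytic error at fixed O2 extraction and fixed relative
#' sigmas across inspired O2 levels. At matched extraction the error is
#' non-decreasing in FIO2: the `sigma_R * R * FIO2` numerator term grows
#' with FIO2 while the denominator stays fixed.
#'
#' @param model An [error_model()].
#' @param fio2_grid Vector of inspired O2 fractions.
#' @param extraction O2 extraction `r*fio2 - feo2` (fraction), > 0.
#' @param r Molar ratio used at every grid point.
#' @return A data.frame: `fio2, extraction, feo2, analytic_rel_err`.
#' @export
error_vs_fio2_profile <- function(model, fio2_grid = c(0.3, 0.6, 1.0),
                                  extraction = 0.048, r = 1.009) {
  stopifnot(inherits(model, "error_model"), extraction > 0)
  if (any(fio2_grid * r <= extraction)) {
    stop("grid contains fio2 with r*fio2 <= extraction (feo2 would be <= 0)",
         call. = FALSE)
  }
  feo2 <- r * fio2_grid - extraction
  err <- vapply(seq_along(fio2_grid), function(i) {
    analytic_vo2_relative_error(model, r, fio2_grid[i], feo2[i])
  }, numeric(1))
  data.frame(fio2 = fio2_grid, extraction = extraction, feo2 = feo2,
             analytic_rel_err = err)
}
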