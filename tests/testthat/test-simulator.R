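test_that("forward model limits: test lung and mole-conserving exchange", {
  lung <- virtual_subject(fio2 = 0.3, vo2_mito_ml_kg_min = 0, rq_tissue = 0)
  fm <- forward_model(lung)
  expect_equal(fm$feo2_dry, 0.3)
  expect_equal(fm$feco2_dry, 0)
  expect_equal(fm$r_dry, 1.0)
  # RQ-1 exchange swaps O2 for CO2 one-for-one: VE = VI, R = 1
  even <- virtual_subject(fio2 = 0.3, vo2_mito_ml_kg_min = 14, rq_tissue = 1)
  expect_equal(forward_model(even)$r_dry, 1.0)
})

test_that("molecule conservation identities hold exactly", {
  set.seed(8)
  for (i in 1:30) {
    sub <- virtual_subject(
      mass_kg = runif(1, 0.4, 0.5), fio2 = runif(1, 0.21, 0.95),
      vo2_mito_ml_kg_min = runif(1, 10, 16), rq_tissue = runif(1, 0.7, 1),
      k_p450_ml_kg_min = runif(1, 0, 8), k_skin_ml_kg_min = runif(1, 0, 3),
      dn2_ml_min = runif(1, -1, 1))
    fm <- forward_model(sub)
    expect_equal(fm$vi_ml_min * sub$fio2 - fm$ve_dry_ml_min * fm$feo2_dry,
                 fm$vo2_total_ml_min, tolerance = 1e-12)
    expect_equal(fm$ve_dry_ml_min * fm$feco2_dry, fm$vco2_ml_min,
                 tolerance = 1e-12)
    expect_equal(fm$vi_ml_min * (1 - sub$fio2) -
                   fm$ve_dry_ml_min * (1 - fm$feo2_dry - fm$feco2_dry),
                 -sub$dn2_ml_min, tolerance = 1e-10)
  }
})

test_that("dn2 = 0 makes direct R equal the Haldane estimate", {
  # including the worked operating point: ~5% extraction, FECO2 ~4.5%
  sub <- virtual_subject(mass_kg = 0.45, fio2 = 0.21, mvv_ml_min = 180,
                         vo2_mito_ml_kg_min = 19.7, rq_tissue = 0.906,
                         dn2_ml_min = 0)
  fm <- forward_model(sub)
  expect_equal(fm$r_dry, haldane_ratio(0.21, fm$feo2_dry, fm$feco2_dry),
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    s <- virtual_subject(fio2 = runif(1, 0.21, 0.9),
                         vo2_mito_ml_kg_min = runif(1, 10, 16),
                         rq_tissue = runif(1, 0.7, 1),
                         k_p450_ml_kg_min = runif(1, 0, 5))
    f <- forward_model(s)
    expect_equal(f$r_dry, haldane_ratio(s$fio2, f$feo2_dry, f$feco2_dry),
                 tolerance = 1e-12)
  }
})

test_that("infeasible subjects are rejected", {
  expect_error(forward_model(virtual_subject(fio2 = 0.21, mvv_ml_min = 10,
                                             vo2_mito_ml_kg_min = 16,
                                             rq_tissue = 0.2)),
               "infeasible")
  expect_error(virtual_subject(fio2 = 0.1), "fio2")
  expect_error(virtual_subject(vo2_mito_ml_kg_min = -1), "non-negative")
})

test_that("zero-noise measurement is inverted exactly by the pipeline", {
  set.seed(10)
  for (i in 1:10) {
    sub <- virtual_subject(
      mass_kg = runif(1, 0.4, 0.5), fio2 = sample(c(0.3, 1.0), 1),
      vo2_mito_ml_kg_min = runif(1, 11, 15), rq_tissue = runif(1, 0.75, 0.95),
      k_p450_ml_kg_min = runif(1, 0, 8), dn2_ml_min = runif(1, 0, 0.5),
      exhalation_rh = runif(1, 0.9, 0.93))
    fm <- forward_model(sub)
    rec <- recover_measurement(simulate_measurement(sub, error_model(0, 0),
                                                    seed = i))
    expect_equal(rec$vo2_ml_kg_min, fm$vo2_ml_kg_min, tolerance = 1e-9)
    expect_equal(rec$vco2_ml_kg_min, fm$vco2_ml_kg_min, tolerance = 1e-9)
    expect_equal(rec$rq, fm$rq, tolerance = 1e-9)
    expect_equal(rec$r, fm$r_dry, tolerance = 1e-9)
  }
})

test_that("same seed gives identical measurements", {
  sub <- virtual_subject(fio2 = 0.3, vo2_mito_ml_kg_min = 13)
  noise <- error_model(0.003, 0.002)
  m1 <- simulate_measurement(sub, noise, seed = 123)
  m2 <- simulate_measurement(sub, noise, seed = 123)
  expect_identical(m1, m2)
  m3 <- simulate_measurement(sub, noise, seed = 124)
  expect_false(identical(m1$timing$ti_s, m3$timing$ti_s))
})

test_that("noise level of recovered VO2 tracks the analytic prediction", {
  sub <- virtual_subject(fio2 = 1.0, vo2_mito_ml_kg_min = 13,
                         rq_tissue = 0.946, k_p450_ml_kg_min = 8)
  fm <- forward_model(sub)
  noise <- error_model(0.003, 0.002)
  rec <- vapply(1:200, function(s) {
    recover_measurement(simulate_measurement(sub, noise,
                                             seed = s))$vo2_ml_kg_min
  }, numeric(1))
  emp_rel_sd <- sd(rec) / fm$vo2_ml_kg_min
  an <- analytic_vo2_relative_error(noise, fm$r_dry, sub$fio2, fm$feo2_dry)
  expect_lt(abs(emp_rel_sd - an) / an, 0.20)
})

test_that("O2 sinks raise VO2 and depress RQ with FIO2; VCO2 fixed", {
  mk <- function(fio2) virtual_subject(fio2 = fio2, vo2_mito_ml_kg_min = 13,
                                       rq_tissue = 0.946,
                                       k_p450_ml_kg_min = 6,
                                       k_skin_ml_kg_min = 2)
  lo <- forward_model(mk(0.3)); hi <- forward_model(mk(1.0))
  expect_gt(hi$vo2_ml_kg_min, lo$vo2_ml_kg_min)
  expect_lt(hi$rq, lo$rq)
  expect_equal(hi$vco2_ml_kg_min, lo$vco2_ml_kg_min)
  # monotone along a grid
  grid <- seq(0.3, 1, by = 0.1)
  vo2s <- vapply(grid, function(f) forward_model(mk(f))$vo2_ml_kg_min,
                 numeric(1))
  expect_true(all(diff(vo2s) > 0))
})

test_that("cohort generation: shape, determinism, edge cases", {
  tab <- generate_cohort(cohort_preset_2x2(2), seed = 77)
  expect_equal(nrow(tab), 8)
  expect_equal(sort(unique(tab$group)), c("a", "b", "c", "d"))
  expect_true(all(c("r_humid", "true_vo2", "true_vco2", "true_rq",
                    "seed") %in% names(tab)))
  tab2 <- generate_cohort(cohort_preset_2x2(2), seed = 77)
  expect_identical(tab, tab2)
  empty <- generate_cohort(list(), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(tab$r_dry_recovered > 0.99 & tab$r_dry_recovered < 1.03))
})
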