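test_that("vo2 equation and guards", {
  expect_equal(vo2(1.0, 0.21, 0.16, 400), 20.0)
  expect_equal(vo2(1.009, 1.0, 0.962, 400), (1.009 - 0.962) * 400)
  expect_equal(vo2(1.0074, 0.3, 0.26, 400), (1.0074 * 0.3 - 0.26) * 400)
  expect_error(vo2(1.0, 0.21, 0.22, 400), "nonpositive O2 uptake")
  expect_error(vo2(1.2, 0.21, 0.16, 400), "physiological band")
  # strictly increasing in r and fio2, decreasing in feo2
  expect_true(all(diff(vapply(seq(1.0, 1.05, 0.01), vo2, numeric(1),
                              fio2 = 0.3, feo2 = 0.26, ve_stpd = 400)) > 0))
  expect_true(all(diff(vapply(seq(0.3, 1, 0.1), function(f)
    vo2(1.01, f, 0.25, 400), numeric(1))) > 0))
  expect_true(all(diff(vapply(seq(0.20, 0.28, 0.02), function(f)
    vo2(1.01, 0.3, f, 400), numeric(1))) < 0))
})

test_that("vco2 equation with and without inspired CO2", {
  expect_equal(vco2(0.04, 400), 16.0)
  expect_equal(vco2(0.04, 400, fico2 = 0.001, vi_stpd = 403), 16 - 0.403)
  expect_equal(vco2(0, 400), 0)
  expect_error(vco2(0.001, 400, fico2 = 0.5, vi_stpd = 403), "negative")
  expect_error(vco2(0.04, 400, fico2 = 0.001), "vi_stpd required")
})

test_that("rq and per-kg normalization", {
  expect_equal(rq(16, 20), 0.8)
  expect_equal(rq(12, 12), 1.0)
  expect_equal(rq(12.5, 21.0), 12.5 / 21)
  expect_error(rq(10, 0), "positive")
  expect_equal(per_kg(9.0, 0.45), 20.0)
  expect_equal(per_kg(6.93, 0.45), 15.4)
  expect_identical(per_kg(3.7, 1.0), 3.7)
  expect_error(per_kg(1, 0), "positive")
  # rq invariant to common scaling of ve
  for (k in c(0.5, 2, 10)) {
    expect_equal(rq(vco2(0.031, 180 * k), vo2(1.008, 0.3, 0.264, 180 * k)),
                 rq(vco2(0.031, 180), vo2(1.008, 0.3, 0.264, 180)))
  }
})

test_that("haldane ratio: worked values, singularity, N2 identity", {
  expect_equal(haldane_ratio(0.21, 0.16, 0.045), 0.795 / 0.79)
  expect_equal(round(haldane_ratio(0.21, 0.16, 0.045), 3), 1.006)
  expect_equal(haldane_ratio(0.21, 0.16, 0.04), 0.80 / 0.79)
  expect_equal(haldane_ratio(0.21, 0.21, 0), 1.0)
  expect_error(haldane_ratio(1.0, 0.95, 0.04), "fio2 >= 1")
  # Eq 10: setting R to the Haldane value conserves N2 exactly
  set.seed(5)
  for (i in 1:20) {
    fio2 <- runif(1, 0.21, 0.95)
    feo2 <- fio2 - runif(1, 0.02, 0.05)
    feco2 <- runif(1, 0.03, 0.05)
    r <- haldane_ratio(fio2, feo2, feco2)
    ve <- runif(1, 100, 400); vi <- r * ve
    expect_equal(vi * (1 - fio2), ve * (1 - feo2 - feco2), tolerance = 1e-12)
  }
})

test_that("STPD conversion", {
  expect_equal(ve_to_stpd(400, dry_state(0, 1013.25)), 400)
  expect_equal(ve_to_stpd(400, dry_state(22.5, 1013.25)),
               400 * 273.15 / 295.65)
  expect_equal(ve_to_stpd(400, psychro_state(22.5, 0.925, 1002)),
               356.2589, tolerance = 1e-4)
})

test_that("full pipeline recovers a Haldane-consistent world both ways", {
  # build a measurement whose R equals its own Haldane ratio (dn2 = 0):
  # the direct-R VO2 and the Haldane-based VO2 must coincide
  sub <- virtual_subject(fio2 = 0.3, vo2_mito_ml_kg_min = 14,
                         rq_tissue = 0.8, dn2_ml_min = 0)
  m <- simulate_measurement(sub, error_model(0, 0), seed = 2)
  rec <- recover_measurement(m)
  r_hald <- haldane_ratio(rec$fio2_dry, rec$feo2_dry, rec$feco2_dry)
  expect_equal(rec$r, r_hald, tolerance = 1e-9)
  vo2_direct <- vo2(rec$r, rec$fio2_dry, rec$feo2_dry, rec$ve_stpd_ml_min)
  vo2_hald <- vo2(r_hald, rec$fio2_dry, rec$feo2_dry, rec$ve_stpd_ml_min)
  expect_equal(vo2_direct, vo2_hald, tolerance = 1e-9)
})

test_that("full pipeline reports the failing stage", {
  sub <- virtual_subject(fio2 = 0.3, vo2_mito_ml_kg_min = 14)
  m <- simulate_measurement(sub, error_model(0, 0), seed = 3)
  # poison the expired O2 so r*fio2 <= feo2
  m$exhale$o2_frac <- m$inhale$o2_frac * 1.01
  expect_error(recover_measurement(m), "\\[metabolism\\]")
  m2 <- simulate_measurement(sub, error_model(0, 0), seed = 3)
  m2$timing$equilibrated <- FALSE
  expect_error(recover_measurement(m2), "\\[molar_ratio\\]")
})

test_that("metabolic result fields are mutually consistent", {
  sub <- virtual_subject(fio2 = 1.0, vo2_mito_ml_kg_min = 13,
                         rq_tissue = 0.95, k_p450_ml_kg_min = 8)
  rec <- recover_measurement(simulate_measurement(sub, error_model(0, 0),
                                                  seed = 4))
  expect_equal(rec$vi_stpd_ml_min, rec$r * rec$ve_stpd_ml_min)
  expect_equal(rec$rq * rec$vo2_ml_kg_min, rec$vco2_ml_kg_min,
               tolerance = 1e-12)
})
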