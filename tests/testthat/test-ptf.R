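test_that("organic carbon to organic matter uses the factor-2 conversion", {
  out <- oc_to_om(c(10, 0, 17.24))
  expect_equal(out$organic_carbon_pct, c(1.0, 0, 1.724))
  expect_equal(out$organic_matter_pct, c(2.0, 0, 3.448))
  # explicitly not the van-Bemmelen factor
  expect_false(isTRUE(all.equal(out$organic_matter_pct[3], 1.724 * 1.724)))
  expect_error(oc_to_om(-1), "non-negative")
})

test_that("wilting point and field capacity match hand-evaluated cases", {
  # zero-texture corner, evaluated by hand from the printed coefficients
  expect_equal(ptf_wilting_point(0, 0, 0), 0.031 + (0.14 * 0.031 - 0.02),
    tolerance = 1e-12)
  expect_equal(ptf_wilting_point(0, 0, 0), 0.01534, tolerance = 1e-9)
  t33t0 <- 0.299
  expect_equal(ptf_field_capacity(0, 0, 0),
    t33t0 + 1.283 * t33t0^2 - 0.374 * t33t0 - 0.015, tolerance = 1e-12)

  # loamy-clay case frozen from the independent oracle
  expect_equal(ptf_wilting_point(0.20, 0.30, 2.0), 0.1881412,
    tolerance = 1e-6)
  expect_equal(ptf_field_capacity(0.20, 0.30, 2.0), 0.35008952,
    tolerance = 1e-6)
  expect_gt(ptf_saturation(0.20, 0.30, 2.0),
    ptf_field_capacity(0.20, 0.30, 2.0))
})

test_that("saturation follows its compositional identity at the sand corner", {
  S <- 1; C <- 0; OM <- 0
  ts33t <- 0.278 * S + 0.078
  ts33 <- ts33t + (0.636 * ts33t - 0.107)
  expect_equal(ptf_saturation(S, C, OM),
    ptf_field_capacity(S, C, OM) + ts33 - 0.097 + 0.043, tolerance = 1e-12)
})

test_that("wilting point increases with clay over the agricultural domain", {
  # partial derivative wrt C is (0.487 + 0.068 S - 0.013 OM) x 1.14 > 0
  for (S in c(0, 0.2, 0.5)) {
    for (OM in c(0, 2, 8)) {
      cl <- seq(0.05, 0.6, by = 0.05)
      expect_true(all(diff(ptf_wilting_point(S, cl, OM)) > 0))
    }
  }
})

test_that("saturated conductivity reproduces the worked power-law case", {
  B <- log(1500 / 33) / log(3)
  ks <- 1930 * 0.15^(3 - 1 / B)
  expect_equal(ptf_ksat(0.10, 0.30, 0.45), ks, tolerance = 1e-12)
  expect_equal(ks, 11.23, tolerance = 0.02) # mm/h
  # zero base, positive exponent
  expect_equal(ptf_ksat(0.10, 0.30, 0.30), 0)
  # monotone in the moisture difference at fixed lambda
  expect_true(all(diff(ptf_ksat(0.10, 0.30, seq(0.31, 0.5, 0.01))) > 0))
  expect_error(ptf_ksat(0.30, 0.30, 0.45), "exceed")
})

test_that("equations match the literal oracle transcription on a sweep", {
  g <- oracle_sweep_grid(step = 0.05, om = c(0, 2, 5, 8))
  expect_equal(ptf_wilting_point(g$S, g$C, g$OM),
    oracle_theta1500(g$S, g$C, g$OM), tolerance = 1e-12)
  expect_equal(ptf_field_capacity(g$S, g$C, g$OM),
    oracle_theta33(g$S, g$C, g$OM), tolerance = 1e-12)
  expect_equal(ptf_saturation(g$S, g$C, g$OM),
    oracle_thetaS(g$S, g$C, g$OM), tolerance = 1e-12)
})

test_that("percentage-scale sand/clay are rejected at the equation boundary", {
  expect_error(ptf_wilting_point(40, 0.2, 2), "fraction")
  expect_error(ptf_field_capacity(0.4, 20, 2), "fraction")
})

test_that("derive_hydraulics bundles, orders, clamps and is pure", {
  loam <- tibble::tibble(sand = 40, silt = 40, clay = 20, oc = 15)
  h <- derive_hydraulics(loam)
  expect_true(h$theta1500 < h$theta33 && h$theta33 < h$thetaS)
  expect_false(h$ptf_clamped)
  expect_equal(h$ks_cm_h, h$ks_mm_h / 10)
  # against the oracle (OM = 2 x OC% = 3)
  expect_equal(h$theta1500, oracle_theta1500(0.4, 0.2, 3), tolerance = 1e-12)
  expect_equal(h$ks_mm_h,
    oracle_ks(oracle_theta1500(0.4, 0.2, 3), oracle_theta33(0.4, 0.2, 3),
      oracle_thetaS(0.4, 0.2, 3)), tolerance = 1e-12)

  # determinism: repeated evaluation is bit-identical
  expect_identical(derive_hydraulics(loam), h)

  # missing inputs
  expect_error(derive_hydraulics(tibble::tibble(sand = 40, silt = 40,
    clay = 20)), "incomplete")
  expect_error(derive_hydraulics(tibble::tibble(sand = 40, silt = 40,
    clay = 20, oc = NA)), "incomplete")
  expect_error(derive_hydraulics(tibble::tibble(sand = 50, silt = 40,
    clay = 20, oc = 5)), "sum to 100")

  # pure sand is outside the validity domain: clamped and flagged
  sandy <- derive_hydraulics(tibble::tibble(sand = 100, silt = 0, clay = 0,
    oc = 0))
  expect_true(sandy$ptf_clamped)
  expect_gte(sandy$theta1500, 0.01)
  expect_gte(sandy$theta33 - sandy$theta1500, 0.01)
  expect_lte(sandy$thetaS, 0.60 + 0.011)
})
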