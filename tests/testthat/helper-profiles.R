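# Randomized valid soil profiles, pre-rounded to the printed precision of
# the *.SOL descriptor so write -> read round-trips can be compared exactly.

random_profile <- function(i) {
  n <- 6
  slll <- round(runif(n, 0.05, 0.20), 3)
  sdul <- round(slll + runif(n, 0.02, 0.15), 3)
  ssat <- round(sdul + runif(n, 0.02, 0.20), 3)
  clay <- round(runif(n, 5, 60), 1)
  silt <- round(runif(n, 5, 95 - clay), 1)
  layers <- tibble::tibble(
    slb = c(5, 15, 30, 60, 100, 200),
    slmh = c("A", "A", "AB", "BA", "B", "BC"),
    slll = slll, sdul = sdul, ssat = ssat,
    srgf = round(sort(runif(n), decreasing = TRUE), 3),
    ssks = round(runif(n, 0.01, 30), 2),
    sbdm = round(runif(n, 0.9, 1.8), 2),
    sloc = round(runif(n, 0.05, 4), 2),
    slcl = clay, slsi = silt,
    slcf = -99,
    slni = round(runif(n, 0.005, 0.3), 3),
    slhw = round(runif(n, 4, 9), 1),
    slhb = -99,
    scec = round(runif(n, 1, 40), 1)
  )
  new_soil_profile(
    profile_id = sprintf("TP%08d", i),
    source = "TEST",
    texture_label = sample(c("C", "L", "S"), 1),
    depth_cm = 200,
    description = "randomized test profile",
    site = list(site = "Test", country = "XX",
      lat = round(runif(1, -60, 60), 3), lon = round(runif(1, -179, 179), 3),
      scs = "Generic"),
    surface = list(SCOM = "BN", SALB = round(runif(1, 0.05, 0.3), 2),
      SLU1 = round(runif(1, 4, 12), 1), SLDR = round(runif(1, 0.1, 0.9), 2),
      SLRO = round(runif(1, 60, 95), 1), SLNF = 1.00, SLPF = 1.00,
      SMHB = "IB001", SMPX = "IB001", SMKE = "IB001"),
    layers = layers
  )
}

expect_profile_roundtrip_equal <- function(p, q) {
  expect_identical(q$profile_id, p$profile_id)
  expect_identical(q$layers$slmh, p$layers$slmh)
  for (col in setdiff(names(p$layers), "slmh")) {
    expect_equal(q$layers[[col]], p$layers[[col]], tolerance = 0,
      label = paste("layer column", col))
  }
  num_surf <- names(which(vapply(p$surface, is.numeric, logical(1))))
  for (nm in num_surf) {
    expect_equal(q$surface[[nm]], p$surface[[nm]], tolerance = 0,
      label = paste("surface field", nm))
  }
  expect_equal(q$site$lat, p$site$lat)
  expect_equal(q$site$lon, p$site$lon)
}

# small fine stack for pipeline tests
small_stack <- function(seed = 11, preset = "smooth", nrow = 30, ncol = 30,
                        nodata_fraction = 0.1) {
  generate_input_stack(fixture_spec(
    nrow = nrow, ncol = ncol, seed = seed, preset = preset,
    nodata_fraction = nodata_fraction
  ))
}
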