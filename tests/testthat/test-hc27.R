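test_that("the decision table is a bijection over the 27 class triples", {
  tab <- hc27_table()
  expect_equal(nrow(tab), 27)
  expect_equal(length(unique(tab$profile_id)), 27)
  expect_equal(nrow(dplyr::distinct(tab[c("texture", "fertility", "depth")])),
    27)
  # anchor rows of the published ordering
  expect_equal(select_generic_profile("CLAY", "HIGH", "DEEP"), "HC_GEN0001")
  expect_equal(select_generic_profile("LOAM", "HIGH", "DEEP"), "HC_GEN0010")
  expect_equal(select_generic_profile("SAND", "LOW", "SHALLOW"), "HC_GEN0027")
  # every triple resolves, and each ID is hit exactly once
  ids <- with(expand.grid(t = c("CLAY", "LOAM", "SAND"),
    f = c("HIGH", "MEDIUM", "LOW"), d = c("DEEP", "MEDIUM", "SHALLOW"),
    stringsAsFactors = FALSE),
    select_generic_profile(t, f, d))
  expect_setequal(ids, tab$profile_id)
  expect_equal(anyDuplicated(ids), 0)
  expect_error(select_generic_profile("CLAY", "HIGH", "BOTTOMLESS"),
    "invalid class triple")
})

test_that("texture and fertility classification apply the default rules", {
  expect_equal(classify_texture(sand = 30, clay = 45), "CLAY")
  expect_equal(classify_texture(sand = 80, clay = 5), "SAND")
  expect_equal(classify_texture(sand = 40, clay = 20), "LOAM")
  # sandy but clay-rich stays loam under the default rule
  expect_equal(classify_texture(sand = 70, clay = 20), "LOAM")
  expect_equal(classify_fertility(c(1.5, 0.9, 0.2)),
    c("HIGH", "MEDIUM", "LOW"))
  # thresholds are configuration, not constants
  expect_equal(classify_fertility(0.9, thresholds = list(high = 0.8,
    medium = 0.3)), "HIGH")
})

test_that("AWC of the top metre integrates layer intersections", {
  uniform <- tibble::tibble(slb = c(5, 15, 30, 60, 100, 200),
    sdul = 0.35, slll = 0.188)
  expect_equal(compute_awc_1m(uniform)$awc_mm, 1000 * (0.35 - 0.188),
    tolerance = 1e-12)
  # SDUL = SLLL everywhere
  dry <- dplyr::mutate(uniform, slll = sdul)
  expect_equal(compute_awc_1m(dry)$awc_mm, 0)
  # only the 60-100 cm layer holds water: 0.40 m of thickness counts
  spot <- dplyr::mutate(uniform, sdul = slll)
  spot$sdul[5] <- spot$slll[5] + 0.10
  expect_equal(compute_awc_1m(spot)$awc_mm, 1000 * 0.10 * 0.40,
    tolerance = 1e-12)
  # the 100-200 cm layer contributes nothing
  deep <- dplyr::mutate(uniform, sdul = slll)
  deep$sdul[6] <- deep$slll[6] + 0.10
  expect_equal(compute_awc_1m(deep)$awc_mm, 0)
  expect_error(compute_awc_1m(uniform[c("slb", "sdul")]), "incomplete")
})

test_that("rooting depth lookup honors the clay/140 worked example", {
  expect_equal(classify_rooting_depth(140, "CLAY"), "MEDIUM")
  expect_equal(classify_rooting_depth(200, "CLAY"), "DEEP")
  expect_equal(classify_rooting_depth(10, "CLAY"), "SHALLOW")
  expect_equal(classify_rooting_depth(10, "LOAM"), "SHALLOW")
  expect_equal(classify_rooting_depth(10, "SAND"), "SHALLOW")
  # boundaries are lower-exclusive / upper-inclusive
  expect_equal(classify_rooting_depth(150, "CLAY"), "MEDIUM")
  expect_equal(classify_rooting_depth(150 + 1e-9, "CLAY"), "DEEP")
  expect_equal(classify_rooting_depth(100, "CLAY"), "SHALLOW")
  # sand promotes to DEEP at a lower AWC than clay
  expect_equal(classify_rooting_depth(140, "SAND"), "DEEP")
})

test_that("depth class is monotone non-decreasing in AWC at fixed texture", {
  rank <- c(SHALLOW = 1, MEDIUM = 2, DEEP = 3)
  awc <- seq(0, 250, by = 5)
  for (tx in c("CLAY", "LOAM", "SAND")) {
    cls <- rank[classify_rooting_depth(awc, tx)]
    expect_true(all(diff(cls) >= 0), info = tx)
  }
})

test_that("packaged default templates satisfy the template invariants", {
  templates <- default_templates()
  expect_length(templates, 27)
  tab <- hc27_table()
  for (i in seq_len(27)) {
    p <- templates[[tab$profile_id[i]]]
    srgf <- p$layers$srgf
    expect_true(all(srgf >= 0 & srgf <= 1))
    expect_true(all(diff(srgf) <= 1e-12))
    top <- c(0, utils::head(p$layers$slb, -1))
    rd <- c(DEEP = 180, MEDIUM = 120, SHALLOW = 60)[[tab$depth[i]]]
    expect_true(all(srgf[top >= rd] == 0))
    # water contents physically ordered
    expect_true(all(p$layers$slll < p$layers$sdul &
      p$layers$sdul < p$layers$ssat))
  }
  # shallow templates are rootless below 60 cm
  shallow <- templates[[select_generic_profile("LOAM", "HIGH", "SHALLOW")]]
  expect_true(all(shallow$layers$srgf[shallow$layers$slb > 60] == 0))
})

test_that("load_templates validates user-supplied template directories", {
  dir <- withr::local_tempdir()
  generate_template_set(dir, seed = 3)
  templates <- load_templates(dir)
  expect_length(templates, 27)
  expect_setequal(names(templates), hc27_table()$profile_id)

  # user templates override the defaults ID-by-ID
  expect_false(isTRUE(all.equal(templates$HC_GEN0001$surface$SALB,
    default_templates()$HC_GEN0001$surface$SALB)))

  # a missing template is a configuration error naming the ID
  file.remove(file.path(dir, "HC_GEN0013.SOL"))
  expect_error(load_templates(dir), "HC_GEN0013")
})
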