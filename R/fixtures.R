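#' Synthetic input grids
#'
#' Seeded generators producing per-layer soil property grids with the
#' statistical structure the pipeline assumes -- spatially correlated
#' fields, texture closing to exactly 100 % per pixel, plausible organic
#' carbon / bulk density / pH / CEC ranges, and a consistent nodata region
#' emulating a coastline -- so every module and the end-to-end build are
#' testable without downloading any real dataset. Spatial correlation comes
#' from kernel-smoothing white noise (the algorithm is pinned here, not
#' delegated, so seeded output is stable across library versions).
#'
#' @name fixtures
NULL

#' Describe a synthetic grid fixture
#'
#' @param nrow,ncol Fine-grid dimensions (pixels).
#' @param seed Integer seed; same spec + seed gives identical output.
#' @param preset `"smooth"` (continuously varying fields) or
#'   `"three-zone"` (three vertical bands constructed to classify as clay,
#'   loam and sand respectively).
#' @param nodata_fraction Fraction of pixels masked as nodata, applied
#'   consistently across all properties and layers.
#' @param correlation_length Smoothing length of the random fields, pixels.
#' @param xmin,ymax,cellsize_deg Georeference of the fine grid (north-up,
#'   row-major, WGS84 decimal degrees).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(nrow = 60, ncol = 60, seed = 1,
                         preset = c("smooth", "three-zone"),
                         nodata_fraction = 0.1, correlation_length = 6,
                         xmin = 30, ymax = 0, cellsize_deg = 1 / 120) {
  structure(
    list(
      nrow = as.integer(nrow), ncol = as.integer(ncol),
      seed = as.integer(seed), preset = match.arg(preset),
      nodata_fraction = nodata_fraction,
      correlation_length = correlation_length,
      xmin = xmin, ymax = ymax, cellsize_deg = cellsize_deg,
      n_layers = 6L
    ),
    class = "fixture_spec"
  )
}

# Separable Gaussian smoothing of a matrix with edge renormalisation.
smooth_matrix <- function(m, corlen) {
  if (corlen <= 0) return(m)
  half <- max(1L, ceiling(2 * corlen))
  k <- stats::dnorm(-half:half, sd = corlen)
  k <- k / sum(k)
  smooth_1d <- function(x) {
    n <- length(x)
    num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
    (num / den)[(half + 1):(half + n)]
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

# Standardised smooth random field.
smooth_field <- function(nr, nc, corlen) {
  z <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), corlen)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic per-layer soil property stack
#'
#' Returns a long tibble with one row per (pixel, layer): columns `row`,
#' `col`, `layer` (1-6, the standard depth intervals), `sand`, `silt`,
#' `clay` (mass %, summing to 100 exactly on valid pixels), `oc` (g/kg),
#' `bd` (kg/m3), `ph` and `cec` (cmol/kg). Nodata pixels carry NA in every
#' property. The fixture spec is attached as attribute `grid_spec`.
#'
#' @param spec A [fixture_spec()].
#' @return A `soil_stack` tibble.
#' @export
generate_input_stack <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  nr <- spec$nrow
  nc <- spec$ncol
  cl <- spec$correlation_length

  zone <- matrix(rep(ceiling(3 * (seq_len(nc) - 0.5) / nc), each = nr), nr, nc)
  zone_tex <- list(
    `1` = c(sand = 20, clay = 50), # clayey zone
    `2` = c(sand = 40, clay = 20), # loamy zone
    `3` = c(sand = 80, clay = 8)   # sandy zone
  )

  z_sand <- smooth_field(nr, nc, cl)
  z_clay <- smooth_field(nr, nc, cl)
  z_oc <- smooth_field(nr, nc, cl)
  z_bd <- smooth_field(nr, nc, cl)
  z_ph <- smooth_field(nr, nc, cl)
  z_cec <- smooth_field(nr, nc, cl)
  z_mask <- smooth_field(nr, nc, cl)

  if (spec$preset == "three-zone") {
    sand0 <- matrix(vapply(zone, function(z) zone_tex[[z]][["sand"]],
      numeric(1)), nr, nc) + 3 * z_sand
    clay0 <- matrix(vapply(zone, function(z) zone_tex[[z]][["clay"]],
      numeric(1)), nr, nc) + 2 * z_clay
  } else {
    sand0 <- 45 + 18 * z_sand
    clay0 <- 27 + 12 * z_clay
  }
  sand0 <- pmin(pmax(sand0, 1), 92)
  clay0 <- pmin(pmax(clay0, 1), 90)
  # keep room for silt, then close the simplex exactly
  over <- sand0 + clay0 > 97
  scl <- ifelse(over, 97 / (sand0 + clay0), 1)
  sand0 <- sand0 * scl
  clay0 <- clay0 * scl
  silt0 <- 100 - sand0 - clay0

  oc_surface <- pmin(pmax(12 * exp(0.45 * z_oc), 1), 60)
  bd0 <- pmin(pmax(1300 + 140 * z_bd, 900), 1750)
  ph0 <- pmin(pmax(6.5 + 0.8 * z_ph, 4), 9)
  cec0 <- pmax(4 + 0.4 * clay0 + 3 * z_cec, 0.5)

  n_mask <- round(spec$nodata_fraction * nr * nc)
  nodata <- matrix(FALSE, nr, nc)
  if (n_mask > 0) {
    nodata[order(z_mask)[seq_len(n_mask)]] <- TRUE
  }

  mid <- (STD_LAYER_TOP + STD_LAYER_BOTTOM) / 2
  layers <- purrr::map(seq_len(spec$n_layers), function(l) {
    depth_oc <- exp(-0.012 * pmax(mid[l] - 2.5, 0))
    tibble::tibble(
      row = rep(seq_len(nr), times = nc),
      col = rep(seq_len(nc), each = nr),
      layer = l,
      sand = as.vector(sand0),
      silt = as.vector(silt0),
      clay = as.vector(clay0),
      oc = as.vector(oc_surface) * depth_oc,
      bd = pmin(as.vector(bd0) + 15 * (l - 1), 1800),
      ph = as.vector(ph0),
      cec = as.vector(cec0)
    )
  })
  stack <- dplyr::bind_rows(layers)
  na_idx <- nodata[cbind(stack$row, stack$col)]
  for (prop in c("sand", "silt", "clay", "oc", "bd", "ph", "cec")) {
    stack[[prop]][na_idx] <- NA_real_
  }
  stack <- dplyr::arrange(stack, .data$layer, .data$row, .data$col)
  attr(stack, "grid_spec") <- spec
  class(stack) <- c("soil_stack", class(stack))
  stack
}

#' The constructed texture zone of each pixel (three-zone preset)
#'
#' @param spec The fixture spec used to build the stack.
#' @return Tibble with `row`, `col`, `zone_class` in CLAY/LOAM/SAND.
#' @export
fixture_zones <- function(spec) {
  zone <- ceiling(3 * (seq_len(spec$ncol) - 0.5) / spec$ncol)
  col <- rep(seq_len(spec$ncol), each = spec$nrow)
  tibble::tibble(
    row = rep(seq_len(spec$nrow), times = spec$ncol),
    col = col,
    zone_class = c("CLAY", "LOAM", "SAND")[zone[col]]
  )
}

#' Generate a synthetic country mask
#'
#' Splits the coarse grid into `n_countries` vertical bands with two-letter
#' ISO-like codes, for exercising per-country output partitioning.
#'
#' @param spec Fixture spec of the fine grid.
#' @param block Aggregation factor (fine pixels per coarse cell edge).
#' @param n_countries Number of bands (1-26).
#' @return Tibble with `crow`, `ccol`, `iso`.
#' @export
generate_country_mask <- function(spec, block = 10L, n_countries = 2) {
  ncr <- ceiling(spec$nrow / block)
  ncc <- ceiling(spec$ncol / block)
  codes <- paste0("A", LETTERS[seq_len(n_countries)])
  band <- ceiling(n_countries * (seq_len(ncc) - 0.5) / ncc)
  tidyr::expand_grid(crow = seq_len(ncr), ccol = seq_len(ncc)) |>
    dplyr::mutate(iso = codes[band[.data$ccol]])
}

#' Write a synthetic template set as *.SOL files
#'
#' Produces 27 valid generic-profile template files (one per profile,
#' `HC_GEN0001.SOL` ... `HC_GEN0027.SOL`) derived from the packaged
#' defaults with a small seeded perturbation of the surface albedo and
#' evaporation limit, so distinct seeds give distinguishable but still
#' valid template sets.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the vector of file paths.
#' @export
generate_template_set <- function(dir, seed = 1) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  templates <- default_templates()
  paths <- purrr::imap_chr(templates, function(p, id) {
    p$surface$SALB <- round(pmin(pmax(
      p$surface$SALB + stats::runif(1, -0.02, 0.02), 0.05), 0.3), 2)
    p$surface$SLU1 <- round(pmin(pmax(
      p$surface$SLU1 + stats::runif(1, -1, 1), 4), 12), 1)
    path <- file.path(dir, paste0(id, ".SOL"))
    write_sol(p, path, title = paste("synthetic generic template", id))
    path
  })
  invisible(unname(paths))
}
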