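#' End-to-end grid pipeline
#'
#' Orchestrates the build: aggregate the fine property grids to coarse
#' cells by arithmetic block means, run the pedo-transfer functions (per
#' fine pixel by default, on coarse means optionally), classify every
#' complete coarse cell into its generic profile, remap template root
#' growth factor and nitrogen onto the six output layers, assemble one
#' soil profile per cell and partition output files by country.
#'
#' @name grid_pipeline
NULL

#' Arithmetic block mean with a minimum-validity rule
#'
#' Mean over valid (non-NA) values; returns NA when the valid fraction of
#' the block falls below the threshold (including the all-nodata block).
#'
#' @param x Values of one property over one coarse cell's block of fine
#'   pixels; NA marks nodata.
#' @param min_valid_fraction Minimum fraction of valid pixels.
#' @return The block mean, or NA.
#' @examples
#' aggregate_block(c(10, 30, NA, NA), min_valid_fraction = 0.25)
#' @export
aggregate_block <- function(x, min_valid_fraction = 0.5) {
  frac <- mean(!is.na(x))
  if (frac < min_valid_fraction || frac == 0) return(NA_real_)
  mean(x, na.rm = TRUE)
}

#' Re-close averaged texture fractions to 100 %
#'
#' Independent averaging of sand, silt and clay breaks the simplex
#' closure; this rescales the three means so they sum to exactly 100.
#' The pre-rescale deviation is returned for the run report. A zero or
#' missing sum yields NA (nodata cell).
#'
#' @param sand,silt,clay Averaged percentages (vectorised).
#' @return Tibble with rescaled `sand`, `silt`, `clay` and the absolute
#'   pre-rescale `closure_dev` (percentage points).
#' @export
renormalize_texture <- function(sand, silt, clay) {
  total <- sand + silt + clay
  bad <- is.na(total) | total <= 0
  f <- ifelse(bad, NA_real_, 100 / total)
  tibble::tibble(
    sand = sand * f, silt = silt * f, clay = clay * f,
    closure_dev = ifelse(bad, NA_real_, abs(total - 100))
  )
}

PROPERTY_COLS <- c("sand", "silt", "clay", "oc", "bd", "ph", "cec")

#' Aggregate a fine soil stack to coarse cells
#'
#' Groups fine pixels into `block` x `block` coarse cells and takes the
#' arithmetic mean of every property (and, when present, of the fine-pixel
#' hydraulic properties) per cell and layer, applying the
#' minimum-valid-fraction rule of [aggregate_block()]. Averaged texture is
#' re-closed to 100 %.
#'
#' @param stack A `soil_stack` long tibble (see [generate_input_stack()]).
#' @param block Fine pixels per coarse cell edge.
#' @param min_valid_fraction Minimum valid fine-pixel fraction per cell.
#' @return Coarse tibble keyed by `crow`, `ccol`, `layer` with the same
#'   property columns plus `valid_fraction` and `closure_dev`.
#' @export
aggregate_stack <- function(stack, block = 10L, min_valid_fraction = 0.5) {
  value_cols <- intersect(
    c(PROPERTY_COLS, "theta1500", "theta33", "thetaS", "ks_cm_h"),
    names(stack)
  )
  coarse <- stack |>
    dplyr::mutate(
      crow = (.data$row - 1L) %/% block + 1L,
      ccol = (.data$col - 1L) %/% block + 1L
    ) |>
    dplyr::group_by(.data$crow, .data$ccol, .data$layer) |>
    dplyr::summarise(
      valid_fraction = mean(!is.na(.data$sand)),
      dplyr::across(dplyr::all_of(value_cols),
        ~ aggregate_block(.x, min_valid_fraction)),
      .groups = "drop"
    )
  tex <- renormalize_texture(coarse$sand, coarse$silt, coarse$clay)
  coarse$sand <- tex$sand
  coarse$silt <- tex$silt
  coarse$clay <- tex$clay
  coarse$closure_dev <- tex$closure_dev
  coarse
}

#' Spatial variance reduction under block aggregation
#'
#' Quantifies the smoothing effect of fine-to-coarse averaging: for every
#' property and layer, the population variance across fine valid pixels is
#' compared with the variance across coarse block means, each mean
#' weighted by the number of valid pixels in its block. Under that
#' weighting the law of total variance makes the ratio at most 1 exactly
#' -- aggregation can only narrow the spatial distribution.
#'
#' @param stack Fine-resolution `soil_stack` tibble.
#' @param block Fine pixels per coarse cell edge.
#' @return Tibble with `property`, `layer`, `var_fine`, `var_coarse` and
#'   `ratio` (`var_coarse / var_fine`).
#' @export
smoothing_variance_ratio <- function(stack, block = 10L) {
  props <- intersect(PROPERTY_COLS, names(stack))
  out <- list()
  for (prop in props) {
    for (l in sort(unique(stack$layer))) {
      d <- stack[stack$layer == l & !is.na(stack[[prop]]), ]
      if (nrow(d) == 0) next
      x <- d[[prop]]
      crow <- (d$row - 1L) %/% block
      ccol <- (d$col - 1L) %/% block
      key <- paste(crow, ccol)
      m <- tapply(x, key, mean)
      n <- tapply(x, key, length)
      grand <- sum(m * n) / sum(n)
      var_fine <- mean((x - mean(x))^2)
      var_coarse <- sum(n * (m - grand)^2) / sum(n)
      out[[length(out) + 1]] <- tibble::tibble(
        property = prop, layer = l,
        var_fine = var_fine, var_coarse = var_coarse,
        ratio = var_coarse / var_fine
      )
    }
  }
  dplyr::bind_rows(out)
}

encode_base36 <- function(n, width = 8) {
  digits <- c(0:9, LETTERS)
  out <- character(length(n))
  for (i in seq_along(n)) {
    v <- n[i]
    s <- ""
    repeat {
      s <- paste0(digits[v %% 36 + 1], s)
      v <- v %/% 36
      if (v == 0) break
    }
    out[i] <- formatC(s, width = width, flag = "0")
  }
  gsub(" ", "0", out)
}

topsoil_mean <- function(values_by_layer) {
  # thickness-weighted mean over 0-30 cm (layers 1-3: 5, 10, 15 cm)
  w <- c(5, 10, 15)
  sum(values_by_layer[1:3] * w) / sum(w)
}

#' Build soil profiles from a fine-resolution property stack
#'
#' Runs the full chain for every coarse cell: hydraulic properties from
#' the pedo-transfer functions (computed per fine pixel and then averaged
#' when `config$ptf_stage == "fine"`, the default; computed on coarse-cell
#' means when `"coarse"`), available water content of the top metre,
#' texture / fertility / rooting-depth classification, generic-profile
#' selection, template remapping of SRGF and SLNI, and assembly of the
#' six-layer profile records. Grid-derived fields (SBDM, SLOC, SLCL, SLSI,
#' SLHW, SCEC) come from the aggregated grids; SLCF and SLHB are set to
#' -99; the master horizon sequence is fixed at A, A, AB, BA, B, BC; the
#' ten surface parameters are inherited from the selected template.
#' Incomplete cells are skipped and counted in the run report.
#'
#' @param stack Fine-resolution `soil_stack` tibble.
#' @param templates Named list of 27 templates, from [load_templates()].
#' @param config Configuration list, from [sol_config()].
#' @param mask Optional country mask tibble (`crow`, `ccol`, `iso`).
#' @return A `sol_build` object: list with `profiles` (named list of
#'   `soil_profile`), `cells` (per-cell classification tibble) and
#'   `report` (counts of cells processed / skipped / clamped).
#' @export
build_profiles <- function(stack, templates = load_templates(),
                           config = sol_config(), mask = NULL) {
  validate_template_set(templates)
  spec <- attr(stack, "grid_spec")
  block <- config$block

  n_clamped_fine <- 0L
  if (config$ptf_stage == "fine") {
    complete <- !is.na(stack$sand) & !is.na(stack$silt) &
      !is.na(stack$clay) & !is.na(stack$oc)
    hyd <- derive_hydraulics(stack[complete, c("sand", "silt", "clay", "oc")])
    for (colname in c("theta1500", "theta33", "thetaS", "ks_cm_h")) {
      stack[[colname]] <- NA_real_
      stack[[colname]][complete] <- hyd[[colname]]
    }
    n_clamped_fine <- sum(hyd$ptf_clamped)
  }

  coarse <- aggregate_stack(stack, block = block,
    min_valid_fraction = config$min_valid_fraction)

  if (config$ptf_stage == "coarse") {
    ok <- !is.na(coarse$sand) & !is.na(coarse$oc)
    hyd <- derive_hydraulics(coarse[ok, c("sand", "silt", "clay", "oc")])
    for (colname in c("theta1500", "theta33", "thetaS", "ks_cm_h")) {
      coarse[[colname]] <- NA_real_
      coarse[[colname]][ok] <- hyd[[colname]]
    }
    n_clamped_fine <- sum(hyd$ptf_clamped)
  }

  wide <- tidyr::nest(coarse, layer_data = !dplyr::all_of(c("crow", "ccol")))
  tab <- hc27_table()
  iso_of <- function(crow, ccol) {
    if (is.null(mask)) return(config$catchall_iso)
    hit <- mask$iso[mask$crow == crow & mask$ccol == ccol]
    if (length(hit) == 1) hit else config$catchall_iso
  }

  cells <- list()
  profiles <- list()
  n_skipped <- 0L
  ncc_total <- max(1L, ceiling(if (!is.null(spec)) spec$ncol / block else
    max(wide$ccol)))

  for (i in seq_len(nrow(wide))) {
    crow <- wide$crow[i]
    ccol <- wide$ccol[i]
    ld <- dplyr::arrange(wide$layer_data[[i]], .data$layer)
    need <- c(PROPERTY_COLS, "theta1500", "theta33", "thetaS", "ks_cm_h")
    if (nrow(ld) != 6 || any(is.na(ld[need]))) {
      n_skipped <- n_skipped + 1L
      next
    }
    tex_sand <- topsoil_mean(ld$sand)
    tex_clay <- topsoil_mean(ld$clay)
    oc_top_pct <- topsoil_mean(ld$oc) / 10
    texture <- classify_texture(tex_sand, tex_clay, rule = config$texture_rule)
    fertility <- classify_fertility(oc_top_pct,
      thresholds = config$fertility_thresholds_pct)
    awc <- compute_awc_1m(tibble::tibble(
      slb = STD_LAYER_BOTTOM, sdul = ld$theta33, slll = ld$theta1500
    ))
    depth <- classify_rooting_depth(awc$awc_mm, texture,
      lookup = config$depth_lookup_mm)
    profile_key <- select_generic_profile(texture, fertility, depth)
    template <- templates[[profile_key]]

    srgf6 <- remap_hc27(template$layers$srgf, clamp01 = TRUE)
    slni6 <- remap_hc27(template$layers$slni)

    iso <- iso_of(crow, ccol)
    cell_index <- (crow - 1) * ncc_total + (ccol - 1)
    profile_id <- paste0(iso, encode_base36(cell_index, width = 8))
    lon <- if (!is.null(spec)) {
      spec$xmin + (ccol - 0.5) * block * spec$cellsize_deg
    } else ccol
    lat <- if (!is.null(spec)) {
      spec$ymax - (crow - 0.5) * block * spec$cellsize_deg
    } else -crow

    layers <- tibble::tibble(
      slb = STD_LAYER_BOTTOM,
      slmh = c("A", "A", "AB", "BA", "B", "BC"),
      slll = ld$theta1500,
      sdul = ld$theta33,
      ssat = ld$thetaS,
      srgf = srgf6,
      ssks = ld$ks_cm_h,
      sbdm = ld$bd / 1000,
      sloc = ld$oc / 10,
      slcl = ld$clay,
      slsi = ld$silt,
      slcf = -99,
      slni = slni6,
      slhw = ld$ph,
      slhb = -99,
      scec = ld$cec
    )
    profiles[[profile_id]] <- new_soil_profile(
      profile_id = profile_id,
      source = "GENSOL",
      texture_label = substr(texture, 1, 1),
      depth_cm = max(STD_LAYER_BOTTOM),
      description = paste(tolower(texture), tolower(fertility),
        tolower(depth), "generic profile"),
      site = list(site = "Grid", country = iso, lat = lat, lon = lon,
        scs = "Generic"),
      surface = template$surface,
      layers = layers
    )
    cells[[length(cells) + 1]] <- tibble::tibble(
      crow = crow, ccol = ccol, lon = lon, lat = lat, iso = iso,
      texture = texture, fertility = fertility, depth = depth,
      awc_mm = awc$awc_mm, generic_profile = profile_key,
      profile_id = profile_id
    )
  }

  cells <- if (length(cells) > 0) dplyr::bind_rows(cells) else tibble::tibble()
  structure(
    list(
      profiles = profiles,
      cells = cells,
      report = list(
        n_cells = nrow(wide),
        n_built = length(profiles),
        n_skipped = n_skipped,
        n_fine_clamped = n_clamped_fine,
        ptf_stage = config$ptf_stage
      )
    ),
    class = "sol_build"
  )
}

#' @export
print.sol_build <- function(x, ...) {
  cat("<sol_build> ", x$report$n_built, " profiles from ", x$report$n_cells,
    " coarse cells (", x$report$n_skipped, " skipped, ptf_stage=",
    x$report$ptf_stage, ")\n", sep = "")
  invisible(x)
}

#' Partition built profiles into per-country *.SOL files
#'
#' Writes one file `<ISO>.SOL` per country occurring in the build (a
#' profile's country is fixed at build time by the cell-center rule
#' against the mask); countries are emitted in sorted order and profiles
#' in row-major cell order, so reruns are byte-identical. No file is
#' written for a country with no profiles. Without a mask the build puts
#' everything in the catch-all code, yielding a single combined file.
#'
#' @param build A `sol_build` object.
#' @param out_dir Output directory (created if needed).
#' @return Tibble with `iso`, `file`, `n_profiles`.
#' @export
partition_by_country <- function(build, out_dir) {
  stopifnot(inherits(build, "sol_build"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- dplyr::arrange(build$cells, .data$iso, .data$crow, .data$ccol)
  out <- list()
  for (iso in sort(unique(cells$iso))) {
    ids <- cells$profile_id[cells$iso == iso]
    path <- file.path(out_dir, paste0(iso, ".SOL"))
    write_sol(build$profiles[ids], path,
      title = paste0("country ", iso, " soil profiles"))
    out[[length(out) + 1]] <- tibble::tibble(
      iso = iso, file = path, n_profiles = length(ids)
    )
  }
  dplyr::bind_rows(out)
}

#' Run the whole build in one call
#'
#' Convenience wrapper: derive, classify and assemble profiles from a fine
#' stack, then write per-country *.SOL files.
#'
#' @inheritParams build_profiles
#' @param out_dir Directory for the *.SOL output.
#' @return The `sol_build` object, with the partition table attached as
#'   `$files`.
#' @export
sol_build_pipeline <- function(stack, out_dir, templates = load_templates(),
                               config = sol_config(), mask = NULL) {
  build <- build_profiles(stack, templates = templates, config = config,
    mask = mask)
  build$files <- partition_by_country(build, out_dir)
  build
}
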