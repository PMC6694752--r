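#' Generic soil profile classification (27 texture x fertility x depth types)
#'
#' Each grid cell is assigned one of 27 generic soil profiles keyed by a
#' three-way texture class (clay/loam/sand), a fertility class (high/medium/
#' low, proxied by topsoil organic carbon) and a rooting-depth class (deep/
#' medium/shallow, proxied by available water content of the top metre).
#' The selected generic profile supplies the surface parameters, the root
#' growth factor (SRGF) and total nitrogen (SLNI) that cannot be read off
#' the input grids.
#'
#' @name hc27
NULL

# Standard output depth intervals (cm) and generic-profile template depths.
STD_LAYER_TOP <- c(0, 5, 15, 30, 60, 100)
STD_LAYER_BOTTOM <- c(5, 15, 30, 60, 100, 200)
HC27_LAYER_TOP <- c(0, 10, 30, 60, 90, 120, 150)
HC27_LAYER_BOTTOM <- c(10, 30, 60, 90, 120, 150, 180)

TEXTURE_LEVELS <- c("CLAY", "LOAM", "SAND")
FERTILITY_LEVELS <- c("HIGH", "MEDIUM", "LOW")
DEPTH_LEVELS <- c("DEEP", "MEDIUM", "SHALLOW")

# Rootable depth (cm) by depth class, used to zero template SRGF at depth.
ROOTABLE_DEPTH_CM <- c(DEEP = 180, MEDIUM = 120, SHALLOW = 60)

#' The 27-row generic-profile decision table
#'
#' Texture varies slowest (clay, loam, sand), then fertility (high, medium,
#' low), then depth (deep, medium, shallow), so clay/high/deep is
#' `HC_GEN0001` and sand/low/shallow is `HC_GEN0027`. The mapping is a
#' bijection: every class triple appears exactly once.
#'
#' @return A 27-row tibble with columns `texture`, `fertility`, `depth`,
#'   `profile_id`.
#' @export
hc27_table <- function() {
  grid <- expand.grid(
    depth = DEPTH_LEVELS, fertility = FERTILITY_LEVELS,
    texture = TEXTURE_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(
    texture = grid$texture,
    fertility = grid$fertility,
    depth = grid$depth,
    profile_id = sprintf("HC_GEN%04d", seq_len(27))
  )
}

#' Classify texture into clay / loam / sand
#'
#' Collapses the texture triangle to three regions: CLAY when clay >= 40 %,
#' SAND when sand >= 65 % and clay < 18 %, otherwise LOAM. The thresholds
#' are configuration keys (`texture_rule`), not measured constants.
#'
#' @param sand,clay Mass percentages.
#' @param rule Named list with `clay_min`, `sand_min`, `sand_clay_max`.
#' @return Character vector over `"CLAY"`, `"LOAM"`, `"SAND"`.
#' @export
classify_texture <- function(sand, clay,
                             rule = sol_config()$texture_rule) {
  dplyr::case_when(
    clay >= rule$clay_min ~ "CLAY",
    sand >= rule$sand_min & clay < rule$sand_clay_max ~ "SAND",
    TRUE ~ "LOAM"
  )
}

#' Classify fertility from topsoil organic carbon
#'
#' @param oc_topsoil_pct Organic carbon %, thickness-weighted over 0--30 cm.
#' @param thresholds Named list with `high` and `medium` lower bounds (%).
#' @return Character vector over `"HIGH"`, `"MEDIUM"`, `"LOW"`.
#' @export
classify_fertility <- function(oc_topsoil_pct,
                               thresholds = sol_config()$fertility_thresholds_pct) {
  dplyr::case_when(
    oc_topsoil_pct >= thresholds$high ~ "HIGH",
    oc_topsoil_pct >= thresholds$medium ~ "MEDIUM",
    TRUE ~ "LOW"
  )
}

#' Available water content of the top metre
#'
#' AWC = 1000 (SDUL - SLLL) Zr, accumulated layer by layer over the part of
#' each layer that intersects 0--100 cm (so the 100--200 cm layer
#' contributes nothing). Units: mm per metre of soil.
#'
#' @param layers Data frame with columns `slb` (layer bottom, cm, strictly
#'   increasing from the surface), `sdul` and `slll` (cm3/cm3).
#' @param zr_m Root-zone depth over which AWC is integrated (m).
#' @return A one-row tibble with `awc_mm` and `zr_m`.
#' @export
compute_awc_1m <- function(layers, zr_m = 1.0) {
  layers <- tibble::as_tibble(layers)
  need <- c("slb", "sdul", "slll")
  if (!all(need %in% names(layers))) {
    stop("incomplete profile: need columns slb, sdul, slll", call. = FALSE)
  }
  if (any(is.na(layers$sdul) | is.na(layers$slll))) {
    stop("incomplete profile: nodata in sdul/slll", call. = FALSE)
  }
  top <- c(0, utils::head(layers$slb, -1))
  zr_cm <- zr_m * 100
  thick_m <- pmax(pmin(layers$slb, zr_cm) - pmin(top, zr_cm), 0) / 100
  tibble::tibble(
    awc_mm = 1000 * sum((layers$sdul - layers$slll) * thick_m),
    zr_m = zr_m
  )
}

#' Classify rooting depth from AWC and texture
#'
#' Per-texture lookup on AWC (mm per m). Intervals are lower-exclusive /
#' upper-inclusive: a clay soil is DEEP above 150 mm/m, MEDIUM in
#' (100, 150] and SHALLOW at or below 100; loam splits at 150/75 and sand
#' at 125/75. The table is a configuration key (`depth_lookup_mm`) and
#' reproduces the worked example clay + AWC 140 mm/m -> MEDIUM.
#'
#' @param awc_mm AWC of the top metre, mm.
#' @param texture Texture class vector (`"CLAY"`, `"LOAM"`, `"SAND"`).
#' @param lookup Per-texture list of `deep_gt` and `medium_gt` breakpoints.
#' @return Character vector over `"DEEP"`, `"MEDIUM"`, `"SHALLOW"`.
#' @export
classify_rooting_depth <- function(awc_mm, texture,
                                   lookup = sol_config()$depth_lookup_mm) {
  stopifnot(length(awc_mm) == length(texture) || length(texture) == 1)
  texture <- rep_len(texture, length(awc_mm))
  purrr::map2_chr(awc_mm, texture, function(a, tx) {
    br <- lookup[[tx]]
    if (is.null(br)) stop("unknown texture class: ", tx, call. = FALSE)
    if (a > br$deep_gt) "DEEP" else if (a > br$medium_gt) "MEDIUM" else "SHALLOW"
  })
}

#' Select the generic profile for a class triple
#'
#' @param texture,fertility,depth Class labels (vectorised).
#' @return Character vector of profile IDs, `HC_GEN0001` ... `HC_GEN0027`.
#' @export
select_generic_profile <- function(texture, fertility, depth) {
  tab <- hc27_table()
  key <- paste(texture, fertility, depth)
  id <- tab$profile_id[match(key, paste(tab$texture, tab$fertility, tab$depth))]
  if (any(is.na(id))) {
    stop("invalid class triple: ", paste(unique(key[is.na(id)]), collapse = "; "),
      call. = FALSE)
  }
  id
}

# ---- packaged default templates -------------------------------------------

# Surface parameters by texture class. These are crop-model-conventional
# defaults (albedo, first-stage evaporation limit, drainage rate, runoff
# curve number), synthetic stand-ins for the original generic-profile
# values, which are not distributed with this package. Supplying real
# template files via load_templates(dir) is the supported path to fidelity.
SURFACE_DEFAULTS <- list(
  CLAY = list(SCOM = "BN", SALB = 0.13, SLU1 = 10.0, SLDR = 0.25, SLRO = 85,
    SLNF = 1.00, SLPF = 1.00, SMHB = "IB001", SMPX = "IB001", SMKE = "IB001"),
  LOAM = list(SCOM = "BN", SALB = 0.12, SLU1 = 9.0, SLDR = 0.50, SLRO = 76,
    SLNF = 1.00, SLPF = 1.00, SMHB = "IB001", SMPX = "IB001", SMKE = "IB001"),
  SAND = list(SCOM = "BN", SALB = 0.15, SLU1 = 6.0, SLDR = 0.75, SLRO = 64,
    SLNF = 1.00, SLPF = 1.00, SMHB = "IB001", SMPX = "IB001", SMKE = "IB001")
)

# Representative texture (%) and topsoil OC (g/kg) used to give the default
# templates physically consistent water contents via the package's own PTFs.
TEMPLATE_TEXTURE <- list(
  CLAY = c(sand = 20, silt = 30, clay = 50),
  LOAM = c(sand = 40, silt = 40, clay = 20),
  SAND = c(sand = 80, silt = 12, clay = 8)
)
TEMPLATE_TOPSOIL_OC <- c(HIGH = 16, MEDIUM = 9, LOW = 4)
TEMPLATE_TOPSOIL_SLNI <- c(HIGH = 0.15, MEDIUM = 0.10, LOW = 0.05)

template_srgf <- function(depth_class) {
  mid <- (HC27_LAYER_TOP + HC27_LAYER_BOTTOM) / 2
  srgf <- ifelse(mid <= 15, 1.0, exp(-0.02 * (mid - 15)))
  srgf[HC27_LAYER_TOP >= ROOTABLE_DEPTH_CM[[depth_class]]] <- 0
  srgf
}

template_slni <- function(fertility_class) {
  mid <- (HC27_LAYER_TOP + HC27_LAYER_BOTTOM) / 2
  TEMPLATE_TOPSOIL_SLNI[[fertility_class]] * exp(-0.015 * pmax(mid - 5, 0))
}

build_default_template <- function(texture, fertility, depth, profile_id) {
  tex <- TEMPLATE_TEXTURE[[texture]]
  oc_top <- TEMPLATE_TOPSOIL_OC[[fertility]]
  mid <- (HC27_LAYER_TOP + HC27_LAYER_BOTTOM) / 2
  oc <- oc_top * exp(-0.015 * pmax(mid - 5, 0))
  hyd <- derive_hydraulics(tibble::tibble(
    sand = tex[["sand"]], silt = tex[["silt"]], clay = tex[["clay"]], oc = oc
  ))
  layers <- tibble::tibble(
    slb = HC27_LAYER_BOTTOM,
    slmh = c("A", "A", "AB", "BA", "B", "BC", "C"),
    slll = hyd$theta1500,
    sdul = hyd$theta33,
    ssat = hyd$thetaS,
    srgf = template_srgf(depth),
    ssks = hyd$ks_cm_h,
    sbdm = c(1.25, 1.30, 1.35, 1.40, 1.45, 1.50, 1.55),
    sloc = oc / 10,
    slcl = tex[["clay"]],
    slsi = tex[["silt"]],
    slcf = -99,
    slni = template_slni(fertility),
    slhw = 6.5,
    slhb = -99,
    scec = switch(texture, CLAY = 25, LOAM = 15, SAND = 5)
  )
  new_soil_profile(
    profile_id = profile_id,
    source = "GENSOL",
    texture_label = substr(texture, 1, 1),
    depth_cm = max(HC27_LAYER_BOTTOM),
    description = paste("Generic", tolower(texture), tolower(fertility),
      tolower(depth), "(synthetic template)"),
    site = list(site = "Generic", country = "Generic", lat = -99, lon = -99,
      scs = "Generic"),
    surface = SURFACE_DEFAULTS[[texture]],
    layers = layers
  )
}

#' Packaged default generic-profile templates
#'
#' Builds the 27 default templates in memory. Root growth factor follows a
#' fall-off rule (1.0 down to a 15 cm layer midpoint, then
#' `exp(-0.02 (midpoint - 15))`), zeroed below the rootable depth of the
#' class (deep 180 cm, medium 120 cm, shallow 60 cm). Water contents are
#' internally consistent with the package's pedo-transfer functions for a
#' representative texture per class. All values are documented synthetic
#' stand-ins for the original generic profiles.
#'
#' @return Named list of 27 `soil_profile` objects, `HC_GEN0001` ...
#'   `HC_GEN0027`.
#' @export
default_templates <- function() {
  tab <- hc27_table()
  out <- purrr::pmap(tab, function(texture, fertility, depth, profile_id) {
    build_default_template(texture, fertility, depth, profile_id)
  })
  stats::setNames(out, tab$profile_id)
}

validate_template_set <- function(templates) {
  tab <- hc27_table()
  ids <- names(templates)
  missing <- setdiff(tab$profile_id, ids)
  dup <- ids[duplicated(ids)]
  if (length(missing) > 0 || length(dup) > 0) {
    stop("template set must contain each of HC_GEN0001..HC_GEN0027 exactly once",
      if (length(missing) > 0) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(dup) > 0) paste0("; duplicated: ", paste(dup, collapse = ", ")),
      call. = FALSE)
  }
  for (id in tab$profile_id) {
    p <- templates[[id]]
    srgf <- p$layers$srgf
    if (any(srgf < 0 | srgf > 1)) {
      stop("template ", id, ": SRGF outside [0,1]", call. = FALSE)
    }
    if (any(diff(srgf) > 1e-9)) {
      stop("template ", id, ": SRGF must be non-increasing with depth",
        call. = FALSE)
    }
    depth_class <- tab$depth[tab$profile_id == id]
    rd <- ROOTABLE_DEPTH_CM[[depth_class]]
    top <- c(0, utils::head(p$layers$slb, -1))
    if (any(srgf[top >= rd] > 0)) {
      stop("template ", id, ": SRGF must be 0 below the rootable depth of a ",
        tolower(depth_class), " profile (", rd, " cm)", call. = FALSE)
    }
  }
  invisible(templates)
}

#' Load generic-profile templates
#'
#' With no directory, returns the 27 packaged defaults. With a directory of
#' *.SOL files, parses them with [read_sol()] and uses them instead,
#' ID-by-ID; the set must cover `HC_GEN0001`..`HC_GEN0027` exactly once and
#' pass the template invariants (SRGF within 0--1, non-increasing, zero
#' below the rootable depth of the class), which are enforced with a hard
#' error for user-supplied files.
#'
#' @param dir Optional directory containing template *.SOL files.
#' @return Named list of 27 `soil_profile` objects.
#' @export
load_templates <- function(dir = NULL) {
  if (is.null(dir)) {
    return(validate_template_set(default_templates()))
  }
  files <- list.files(dir, pattern = "\\.SOL$", ignore.case = TRUE,
    full.names = TRUE)
  if (length(files) == 0) {
    stop("no *.SOL template files found in ", dir, call. = FALSE)
  }
  profs <- purrr::flatten(purrr::map(sort(files), read_sol))
  user <- stats::setNames(profs, purrr::map_chr(profs, "profile_id"))
  want <- hc27_table()$profile_id
  extra <- setdiff(names(user), want)
  if (length(extra) > 0) {
    stop("unrecognized template IDs: ", paste(extra, collapse = ", "),
      call. = FALSE)
  }
  missing <- setdiff(want, names(user))
  if (length(missing) > 0) {
    stop("template directory must supply all 27 profiles; missing: ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_template_set(user[want])
}
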