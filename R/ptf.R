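#' Pedo-transfer functions for soil hydraulic properties
#'
#' Empirical regressions predicting volumetric soil water content at wilting
#' point (-1500 kPa, DSSAT name SLLL), field capacity (-33 kPa, SDUL) and
#' saturation (SSAT), plus saturated hydraulic conductivity (SSKS), from soil
#' texture and organic matter.
#'
#' Input scaling matters: sand and clay enter the regressions as *decimal
#' fractions* (0--1) while organic matter enters as a mass percentage. This is
#' the only convention under which the published coefficients yield physical
#' water contents, and every function in this file enforces it with a sanity
#' assertion (`sand`/`clay` greater than 1.5 are rejected as almost certainly
#' percentages passed by mistake).
#'
#' All functions are vectorised, pure and deterministic.
#'
#' @name ptf
NULL

#' Convert organic carbon to organic matter
#'
#' Source grids carry soil organic carbon (SOC) in g/kg; the pedo-transfer
#' equations want organic matter (OM) in mass %. SOC in % is g/kg divided by
#' 10; OM is taken as 2 x SOC (the factor 2 conversion, in preference to the
#' conventional van-Bemmelen factor 1.724).
#'
#' @param oc_g_per_kg Organic carbon in g per kg soil (non-negative).
#' @return A tibble with columns `organic_carbon_pct` and `organic_matter_pct`.
#' @examples
#' oc_to_om(10)  # OC 1 %, OM 2 %
#' @export
oc_to_om <- function(oc_g_per_kg) {
  if (any(!is.na(oc_g_per_kg) & oc_g_per_kg < 0)) {
    stop("organic carbon must be non-negative", call. = FALSE)
  }
  oc_pct <- oc_g_per_kg / 10
  tibble::tibble(
    organic_carbon_pct = oc_pct,
    organic_matter_pct = 2 * oc_pct
  )
}

assert_fraction_scale <- function(sand, clay) {
  bad <- !is.na(sand) & !is.na(clay) & (sand > 1.5 | clay > 1.5)
  if (any(bad)) {
    stop(
      "sand/clay must be decimal fractions (0-1); values > 1.5 look like percentages",
      call. = FALSE
    )
  }
  invisible(NULL)
}

#' Wilting-point water content (-1500 kPa)
#'
#' First-solution regression followed by its density correction:
#' theta1500t = -0.024 S + 0.487 C + 0.006 OM + 0.005 (S x OM)
#'              - 0.013 (C x OM) + 0.068 (S x C) + 0.031;
#' theta1500  = theta1500t + (0.14 theta1500t - 0.02).
#'
#' @param sand,clay Sand and clay as decimal fractions (0--1).
#' @param om Organic matter, mass %.
#' @return Volumetric water content, cm3/cm3.
#' @export
ptf_wilting_point <- function(sand, clay, om) {
  assert_fraction_scale(sand, clay)
  t1500t <- -0.024 * sand + 0.487 * clay + 0.006 * om +
    0.005 * (sand * om) - 0.013 * (clay * om) + 0.068 * (sand * clay) + 0.031
  t1500t + (0.14 * t1500t - 0.02)
}

#' Field-capacity water content (-33 kPa)
#'
#' theta33t = -0.251 S + 0.195 C + 0.011 OM + 0.006 (S x OM)
#'            - 0.027 (C x OM) + 0.452 (S x C) + 0.299;
#' theta33  = theta33t + (1.283 theta33t^2 - 0.374 theta33t - 0.015).
#'
#' @inheritParams ptf_wilting_point
#' @return Volumetric water content, cm3/cm3.
#' @export
ptf_field_capacity <- function(sand, clay, om) {
  assert_fraction_scale(sand, clay)
  t33t <- -0.251 * sand + 0.195 * clay + 0.011 * om +
    0.006 * (sand * om) - 0.027 * (clay * om) + 0.452 * (sand * clay) + 0.299
  t33t + (1.283 * t33t^2 - 0.374 * t33t - 0.015)
}

#' Saturation water content (0 kPa)
#'
#' Built from the SAT-33 kPa moisture regression:
#' thetaS33t = 0.278 S + 0.034 C + 0.022 OM - 0.018 (S x OM)
#'             - 0.027 (C x OM) - 0.584 (S x C) + 0.078;
#' thetaS33  = thetaS33t + (0.636 thetaS33t - 0.107);
#' thetaS    = theta33 + thetaS33 - 0.097 S + 0.043.
#'
#' @inheritParams ptf_wilting_point
#' @param theta33 Optional precomputed field capacity for the same inputs;
#'   recomputed when missing.
#' @return Volumetric water content, cm3/cm3.
#' @export
ptf_saturation <- function(sand, clay, om, theta33 = NULL) {
  assert_fraction_scale(sand, clay)
  if (is.null(theta33)) theta33 <- ptf_field_capacity(sand, clay, om)
  ts33t <- 0.278 * sand + 0.034 * clay + 0.022 * om -
    0.018 * (sand * om) - 0.027 * (clay * om) - 0.584 * (sand * clay) + 0.078
  ts33 <- ts33t + (0.636 * ts33t - 0.107)
  theta33 + ts33 - 0.097 * sand + 0.043
}

#' Saturated hydraulic conductivity
#'
#' KS = 1930 (thetaS - theta33)^(3 - lambda), with lambda = 1/B and
#' B = [ln(1500) - ln(33)] / [ln(theta33) - ln(theta1500)]. The exponent
#' applies to the moisture difference. Returned in mm/h; divide by 10 for the
#' DSSAT unit (cm/h).
#'
#' @param theta1500,theta33,thetaS Water contents, cm3/cm3, ordered
#'   0 < theta1500 < theta33 and theta33 <= thetaS.
#' @return Saturated conductivity, mm/h.
#' @export
ptf_ksat <- function(theta1500, theta33, thetaS) {
  if (any(!is.na(theta1500) & !is.na(theta33) & theta33 <= theta1500)) {
    stop("theta33 must exceed theta1500 (log-slope undefined otherwise)",
      call. = FALSE)
  }
  B <- (log(1500) - log(33)) / (log(theta33) - log(theta1500))
  lambda <- 1 / B
  1930 * (pmax(thetaS - theta33, 0))^(3 - lambda)
}

# Validity-domain bounds for clamping non-physical regression output.
PTF_DOMAIN <- list(min_theta1500 = 0.01, min_awc_gap = 0.01, max_thetaS = 0.60)

#' Derive the full set of hydraulic properties for soil layers
#'
#' Applies the four pedo-transfer functions to a table of layer records and
#' appends the results. Texture comes in as percentages (the native unit of
#' the source grids); the conversion to the fractional scale the regressions
#' require happens here, once.
#'
#' Regression output falling outside the validity domain (theta1500 < 0.01,
#' theta33 - theta1500 < 0.01, thetaS > 0.60, or an inverted
#' saturation/field-capacity pair) is clamped to the nearest bound and flagged
#' in the logical `ptf_clamped` column -- non-physical water contents are
#' never emitted silently.
#'
#' @param layers A data frame with columns `sand`, `silt`, `clay` (mass %,
#'   summing to 100 within 0.5) and `oc` (organic carbon, g/kg). Extra
#'   columns pass through.
#' @param sum_tol Tolerance on the texture closure check, percentage points.
#' @return The input tibble plus `theta1500`, `theta33`, `thetaS`,
#'   `ks_mm_h`, `ks_cm_h` and `ptf_clamped`.
#' @examples
#' derive_hydraulics(tibble::tibble(sand = 40, silt = 40, clay = 20, oc = 15))
#' @export
derive_hydraulics <- function(layers, sum_tol = 0.5) {
  layers <- tibble::as_tibble(layers)
  need <- c("sand", "silt", "clay", "oc")
  miss <- setdiff(need, names(layers))
  if (length(miss) > 0) {
    stop("incomplete layer inputs: missing ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  if (any(is.na(layers$sand) | is.na(layers$silt) | is.na(layers$clay) |
      is.na(layers$oc))) {
    stop("incomplete layer inputs: nodata in sand/silt/clay/oc", call. = FALSE)
  }
  tex_sum <- layers$sand + layers$silt + layers$clay
  if (any(abs(tex_sum - 100) > sum_tol)) {
    stop("texture fractions must sum to 100 (tolerance ", sum_tol, ")",
      call. = FALSE)
  }
  if (any(layers$sand < 0 | layers$silt < 0 | layers$clay < 0)) {
    stop("texture fractions must be non-negative", call. = FALSE)
  }

  S <- layers$sand / 100
  C <- layers$clay / 100
  om <- oc_to_om(layers$oc)$organic_matter_pct

  t1500 <- ptf_wilting_point(S, C, om)
  t33 <- ptf_field_capacity(S, C, om)
  tS <- ptf_saturation(S, C, om, theta33 = t33)

  dom <- PTF_DOMAIN
  clamped <- t1500 < dom$min_theta1500 |
    (t33 - t1500) < dom$min_awc_gap |
    tS > dom$max_thetaS |
    tS <= t33
  t1500c <- pmax(t1500, dom$min_theta1500)
  t33c <- pmax(t33, t1500c + dom$min_awc_gap)
  tSc <- pmin(tS, dom$max_thetaS)
  tSc <- pmax(tSc, t33c + dom$min_awc_gap)

  ks <- ptf_ksat(t1500c, t33c, tSc)

  dplyr::mutate(layers,
    theta1500 = t1500c,
    theta33 = t33c,
    thetaS = tSc,
    ks_mm_h = ks,
    ks_cm_h = ks / 10,
    ptf_clamped = clamped
  )
}
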