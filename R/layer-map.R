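#' Remap generic-profile layers onto the standard output layers
#'
#' The generic profiles carry seven layers (0-10, 10-30, 30-60, 60-90,
#' 90-120, 120-150, 150-180 cm) while the output profiles use the six
#' standard grid intervals (0-5, 5-15, 15-30, 30-60, 60-100, 100-200 cm).
#' Template-inherited per-layer values (SRGF, SLNI) are transferred with
#' fixed weighted averages; the 5-15 cm output deliberately uses equal
#' weights on the first two template layers rather than exact overlap
#' fractions, matching the published allocation.
#'
#' @name layer_mapping
NULL

#' Default layer weight scheme
#'
#' Weights of the seven template layers for each of the six output layers:
#' 0-5 cm takes template layer 1; 5-15 averages layers 1 and 2 equally;
#' 15-30 takes layer 2; 30-60 takes layer 3; 60-100 mixes layers 4 and 5 at
#' 0.75/0.25; 100-200 mixes layers 5, 6, 7 at 0.2/0.3/0.5. Each row sums
#' to 1 exactly.
#'
#' @return A tibble with columns `out_layer` (1-6), `slb` (output layer
#'   bottom, cm), `hc27_layer` (1-7) and `weight`.
#' @export
layer_weight_scheme <- function() {
  tibble::tibble(
    out_layer = c(1L, 2L, 2L, 3L, 4L, 5L, 5L, 6L, 6L, 6L),
    slb = STD_LAYER_BOTTOM[c(1, 2, 2, 3, 4, 5, 5, 6, 6, 6)],
    hc27_layer = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L, 6L, 7L),
    weight = c(1, 0.5, 0.5, 1, 1, 0.75, 0.25, 0.2, 0.3, 0.5)
  )
}

validate_scheme <- function(scheme) {
  stopifnot(all(c("out_layer", "hc27_layer", "weight") %in% names(scheme)))
  if (any(scheme$weight < 0 | scheme$weight > 1)) {
    stop("scheme weights must lie in [0,1]", call. = FALSE)
  }
  sums <- tapply(scheme$weight, scheme$out_layer, sum)
  if (length(sums) != 6 || any(abs(sums - 1) > 1e-12)) {
    stop("scheme weights must sum to 1 within each of the 6 output layers",
      call. = FALSE)
  }
  invisible(scheme)
}

#' Remap seven template-layer values to the six output layers
#'
#' Output layer j is the weighted sum of the template values under the
#' scheme. With `clamp01 = TRUE` (used for SRGF) results are clamped to
#' the unit interval; weighted averages of in-range inputs cannot leave it,
#' so the clamp only guards user-supplied out-of-range templates.
#'
#' @param values_7 Numeric vector of exactly 7 per-template-layer values.
#' @param scheme Weight scheme tibble, by default [layer_weight_scheme()].
#' @param clamp01 Clamp outputs to the unit interval.
#' @return Numeric vector of 6 per-output-layer values.
#' @examples
#' remap_hc27(c(1, 1, 1, 0.8, 0.4, 0.2, 0))
#' @export
remap_hc27 <- function(values_7, scheme = layer_weight_scheme(),
                       clamp01 = FALSE) {
  if (length(values_7) != 7 || any(is.na(values_7))) {
    stop("values_7 must be 7 non-missing template-layer values", call. = FALSE)
  }
  validate_scheme(scheme)
  out <- vapply(
    split(scheme, scheme$out_layer),
    function(s) sum(s$weight * values_7[s$hc27_layer]),
    numeric(1)
  )
  out <- unname(out[order(as.integer(names(out)))])
  if (clamp01) out <- pmin(pmax(out, 0), 1)
  out
}
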