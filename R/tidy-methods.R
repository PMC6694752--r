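#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a soil profile into one row per layer
#'
#' @param x A `soil_profile`.
#' @param ... Unused.
#' @return A tibble of the layer records with `profile_id`, `top` and
#'   depth columns prepended.
#' @method tidy soil_profile
#' @export
tidy.soil_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      profile_id = x$profile_id,
      top = c(0, utils::head(x$layers$slb, -1))
    ),
    x$layers
  )
}

#' One-row summary of a soil profile
#'
#' @param x A `soil_profile`.
#' @param ... Unused.
#' @return A one-row tibble: ID, site, layer count, depth and AWC of the
#'   top metre.
#' @method glance soil_profile
#' @export
glance.soil_profile <- function(x, ...) {
  awc <- compute_awc_1m(x$layers)
  tibble::tibble(
    profile_id = x$profile_id,
    country = x$site$country,
    lat = x$site$lat,
    lon = x$site$lon,
    n_layers = nrow(x$layers),
    depth_cm = x$depth_cm,
    awc_mm = awc$awc_mm
  )
}

#' Tidy a build result into its per-cell classification table
#'
#' @param x A `sol_build`.
#' @param ... Unused.
#' @return The `cells` tibble (one row per built coarse cell).
#' @method tidy sol_build
#' @export
tidy.sol_build <- function(x, ...) x$cells

#' One-row summary of a build
#'
#' @param x A `sol_build`.
#' @param ... Unused.
#' @return A one-row tibble of the run report counts.
#' @method glance sol_build
#' @export
glance.sol_build <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Water-retention depth plot for a soil profile
#'
#' Step plot of wilting point, field capacity and saturation against
#' depth, the standard way to eyeball a profile's plant-available water.
#'
#' @param object A `soil_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot soil_profile
#' @export
autoplot.soil_profile <- function(object, ...) {
  d <- tidy.soil_profile(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("slll", "sdul", "ssat")),
      names_to = "property", values_to = "theta") |>
    dplyr::mutate(property = dplyr::recode(.data$property,
      slll = "wilting point (SLLL)", sdul = "field capacity (SDUL)",
      ssat = "saturation (SSAT)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$slb,
    colour = .data$property)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = expression(paste("water content (", cm^3, " ", cm^-3, ")")),
      y = "layer bottom depth (cm)",
      colour = NULL,
      title = object$profile_id
    )
}

#' Map of the classified coarse grid
#'
#' Tile map of one classification facet (texture, fertility, rooting
#' depth or generic profile) over the built coarse cells.
#'
#' @param object A `sol_build`.
#' @param what Column of the cell table to map.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sol_build
#' @export
autoplot.sol_build <- function(object, what = "texture", ...) {
  stopifnot(what %in% names(object$cells))
  ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$ccol, y = .data$crow,
    fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "coarse column", y = "coarse row", fill = what)
}

#' Kernel-density overview of derived water contents
#'
#' Density curves of wilting point and field capacity across all built
#' profiles -- the narrow, agricultural-range shape of these
#' distributions is the first sanity check on a build.
#'
#' @param build A `sol_build`.
#' @return A ggplot object.
#' @export
plot_water_content_density <- function(build) {
  d <- purrr::map_dfr(build$profiles, tidy.soil_profile) |>
    tidyr::pivot_longer(dplyr::all_of(c("slll", "sdul")),
      names_to = "property", values_to = "theta")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, colour = .data$property)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = expression(paste("water content (", cm^3, " ", cm^-3,
      ")")), colour = NULL)
}
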