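#' Pipeline configuration
#'
#' All tunable thresholds of the build live in one flat configuration list:
#' the three-way texture collapse (`texture_rule`), the fertility bounds on
#' topsoil organic carbon (`fertility_thresholds_pct`), the per-texture
#' rooting-depth lookup on AWC (`depth_lookup_mm`), the minimum fraction of
#' valid fine pixels for a coarse cell to be emitted
#' (`min_valid_fraction`), whether the pedo-transfer functions run on fine
#' pixels before aggregation or on coarse-cell means (`ptf_stage`), the
#' aggregation block size (`block`, fine pixels per coarse cell edge), and
#' the ISO code used for cells outside the country mask (`catchall_iso`).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of configuration values.
#' @examples
#' sol_config(min_valid_fraction = 0.25)
#' @export
sol_config <- function(...) {
  cfg <- list(
    texture_rule = list(clay_min = 40, sand_min = 65, sand_clay_max = 18),
    fertility_thresholds_pct = list(high = 1.2, medium = 0.7),
    depth_lookup_mm = list(
      CLAY = list(deep_gt = 150, medium_gt = 100),
      LOAM = list(deep_gt = 150, medium_gt = 75),
      SAND = list(deep_gt = 125, medium_gt = 75)
    ),
    min_valid_fraction = 0.5,
    ptf_stage = "fine",
    block = 10L,
    catchall_iso = "XX"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
      call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (!cfg$ptf_stage %in% c("fine", "coarse")) {
    stop("ptf_stage must be 'fine' or 'coarse'", call. = FALSE)
  }
  cfg
}

#' Read configuration overrides from a YAML file
#'
#' @param path YAML file whose top-level keys override [sol_config()]
#'   defaults.
#' @return A configuration list.
#' @export
read_sol_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files",
      call. = FALSE)
  }
  do.call(sol_config, yaml::read_yaml(path))
}
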