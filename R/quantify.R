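#' Field geometry and culture-vessel specification
#'
#' A field of view's physical area follows from its pixel dimensions and the
#' working-resolution pixel pitch: `area_mm2 = W * H * (um_per_px/1000)^2`.
#' Vessel growth areas use vendor-standard defaults (6-well well 9.6 cm^2,
#' T25 25 cm^2, T75 75 cm^2) or a custom area.
#'
#' @param width_px,height_px Field size in pixels at working resolution.
#' @param um_per_px_working Pixel pitch at working resolution (acquisition
#'   pitch divided by the preprocessing resize factor).
#' @return `cec_field_geometry` with a precomputed `field_area_mm2`.
#' @export
field_geometry <- function(width_px, height_px, um_per_px_working) {
  stopifnot(width_px > 0, height_px > 0, um_per_px_working > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 um_per_px_working = um_per_px_working,
                 field_area_mm2 = width_px * height_px *
                   (um_per_px_working / 1000)^2),
            class = "cec_field_geometry")
}

#' @rdname field_geometry
#' @param vessel_type `"well_6"`, `"T25"`, `"T75"`, or `"custom"`.
#' @param growth_area_cm2 Growth area; required for `"custom"`.
#' @export
vessel_spec <- function(vessel_type = c("well_6", "T25", "T75", "custom"),
                        growth_area_cm2 = NULL) {
  vessel_type <- match.arg(vessel_type)
  defaults <- c(well_6 = 9.6, T25 = 25, T75 = 75)
  if (vessel_type == "custom") {
    if (is.null(growth_area_cm2)) stop("custom vessel needs growth_area_cm2")
  } else {
    growth_area_cm2 <- growth_area_cm2 %||% defaults[[vessel_type]]
  }
  stopifnot(growth_area_cm2 > 0)
  structure(list(vessel_type = vessel_type,
                 growth_area_cm2 = growth_area_cm2),
            class = "cec_vessel_spec")
}

#' Cell density of one field
#'
#' @param det A `cec_detection_result` (or anything with a `centers` data
#'   frame and `image_id`).
#' @param geom A [field_geometry()].
#' @return `cec_density_estimate`: `image_id`, `n_centers`,
#'   `density_cells_per_mm2`.
#' @export
density_from_centers <- function(det, geom) {
  stopifnot(inherits(geom, "cec_field_geometry"))
  n <- nrow(as_centers_df(det$centers))
  structure(list(image_id = det$image_id %||% "", n_centers = n,
                 density_cells_per_mm2 = n / geom$field_area_mm2),
            class = "cec_density_estimate")
}

#' Total cell number in a vessel
#'
#' Averages the per-field densities with equal weights and multiplies by the
#' vessel growth area (1 cm^2 = 100 mm^2).
#'
#' @param estimates Nonempty list of `cec_density_estimate`.
#' @param vessel A [vessel_spec()].
#' @param passage Optional passage number recorded in the result.
#' @return `cec_total_cell_estimate`: `passage`, `mean_density`,
#'   `total_cells`, `n_fields`.
#' @export
total_cells <- function(estimates, vessel, passage = NA_integer_) {
  if (inherits(estimates, "cec_density_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0) stop("total_cells needs at least one field")
  stopifnot(inherits(vessel, "cec_vessel_spec"))
  dens <- vapply(estimates, `[[`, numeric(1), "density_cells_per_mm2")
  md <- mean(dens)
  structure(list(passage = passage, mean_density = md,
                 total_cells = md * vessel$growth_area_cm2 * 100,
                 n_fields = length(estimates)),
            class = "cec_total_cell_estimate")
}
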