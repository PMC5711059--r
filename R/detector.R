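# Detector sampling models: element lattices, area-averaging, presets.

#' Describe a planar detector's sampling pattern
#'
#' Detectors are modeled purely by their sampling lattice at the isocenter
#' plane: a square grid of elements with pitch `element_spacing_cm` that
#' either point-sample the dose at their centers or average it over a
#' square footprint of side `element_size_cm`.
#'
#' Presets (by `name`):
#' \describe{
#'   \item{`array729`}{A 27 x 27 ion-chamber array: 1 cm center-to-center
#'     pitch, 0.5 cm cubic chambers, area-average.}
#'   \item{`epid`}{A flat-panel portal imager: 0.025 cm pixel pitch at
#'     isocenter, point-sample.}
#'   \item{`analysis3mm`}{The 3 mm calculation/analysis grid used for dose
#'     comparison, area-average over the 0.3 cm cell.}
#' }
#'
#' @param name Preset name, or `NULL` to specify the geometry directly.
#' @param element_spacing_cm Center-to-center pitch in cm.
#' @param element_size_cm Averaging footprint side in cm (must not exceed
#'   the pitch).
#' @param mode `"area-average"` or `"point-sample"`.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(name = NULL, element_spacing_cm = NULL,
                          element_size_cm = NULL,
                          mode = c("area-average", "point-sample")) {
  if (!is.null(name) && is.null(element_spacing_cm)) {
    return(switch(name,
      array729 = detector_spec("array729", 1.0, 0.5, "area-average"),
      epid = detector_spec("epid", 0.025, 0.025, "point-sample"),
      analysis3mm = detector_spec("analysis3mm", 0.3, 0.3, "area-average"),
      abort(sprintf("unknown detector preset '%s'", name), "arcqa_config_error")
    ))
  }
  mode <- match.arg(mode)
  if (element_spacing_cm <= 0 || element_size_cm <= 0) {
    abort("detector pitch and size must be > 0", "arcqa_config_error")
  }
  if (element_size_cm > element_spacing_cm + 1e-9) {
    abort("element_size_cm must not exceed element_spacing_cm",
          "arcqa_config_error")
  }
  structure(
    list(name = if (is.null(name)) "custom" else name,
         element_spacing_cm = element_spacing_cm,
         element_size_cm = element_size_cm, mode = mode),
    class = "detector_spec"
  )
}

#' Resample a planar dose onto a detector lattice
#'
#' The detector lattice is centered on the isocenter with the largest odd
#' number of elements whose footprints fit inside the dose grid. In
#' point-sample mode each element takes the dose at the grid node nearest
#' its center; in area-average mode it takes the mean of all nodes whose
#' centers fall within the element footprint (which requires the dose pitch
#' to be no coarser than the element size).
#'
#' @param dose A `planar_dose`.
#' @param det A [detector_spec()].
#' @return A `planar_dose` on the detector lattice (pitch =
#'   `element_spacing_cm`), carrying over the frame and delivery-mode tags.
#' @export
resample_to_detector <- function(dose, det) {
  g <- dose$grid
  s <- det$element_spacing_cm
  margin <- if (det$mode == "area-average") det$element_size_cm / 2 else 0
  if (det$mode == "area-average" && g$spacing_cm > det$element_size_cm + 1e-9) {
    abort("dose grid pitch exceeds detector element size; cannot area-average",
          "arcqa_config_error")
  }
  k <- floor((g$half_extent_cm - margin) / s + 1e-9)
  if (k < 0) {
    abort("detector lattice does not fit inside the dose grid",
          "arcqa_extent_error")
  }
  centers <- s * (-k:k)
  ax <- grid_axis(g)
  if (det$mode == "point-sample") {
    idx <- vapply(centers, function(c) which.min(abs(ax - c)), integer(1))
    if (any(abs(ax[idx] - centers) > g$spacing_cm / 2 + 1e-9)) {
      abort("detector element center outside the dose grid", "arcqa_extent_error")
    }
    V <- dose$values[idx, idx, drop = FALSE]
  } else {
    half <- det$element_size_cm / 2 + 1e-9
    A <- matrix(0, length(centers), length(ax))
    for (m in seq_along(centers)) {
      inside <- which(abs(ax - centers[m]) <= half)
      if (!length(inside)) {
        abort("detector element footprint contains no dose nodes",
              "arcqa_extent_error")
      }
      A[m, inside] <- 1 / length(inside)
    }
    V <- A %*% dose$values %*% t(A)
  }
  planar_dose(V, grid_spec(s, k * s), frame = dose$frame,
              delivery_mode = dose$delivery_mode)
}
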