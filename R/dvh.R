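# Dose-volume-histogram metrics over planar regions of interest.

#' Define a region of interest on a dose grid
#'
#' @param mask Logical matrix congruent with the `planar_dose` grid it will
#'   score; must contain at least one `TRUE` element.
#' @param name ROI name (e.g. `"PTV"`, `"parotid"`).
#' @param role `"target"`, `"parallel-organ"` or `"serial-organ"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, name,
                     role = c("target", "parallel-organ", "serial-organ")) {
  role <- match.arg(role)
  if (!is.logical(mask) || !is.matrix(mask)) {
    abort("ROI mask must be a logical matrix", "arcqa_validation_error")
  }
  if (!any(mask)) abort(sprintf("ROI '%s' is empty", name),
                        "arcqa_validation_error")
  structure(list(name = name, mask = mask, role = role), class = "roi_mask")
}

#' DVH metrics of a dose distribution over an ROI
#'
#' Cumulative-DVH summary under a discrete (no-interpolation) convention:
#' `D_p` is the largest dose `d` such that at least a fraction `p` of the
#' ROI receives `>= d` (the descending order statistic at
#' `ceiling(p * n)`), and `V_x` is the fraction of the ROI receiving
#' `>= x`. Reported metrics are `d95` (coverage), `d1pct` (near-maximum,
#' hottest 1%), `mean_dose`, and `v107_fraction` (hot-spot volume at 107%
#' of the prescription).
#'
#' @param dose A `planar_dose`.
#' @param roi An [roi_mask()] congruent with the dose grid.
#' @param prescription Prescription dose in the units of `dose` (must be
#'   > 0).
#' @return An object of class `dvh_metrics` with fields `d95`, `d1pct`,
#'   `mean_dose`, `v107_fraction`, and the functions `d_at(p)` and
#'   `v_at(x)` for arbitrary coverage levels and dose thresholds.
#' @export
dvh_metrics <- function(dose, roi, prescription) {
  if (!identical(dim(roi$mask), dim(dose$values))) {
    abort("ROI mask and dose grid are not congruent", "arcqa_validation_error")
  }
  if (prescription <= 0) abort("prescription must be > 0", "arcqa_config_error")
  v <- dose$values[roi$mask]
  n <- length(v)
  if (n == 0L) abort("ROI mask is empty", "arcqa_validation_error")
  s <- sort(v, decreasing = TRUE)
  d_at <- function(p) {
    if (p <= 0 || p > 1) abort("coverage fraction must be in (0, 1]",
                               "arcqa_config_error")
    s[ceiling(p * n)]
  }
  v_at <- function(x) mean(v >= x - 1e-12)
  structure(
    list(
      d95 = d_at(0.95),
      d1pct = d_at(0.01),
      mean_dose = mean(v),
      v107_fraction = v_at(1.07 * prescription),
      prescription = prescription,
      roi_name = roi$name,
      n_points = n,
      d_at = d_at,
      v_at = v_at
    ),
    class = "dvh_metrics"
  )
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf(
    "<dvh_metrics '%s'>  mean %.4g  D95 %.4g  D1%% %.4g  V107%% %.1f%%  (n = %d, Rx %.4g)\n",
    x$roi_name, x$mean_dose, x$d95, x$d1pct, 100 * x$v107_fraction,
    x$n_points, x$prescription
  ))
  invisible(x)
}

#' Relative differences between two DVH metric sets
#'
#' Computes `100 * |m0 - m1| / m0` per metric with the unperturbed
#' (MLC0PE) value as denominator, reporting the direction of change
#' separately (`+1` if the perturbed value is larger). A zero denominator
#' yields `NA` with `defined = FALSE` rather than a number.
#'
#' @param m0 `dvh_metrics` of the reference (error-free) plan.
#' @param m1 `dvh_metrics` of the perturbed plan, same ROI and
#'   prescription.
#' @return A data frame with columns `metric`, `mlc0pe`, `mlc1pe`,
#'   `rel_diff_pct`, `sign`, `defined`.
#' @export
metric_relative_difference <- function(m0, m1) {
  if (!identical(m0$roi_name, m1$roi_name) ||
      !isTRUE(all.equal(m0$prescription, m1$prescription))) {
    abort("metrics come from different ROIs or prescriptions",
          "arcqa_validation_error")
  }
  mets <- c("d95", "d1pct", "mean_dose", "v107_fraction")
  rows <- lapply(mets, function(m) {
    a <- m0[[m]]; b <- m1[[m]]
    def <- is.finite(a) && a != 0
    data.frame(
      metric = m, mlc0pe = a, mlc1pe = b,
      rel_diff_pct = if (def) 100 * abs(a - b) / a else NA_real_,
      sign = sign(b - a), defined = def
    )
  })
  do.call(rbind, rows)
}
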