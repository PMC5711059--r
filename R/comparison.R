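# Point-to-point (DTA = 0) dose comparison: signed percent-difference maps,
# pass fractions under the Van Dyk convention, and the dose-difference
# threshold needed to reach a target match rate.

# floating-point guard on |diff| <= delta comparisons
.pass_tol <- 1e-9

#' Configuration for percent-difference comparisons
#'
#' @param normalization `"global"` (Van Dyk: percent differences normalized
#'   to the maximum of the reference map) or `"local"` (normalized to the
#'   reference dose at each point).
#' @param low_dose_cutoff_fraction Points where the reference dose is below
#'   this fraction of the reference maximum are excluded from all
#'   statistics. Default 0.10; use 0 in analytic tests.
#' @param target_match_fraction Target fraction of points required to agree
#'   (default 0.95, the conventional QA pass level).
#' @return An object of class `comparison_config`.
#' @export
comparison_config <- function(normalization = c("global", "local"),
                              low_dose_cutoff_fraction = 0.10,
                              target_match_fraction = 0.95) {
  normalization <- match.arg(normalization)
  if (low_dose_cutoff_fraction < 0 || low_dose_cutoff_fraction >= 1) {
    abort("low_dose_cutoff_fraction must be in [0, 1)", "arcqa_config_error")
  }
  if (target_match_fraction <= 0 || target_match_fraction > 1) {
    abort("target_match_fraction must be in (0, 1]", "arcqa_config_error")
  }
  structure(
    list(normalization = normalization,
         low_dose_cutoff_fraction = low_dose_cutoff_fraction,
         target_match_fraction = target_match_fraction),
    class = "comparison_config"
  )
}

check_same_grid <- function(ref, eval) {
  if (!grids_equal(ref$grid, eval$grid)) {
    abort("reference and evaluated doses are on different grids; refusing to resample silently",
          "arcqa_alignment_error")
  }
}

#' Signed percent-difference map between two planar doses
#'
#' Computes `100 * (ref - eval) / N` point by point at identical detector
#' positions (DTA = 0, no spatial search). Under global normalization
#' `N = max(ref)` everywhere; under local normalization `N = ref` at each
#' point. Points with reference dose below the low-dose cutoff are excluded
#' from the inclusion mask (and so from every downstream statistic).
#'
#' @param ref Reference `planar_dose` (conventionally the error-free
#'   MLC0PE delivery).
#' @param eval Evaluated `planar_dose` (e.g. the MLC1PE delivery) on the
#'   identical grid.
#' @param cfg A [comparison_config()].
#' @param norm_value Optional fixed global normalization dose; default
#'   `max(ref)`. Supplying the same value for both orderings of a pair
#'   makes the comparison exactly symmetric.
#' @return A list with `diff` (signed percent matrix, `NA` where
#'   undefined), `mask` (logical inclusion matrix), `normalization_value`
#'   (`max(ref)` unless overridden), and `cfg`.
#' @export
percent_diff_map <- function(ref, eval, cfg = comparison_config(),
                             norm_value = NULL) {
  check_same_grid(ref, eval)
  R <- ref$values; E <- eval$values
  N <- if (is.null(norm_value)) max(R) else norm_value
  if (N <= 0) abort("reference map is identically zero", "arcqa_statistic_error")
  mask <- R >= cfg$low_dose_cutoff_fraction * N
  if (cfg$normalization == "global") {
    diff <- 100 * (R - E) / N
  } else {
    diff <- matrix(NA_real_, nrow(R), ncol(R))
    pos <- R > 0
    diff[pos] <- 100 * (R[pos] - E[pos]) / R[pos]
    mask <- mask & pos
  }
  list(diff = diff, mask = mask, normalization_value = N, cfg = cfg)
}

#' Fraction of included points agreeing within a dose-difference criterion
#'
#' @param diff Signed percent-difference matrix (from
#'   [percent_diff_map()]).
#' @param mask Logical inclusion mask.
#' @param delta Dose-difference criterion in percent.
#' @return Fraction of masked points with `|diff| <= delta`.
#' @export
pass_fraction <- function(diff, mask, delta) {
  if (!any(mask)) {
    abort("inclusion mask is empty; pass fraction undefined",
          "arcqa_statistic_error")
  }
  mean(abs(diff[mask]) <= delta + .pass_tol)
}

#' Dose-difference threshold required to reach a target match rate
#'
#' The smallest percent-difference criterion delta at which at least
#' `target_match_fraction` of the included points agree between the two
#' maps. Computed exactly as the ceiling order statistic of the sorted
#' `|diff|` values (the k-th smallest with `k = ceiling(target * n)`),
#' which coincides with the smallest passing delta on an arbitrarily fine
#' scan; `method = "scan"` instead searches a discrete delta grid
#' (default 0 to 50% in 0.1% steps) and returns its smallest passing value.
#'
#' @inheritParams percent_diff_map
#' @param cfg A [comparison_config()]; `target_match_fraction` sets the
#'   match rate.
#' @param method `"order-statistic"` (exact, default) or `"scan"`.
#' @param scan_step,scan_max Scan grid resolution and upper bound, percent.
#' @return A list of class `comparison_result`: `threshold_at_target`
#'   (percent), `pass_fraction_curve` (data frame `delta`, `pass_fraction`
#'   sampled on the scan grid), plus the `diff`/`mask` of the comparison.
#' @export
threshold_to_target <- function(ref, eval, cfg = comparison_config(),
                                method = c("order-statistic", "scan"),
                                scan_step = 0.1, scan_max = 50,
                                norm_value = NULL) {
  method <- match.arg(method)
  pd <- percent_diff_map(ref, eval, cfg, norm_value = norm_value)
  a <- abs(pd$diff[pd$mask])
  n <- length(a)
  if (n == 0L) abort("inclusion mask is empty", "arcqa_statistic_error")
  k <- ceiling(cfg$target_match_fraction * n)
  q <- sort(a, partial = k)[k]
  if (q > scan_max + .pass_tol) {
    abort(sprintf(
      "target match fraction unreachable within the %g%% scan range (needs %.2f%%)",
      scan_max, q), "arcqa_range_error")
  }
  deltas <- seq(0, scan_max, by = scan_step)
  curve <- vapply(deltas, function(d) mean(a <= d + .pass_tol), numeric(1))
  thr <- if (method == "scan") {
    deltas[which(curve >= cfg$target_match_fraction)[1]]
  } else q
  structure(
    list(threshold_at_target = thr,
         pass_fraction_curve = data.frame(delta = deltas,
                                          pass_fraction = curve),
         diff = pd$diff, mask = pd$mask,
         normalization_value = pd$normalization_value, cfg = cfg,
         method = method),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result>  threshold to %.0f%% match: %.2f%% (%s, %s norm, cutoff %.0f%%)\n  %d points included\n",
    100 * x$cfg$target_match_fraction, x$threshold_at_target, x$method,
    x$cfg$normalization, 100 * x$cfg$low_dose_cutoff_fraction, sum(x$mask)
  ))
  invisible(x)
}

#' Pass-fraction curve of a comparison
#'
#' Plots the fraction of matching points against the percent-difference
#' criterion delta, with the target match rate and the threshold marked.
#'
#' @param x A `comparison_result`.
#' @param xmax Right limit of the delta axis (default: a little past the
#'   threshold).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.comparison_result <- function(x, xmax = NULL, ...) {
  cu <- x$pass_fraction_curve
  if (is.null(xmax)) xmax <- max(1, 2 * x$threshold_at_target)
  graphics::plot(cu$delta, cu$pass_fraction, type = "l",
                 xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "dose-difference criterion delta (%)",
                 ylab = "fraction of points matching", ...)
  graphics::abline(h = x$cfg$target_match_fraction, lty = 2)
  graphics::abline(v = x$threshold_at_target, lty = 3)
  invisible(x)
}
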