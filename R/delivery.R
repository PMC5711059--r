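# Dual-frame delivery simulator: aperture rasterization, the GS/CS frame
# transform (the laterality-flip mechanism), and MU-weighted accumulation.

# fraction of each cell [c - h/2, c + h/2] covered by the interval [lo, hi]
interval_coverage <- function(lo, hi, centers, h) {
  pmax(0, pmin(hi, centers + h / 2) - pmax(lo, centers - h / 2)) / h
}

# leaf-pair band limits along y: pair i covers [y0 + (i-1) w, y0 + i w],
# with the bank centered on the inplane axis
leaf_bands <- function(n_pairs, leaf_width_cm) {
  y0 <- -n_pairs * leaf_width_cm / 2
  list(lo = y0 + (seq_len(n_pairs) - 1) * leaf_width_cm,
       hi = y0 + seq_len(n_pairs) * leaf_width_cm)
}

#' Rasterize a control-point aperture to a unit-fluence map
#'
#' Produces an idealized unit-intensity fluence map in collimator (beam's
#' eye view) coordinates: value 1 where a point lies inside leaf-pair row
#' i's open interval `[A_i, B_i]`, 0 elsewhere, with exact partial-area
#' weighting for cells straddling an aperture edge or a leaf-band boundary.
#' An optional isotropic Gaussian penumbra blur of standard deviation
#' `blur_sigma_cm` is applied afterwards; the blur kernel is normalized so
#' the fluence integral is conserved (up to truncation at the grid border).
#'
#' @param cp A [control_point()].
#' @param grid A [grid_spec()] covering the field.
#' @param leaf_width_cm Projected leaf width in cm.
#' @param blur_sigma_cm Gaussian penumbra sigma in cm; 0 disables the blur.
#' @return A `planar_dose` (frame `"GS"`, i.e. collimator-fixed) with the
#'   unit-fluence aperture map.
#' @export
rasterize_aperture <- function(cp, grid, leaf_width_cm = 1.0,
                               blur_sigma_cm = 0) {
  ax <- grid_axis(grid)
  h <- grid$spacing_cm
  n_pairs <- length(cp$bankA_edges)
  bands <- leaf_bands(n_pairs, leaf_width_cm)
  M <- matrix(0, grid$n, grid$n)
  any_open <- FALSE
  for (i in seq_len(n_pairs)) {
    A <- cp$bankA_edges[i]; B <- cp$bankB_edges[i]
    if (B - A <= 1e-12) next
    any_open <- TRUE
    ycov <- interval_coverage(bands$lo[i], bands$hi[i], ax, h)
    xcov <- interval_coverage(A, B, ax, h)
    iy <- which(ycov > 0); ix <- which(xcov > 0)
    if (length(iy) && length(ix)) {
      M[iy, ix] <- M[iy, ix] + ycov[iy] %o% xcov[ix]
    }
  }
  if (any_open && sum(M) == 0) {
    abort("grid does not contain any part of the open aperture",
          "arcqa_extent_error")
  }
  if (blur_sigma_cm > 0) M <- gaussian_blur(M, blur_sigma_cm, h)
  planar_dose(M, grid, frame = "GS", delivery_mode = "rotational")
}

# separable Gaussian blur via banded convolution matrices; kernel sums to 1
# so interior mass is conserved exactly
gaussian_blur <- function(M, sigma_cm, spacing_cm) {
  r <- ceiling(4 * sigma_cm / spacing_cm)
  kern <- stats::dnorm((-r:r) * spacing_cm, sd = sigma_cm)
  kern <- kern / sum(kern)
  half <- kern[(r + 1L):(2L * r + 1L)]  # half[d + 1] = weight at distance d
  n <- nrow(M)
  idx <- seq_len(n)
  D <- abs(outer(idx, idx, "-"))
  B <- matrix(0, n, n)
  keep <- D <= r
  B[keep] <- half[D[keep] + 1L]
  B %*% M %*% B
}

#' Map a single-control-point fluence into a detector reference frame
#'
#' The geometric core of the experiment. A gantry-stationary (GS) detector
#' rotates with the source and collimator, so in its frame every control
#' point projects identically: the transform is the identity at all gantry
#' angles, and an MLC bank stays on the same lateral side of the image
#' throughout the arc. A couch-stationary (CS) detector (or the patient)
#' sees the collimator flip laterally as the gantry crosses +/-90 degrees:
#' for `|angle| >= 90` the map is mirrored about the inplane axis
#' (x to -x). Exactly +/-90 is assigned to the flipped branch.
#'
#' An optional per-angle deposition weight multiplies the map; the default
#' weight is 1 for every angle so both frames conserve total fluence.
#'
#' @param fluence A single-control-point `planar_dose` in collimator
#'   coordinates.
#' @param gantry_angle_deg IEC 61217 gantry angle, in `[-180, 180]`.
#' @param frame `"GS"` or `"CS"`.
#' @param angle_weight `NULL` (weight 1) or a function of the angle in
#'   degrees returning a non-negative scalar, e.g.
#'   `function(a) abs(cospi(a / 180))^0.5`.
#' @return A `planar_dose` in the requested frame.
#' @export
frame_transform <- function(fluence, gantry_angle_deg,
                            frame = c("GS", "CS"), angle_weight = NULL) {
  frame <- match.arg(frame)
  if (abs(gantry_angle_deg) > 180 + 1e-9) {
    abort(sprintf("gantry angle %.3f outside [-180, 180]", gantry_angle_deg),
          "arcqa_domain_error")
  }
  V <- fluence$values
  if (frame == "CS" && abs(gantry_angle_deg) >= 90) {
    V <- V[, ncol(V):1, drop = FALSE]
  }
  w <- if (is.null(angle_weight)) 1 else angle_weight(gantry_angle_deg)
  planar_dose(V * w, fluence$grid, frame = frame,
              delivery_mode = fluence$delivery_mode)
}

#' Accumulate the planar dose of a full plan in a detector frame
#'
#' Sums `mu_weight x frame_transform(rasterize_aperture(cp))` over the
#' plan's control points. The penumbra blur is applied once to the
#' accumulated map: the isotropic Gaussian commutes with the x-mirror and
#' with scalar MU weights, so this equals per-control-point blurring.
#'
#' @param plan A valid `arc_plan`.
#' @param frame `"GS"` or `"CS"`.
#' @param grid A [grid_spec()]; default 0.05 cm pitch over the full field.
#' @param config List of options: `penumbra_sigma_cm` (default 0.3; set 0
#'   for sharp apertures) and `angle_weight` (default `NULL`, weight 1; see
#'   [frame_transform()]).
#' @return A `planar_dose` tagged with the frame and the plan's delivery
#'   mode.
#' @export
accumulate_dose <- function(plan, frame = c("GS", "CS"),
                            grid = grid_spec(), config = list()) {
  frame <- match.arg(frame)
  validate_arc_plan(plan)
  sigma <- if (is.null(config$penumbra_sigma_cm)) 0.3 else config$penumbra_sigma_cm
  aw <- config$angle_weight
  acc <- matrix(0, grid$n, grid$n)
  for (cp in plan$control_points) {
    r <- rasterize_aperture(cp, grid, plan$leaf_width_cm, blur_sigma_cm = 0)
    t <- frame_transform(r, cp$gantry_angle_deg, frame, angle_weight = aw)
    acc <- acc + cp$mu_weight * t$values
  }
  if (sigma > 0) acc <- gaussian_blur(acc, sigma, grid$spacing_cm)
  planar_dose(acc, grid, frame = frame, delivery_mode = plan$delivery_mode)
}
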