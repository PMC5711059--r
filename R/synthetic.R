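# Seeded generators for modulated single-arc plans and planar ROIs. These
# stand in for clinical head-and-neck / esophagus arc plans: what matters
# for the reference-frame mechanism is a full arc with modulated, high-
# gradient apertures, not clinical optimality.

#' Configuration for the synthetic arc-plan generator
#'
#' Defaults emulate a single full-arc delivery: 72 control points spanning
#' -170 to +170 degrees, 40 leaf pairs of 1 cm projected width, modulated
#' apertures a few cm wide. Aperture centers and widths evolve as smooth
#' per-leaf random walks, bounded by a maximum leaf travel per control
#' point, so adjacent control points have physically plausible continuity.
#'
#' @param seed Integer seed; the same seed always reproduces the same plan.
#' @param n_control_points Number of control points (default 72).
#' @param arc_start_deg,arc_end_deg Arc limits in IEC 61217 degrees
#'   (default -170, +170).
#' @param n_leaf_pairs Leaf pairs (default 40).
#' @param leaf_width_cm Projected leaf width (default 1 cm).
#' @param mean_aperture_width_cm Mean open-pair width (default 6 cm).
#' @param aperture_jitter_cm SD of the initial per-leaf center/width spread
#'   (default 1.5 cm).
#' @param max_leaf_speed_cm_per_cp Bound on per-control-point edge travel
#'   (default 0.5 cm).
#' @param min_gap_cm Minimum open-pair gap (default 0.5 cm).
#' @param n_open_pairs Integer range (length 2) for the number of open leaf
#'   pairs, drawn once per plan (default 16 to 24).
#' @param mu_weight_dispersion Log-normal sigma of the raw MU weights
#'   before normalization (default 0.5).
#' @param edge_margin_cm Keep-out margin from the +/-13.5 cm travel limit,
#'   leaving room for subsequent bank perturbations (default 1.5 cm).
#' @param target_corridor_cm Crossplane half-width of the central target
#'   corridor (default 2.5 cm; 0 disables). Open leaf pairs within 5.5 cm
#'   of the inplane axis never close across the corridor, mimicking
#'   optimizer-driven apertures that conform around the planning target
#'   rather than crossing its projection; it guarantees the synthetic
#'   target ROI lies inside the union aperture footprint.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_control_points = 72L,
                             arc_start_deg = -170, arc_end_deg = 170,
                             n_leaf_pairs = 40L, leaf_width_cm = 1.0,
                             mean_aperture_width_cm = 6,
                             aperture_jitter_cm = 1.5,
                             max_leaf_speed_cm_per_cp = 0.5,
                             min_gap_cm = 0.5,
                             n_open_pairs = c(16L, 24L),
                             mu_weight_dispersion = 0.5,
                             edge_margin_cm = 1.5,
                             target_corridor_cm = 2.5) {
  if (arc_start_deg >= arc_end_deg ||
      arc_start_deg < -180 || arc_end_deg > 180) {
    abort("arc limits must satisfy -180 <= start < end <= 180",
          "arcqa_config_error")
  }
  if (min_gap_cm < 0) abort("min_gap_cm must be >= 0", "arcqa_config_error")
  if (mean_aperture_width_cm <= min_gap_cm) {
    abort("mean aperture width must exceed the minimum gap",
          "arcqa_config_error")
  }
  if (length(n_open_pairs) != 2L || n_open_pairs[1] > n_open_pairs[2] ||
      n_open_pairs[2] > n_leaf_pairs) {
    abort("n_open_pairs must be an increasing range within the leaf count",
          "arcqa_config_error")
  }
  if (max_leaf_speed_cm_per_cp <= 0 || mean_aperture_width_cm <= 0 ||
      leaf_width_cm <= 0) {
    abort("speeds and widths must be positive", "arcqa_config_error")
  }
  structure(as.list(environment()), class = "generator_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a modulated synthetic single-arc plan
#'
#' Gantry angles are equally spaced over the configured arc. A contiguous
#' central block of leaf pairs (size drawn from `n_open_pairs`) is open;
#' each open pair's aperture center and width start from a smoothed random
#' profile and evolve as clipped Gaussian random walks, so per-control-
#' point edge travel never exceeds `max_leaf_speed_cm_per_cp` and widths
#' stay at or above `min_gap_cm`. Closed pairs are parked (`A == B`).
#' MU weights are positive log-normal draws, normalized. Deterministic per
#' seed; no global RNG state is consumed.
#'
#' @param cfg A [generator_config()].
#' @return A validated `arc_plan` (variant `MLC0PE`, rotational).
#' @export
generate_arc_plan <- function(cfg = generator_config()) {
  if (!inherits(cfg, "generator_config")) {
    abort("`cfg` must be a generator_config", "arcqa_config_error")
  }
  local_seed(cfg$seed, {
    n_cp <- cfg$n_control_points
    n_lp <- cfg$n_leaf_pairs
    angles <- seq(cfg$arc_start_deg, cfg$arc_end_deg, length.out = n_cp)
    lim <- .max_crossplane_cm - cfg$edge_margin_cm

    n_open <- sample(seq(cfg$n_open_pairs[1], cfg$n_open_pairs[2]), 1L)
    center_row <- n_lp / 2 + sample(-1:1, 1L)
    first <- max(1L, round(center_row - n_open / 2))
    open_rows <- first:min(n_lp, first + n_open - 1L)
    # leaf pairs whose band center lies within 5.5 cm of the inplane axis
    # hold the target corridor open (see `target_corridor_cm`)
    bands <- leaf_bands(n_lp, cfg$leaf_width_cm)
    band_centers <- (bands$lo + bands$hi) / 2
    corridor_rows <- intersect(open_rows, which(abs(band_centers) <= 5.5))
    corridor <- match(corridor_rows, open_rows)

    # smoothed initial per-leaf profiles (3-point running mean keeps the
    # aperture connected-looking across adjacent leaves)
    smooth3 <- function(z) stats::filter(z, rep(1 / 3, 3), circular = TRUE)
    c_prof <- as.numeric(smooth3(stats::rnorm(length(open_rows),
                                              0, cfg$aperture_jitter_cm)))
    w_prof <- as.numeric(smooth3(stats::rnorm(length(open_rows),
                                              cfg$mean_aperture_width_cm,
                                              cfg$aperture_jitter_cm)))
    w_min <- max(cfg$min_gap_cm, cfg$mean_aperture_width_cm / 3)
    w_max <- min(2 * cfg$mean_aperture_width_cm, 2 * lim)
    w_prof <- clamp(w_prof, w_min, w_max)

    v <- cfg$max_leaf_speed_cm_per_cp
    centers <- c_prof
    widths <- w_prof
    cps <- vector("list", n_cp)
    for (t in seq_len(n_cp)) {
      if (t > 1L) {
        # |dA|, |dB| <= |dc| + |dw|/2 <= 0.6 v + 0.4 v = v
        dc <- clamp(stats::rnorm(length(centers), 0, v / 3), -0.6 * v, 0.6 * v)
        dw <- clamp(stats::rnorm(length(widths), 0, v / 3), -0.8 * v, 0.8 * v)
        centers <- clamp(centers + dc, -lim + w_max / 2, lim - w_max / 2)
        widths <- clamp(widths + dw, w_min, w_max)
      }
      eA <- clamp(centers - widths / 2, -lim, lim)
      eB <- clamp(centers + widths / 2, -lim, lim)
      if (cfg$target_corridor_cm > 0 && length(corridor)) {
        # min/max with a constant is a contraction, so the leaf-speed
        # bound survives the corridor clamp
        eA[corridor] <- pmin(eA[corridor], -cfg$target_corridor_cm)
        eB[corridor] <- pmax(eB[corridor], cfg$target_corridor_cm)
      }
      A <- rep(0, n_lp); B <- rep(0, n_lp)
      A[open_rows] <- eA
      B[open_rows] <- eB
      cps[[t]] <- control_point(
        index = t, gantry_angle_deg = angles[t],
        mu_weight = stats::rlnorm(1, 0, cfg$mu_weight_dispersion),
        bankA_edges = A, bankB_edges = B
      )
    }
    arc_plan(
      plan_id = sprintf("synthetic-arc-seed%d", cfg$seed),
      control_points = cps, n_leaf_pairs = n_lp,
      leaf_width_cm = cfg$leaf_width_cm,
      variant_label = "MLC0PE", delivery_mode = "rotational"
    )
  })
}

#' Generate synthetic planar ROI masks
#'
#' Produces one central target-like ellipse (inside the high-dose core of
#' plans from [generate_arc_plan()] with the same seed) and two lateral
#' organ-like ellipses, all on the given grid. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param grid A [grid_spec()] congruent with the dose the ROIs will score.
#' @return Named list of [roi_mask()] objects: `target`, `organ_left`,
#'   `organ_right`.
#' @export
generate_roi_masks <- function(seed, grid) {
  local_seed(seed, {
    ax <- grid_axis(grid)
    X <- matrix(ax, grid$n, grid$n, byrow = TRUE)
    Y <- matrix(ax, grid$n, grid$n)
    ellipse <- function(cx, cy, rx, ry) {
      m <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
      if (!any(m)) abort("generated ROI is empty on this grid",
                         "arcqa_config_error")
      m
    }
    jit <- function(s) stats::runif(1, -s, s)
    tgt <- ellipse(jit(0.3), jit(0.5), 1.5 + stats::runif(1, 0, 0.4),
                   3.0 + stats::runif(1, 0, 0.8))
    oL <- ellipse(-4.5 + jit(0.5), jit(1), 1.3, 2.0)
    oR <- ellipse(4.5 + jit(0.5), jit(1), 1.3, 2.0)
    list(
      target = roi_mask(tgt, "target", "target"),
      organ_left = roi_mask(oL, "organ_left", "parallel-organ"),
      organ_right = roi_mask(oR, "organ_right", "parallel-organ")
    )
  })
}
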