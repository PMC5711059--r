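# Small in-code fixtures shared across tests.

# a hand-sized 3-control-point arc with 40 leaf pairs, a few of them open
tiny_plan <- function(delivery_mode = "rotational") {
  mk_cp <- function(i, ang, w, shift) {
    A <- rep(0, 40); B <- rep(0, 40)
    open <- 18:23
    A[open] <- -3 + shift + 0.2 * seq_along(open)
    B[open] <- 2 + shift - 0.1 * seq_along(open)
    control_point(i, ang, w, A, B)
  }
  angs <- if (delivery_mode == "collapsed") c(0, 0, 0) else c(-170, 0, 170)
  arc_plan(
    plan_id = "tiny",
    control_points = list(
      mk_cp(1, angs[1], 0.2, -0.5),
      mk_cp(2, angs[2], 0.5, 0.0),
      mk_cp(3, angs[3], 0.3, 0.7)
    ),
    delivery_mode = delivery_mode
  )
}

# single open pair, optionally asymmetric, on an arbitrary-size bank
single_pair_cp <- function(A = -3, B = 2, pair = 20, n = 40,
                           angle = 0, w = 1) {
  Av <- rep(0, n); Bv <- rep(0, n)
  Av[pair] <- A; Bv[pair] <- B
  control_point(1, angle, w, Av, Bv)
}

# wrap a matrix as a planar_dose on a matching grid
as_dose <- function(values, spacing = 0.3, frame = "CS") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), nrow(values) %% 2 == 1)
  half <- spacing * (nrow(values) - 1) / 2
  planar_dose(values, grid_spec(spacing, half), frame = frame)
}

# brute-force all-pairs discrete gamma: the independent oracle
gamma_bruteforce <- function(ref, eval, crit) {
  h <- ref$grid$spacing_cm
  R <- ref$values; E <- eval$values
  N <- max(R)
  dcrit <- crit$distance_mm / 10
  Dcrit <- if (crit$normalization == "global") {
    matrix(crit$dose_diff_percent / 100 * N, nrow(R), ncol(R))
  } else {
    pmax(crit$dose_diff_percent / 100 * R, 1e-300)
  }
  n <- nrow(R); m <- ncol(R)
  gam <- matrix(NA_real_, n, m)
  mask <- R >= crit$low_dose_cutoff_fraction * N
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j]) next
    # exhaustive search over every evaluation point, no radius restriction
    d2 <- outer((seq_len(n) - i)^2, (seq_len(m) - j)^2, "+") * h^2
    cand <- ((E - R[i, j]) / Dcrit[i, j])^2 + d2 / dcrit^2
    gam[i, j] <- sqrt(min(cand))
  }
  list(gamma = gam, mask = mask,
       pass_rate = mean(gam[mask] <= 1 + 1e-9))
}

# union aperture footprint (logical matrix) of a plan on a grid
union_footprint <- function(plan, grid) {
  U <- matrix(FALSE, grid$n, grid$n)
  for (cp in plan$control_points) {
    r <- rasterize_aperture(cp, grid, plan$leaf_width_cm)
    U <- U | (r$values > 1e-12)
  }
  U
}
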