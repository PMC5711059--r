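# Planar dose grids: construction, CSV round-trip, plotting.

#' Define a square planar grid at the isocenter plane
#'
#' Grids are square and centered on the isocenter with a node exactly on the
#' beam axis, so `half_extent_cm` must be an integer multiple of
#' `spacing_cm` (giving an odd number of nodes per axis). The x axis is the
#' crossplane (leaf-travel) direction, the y axis the inplane (leaf-index)
#' direction.
#'
#' @param spacing_cm Grid pitch in cm (both axes). The simulation default is
#'   0.05 cm; the analysis default 0.3 cm (the resolution treatment planning
#'   systems and QA software typically calculate at).
#' @param half_extent_cm Half-width of the grid in cm (default 13.5, the
#'   maximum 27 x 27 cm2 field).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(spacing_cm = 0.05, half_extent_cm = 13.5) {
  if (spacing_cm <= 0) abort("spacing must be > 0", "arcqa_config_error")
  k <- half_extent_cm / spacing_cm
  if (abs(k - round(k)) > 1e-6) {
    abort("half_extent_cm must be an integer multiple of spacing_cm (odd grid, node on axis)",
          "arcqa_config_error")
  }
  structure(
    list(spacing_cm = spacing_cm, half_extent_cm = half_extent_cm,
         n = 2L * as.integer(round(k)) + 1L),
    class = "grid_spec"
  )
}

#' Node coordinates of a grid axis
#' @param grid A `grid_spec`.
#' @return Numeric vector of node coordinates in cm, centered on 0.
#' @export
grid_axis <- function(grid) {
  k <- (grid$n - 1L) %/% 2L
  grid$spacing_cm * (-k:k)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$spacing_cm, b$spacing_cm, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$half_extent_cm, b$half_extent_cm, tolerance = 1e-9))
}

#' Construct a planar dose object
#'
#' A planar dose is a non-negative 2D array of MU-weighted fluence on a
#' [grid_spec()] lattice, tagged with the detector reference frame it was
#' accumulated in (`GS` gantry-stationary or `CS` couch-stationary) and the
#' delivery mode of the plan that produced it. `values[i, j]` is the dose at
#' inplane coordinate `y_i` and crossplane coordinate `x_j`.
#'
#' @param values Numeric matrix, `grid$n` x `grid$n`, finite and `>= 0`.
#' @param grid A `grid_spec`.
#' @param frame `"GS"` or `"CS"`.
#' @param delivery_mode `"rotational"` or `"collapsed"`.
#' @return An object of class `planar_dose`.
#' @export
planar_dose <- function(values, grid, frame = c("GS", "CS"),
                        delivery_mode = c("rotational", "collapsed")) {
  frame <- match.arg(frame)
  delivery_mode <- match.arg(delivery_mode)
  if (!is.matrix(values) || nrow(values) != grid$n || ncol(values) != grid$n) {
    abort(sprintf("values must be a %d x %d matrix", grid$n, grid$n),
          "arcqa_validation_error")
  }
  if (any(!is.finite(values)) || any(values < -1e-12)) {
    abort("dose values must be finite and non-negative", "arcqa_validation_error")
  }
  values[values < 0] <- 0
  structure(
    list(values = values, grid = grid, frame = frame,
         delivery_mode = delivery_mode),
    class = "planar_dose"
  )
}

#' @export
print.planar_dose <- function(x, ...) {
  cat(sprintf(
    "<planar_dose>  %d x %d @ %.3g cm, half-extent %.3g cm\n  frame %s, %s delivery; max %.4g, integral %.4g cm^2\n",
    x$grid$n, x$grid$n, x$grid$spacing_cm, x$grid$half_extent_cm,
    x$frame, x$delivery_mode, max(x$values),
    sum(x$values) * x$grid$spacing_cm^2
  ))
  invisible(x)
}

#' Heatmap of a planar dose (or difference) map
#'
#' @param x A `planar_dose`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.planar_dose <- function(x, main = NULL, ...) {
  ax <- grid_axis(x$grid)
  if (is.null(main)) {
    main <- sprintf("%s frame, %s delivery", x$frame, x$delivery_mode)
  }
  # image() wants z[x, y]: transpose so crossplane runs along the plot x axis
  graphics::image(ax, ax, t(x$values), xlab = "crossplane x (cm)",
                  ylab = "inplane y (cm)", main = main, asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write a planar dose to a headered CSV matrix
#'
#' The file starts with three comment lines (`# spacing_cm`,
#' `# half_extent_cm`, `# frame ... mode ...`) followed by the dose matrix,
#' one inplane row per line.
#'
#' @param dose A `planar_dose`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_dose_csv <- function(dose, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# spacing_cm: %.9g", dose$grid$spacing_cm),
    sprintf("# half_extent_cm: %.9g", dose$grid$half_extent_cm),
    sprintf("# frame: %s mode: %s", dose$frame, dose$delivery_mode)
  ), con)
  utils::write.table(format(dose$values, digits = 9, scientific = TRUE,
                            trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a planar dose written by [write_dose_csv()]
#' @param path Path to the dose CSV.
#' @return A `planar_dose`.
#' @export
read_dose_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("dose file not found: %s", path), "arcqa_parse_error")
  }
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L || !all(startsWith(hdr, "#"))) {
    abort("dose CSV must start with the 3-line '#' header", "arcqa_parse_error")
  }
  gv <- function(line) as.numeric(sub("^# [a-z_]+: *", "", line))
  spacing <- gv(hdr[1]); half <- gv(hdr[2])
  m <- regmatches(hdr[3], regexec("# frame: (\\S+) mode: (\\S+)", hdr[3]))[[1]]
  if (length(m) != 3L) abort("malformed frame/mode header line", "arcqa_parse_error")
  vals <- as.matrix(utils::read.table(path, sep = ",", skip = 3L,
                                      colClasses = "numeric"))
  dimnames(vals) <- NULL
  planar_dose(vals, grid_spec(spacing, half), frame = m[2], delivery_mode = m[3])
}
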