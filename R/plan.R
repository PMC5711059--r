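# Arc-plan domain model: control points, plans, serialization, and the two
# plan edits the QA experiment needs (bank-error injection, gantry collapse).

#' Construct a control point
#'
#' A control point is one discrete sample of an arc delivery: the gantry
#' angle, the fraction of total monitor units (MU) delivered there, and the
#' leaf-edge positions of both MLC banks. Bank A approaches the aperture from
#' the negative crossplane (x) side, bank B from the positive side, so the
#' open interval of leaf pair i is `[bankA_edges[i], bankB_edges[i]]`.
#' `bankA_edges[i] == bankB_edges[i]` represents a closed (parked) pair.
#'
#' @param index 1-based ordinal of the control point within its plan.
#' @param gantry_angle_deg IEC 61217 gantry angle in degrees, in
#'   `[-180, 180]`.
#' @param mu_weight Non-negative MU fraction (normalized at the plan level).
#' @param bankA_edges,bankB_edges Numeric vectors of signed crossplane leaf
#'   edge coordinates (cm at the isocenter plane), one per leaf pair.
#' @return A list of class `control_point`.
#' @export
control_point <- function(index, gantry_angle_deg, mu_weight,
                          bankA_edges, bankB_edges) {
  cp <- structure(
    list(
      index = as.integer(index),
      gantry_angle_deg = as.numeric(gantry_angle_deg),
      mu_weight = as.numeric(mu_weight),
      bankA_edges = as.numeric(bankA_edges),
      bankB_edges = as.numeric(bankB_edges)
    ),
    class = "control_point"
  )
  cp
}

#' Construct an arc plan
#'
#' Bundles an ordered sequence of control points with the plan-level MLC
#' geometry (number of leaf pairs, projected leaf width) and two labels used
#' throughout the QA experiment: the error variant (`MLC0PE` = no positional
#' error, `MLC1PE` = systematic bank error injected) and the delivery mode
#' (`rotational` arc vs `collapsed`, all gantry angles forced to 0).
#'
#' MU weights are normalized to sum to one on construction; only relative
#' weights matter for the planar fluence shape.
#'
#' @param plan_id Character plan identifier.
#' @param control_points List of [control_point()] objects.
#' @param n_leaf_pairs Number of MLC leaf pairs (default 40).
#' @param leaf_width_cm Projected leaf width at isocenter in cm (default 1.0).
#' @param variant_label `"MLC0PE"` or `"MLC1PE"`.
#' @param delivery_mode `"rotational"` or `"collapsed"`.
#' @param validate Run [validate_arc_plan()] on the result (default `TRUE`).
#' @return An object of class `arc_plan`.
#' @export
arc_plan <- function(plan_id, control_points, n_leaf_pairs = 40L,
                     leaf_width_cm = 1.0,
                     variant_label = c("MLC0PE", "MLC1PE"),
                     delivery_mode = c("rotational", "collapsed"),
                     validate = TRUE) {
  variant_label <- match.arg(variant_label)
  delivery_mode <- match.arg(delivery_mode)
  w <- vapply(control_points, function(cp) cp$mu_weight, numeric(1))
  if (any(w < 0)) {
    abort(sprintf("negative mu_weight at control point(s) %s",
                  fmt_idx(which(w < 0))), "arcqa_validation_error")
  }
  tot <- sum(w)
  if (tot <= 0) abort("plan has zero total MU weight", "arcqa_validation_error")
  for (i in seq_along(control_points)) {
    control_points[[i]]$mu_weight <- w[i] / tot
    control_points[[i]]$index <- i
  }
  plan <- structure(
    list(
      plan_id = as.character(plan_id),
      control_points = control_points,
      n_leaf_pairs = as.integer(n_leaf_pairs),
      leaf_width_cm = as.numeric(leaf_width_cm),
      variant_label = variant_label,
      delivery_mode = delivery_mode
    ),
    class = "arc_plan"
  )
  if (validate) validate_arc_plan(plan)
  plan
}

#' Validate an arc plan
#'
#' Checks the structural invariants of the plan model: edge-vector lengths
#' match `n_leaf_pairs`; per pair `A_i <= B_i`; all edges inside the maximum
#' 27 cm crossplane field (`|edge| <= 13.5` cm); MU weights normalized; and
#' gantry angles consistent with the delivery mode (strictly monotone for a
#' rotational arc, all exactly 0 for collapsed delivery).
#'
#' @param plan An `arc_plan`.
#' @return Invisibly `TRUE`; signals a validation error otherwise.
#' @export
validate_arc_plan <- function(plan) {
  if (!inherits(plan, "arc_plan")) {
    abort("not an arc_plan object", "arcqa_validation_error")
  }
  cps <- plan$control_points
  if (length(cps) < 1L) abort("plan has no control points", "arcqa_validation_error")
  n <- plan$n_leaf_pairs
  tol <- 1e-9
  for (cp in cps) {
    if (length(cp$bankA_edges) != n || length(cp$bankB_edges) != n) {
      abort(sprintf(
        "control point %d: edge vectors have length %d/%d, expected %d",
        cp$index, length(cp$bankA_edges), length(cp$bankB_edges), n
      ), "arcqa_validation_error")
    }
    bad <- which(cp$bankA_edges > cp$bankB_edges + tol)
    if (length(bad)) {
      abort(sprintf("control point %d: bankA edge exceeds bankB edge at pair(s) %s",
                    cp$index, fmt_idx(bad)), "arcqa_validation_error")
    }
    out <- which(abs(cp$bankA_edges) > .max_crossplane_cm + tol |
                 abs(cp$bankB_edges) > .max_crossplane_cm + tol)
    if (length(out)) {
      abort(sprintf("control point %d: edge outside +/-%.1f cm at pair(s) %s",
                    cp$index, .max_crossplane_cm, fmt_idx(out)),
            "arcqa_validation_error")
    }
    if (abs(cp$gantry_angle_deg) > 180 + tol) {
      abort(sprintf("control point %d: gantry angle %.3f outside [-180, 180]",
                    cp$index, cp$gantry_angle_deg), "arcqa_validation_error")
    }
  }
  w <- vapply(cps, function(cp) cp$mu_weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("mu weights sum to %.12f, expected 1", sum(w)),
          "arcqa_validation_error")
  }
  ang <- vapply(cps, function(cp) cp$gantry_angle_deg, numeric(1))
  if (plan$delivery_mode == "collapsed") {
    if (any(ang != 0)) {
      abort("collapsed plan has nonzero gantry angles", "arcqa_validation_error")
    }
  } else if (length(ang) > 1L) {
    d <- diff(ang)
    if (!(all(d > 0) || all(d < 0))) {
      abort("rotational plan gantry angles are not strictly monotone",
            "arcqa_validation_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.arc_plan <- function(x, ...) {
  ang <- vapply(x$control_points, function(cp) cp$gantry_angle_deg, numeric(1))
  cat(sprintf(
    "<arc_plan '%s'>  %s, %s\n  %d control points, gantry %g to %g deg\n  %d leaf pairs x %.1f cm\n",
    x$plan_id, x$variant_label, x$delivery_mode,
    length(x$control_points), ang[1], ang[length(ang)],
    x$n_leaf_pairs, x$leaf_width_cm
  ))
  invisible(x)
}

#' Write an arc plan to a JSON file
#'
#' Plans serialize to a small JSON schema (keys `plan_id`, `n_leaf_pairs`,
#' `leaf_width_cm`, `variant_label`, `delivery_mode`, `control_points`).
#' Coordinates are written in cm with 6 decimal places, so a write/read
#' cycle round-trips numerically at that precision.
#'
#' @param plan An `arc_plan`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @seealso [read_plan()], [plan_to_csv()]
#' @export
write_plan <- function(plan, path) {
  validate_arc_plan(plan)
  cps <- lapply(plan$control_points, function(cp) {
    list(
      index = cp$index,
      gantry_angle_deg = round(cp$gantry_angle_deg, 6),
      mu_weight = round(cp$mu_weight, 9),
      bankA_edges = round(cp$bankA_edges, 6),
      bankB_edges = round(cp$bankB_edges, 6)
    )
  })
  obj <- list(
    plan_id = plan$plan_id,
    n_leaf_pairs = plan$n_leaf_pairs,
    leaf_width_cm = plan$leaf_width_cm,
    variant_label = plan$variant_label,
    delivery_mode = plan$delivery_mode,
    control_points = cps
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read an arc plan from a JSON file
#'
#' @param path Path to a plan JSON file written by [write_plan()] (schema in
#'   its documentation). MU weights are re-normalized on read.
#' @return A validated `arc_plan`.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("plan file not found: %s", path), "arcqa_parse_error")
  }
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) abort(sprintf("cannot parse plan JSON: %s",
                                      conditionMessage(e)), "arcqa_parse_error")
  )
  need <- c("plan_id", "n_leaf_pairs", "leaf_width_cm", "control_points")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    abort(sprintf("plan file missing field(s): %s", fmt_idx(miss)),
          "arcqa_parse_error")
  }
  cps <- lapply(obj$control_points, function(cp) {
    cneed <- c("gantry_angle_deg", "mu_weight", "bankA_edges", "bankB_edges")
    cmiss <- setdiff(cneed, names(cp))
    if (length(cmiss)) {
      abort(sprintf("control point missing field(s): %s", fmt_idx(cmiss)),
            "arcqa_parse_error")
    }
    control_point(
      index = if (is.null(cp$index)) NA_integer_ else cp$index,
      gantry_angle_deg = unlist(cp$gantry_angle_deg),
      mu_weight = unlist(cp$mu_weight),
      bankA_edges = unlist(cp$bankA_edges),
      bankB_edges = unlist(cp$bankB_edges)
    )
  })
  arc_plan(
    plan_id = obj$plan_id,
    control_points = cps,
    n_leaf_pairs = obj$n_leaf_pairs,
    leaf_width_cm = obj$leaf_width_cm,
    variant_label = if (is.null(obj$variant_label)) "MLC0PE" else obj$variant_label,
    delivery_mode = if (is.null(obj$delivery_mode)) "rotational" else obj$delivery_mode
  )
}

#' Export an arc plan as a long-format CSV for inspection
#'
#' One row per control point per leaf pair, columns
#' `cp`, `gantry_angle_deg`, `mu_weight`, `pair`, `bankA_cm`, `bankB_cm`.
#'
#' @inheritParams write_plan
#' @return Invisibly `path`.
#' @export
plan_to_csv <- function(plan, path) {
  validate_arc_plan(plan)
  rows <- do.call(rbind, lapply(plan$control_points, function(cp) {
    data.frame(
      cp = cp$index,
      gantry_angle_deg = cp$gantry_angle_deg,
      mu_weight = cp$mu_weight,
      pair = seq_len(plan$n_leaf_pairs),
      bankA_cm = cp$bankA_edges,
      bankB_cm = cp$bankB_edges
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Specify a systematic MLC bank perturbation
#'
#' @param bank `"A"` or `"B"`: which leaf bank to offset.
#' @param offset_cm Signed offset in cm; positive opens the named bank
#'   (bank A edges move towards -x, bank B edges towards +x). 1 mm = 0.1 cm
#'   is the TG-142 calibration tolerance exercised by the experiment.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(bank = c("A", "B"), offset_cm = 0.1) {
  bank <- match.arg(bank)
  structure(list(bank = bank, offset_cm = as.numeric(offset_cm)),
            class = "perturbation_spec")
}

#' Inject a systematic bank positional error into a plan
#'
#' Applies the perturbation identically to every *open* leaf pair of every
#' control point: for bank A each edge `A_i` becomes `A_i - offset_cm`, for
#' bank B each `B_i` becomes `B_i + offset_cm` (positive offsets open the
#' bank). Closed pairs (`A_i == B_i`) are parked under the backup diaphragm
#' and are left closed. The result carries `variant_label = "MLC1PE"`;
#' everything else is untouched, so the pair of plans differs only by the
#' systematic error.
#'
#' @param plan A valid `arc_plan`.
#' @param spec A [perturbation_spec()].
#' @return A new `arc_plan` with the perturbed bank.
#' @export
inject_bank_error <- function(plan, spec) {
  validate_arc_plan(plan)
  if (!inherits(spec, "perturbation_spec")) {
    abort("`spec` must be a perturbation_spec", "arcqa_validation_error")
  }
  d <- spec$offset_cm
  out <- plan
  tol <- 1e-12
  for (k in seq_along(out$control_points)) {
    cp <- out$control_points[[k]]
    open <- cp$bankA_edges < cp$bankB_edges - tol
    if (spec$bank == "A") {
      newA <- ifelse(open, cp$bankA_edges - d, cp$bankA_edges)
      bad <- which(abs(newA) > .max_crossplane_cm + 1e-9)
      if (length(bad)) {
        abort(sprintf(
          "offset pushes bankA edge beyond +/-%.1f cm at control point %d, pair(s) %s",
          .max_crossplane_cm, cp$index, fmt_idx(bad)), "arcqa_range_error")
      }
      inv <- which(newA > cp$bankB_edges + 1e-12)
      if (length(inv)) {
        abort(sprintf(
          "offset closes aperture past bankB at control point %d, pair(s) %s",
          cp$index, fmt_idx(inv)), "arcqa_range_error")
      }
      cp$bankA_edges <- newA
    } else {
      newB <- ifelse(open, cp$bankB_edges + d, cp$bankB_edges)
      bad <- which(abs(newB) > .max_crossplane_cm + 1e-9)
      if (length(bad)) {
        abort(sprintf(
          "offset pushes bankB edge beyond +/-%.1f cm at control point %d, pair(s) %s",
          .max_crossplane_cm, cp$index, fmt_idx(bad)), "arcqa_range_error")
      }
      inv <- which(newB < cp$bankA_edges - 1e-12)
      if (length(inv)) {
        abort(sprintf(
          "offset closes aperture past bankA at control point %d, pair(s) %s",
          cp$index, fmt_idx(inv)), "arcqa_range_error")
      }
      cp$bankB_edges <- newB
    }
    out$control_points[[k]] <- cp
  }
  out$variant_label <- "MLC1PE"
  validate_arc_plan(out)
  out
}

#' Collapse all gantry angles of a plan to zero
#'
#' Produces the static-gantry ("collapsed", G\eqn{\theta}=0\eqn{^\circ})
#' counterpart of an arc plan: every control point keeps its MU weight and
#' MLC aperture but is delivered straight down. Idempotent.
#'
#' @param plan A valid `arc_plan`.
#' @return A new `arc_plan` with `delivery_mode = "collapsed"` and all
#'   gantry angles exactly 0.
#' @export
collapse_gantry <- function(plan) {
  validate_arc_plan(plan)
  out <- plan
  for (k in seq_along(out$control_points)) {
    out$control_points[[k]]$gantry_angle_deg <- 0.0
  }
  out$delivery_mode <- "collapsed"
  out
}

# per-control-point open aperture area (cm^2), used by tests and the
# generator's modulation diagnostics
aperture_areas <- function(plan) {
  vapply(plan$control_points, function(cp) {
    sum(pmax(0, cp$bankB_edges - cp$bankA_edges)) * plan$leaf_width_cm
  }, numeric(1))
}
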