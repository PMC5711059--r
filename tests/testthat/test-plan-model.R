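# Plan domain model: serialization, validation, and the two plan edits.

test_that("plans round-trip through JSON losslessly at 6 decimals", {
  p <- tiny_plan()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_plan(p, f1)
  q <- read_plan(f1)
  expect_equal(q$plan_id, p$plan_id)
  expect_equal(q$n_leaf_pairs, 40L)
  expect_equal(q$variant_label, p$variant_label)
  for (k in seq_along(p$control_points)) {
    expect_equal(q$control_points[[k]]$bankA_edges,
                 p$control_points[[k]]$bankA_edges, tolerance = 1e-6)
    expect_equal(q$control_points[[k]]$bankB_edges,
                 p$control_points[[k]]$bankB_edges, tolerance = 1e-6)
    expect_equal(q$control_points[[k]]$mu_weight,
                 p$control_points[[k]]$mu_weight, tolerance = 1e-8)
  }
  # a second write/read cycle is bit-stable
  write_plan(q, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("plan validation names the offending pairs and fields", {
  cps <- list(single_pair_cp(A = 2, B = -3))  # inverted pair 20
  expect_error(arc_plan("bad", cps), class = "arcqa_validation_error")
  expect_error(arc_plan("bad", cps), "pair\\(s\\) 20")
  cps2 <- list(single_pair_cp(A = -14, B = 2))  # beyond travel limit
  expect_error(arc_plan("bad", cps2), class = "arcqa_validation_error")
  # malformed file -> parse error naming the missing field
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"plan_id": "x", "n_leaf_pairs": 40}', f)
  expect_error(read_plan(f), "leaf_width_cm", class = "arcqa_parse_error")
  # collapsed plans must have every angle at exactly 0
  p <- tiny_plan()
  p$delivery_mode <- "collapsed"
  expect_error(validate_arc_plan(p), class = "arcqa_validation_error")
})

test_that("mu weights are normalized on construction and on read", {
  cps <- list(single_pair_cp(w = 2, angle = -170),
              single_pair_cp(w = 6, angle = 170))
  p <- arc_plan("w", cps)
  expect_equal(vapply(p$control_points, `[[`, numeric(1), "mu_weight"),
               c(0.25, 0.75))
})

test_that("bank-A injection applies the stated edge arithmetic", {
  p <- tiny_plan()
  q <- inject_bank_error(p, perturbation_spec("A", 0.1))
  expect_equal(q$variant_label, "MLC1PE")
  for (k in seq_along(p$control_points)) {
    A0 <- p$control_points[[k]]$bankA_edges
    B0 <- p$control_points[[k]]$bankB_edges
    A1 <- q$control_points[[k]]$bankA_edges
    open <- A0 < B0
    expect_equal(A1[open], A0[open] - 0.1)
    expect_equal(A1[!open], A0[!open])  # closed pairs stay parked
    expect_equal(q$control_points[[k]]$bankB_edges, B0)
    expect_equal(q$control_points[[k]]$gantry_angle_deg,
                 p$control_points[[k]]$gantry_angle_deg)
    # every open aperture widens by exactly the offset
    expect_equal((B0 - A1)[open], (B0 - A0)[open] + 0.1)
  }
})

test_that("injection changes aperture area by offset x leaf width x open pairs", {
  p <- tiny_plan()
  q <- inject_bank_error(p, perturbation_spec("A", 0.1))
  a0 <- arcqa:::aperture_areas(p)
  a1 <- arcqa:::aperture_areas(q)
  n_open <- vapply(p$control_points, function(cp) {
    sum(cp$bankA_edges < cp$bankB_edges)
  }, numeric(1))
  expect_equal(a1 - a0, 0.1 * 1.0 * n_open)
})

test_that("zero offset changes nothing but the variant label", {
  p <- tiny_plan()
  q <- inject_bank_error(p, perturbation_spec("A", 0))
  expect_equal(q$variant_label, "MLC1PE")
  q$variant_label <- p$variant_label
  expect_equal(q, p)
})

test_that("injection is linear in the offset and errors past the travel limit", {
  p <- generate_arc_plan(generator_config(seed = 7))
  ab <- inject_bank_error(inject_bank_error(p, perturbation_spec("A", 0.04)),
                          perturbation_spec("A", 0.06))
  once <- inject_bank_error(p, perturbation_spec("A", 0.1))
  for (k in seq_along(p$control_points)) {
    expect_equal(ab$control_points[[k]]$bankA_edges,
                 once$control_points[[k]]$bankA_edges)
  }
  expect_error(inject_bank_error(p, perturbation_spec("A", 12)),
               class = "arcqa_range_error")
  # bank B opens the other side
  qb <- inject_bank_error(p, perturbation_spec("B", 0.1))
  cp <- p$control_points[[1]]; cpb <- qb$control_points[[1]]
  open <- cp$bankA_edges < cp$bankB_edges
  expect_equal(cpb$bankB_edges[open], cp$bankB_edges[open] + 0.1)
  expect_equal(cpb$bankA_edges, cp$bankA_edges)
})

test_that("gantry collapse zeroes angles, is idempotent, commutes with injection", {
  p <- generate_arc_plan(generator_config(seed = 3))
  c1 <- collapse_gantry(p)
  expect_true(all(vapply(c1$control_points, `[[`, numeric(1),
                         "gantry_angle_deg") == 0))
  expect_equal(c1$delivery_mode, "collapsed")
  expect_equal(collapse_gantry(c1), c1)
  # MLC and MU untouched
  for (k in seq_along(p$control_points)) {
    expect_identical(c1$control_points[[k]]$bankA_edges,
                     p$control_points[[k]]$bankA_edges)
    expect_identical(c1$control_points[[k]]$mu_weight,
                     p$control_points[[k]]$mu_weight)
  }
  spec <- perturbation_spec("A", 0.1)
  expect_equal(collapse_gantry(inject_bank_error(p, spec)),
               inject_bank_error(collapse_gantry(p), spec))
})

test_that("the CSV exporter writes one row per control point per pair", {
  p <- tiny_plan()
  f <- withr::local_tempfile(fileext = ".csv")
  plan_to_csv(p, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 3 * 40)
  expect_equal(tab$bankA_cm[tab$cp == 2 & tab$pair == 19],
               p$control_points[[2]]$bankA_edges[19])
})
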