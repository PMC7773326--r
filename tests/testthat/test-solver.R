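test_that("cost terms are hinge losses with a well-defined zero", {
  nuc <- fixture_nucleus()
  specs <- bead_specs(c("chr1_A", "chr2_A"), c(0, 0), c(1e6, 1e6),
                      c("a", "b"), edges = list("b", "a"),
                      radius = c(0.5, 0.5))
  # touching pair inside the nucleus: every term zero
  conf <- genome_conformation(specs, rbind(c(0, 0, 0), c(1, 0, 0)), nuc)
  cost <- evaluate_cost(conf, contact_constraints(specs))
  expect_equal(cost$contact, 0)
  expect_equal(cost$boundary, 0)
  expect_equal(cost$lad, 0)
  expect_equal(cost$overlap, 0)
  expect_equal(cost$total, 0)
  # bead centre 1 um beyond the boundary costs exactly 1
  conf2 <- genome_conformation(specs, rbind(c(6, 0, 0), c(1, 0, 0)), nuc)
  expect_equal(evaluate_cost(conf2, NULL)$boundary, 1, tolerance = 1e-12)
  expect_equal(evaluate_cost(
    conf2, NULL, solver_config(constrain_nucleus = FALSE))$boundary, 0)
  # separated contact pair: gap beyond touching distance
  conf3 <- genome_conformation(specs, rbind(c(0, 0, 0), c(3, 0, 0)), nuc)
  expect_equal(evaluate_cost(conf3, contact_constraints(specs))$contact, 2)
  # overlapping pair
  conf4 <- genome_conformation(specs, rbind(c(0, 0, 0), c(0.5, 0, 0)), nuc)
  expect_equal(evaluate_cost(conf4, NULL)$overlap, 0.5)
  expect_error(
    evaluate_cost(conf, data.frame(bead_a = "a", bead_b = "zz")),
    "unknown bead")
})

test_that("lad term pulls flagged beads out of the inner shell", {
  nuc <- fixture_nucleus()
  specs <- bead_specs("chr1_A", 0, 1e6, "a", periphery = TRUE,
                      radius = 0.5)
  at <- function(x) genome_conformation(specs, matrix(c(x, 0, 0), 1), nuc)
  expect_equal(evaluate_cost(at(0.0), NULL)$lad, 4, tolerance = 1e-9)
  expect_equal(evaluate_cost(at(2.0), NULL)$lad, 2, tolerance = 1e-9)
  expect_equal(evaluate_cost(at(4.5), NULL)$lad, 0)
})

test_that("proposals preserve rigid-motion geometry and respect bounds", {
  specs <- fixture_specs()
  conf <- fixture_conformation(specs = specs)
  set.seed(99)
  seen <- character(0)
  for (k in 1:300) {
    type <- c("crankshaft", "arm_rotation", "translation", "rotation")[
      1 + (k %% 4)]
    cfg <- solver_config(move_weights = stats::setNames(
      as.numeric(c("crankshaft", "arm_rotation", "arm_wiggle",
                   "translation", "rotation") == type),
      c("crankshaft", "arm_rotation", "arm_wiggle", "translation",
        "rotation")))
    prop <- propose_move(conf, cfg)
    seen <- c(seen, prop$move_type)
    rows <- prop$rows
    expect_equal(length(unique(conf$specs$chrom[rows])), 1)
    if (type %in% c("translation", "rotation")) {
      idx <- conf$chains[[prop$chrom]]
      expect_setequal(rows, idx)
      old_d <- stats::dist(conf$coords[idx, , drop = FALSE])
      newc <- conf$coords
      newc[rows, ] <- prop$new_coords
      expect_equal(max(abs(stats::dist(newc[idx, , drop = FALSE]) - old_d)),
                   0, tolerance = 1e-9)
    }
    if (type == "translation") {
      expect_true(all(abs(prop$new_coords - conf$coords[rows, ]) <= 1))
    }
    if (type == "crankshaft") {
      idx <- conf$chains[[prop$chrom]]
      pivots <- setdiff(idx, rows)
      expect_gte(length(pivots), 2)   # pivot beads stay fixed
    }
  }
  expect_setequal(unique(seen),
                  c("crankshaft", "arm_rotation", "translation", "rotation"))
})

test_that("arm wiggle keeps the re-grown arm connected and inside the nucleus", {
  specs <- fixture_specs()
  conf <- fixture_conformation(specs = specs)
  cfg <- solver_config(move_weights = c(crankshaft = 0, arm_rotation = 0,
                                        arm_wiggle = 1, translation = 0,
                                        rotation = 0))
  set.seed(5)
  for (k in 1:50) {
    prop <- propose_move(conf, cfg)
    expect_true(all(nucleus_contains(prop$new_coords, conf$nucleus)))
    newc <- conf$coords
    newc[prop$rows, ] <- prop$new_coords
    idx <- conf$chains[[prop$chrom]]
    d <- sqrt(rowSums((newc[idx[-1], , drop = FALSE] -
                         newc[idx[-length(idx)], , drop = FALSE])^2))
    touch <- conf$specs$radius[idx[-1]] + conf$specs$radius[idx[-length(idx)]]
    moved <- idx %in% prop$rows
    link_moved <- moved[-1] | moved[-length(moved)]
    expect_equal(d[link_moved], touch[link_moved], tolerance = 1e-9)
  }
})

test_that("acceptance rules follow the greedy and metropolis definitions", {
  expect_true(accept_move(-0.5, "greedy"))
  expect_false(accept_move(0.0, "greedy"))
  expect_true(accept_move(0.0, "metropolis", 1))
  set.seed(1)
  acc <- mean(vapply(1:10000, function(i) {
    accept_move(log(2) * 0.7, "metropolis", 0.7)
  }, logical(1)))
  expect_equal(acc, 0.5, tolerance = 0.02)
})

test_that("metropolis acceptance of uphill moves matches exp(-delta/T)", {
  set.seed(7)
  t_fix <- 0.8
  for (delta in c(0.2, 0.8, 1.6)) {
    n <- 10000
    acc <- mean(vapply(seq_len(n), function(i) {
      accept_move(delta, "metropolis", t_fix)
    }, logical(1)))
    p <- exp(-delta / t_fix)
    expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("solver identity, determinism, and state conservation hold", {
  specs <- fixture_specs()
  conf <- fixture_conformation(specs = specs)
  cons <- contact_constraints(specs)
  res0 <- solve_conformation(conf, cons,
                             solver_config(n_successful_moves = 0))
  expect_identical(res0$conformation$coords, conf$coords)
  cfg <- solver_config(n_successful_moves = 300, temperature = 0.5,
                       seed = 12)
  r1 <- solve_conformation(conf, cons, cfg)
  r2 <- solve_conformation(conf, cons, cfg)
  expect_identical(r1$conformation$coords, r2$conformation$coords)
  expect_identical(r1$trace, r2$trace)
  # conserved: bead count, radii, bp, chain ordering
  expect_identical(r1$conformation$specs, conf$specs)
  expect_identical(r1$conformation$chains, conf$chains)
  # incremental bookkeeping agrees with a from-scratch evaluation
  expect_equal(unname(r1$trace[length(r1$trace)]), r1$final_cost$total,
               tolerance = 1e-8)
})

test_that("greedy trace is monotone non-increasing and never worsens the cost", {
  specs <- fixture_specs()
  conf <- fixture_conformation(specs = specs)
  cons <- contact_constraints(specs)
  cfg <- solver_config(n_successful_moves = 10000, scheme = "greedy",
                       seed = 8)
  res <- solve_conformation(conf, cons, cfg)
  expect_gt(length(res$trace), 0)
  expect_true(all(diff(res$trace) <= 1e-12))
  expect_lte(res$final_cost$total, res$initial_cost$total)
})

test_that("annealing cools the temperature and still tracks cost exactly", {
  specs <- fixture_specs()
  conf <- fixture_conformation(specs = specs)
  cons <- contact_constraints(specs)
  cfg <- solver_config(n_successful_moves = 500, scheme = "anneal",
                       temperature = 1, cooling = 0.99, seed = 3)
  res <- solve_conformation(conf, cons, cfg)
  expect_equal(unname(res$trace[length(res$trace)]), res$final_cost$total,
               tolerance = 1e-8)
})

test_that("scaled solve confines beads and improves contacts over random", {
  specs <- fixture_specs()
  nuc <- fixture_nucleus()
  conf <- fixture_conformation(specs = specs)
  cons <- contact_constraints(specs)
  cfg <- solver_config(n_successful_moves = 50000, scheme = "metropolis",
                       temperature = 0.3, cost_weights = c(boundary = 10),
                       seed = 4)
  res <- solve_conformation(conf, cons, cfg)
  outside <- mean(boundary_excess(res$conformation$coords, nuc) > 0)
  expect_lt(outside, 0.01)
  rand <- generate_pseudo_random(specs, nuc, seed = 5)
  rand_cost <- evaluate_cost(rand, cons, cfg)
  expect_lt(res$final_cost$contact, rand_cost$contact)
  expect_lt(proximity_score(res$conformation, cons)$score,
            proximity_score(rand, cons)$score)
})
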