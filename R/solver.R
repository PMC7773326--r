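#' Solver configuration
#'
#' Controls the Markov-chain Monte Carlo optimisation of a genome
#' conformation. Iterations are counted as *accepted* ("successful")
#' moves; the study default target is 2 million successful moves, with
#' an attempted-move cap of 50 times the target to guarantee
#' termination.
#'
#' @param n_successful_moves Number of accepted moves to perform.
#' @param max_attempts Cap on attempted moves (default 50x the target).
#' @param scheme Acceptance scheme: `"greedy"` (downhill only),
#'   `"metropolis"` (fixed temperature), or `"anneal"` (geometric
#'   cooling per accepted move).
#' @param temperature Initial temperature for metropolis/anneal.
#' @param cooling Multiplicative cooling factor per accepted move
#'   (anneal only); the default 0.999995 decays slowly over 2e6
#'   acceptances.
#' @param move_weights Named non-negative weights over the five move
#'   types `crankshaft`, `arm_rotation`, `arm_wiggle`, `translation`,
#'   `rotation` (uniform by default).
#' @param constrain_nucleus Apply the nuclear-boundary cost term?
#' @param cost_weights Named weights for the `contact`, `boundary`,
#'   `lad`, and `overlap` cost terms (all 1 by default).
#' @param lad_shell_fraction Periphery-flagged beads are pulled outside
#'   the inner shell of this fraction of the (normalised) nuclear
#'   radius.
#' @param seed Integer seed for [solve_conformation()].
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(n_successful_moves = 2e6,
                          max_attempts = 50 * n_successful_moves,
                          scheme = c("metropolis", "greedy", "anneal"),
                          temperature = 1.0, cooling = 0.999995,
                          move_weights = NULL, constrain_nucleus = TRUE,
                          cost_weights = NULL, lad_shell_fraction = 0.8,
                          seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_successful_moves < 0) stop("n_successful_moves must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  mw <- c(crankshaft = 1, arm_rotation = 1, arm_wiggle = 1,
          translation = 1, rotation = 1)
  if (!is.null(move_weights)) mw[names(move_weights)] <- move_weights
  if (any(mw < 0) || all(mw == 0)) {
    stop("move weights must be >= 0 with at least one > 0")
  }
  cw <- c(contact = 1, boundary = 1, lad = 1, overlap = 1)
  if (!is.null(cost_weights)) cw[names(cost_weights)] <- cost_weights
  structure(list(n_successful_moves = n_successful_moves,
                 max_attempts = max_attempts, scheme = scheme,
                 temperature = temperature, cooling = cooling,
                 move_weights = mw, constrain_nucleus = constrain_nucleus,
                 cost_weights = cw,
                 lad_shell_fraction = lad_shell_fraction,
                 seed = as.integer(seed)),
            class = "solver_config")
}

# map bead-id constraint pairs to row indices; errors on unknown ids
constraint_indices <- function(specs, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  ia <- match(constraints$bead_a, specs$bead_id)
  ib <- match(constraints$bead_b, specs$bead_id)
  bad <- is.na(ia) | is.na(ib)
  if (any(bad)) {
    stop("constraint references unknown bead id(s): ",
         paste(unique(c(constraints$bead_a[bad & is.na(ia)],
                        constraints$bead_b[bad & is.na(ib)])),
               collapse = ", "))
  }
  cbind(ia, ib)
}

# hinge losses on surface-gap distances -------------------------------------

# contact: sum over constraints of max(0, d - (ra + rb))
contact_cost <- function(coords, radii, cidx) {
  if (!nrow(cidx)) return(0)
  d <- sqrt(rowSums((coords[cidx[, 1], , drop = FALSE] -
                       coords[cidx[, 2], , drop = FALSE])^2))
  sum(pmax(0, d - (radii[cidx[, 1]] + radii[cidx[, 2]])))
}

# LAD: hinge pulling flagged beads out of the inner shell; measured as the
# radial distance (um) from the bead centre to the shell along its ray
lad_cost <- function(coords, nucleus, flagged, shell_fraction) {
  if (!length(flagged)) return(0)
  pts <- coords[flagged, , drop = FALSE]
  u <- nucleus_radial(pts, nucleus)
  r <- sqrt(rowSums(pts^2))
  # boundary distance along the ray: r / u (min semi-axis at the centre)
  rb <- ifelse(u > 0, r / u, min(nucleus$semi_axes))
  sum(pmax(0, (shell_fraction - u) * rb))
}

# overlap between all pairs within `rows` and between `rows` and the rest;
# chunked cross-distance to bound memory
overlap_cost_subset <- function(coords, radii, rows) {
  n <- nrow(coords)
  m <- length(rows)
  if (m == 0 || n < 2) return(0)
  a <- coords[rows, , drop = FALSE]
  ra <- radii[rows]
  tot <- 0
  step <- 2048L
  others <- setdiff(seq_len(n), rows)
  if (length(others)) {
    for (s in seq(1, length(others), by = step)) {
      j <- others[s:min(s + step - 1L, length(others))]
      b <- coords[j, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
      gap <- outer(ra, radii[j], `+`) - sqrt(pmax(d2, 0))
      tot <- tot + sum(gap[gap > 0])
    }
  }
  if (m > 1) {
    d2 <- outer(rowSums(a^2), rowSums(a^2), `+`) - 2 * tcrossprod(a)
    gap <- outer(ra, ra, `+`) - sqrt(pmax(d2, 0))
    diag(gap) <- 0
    tot <- tot + sum(gap[gap > 0]) / 2
  }
  tot
}

# cost restricted to the terms that involve beads in `rows`
cost_subset <- function(coords, radii, rows, nucleus, periphery, cidx_sub,
                        config) {
  w <- config$cost_weights
  boundary <- if (config$constrain_nucleus) {
    sum(boundary_excess(coords[rows, , drop = FALSE], nucleus))
  } else 0
  flagged <- rows[periphery[rows]]
  lad <- lad_cost(coords, nucleus, flagged, config$lad_shell_fraction)
  overlap <- overlap_cost_subset(coords, radii, rows)
  contact <- contact_cost(coords, radii, cidx_sub)
  w[["contact"]] * contact + w[["boundary"]] * boundary +
    w[["lad"]] * lad + w[["overlap"]] * overlap
}

#' Evaluate the solver cost of a conformation
#'
#' The objective is a weighted sum of four hinge terms, each zero at
#' satisfaction: `contact` (surface gap of constrained pairs beyond
#' touching), `boundary` (distance of bead centres outside the nucleus;
#' zero inside, active only with `constrain_nucleus`), `lad` (distance
#' of periphery-flagged beads inward of the peripheral shell), and
#' `overlap` (pairwise surface interpenetration).
#'
#' @param conformation A [genome_conformation()].
#' @param constraints Contact pairs from [contact_constraints()].
#' @param config A [solver_config()].
#' @return A list of class `cost_breakdown` with the four terms
#'   (unweighted), their weighted `total`, and the `weights` used.
#' @export
evaluate_cost <- function(conformation, constraints = NULL,
                          config = solver_config()) {
  stopifnot(inherits(conformation, "genome_conformation"))
  specs <- conformation$specs
  coords <- conformation$coords
  radii <- specs$radius
  cidx <- constraint_indices(specs, constraints)
  boundary <- if (config$constrain_nucleus) {
    sum(boundary_excess(coords, conformation$nucleus))
  } else 0
  lad <- lad_cost(coords, conformation$nucleus, which(specs$periphery),
                  config$lad_shell_fraction)
  overlap <- overlap_cost_subset(coords, radii, seq_len(nrow(coords)))
  contact <- contact_cost(coords, radii, cidx)
  w <- config$cost_weights
  terms <- list(contact = contact, boundary = boundary, lad = lad,
                overlap = overlap)
  total <- sum(unlist(terms) * w[names(terms)])
  structure(c(terms, list(total = total, weights = w)),
            class = "cost_breakdown")
}

# Rodrigues rotation of points about `axis` (unit) through `origin`
rotate_about <- function(pts, origin, axis, angle) {
  p1 <- pts[, 1] - origin[1]
  p2 <- pts[, 2] - origin[2]
  p3 <- pts[, 3] - origin[3]
  k <- axis / sqrt(sum(axis^2))
  cosa <- cos(angle); sina <- sin(angle)
  kx <- p2 * k[3] - p3 * k[2]
  ky <- p3 * k[1] - p1 * k[3]
  kz <- p1 * k[2] - p2 * k[1]
  kd <- (p1 * k[1] + p2 * k[2] + p3 * k[3]) * (1 - cosa)
  cbind(p1 * cosa + kx * sina + kd * k[1] + origin[1],
        p2 * cosa + ky * sina + kd * k[2] + origin[2],
        p3 * cosa + kz * sina + kd * k[3] + origin[3],
        deparse.level = 0)
}

random_axis <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Propose a single solver move
#'
#' Draws one of five move types on a uniformly chosen chromosome:
#' `crankshaft` rotates the beads between two fixed pivot beads about
#' the pivot-pivot axis; `arm_rotation` rigidly rotates one arm (from a
#' random position to the start or end) about the pivot bead;
#' `arm_wiggle` re-grows one arm as a touching-bead random walk inside
#' the nucleus; `translation` shifts the whole chromosome by a uniform
#' per-component offset in \[-1, 1\] um; `rotation` rigidly rotates the
#' whole chromosome about its centroid. Move types infeasible for the
#' chosen chain length are resampled.
#'
#' @param conformation A [genome_conformation()].
#' @param config A [solver_config()].
#' @return A list of class `move_proposal` with `move_type`, `chrom`,
#'   `rows` (global bead row indices changed), and `new_coords`.
#' @export
propose_move <- function(conformation, config = solver_config()) {
  propose_move_core(conformation$coords, conformation$chains,
                    conformation$specs$radius, conformation$nucleus,
                    config)
}

propose_move_core <- function(coords, chains, radii, nucleus, config) {
  types <- names(config$move_weights)
  cumw <- cumsum(config$move_weights) / sum(config$move_weights)
  for (try in 1:100) {
    ci <- sample.int(length(chains), 1)
    idx <- chains[[ci]]
    L <- length(idx)
    type <- types[findInterval(stats::runif(1), cumw) + 1L]
    if (type == "crankshaft" && L < 3) next
    if (type %in% c("arm_rotation", "arm_wiggle") && L < 2) next
    prop <- switch(type,
      crankshaft = {
        i <- sample(L - 2, 1)
        j <- i + 1 + sample(L - i - 1, 1)     # j >= i + 2
        mid <- idx[(i + 1):(j - 1)]
        axis <- coords[idx[j], ] - coords[idx[i], ]
        if (sum(axis^2) < 1e-24) next
        new_pts <- rotate_about(coords[mid, , drop = FALSE],
                                coords[idx[i], ], axis,
                                stats::runif(1, 0, 2 * pi))
        list(rows = mid, new_coords = new_pts)
      },
      arm_rotation = {
        k <- if (L >= 3) (2:(L - 1))[sample.int(L - 2, 1)] else sample.int(2, 1)
        towards_end <- if (k == 1) TRUE else if (k == L) FALSE else
          stats::runif(1) < 0.5
        arm <- if (towards_end) idx[(k + 1):L] else idx[1:(k - 1)]
        new_pts <- rotate_about(coords[arm, , drop = FALSE],
                                coords[idx[k], ], random_axis(),
                                stats::runif(1, 0, 2 * pi))
        list(rows = arm, new_coords = new_pts)
      },
      arm_wiggle = {
        k <- if (L >= 3) (2:(L - 1))[sample.int(L - 2, 1)] else sample.int(2, 1)
        towards_end <- if (k == 1) TRUE else if (k == L) FALSE else
          stats::runif(1) < 0.5
        ord <- if (towards_end) (k + 1):L else (k - 1):1
        new_pts <- matrix(NA_real_, length(ord), 3)
        semi <- nucleus$semi_axes
        prev <- coords[idx[k], ]
        prev_r <- radii[idx[k]]
        ok <- TRUE
        for (m in seq_along(ord)) {
          b <- idx[ord[m]]
          step <- prev_r + radii[b]
          good <- FALSE
          for (t2 in 1:200) {
            dir <- stats::rnorm(3)
            cand <- prev + step * dir / sqrt(sum(dir^2))
            if ((cand[1] / semi[1])^2 + (cand[2] / semi[2])^2 +
                  (cand[3] / semi[3])^2 <= 1) { good <- TRUE; break }
          }
          if (!good) { ok <- FALSE; break }
          new_pts[m, ] <- cand
          prev <- cand
          prev_r <- radii[b]
        }
        if (!ok) next
        list(rows = idx[ord], new_coords = new_pts)
      },
      translation = {
        delta <- stats::runif(3, -1, 1)
        list(rows = idx,
             new_coords = sweep(coords[idx, , drop = FALSE], 2, delta, `+`))
      },
      rotation = {
        centroid <- colMeans(coords[idx, , drop = FALSE])
        list(rows = idx,
             new_coords = rotate_about(coords[idx, , drop = FALSE],
                                       centroid, random_axis(),
                                       stats::runif(1, 0, 2 * pi)))
      })
    return(structure(list(move_type = type,
                          chrom = names(chains)[ci],
                          rows = prop$rows,
                          new_coords = prop$new_coords),
                     class = "move_proposal"))
  }
  stop("could not propose a feasible move in 100 attempts")
}

#' Move acceptance rule
#'
#' Greedy accepts only strict improvements; metropolis and simulated
#' annealing accept non-worsening moves always and worsening moves with
#' probability exp(-delta / temperature).
#'
#' @param delta_cost Proposed total-cost change.
#' @param scheme `"greedy"`, `"metropolis"`, or `"anneal"`.
#' @param temperature Current temperature (metropolis/anneal).
#' @return Logical: accept?
#' @export
accept_move <- function(delta_cost, scheme = "metropolis",
                        temperature = 1.0) {
  stopifnot(is.finite(delta_cost))
  if (scheme == "greedy") return(delta_cost < 0)
  if (delta_cost <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_cost / temperature)
}

#' Optimise a conformation by MCMC
#'
#' Runs the move/accept loop until `n_successful_moves` moves have been
#' accepted or `max_attempts` attempts are exhausted. Cost changes are
#' evaluated incrementally over the beads a proposal touches. The loop
#' is bit-reproducible given `config$seed`.
#'
#' @param conformation A [genome_conformation()].
#' @param constraints Contact pairs from [contact_constraints()]; `NULL`
#'   uses the edges carried by the conformation's bead specs.
#' @param config A [solver_config()].
#' @return A list of class `solve_result`: `conformation` (final),
#'   `trace` (total cost after each accepted move), `initial_cost`,
#'   `final_cost` (both [evaluate_cost()] breakdowns), `attempted` and
#'   `accepted` (named counts by move type).
#' @export
solve_conformation <- function(conformation, constraints = NULL,
                               config = solver_config()) {
  stopifnot(inherits(conformation, "genome_conformation"))
  if (is.null(constraints)) {
    constraints <- contact_constraints(conformation$specs)
  }
  specs <- conformation$specs
  cidx <- constraint_indices(specs, constraints)
  coords <- conformation$coords
  radii <- specs$radius
  periphery <- specs$periphery
  nucleus <- conformation$nucleus
  # constraints touching each bead, for incremental contact deltas
  by_bead <- vector("list", nrow(specs))
  if (nrow(cidx)) {
    for (k in seq_len(nrow(cidx))) {
      by_bead[[cidx[k, 1]]] <- c(by_bead[[cidx[k, 1]]], k)
      by_bead[[cidx[k, 2]]] <- c(by_bead[[cidx[k, 2]]], k)
    }
  }
  initial_cost <- evaluate_cost(conformation, constraints, config)
  set.seed(config$seed)
  target <- config$n_successful_moves
  types <- names(config$move_weights)
  state <- conformation
  by_bead <- lapply(by_bead, function(v) {
    if (is.null(v)) integer(0) else as.integer(v)
  })
  w <- config$cost_weights
  weights <- c(w[["contact"]],
               if (config$constrain_nucleus) w[["boundary"]] else 0,
               w[["lad"]], w[["overlap"]])
  cumw <- cumsum(config$move_weights) / sum(config$move_weights)
  scheme_code <- match(config$scheme, c("greedy", "metropolis", "anneal")) - 1L
  storage.mode(cidx) <- "integer"
  res <- .solve_loop_cpp(coords, radii, periphery,
                         lapply(state$chains, as.integer), cidx, by_bead,
                         nucleus$semi_axes, config$lad_shell_fraction,
                         weights, unname(cumw), scheme_code,
                         config$temperature, config$cooling,
                         target, config$max_attempts,
                         initial_cost$total)
  accepted <- as.integer(res$n_accepted)
  if (accepted == 0L && target > 0L) {
    warning("no move accepted within max_attempts; returning input")
  }
  state$coords <- res$coords
  dimnames(state$coords) <- dimnames(coords)
  final_cost <- evaluate_cost(state, constraints, config)
  structure(list(conformation = state, trace = res$trace,
                 initial_cost = initial_cost, final_cost = final_cost,
                 attempted = stats::setNames(res$attempted, types),
                 accepted = stats::setNames(res$accepted, types),
                 n_attempts = res$n_attempts, n_accepted = accepted),
            class = "solve_result")
}
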