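#' Labelled 3D point set
#'
#' A set of points (bead centres or DSB centroids) with chromosome
#' labels inside a nucleus; the unit of the spatial clustering and
#' Ripley-K analyses. Homolog keys are derived by stripping the
#' `"_A"`/`"_B"` suffix, so the two copies of a chromosome share a key.
#'
#' @param points Numeric matrix n x 3 (um).
#' @param labels Character chromosome label per point.
#' @param nucleus A [nucleus_shape()].
#' @return An object of class `labeled_point_set`.
#' @export
labeled_point_set <- function(points, labels, nucleus) {
  points <- coords_matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels),
            inherits(nucleus, "nucleus_shape"))
  if (!all(nucleus_contains(points, nucleus))) {
    warning("some points lie outside the nucleus")
  }
  structure(list(points = points, labels = labels,
                 homolog_key = homolog_key(labels), nucleus = nucleus),
            class = "labeled_point_set")
}

#' Point set from a conformation or damage-site table
#'
#' @param x A [genome_conformation()] or a damage-site table from
#'   [cluster_breaks()]/[photon_exposure()].
#' @param nucleus Nucleus for a damage-site table.
#' @return A [labeled_point_set()].
#' @export
as_point_set <- function(x, nucleus = NULL) {
  if (inherits(x, "genome_conformation")) {
    return(labeled_point_set(x$coords, x$specs$chrom, x$nucleus))
  }
  if (is.data.frame(x) && all(c("x", "y", "z", "chrom") %in% names(x))) {
    stopifnot(!is.null(nucleus))
    return(labeled_point_set(cbind(x$x, x$y, x$z), x$chrom, nucleus))
  }
  stop("cannot convert to labeled_point_set")
}

# chunked pairwise neighbour counting under a label filter.
# mode: total  = all other points;
#       inter  = different homolog key;
#       intra  = same label;
#       homolog= same key, different label.
neighbour_counts <- function(points, labels, keys, radius, mode) {
  n <- nrow(points)
  counts <- numeric(n)
  r2 <- radius^2
  step <- 1024L
  for (s in seq(1, n, by = step)) {
    i <- s:min(s + step - 1L, n)
    d2 <- outer(rowSums(points[i, , drop = FALSE]^2), rowSums(points^2),
                `+`) - 2 * tcrossprod(points[i, , drop = FALSE], points)
    within <- d2 <= r2 + 1e-12
    within[cbind(seq_along(i), i)] <- FALSE   # exclude self
    keep <- switch(mode,
      total = within,
      inter = within & outer(keys[i], keys, `!=`),
      intra = within & outer(labels[i], labels, `==`),
      homolog = within & outer(keys[i], keys, `==`) &
        outer(labels[i], labels, `!=`))
    counts[i] <- rowSums(keep)
  }
  counts
}

#' Clustering: neighbour counts within a radius
#'
#' For every object, counts the other objects whose centre lies within
#' the cluster radius and passes the mode's chromosome-label filter,
#' then averages over objects. `"inter"` counts objects on a different
#' chromosome *excluding* homologous copies; `"intra"` counts objects on
#' the same chromosome copy; pairs on homologous copies (same key,
#' different label) are excluded from both and available as
#' `"homolog"`, so per object `total = inter + intra + homolog`.
#' Membership is `distance <= radius`.
#'
#' @param pointset A [labeled_point_set()].
#' @param radius Cluster radius in micrometres (> 0).
#' @param mode One of `"total"`, `"inter"`, `"intra"`, `"homolog"`.
#' @return A list of class `cluster_summary`: `radius`, `mode`,
#'   `counts` (per object) and `mean`.
#' @export
cluster_counts <- function(pointset, radius,
                           mode = c("total", "inter", "intra", "homolog")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pointset, "labeled_point_set"), radius > 0)
  n <- nrow(pointset$points)
  if (n == 0) stop("empty point set")
  counts <- neighbour_counts(pointset$points, pointset$labels,
                             pointset$homolog_key, radius, mode)
  structure(list(radius = radius, mode = mode, counts = counts,
                 mean = mean(counts)),
            class = "cluster_summary")
}

#' Inter/intra-chromosomal clustering ratio
#'
#' Ratio of the mean interchromosomal clustering to the mean
#' intrachromosomal clustering at one radius. When the intra mean is
#' zero the ratio is undefined (flagged, not an error); when only the
#' inter mean is zero the ratio is 0.
#'
#' @inheritParams cluster_counts
#' @return A list with `inter`, `intra`, `ratio`, and `undefined`.
#' @export
inter_intra_ratio <- function(pointset, radius) {
  inter <- cluster_counts(pointset, radius, "inter")$mean
  intra <- cluster_counts(pointset, radius, "intra")$mean
  if (intra == 0) {
    list(inter = inter, intra = intra, ratio = NA_real_, undefined = TRUE)
  } else {
    list(inter = inter, intra = intra, ratio = inter / intra,
         undefined = FALSE)
  }
}

# sphere-sphere lens: volume of intersection of spheres (R, centred 0)
# and (r, centred at distance d); vectorised over d
sphere_lens_volume <- function(R, r, d) {
  full <- (4 / 3) * pi * pmin(R, r)^3
  v <- ifelse(d + pmin(R, r) <= pmax(R, r), full,
              ifelse(d >= R + r, 0,
                     pi * (R + r - d)^2 *
                       (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R -
                          3 * R^2) / (12 * d)))
  pmax(v, 0)
}

#' Edge-correction fraction V_s
#'
#' Fraction of a cluster-radius sphere centred at a point that lies
#' inside the nucleus; the Ripley-K edge correction weights each
#' neighbour count by 1/V_s. Analytic (sphere-sphere lens) for
#' spherical nuclei; seeded Monte Carlo for ellipsoids.
#'
#' @param center Length-3 point inside the nucleus (um).
#' @param cr Cluster radius (um).
#' @param nucleus A [nucleus_shape()].
#' @param n_mc Monte-Carlo sample count (ellipsoid only).
#' @param mc_seed Seed for the Monte-Carlo draw (ellipsoid only).
#' @return Fraction in (0, 1].
#' @export
edge_correction_vs <- function(center, cr, nucleus, n_mc = 10000L,
                               mc_seed = 1L) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, cr > 0)
  if (!nucleus_contains(center, nucleus)) {
    stop("center must lie inside the nucleus")
  }
  if (nucleus$kind == "sphere") {
    R <- nucleus$semi_axes[1]
    d <- sqrt(sum(center^2))
    return(sphere_lens_volume(R, cr, d) / ((4 / 3) * pi * cr^3))
  }
  set.seed(mc_seed)
  z <- matrix(stats::rnorm(3 * n_mc), n_mc, 3)
  z <- z / sqrt(rowSums(z^2)) * stats::runif(n_mc)^(1 / 3) * cr
  pts <- sweep(z, 2, center, `+`)
  mean(nucleus_contains(pts, nucleus))
}

# per-point V_s for many centres at one radius (vectorised sphere path,
# one shared MC cloud for ellipsoids)
edge_correction_vs_many <- function(points, cr, nucleus, n_mc = 10000L,
                                    mc_seed = 1L) {
  if (nucleus$kind == "sphere") {
    R <- nucleus$semi_axes[1]
    d <- sqrt(rowSums(points^2))
    return(sphere_lens_volume(R, cr, d) / ((4 / 3) * pi * cr^3))
  }
  set.seed(mc_seed)
  z <- matrix(stats::rnorm(3 * n_mc), n_mc, 3)
  cloud <- z / sqrt(rowSums(z^2)) * stats::runif(n_mc)^(1 / 3) * cr
  s <- nucleus$semi_axes
  vapply(seq_len(nrow(points)), function(i) {
    p <- sweep(cloud, 2, points[i, ], `+`)
    mean((p[, 1] / s[1])^2 + (p[, 2] / s[2])^2 + (p[, 3] / s[3])^2 <= 1)
  }, numeric(1))
}

#' 3D Ripley-K with nuclear edge correction
#'
#' For each cluster radius CR computes
#' K(CR) = V_nuc / n^2 * sum_i sum_{j != i} I(D(i,j) <= CR) / V_s(i),
#' where V_s(i) is the fraction of the CR-sphere around point i inside
#' the nucleus ([edge_correction_vs()]). The normalised statistic is
#' K / ((4/3) pi CR^3) - 1, which is 0 in expectation under complete
#' spatial randomness.
#'
#' @param pointset A [labeled_point_set()] (n >= 2 points).
#' @param cr Numeric vector of cluster radii (um).
#' @param edge_correct Apply the 1/V_s correction? (`TRUE`).
#' @return A `data.frame` of class `ripley_result` with columns `cr`,
#'   `K` (um^3), and `K_norm`.
#' @export
ripley_k <- function(pointset, cr, edge_correct = TRUE) {
  stopifnot(inherits(pointset, "labeled_point_set"))
  pts <- pointset$points
  n <- nrow(pts)
  if (n < 2) stop("ripley_k needs at least 2 points")
  v_nuc <- nucleus_volume(pointset$nucleus)
  out <- data.frame(cr = cr, K = NA_real_, K_norm = NA_real_)
  sq <- rowSums(pts^2)
  for (m in seq_along(cr)) {
    r2 <- cr[m]^2
    vs <- if (edge_correct) {
      edge_correction_vs_many(pts, cr[m], pointset$nucleus)
    } else rep(1, n)
    acc <- 0
    step <- 1024L
    for (s in seq(1, n, by = step)) {
      i <- s:min(s + step - 1L, n)
      d2 <- outer(sq[i], sq, `+`) -
        2 * tcrossprod(pts[i, , drop = FALSE], pts)
      cnt <- rowSums(d2 <= r2 + 1e-12) - 1     # drop self
      acc <- acc + sum(cnt / vs[i])
    }
    K <- v_nuc * acc / n^2
    out$K[m] <- K
    out$K_norm[m] <- K / ((4 / 3) * pi * cr[m]^3) - 1
  }
  class(out) <- c("ripley_result", "data.frame")
  out
}

#' Central/peripheral radial positioning
#'
#' Scores each bead as central when its centre lies in the inner region
#' holding half the nuclear volume (sphere: radius R * 2^(-1/3);
#' ellipsoid: the axis-preserving scaled copy by 2^(-1/3)), then
#' aggregates bead-bp-weighted central/peripheral fractions per genomic
#' bin per chromosome (homolog copies pooled by key).
#'
#' @param conformation A [genome_conformation()].
#' @param bin_bp Genomic bin width in bp (default 10 Mbp).
#' @return A list of class `radial_positioning`: `bins` (data frame
#'   with `chrom`, `bin_start`, `bp`, `central_frac`, `peripheral_frac`)
#'   and `periphery_pct`, the bp-weighted percentage of DNA in the
#'   peripheral half.
#' @export
radial_positioning <- function(conformation, bin_bp = 1e7) {
  stopifnot(inherits(conformation, "genome_conformation"))
  specs <- conformation$specs
  u <- nucleus_radial(conformation$coords, conformation$nucleus)
  central <- u <= 2^(-1 / 3)
  bp <- specs$end - specs$start
  key <- homolog_key(specs$chrom)
  bin <- floor(specs$start / bin_bp) * bin_bp
  g <- paste(key, bin, sep = "\r")
  agg <- function(v) tapply(v, g, sum)
  bp_tot <- agg(bp)
  bp_central <- agg(bp * central)
  first <- !duplicated(g)
  ord <- order(key[first], bin[first])
  gid <- g[first][ord]
  bins <- data.frame(chrom = key[first][ord], bin_start = bin[first][ord],
                     bp = as.numeric(bp_tot[gid]),
                     central_frac = as.numeric(bp_central[gid] / bp_tot[gid]),
                     stringsAsFactors = FALSE)
  bins$peripheral_frac <- 1 - bins$central_frac
  structure(list(bins = bins,
                 periphery_pct = 100 * sum(bp * !central) / sum(bp)),
            class = "radial_positioning")
}

#' Consistently proximal chromosome pairs across an ensemble
#'
#' A chromosome pair (different homolog keys) is reported when, in at
#' least `threshold` of the geometries, the pair shares at least one
#' interchromosomal bead pair with centre distance strictly below
#' `distance_um`.
#'
#' @param conformations List of [genome_conformation()] objects.
#' @param distance_um Proximity distance in micrometres (default 0.5,
#'   i.e. 500 nm).
#' @param threshold Minimum fraction of geometries, in (0, 1].
#' @return A `data.frame` with `chrom_a`, `chrom_b` (homolog keys,
#'   `chrom_a < chrom_b`) and `fraction` of geometries with a proximal
#'   pair, filtered to `fraction >= threshold`.
#' @export
chord_adjacency <- function(conformations, distance_um = 0.5,
                            threshold = 0.4) {
  stopifnot(length(conformations) >= 1, threshold > 0, threshold <= 1)
  tallies <- new.env(parent = emptyenv())
  n_geom <- length(conformations)
  for (conf in conformations) {
    stopifnot(inherits(conf, "genome_conformation"))
    pts <- conf$coords
    keys <- homolog_key(conf$specs$chrom)
    sq <- rowSums(pts^2)
    seen <- character(0)
    step <- 1024L
    n <- nrow(pts)
    for (s in seq(1, n, by = step)) {
      i <- s:min(s + step - 1L, n)
      d2 <- outer(sq[i], sq, `+`) -
        2 * tcrossprod(pts[i, , drop = FALSE], pts)
      hit <- which(d2 < distance_um^2 & outer(keys[i], keys, `!=`),
                   arr.ind = TRUE)
      if (nrow(hit)) {
        ka <- keys[i[hit[, 1]]]
        kb <- keys[hit[, 2]]
        seen <- c(seen, paste(pmin(ka, kb), pmax(ka, kb), sep = "\r"))
      }
    }
    for (p in unique(seen)) {
      tallies[[p]] <- (if (is.null(tallies[[p]])) 0 else tallies[[p]]) + 1
    }
  }
  pairs <- ls(tallies)
  if (!length(pairs)) {
    return(data.frame(chrom_a = character(0), chrom_b = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  frac <- vapply(pairs, function(p) tallies[[p]] / n_geom, numeric(1))
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  out <- data.frame(chrom_a = vapply(parts, `[`, "", 1),
                    chrom_b = vapply(parts, `[`, "", 2),
                    fraction = unname(frac), stringsAsFactors = FALSE)
  out <- out[out$fraction >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom_a, out$chrom_b), , drop = FALSE]
}

#' Proximity score of contact-constraint satisfaction
#'
#' For every bead that carries at least one contact constraint, the
#' mean centre-to-centre distance to its constrained partners is taken;
#' the score is the average of those per-bead means. Lower is better;
#' nuclear-boundary and lamina terms are ignored.
#'
#' @param conformation A [genome_conformation()].
#' @param constraints Contact pairs from [contact_constraints()]; `NULL`
#'   derives them from the conformation's bead edges.
#' @return A list with `score` (um; `NA` when no constraints exist) and
#'   `undefined`.
#' @export
proximity_score <- function(conformation, constraints = NULL) {
  stopifnot(inherits(conformation, "genome_conformation"))
  if (is.null(constraints)) {
    constraints <- contact_constraints(conformation$specs)
  }
  cidx <- constraint_indices(conformation$specs, constraints)
  if (!nrow(cidx)) return(list(score = NA_real_, undefined = TRUE))
  coords <- conformation$coords
  d <- sqrt(rowSums((coords[cidx[, 1], , drop = FALSE] -
                       coords[cidx[, 2], , drop = FALSE])^2))
  bead <- c(cidx[, 1], cidx[, 2])
  dist2 <- c(d, d)
  per_bead <- tapply(dist2, bead, mean)
  list(score = mean(per_bead), undefined = FALSE)
}
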