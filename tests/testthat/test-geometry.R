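test_that("clustering modes follow the homolog rule on hand-built cases", {
  nuc <- fixture_nucleus()
  tri <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0)),
                           c("chr1_A", "chr2_A", "chr3_A"), nuc)
  expect_equal(cluster_counts(tri, 0.5, "inter")$mean, 2)
  expect_equal(cluster_counts(tri, 0.5, "intra")$mean, 0)
  # homologous pair counts in neither inter nor intra
  hom <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                           c("chr1_A", "chr1_B"), nuc)
  expect_equal(cluster_counts(hom, 0.5, "inter")$mean, 0)
  expect_equal(cluster_counts(hom, 0.5, "intra")$mean, 0)
  expect_equal(cluster_counts(hom, 0.5, "homolog")$mean, 1)
  same <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                            c("chr1_A", "chr1_A"), nuc)
  expect_equal(cluster_counts(same, 0.5, "intra")$mean, 1)
  expect_equal(cluster_counts(same, 0.5, "inter")$mean, 0)
})

test_that("clustering equals the brute-force oracle in all modes", {
  nuc <- fixture_nucleus()
  set.seed(31)
  n <- 400
  pts <- sample_in_nucleus(n, nuc)
  labs <- paste0("chr", sample(1:6, n, replace = TRUE),
                 sample(c("_A", "_B"), n, replace = TRUE))
  ps <- labeled_point_set(pts, labs, nuc)
  for (mode in c("total", "inter", "intra", "homolog")) {
    for (radius in c(0.3, 1.0)) {
      expect_equal(cluster_counts(ps, radius, mode)$mean,
                   oracle_cluster_mean(pts, labs, radius, mode),
                   info = paste(mode, radius))
    }
  }
  # audit: total = inter + intra + homolog per object
  tot <- cluster_counts(ps, 0.8, "total")$counts
  parts <- cluster_counts(ps, 0.8, "inter")$counts +
    cluster_counts(ps, 0.8, "intra")$counts +
    cluster_counts(ps, 0.8, "homolog")$counts
  expect_equal(tot, parts)
})

test_that("cluster means and K are monotone in radius", {
  nuc <- fixture_nucleus()
  set.seed(13)
  ps <- labeled_point_set(sample_in_nucleus(500, nuc),
                          paste0("chr", rep(1:10, 50), "_A"), nuc)
  radii <- c(0.2, 0.5, 1, 2)
  m <- vapply(radii, function(r) cluster_counts(ps, r, "total")$mean,
              numeric(1))
  expect_true(all(diff(m) >= 0))
  k <- ripley_k(ps, radii)$K
  expect_true(all(diff(k) >= 0))
})

test_that("inter/intra ratio handles zero denominators as flagged, not errors", {
  nuc <- fixture_nucleus()
  mixed <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0)),
                             c("chr1_A", "chr1_A", "chr2_A"), nuc)
  rr <- inter_intra_ratio(mixed, 0.5)
  expect_false(rr$undefined)
  expect_equal(rr$ratio, rr$inter / rr$intra)
  only_intra <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                                  c("chr1_A", "chr1_A"), nuc)
  expect_equal(inter_intra_ratio(only_intra, 0.5)$ratio, 0)
  only_inter <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                                  c("chr1_A", "chr2_A"), nuc)
  rr3 <- inter_intra_ratio(only_inter, 0.5)
  expect_true(rr3$undefined)
  expect_true(is.na(rr3$ratio))
})

test_that("edge correction matches the lens formula limits and Monte Carlo", {
  nuc <- fixture_nucleus()
  expect_equal(edge_correction_vs(c(0, 0, 0), 1, nuc), 1)
  expect_equal(edge_correction_vs(c(5, 0, 0), 0.05, nuc), 0.5,
               tolerance = 1e-2)
  expect_error(edge_correction_vs(c(6, 0, 0), 1, nuc), "inside")
  # dual oracle: analytic lens vs 1e6-sample Monte Carlo on a grid
  set.seed(77)
  cloud <- matrix(stats::rnorm(3e6), 1e6, 3)
  cloud <- cloud / sqrt(rowSums(cloud^2)) * stats::runif(1e6)^(1 / 3)
  for (dc in c(2.5, 4, 4.9)) {
    for (cr in c(0.5, 1, 5)) {
      mc <- mean(nucleus_contains(
        sweep(cloud * cr, 2, c(dc, 0, 0), `+`), nuc))
      expect_equal(edge_correction_vs(c(dc, 0, 0), cr, nuc), mc,
                   tolerance = 2e-3, info = paste(dc, cr))
    }
  }
  # ellipsoid path is Monte-Carlo and seeded
  ell <- nucleus_shape(c(1, 11.8, 11.8))
  v1 <- edge_correction_vs(c(0.9, 0, 0), 0.3, ell, mc_seed = 5)
  expect_identical(v1, edge_correction_vs(c(0.9, 0, 0), 0.3, ell,
                                          mc_seed = 5))
  expect_true(v1 > 0.5 && v1 < 1)
})

test_that("ripley K reproduces the two-point oracle", {
  nuc <- fixture_nucleus()
  near <- labeled_point_set(rbind(c(0, 0, 0), c(0.1, 0, 0)),
                            c("a", "b"), nuc)
  expect_equal(ripley_k(near, 0.5)$K, nucleus_volume(nuc) / 2,
               tolerance = 1e-9)
  far <- labeled_point_set(rbind(c(0, 0, 0), c(2, 0, 0)), c("a", "b"), nuc)
  expect_equal(ripley_k(far, 0.5)$K, 0)
  expect_error(ripley_k(labeled_point_set(matrix(0, 1, 3), "a", nuc), 0.5),
               "at least 2")
})

test_that("CSR point patterns give a flat normalised ripley K near zero", {
  nuc <- fixture_nucleus()
  set.seed(101)
  pts <- sample_in_nucleus(3000, nuc)
  ps <- labeled_point_set(pts, rep("chr1_A", 3000), nuc)
  res <- ripley_k(ps, c(0.2, 0.6, 1.0))
  expect_true(all(abs(res$K_norm) < 0.05))
  # without edge correction K matches the exact CSR closed form
  # V * P(D <= r), i.e. (4/3) pi r^3 (1 - 9x/16 + x^3/32), x = r/R
  res_u <- ripley_k(ps, 0.5, edge_correct = FALSE)
  expected <- nucleus_volume(nuc) * csr_pair_probability(0.5, 5)
  expect_equal(res_u$K, expected, tolerance = 0.05)
})

test_that("radial positioning splits the nucleus into equal-volume halves", {
  nuc <- fixture_nucleus()
  specs <- bead_specs(rep("chr1_A", 3), c(0, 1e7, 2e7),
                      c(1e7, 2e7, 3e7), paste0("b", 1:3),
                      radius = 0.2)
  coords <- rbind(c(0, 0, 0), c(4.5, 0, 0), c(0, 3.9, 0))
  conf <- genome_conformation(specs, coords, nuc)
  rp <- radial_positioning(conf, bin_bp = 1e7)
  # threshold radius is 5 * 2^(-1/3) = 3.9685: bead2 peripheral, bead3 central
  expect_equal(rp$bins$central_frac, c(1, 0, 1))
  expect_equal(rp$periphery_pct, 100 / 3, tolerance = 1e-9)
  # uniform beads split 50/50 by bp weight
  n <- 10000
  big <- bead_specs(rep("chr1_A", n), seq(0, by = 1e5, length.out = n),
                    seq(1e5, by = 1e5, length.out = n), paste0("b", 1:n))
  big$radius <- assign_radii(big, nuc, 0.15)
  conf2 <- generate_pseudo_random(big, nuc, seed = 4)
  expect_equal(radial_positioning(conf2)$periphery_pct, 50, tolerance = 2)
})

test_that("chord adjacency thresholds the fraction of proximal geometries", {
  nuc <- fixture_nucleus()
  mk <- function(d_apart) {
    specs <- bead_specs(c("chr1_A", "chr2_A"), c(0, 0), c(1e6, 1e6),
                        c("a", "b"), radius = 0.1)
    genome_conformation(specs, rbind(c(0, 0, 0), c(d_apart, 0, 0)), nuc)
  }
  always <- replicate(5, mk(0.3), simplify = FALSE)
  expect_equal(nrow(chord_adjacency(always, threshold = 1)), 1)
  apart <- replicate(5, mk(0.6), simplify = FALSE)
  expect_equal(nrow(chord_adjacency(apart, threshold = 0.4)), 0)
  # proximal in 45% of geometries: included at 0.40, excluded at 0.50
  ens <- c(replicate(9, mk(0.3), simplify = FALSE),
           replicate(11, mk(0.6), simplify = FALSE))
  expect_equal(chord_adjacency(ens, threshold = 0.40)$fraction, 0.45)
  expect_equal(nrow(chord_adjacency(ens, threshold = 0.50)), 0)
  # homologous pairs are never reported
  specs <- bead_specs(c("chr1_A", "chr1_B"), c(0, 0), c(1e6, 1e6),
                      c("a", "b"), radius = 0.1)
  homs <- list(genome_conformation(specs, rbind(c(0, 0, 0), c(0.1, 0, 0)),
                                   nuc))
  expect_equal(nrow(chord_adjacency(homs, threshold = 0.4)), 0)
})

test_that("proximity score equals mean partner distance and flags no-constraint input", {
  nuc <- fixture_nucleus()
  specs <- bead_specs(c("chr1_A", "chr2_A"), c(0, 0), c(1e6, 1e6),
                      c("a", "b"), edges = list("b", "a"),
                      radius = c(0.5, 0.5))
  conf <- genome_conformation(specs, rbind(c(0, 0, 0), c(1, 0, 0)), nuc)
  ps <- proximity_score(conf)
  expect_equal(ps$score, 1.0)
  expect_false(ps$undefined)
  no_edges <- bead_specs("chr1_A", 0, 1e6, "a", radius = 0.5)
  conf2 <- genome_conformation(no_edges, matrix(0, 1, 3), nuc)
  expect_true(proximity_score(conf2)$undefined)
})
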