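test_that("energy ramp endpoints and midpoint follow the calibrated values", {
  expect_equal(energy_probability(5), 0)
  expect_equal(energy_probability(37.5), 1)
  expect_equal(energy_probability(21.25), 0.5)
  expect_equal(energy_probability(4), 0)
  expect_equal(energy_probability(100), 1)
  expect_error(energy_probability(-1), "> 0")
})

one_bead_conformation <- function(radius = 2) {
  specs <- bead_specs("chr1_A", 0, 1e6, "b1", radius = radius)
  genome_conformation(specs, matrix(0, 1, 3), fixture_nucleus())
}

uniform_deposits_in_bead <- function(n, radius, energy, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(3 * n), n, 3)
  z <- z / sqrt(rowSums(z^2)) * stats::runif(n)^(1 / 3) * radius
  data.frame(x = z[, 1], y = z[, 2], z = z[, 3], energy_ev = energy,
             track_id = seq_len(n))
}

test_that("deposit classification applies the geometric and sensitive-fraction filters", {
  conf <- one_bead_conformation()
  outside <- data.frame(x = 4, y = 0, z = 0, energy_ev = 100, track_id = 1)
  expect_equal(nrow(classify_deposits(outside, conf)), 0)
  low_e <- data.frame(x = 0, y = 0, z = 0, energy_ev = 4, track_id = 1)
  for (s in 1:20) {
    expect_equal(nrow(classify_deposits(low_e, conf, seed = s)), 0)
  }
  dep <- uniform_deposits_in_bead(1e5, 2, 100, seed = 6)
  br <- classify_deposits(dep, conf, seed = 7)
  expect_equal(nrow(br) / 1e5, 0.141, tolerance = 0.004 / 0.141)
  expect_true(all(br$strand %in% c(1, 2)))
  expect_equal(mean(br$strand == 1), 0.5, tolerance = 0.02)
  expect_true(all(br$bp >= 0 & br$bp < 1e6))
  expect_identical(br, classify_deposits(dep, conf, seed = 7))
  expect_error(classify_deposits(
    data.frame(x = 0, y = 0, z = 0, energy_ev = 0), conf), "> 0")
})

test_that("mid-ramp deposits are accepted at sensitive_fraction times ramp probability", {
  conf <- one_bead_conformation()
  dep <- uniform_deposits_in_bead(1e5, 2, 21.25, seed = 8)
  br <- classify_deposits(dep, conf, seed = 9)
  expect_equal(nrow(br) / 1e5, 0.141 * 0.5, tolerance = 0.1)
})

# breaks with 3D positions consistent with the double helix:
# 0.34 nm per bp along x
mkbreaks <- function(bp, strand, chrom = "chr1_A") {
  data.frame(chrom = chrom, strand = as.integer(strand), bp = bp,
             x = bp * 0.34e-3, y = 0, z = 0, origin = "particle",
             stringsAsFactors = FALSE)
}

test_that("break clustering applies the 10 bp opposite-strand window", {
  s1 <- cluster_breaks(mkbreaks(c(100, 108), c(1, 2)))
  expect_equal(s1$kind, "DSB")
  expect_equal(s1$complexity, 2)
  s2 <- cluster_breaks(mkbreaks(c(100, 111), c(1, 2)))
  expect_equal(s2$kind, c("SSB", "SSB"))
  s3 <- cluster_breaks(mkbreaks(c(100, 105, 109), c(1, 2, 1)))
  expect_equal(s3$kind, "DSB")
  expect_equal(s3$complexity, 3)
  # same-strand chains never form a DSB
  s4 <- cluster_breaks(mkbreaks(c(100, 105), c(1, 1)))
  expect_equal(s4$kind, c("SSB", "SSB"))
  # exact window sweep: merge iff separation <= 10
  for (k in 1:15) {
    s <- cluster_breaks(mkbreaks(c(100, 100 + k), c(1, 2)))
    if (k <= 10) {
      expect_equal(sum(s$kind == "DSB"), 1, info = k)
    } else {
      expect_equal(sum(s$kind == "DSB"), 0, info = k)
    }
  }
})

test_that("spatially coincident breaks cluster even when bp positions are far", {
  # same chromosome, 3 kbp apart genomically, 1 nm apart in space
  br <- data.frame(chrom = "chr1_A", strand = c(1L, 2L),
                   bp = c(1000, 4000), x = c(0, 0.001), y = 0, z = 0)
  s <- cluster_breaks(br)
  expect_equal(s$kind, "DSB")
  expect_equal(s$complexity, 2)
  # 5 nm apart in space and far in bp: two SSBs
  br2 <- transform(br, x = c(0, 0.005))
  expect_equal(cluster_breaks(br2)$kind, c("SSB", "SSB"))
  # spatial window never reaches across chromosomes
  br3 <- transform(br, chrom = c("chr1_A", "chr2_A"))
  expect_equal(cluster_breaks(br3)$kind, c("SSB", "SSB"))
})

test_that("break clustering partitions breaks, dedups, and is order-invariant", {
  set.seed(20)
  n <- 300
  br <- mkbreaks(sample(1:2000, n, replace = TRUE),
                 sample(1:2, n, replace = TRUE),
                 chrom = sample(c("chr1_A", "chr1_B", "chr2_A"), n,
                                replace = TRUE))
  dedup <- br[!duplicated(br[c("chrom", "strand", "bp")]), ]
  sites <- cluster_breaks(br)
  expect_equal(sum(sites$complexity), nrow(dedup))
  shuffled <- br[sample(nrow(br)), ]
  sites2 <- cluster_breaks(shuffled)
  expect_equal(sites[order(sites$chrom, sites$bp, sites$kind), ],
               sites2[order(sites2$chrom, sites2$bp, sites2$kind), ],
               ignore_attr = TRUE)
  # breaks on different chromosomes never merge
  twoc <- rbind(mkbreaks(100, 1, "chr1_A"), mkbreaks(105, 2, "chr2_A"))
  expect_equal(cluster_breaks(twoc)$kind, c("SSB", "SSB"))
  # homolog copies are distinct chromosomes for clustering
  hom <- rbind(mkbreaks(100, 1, "chr1_A"), mkbreaks(105, 2, "chr1_B"))
  expect_equal(cluster_breaks(hom)$kind, c("SSB", "SSB"))
})

test_that("photon exposures follow the 25 DSB/Gy poisson model", {
  specs <- fixture_specs()
  conf <- generate_pseudo_random(specs, fixture_nucleus(), seed = 2)
  expect_equal(nrow(photon_exposure(conf, 0, seed = 1)), 0)
  counts <- vapply(1:200, function(s) {
    nrow(photon_exposure(conf, 1, seed = s))
  }, numeric(1))
  expect_equal(mean(counts), 25, tolerance = 1 / 25)
  expect_gt(stats::var(counts) / mean(counts), 0.75)
  expect_lt(stats::var(counts) / mean(counts), 1.25)
  sites <- photon_exposure(conf, 5, seed = 3)
  expect_true(all(sites$kind == "DSB"))
  expect_true(all(sites$complexity == 2))
  # sites sit inside their host bead and inside the chromosome intervals
  expect_true(all(sites$bp >= 0))
})

test_that("photon DSBs land on chromosomes proportionally to their bp", {
  nuc <- fixture_nucleus()
  specs <- bead_specs(c("chr1_A", "chr2_A"), c(0, 0), c(1e8, 9e8),
                      c("a", "b"))
  specs$radius <- assign_radii(specs, nuc, 0.15)
  conf <- generate_pseudo_random(specs, nuc, seed = 1)
  sites <- do.call(rbind, lapply(1:400, function(s) {
    photon_exposure(conf, 1, seed = s)
  }))
  expect_gt(nrow(sites), 9000)
  expect_equal(mean(sites$chrom == "chr1_A"), 0.1, tolerance = 0.1)
})

test_that("damage yields divide by dose and flag the no-DSB case", {
  sites <- data.frame(kind = c(rep("DSB", 50), rep("SSB", 10)),
                      chrom = "chr1_A", bp = 1, x = 0, y = 0, z = 0,
                      complexity = c(rep(2L, 50), rep(1L, 10)))
  y <- damage_yields(sites, 2)
  expect_equal(y$dsb_per_gy, 25)
  expect_equal(y$ssb_per_gy, 5)
  expect_equal(y$backbones_per_dsb, 2)
  ssb_only <- sites[sites$kind == "SSB", ]
  y2 <- damage_yields(ssb_only, 1)
  expect_true(y2$undefined)
  expect_true(is.na(y2$backbones_per_dsb))
  expect_error(damage_yields(sites, 0), "dose")
  y3 <- damage_yields(cluster_breaks(mkbreaks(c(100, 105, 109),
                                              c(1, 2, 1))), 1)
  expect_equal(y3$backbones_per_dsb, 3)
})

test_that("SDD files round-trip sites exactly", {
  specs <- fixture_specs()
  conf <- generate_pseudo_random(specs, fixture_nucleus(), seed = 2)
  sites <- photon_exposure(conf, 4, seed = 5)
  expect_gt(nrow(sites), 50)
  path <- withr::local_tempfile(fileext = ".sdd")
  write_sdd(sites, path, header = list(
    "Dose or fluence" = c(1, 4),
    "Chromosome sizes" = c(2, 100, 200)))
  back <- read_sdd(path)
  expect_equal(back$sites, sites, ignore_attr = TRUE)
  expect_equal(back$header[["SDD version"]], "1.0")
  expect_equal(back$header[["Dose or fluence"]], c("1", "4"))
  # empty site list -> header-only file
  write_sdd(empty <- sites[0, ], path)
  expect_equal(nrow(read_sdd(path)$sites), 0)
})

test_that("deposit TSV round-trips and validates its columns", {
  dep <- uniform_deposits_in_bead(50, 1, 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_deposits_tsv(dep, path)
  back <- read_deposits_tsv(path)
  expect_equal(back, dep, tolerance = 1e-12)
  writeLines("x\ty\tz\n0\t0\t0", path)
  expect_error(read_deposits_tsv(path), "energy_ev")
})
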