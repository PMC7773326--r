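# Shared fixture builders; everything is generated in code.

fixture_nucleus <- function() nucleus_shape(5)

# small diploid genome: 10 chromosomes (5 x 2 homologs), ~200 beads
fixture_specs <- function(seed = 2, contacts_per_bead = 1) {
  cfg <- synth_config(n_chrom = 5, genome_bp = 6e8, diploid = TRUE,
                      tad_mean_bp = 3e6,
                      contacts_per_bead = contacts_per_bead)
  specs <- synthesize_genome(cfg, seed = seed)
  specs$radius <- assign_radii(specs, fixture_nucleus(), 0.15)
  specs
}

fixture_conformation <- function(seed = 3, specs = fixture_specs()) {
  build_initial_conformation(specs, fixture_nucleus(), seed = seed)
}

# hand-built two-bead gtrack content used by the I/O tests
fixture_two_bead_gtrack <- function(path) {
  writeLines(c(
    "##gtrack version: 1.0",
    "###seqid\tstart\tend\tid\tradius\tperiphery\tedges",
    "chr1_A\t0\t1000000\tb1\t.\t.\tb2",
    "chr2_A\t0\t1000000\tb2\t.\t1\tb1"), path)
  path
}

# brute-force O(n^2) clustering oracle (independent of the package path)
oracle_cluster_mean <- function(points, labels, radius, mode) {
  n <- nrow(points)
  keys <- sub("_[AB]$", "", labels)
  counts <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d > radius) next
      hit <- switch(mode,
        total = TRUE,
        inter = keys[i] != keys[j],
        intra = labels[i] == labels[j],
        homolog = keys[i] == keys[j] && labels[i] != labels[j])
      if (hit) counts[i] <- counts[i] + 1
    }
  }
  mean(counts)
}

# LET-trend study: 10 LET points x 10 exposures of 20 Gy on a
# territorial (chain-random-walk) conformation; computed once and
# cached because two acceptance properties read it
.trend_cache <- new.env(parent = emptyenv())
let_trend_data <- function() {
  if (!is.null(.trend_cache$res)) return(.trend_cache$res)
  nuc <- fixture_nucleus()
  specs <- fixture_specs(seed = 2)
  conf <- build_initial_conformation(specs, nuc, seed = 3)
  lets <- c(5, 8, 12, 18, 25, 35, 50, 65, 80, 100)
  out <- data.frame(let = lets, dsb_frac = NA_real_, ssb_frac = NA_real_,
                    breaks_per_gy = NA_real_, inter = NA_real_,
                    intra = NA_real_, ratio = NA_real_)
  for (i in seq_along(lets)) {
    n_dsb <- n_ssb <- n_breaks <- dose <- 0
    pool <- vector("list", 10)
    for (r in 1:10) {
      s <- track_exposure(conf, 20, track_config(let = lets[i]),
                          seed = 1000 * i + r)
      n_dsb <- n_dsb + sum(s$kind == "DSB")
      n_ssb <- n_ssb + sum(s$kind == "SSB")
      n_breaks <- n_breaks + sum(s$complexity)
      dose <- dose + attr(s, "realized_dose_gy")
      pool[[r]] <- s[s$kind == "DSB", , drop = FALSE]
    }
    out$dsb_frac[i] <- n_dsb / n_breaks
    out$ssb_frac[i] <- n_ssb / n_breaks
    out$breaks_per_gy[i] <- n_breaks / dose
    dall <- do.call(rbind, pool)
    rr <- inter_intra_ratio(
      suppressWarnings(as_point_set(dall, nuc)), 0.5)
    out$inter[i] <- rr$inter
    out$intra[i] <- rr$intra
    out$ratio[i] <- rr$ratio
  }
  .trend_cache$res <- out
  out
}

# closed-form P(D <= r) for two uniform points in a sphere of radius R
csr_pair_probability <- function(r, R) {
  x <- r / R
  x^3 - (9 / 16) * x^4 + (1 / 32) * x^6
}
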