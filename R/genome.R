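#' Assign bead radii from a nuclear occupancy fraction
#'
#' Bead volumes are proportional to genomic content, and the total bead
#' volume equals `occupancy` times the nuclear volume: r_i^3 is
#' proportional to (end_i - start_i) with
#' sum (4/3) pi r_i^3 = occupancy * V_nucleus.
#'
#' @param specs A [bead_specs()] table.
#' @param nucleus A [nucleus_shape()].
#' @param occupancy Fraction of the nuclear volume occupied by beads,
#'   in (0, 1). The study default is 0.15.
#' @return Numeric vector of radii in micrometres.
#' @examples
#' s <- bead_specs("chr1_A", 0, 1e6, "b1")
#' assign_radii(s, nucleus_shape(5), 0.15)  # 5 * 0.15^(1/3)
#' @export
assign_radii <- function(specs, nucleus, occupancy = 0.15) {
  specs <- validate_bead_specs(specs)
  if (!is.numeric(occupancy) || occupancy <= 0 || occupancy >= 1) {
    stop("occupancy must be in (0, 1)")
  }
  bp <- specs$end - specs$start
  total_bp <- sum(bp)
  if (total_bp <= 0) stop("zero-length genome")
  v_total <- occupancy * nucleus_volume(nucleus)
  (v_total * bp / total_bp * 3 / (4 * pi))^(1 / 3)
}

#' Construct a genome conformation object
#'
#' The solver's state: positioned beads grouped into ordered per-chromosome
#' chains inside a nucleus.
#'
#' @param specs A [bead_specs()] table with a `radius` column (no `NA`).
#' @param coords Numeric matrix `nrow(specs)` x 3 of bead centres (um).
#' @param nucleus A [nucleus_shape()].
#' @param occupancy Occupancy fraction recorded on the object (computed
#'   from the radii when `NULL`).
#' @param seed The seed the conformation was built with (bookkeeping).
#' @return An object of class `genome_conformation`: list with `specs`,
#'   `coords`, `nucleus`, `occupancy`, `seed`, and `chains` (a named list
#'   of row indices per chromosome, ordered by `start`).
#' @export
genome_conformation <- function(specs, coords, nucleus, occupancy = NULL,
                                seed = NA_integer_) {
  specs <- validate_bead_specs(specs)
  coords <- coords_matrix(coords)
  stopifnot(nrow(coords) == nrow(specs))
  if (any(is.na(specs$radius))) stop("all beads must have a radius")
  chains <- split(seq_len(nrow(specs)), specs$chrom)
  chains <- chains[unique(specs$chrom)]            # keep file order
  chains <- lapply(chains, function(i) i[order(specs$start[i])])
  if (is.null(occupancy)) {
    occupancy <- sum((4 / 3) * pi * specs$radius^3) / nucleus_volume(nucleus)
  }
  structure(list(specs = specs, coords = coords, nucleus = nucleus,
                 occupancy = occupancy, seed = seed, chains = chains),
            class = "genome_conformation")
}

#' @export
print.genome_conformation <- function(x, ...) {
  cat(sprintf(
    "<genome_conformation: %d beads, %d chromosomes, %.3g bp, occupancy %.3f>\n",
    nrow(x$specs), length(x$chains), sum(x$specs$end - x$specs$start),
    x$occupancy))
  print(x$nucleus)
  invisible(x)
}

#' Build an initial conformation by per-chromosome random walks
#'
#' Each chain is grown as a random walk of touching beads (consecutive
#' centre distance exactly r_i + r_{i+1}); every centre must fall inside
#' the nucleus, with up to `max_retries` direction redraws per bead.
#' Overlap with non-adjacent beads is tolerated at initialisation and
#' penalised later by the solver. Deterministic given `seed`.
#'
#' @param specs A [bead_specs()] table; radii taken from its `radius`
#'   column, or assigned via [assign_radii()] when absent.
#' @param nucleus A [nucleus_shape()].
#' @param seed Integer seed.
#' @param occupancy Occupancy used when radii must be assigned.
#' @param max_retries Direction redraws allowed per bead before failing.
#' @return A [genome_conformation()].
#' @export
build_initial_conformation <- function(specs, nucleus, seed = 1L,
                                       occupancy = 0.15,
                                       max_retries = 1000L) {
  specs <- validate_bead_specs(specs)
  if (any(is.na(specs$radius))) {
    specs$radius <- assign_radii(specs, nucleus, occupancy)
  }
  set.seed(seed)
  coords <- matrix(NA_real_, nrow(specs), 3)
  chains <- split(seq_len(nrow(specs)), specs$chrom)[unique(specs$chrom)]
  chains <- lapply(chains, function(i) i[order(specs$start[i])])
  for (idx in chains) {
    r <- specs$radius[idx]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      p <- sample_in_nucleus(1, nucleus)
      if (nucleus_contains(p, nucleus)) { placed <- TRUE; break }
    }
    if (!placed) stop("placement error: could not seed chain inside nucleus")
    coords[idx[1], ] <- p
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        step <- r[k - 1] + r[k]
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          dir <- stats::rnorm(3)
          cand <- coords[idx[k - 1], ] + step * dir / sqrt(sum(dir^2))
          if (nucleus_contains(cand, nucleus)) { ok <- TRUE; break }
        }
        if (!ok) {
          stop("placement error: nucleus too small to host chain '",
               specs$chrom[idx[1]], "'")
        }
        coords[idx[k], ] <- cand
      }
    }
  }
  genome_conformation(specs, coords, nucleus, seed = seed)
}

#' Pseudo-random reference conformation
#'
#' Places every bead centre independently and uniformly in the nuclear
#' volume, ignoring chain adjacency and all constraints. This is the
#' unstructured reference geometry: it has no chromosome territories and
#' its normalised Ripley-K is zero at all radii in expectation.
#'
#' @inheritParams build_initial_conformation
#' @return A [genome_conformation()].
#' @export
generate_pseudo_random <- function(specs, nucleus, seed = 1L,
                                   occupancy = 0.15) {
  specs <- validate_bead_specs(specs)
  if (any(is.na(specs$radius))) {
    specs$radius <- assign_radii(specs, nucleus, occupancy)
  }
  set.seed(seed)
  coords <- sample_in_nucleus(nrow(specs), nucleus)
  genome_conformation(specs, coords, nucleus, seed = seed)
}

#' Synthetic genome configuration
#'
#' Defaults emulate a diploid human-like genome: 6 Gbp over 46
#' chromosomes (23 haploid chromosomes duplicated with `"_A"`/`"_B"`
#' suffixes and independent contact edges), segmented into TAD beads of
#' 1 Mbp mean size, with 0.5 contact edges per bead (80 percent
#' intra-chromosomal) and 30 percent of beads lamina-flagged.
#'
#' @param n_chrom Haploid chromosome count.
#' @param genome_bp Total genome size in bp (across both homolog sets
#'   when `diploid`).
#' @param diploid Duplicate each chromosome as `"_A"`/`"_B"`?
#' @param tad_mean_bp Mean TAD (bead) size in bp.
#' @param tad_cv Coefficient of variation of TAD sizes (lognormal).
#' @param contacts_per_bead Expected number of contact edges per bead.
#' @param intra_fraction Fraction of edges drawn intra-chromosomally.
#' @param periphery_fraction Fraction of beads flagged as
#'   lamina-associated.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chrom = 23L, genome_bp = 6e9, diploid = TRUE,
                         tad_mean_bp = 1e6, tad_cv = 0.5,
                         contacts_per_bead = 0.5, intra_fraction = 0.8,
                         periphery_fraction = 0.3) {
  cfg <- list(n_chrom = as.integer(n_chrom), genome_bp = genome_bp,
              diploid = isTRUE(diploid), tad_mean_bp = tad_mean_bp,
              tad_cv = tad_cv, contacts_per_bead = contacts_per_bead,
              intra_fraction = intra_fraction,
              periphery_fraction = periphery_fraction)
  if (cfg$n_chrom < 1) stop("n_chrom must be >= 1")
  hap_bp <- cfg$genome_bp / (if (cfg$diploid) 2 else 1)
  if (hap_bp < cfg$n_chrom) stop("genome_bp too small for n_chrom")
  if (cfg$tad_mean_bp <= 0) stop("tad_mean_bp must be > 0")
  if (cfg$periphery_fraction < 0 || cfg$periphery_fraction > 1) {
    stop("periphery_fraction must be in [0, 1]")
  }
  class(cfg) <- "synth_config"
  cfg
}

# split `total` into n positive integers with given proportions
integer_partition <- function(total, weights) {
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  out <- pmax(out, 1)
  rem <- total - sum(out)
  if (rem > 0) {
    i <- order(raw - floor(raw), decreasing = TRUE)
    add <- rep_len(i, rem)
    tab <- tabulate(add, nbins = length(out))
    out <- out + tab
  } else if (rem < 0) {
    i <- order(out, decreasing = TRUE)
    k <- 1
    while (rem < 0) {
      if (out[i[k]] > 1) { out[i[k]] <- out[i[k]] - 1; rem <- rem + 1 }
      k <- if (k == length(i)) 1 else k + 1
    }
  }
  out
}

#' Generate a synthetic TAD-bead genome
#'
#' Produces a gtrack-ready bead table emulating Hi-C-derived solver
#' input: chromosome sizes decrease roughly like human chromosomes,
#' TAD sizes are lognormal, contact edges mix short-range
#' intra-chromosomal with random inter-chromosomal pairs, and periphery
#' flags are i.i.d. Bernoulli. In diploid mode each chromosome is
#' duplicated as `"_A"`/`"_B"` with independently drawn edges.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A [bead_specs()] table (radius column left `NA`).
#' @export
synthesize_genome <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n_sets <- if (config$diploid) 2L else 1L
  hap_bp <- round(config$genome_bp / n_sets)
  # human-like decreasing size profile
  w <- (config$n_chrom:1)^0.7
  chrom_bp <- integer_partition(hap_bp, w)
  chrom_names <- if (config$n_chrom == 23L) {
    c(paste0("chr", 1:22), "chrX")
  } else {
    paste0("chr", seq_len(config$n_chrom))
  }
  suffixes <- if (config$diploid) c("_A", "_B") else ""
  sdlog <- sqrt(log(1 + config$tad_cv^2))
  # one TAD partition per haploid chromosome, shared by both homologs
  partitions <- lapply(seq_len(config$n_chrom), function(c_i) {
    bp <- chrom_bp[c_i]
    n_tad <- max(1L, round(bp / config$tad_mean_bp))
    sizes <- stats::rlnorm(n_tad, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    tad_bp <- integer_partition(bp, sizes)
    ends <- cumsum(tad_bp)
    list(start = c(0, ends[-n_tad]), end = ends)
  })
  chrom <- character(0); start <- numeric(0); end <- numeric(0)
  bead_id <- character(0); periphery <- logical(0)
  for (set_i in seq_len(n_sets)) {
    for (c_i in seq_len(config$n_chrom)) {
      lab <- paste0(chrom_names[c_i], suffixes[set_i])
      part <- partitions[[c_i]]
      n_tad <- length(part$end)
      chrom <- c(chrom, rep(lab, n_tad))
      start <- c(start, part$start)
      end <- c(end, part$end)
      bead_id <- c(bead_id, paste0(lab, ".", seq_len(n_tad)))
      periphery <- c(periphery,
                     stats::runif(n_tad) < config$periphery_fraction)
    }
  }
  specs <- bead_specs(chrom, start, end, bead_id, periphery)
  n <- nrow(specs)
  n_edges <- round(config$contacts_per_bead * n)
  if (n_edges > 0 && n > 1) {
    edges <- specs$edges
    chain_idx <- split(seq_len(n), specs$chrom)
    labs <- names(chain_idx)
    for (k in seq_len(n_edges)) {
      if (stats::runif(1) < config$intra_fraction) {
        ci <- chain_idx[[sample(length(chain_idx), 1)]]
        if (length(ci) < 2) next
        i <- sample(length(ci), 1)
        span <- 1 + stats::rgeom(1, prob = 0.3)
        j <- i + sample(c(-1, 1), 1) * span
        if (j < 1 || j > length(ci)) next
        a <- ci[i]; b <- ci[j]
      } else {
        ab <- sample(n, 2)
        a <- ab[1]; b <- ab[2]
        if (specs$chrom[a] == specs$chrom[b]) next
      }
      edges[[a]] <- c(edges[[a]], specs$bead_id[b])
      edges[[b]] <- c(edges[[b]], specs$bead_id[a])
    }
    specs$edges <- edges
    specs <- validate_bead_specs(specs)
  }
  specs
}

#' Export a conformation as a Chimera marker (CMM) file
#'
#' Writes an XML `<marker_set>` with one `<marker>` per bead carrying
#' id, x/y/z centre (um), radius, and a per-chromosome RGB colour.
#'
#' @param conformation A [genome_conformation()].
#' @param path Output path.
#' @param name Marker-set name attribute.
#' @return `path`, invisibly.
#' @export
write_cmm <- function(conformation, path, name = "genome") {
  stopifnot(inherits(conformation, "genome_conformation"))
  specs <- conformation$specs
  coords <- conformation$coords
  labs <- unique(specs$chrom)
  cols <- grDevices::col2rgb(grDevices::rainbow(length(labs))) / 255
  col_i <- match(specs$chrom, labs)
  doc <- xml2::xml_new_root("marker_set", name = name)
  num <- function(x) trimws(formatC(x, format = "g", digits = 10))
  for (i in seq_len(nrow(specs))) {
    xml2::xml_add_child(doc, "marker",
                        id = as.character(i),
                        x = num(coords[i, 1]), y = num(coords[i, 2]),
                        z = num(coords[i, 3]),
                        radius = num(specs$radius[i]),
                        r = num(cols[1, col_i[i]]),
                        g = num(cols[2, col_i[i]]),
                        b = num(cols[3, col_i[i]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
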