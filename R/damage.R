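#' Damage-model parameters
#'
#' Defaults are the study's calibrated values: a 14.1 percent sensitive
#' fraction of each bead, a linear energy-acceptance ramp from 0 at
#' 5 eV to 1 at 37.5 eV, a 10 bp (3.2 nm) opposite-strand window for
#' DSB formation, and a photon induction rate of 25 DSB/Gy.
#'
#' @param sensitive_fraction Probability that an in-bead deposit falls
#'   in the damage-sensitive sub-volume.
#' @param e_zero Energy (eV) at and below which acceptance is 0.
#' @param e_one Energy (eV) at and above which acceptance is 1.
#' @param dsb_bp_window Maximum bp separation merging opposite-strand
#'   breaks into one DSB.
#' @param dsb_spatial_nm Equivalent spatial separation (3.2 nm, the
#'   double-helix extent of 10 bp) merging breaks whose recorded 3D
#'   positions are that close.
#' @param photon_dsb_per_gy Poisson mean DSB count per Gy of photons.
#' @return A list of class `damage_params`.
#' @export
damage_params <- function(sensitive_fraction = 0.141, e_zero = 5,
                          e_one = 37.5, dsb_bp_window = 10,
                          dsb_spatial_nm = 3.2, photon_dsb_per_gy = 25) {
  stopifnot(sensitive_fraction > 0, sensitive_fraction < 1,
            e_one > e_zero, dsb_bp_window > 0, dsb_spatial_nm >= 0,
            photon_dsb_per_gy >= 0)
  structure(list(sensitive_fraction = sensitive_fraction, e_zero = e_zero,
                 e_one = e_one, dsb_bp_window = dsb_bp_window,
                 dsb_spatial_nm = dsb_spatial_nm,
                 photon_dsb_per_gy = photon_dsb_per_gy),
            class = "damage_params")
}

#' Strand-break acceptance probability of a deposit energy
#'
#' Linear ramp clamped to \[0, 1\]: 0 at or below `e_zero` (5 eV), 1 at
#' or above `e_one` (37.5 eV).
#'
#' @param energy_ev Deposit energies in eV (> 0).
#' @param params A [damage_params()].
#' @return Probabilities in \[0, 1\].
#' @export
energy_probability <- function(energy_ev, params = damage_params()) {
  if (any(energy_ev <= 0)) stop("deposit energy must be > 0")
  pmin(1, pmax(0, (energy_ev - params$e_zero) /
                 (params$e_one - params$e_zero)))
}

empty_breaks <- function() {
  data.frame(chrom = character(0), strand = integer(0), bp = numeric(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             origin = character(0), stringsAsFactors = FALSE)
}

#' Classify energy deposits into strand breaks
#'
#' Deposits outside every bead are discarded. In-bead deposits pass a
#' Bernoulli(`sensitive_fraction`) draw and then an energy-ramp draw
#' ([energy_probability()]). Survivors become strand breaks: strand 1
#' or 2 with equal probability, genomic position uniform in the host
#' bead's interval, chromosome inherited from the bead. A deposit
#' inside several overlapping beads is attributed to the bead of
#' deepest relative containment (smallest distance/radius).
#'
#' @param deposits A `data.frame` with columns `x`, `y`, `z` (um),
#'   `energy_ev`, and optionally `track_id`.
#' @param conformation A [genome_conformation()].
#' @param params A [damage_params()].
#' @param seed Integer seed.
#' @return A `data.frame` of breaks: `chrom`, `strand` (1/2), `bp`,
#'   `x`, `y`, `z`, `origin = "particle"`.
#' @export
classify_deposits <- function(deposits, conformation,
                              params = damage_params(), seed = 1L) {
  stopifnot(inherits(conformation, "genome_conformation"),
            all(c("x", "y", "z", "energy_ev") %in% names(deposits)))
  if (any(deposits$energy_ev <= 0)) stop("deposit energy must be > 0")
  set.seed(seed)
  if (!nrow(deposits)) return(empty_breaks())
  beads <- conformation$coords
  radii <- conformation$specs$radius
  # host bead: deepest relative containment (0 = outside every bead)
  host <- .host_bead_cpp(deposits$x, deposits$y, deposits$z, beads, radii)
  idx <- which(host > 0)
  if (!length(idx)) return(empty_breaks())
  # sensitive-fraction draw, then energy-ramp draw
  idx <- idx[stats::runif(length(idx)) < params$sensitive_fraction]
  if (length(idx)) {
    p <- energy_probability(deposits$energy_ev[idx], params)
    idx <- idx[stats::runif(length(idx)) < p]
  }
  if (!length(idx)) return(empty_breaks())
  b <- host[idx]
  specs <- conformation$specs
  span <- specs$end[b] - specs$start[b]
  data.frame(chrom = specs$chrom[b],
             strand = sample(1:2, length(idx), replace = TRUE),
             bp = floor(specs$start[b] + stats::runif(length(idx)) * span),
             x = deposits$x[idx], y = deposits$y[idx], z = deposits$z[idx],
             origin = "particle", stringsAsFactors = FALSE)
}

# transitive components over sorted breaks: consecutive genomic gaps
# <= bp_window within a chromosome, plus per-chromosome spatial pairs
# <= spatial_um; returns component ids in first-occurrence order
cluster_components <- function(breaks, bp_window, spatial_um) {
  n <- nrow(breaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
    invisible(NULL)
  }
  if (n > 1) {
    link <- breaks$chrom[-1] == breaks$chrom[-n] &
      diff(breaks$bp) <= bp_window
    for (i in which(link)) union2(i, i + 1L)
    if (spatial_um > 0) {
      for (ch in unique(breaks$chrom)) {
        rows <- which(breaks$chrom == ch)
        k <- length(rows)
        if (k < 2) next
        d <- as.matrix(stats::dist(cbind(breaks$x[rows], breaks$y[rows],
                                         breaks$z[rows])))
        hits <- which(d <= spatial_um & upper.tri(d), arr.ind = TRUE)
        for (h in seq_len(nrow(hits))) {
          union2(rows[hits[h, 1]], rows[hits[h, 2]])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

empty_sites <- function() {
  data.frame(kind = character(0), chrom = character(0), bp = numeric(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             complexity = integer(0), stringsAsFactors = FALSE)
}

#' Cluster strand breaks into DSB and SSB damage sites
#'
#' Per chromosome, breaks are chained transitively: two breaks link
#' when they are within the genomic window (10 bp) *or* their recorded
#' 3D positions are within the equivalent spatial window (3.2 nm). A
#' chain containing both strands becomes one DSB whose complexity
#' (backbone count) is the number of member breaks; every other break
#' is a singleton SSB. Duplicate breaks at identical (chrom, strand,
#' bp) are merged first, and the result is invariant to input ordering
#' (breaks are sorted on chrom, bp, strand).
#'
#' @param breaks A break table from [classify_deposits()].
#' @param params A [damage_params()].
#' @return A `data.frame` of damage sites: `kind` ("DSB"/"SSB"),
#'   `chrom`, `bp` (rounded mean of member positions), centroid `x`,
#'   `y`, `z`, and `complexity`.
#' @export
cluster_breaks <- function(breaks, params = damage_params()) {
  if (is.null(breaks) || !nrow(breaks)) return(empty_sites())
  stopifnot(all(c("chrom", "strand", "bp") %in% names(breaks)))
  if (!all(breaks$strand %in% c(1L, 2L))) stop("strand must be 1 or 2")
  breaks <- breaks[!duplicated(breaks[c("chrom", "strand", "bp")]), ,
                   drop = FALSE]
  breaks <- breaks[order(breaks$chrom, breaks$bp, breaks$strand), ,
                   drop = FALSE]
  w <- params$dsb_bp_window
  if (is.null(breaks$x)) breaks$x <- 0
  if (is.null(breaks$y)) breaks$y <- 0
  if (is.null(breaks$z)) breaks$z <- 0
  comp <- cluster_components(breaks, w, params$dsb_spatial_nm / 1000)
  size <- as.vector(rowsum(rep(1, nrow(breaks)), comp))
  has1 <- as.vector(rowsum(as.numeric(breaks$strand == 1L), comp)) > 0
  has2 <- as.vector(rowsum(as.numeric(breaks$strand == 2L), comp)) > 0
  is_dsb <- has1 & has2
  first <- !duplicated(comp)
  dsb_rows <- is_dsb[comp]
  dsb <- if (any(is_dsb)) {
    data.frame(
      kind = "DSB", chrom = breaks$chrom[first][is_dsb],
      bp = round(as.vector(rowsum(breaks$bp, comp))[is_dsb] /
                   size[is_dsb]),
      x = as.vector(rowsum(breaks$x, comp))[is_dsb] / size[is_dsb],
      y = as.vector(rowsum(breaks$y, comp))[is_dsb] / size[is_dsb],
      z = as.vector(rowsum(breaks$z, comp))[is_dsb] / size[is_dsb],
      complexity = as.integer(size[is_dsb]), stringsAsFactors = FALSE)
  } else empty_sites()
  ssb <- if (any(!dsb_rows)) {
    data.frame(
      kind = "SSB", chrom = breaks$chrom[!dsb_rows],
      bp = breaks$bp[!dsb_rows], x = breaks$x[!dsb_rows],
      y = breaks$y[!dsb_rows], z = breaks$z[!dsb_rows],
      complexity = 1L, stringsAsFactors = FALSE)
  } else empty_sites()
  sites <- rbind(dsb, ssb)
  sites <- sites[order(sites$chrom, sites$bp, sites$kind), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Simulate a photon exposure
#'
#' DSB induction under photons follows a Poisson law with mean
#' `photon_dsb_per_gy * dose_gy` (25 DSB/Gy by default). Each DSB picks
#' a chromosome with probability proportional to its bp content, a bead
#' within the chromosome proportional to bead bp, a uniform position
#' inside the bead sphere, and a uniform genomic position in the bead's
#' interval; it is emitted directly as one DSB site of complexity 2
#' (two opposite-strand breaks at the sampled bp).
#'
#' @param conformation A [genome_conformation()].
#' @param dose_gy Absorbed dose in Gy (>= 0).
#' @param params A [damage_params()].
#' @param seed Integer seed.
#' @return A damage-site `data.frame` as from [cluster_breaks()].
#' @export
photon_exposure <- function(conformation, dose_gy,
                            params = damage_params(), seed = 1L) {
  stopifnot(inherits(conformation, "genome_conformation"))
  if (dose_gy < 0) stop("dose must be >= 0")
  set.seed(seed)
  n <- stats::rpois(1, params$photon_dsb_per_gy * dose_gy)
  if (n == 0) return(empty_sites())
  specs <- conformation$specs
  bp <- specs$end - specs$start
  chrom_bp <- tapply(bp, specs$chrom, sum)
  chroms <- sample(names(chrom_bp), n, replace = TRUE,
                   prob = as.numeric(chrom_bp))
  bead_i <- integer(n)
  for (ch in unique(chroms)) {
    rows <- which(specs$chrom == ch)
    k <- which(chroms == ch)
    bead_i[k] <- if (length(rows) == 1) rows else
      sample(rows, length(k), replace = TRUE, prob = bp[rows])
  }
  # uniform point inside each host bead sphere
  z <- matrix(stats::rnorm(3 * n), n, 3)
  z <- z / sqrt(rowSums(z^2)) * stats::runif(n)^(1 / 3) *
    specs$radius[bead_i]
  pos <- conformation$coords[bead_i, , drop = FALSE] + z
  bp_pos <- floor(specs$start[bead_i] +
                    stats::runif(n) * (specs$end[bead_i] -
                                         specs$start[bead_i]))
  data.frame(kind = "DSB", chrom = specs$chrom[bead_i], bp = bp_pos,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             complexity = 2L, stringsAsFactors = FALSE)
}

#' Damage yields per unit dose
#'
#' @param sites A damage-site table.
#' @param dose_gy Dose in Gy (> 0).
#' @return A list with `dsb_per_gy`, `ssb_per_gy`, and
#'   `backbones_per_dsb` (mean complexity over DSBs, `NA` when there
#'   are none, with `undefined` flagging that case).
#' @export
damage_yields <- function(sites, dose_gy) {
  if (dose_gy <= 0) stop("dose must be > 0")
  n_dsb <- sum(sites$kind == "DSB")
  n_ssb <- sum(sites$kind == "SSB")
  list(dsb_per_gy = n_dsb / dose_gy, ssb_per_gy = n_ssb / dose_gy,
       backbones_per_dsb = if (n_dsb) {
         mean(sites$complexity[sites$kind == "DSB"])
       } else NA_real_,
       undefined = n_dsb == 0)
}

#' Write damage sites in a minimal SDD dialect
#'
#' A compact subset of the Standard DNA Damage format: a header block
#' of `key, value;` lines closed by `***EndOfHeader***;`, then one
#' record per site with semicolon-delimited field groups
#' `kind; x, y, z; chrom; bp; backbones;` (coordinates in um, full
#' precision). [read_sdd()] round-trips exactly.
#'
#' @param sites A damage-site table.
#' @param path Output path.
#' @param header Named list of header entries (e.g. dose, chromosome
#'   sizes); `SDD version` is always written first.
#' @return `path`, invisibly.
#' @export
write_sdd <- function(sites, path, header = list()) {
  hdr <- c(list("SDD version" = "1.0"), header)
  num <- function(x) trimws(formatC(x, format = "g", digits = 17))
  lines <- vapply(names(hdr), function(k) {
    v <- hdr[[k]]
    paste0(k, ", ", paste(as.character(v), collapse = ", "), ";")
  }, "")
  lines <- c(lines, "***EndOfHeader***;")
  if (nrow(sites)) {
    lines <- c(lines, paste0(
      sites$kind, "; ", num(sites$x), ", ", num(sites$y), ", ",
      num(sites$z), "; ", sites$chrom, "; ",
      format(sites$bp, scientific = FALSE, trim = TRUE), "; ",
      sites$complexity, ";"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read the SDD dialect written by [write_sdd()]
#'
#' @param path Path to an SDD file.
#' @return A list with `sites` (damage-site table) and `header`
#'   (named list of character vectors).
#' @export
read_sdd <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  end_i <- match("***EndOfHeader***;", lines)
  if (is.na(end_i)) stop("SDD format error: missing end-of-header marker")
  header <- list()
  for (ln in lines[seq_len(end_i - 1L)]) {
    parts <- strsplit(sub(";\\s*$", "", ln), ",\\s*")[[1]]
    header[[parts[1]]] <- parts[-1]
  }
  data_lines <- lines[-seq_len(end_i)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) return(list(sites = empty_sites(),
                                       header = header))
  grp <- strsplit(sub(";\\s*$", "", data_lines), ";\\s*")
  xyz <- lapply(grp, function(g) as.numeric(strsplit(g[2], ",\\s*")[[1]]))
  sites <- data.frame(
    kind = vapply(grp, `[`, "", 1),
    chrom = vapply(grp, `[`, "", 3),
    bp = as.numeric(vapply(grp, `[`, "", 4)),
    x = vapply(xyz, `[`, 0, 1), y = vapply(xyz, `[`, 0, 2),
    z = vapply(xyz, `[`, 0, 3),
    complexity = as.integer(vapply(grp, `[`, "", 5)),
    stringsAsFactors = FALSE)
  list(sites = sites, header = header)
}

#' Read/write the deposit TSV dialect
#'
#' Tab-separated columns `x`, `y`, `z` (um), `energy_ev`, `track_id`,
#' so externally produced energy depositions can be classified.
#'
#' @param path File path.
#' @return `read_deposits_tsv`: a deposit `data.frame`.
#' @export
read_deposits_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "energy_ev")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("deposit TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(d$track_id)) d$track_id <- seq_len(nrow(d))
  d
}

#' @rdname read_deposits_tsv
#' @param deposits A deposit `data.frame`.
#' @export
write_deposits_tsv <- function(deposits, path) {
  utils::write.table(deposits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
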