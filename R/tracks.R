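#' Track-surrogate configuration
#'
#' Parameterised amorphous-track generator: straight particle tracks
#' whose only contract is an LET-correct energy budget with spatially
#' concentrated deposition. It stands in for full track-structure
#' transport so ion exposures are testable desk-side; absolute ion
#' yields are outside its scope.
#'
#' @param let Track-averaged linear energy transfer in keV/um (> 0).
#' @param mean_deposit_ev Mean single-deposit energy in eV (default
#'   60 eV, a typical ionisation-scale quantum).
#' @param lateral_sigma_nm Gaussian lateral jitter of deposits about
#'   the track axis, in nm.
#' @param direction Unit beam direction (default +z). Ellipsoid nuclei
#'   require an axis-aligned +/-z beam.
#' @param isotropic Draw a fresh uniform random direction per track
#'   (sphere nuclei only) instead of the fixed parallel beam.
#' @return A list of class `track_config`.
#' @export
track_config <- function(let, mean_deposit_ev = 60, lateral_sigma_nm = 5,
                         direction = c(0, 0, 1), isotropic = FALSE) {
  if (let <= 0) stop("let must be > 0")
  if (mean_deposit_ev <= 0) stop("mean_deposit_ev must be > 0")
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L, sum(direction^2) > 0)
  structure(list(let = let, mean_deposit_ev = mean_deposit_ev,
                 lateral_sigma_nm = lateral_sigma_nm,
                 direction = direction / sqrt(sum(direction^2)),
                 isotropic = isotropic),
            class = "track_config")
}

joule_per_kev <- 1.602e-16

#' Nucleus mass in kg (liquid water, 1.0 g/cm^3)
#'
#' @param nucleus A [nucleus_shape()].
#' @return Mass in kg.
#' @export
nucleus_mass_kg <- function(nucleus) {
  1000 * nucleus_volume(nucleus) * 1e-18   # um^3 -> m^3
}

#' Number of tracks delivering a dose
#'
#' Mean energy per track is LET times the mean chord length
#' (Cauchy, 4V/S), so
#' n = round(dose * mass / (let * chord * 1.602e-16 J/keV)).
#'
#' @param nucleus A [nucleus_shape()].
#' @param let LET in keV/um (> 0).
#' @param dose_gy Requested dose in Gy (>= 0).
#' @return Integer track count.
#' @examples
#' tracks_for_dose(nucleus_shape(5), let = 10, dose_gy = 1)  # 49
#' @export
tracks_for_dose <- function(nucleus, let, dose_gy) {
  if (let <= 0) stop("let must be > 0")
  if (dose_gy < 0) stop("dose must be >= 0")
  chord <- mean_chord_length(nucleus)
  round(dose_gy * nucleus_mass_kg(nucleus) /
          (let * chord * joule_per_kev))
}

# orthonormal basis with third column = dir
beam_basis <- function(dir) {
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  cbind(u, v, dir)
}

#' Generate LET-scaled straight-track energy deposits
#'
#' Each track enters uniformly over the nucleus's projected disc along
#' the beam direction and traverses the full chord. Deposit count is
#' Poisson with mean `let * chord / mean_deposit_ev` (unit-consistent),
#' positions are uniform along the chord with Gaussian lateral jitter,
#' and energies are exponential with mean `mean_deposit_ev`, so the
#' expected deposited energy per track is `let * chord`.
#'
#' @param nucleus A [nucleus_shape()].
#' @param config A [track_config()].
#' @param n_tracks Number of tracks (>= 0).
#' @param seed Integer seed.
#' @return A deposit `data.frame` (`x`, `y`, `z` um, `energy_ev`,
#'   `track_id`).
#' @export
generate_track_deposits <- function(nucleus, config, n_tracks, seed = 1L) {
  stopifnot(inherits(config, "track_config"), n_tracks >= 0)
  set.seed(seed)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      energy_ev = numeric(0), track_id = integer(0))
  if (n_tracks == 0) return(empty)
  s <- nucleus$semi_axes
  axis_z <- all(abs(config$direction - c(0, 0, 1)) < 1e-12) ||
    all(abs(config$direction + c(0, 0, 1)) < 1e-12)
  if (nucleus$kind == "ellipsoid" && (!axis_z || config$isotropic)) {
    stop("ellipsoid nuclei support only a fixed +/-z beam")
  }
  out <- vector("list", n_tracks)
  for (t in seq_len(n_tracks)) {
    dir <- if (config$isotropic) random_axis() else config$direction
    basis <- beam_basis(dir)
    # entry uniform over the projected disc/ellipse (rejection from a box)
    if (nucleus$kind == "sphere") {
      R <- s[1]
      repeat {
        uv <- stats::runif(2, -R, R)
        if (sum(uv^2) < R^2) break
      }
      half <- sqrt(R^2 - sum(uv^2))
    } else {
      repeat {
        uv <- stats::runif(2, -s[1:2], s[1:2])
        if ((uv[1] / s[1])^2 + (uv[2] / s[2])^2 < 1) break
      }
      half <- s[3] * sqrt(1 - (uv[1] / s[1])^2 - (uv[2] / s[2])^2)
    }
    chord <- 2 * half
    lambda <- config$let * chord * 1000 / config$mean_deposit_ev
    m <- stats::rpois(1, lambda)
    if (m == 0) next
    along <- stats::runif(m, -half, half)
    lat <- matrix(stats::rnorm(2 * m, sd = config$lateral_sigma_nm / 1000),
                  m, 2)
    pts <- cbind(uv[1] + lat[, 1], uv[2] + lat[, 2], along) %*% t(basis)
    out[[t]] <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                           energy_ev = stats::rexp(
                             m, rate = 1 / config$mean_deposit_ev),
                           track_id = t)
  }
  got <- !vapply(out, is.null, logical(1))
  if (!any(got)) return(empty)
  res <- do.call(rbind, out[got])
  rownames(res) <- NULL
  res
}

#' Full track-mode exposure
#'
#' Convenience wrapper: computes the track count for the dose,
#' generates surrogate deposits, classifies them into breaks, and
#' clusters the breaks into damage sites.
#'
#' @param conformation A [genome_conformation()].
#' @param dose_gy Dose in Gy.
#' @param config A [track_config()].
#' @param params A [damage_params()].
#' @param seed Integer seed.
#' @return A damage-site table (see [cluster_breaks()]) with an
#'   attribute `realized_dose_gy`, the dose actually deposited by the
#'   generated tracks (track-count rounding and Poisson deposit counts
#'   make it fluctuate around `dose_gy`) — divide yields by it for
#'   dose-exact normalisation.
#' @export
track_exposure <- function(conformation, dose_gy, config,
                           params = damage_params(), seed = 1L) {
  n <- tracks_for_dose(conformation$nucleus, config$let, dose_gy)
  deposits <- generate_track_deposits(conformation$nucleus, config, n,
                                      seed = seed)
  breaks <- classify_deposits(deposits, conformation, params,
                              seed = seed + 1L)
  sites <- cluster_breaks(breaks, params)
  attr(sites, "realized_dose_gy") <-
    sum(deposits$energy_ev) / 1000 * joule_per_kev /
      nucleus_mass_kg(conformation$nucleus)
  sites
}
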