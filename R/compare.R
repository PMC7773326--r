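#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the
#' p-value uses the asymptotic two-sample formula (the convention for
#' ensembles of ~200 geometries per group). The null hypothesis is
#' that both samples come from the same continuous distribution.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_two_sided <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  res <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, alternative = "two.sided",
                   exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (p * m / rank with running-minimum
#' monotonicity, capped at 1).
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

significance_classes <- c("red", "purple", "yellow", "green")

classify_p <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = rev(significance_classes), right = FALSE)
}

#' KS/BH significance grid over LET and cluster radius
#'
#' For each (LET, radius) cell, compares the per-geometry metric values
#' of two groups with a two-sided KS test, adjusts all cell p-values of
#' the grid together by Benjamini-Hochberg, stores the group mean
#' difference, and classes each cell by the adjusted p: `red`
#' (p > 0.05), `purple` (0.05 > p > 0.01), `yellow` (0.01 > p > 0.001),
#' `green` (p < 0.001).
#'
#' @param group_a,group_b 3D arrays of metric values with dimensions
#'   (geometry, LET, radius); matrices are treated as a single-LET
#'   grid.
#' @param lets Numeric LET values labelling dimension 2.
#' @param radii_nm Numeric cluster radii (nm) labelling dimension 3.
#' @return A `data.frame` of class `significance_grid` with columns
#'   `let`, `radius_nm`, `mean_diff` (mean_a - mean_b), `p`, `p_adj`,
#'   `class`.
#' @export
significance_grid <- function(group_a, group_b, lets, radii_nm) {
  as_arr <- function(x) {
    if (is.matrix(x)) x <- array(x, dim = c(nrow(x), 1L, ncol(x)))
    stopifnot(length(dim(x)) == 3L)
    x
  }
  group_a <- as_arr(group_a)
  group_b <- as_arr(group_b)
  if (!identical(dim(group_a)[2:3], dim(group_b)[2:3])) {
    stop("mismatched grid shapes between groups")
  }
  stopifnot(dim(group_a)[2] == length(lets),
            dim(group_a)[3] == length(radii_nm))
  grid <- expand.grid(let = lets, radius_nm = radii_nm,
                      KEEP.OUT.ATTRS = FALSE)
  p <- numeric(nrow(grid))
  md <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    i <- match(grid$let[k], lets)
    j <- match(grid$radius_nm[k], radii_nm)
    a <- group_a[, i, j]
    b <- group_b[, i, j]
    ks <- ks_two_sided(a, b)
    p[k] <- ks$p_value
    md[k] <- mean(a) - mean(b)
  }
  grid$mean_diff <- md
  grid$p <- p
  grid$p_adj <- bh_adjust(p)
  grid$class <- classify_p(grid$p_adj)
  class(grid) <- c("significance_grid", "data.frame")
  grid
}
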