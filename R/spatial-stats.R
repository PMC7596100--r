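#' Radius grid for spatial statistics
#'
#' Statistics are evaluated at radii `dr, 2*dr, ..., r_max`.  For the
#' pair correlation function, bin i covers the half-open annulus
#' `(i*dr - dr/2, i*dr + dr/2]` (ties assigned to the upper bin).  The
#' default `dr = 0.005` mm resolves the pair-correlation contact peak
#' at the 0.02 mm hard-core diameter (a 0.01 mm bin straddles the
#' exclusion boundary and flattens the peak); `r_max = 0.75` mm is half
#' the default window side.
#'
#' @param dr Bin / annulus width in mm (> 0).
#' @param r_max Largest radius in mm.
#' @return An object of class `radius_grid` with fields `r` (radii),
#'   `dr`, `r_max` and `breaks` (PCF bin edges).
#' @export
radius_grid <- function(dr = 0.005, r_max = 0.75) {
  stopifnot(dr > 0, r_max > dr)
  r <- seq(dr, r_max, by = dr)
  structure(list(r = r, dr = dr, r_max = max(r),
                 breaks = c(r[1] - dr / 2, r + dr / 2)),
            class = "radius_grid")
}

#' @export
print.radius_grid <- function(x, ...) {
  cat(sprintf("radius_grid: %d radii, dr = %g mm, r_max = %g mm\n",
              length(x$r), x$dr, x$r_max))
  invisible(x)
}

# Internal constructor for statistic curves.
stat_curve <- function(kind, grid, values, defined = NULL) {
  kind <- match.arg(kind, c("PCF", "NN_CDF", "SCD_CDF", "J"))
  if (is.null(defined)) defined <- rep(TRUE, length(values))
  structure(list(kind = kind, grid = grid, r = grid$r, values = values,
                 defined = defined),
            class = "stat_curve")
}

#' @export
print.stat_curve <- function(x, ...) {
  rng <- range(x$values[x$defined], na.rm = TRUE)
  cat(sprintf("stat_curve [%s]: %d radii in (0, %g] mm, values in [%.4g, %.4g]\n",
              x$kind, length(x$r), x$grid$r_max, rng[1], rng[2]))
  invisible(x)
}

#' Export a statistic curve as a tidy data frame
#'
#' @param x A `stat_curve`.
#' @param ... Unused.
#' @return Data frame with columns `kind`, `r`, `value` (undefined radii
#'   carry `NA`).
#' @export
as.data.frame.stat_curve <- function(x, ...) {
  v <- x$values
  v[!x$defined] <- NA_real_
  data.frame(kind = x$kind, r = x$r, value = v)
}

#' Pair correlation function with rectangular edge correction
#'
#' For each point, the number of other points in the annulus
#' `(r - dr/2, r + dr/2]` is counted and divided by the number expected
#' under complete spatial randomness (CSR) at the pattern's global
#' intensity, using the exact analytic area of the annulus-window
#' intersection as the edge correction.  The curve is the average of
#' these per-point ratios; under CSR g(r) is identically 1.
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param grid A [radius_grid()].
#' @return A `stat_curve` of kind `"PCF"`.
#' @export
pair_correlation <- function(pattern, grid = radius_grid()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radius_grid"))
  n <- pattern$n
  if (n < 2L) stop("pair correlation requires at least 2 points", call. = FALSE)
  w <- pattern$window
  lambda <- n / w$area
  counts <- pair_bin_counts_cpp(pattern$x, pattern$y, grid$breaks)  # n x B
  B <- length(grid$r)
  # per-point disc areas at each bin edge -> annulus-window areas
  # (single vectorised call over all n x (B+1) point/edge combinations)
  nr <- B + 1L
  edge_area <- matrix(
    disc_window_area(rep(pattern$x, nr), rep(pattern$y, nr),
                     rep(grid$breaks, each = n), w$width, w$height),
    n, nr)
  ann_area <- edge_area[, -1L, drop = FALSE] - edge_area[, -(B + 1L), drop = FALSE]
  expected <- lambda * ann_area
  g <- colMeans(counts / expected)
  stat_curve("PCF", grid, g)
}

#' Nearest-neighbour distance distribution G(r)
#'
#' Empirical CDF of the distance from each point to its nearest other
#' point, sampled on the radius grid (right-continuous step function).
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param grid A [radius_grid()].
#' @return A `stat_curve` of kind `"NN_CDF"`; the raw nearest-neighbour
#'   distances are attached as attribute `"distances"`.
#' @export
nn_distribution <- function(pattern, grid = radius_grid()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radius_grid"))
  if (pattern$n < 2L) {
    stop("nearest-neighbour distribution requires at least 2 points",
         call. = FALSE)
  }
  d <- nn_dist_cpp(pattern$x, pattern$y)
  vals <- vapply(grid$r, function(r) mean(d <= r), numeric(1))
  out <- stat_curve("NN_CDF", grid, vals)
  attr(out, "distances") <- d
  out
}

#' Spherical contact (empty-space) distribution F(r)
#'
#' Empirical CDF of the distance from uniformly random reference
#' locations in the window to the nearest pattern point.  By default the
#' number of reference points equals the number of pattern points so
#' that F and G share a denominator.
#'
#' @param pattern A [point_pattern()] with at least 1 point.
#' @param grid A [radius_grid()].
#' @param n_reference Number of reference points (default `pattern$n`).
#' @param seed Integer seed for the reference sampling (recorded with
#'   every feature row; F is a stochastic statistic).
#' @param reference_points Optional list with components `x`, `y`
#'   overriding the random sampling (used for deterministic checks).
#' @return A `stat_curve` of kind `"SCD_CDF"`; reference distances are
#'   attached as attribute `"distances"`.
#' @export
spherical_contact <- function(pattern, grid = radius_grid(),
                              n_reference = NULL, seed = NULL,
                              reference_points = NULL) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(grid, "radius_grid"))
  if (pattern$n < 1L) stop("empty pattern: spherical contact undefined",
                           call. = FALSE)
  if (is.null(reference_points)) {
    if (is.null(n_reference)) n_reference <- pattern$n
    stopifnot(n_reference >= 1L)
    if (!is.null(seed)) set.seed(seed)
    rx <- runif(n_reference, 0, pattern$window$width)
    ry <- runif(n_reference, 0, pattern$window$height)
  } else {
    rx <- reference_points$x
    ry <- reference_points$y
  }
  d <- ref_nn_dist_cpp(rx, ry, pattern$x, pattern$y)
  vals <- vapply(grid$r, function(r) mean(d <= r), numeric(1))
  out <- stat_curve("SCD_CDF", grid, vals)
  attr(out, "distances") <- d
  out
}

#' J-function
#'
#' `J(r) = (1 - G(r)) / (1 - F(r))`, defined wherever `F(r) < 1`.
#' Under CSR, G and F approximately coincide and J is approximately 1;
#' J < 1 indicates clustering, J > 1 dispersal.
#'
#' @param G A `stat_curve` of kind `"NN_CDF"`.
#' @param F A `stat_curve` of kind `"SCD_CDF"`.
#' @return A `stat_curve` of kind `"J"` with undefined radii (where
#'   `F(r) = 1`) flagged in `$defined`.
#' @export
j_function <- function(G, F) {
  stopifnot(inherits(G, "stat_curve"), inherits(F, "stat_curve"))
  if (G$kind != "NN_CDF" || F$kind != "SCD_CDF") {
    stop("j_function expects G of kind NN_CDF and F of kind SCD_CDF",
         call. = FALSE)
  }
  if (length(G$r) != length(F$r) || any(abs(G$r - F$r) > 1e-12)) {
    stop("G and F evaluated on different radius grids", call. = FALSE)
  }
  defined <- F$values < 1
  vals <- rep(NA_real_, length(G$r))
  vals[defined] <- (1 - G$values[defined]) / (1 - F$values[defined])
  stat_curve("J", G$grid, vals, defined = defined)
}

#' Summary features of a point pattern
#'
#' Reduces a pattern to the triple used for infiltration inference:
#' * `g_max` — peak of the pair correlation function (maximum clustering
#'   intensity over all radii);
#' * `F_max` — the largest observed reference-to-nearest-point distance,
#'   i.e. the smallest r with F(r) = 1 (radius of the largest empty
#'   circle, the "immune desert" size), in mm;
#' * `J_min` — minimum of the J-function over its domain of definition,
#'   clamped to `[0, 1]` (clustering depth);
#' plus the cell density `d` (cells/mm^2).
#'
#' `J_min` is taken as the exact minimum of the empirical J over its
#' continuous domain, restricted to radii where at least `j_tail_min`
#' reference distances exceed r: the ratio `(1 - G)/(1 - F)` is
#' unstable where the empty-space CDF rests on only one or two
#' reference points, and the guard keeps the minimum away from that
#' noise-dominated tail.
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param grid A [radius_grid()].
#' @param seed Integer seed for the spherical-contact reference sampling.
#' @param j_tail_min Minimum number of reference distances that must
#'   exceed r for r to enter the J_min search (tail-stability guard).
#' @return An object of class `summary_features`: a list with fields
#'   `g_max`, `F_max`, `J_min`, `d` and `seed`.
#' @export
summary_features <- function(pattern, grid = radius_grid(), seed = NULL,
                             j_tail_min = 5L) {
  g <- pair_correlation(pattern, grid)
  G <- nn_distribution(pattern, grid)
  F <- spherical_contact(pattern, grid, seed = seed)
  nn_d <- sort(attr(G, "distances"))
  ref_d <- sort(attr(F, "distances"))
  f_max <- max(ref_d)
  # Exact minimum of J over its continuous domain: G and F are step
  # functions, and J = (1 - G)/(1 - F) only decreases at jumps of G,
  # so the minimum is attained at an observed distance.  Evaluating at
  # all jump radii avoids the upward bias a coarse sampling grid would
  # introduce at high densities; the tail guard excludes radii where
  # 1 - F rests on fewer than j_tail_min reference points.
  cand <- unique(c(nn_d, ref_d))
  cand <- cand[cand < f_max]
  j_min <- 1  # J(0) = 1
  if (length(cand)) {
    m <- length(ref_d)
    Gv <- findInterval(cand, nn_d) / length(nn_d)
    Fv <- findInterval(cand, ref_d) / m
    ok <- m * (1 - Fv) >= j_tail_min
    if (any(ok)) j_min <- min(1, (1 - Gv[ok]) / (1 - Fv[ok]))
  }
  structure(list(g_max = max(g$values),
                 F_max = f_max,
                 J_min = max(j_min, 0),
                 d = pattern_density(pattern),
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "summary_features")
}

#' @export
print.summary_features <- function(x, ...) {
  cat(sprintf("summary_features: g_max = %.3f, F_max = %.3f mm, J_min = %.3f, d = %.1f cells/mm^2\n",
              x$g_max, x$F_max, x$J_min, x$d))
  invisible(x)
}

#' @export
as.data.frame.summary_features <- function(x, ...) {
  data.frame(g_max = x$g_max, F_max = x$F_max, J_min = x$J_min, d = x$d,
             seed = x$seed)
}
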