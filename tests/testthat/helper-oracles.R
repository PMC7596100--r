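# Independent brute-force oracles for the spatial statistics.  These
# deliberately avoid the package's computational paths: areas come from
# numerical polar integration, counts and CDFs from direct enumeration.

# Area of disc(centre, r) intersect [0,W]x[0,H] by polar integration
# (the intersection is star-shaped about any interior centre).
oracle_disc_area <- function(cx, cy, r, width, height, n_angles = 40000L) {
  theta <- (seq_len(n_angles) - 0.5) / n_angles * 2 * pi
  ct <- cos(theta); st <- sin(theta)
  tx <- ifelse(ct > 0, (width - cx) / ct, ifelse(ct < 0, -cx / ct, Inf))
  ty <- ifelse(st > 0, (height - cy) / st, ifelse(st < 0, -cy / st, Inf))
  rr <- pmin(r, pmin(tx, ty))
  sum(0.5 * rr^2) * (2 * pi / n_angles)
}

# Naive edge-corrected PCF by direct pair enumeration.
oracle_pcf <- function(pattern, grid) {
  n <- pattern$n
  w <- pattern$window
  lambda <- n / w$area
  vals <- numeric(length(grid$r))
  for (b in seq_along(grid$r)) {
    lo <- grid$breaks[b]; hi <- grid$breaks[b + 1]
    ratios <- numeric(n)
    for (i in seq_len(n)) {
      d <- sqrt((pattern$x[i] - pattern$x)^2 + (pattern$y[i] - pattern$y)^2)
      d <- d[-i]
      cnt <- sum(d > lo & d <= hi)
      a <- oracle_disc_area(pattern$x[i], pattern$y[i], hi, w$width, w$height) -
           oracle_disc_area(pattern$x[i], pattern$y[i], lo, w$width, w$height)
      ratios[i] <- cnt / (lambda * a)
    }
    vals[b] <- mean(ratios)
  }
  vals
}

# Naive nearest-neighbour CDF.
oracle_G <- function(pattern, grid) {
  n <- pattern$n
  nn <- vapply(seq_len(n), function(i) {
    d <- sqrt((pattern$x[i] - pattern$x)^2 + (pattern$y[i] - pattern$y)^2)
    min(d[-i])
  }, numeric(1))
  list(values = vapply(grid$r, function(r) mean(nn <= r), numeric(1)),
       distances = nn)
}

# Naive spherical contact CDF for given reference points.
oracle_F <- function(pattern, refs, grid) {
  d <- vapply(seq_along(refs$x), function(i) {
    min(sqrt((refs$x[i] - pattern$x)^2 + (refs$y[i] - pattern$y)^2))
  }, numeric(1))
  list(values = vapply(grid$r, function(r) mean(d <= r), numeric(1)),
       distances = d)
}

# Independent J_min implementation from raw distances (same definition
# as the package: exact minimum over step-function jumps, tail guard).
oracle_jmin <- function(nn_d, ref_d, guard = 5L) {
  f_max <- max(ref_d)
  cand <- sort(unique(c(nn_d, ref_d)))
  cand <- cand[cand < f_max]
  best <- 1
  m <- length(ref_d)
  for (r in cand) {
    Gv <- sum(nn_d <= r) / length(nn_d)
    Fv <- sum(ref_d <= r) / m
    if (m * (1 - Fv) >= guard) {
      best <- min(best, (1 - Gv) / (1 - Fv))
    }
  }
  max(best, 0)
}

# Uniform random pattern, optionally with a hard core (rejection).
random_pattern <- function(n, window = roi_window(), seed = NULL,
                           hard_core = 0) {
  if (!is.null(seed)) set.seed(seed)
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    x <- runif(1, 0, window$width); y <- runif(1, 0, window$height)
    if (hard_core > 0 && length(xs) &&
        any((x - xs)^2 + (y - ys)^2 < hard_core^2)) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  point_pattern(xs, ys, window)
}

# Hand-built feature model for likelihood tests: exponential mean and
# SD triples plus a constant correlation matrix on a small rho grid.
toy_model <- function(mean_curves, sd_curves, corr = diag(3),
                      rho_grid = seq(0, 0.5, by = 0.1)) {
  stats <- c("g_max", "F_max", "J_min")
  corrs <- array(rep(corr, length(rho_grid)), c(3, 3, length(rho_grid)),
                 dimnames = list(stats, stats, NULL))
  structure(list(stats = stats,
                 mean_curves = mean_curves,
                 sd_curves = lapply(sd_curves, function(v)
                   list(type = "exp", a = v[["a"]], b = v[["b"]], c = v[["c"]])),
                 rho_grid = rho_grid,
                 empirical = NULL, correlations = corrs,
                 meta = list()),
            class = "feature_model")
}

# Cofactor-expansion determinant (3x3 or 2x2) for likelihood oracles.
oracle_det <- function(M) {
  if (nrow(M) == 1L) return(M[1, 1])
  if (nrow(M) == 2L) return(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
}
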