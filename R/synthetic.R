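#' Parameters for synthetic two-compartment pattern generation
#'
#' @param rho Infiltration ratio `d_t / d_s` of tumour-nest to stroma
#'   cell density, in `[0, 1]`; 0 = complete exclusion from nests,
#'   1 = uniform.
#' @param d Target overall cell density (cells/mm^2).
#' @param l Characteristic tumour-nest length scale (mm).
#' @param exclusion_radius Hard-core exclusion distance between cell
#'   centres (mm); default 0.02 mm, about one macrophage diameter.
#' @param window An [roi_window()].
#' @param mask_resolution Pixels per side of the tissue mask grid.
#' @param max_rejections Consecutive rejected candidates tolerated
#'   before the placement reports a packing failure.
#' @return An object of class `generation_params`.
#' @export
generation_params <- function(rho, d, l, exclusion_radius = 0.02,
                              window = roi_window(), mask_resolution = 256L,
                              max_rejections = 10000L) {
  stopifnot(rho >= 0, rho <= 1, d > 0, l > 0, exclusion_radius >= 0,
            mask_resolution >= 64L)
  structure(list(rho = rho, d = d, l = l,
                 exclusion_radius = exclusion_radius, window = window,
                 mask_resolution = as.integer(mask_resolution),
                 max_rejections = as.integer(max_rejections)),
            class = "generation_params")
}

#' @export
print.generation_params <- function(x, ...) {
  cat(sprintf("generation_params: rho = %g, d = %g cells/mm^2, l = %g mm, hard core = %g mm\n",
              x$rho, x$d, x$l, x$exclusion_radius))
  invisible(x)
}

# One sample of a stationary Gaussian random field with isotropic
# Gaussian correlation exp(-r^2 / (2 l^2)) on a res x res grid,
# synthesised in spectral space: the kernel's spectral density
# exp(-l^2 k^2 / 2) is strictly positive, so the construction is
# well conditioned even when l is comparable to the window (where
# circulant embedding of the covariance fails).  Only the correlation
# structure matters downstream (the field is thresholded at its
# median), so the overall scale is left unnormalised.
grf_sample <- function(res, width, height, l) {
  fx <- c(0:(res %/% 2), -((res - res %/% 2 - 1):1)) / width
  fy <- c(0:(res %/% 2), -((res - res %/% 2 - 1):1)) / height
  k2 <- outer((2 * pi * fx)^2, (2 * pi * fy)^2, "+")
  amp <- exp(-l^2 * k2 / 4)  # sqrt of the Gaussian spectral density
  eps <- matrix(complex(real = rnorm(res * res), imaginary = rnorm(res * res)),
                res, res)
  Re(fft(amp * eps, inverse = TRUE))
}

#' Generate a two-compartment tissue geometry
#'
#' Samples a stationary Gaussian random field with correlation length
#' `l` on a square pixel grid over the window and thresholds it at its
#' median to split the window into tumour-nest and stroma compartments.
#' A geometry is accepted only if each compartment covers at least 25%
#' of the window area; otherwise the field is regenerated (new
#' sub-seed) up to `max_attempts` times.
#'
#' @param l Nest length scale in mm (`0 < l < min(window dims)`).
#' @param window An [roi_window()].
#' @param resolution Pixels per side (>= 64).
#' @param seed Integer seed; the mask is bit-identical for a fixed seed.
#' @param max_attempts Regeneration bound before a generation-failure
#'   error.
#' @return An object of class `tissue_geometry`: list with the logical
#'   `mask` (TRUE = tumour nest; rows index x, columns y), `l`,
#'   `window`, `resolution` and the measured `area_fraction_tumour` /
#'   `area_fraction_stroma`.
#' @export
generate_geometry <- function(l, window = roi_window(), resolution = 256L,
                              seed = NULL, max_attempts = 100L) {
  stopifnot(l > 0, l < min(window$width, window$height), resolution >= 64L)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    field <- grf_sample(resolution, window$width, window$height, l)
    mask <- field > median(field)
    frac_t <- mean(mask)
    if (frac_t >= 0.25 && frac_t <= 0.75) {
      return(structure(list(mask = mask, l = l, window = window,
                            resolution = as.integer(resolution),
                            area_fraction_tumour = frac_t,
                            area_fraction_stroma = 1 - frac_t,
                            attempts = attempt),
                       class = "tissue_geometry"))
    }
  }
  stop(sprintf("geometry generation failed after %d attempts (l = %g)",
               max_attempts, l), call. = FALSE)
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("tissue_geometry: %dx%d mask, l = %g mm, tumour fraction %.3f\n",
              x$resolution, x$resolution, x$l, x$area_fraction_tumour))
  invisible(x)
}

#' Per-compartment point quotas
#'
#' Solves `n_t + n_s = round(d * A)` and `(n_t / A_t) = rho * (n_s / A_s)`
#' for integer quotas, so the realised ratio of compartment densities
#' matches `rho` up to rounding.
#'
#' @param params A [generation_params()].
#' @param geometry A `tissue_geometry`.
#' @return An object of class `compartment_quota`: list with `n_tumour`,
#'   `n_stroma`, `n_total`.
#' @export
compartment_quotas <- function(params, geometry) {
  stopifnot(inherits(params, "generation_params"),
            inherits(geometry, "tissue_geometry"))
  N <- round(params$d * params$window$area)
  at <- geometry$area_fraction_tumour
  as_ <- geometry$area_fraction_stroma
  n_t <- round(N * params$rho * at / (params$rho * at + as_))
  structure(list(n_tumour = as.integer(n_t),
                 n_stroma = as.integer(N - n_t),
                 n_total = as.integer(N)),
            class = "compartment_quota")
}

#' Place points under compartment quotas and a hard-core constraint
#'
#' Candidate points are proposed uniformly over the window and accepted
#' iff their compartment's quota is not yet filled and they lie at least
#' `exclusion_radius` from every accepted point (a single global hard
#' core across both compartments).
#'
#' @param params A [generation_params()].
#' @param geometry A `tissue_geometry`.
#' @param quota A [compartment_quotas()] result.
#' @param seed Integer seed.
#' @return A [point_pattern()] with attribute `"in_tumour"` (logical per
#'   point) and `"rejections"`.
#' @export
place_points <- function(params, geometry, quota, seed = NULL) {
  stopifnot(inherits(quota, "compartment_quota"))
  A <- params$window$area
  # centres >= exclusion apart <=> non-overlapping discs of radius
  # exclusion/2; refuse if those discs would cover half the window
  if (quota$n_total * pi * (params$exclusion_radius / 2)^2 >= 0.5 * A) {
    stop("hard-core packing infeasible: exclusion discs would cover half the window",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- place_points_cpp(geometry$mask, params$window$width,
                          params$window$height, quota$n_tumour,
                          quota$n_stroma, params$exclusion_radius,
                          params$max_rejections)
  if (!res$complete) {
    stop(sprintf(
      "packing failure: filled %d/%d tumour and %d/%d stroma points before %d consecutive rejections",
      res$filled_tumour, quota$n_tumour, res$filled_stroma, quota$n_stroma,
      params$max_rejections), call. = FALSE)
  }
  p <- point_pattern(res$x, res$y, params$window)
  attr(p, "in_tumour") <- as.logical(res$in_tumour)
  attr(p, "rejections") <- res$rejections
  p
}

#' Sample a cell density from the cohort distribution
#'
#' Draws from Normal(mean 333, SD 170) cells/mm^2, rejecting draws below
#' 150 (the stability floor for the spatial statistics), emulating the
#' CD68+ macrophage density distribution of the head-and-neck cohort.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param mean,sd,min_density Distribution parameters.
#' @return Numeric vector of densities (cells/mm^2).
#' @export
sample_density <- function(n = 1L, seed = NULL, mean = 333, sd = 170,
                           min_density = 150) {
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= min_density])
  }
  out[seq_len(n)]
}

#' Generate one synthetic infiltration pattern
#'
#' Convenience wrapper: geometry, quotas and placement from a single
#' seed.  On a packing failure the geometry is regenerated (fresh
#' sub-seed) up to `retries` times.
#'
#' @param params A [generation_params()].
#' @param seed Integer seed.
#' @param retries Regeneration attempts after packing failure.
#' @return A [point_pattern()] with attributes `"in_tumour"` and
#'   `"geometry"`.
#' @export
generate_pattern <- function(params, seed = NULL, retries = 5L) {
  if (!is.null(seed)) set.seed(seed)
  last <- NULL
  for (k in seq_len(retries + 1L)) {
    geom <- generate_geometry(params$l, params$window,
                              params$mask_resolution)
    quota <- compartment_quotas(params, geom)
    p <- tryCatch(place_points(params, geom, quota), error = function(e) e)
    if (!inherits(p, "error")) {
      attr(p, "geometry") <- geom
      return(p)
    }
    last <- p
  }
  stop("pattern generation failed after ", retries + 1L, " attempts: ",
       conditionMessage(last), call. = FALSE)
}

# Draw per-pattern sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Core ensemble driver shared by the training/validation generators and
# the in-memory feature simulator.  `rho` is a vector (one per pattern).
simulate_patterns <- function(rho, seed, l_range = c(0.1, 0.75),
                              density = list(mean = 333, sd = 170, min = 150),
                              window = roi_window(), resolution = 256L,
                              exclusion_radius = 0.02,
                              callback) {
  n <- length(rho)
  seeds <- derive_seeds(seed, n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    p <- NULL
    for (attempt in 1:10) {
      # resample the pattern's conditions from its own stream on a
      # generation failure (extreme density draws can sit near the
      # hard-core jamming limit when confined to one compartment)
      d <- sample_density(1L, mean = density$mean, sd = density$sd,
                          min_density = density$min)
      l <- runif(1, l_range[1], l_range[2])
      params <- generation_params(rho[i], d, l, exclusion_radius,
                                  window, resolution)
      p <- tryCatch(generate_pattern(params), error = function(e) e)
      if (!inherits(p, "error")) break
      message(sprintf("pattern %d (rho = %.3f): regenerating after %s",
                      i, rho[i], conditionMessage(p)))
    }
    if (inherits(p, "error")) {
      stop("pattern ", i, " failed after 10 resampling attempts: ",
           conditionMessage(p), call. = FALSE)
    }
    callback(i, p, params, seeds[i])
  }
  invisible(seeds)
}

#' Simulate patterns and return their summary features
#'
#' Generates one pattern per entry of `rho` (density and nest length
#' scale resampled per pattern, as in the training design) and computes
#' the summary features in memory without touching disk.  This is the
#' engine behind model training and validation studies.
#'
#' @param rho Vector of infiltration ratios, one per pattern.
#' @param seed Master seed; everything (densities, length scales,
#'   geometries, placements, reference points) derives from it.
#' @param grid [radius_grid()] for the statistics.
#' @param l_range Range of the nest length scale (mm), sampled uniformly
#'   per pattern.
#' @param density List with `mean`, `sd`, `min` of the cell-density
#'   distribution (cells/mm^2).
#' @param window,resolution,exclusion_radius Generator geometry settings.
#' @return Data frame with columns `pattern_id`, `rho`, `l`, `d`,
#'   `seed`, `g_max`, `F_max`, `J_min`.
#' @export
simulate_feature_table <- function(rho, seed, grid = radius_grid(),
                                   l_range = c(0.1, 0.75),
                                   density = list(mean = 333, sd = 170, min = 150),
                                   window = roi_window(), resolution = 256L,
                                   exclusion_radius = 0.02) {
  n <- length(rho)
  out <- data.frame(pattern_id = sprintf("p%06d", seq_len(n)), rho = rho,
                    l = NA_real_, d = NA_real_, seed = NA_integer_,
                    g_max = NA_real_, F_max = NA_real_, J_min = NA_real_)
  simulate_patterns(rho, seed, l_range, density, window, resolution,
                    exclusion_radius,
                    callback = function(i, p, params, sub_seed) {
    # reference sampling uses seed + 1 so it does not replay the
    # generation stream of the same seed
    feats <- summary_features(p, grid, seed = sub_seed + 1)
    out$l[i] <<- params$l
    out$d[i] <<- pattern_density(p)
    out$seed[i] <<- sub_seed
    out$g_max[i] <<- feats$g_max
    out$F_max[i] <<- feats$F_max
    out$J_min[i] <<- feats$J_min
  })
  out
}

# Shared writer for the two on-disk dataset generators.
write_dataset <- function(rho, seed, out_dir, l_range, density, window,
                          resolution, exclusion_radius) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(rho)
  manifest <- data.frame(pattern_id = sprintf("p%06d", seq_len(n)),
                         file = sprintf("p%06d.csv", seq_len(n)),
                         rho = rho, l = NA_real_, d = NA_real_,
                         seed = NA_integer_)
  simulate_patterns(rho, seed, l_range, density, window, resolution,
                    exclusion_radius,
                    callback = function(i, p, params, sub_seed) {
    write_pattern(p, file.path(out_dir, manifest$file[i]))
    manifest$l[i] <<- params$l
    manifest$d[i] <<- pattern_density(p)
    manifest$seed[i] <<- sub_seed
  })
  write_manifest(manifest, file.path(out_dir, "manifest.csv"), seed = seed)
  manifest
}

#' Generate a training dataset on disk
#'
#' For each value on the `rho_grid` and each repetition, a density is
#' drawn from the cohort distribution, a nest length scale from
#' `l_range`, and a pattern generated and written as CSV, together with
#' a manifest.  Fully reproducible from the master seed.
#'
#' @param rho_grid Training grid of infiltration ratios (default
#'   `seq(0, 0.5, by = 0.02)`).
#' @param reps_per_rho Patterns per grid value.
#' @param l_range Nest length-scale range (mm).
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @inheritParams simulate_feature_table
#' @return The manifest data frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_training_set <- function(rho_grid = seq(0, 0.5, by = 0.02),
                                  reps_per_rho = 1200L,
                                  l_range = c(0.1, 0.75), out_dir, seed,
                                  density = list(mean = 333, sd = 170, min = 150),
                                  window = roi_window(), resolution = 256L,
                                  exclusion_radius = 0.02) {
  stopifnot(length(rho_grid) >= 1L, reps_per_rho >= 1L)
  rho <- rep(rho_grid, each = reps_per_rho)
  write_dataset(rho, seed, out_dir, l_range, density, window, resolution,
                exclusion_radius)
}

#' Generate a validation dataset on disk
#'
#' As [generate_training_set()], but with `rho` sampled uniformly at
#' random from `rho_range` for each pattern.
#'
#' @param n_patterns Number of patterns.
#' @param rho_range Uniform sampling range for rho.
#' @inheritParams generate_training_set
#' @return The manifest data frame.
#' @export
generate_validation_set <- function(n_patterns, rho_range = c(0, 0.5),
                                    out_dir, seed,
                                    l_range = c(0.1, 0.75),
                                    density = list(mean = 333, sd = 170, min = 150),
                                    window = roi_window(), resolution = 256L,
                                    exclusion_radius = 0.02) {
  stopifnot(n_patterns >= 1L)
  set.seed(seed)
  rho <- runif(n_patterns, rho_range[1], rho_range[2])
  # pattern seeds derive from a distinct stream so rho and sub-seeds do
  # not alias
  write_dataset(rho, seed + 1L, out_dir, l_range, density, window,
                resolution, exclusion_radius)
}

#' Compute summary features for every pattern in a manifest
#'
#' @param manifest Data frame from [read_manifest()] (or a generator).
#' @param grid A [radius_grid()].
#' @param dir Directory holding the pattern files (defaults to the
#'   manifest's recorded directory).
#' @param window Window the patterns live in.
#' @return The manifest with `g_max`, `F_max`, `J_min` columns appended;
#'   patterns whose features fail are dropped with a warning reporting
#'   the skip count.
#' @export
compute_features_batch <- function(manifest, grid = radius_grid(),
                                   dir = attr(manifest, "dir"),
                                   window = roi_window()) {
  if (is.null(dir)) dir <- "."
  out <- manifest
  out$g_max <- out$F_max <- out$J_min <- NA_real_
  skipped <- 0L
  for (i in seq_len(nrow(out))) {
    res <- tryCatch({
      p <- read_pattern(file.path(dir, out$file[i]), window)
      s <- out$seed[i]
      # convention shared with simulate_feature_table: reference
      # sampling uses the recorded generation seed + 1
      summary_features(p, grid, seed = if (is.na(s)) NULL else s + 1)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
    } else {
      out$g_max[i] <- res$g_max
      out$F_max[i] <- res$F_max
      out$J_min[i] <- res$J_min
    }
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d pattern(s) whose features failed", skipped))
  }
  out[!is.na(out$g_max), , drop = FALSE]
}
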