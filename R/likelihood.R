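#' Univariate Gaussian log-likelihood of a feature observation
#'
#' `ln L = -0.5 * (ln(2 pi sigma^2) + (x - mu)^2 / sigma^2)` with
#' `mu = mean_curve(rho)` and `sigma = sd_curve(rho)` taken from the
#' trained model.
#'
#' @param x Observed feature value.
#' @param rho Infiltration ratio(s) in `[0, 0.5]` (vectorised).
#' @param model A trained `feature_model`.
#' @param statistic One of `"g_max"`, `"F_max"`, `"J_min"` (or the
#'   one-letter codes `"g"`, `"F"`, `"J"`).
#' @return `ln L` (same length as `rho`).
#' @export
log_likelihood_single <- function(x, rho, model, statistic) {
  stopifnot(inherits(model, "feature_model"))
  if (statistic %in% names(STAT_NAMES)) statistic <- STAT_NAMES[[statistic]]
  stopifnot(statistic %in% model$stats)
  if (any(rho < 0 | rho > 0.5)) {
    stop("rho must lie in [0, 0.5]", call. = FALSE)
  }
  mu <- model_mean(model, statistic, rho)
  s <- model_sd(model, statistic, rho)
  if (any(s <= 0)) stop("model SD non-positive: model invalid", call. = FALSE)
  -0.5 * (log(2 * pi * s^2) + (x - mu)^2 / s^2)
}

#' Multivariate Gaussian log-likelihood of a feature vector
#'
#' `ln L = -0.5 * (ln|Sigma| + (x - mu)' Sigma^{-1} (x - mu) + k ln(2 pi))`
#' with `Sigma(rho) = D(rho) C(rho) D(rho)` restricted to the requested
#' subset; for a single statistic this reduces exactly to
#' [log_likelihood_single()].
#'
#' @param x Named vector of observed feature values (must contain the
#'   subset's statistics).
#' @param rho Infiltration ratio(s) in `[0, 0.5]` (vectorised).
#' @param model A trained `feature_model` with correlation structure.
#' @param subset Subset label, e.g. `"gFJ"`, `"gF"`, `"J"`.
#' @return `ln L` (same length as `rho`).
#' @export
log_likelihood_multi <- function(x, rho, model, subset = "gFJ") {
  stopifnot(inherits(model, "feature_model"))
  stats <- parse_subset(subset)
  k <- length(stats)
  if (k == 1L) return(log_likelihood_single(x[[stats]], rho, model, stats))
  if (is.null(model$correlations)) {
    stop("model has no correlation structure; run train_feature_model()",
         call. = FALSE)
  }
  if (any(rho < 0 | rho > 0.5)) stop("rho must lie in [0, 0.5]", call. = FALSE)
  xv <- vapply(stats, function(s) x[[s]], numeric(1))
  m <- length(rho)
  z <- matrix(NA_real_, m, k)
  sdm <- matrix(NA_real_, m, k)
  for (j in seq_len(k)) {
    mu <- model_mean(model, stats[j], rho)
    s <- model_sd(model, stats[j], rho)
    if (any(s <= 0)) stop("model SD non-positive: model invalid", call. = FALSE)
    z[, j] <- (xv[j] - mu) / s
    sdm[, j] <- s
  }
  gi <- nearest_grid_index(model, rho)
  idx <- match(stats, model$stats)
  if (k == 2L) {
    c12 <- model$correlations[idx[1], idx[2], gi]
    detC <- 1 - c12^2
    detC <- pmax(detC, 1e-12)
    quad <- (z[, 1]^2 + z[, 2]^2 - 2 * c12 * z[, 1] * z[, 2]) / detC
    logdet <- log(detC) + 2 * (log(sdm[, 1]) + log(sdm[, 2]))
  } else {
    c12 <- model$correlations[idx[1], idx[2], gi]
    c13 <- model$correlations[idx[1], idx[3], gi]
    c23 <- model$correlations[idx[2], idx[3], gi]
    detC <- 1 + 2 * c12 * c13 * c23 - c12^2 - c13^2 - c23^2
    detC <- pmax(detC, 1e-12)
    quad <- (z[, 1]^2 * (1 - c23^2) + z[, 2]^2 * (1 - c13^2) +
             z[, 3]^2 * (1 - c12^2) +
             2 * z[, 1] * z[, 2] * (c13 * c23 - c12) +
             2 * z[, 1] * z[, 3] * (c12 * c23 - c13) +
             2 * z[, 2] * z[, 3] * (c12 * c13 - c23)) / detC
    logdet <- log(detC) + 2 * rowSums(log(sdm))
  }
  -0.5 * (logdet + quad + k * log(2 * pi))
}

#' Maximum-likelihood estimate of the infiltration ratio
#'
#' Evaluates the profile log-likelihood of the observed features on a
#' dense rho grid over `[0, 0.5]`.  The estimate `eta` is the argmax
#' (ties broken towards the smallest rho); the 95% confidence interval
#' is the range of grid values whose log-likelihood lies within
#' `0.5 * qchisq(0.95, 1)` (= 1.9207) of the maximum, truncated to
#' `[0, 0.5]`.
#'
#' @param features A [summary_features()] object or named list/vector
#'   with `g_max`, `F_max`, `J_min` (only the subset's members needed).
#' @param model A trained `feature_model`.
#' @param subset Statistic subset label (`"g"`, `"F"`, `"J"`, `"gF"`,
#'   `"gJ"`, `"FJ"`, `"gFJ"`).
#' @param rho_step Grid step for the profile evaluation.
#' @return An object of class `rho_estimate`: list with `eta`,
#'   `ci_lower`, `ci_upper`, `subset`, `rho_step` and the `profile`
#'   data frame (rho, log_lik).
#' @export
estimate_rho <- function(features, model, subset = "gFJ", rho_step = 0.002) {
  stopifnot(inherits(model, "feature_model"), rho_step > 0)
  grid <- seq(0, 0.5, by = rho_step)
  ll <- log_likelihood_multi(features, grid, model, subset)
  if (all(!is.finite(ll))) {
    stop("likelihood non-finite over the entire rho grid", call. = FALSE)
  }
  ll[!is.finite(ll)] <- -Inf
  best <- which.max(ll)  # first maximum = smallest rho on ties
  thr <- ll[best] - 0.5 * qchisq(0.95, 1)
  inside <- which(ll >= thr)
  structure(list(eta = grid[best],
                 ci_lower = grid[min(inside)],
                 ci_upper = grid[max(inside)],
                 log_lik_max = ll[best],
                 subset = subset, rho_step = rho_step,
                 profile = data.frame(rho = grid, log_lik = ll)),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho_estimate [%s]: eta = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$subset, x$eta, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Batch prediction of the infiltration ratio
#'
#' Predicts `eta` with confidence intervals for every pattern in a
#' feature table (or manifest) and every requested statistic subset.
#'
#' @param features Either a feature table (columns `pattern_id`,
#'   optional `rho`, `g_max`, `F_max`, `J_min`) or a manifest data frame
#'   (features are then computed from the pattern files).
#' @param model A trained `feature_model`.
#' @param subsets Character vector of subset labels (default: all 7).
#' @param rho_step Profile grid step.
#' @param grid Radius grid used if features must be computed.
#' @return Data frame with one row per pattern x subset: `pattern_id`,
#'   `rho` (NA if unknown), `subset`, `eta`, `ci_lower`, `ci_upper`,
#'   `ci_width`.
#' @export
predict_batch <- function(features, model, subsets = all_subsets(),
                          rho_step = 0.002, grid = radius_grid()) {
  if (!all(STAT_NAMES %in% names(features))) {
    features <- compute_features_batch(features, grid)
  }
  n <- nrow(features)
  rows <- vector("list", n * length(subsets))
  skipped <- 0L
  k <- 0L
  for (i in seq_len(n)) {
    x <- as.list(features[i, STAT_NAMES])
    if (anyNA(x)) { skipped <- skipped + 1L; next }
    for (ss in subsets) {
      est <- tryCatch(estimate_rho(x, model, ss, rho_step),
                      error = function(e) NULL)
      if (is.null(est)) { skipped <- skipped + 1L; next }
      k <- k + 1L
      rows[[k]] <- data.frame(
        pattern_id = if ("pattern_id" %in% names(features))
          features$pattern_id[i] else sprintf("p%06d", i),
        rho = if ("rho" %in% names(features)) features$rho[i] else NA_real_,
        subset = ss, eta = est$eta, ci_lower = est$ci_lower,
        ci_upper = est$ci_upper,
        ci_width = est$ci_upper - est$ci_lower)
    }
  }
  if (skipped > 0L) message(sprintf("predict_batch: skipped %d estimation(s)",
                                    skipped))
  out <- do.call(rbind, rows[seq_len(k)])
  attr(out, "skipped") <- skipped
  out
}
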