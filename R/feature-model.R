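# Canonical order of the summary statistics and their one-letter codes.
STAT_NAMES <- c(g = "g_max", F = "F_max", J = "J_min")

# Translate a subset label such as "gFJ" into statistic names.
parse_subset <- function(subset) {
  letters_in <- strsplit(subset, "")[[1]]
  bad <- setdiff(letters_in, names(STAT_NAMES))
  if (length(bad) || length(letters_in) == 0L) {
    stop("subset must be a non-empty combination of 'g', 'F', 'J'",
         call. = FALSE)
  }
  # canonical g, F, J ordering regardless of input order
  unname(STAT_NAMES[names(STAT_NAMES) %in% letters_in])
}

#' All seven statistic subsets
#'
#' @return Character vector `c("g","F","J","gF","gJ","FJ","gFJ")`.
#' @export
all_subsets <- function() c("g", "F", "J", "gF", "gJ", "FJ", "gFJ")

# Evaluate a * exp(-b * rho) + c.
eval_exp_curve <- function(curve, rho) {
  curve[["a"]] * exp(-curve[["b"]] * rho) + curve[["c"]]
}

# Least-squares fit of y = a*exp(-b*rho) + c by profiling b: for fixed
# b the problem is linear in (a, c), so a 1-D search over log(b)
# (multi-start + golden-section polish) always converges and is exact
# for noiseless model data.
fit_exp_curve <- function(rho, y) {
  stopifnot(length(rho) == length(y), length(unique(rho)) >= 2L)
  if (sd(y) < 1e-14) {
    return(c(a = 0, b = 0, c = mean(y)))
  }
  rss_for <- function(logb) {
    b <- exp(logb)
    X <- cbind(exp(-b * rho), 1)
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  coef_for <- function(logb) {
    b <- exp(logb)
    X <- cbind(exp(-b * rho), 1)
    fit <- lm.fit(X, y)
    c(a = unname(fit$coefficients[1]), b = b,
      c = unname(fit$coefficients[2]))
  }
  starts <- log(c(0.05, 0.2, 0.5, 1, 2, 4, 8, 16, 32, 64))
  best <- NULL
  for (s in starts) {
    opt <- optimise(rss_for, interval = c(s - 1.5, s + 1.5))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  # polish around the best start
  opt <- optimise(rss_for, interval = c(best$minimum - 1.5, best$minimum + 1.5),
                  tol = 1e-12)
  if (opt$objective < best$objective) best <- opt
  cf <- coef_for(best$minimum)
  if (anyNA(cf) || any(!is.finite(cf))) {
    stop("exponential fit failed to converge", call. = FALSE)
  }
  cf
}

# Floor the eigenvalues of a correlation matrix to keep it positive
# definite, then renormalise the diagonal to 1.
repair_psd <- function(C, floor = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) > floor) return(C)
  v <- pmax(e$values, floor)
  C2 <- e$vectors %*% diag(v, nrow = length(v)) %*% t(e$vectors)
  d <- sqrt(diag(C2))
  C2 <- C2 / outer(d, d)
  (C2 + t(C2)) / 2
}

#' Fit exponential mean and SD curves per summary statistic
#'
#' For each statistic (g_max, F_max, J_min), the per-rho ensemble means
#' and SDs are each fitted with the three-parameter exponential
#' `a * exp(-b * rho) + c` by profiled least squares.  If a fitted SD
#' curve is not strictly positive on [0, 0.5], that statistic falls back
#' to linear interpolation of the empirical SDs (with a warning).
#'
#' @param features Data frame with columns `rho`, `g_max`, `F_max`,
#'   `J_min` (one row per training pattern).
#' @param rho_grid Optional training grid; defaults to the sorted unique
#'   `rho` values present.
#' @return An object of class `feature_model` (without correlation
#'   structure; see [train_feature_model()] for the full model).
#' @export
fit_feature_curves <- function(features, rho_grid = NULL) {
  stopifnot(all(c("rho", STAT_NAMES) %in% names(features)))
  if (is.null(rho_grid)) rho_grid <- sort(unique(features$rho))
  if (length(rho_grid) < 2L) {
    stop("need at least 2 distinct rho values to fit curves", call. = FALSE)
  }
  grp <- match(features$rho, rho_grid)
  if (anyNA(grp)) stop("features contain rho values off the training grid",
                       call. = FALSE)
  counts <- tabulate(grp, nbins = length(rho_grid))
  if (any(counts < 30L)) {
    warning("fewer than 30 observations at some rho grid points; ",
            "mean/SD estimates may be noisy")
  }
  mean_curves <- sd_curves <- list()
  emp_means <- emp_sds <- matrix(NA_real_, length(rho_grid), length(STAT_NAMES),
                                 dimnames = list(NULL, STAT_NAMES))
  for (s in STAT_NAMES) {
    mu <- tapply(features[[s]], grp, mean)
    sg <- tapply(features[[s]], grp, sd)
    emp_means[, s] <- mu
    emp_sds[, s] <- sg
    mean_curves[[s]] <- tryCatch(fit_exp_curve(rho_grid, as.numeric(mu)),
                                 error = function(e)
                                   stop("mean-curve fit failed for ", s, ": ",
                                        conditionMessage(e), call. = FALSE))
    sd_fit <- tryCatch(fit_exp_curve(rho_grid, as.numeric(sg)),
                       error = function(e) NULL)
    dense <- seq(0, 0.5, by = 0.005)
    if (is.null(sd_fit) ||
        any(eval_exp_curve(sd_fit, dense) <= 0)) {
      warning("SD curve for ", s,
              " not positive on [0, 0.5]; using interpolated empirical SDs")
      sd_curves[[s]] <- list(type = "interp", rho = rho_grid,
                             sd = as.numeric(sg))
    } else {
      sd_curves[[s]] <- c(list(type = "exp"), as.list(sd_fit))
    }
  }
  structure(list(stats = unname(STAT_NAMES),
                 mean_curves = mean_curves, sd_curves = sd_curves,
                 rho_grid = rho_grid,
                 empirical = list(means = emp_means, sds = emp_sds,
                                  n = counts),
                 correlations = NULL,
                 meta = list(n_patterns = nrow(features))),
            class = "feature_model")
}

#' Empirical feature correlations per training rho
#'
#' Pearson correlation matrices of (g_max, F_max, J_min) computed at
#' each training rho grid point; off-grid rho values use the nearest
#' grid point.  Non-positive-definite matrices are repaired by flooring
#' eigenvalues (with a warning).
#'
#' @param features Training feature table with a `rho` column.
#' @param rho_grid Training grid (default: unique rho values present).
#' @param on_constant What to do when a feature is constant at a grid
#'   point (its correlation is undefined): `"error"` (default) or
#'   `"zero"`, which substitutes independence for the affected pairs
#'   with a warning (used by [train_feature_model()], since a feature
#'   with no variance carries no correlation information).
#' @return A 3 x 3 x length(rho_grid) array of correlation matrices.
#' @export
estimate_correlation <- function(features, rho_grid = NULL,
                                 on_constant = c("error", "zero")) {
  stopifnot(all(c("rho", STAT_NAMES) %in% names(features)))
  on_constant <- match.arg(on_constant)
  if (is.null(rho_grid)) rho_grid <- sort(unique(features$rho))
  grp <- match(features$rho, rho_grid)
  out <- array(NA_real_, c(3, 3, length(rho_grid)),
               dimnames = list(unname(STAT_NAMES), unname(STAT_NAMES), NULL))
  for (k in seq_along(rho_grid)) {
    sub <- features[which(grp == k), STAT_NAMES, drop = FALSE]
    if (nrow(sub) < 3L) {
      stop("need at least 3 observations per rho grid point for correlations",
           call. = FALSE)
    }
    const <- vapply(sub, sd, numeric(1)) < 1e-14
    if (any(const)) {
      if (on_constant == "error") {
        stop("constant feature column at rho = ", rho_grid[k],
             ": correlation undefined", call. = FALSE)
      }
      warning("constant feature column at rho = ", rho_grid[k],
              "; treating its correlations as zero")
    }
    C <- diag(3)
    dimnames(C) <- list(unname(STAT_NAMES), unname(STAT_NAMES))
    ok <- !const
    if (sum(ok) >= 2L) {
      C[ok, ok] <- cor(as.matrix(sub[, ok, drop = FALSE]))
    }
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-6) {
      warning("correlation matrix at rho = ", rho_grid[k],
              " near-singular; applying eigenvalue floor")
      C <- repair_psd(C)
    }
    out[, , k] <- C
  }
  out
}

#' Train the full feature model
#'
#' Combines [fit_feature_curves()] and [estimate_correlation()]: the
#' covariance at any rho is assembled as `D(rho) C(rho) D(rho)` with
#' `D` the diagonal of fitted SDs and `C` the empirical correlation at
#' the nearest training grid point.
#'
#' @inheritParams fit_feature_curves
#' @param meta Optional named list merged into the model metadata
#'   (e.g. reps, master seed).
#' @return A `feature_model` with correlation structure.
#' @export
train_feature_model <- function(features, rho_grid = NULL, meta = list()) {
  model <- fit_feature_curves(features, rho_grid)
  model$correlations <- estimate_correlation(features, model$rho_grid,
                                             on_constant = "zero")
  model$meta <- c(model$meta, meta,
                  list(version = as.character(utils::packageVersion("immunospat"))))
  model
}

#' @export
print.feature_model <- function(x, ...) {
  cat("feature_model\n")
  for (s in x$stats) {
    cf <- x$mean_curves[[s]]
    cat(sprintf("  %-6s mean: %.3f * exp(-%.3f rho) + %.3f\n",
                s, cf[["a"]], cf[["b"]], cf[["c"]]))
  }
  cat(sprintf("  trained on %d patterns over %d rho grid points%s\n",
              x$meta$n_patterns %||% NA, length(x$rho_grid),
              if (is.null(x$correlations)) " (no correlation structure)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Model mean for one statistic at rho (vectorised over rho).
model_mean <- function(model, stat, rho) {
  eval_exp_curve(model$mean_curves[[stat]], rho)
}

# Model SD for one statistic at rho (vectorised over rho).
model_sd <- function(model, stat, rho) {
  sc <- model$sd_curves[[stat]]
  if (identical(sc$type, "interp")) {
    approx(sc$rho, sc$sd, xout = rho, rule = 2)$y
  } else {
    eval_exp_curve(c(a = sc$a, b = sc$b, c = sc$c), rho)
  }
}

# Index of the nearest training grid point for each rho.
nearest_grid_index <- function(model, rho) {
  vapply(rho, function(r) which.min(abs(model$rho_grid - r)), integer(1))
}

#' Serialise a feature model to a structured text file
#'
#' Versioned JSON schema storing the exponential parameter triples, the
#' training grid, per-grid-point correlation matrices and metadata.
#'
#' @param model A `feature_model`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_model <- function(model, path) {
  stopifnot(inherits(model, "feature_model"))
  payload <- list(
    schema = "immunospat-feature-model/1",
    stats = model$stats,
    mean_curves = lapply(model$mean_curves, as.list),
    sd_curves = model$sd_curves,
    rho_grid = model$rho_grid,
    correlations = if (is.null(model$correlations)) NULL else
      apply(model$correlations, 3, identity, simplify = FALSE),
    empirical = list(means = model$empirical$means,
                     sds = model$empirical$sds, n = model$empirical$n),
    meta = model$meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialised feature model
#'
#' @param path Path written by [write_feature_model()].
#' @return A `feature_model`.
#' @export
read_feature_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "immunospat-feature-model/1")) {
    stop("unrecognised model schema in ", path, call. = FALSE)
  }
  G <- length(payload$rho_grid)
  corr <- NULL
  if (!is.null(payload$correlations)) {
    corr <- array(NA_real_, c(3, 3, G),
                  dimnames = list(payload$stats, payload$stats, NULL))
    # jsonlite simplifies the list of matrices to a G x 3 x 3 array;
    # fall back to list indexing if simplification did not trigger
    pc <- payload$correlations
    for (k in seq_len(G)) {
      corr[, , k] <- if (is.list(pc)) as.matrix(pc[[k]]) else
        matrix(pc[k, , ], 3, 3)
    }
  }
  mean_curves <- lapply(payload$mean_curves, function(l) unlist(l))
  sd_curves <- lapply(payload$sd_curves, function(l) {
    if (identical(l$type, "interp")) {
      list(type = "interp", rho = as.numeric(l$rho), sd = as.numeric(l$sd))
    } else {
      list(type = "exp", a = l$a, b = l$b, c = l$c)
    }
  })
  emp_means <- as.matrix(payload$empirical$means)
  emp_sds <- as.matrix(payload$empirical$sds)
  colnames(emp_means) <- colnames(emp_sds) <- payload$stats
  structure(list(stats = payload$stats, mean_curves = mean_curves,
                 sd_curves = sd_curves,
                 rho_grid = as.numeric(payload$rho_grid),
                 empirical = list(means = emp_means, sds = emp_sds,
                                  n = payload$empirical$n),
                 correlations = corr, meta = payload$meta),
            class = "feature_model")
}
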