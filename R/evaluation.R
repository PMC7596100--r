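#' Coefficient of determination about the identity line
#'
#' `R^2 = 1 - sum((eta - rho)^2) / sum((rho - mean(rho))^2)`: residuals
#' are measured about the line `rho = eta`, the total sum of squares
#' about the mean of the true values.  May be negative for predictors
#' worse than the constant mean.
#'
#' @param true True parameter values.
#' @param predicted Predicted values (same length).
#' @return The R^2 value.
#' @export
r_squared_identity <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length", call. = FALSE)
  }
  if (length(true) < 2L) stop("need at least 2 observations", call. = FALSE)
  tss <- sum((true - mean(true))^2)
  if (tss <= 0) stop("true values have zero variance", call. = FALSE)
  1 - sum((predicted - true)^2) / tss
}

#' Per-subset validation report
#'
#' Summarises a [predict_batch()] table (which must contain the true
#' `rho`) into per-subset R^2 (about the identity line), mean 95% CI
#' width and pattern count.
#'
#' @param predictions Data frame from [predict_batch()] with a non-NA
#'   `rho` column.
#' @return An object of class `validation_report`: list with `summary`
#'   (data frame: subset, r_squared, mean_ci_width, n_patterns) and
#'   `scatter` (the input table).
#' @export
validation_report <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    stop("empty predictions table", call. = FALSE)
  }
  if (!"rho" %in% names(predictions) || all(is.na(predictions$rho))) {
    stop("predictions lack true rho values", call. = FALSE)
  }
  subsets <- unique(predictions$subset)
  rows <- lapply(subsets, function(ss) {
    sub <- predictions[predictions$subset == ss & !is.na(predictions$rho), ]
    data.frame(subset = ss,
               r_squared = r_squared_identity(sub$rho, sub$eta),
               mean_ci_width = mean(sub$ci_width),
               n_patterns = nrow(sub))
  })
  structure(list(summary = do.call(rbind, rows), scatter = predictions),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s R^2 = %7.4f  mean 95%% CI width = %.4f  (n = %d)\n",
                s$subset[i], s$r_squared[i], s$mean_ci_width[i],
                s$n_patterns[i]))
  }
  invisible(x)
}

#' Two-sided Welch t-test between feature groups
#'
#' Generic group-comparison convenience for feature tables (e.g.
#' comparing g_max between scoring categories).  Thin wrapper around
#' [stats::t.test()] with `var.equal = FALSE`.
#'
#' @param values Numeric vector of feature values.
#' @param groups Factor/vector of group labels (exactly 2 levels used).
#' @return An object of class `htest`.
#' @export
welch_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop("welch_test compares exactly two groups", call. = FALSE)
  }
  t.test(values ~ droplevels(groups), var.equal = FALSE)
}

#' Feature trends and fitted exponential curves (advisory plot)
#'
#' Plots per-rho ensemble means (+/- SD) of g_max, F_max and J_min with
#' the fitted exponential mean curves overlaid.
#'
#' @param model A trained `feature_model`.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_feature_trends <- function(model) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  grid <- seq(0, 0.5, by = 0.005)
  emp <- do.call(rbind, lapply(model$stats, function(s) {
    data.frame(stat = s, rho = model$rho_grid,
               mean = model$empirical$means[, s],
               sd = model$empirical$sds[, s])
  }))
  fit <- do.call(rbind, lapply(model$stats, function(s) {
    data.frame(stat = s, rho = grid, mean = model_mean(model, s, grid))
  }))
  ggplot2::ggplot(emp, ggplot2::aes(x = rho, y = mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0.005, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = expression(rho), y = "feature value")
}

#' Predicted vs true infiltration ratio (advisory plot)
#'
#' Scatter of eta against true rho per subset, coloured by CI width,
#' with the identity line.
#'
#' @param predictions A [predict_batch()] table with true `rho`.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_validation <- function(predictions) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = rho, y = eta, colour = ci_width)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~subset) +
    ggplot2::coord_equal(xlim = c(0, 0.5), ylim = c(0, 0.5)) +
    ggplot2::labs(x = expression(rho), y = expression(eta),
                  colour = "95% CI width")
}

#' Read a run configuration file
#'
#' YAML configuration with sections `generation`, `features`, `training`
#' and `inference`; missing keys fall back to the package defaults.
#'
#' @param path Path to the YAML file (or `NULL` for pure defaults).
#' @return A nested list with all keys populated.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    generation = list(rho_grid = seq(0, 0.5, by = 0.02), reps = 1200L,
                      l_range = c(0.1, 0.75),
                      density = list(mean = 333, sd = 170, min = 150),
                      exclusion_radius = 0.02,
                      window = c(1.5, 1.5), resolution = 256L),
    features = list(dr = 0.005, r_max = 0.75),
    training = list(),
    inference = list(rho_step = 0.002, subsets = all_subsets()),
    seed = 1L)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_lists <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) {
        merge_lists(a[[k]], b[[k]])
      } else {
        b[[k]]
      }
    }
    a
  }
  merge_lists(defaults, user)
}
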