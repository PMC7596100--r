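#' Rectangular observation window
#'
#' Defines the rectangular region of interest (ROI) containing a point
#' pattern.  The origin is fixed at (0, 0); the default 1.5 mm x 1.5 mm
#' window matches the tile size commonly used for stained tumour sections.
#'
#' @param width Window width in mm (> 0).
#' @param height Window height in mm (> 0).
#' @return An object of class `roi_window` with fields `width`, `height`
#'   and `area` (mm^2).
#' @examples
#' w <- roi_window()
#' w$area # 2.25
#' @export
roi_window <- function(width = 1.5, height = 1.5) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L, is.finite(width), is.finite(height))
  if (width <= 0 || height <= 0) {
    stop("window dimensions must be positive", call. = FALSE)
  }
  structure(list(width = width, height = height, area = width * height),
            class = "roi_window")
}

#' @export
print.roi_window <- function(x, ...) {
  cat(sprintf("roi_window: %g mm x %g mm (area %g mm^2), origin (0,0)\n",
              x$width, x$height, x$area))
  invisible(x)
}

#' Planar point pattern of cell centroids
#'
#' A set of (x, y) cell-centroid coordinates (mm) inside a rectangular
#' window.  Points exactly on the window boundary are accepted.
#'
#' @param x,y Numeric coordinate vectors of equal length (mm).
#' @param window An [roi_window()].
#' @param label Optional free-text label.
#' @return An object of class `point_pattern` with fields `x`, `y`,
#'   `n`, `window` and `label`.
#' @examples
#' p <- point_pattern(c(0.1, 0.5), c(0.2, 0.5), roi_window())
#' pattern_density(p)
#' @export
point_pattern <- function(x, y, window = roi_window(), label = NULL) {
  stopifnot(inherits(window, "roi_window"))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("coordinates must be non-missing", call. = FALSE)
  bad <- which(x < 0 | x > window$width | y < 0 | y > window$height)
  if (length(bad)) {
    stop(sprintf("point(s) outside window at row(s) %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(list(x = x, y = y, n = length(x), window = window,
                 label = label),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in %g x %g mm window (d = %.1f cells/mm^2)%s\n",
              x$n, x$window$width, x$window$height, pattern_density(x),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Cell density of a point pattern
#'
#' @param pattern A [point_pattern()].
#' @return Density n / area in cells per mm^2.
#' @export
pattern_density <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  pattern$n / pattern$window$area
}

#' Read a point pattern from a delimited text file
#'
#' Expects two numeric columns (x, y) in mm, comma-delimited, with an
#' optional single header line (auto-detected by a non-numeric first row).
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to the CSV file.
#' @param window An [roi_window()] the points must fall inside.
#' @return A [point_pattern()].
#' @export
read_pattern <- function(path, window = roi_window()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  has_header <- FALSE
  if (length(first)) {
    f1 <- strsplit(first[[1]], ",", fixed = TRUE)[[1]]
    has_header <- anyNA(suppressWarnings(as.numeric(f1[1:2])))
  }
  df <- read.csv(path, header = has_header, comment.char = "#",
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(point_pattern(numeric(0), numeric(0), window))
  }
  if (ncol(df) < 2L) stop("expected two columns (x,y) in ", path, call. = FALSE)
  xs <- suppressWarnings(as.numeric(df[[1]]))
  ys <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(xs) || anyNA(ys)) {
    stop(sprintf("non-numeric row(s) %s in %s",
                 paste(head(which(is.na(xs) | is.na(ys)), 5L), collapse = ", "),
                 path), call. = FALSE)
  }
  bad <- which(xs < 0 | xs > window$width | ys < 0 | ys > window$height)
  if (length(bad)) {
    stop(sprintf("point outside window in %s at row %d (x=%g, y=%g)",
                 path, bad[1L], xs[bad[1L]], ys[bad[1L]]), call. = FALSE)
  }
  point_pattern(xs, ys, window, label = basename(path))
}

#' Write a point pattern to CSV
#'
#' Coordinates are written with full double precision so that
#' `read_pattern(write_pattern(p))` round-trips exactly.
#'
#' @param pattern A [point_pattern()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- data.frame(x = pattern$x, y = pattern$y)
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("x,y", con)
    if (nrow(df)) {
      writeLines(paste(sprintf("%.17g", df$x), sprintf("%.17g", df$y), sep = ","),
                 con)
    }
    TRUE
  }, error = function(e) {
    stop("cannot write pattern to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest lists generated patterns, one row per pattern, with columns
#' `pattern_id`, `file`, `rho`, `l`, `d` and `seed`.  File paths are
#' interpreted relative to the manifest location.
#'
#' @param path Manifest CSV path.
#' @param check If `TRUE` (default), verify `pattern_id` uniqueness and
#'   that every referenced file exists.
#' @return A data.frame with an attribute `dir` holding the manifest
#'   directory.
#' @export
read_manifest <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pattern_id", "file", "rho", "l", "d", "seed")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (check) {
    if (anyDuplicated(df$pattern_id)) {
      stop("duplicate pattern_id in manifest", call. = FALSE)
    }
    paths <- file.path(dirname(path), df$file)
    gone <- !file.exists(paths)
    if (any(gone)) {
      stop("manifest references missing file(s): ",
           paste(head(df$file[gone], 3L), collapse = ", "), call. = FALSE)
    }
  }
  attr(df, "dir") <- dirname(path)
  df
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with the manifest columns (see
#'   [read_manifest()]).
#' @param path Output CSV path.
#' @param seed Master seed recorded in the provenance comment line.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path, seed = NA) {
  write_provenance_csv(manifest, path, seed = seed)
  invisible(path)
}

# CSV writer with a provenance comment line (version, seed, config hash).
write_provenance_csv <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("immunospat"))
  writeLines(sprintf("# immunospat %s seed=%s config_md5=%s", ver,
                     as.character(seed), as.character(config_hash)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# MD5 of a config list, via its canonical YAML rendering.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}
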