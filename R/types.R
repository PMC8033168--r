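#' Wavenumber axis
#'
#' A validated, strictly increasing wavenumber axis in cm^-1. All maps that
#' are pooled or compared must share one axis; the minimum length of 100
#' guarantees that the default Savitzky-Golay frame (99 channels) fits.
#'
#' @param values Numeric vector of wavenumbers (cm^-1), strictly increasing,
#'   length >= 100.
#' @return A numeric vector of class `wn_axis`.
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 100)
    stop("wavenumber axis must have at least 100 channels, got ",
         length(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("wavenumber axis must be finite")
  if (any(diff(values) <= 0))
    stop("wavenumber axis must be strictly increasing")
  structure(values, class = "wn_axis")
}

#' Default fingerprint wavenumber axis
#'
#' 600 to 1800 cm^-1 at 1 cm^-1 spacing (1201 channels), covering the
#' fingerprint bands used for segmentation and classification, including the
#' nucleic-acid doublet at 752/786 cm^-1.
#'
#' @return A `wn_axis`.
#' @export
default_axis <- function() wn_axis(seq(600, 1800, by = 1))

axis_window <- function(axis, lo, hi) {
  idx <- which(axis >= lo & axis <= hi)
  idx
}

#' Hyperspectral single-cell Raman map
#'
#' Container for one cell's map: a `height x width x channels` intensity
#' cube on a shared wavenumber axis, with a condition label and the pixel
#' size in micrometres. Pixel coordinates are 0-based, row-major (row, col).
#'
#' @param cube Numeric array `height x width x channels`, finite.
#' @param axis A [wn_axis()] whose length matches `dim(cube)[3]`.
#' @param map_id Character scalar identifier.
#' @param condition Condition label, `"D0"` or `"D4"`.
#' @param pixel_size Pixel pitch in micrometres (> 0), default 0.2.
#' @return An object of class `hyper_map`.
#' @export
hyper_map <- function(cube, axis, map_id, condition = c("D0", "D4"),
                      pixel_size = 0.2) {
  condition <- match.arg(condition)
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  if (length(dim(cube)) != 3L)
    stop("cube must be a 3-d array (height x width x channels)")
  if (dim(cube)[3] != length(axis))
    stop("cube has ", dim(cube)[3], " channels but axis has ", length(axis))
  if (anyNA(cube) || any(!is.finite(cube)))
    stop("cube intensities must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar")
  structure(list(map_id = as.character(map_id), condition = condition,
                 height = dim(cube)[1], width = dim(cube)[2],
                 pixel_size = pixel_size, cube = cube, axis = axis),
            class = "hyper_map")
}

#' @export
print.hyper_map <- function(x, ...) {
  cat(sprintf("<hyper_map %s> %s, %dx%d px @ %.3g um, %d channels (%g-%g cm-1)\n",
              x$map_id, x$condition, x$height, x$width, x$pixel_size,
              length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Flatten a map's cube to a pixel-by-channel matrix
#'
#' Rows are pixels in row-major order: pixel (r, c) (0-based) maps to matrix
#' row `r * width + c + 1`.
#'
#' @param map A `hyper_map`.
#' @return Numeric matrix, `height*width` rows.
#' @export
map_spectra <- function(map) {
  stopifnot(inherits(map, "hyper_map"))
  h <- map$height; w <- map$width; C <- length(map$axis)
  # aperm so that row-major pixel order is preserved when unrolling
  m <- matrix(aperm(map$cube, c(2, 1, 3)), nrow = h * w, ncol = C)
  m
}

#' Transcript read-count matrix
#'
#' Nonnegative integer counts, transcripts in rows and samples in columns,
#' with one condition label per sample and at least two samples per
#' condition.
#'
#' @param counts Integer matrix with rownames (transcript ids) and colnames
#'   (sample ids).
#' @param conditions Character vector of condition labels, one per sample.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, conditions) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry transcript rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate transcript ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  if (length(conditions) != ncol(counts))
    stop("one condition label per sample required")
  if (any(table(conditions) < 2))
    stop("each condition needs at least 2 samples")
  storage.mode(counts) <- "double"   # keeps >2^31 safe; values are integral
  structure(list(counts = counts, conditions = stats::setNames(
    as.character(conditions), colnames(counts))), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcripts x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
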