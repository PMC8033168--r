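## Common k-means segmentation: spectra from all maps are pooled and
## clustered jointly so cluster identities are shared across cells, cluster
## centroids are assigned to compartments from marker band scores, per-map
## compartment mean spectra are extracted, small/empty nuclei are discarded,
## and a 3-step Savitzky-Golay background subtraction is applied.

#' Pool pixel spectra from a list of maps
#'
#' Stacks every pixel spectrum of every map into one matrix (rows =
#' pixels), with an index mapping each row back to (map_id, row, col);
#' pixel coordinates are 0-based, row-major. All maps must share one
#' wavenumber axis.
#'
#' @param maps List of [hyper_map()].
#' @return List with `spectra` (matrix), `index` (data.frame `map_id`,
#'   `row`, `col`), and the shared `axis`.
#' @export
pool_spectra <- function(maps) {
  if (length(maps) == 0) stop("no maps to pool")
  axis <- maps[[1]]$axis
  for (m in maps) {
    if (length(m$axis) != length(axis) ||
        any(abs(as.numeric(m$axis) - as.numeric(axis)) > 1e-9))
      stop("maps do not share a wavenumber axis (map ", m$map_id,
           "); refusing to pool")
  }
  mats <- lapply(maps, map_spectra)
  idx <- do.call(rbind, lapply(maps, function(m) {
    data.frame(map_id = m$map_id,
               row = rep(0:(m$height - 1), each = m$width),
               col = rep(0:(m$width - 1), times = m$height),
               stringsAsFactors = FALSE)
  }))
  rownames(idx) <- NULL
  list(spectra = do.call(rbind, mats), index = idx, axis = axis)
}

# k-means++ seeding on rows of x; errors if k distinct centers cannot be
# found (k exceeds the number of distinct spectra).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  if (k > 1) for (j in 2:k) {
    tot <- sum(d2)
    if (tot <= 0)
      stop("k exceeds the number of distinct spectra (", j - 1,
           " distinct found)")
    centers[j] <- sample.int(n, 1, prob = d2 / tot)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ])^2))
  }
  x[centers, , drop = FALSE]
}

# One Lloyd run from given centroids; asserts the inertia never increases
# across iterations.
lloyd <- function(x, cent, max_iter, tol) {
  rs_x <- rowSums(x^2)
  inertia_prev <- Inf
  lab <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d <- sweep(-2 * x %*% t(cent), 2, rowSums(cent^2), "+")
    lab_new <- max.col(-d, ties.method = "first")
    inertia <- sum(rs_x + d[cbind(seq_len(nrow(x)), lab_new)])
    if (inertia > inertia_prev * (1 + 1e-8) + 1e-8)
      stop("internal error: k-means inertia increased (",
           inertia_prev, " -> ", inertia, ")")
    sizes <- tabulate(lab_new, nrow(cent))
    if (any(sizes == 0)) {
      # re-seed each empty cluster at the currently worst-fit point
      for (j in which(sizes == 0)) {
        far <- which.max(rs_x + d[cbind(seq_len(nrow(x)), lab_new)])
        cent[j, ] <- x[far, ]
        lab_new[far] <- j
        sizes <- tabulate(lab_new, nrow(cent))
      }
    }
    cent <- rowsum(x, lab_new, reorder = TRUE) /
      tabulate(lab_new, nrow(cent))
    converged <- identical(lab_new, lab) ||
      (is.finite(inertia_prev) && (inertia_prev - inertia) <= tol * inertia)
    lab <- lab_new
    inertia_prev <- inertia
    if (converged) break
  }
  list(centroids = cent, labels = lab, inertia = inertia_prev,
       iterations = it)
}

#' Common k-means clustering of pooled spectra
#'
#' Lloyd's algorithm with squared Euclidean distance, k-means++ seeding and
#' `n_init` restarts (best inertia kept), applied jointly to the pooled
#' spectra of all maps so that the k centroids are shared across cells.
#' Deterministic given `seed`. With `subsample`, centroids are fitted on a
#' random pixel subset for speed and then polished by full-data Lloyd
#' iterations, so the returned centroids are still the means of their
#' full-data members.
#'
#' @param pooled Output of [pool_spectra()] (or a bare spectrum matrix).
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per start.
#' @param tol Relative inertia-change convergence tolerance.
#' @param subsample Optional number of pixels to fit on (`NULL` = all).
#' @return Object of class `cluster_model`: `k`, `centroids`, `labels`
#'   (one per pooled row), `index`, `inertia`, `seed`, `n_init`,
#'   `iterations`, `axis`.
#' @export
common_kmeans <- function(pooled, k = 10, seed = 1L, n_init = 10,
                          max_iter = 100, tol = 1e-10, subsample = NULL) {
  x <- if (is.list(pooled)) pooled$spectra else pooled
  index <- if (is.list(pooled)) pooled$index else NULL
  axis <- if (is.list(pooled)) pooled$axis else NULL
  if (k < 1) stop("k must be >= 1")
  if (nrow(x) < k) stop("fewer spectra than clusters")
  fit_rows <- seq_len(nrow(x))
  res <- with_seed(seed, {
    if (!is.null(subsample) && subsample < nrow(x))
      fit_rows <- sample.int(nrow(x), subsample)
    xf <- x[fit_rows, , drop = FALSE]
    best <- NULL
    for (i in seq_len(n_init)) {
      r <- lloyd(xf, kmeanspp_init(xf, k), max_iter, tol)
      if (is.null(best) || r$inertia < best$inertia) best <- r
    }
    best
  })
  iterations <- res$iterations
  if (length(fit_rows) < nrow(x)) {
    res <- lloyd(x, res$centroids, max_iter, tol)
    iterations <- iterations + res$iterations
  }
  structure(list(k = k, centroids = res$centroids,
                 labels = res$labels, index = index,
                 inertia = res$inertia, seed = seed, n_init = n_init,
                 iterations = iterations, axis = axis),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, %d spectra, inertia %.4g (%d iterations)\n",
              x$k, length(x$labels), x$inertia, x$iterations))
  invisible(x)
}

#' Assign k-means clusters to compartments
#'
#' Each centroid gets a cell-signal score (mean intensity in `signal_band`
#' minus the mean in the quiet band) and a nucleic-acid marker score (same,
#' for `nucleic_band`, default 786 +/- 4 cm^-1). Clusters whose signal is
#' below `bg_frac` of the maximum are background. Remaining clusters are
#' split into nucleus and cytoplasm on the marker score: by default at the
#' largest gap in the sorted scores (`method = "gap"`); `method = "count"`
#' takes the top `n_nucleus` (default: top tercile). A manual `override`
#' takes precedence over everything.
#'
#' @param model A [common_kmeans()] `cluster_model`.
#' @param axis Wavenumber axis (taken from the model when `NULL`).
#' @param nucleic_band,signal_band,quiet_band Band limits in cm^-1.
#' @param bg_frac Background threshold as a fraction of the maximum signal.
#' @param method `"gap"` or `"count"` for the nucleus/cytoplasm split.
#' @param n_nucleus Number of nucleus clusters for `method = "count"`.
#' @param override Named character vector, e.g. `c("3" = "nucleus")`,
#'   forcing cluster index -> compartment.
#' @return Object of class `compartment_assignment`: `mapping` (character
#'   vector of length k, values nucleus/cytoplasm/background) and `scores`.
#' @export
assign_compartments <- function(model, axis = NULL,
                                nucleic_band = c(782, 790),
                                signal_band = c(1420, 1480),
                                quiet_band = c(1780, 1800),
                                bg_frac = 0.25,
                                method = c("gap", "count"),
                                n_nucleus = NULL, override = NULL) {
  method <- match.arg(method)
  axis <- axis %||% model$axis
  if (is.null(axis)) stop("a wavenumber axis is required")
  band_mean <- function(band) {
    idx <- axis_window(axis, band[1], band[2])
    if (length(idx) == 0) stop("band ", band[1], "-", band[2],
                               " cm-1 contains no channels")
    rowMeans(model$centroids[, idx, drop = FALSE])
  }
  quiet <- band_mean(quiet_band)
  signal <- band_mean(signal_band) - quiet
  marker <- band_mean(nucleic_band) - quiet
  if (max(signal) <= 0)
    stop("degenerate segmentation: all clusters classified as background")
  mapping <- rep("cytoplasm", model$k)
  mapping[signal < bg_frac * max(signal)] <- "background"
  nonbg <- which(mapping != "background")
  if (length(nonbg) == 0)
    stop("degenerate segmentation: all clusters classified as background")
  mk <- marker[nonbg]
  nuc <- if (method == "count" || !is.null(n_nucleus)) {
    nn <- n_nucleus %||% ceiling(length(nonbg) / 3)
    nonbg[order(mk, decreasing = TRUE)][seq_len(min(nn, length(nonbg) - 1))]
  } else if (length(nonbg) >= 2) {
    o <- order(mk)
    gaps <- diff(mk[o])
    if (max(gaps) > 0) nonbg[o][seq(which.max(gaps) + 1, length(o))]
    else integer(0)
  } else integer(0)
  mapping[nuc] <- "nucleus"
  if (!is.null(override)) {
    ci <- as.integer(names(override))
    if (any(is.na(ci)) || any(ci < 1 | ci > model$k))
      stop("override cluster indices must be in 1..k")
    mapping[ci] <- as.character(override)
  }
  if (!all(mapping %in% c("nucleus", "cytoplasm", "background")))
    stop("override compartments must be nucleus, cytoplasm or background")
  structure(list(mapping = mapping,
                 scores = data.frame(cluster = seq_len(model$k),
                                     signal = signal, marker = marker,
                                     compartment = mapping)),
            class = "compartment_assignment")
}

#' Per-map compartment mean spectra
#'
#' Averages each map's pixel spectra within nucleus, cytoplasm and
#' background as labelled by the cluster model + assignment; the whole-cell
#' mean is recomputed over the union of nucleus and cytoplasm pixels (so it
#' is the pixel-count-weighted mean of the two compartment means). An
#' absent compartment yields a zero pixel count and no spectrum.
#'
#' @param map A [hyper_map()] that was part of the clustered pool.
#' @param model A `cluster_model` with an index.
#' @param assignment A [assign_compartments()] result.
#' @return Object of class `compartment_spectra`: `map_id`, `condition`,
#'   `means` (list nucleus/cytoplasm/whole_cell/background), `counts`,
#'   `axis`, `pixel_size`, `corrected = FALSE`.
#' @export
extract_compartment_spectra <- function(map, model, assignment) {
  if (is.null(model$index)) stop("cluster model carries no pixel index")
  rows <- which(model$index$map_id == map$map_id)
  if (length(rows) == 0) stop("map ", map$map_id, " not present in cluster model")
  comp <- assignment$mapping[model$labels[rows]]
  sp <- map_spectra(map)   # same row-major order as pool_spectra
  means <- list()
  counts <- c(nucleus = 0L, cytoplasm = 0L, whole_cell = 0L, background = 0L)
  for (cm in c("nucleus", "cytoplasm", "background")) {
    sel <- comp == cm
    counts[cm] <- sum(sel)
    means[[cm]] <- if (any(sel)) colMeans(sp[sel, , drop = FALSE]) else NULL
  }
  cell <- comp %in% c("nucleus", "cytoplasm")
  counts["whole_cell"] <- sum(cell)
  means$whole_cell <- if (any(cell)) colMeans(sp[cell, , drop = FALSE]) else NULL
  structure(list(map_id = map$map_id, condition = map$condition,
                 means = means, counts = counts, axis = map$axis,
                 pixel_size = map$pixel_size, corrected = FALSE),
            class = "compartment_spectra")
}

#' Quality-control filter on segmented maps
#'
#' Discards maps with no nucleus or no cytoplasm pixels, and maps whose
#' nucleus equivalent-circle diameter `2 * pixel_size * sqrt(A_px / pi)`
#' falls strictly below `min_diameter` (default 3 um). Maps at or above the
#' threshold are retained.
#'
#' @param spectra_list List of [extract_compartment_spectra()] results.
#' @param min_diameter Minimum nucleus equivalent diameter in micrometres.
#' @return A `qc_report` data.frame: `map_id`, `condition`, `retained`,
#'   `reason` (ok / no_compartment_pixels / nucleus_too_small),
#'   `nucleus_diameter_um`, pixel counts.
#' @export
qc_filter <- function(spectra_list, min_diameter = 3) {
  rows <- lapply(spectra_list, function(cs) {
    dia <- 2 * cs$pixel_size * sqrt(cs$counts[["nucleus"]] / pi)
    reason <- if (cs$counts[["nucleus"]] == 0 || cs$counts[["cytoplasm"]] == 0)
      "no_compartment_pixels"
    else if (dia < min_diameter) "nucleus_too_small"
    else "ok"
    data.frame(map_id = cs$map_id, condition = cs$condition,
               retained = reason == "ok", reason = reason,
               nucleus_diameter_um = dia,
               nucleus_px = cs$counts[["nucleus"]],
               cytoplasm_px = cs$counts[["cytoplasm"]],
               background_px = cs$counts[["background"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Three-step background subtraction
#'
#' (1) Subtract from each compartment mean spectrum (nucleus, cytoplasm,
#' whole cell, and the background itself) its offset, the mean intensity in
#' the offset band (default 1780-1840 cm^-1, intersected with the axis).
#' (2) Smooth the offset-corrected background with a Savitzky-Golay filter
#' (default order 2, frame length 99). (3) Subtract the smoothed background
#' from the offset-corrected nucleus, cytoplasm and whole-cell spectra.
#'
#' @param cs A [extract_compartment_spectra()] result with a background
#'   spectrum.
#' @param offset_band Length-2 band limits in cm^-1.
#' @param sg_order,sg_frame Savitzky-Golay polynomial order and (odd) frame
#'   length.
#' @return `cs` with corrected `means`, `corrected = TRUE`, raw spectra
#'   kept in `$raw`, and the smoothed background in `$background_smoothed`.
#' @export
subtract_background <- function(cs, offset_band = c(1780, 1840),
                                sg_order = 2, sg_frame = 99) {
  stopifnot(inherits(cs, "compartment_spectra"))
  if (sg_frame %% 2 != 1 || sg_frame > length(cs$axis))
    stop("sg_frame must be odd and no longer than the axis")
  idx <- axis_window(cs$axis, offset_band[1], offset_band[2])
  if (length(idx) == 0)
    stop("offset band ", offset_band[1], "-", offset_band[2],
         " cm-1 contains no channels")
  if (is.null(cs$means$background))
    stop("map ", cs$map_id, " has no background spectrum to subtract")
  off <- function(s) s - mean(s[idx])
  bg0 <- off(cs$means$background)
  bg_s <- signal::sgolayfilt(bg0, p = sg_order, n = sg_frame)
  out <- cs
  out$raw <- cs$means
  for (cm in c("nucleus", "cytoplasm", "whole_cell"))
    if (!is.null(cs$means[[cm]])) out$means[[cm]] <- off(cs$means[[cm]]) - bg_s
  out$means$background <- bg0
  out$background_smoothed <- bg_s
  out$corrected <- TRUE
  out
}

#' Segment a cohort end to end
#'
#' Pools all maps, runs common k-means, assigns compartments, extracts
#' per-map compartment spectra, applies QC and, optionally, the 3-step
#' background subtraction to retained maps.
#'
#' @param maps List of [hyper_map()].
#' @param k,seed,n_init,subsample Passed to [common_kmeans()].
#' @param min_diameter Passed to [qc_filter()].
#' @param correct Apply [subtract_background()] to retained maps.
#' @param ... Passed to [assign_compartments()].
#' @return List: `model`, `assignment`, `spectra` (per-map list, corrected
#'   where retained), `qc`.
#' @export
segment_cohort <- function(maps, k = 10, seed = 1L, n_init = 10,
                           subsample = NULL, min_diameter = 3,
                           correct = TRUE, ...) {
  pooled <- pool_spectra(maps)
  model <- common_kmeans(pooled, k = k, seed = seed, n_init = n_init,
                         subsample = subsample)
  assignment <- assign_compartments(model, ...)
  spectra <- lapply(maps, extract_compartment_spectra, model = model,
                    assignment = assignment)
  qc <- qc_filter(spectra, min_diameter = min_diameter)
  if (correct) {
    for (i in seq_along(spectra)) {
      if (qc$retained[qc$map_id == spectra[[i]]$map_id])
        spectra[[i]] <- subtract_background(spectra[[i]])
    }
  }
  list(model = model, assignment = assignment, spectra = spectra, qc = qc)
}

#' Pixel-level segmentation accuracy against ground-truth masks
#'
#' @param model A `cluster_model` with index.
#' @param assignment A [assign_compartments()] result.
#' @param truth A `synthetic_truth` with per-map masks (0 background,
#'   1 cytoplasm, 2 nucleus).
#' @return Fraction of pixels whose assigned compartment matches the mask.
#' @export
segmentation_accuracy <- function(model, assignment, truth) {
  lv <- c(background = 0L, cytoplasm = 1L, nucleus = 2L)
  pred <- lv[assignment$mapping[model$labels]]
  tru <- integer(length(pred))
  for (id in unique(model$index$map_id)) {
    rows <- which(model$index$map_id == id)
    m <- truth$masks[[id]]
    if (is.null(m)) stop("no truth mask for map ", id)
    tru[rows] <- m[cbind(model$index$row[rows] + 1L,
                         model$index$col[rows] + 1L)]
  }
  mean(pred == tru)
}
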