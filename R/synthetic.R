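## Synthetic cohort generator: Gaussian-peak component spectra on a shared
## wavenumber axis, disk/kidney cell geometry rasterised to compartment
## masks, additive baseline and Gaussian spectral noise, and a matched
## negative-binomial count matrix whose informative transcripts are linearly
## linked (on the log2(1+count) scale) to per-sample Raman PC-score targets.

# Evaluate a set of Gaussian peaks (center cm-1, fwhm cm-1, amplitude) on an
# axis. `peaks` is a data.frame-like list with columns center, fwhm, amp.
eval_peaks <- function(axis, peaks) {
  s <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    s <- s + peaks$amp[i] *
      exp(-4 * log(2) * (axis - peaks$center[i])^2 / peaks$fwhm[i]^2)
  }
  s
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards, so generators are reproducible without trampling
# the session RNG.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

default_peaks <- function() {
  list(
    # nucleus: strong nucleic-acid doublet (752, 786), PO2- backbone, protein
    nucleus = data.frame(
      center = c(752, 786, 1004, 1095, 1450, 1660),
      fwhm   = c(12, 12, 8, 18, 22, 26),
      amp    = c(8, 10, 5, 6, 7, 6)),
    # cytoplasm: protein/lipid dominated, weak residual RNA doublet
    cytoplasm = data.frame(
      center = c(752, 786, 1004, 1305, 1450, 1660),
      fwhm   = c(12, 12, 8, 22, 22, 26),
      amp    = c(3, 2.5, 7, 5, 8, 7)),
    # background: broad coverslip/PBS hump + water bending band
    background = data.frame(
      center = c(950, 1640),
      fwhm   = c(260, 90),
      amp    = c(1.2, 0.8))
  )
}

#' Build a spectral component library for the synthetic generator
#'
#' The library holds, per compartment (nucleus, cytoplasm, background), a set
#' of Gaussian peaks (center, full width at half maximum, amplitude), a
#' slowly varying additive baseline shared by all pixels, and multiplicative
#' condition effects on named peaks. The default D4 effect scales the
#' nucleus 786 cm^-1 nucleic-acid peak by 0.8, so activated cells show a
#' raised 752/786 intensity ratio.
#'
#' @param axis Wavenumber axis the library renders on; default [default_axis()].
#' @param peaks Optional named list overriding the per-compartment peak
#'   tables (data.frames with columns `center`, `fwhm`, `amp`).
#' @param condition_effects Named list: condition -> named numeric vector of
#'   multiplicative amplitude factors keyed `"<compartment>:<center>"`.
#'   Default `list(D4 = c("nucleus:786" = 0.8))`.
#' @param baseline List with `offset` and `slope` (intensity units; slope is
#'   applied over the full axis range).
#' @return Object of class `component_library`.
#' @export
make_component_library <- function(axis = default_axis(), peaks = NULL,
                                   condition_effects = list(D4 = c("nucleus:786" = 0.8)),
                                   baseline = list(offset = 2, slope = -1)) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  pk <- default_peaks()
  if (!is.null(peaks)) for (nm in names(peaks)) pk[[nm]] <- peaks[[nm]]
  for (comp in c("nucleus", "cytoplasm", "background")) {
    p <- pk[[comp]]
    if (is.null(p) || nrow(p) == 0)
      stop("compartment '", comp, "' must have at least one peak")
    if (any(p$center < min(axis) | p$center > max(axis)))
      stop("peak center outside the wavenumber axis range in '", comp, "': ",
           paste(p$center[p$center < min(axis) | p$center > max(axis)],
                 collapse = ", "))
    if (any(p$amp <= 0) || any(p$fwhm <= 0))
      stop("peak amplitudes and widths must be strictly positive ('",
           comp, "')")
  }
  if (!all(c(752, 786) %in% pk$nucleus$center))
    stop("nucleus component must include the 752 and 786 cm-1 peaks")
  structure(list(axis = axis, peaks = pk,
                 condition_effects = condition_effects,
                 baseline = baseline),
            class = "component_library")
}

#' Render one compartment's noiseless component spectrum
#'
#' Applies the library's condition effects (multiplicative amplitude factors
#' on named peaks) but not the baseline.
#'
#' @param library A [make_component_library()] object.
#' @param compartment `"nucleus"`, `"cytoplasm"` or `"background"`.
#' @param condition Condition label whose effects apply (`"D0"` has none by
#'   default).
#' @return Numeric spectrum on the library axis.
#' @export
render_component <- function(library, compartment, condition = "D0") {
  stopifnot(inherits(library, "component_library"))
  p <- library$peaks[[compartment]]
  if (is.null(p)) stop("unknown compartment: ", compartment)
  eff <- library$condition_effects[[condition]]
  if (!is.null(eff)) {
    key <- paste0(compartment, ":", p$center)
    f <- eff[key]
    f[is.na(f)] <- 1
    p$amp <- p$amp * as.numeric(f)
  }
  eval_peaks(library$axis, p)
}

render_baseline <- function(library) {
  ax <- library$axis
  library$baseline$offset +
    library$baseline$slope * (ax - min(ax)) / diff(range(ax))
}

#' Cell geometry for map rendering
#'
#' A circular cell with a circular (optionally kidney-shaped) nucleus on a
#' pixel grid. Coordinates are micrometres with the origin at the grid's
#' top-left corner; pixel (row, col) has its center at
#' `((col + 0.5) * pixel_size, (row + 0.5) * pixel_size)`.
#'
#' @param height,width Grid size in pixels.
#' @param pixel_size Pixel pitch, micrometres (default 0.2: a 75x75 grid
#'   spans 15x15 um).
#' @param cell_center,nucleus_center Length-2 (x, y) in micrometres; default
#'   the grid center.
#' @param cell_radius,nucleus_radius Radii in micrometres.
#' @param nucleus_eccentricity In `[0, 1)`: 0 gives a disk; > 0 carves a
#'   kidney shape by subtracting an offset disk.
#' @return Object of class `cell_geometry`.
#' @export
cell_geometry <- function(height = 75, width = 75, pixel_size = 0.2,
                          cell_center = NULL, cell_radius = 5,
                          nucleus_center = NULL, nucleus_radius = 3,
                          nucleus_eccentricity = 0) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  ext <- c(width, height) * pixel_size
  if (is.null(cell_center)) cell_center <- ext / 2
  if (is.null(nucleus_center)) nucleus_center <- cell_center
  g <- structure(list(height = as.integer(height), width = as.integer(width),
                      pixel_size = pixel_size, cell_center = cell_center,
                      cell_radius = cell_radius,
                      nucleus_center = nucleus_center,
                      nucleus_radius = nucleus_radius,
                      nucleus_eccentricity = nucleus_eccentricity),
                 class = "cell_geometry")
  d <- sqrt(sum((g$nucleus_center - g$cell_center)^2))
  if (d + nucleus_radius > cell_radius + 1e-9)
    stop("nucleus region must be contained in the cell region")
  if (any(cell_center - cell_radius < -1e-9) ||
      any(cell_center + cell_radius > ext + 1e-9))
    stop("cell region must be contained in the grid")
  g
}

# Rasterise a geometry to an integer mask: 0 background, 1 cytoplasm,
# 2 nucleus (pixel-center-in-region test).
geometry_mask <- function(geometry) {
  g <- geometry
  xc <- (seq_len(g$width) - 0.5) * g$pixel_size
  yc <- (seq_len(g$height) - 0.5) * g$pixel_size
  X <- matrix(xc, g$height, g$width, byrow = TRUE)
  Y <- matrix(yc, g$height, g$width)
  in_cell <- (X - g$cell_center[1])^2 + (Y - g$cell_center[2])^2 <=
    g$cell_radius^2
  in_nuc <- (X - g$nucleus_center[1])^2 + (Y - g$nucleus_center[2])^2 <=
    g$nucleus_radius^2
  if (g$nucleus_eccentricity > 0) {
    off <- g$nucleus_eccentricity * g$nucleus_radius
    carve <- (X - g$nucleus_center[1] - off)^2 +
      (Y - g$nucleus_center[2])^2 <= (0.9 * g$nucleus_radius)^2
    in_nuc <- in_nuc & !carve
  }
  mask <- matrix(0L, g$height, g$width)
  mask[in_cell] <- 1L
  mask[in_nuc & in_cell] <- 2L
  mask
}

#' Render one synthetic cell map
#'
#' Each pixel's spectrum is the compartment component (with the condition's
#' peak effects applied), plus the shared additive baseline, times a
#' per-map intensity factor, plus i.i.d. Gaussian noise of standard
#' deviation `noise_sd`. The true compartment of every pixel is returned as
#' an integer mask (0 background, 1 cytoplasm, 2 nucleus).
#'
#' @param geometry A [cell_geometry()].
#' @param library A [make_component_library()].
#' @param condition `"D0"` or `"D4"`.
#' @param noise_sd Spectral noise standard deviation (>= 0). The default
#'   library's nucleus 786 cm^-1 peak has amplitude 10, so `noise_sd = 1`
#'   corresponds to a per-pixel peak SNR of about 10.
#' @param seed Integer seed; identical seeds give bitwise-identical maps.
#' @param map_id Identifier stored in the map.
#' @param intensity Per-map multiplicative intensity factor (focus/laser
#'   drift emulation), applied to component + baseline, not to the noise.
#' @return List with elements `map` (a [hyper_map()]) and `mask`.
#' @export
render_cell_map <- function(geometry, library, condition = "D0",
                            noise_sd = 1, seed = 1L, map_id = "map",
                            intensity = 1) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(library, "component_library"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mask <- geometry_mask(geometry)
  comp <- rbind(background = render_component(library, "background", condition),
                cytoplasm  = render_component(library, "cytoplasm", condition),
                nucleus    = render_component(library, "nucleus", condition))
  base <- render_baseline(library)
  C <- length(library$axis)
  h <- geometry$height; w <- geometry$width
  clean <- intensity * (comp[as.vector(mask) + 1L, , drop = FALSE] +
                          matrix(base, h * w, C, byrow = TRUE))
  cube_vec <- if (noise_sd > 0) {
    with_seed(seed, clean + matrix(stats::rnorm(h * w * C, sd = noise_sd),
                                   h * w, C))
  } else clean
  cube <- array(NA_real_, c(h, w, C))
  for (ch in seq_len(C)) cube[, , ch] <- matrix(cube_vec[, ch], h, w)
  list(map = hyper_map(cube, library$axis, map_id, condition,
                       geometry$pixel_size),
       mask = mask)
}

#' Simulate a two-condition cohort of single-cell Raman maps
#'
#' Draws per-map geometry (radii and center jittered around the template),
#' renders each map with its condition's spectral effects, and records the
#' full ground truth (masks, conditions, noise parameters). A small per-map
#' log-normal intensity factor emulates focus/laser drift between cells; it
#' is independent of `noise_sd`, so a `noise_sd = 0` cohort is still
#' pixelwise noiseless within each map.
#'
#' @param n_d0,n_d4 Number of maps per condition (>= 1).
#' @param library Component library; default [make_component_library()].
#' @param geometry Template [cell_geometry()].
#' @param noise_sd Spectral noise sd (see [render_cell_map()]).
#' @param seed Integer seed driving geometry jitter, intensity factors and
#'   spectral noise; the whole cohort is bit-reproducible given the seed.
#' @param geometry_jitter Relative sd of the radii jitter (uniform,
#'   +/- `geometry_jitter`); 0 disables.
#' @param intensity_sd Log-scale sd of the per-map intensity factor; 0
#'   disables.
#' @param geometries Optional list of explicit per-map geometries (length
#'   `n_d0 + n_d4`), overriding the jittered template.
#' @return List with `maps` (list of [hyper_map()]) and `truth` (class
#'   `synthetic_truth`: `masks`, `conditions`, `noise`, `seed`).
#' @export
simulate_cohort <- function(n_d0, n_d4, library = make_component_library(),
                            geometry = cell_geometry(), noise_sd = 1,
                            seed = 1L, geometry_jitter = 0.08,
                            intensity_sd = 0.02, geometries = NULL) {
  if (n_d0 < 1 || n_d4 < 1) stop("need at least one map per condition")
  n <- n_d0 + n_d4
  conditions <- c(rep("D0", n_d0), rep("D4", n_d4))
  ids <- sprintf("%s-%03d", conditions, c(seq_len(n_d0), seq_len(n_d4)))
  par <- with_seed(seed, list(
    map_seeds = sample.int(.Machine$integer.max - 1L, n),
    rj = matrix(stats::runif(2 * n, -geometry_jitter, geometry_jitter), n, 2),
    cj = matrix(stats::runif(2 * n, -0.5, 0.5) * geometry$pixel_size * 2, n, 2),
    intensity = exp(stats::rnorm(n, 0, intensity_sd))))
  maps <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    g <- if (!is.null(geometries)) geometries[[i]] else {
      ext <- c(geometry$width, geometry$height) * geometry$pixel_size
      ctr <- geometry$cell_center + par$cj[i, ]
      # clamp the jittered cell to the grid and the nucleus to the cell
      rc <- min(geometry$cell_radius * (1 + par$rj[i, 1]),
                ctr[1], ctr[2], ext[1] - ctr[1], ext[2] - ctr[2])
      rn <- min(geometry$nucleus_radius * (1 + par$rj[i, 2]), rc)
      cell_geometry(geometry$height, geometry$width, geometry$pixel_size,
                    cell_center = ctr, cell_radius = rc,
                    nucleus_center = ctr, nucleus_radius = rn,
                    nucleus_eccentricity = geometry$nucleus_eccentricity)
    }
    r <- render_cell_map(g, library, conditions[i], noise_sd,
                         seed = par$map_seeds[i], map_id = ids[i],
                         intensity = par$intensity[i])
    maps[[i]] <- r$map
    masks[[i]] <- r$mask
  }
  names(maps) <- names(masks) <- ids
  truth <- structure(list(masks = masks,
                          conditions = stats::setNames(conditions, ids),
                          noise = list(spectral_sd = noise_sd,
                                       intensity_sd = intensity_sd),
                          seed = seed),
                     class = "synthetic_truth")
  list(maps = maps, truth = truth)
}

#' Simulate a transcript count matrix linked to Raman PC-score targets
#'
#' Non-informative transcripts get condition-independent log2 mean
#' expression; a designated informative subset gets log2(1+count) means that
#' are affine functions of the per-sample PC-score target vector through a
#' planted coefficient matrix `B_true`. Counts are drawn negative-binomial
#' with a common dispersion (`dispersion = 0` gives deterministic rounded
#' means).
#'
#' @param n_transcripts,n_informative Total and informative transcript
#'   counts (`n_informative <= n_transcripts`).
#' @param pc_targets Numeric matrix, samples x PC dimensions, with sample
#'   rownames; one row per RNA sample (typically 6: three pseudo-replicates
#'   per condition).
#' @param conditions Condition label per sample (recycled from rownames
#'   prefix `D0`/`D4` when `NULL`).
#' @param dispersion Negative-binomial dispersion (1/size); 0 = noiseless.
#' @param seed Integer seed.
#' @param effect_scale Scale of the planted link: sd of the planted log2
#'   effect per standardised target column (default 1.5 log2 units).
#' @param base_log2_range Range of baseline log2(1+mean) expression.
#' @return List with `counts` (a [count_matrix()]) and `truth` (list:
#'   `informative` ids, `B_true` in original target units, `intercepts`,
#'   `log2_mean` the noiseless feature matrix, `dispersion`, `seed`).
#' @export
simulate_transcriptome <- function(n_transcripts = 2000, n_informative = 30,
                                   pc_targets, conditions = NULL,
                                   dispersion = 0.1, seed = 1L,
                                   effect_scale = 1.5,
                                   base_log2_range = c(3, 9)) {
  if (n_informative > n_transcripts)
    stop("n_informative must not exceed n_transcripts")
  pc_targets <- as.matrix(pc_targets)
  ns <- nrow(pc_targets)
  if (ns < 4) stop("need at least 4 samples of PC targets")
  if (is.null(rownames(pc_targets)))
    rownames(pc_targets) <- sprintf("S%d", seq_len(ns))
  if (is.null(conditions))
    conditions <- sub("-.*$", "", rownames(pc_targets))
  tid <- sprintf("tx%05d", seq_len(n_transcripts))
  res <- with_seed(seed, {
    informative <- sort(sample.int(n_transcripts, n_informative))
    a <- stats::runif(n_transcripts, base_log2_range[1], base_log2_range[2])
    # isotropic coefficient directions in target units (so the dominant,
    # condition-separating axes dominate the link), with each informative
    # row rescaled to a guaranteed planted effect: its log2 feature sd
    # across samples is drawn uniformly in [0.75, 1.5] * effect_scale.
    # Without the floor, rows drawing near-zero coefficients would carry
    # the "informative" label without any recoverable signal.
    s <- apply(pc_targets, 2, stats::sd)
    use <- s > 1e-12
    G <- matrix(stats::rnorm(n_informative * ncol(pc_targets)),
                n_informative, ncol(pc_targets))
    G[, !use] <- 0
    row_sd <- sqrt(rowSums(sweep(G, 2, ifelse(use, s, 0), "*")^2))
    eff <- stats::runif(n_informative, 0.75, 1.5) * effect_scale
    B_true <- G * (eff / pmax(row_sd, 1e-12))
    planted <- pc_targets %*% t(B_true)        # samples x informative
    # shift intercepts so planted transcripts keep realistic mean expression
    # while log2_mean stays exactly affine in the targets via B_true
    a[informative] <- a[informative] - colMeans(planted)
    log2_mean <- matrix(a, n_transcripts, ns)
    log2_mean[informative, ] <- log2_mean[informative, ] + t(planted)
    mu <- pmax(2^log2_mean - 1, 0)
    counts <- if (dispersion == 0) round(mu) else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_transcripts, ns)
    }
    list(informative = informative, a = a, B_true = B_true,
         log2_mean = log2_mean, counts = counts)
  })
  dimnames(res$counts) <- list(tid, rownames(pc_targets))
  dimnames(res$log2_mean) <- list(tid, rownames(pc_targets))
  rownames(res$B_true) <- tid[res$informative]
  truth <- list(informative = tid[res$informative], B_true = res$B_true,
                intercepts = stats::setNames(res$a, tid),
                log2_mean = res$log2_mean, dispersion = dispersion,
                seed = seed)
  list(counts = count_matrix(res$counts, conditions), truth = truth)
}
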