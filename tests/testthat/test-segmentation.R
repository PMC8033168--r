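test_that("pooled spectra count and index back-reference are correct", {
  lib <- make_component_library()
  g1 <- cell_geometry(10, 8, 0.5, cell_radius = 1.8, nucleus_radius = 1.2)
  g2 <- cell_geometry(12, 12, 0.5, cell_radius = 2.4, nucleus_radius = 1.6)
  m1 <- render_cell_map(g1, lib, "D0", 0, seed = 1, map_id = "a")$map
  m2 <- render_cell_map(g2, lib, "D4", 0, seed = 2, map_id = "b")$map
  pooled <- pool_spectra(list(m1, m2))
  expect_equal(nrow(pooled$spectra), 10 * 8 + 12 * 12)
  # row k of the matrix is pixel (row, col) of its map
  k <- 37
  expect_equal(pooled$spectra[k, ],
               m1$cube[pooled$index$row[k] + 1, pooled$index$col[k] + 1, ])
  expect_error(pool_spectra(list()), "no maps")
})

test_that("k-means matches the exhaustive-search optimum on tight triads", {
  set.seed(5)
  x <- rbind(matrix(rnorm(9, mean = 0, sd = 0.05), 3),
             matrix(rnorm(9, mean = 4, sd = 0.05), 3))
  km <- common_kmeans(x, k = 2, seed = 1, n_init = 10)
  oracle <- brute_kmeans2(x)
  expect_equal(km$inertia, oracle$wss, tolerance = 1e-9)
  agree <- mean((km$labels == km$labels[1]) == (oracle$grp == oracle$grp[1]))
  expect_equal(agree, 1)
})

test_that("k-means degenerate and small-k cases behave", {
  x <- matrix(rnorm(50), 10, 5)
  km1 <- common_kmeans(x, k = 1, seed = 1, n_init = 2)
  expect_equal(drop(km1$centroids), colMeans(x))
  dup <- x[rep(1:2, 5), ]
  expect_error(common_kmeans(dup, k = 3, seed = 1), "distinct spectra")
  km <- common_kmeans(x, k = 3, seed = 7, n_init = 3)
  km2 <- common_kmeans(x, k = 3, seed = 7, n_init = 3)
  expect_identical(km$centroids, km2$centroids)
  # centroids are the means of their members at convergence
  for (j in 1:3)
    expect_equal(km$centroids[j, ],
                 colMeans(x[km$labels == j, , drop = FALSE]),
                 tolerance = 1e-8)
})

test_that("compartment assignment recovers truth on a noiseless cohort", {
  sim <- small_cohort(noise_sd = 0)
  seg <- cached("seg_noiseless_k8", segment_cohort(
    sim$maps, k = 8, seed = 1, n_init = 4, subsample = 4000))
  acc <- segmentation_accuracy(seg$model, seg$assignment, sim$truth)
  expect_equal(acc, 1)
  expect_setequal(unique(seg$assignment$mapping),
                  c("nucleus", "cytoplasm", "background"))
})

test_that("manual override takes precedence over marker scores", {
  sim <- small_cohort(noise_sd = 0)
  seg <- cached("seg_noiseless_k8", segment_cohort(
    sim$maps, k = 8, seed = 1, n_init = 4, subsample = 4000))
  asg <- assign_compartments(seg$model, override = c("3" = "nucleus"))
  expect_identical(asg$mapping[3], "nucleus")
  expect_error(assign_compartments(seg$model, override = c("99" = "nucleus")),
               "1..k")
  expect_error(assign_compartments(seg$model, override = c("3" = "mitochondria")),
               "nucleus, cytoplasm or background")
})

test_that("compartment means and whole-cell weighting are exact", {
  sim <- small_cohort(noise_sd = 0)
  seg <- small_segmented(noise_sd = 0)
  cs <- seg$spectra[[1]]
  # noiseless: all nucleus pixels share one spectrum, so the mean equals it
  m <- sim$maps[[cs$map_id]]
  mask <- sim$truth$masks[[cs$map_id]]
  px <- which(mask == 2L, arr.ind = TRUE)
  raw <- if (cs$corrected) cs$raw else cs$means
  expect_equal(unname(raw$nucleus), m$cube[px[1, 1], px[1, 2], ],
               tolerance = 1e-12)
  # whole-cell mean is the pixel-count-weighted mean of the two compartments
  wc <- (cs$counts[["nucleus"]] * raw$nucleus +
           cs$counts[["cytoplasm"]] * raw$cytoplasm) /
    (cs$counts[["nucleus"]] + cs$counts[["cytoplasm"]])
  expect_equal(raw$whole_cell, wc, tolerance = 1e-12)
  expect_equal(cs$counts[["whole_cell"]],
               cs$counts[["nucleus"]] + cs$counts[["cytoplasm"]])
})

test_that("QC discards small or missing nuclei with exact boundary behaviour", {
  fake_cs <- function(id, nuc, cyt, ps = 0.2) {
    structure(list(map_id = id, condition = "D0",
                   means = list(), counts = c(nucleus = nuc, cytoplasm = cyt,
                                              whole_cell = nuc + cyt,
                                              background = 10),
                   axis = NULL, pixel_size = ps, corrected = FALSE),
              class = "compartment_spectra")
  }
  qc <- qc_filter(list(fake_cs("small", 100, 50), fake_cs("big", 200, 50),
                       fake_cs("nocyt", 200, 0)), min_diameter = 3)
  expect_equal(qc$reason, c("nucleus_too_small", "ok", "no_compartment_pixels"))
  expect_equal(qc$retained, c(FALSE, TRUE, FALSE))
  expect_equal(qc$nucleus_diameter_um[1], 2 * 0.2 * sqrt(100 / pi),
               tolerance = 1e-12)
  # boundary: exactly at the threshold is retained, strictly below is not
  thr <- 2 * 0.2 * sqrt(100 / pi)
  qc2 <- qc_filter(list(fake_cs("at", 100, 50), fake_cs("below", 99, 50)),
                   min_diameter = thr)
  expect_equal(qc2$retained, c(TRUE, FALSE))
})

test_that("a cohort map with a sub-3-um nucleus is flagged downstream", {
  lib <- make_component_library()
  geos <- list(small_geometry(), cell_geometry(24, 24, 0.2, cell_radius = 2.2,
                                               nucleus_radius = 1.4))
  sim <- simulate_cohort(1, 1, lib, noise_sd = 0, seed = 5,
                         geometries = geos)
  seg <- segment_cohort(sim$maps, k = 4, seed = 1, n_init = 4)
  expect_true(seg$qc$retained[1])
  expect_identical(seg$qc$reason[2], "nucleus_too_small")
  expect_lt(seg$qc$nucleus_diameter_um[2], 3)
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  n <- 1201
  x <- seq_len(n)
  for (cf in list(c(2, 0, 0), c(1, -3, 0.5), c(0.1, 0.02, -4e-4))) {
    poly <- cf[1] + cf[2] * x + cf[3] * x^2
    sm <- signal::sgolayfilt(poly, p = 2, n = 99)
    interior <- 50:(n - 49)
    expect_lt(max(abs(sm[interior] - poly[interior])), 1e-9)
  }
})

test_that("3-step background subtraction zeroes constants and the offset band", {
  ax <- default_axis()
  C <- length(ax)
  mk <- function(nuc, cyt, bg) {
    structure(list(map_id = "toy", condition = "D0",
                   means = list(nucleus = nuc, cytoplasm = cyt,
                                whole_cell = (nuc + cyt) / 2,
                                background = bg),
                   counts = c(nucleus = 1, cytoplasm = 1, whole_cell = 2,
                              background = 1),
                   axis = ax, pixel_size = 0.2, corrected = FALSE),
              class = "compartment_spectra")
  }
  # constants: signal 5, background 2 -> everything identically 0
  cs <- subtract_background(mk(rep(5, C), rep(5, C), rep(2, C)))
  expect_lt(max(abs(cs$means$nucleus)), 1e-12)
  expect_lt(max(abs(cs$means$whole_cell)), 1e-12)
  expect_true(cs$corrected)

  # quadratic background is reproduced exactly in the interior, so the
  # interior residual is exactly signal - background
  i <- seq_len(C)
  bg <- 3 + 0.01 * i - 2e-5 * i^2
  sig <- sin(i / 40) + bg
  cs2 <- subtract_background(mk(sig, sig, bg))
  band <- which(ax >= 1780 & ax <= 1840)
  interior <- 50:(C - 49)
  truth <- (sig - mean(sig[band])) - (bg - mean(bg[band]))
  expect_lt(max(abs(cs2$means$nucleus[interior] - truth[interior])), 1e-9)
  # the corrected spectra keep a zero mean in the offset band
  expect_lt(abs(mean(cs2$means$nucleus[band])), 1e-9)
  expect_lt(abs(mean(cs2$means$background[band])), 1e-12)

  expect_error(subtract_background(mk(sig, sig, bg), offset_band = c(1900, 2000)),
               "contains no channels")
  expect_error(subtract_background(mk(sig, sig, bg), sg_frame = 98), "odd")
})

test_that("segmented nucleus fraction tracks the true area ratio at default noise", {
  sim <- small_cohort(noise_sd = 1)
  seg <- small_segmented(noise_sd = 1)
  for (cs in seg$spectra) {
    mask <- sim$truth$masks[[cs$map_id]]
    true_ratio <- sum(mask == 2L) / sum(mask >= 1L)
    obs_ratio <- cs$counts[["nucleus"]] / cs$counts[["whole_cell"]]
    expect_lt(abs(obs_ratio - true_ratio), 0.05)
  }
})
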