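test_that("windowed peak intensity equals the window mean", {
  ax <- default_axis()
  g <- exp(-((as.numeric(ax) - 786)^2) / (2 * 5^2))
  expect_gt(peak_intensity(g, ax, 786), 0.5)
  expect_lt(peak_intensity(g, ax, 752), 1e-6)
  expect_equal(peak_intensity(rep(3.2, length(ax)), ax, 1004), 3.2)
  # window spanning exactly 3 channels, against direct summation
  idx <- which(ax >= 751 & ax <= 753)
  expect_length(idx, 3)
  expect_equal(peak_intensity(g, ax, 752, half_window = 1),
               sum(g[idx]) / 3)
  expect_error(peak_intensity(g, ax, 2000, half_window = 1),
               "no channels")
})

test_that("peak ratio test matches the closed-form Welch statistic", {
  ax <- default_axis()
  C <- length(ax)
  mk <- function(r752) {
    s <- numeric(C)
    s[ax >= 782 & ax <= 790] <- 1
    s[ax >= 748 & ax <= 756] <- r752
    s
  }
  r0 <- c(1.0, 1.2, 1.4); r4 <- c(1.9, 2.1, 2.4)
  X <- do.call(rbind, lapply(c(r0, r4), mk))
  rownames(X) <- sprintf("c%d", 1:6)
  res <- peak_ratio_test(X, rep(c("D0", "D4"), each = 3), ax)
  expect_equal(unname(res$ratios), c(r0, r4), tolerance = 1e-12)
  # Welch oracle computed directly from the ratio groups
  g0 <- res$ratios[1:3]; g4 <- res$ratios[4:6]
  tstat <- (mean(g4) - mean(g0)) /
    sqrt(var(g4) / 3 + var(g0) / 3)
  expect_equal(res$test$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$test$mean_D0, mean(g0))
})

test_that("degenerate and invalid ratio inputs are handled", {
  ax <- default_axis()
  C <- length(ax)
  X <- matrix(rep(1, 4 * C), 4)
  res <- peak_ratio_test(X, c("D0", "D0", "D4", "D4"), ax)
  expect_equal(res$test$statistic, 0)
  expect_equal(res$test$p_value, 1)
  # nonpositive denominator -> excluded with a warning
  Xbad <- X
  Xbad[1, ] <- -1
  expect_warning(res2 <- peak_ratio_test(rbind(Xbad, X[1:2, ]),
                                         c("D0", "D0", "D4", "D4", "D0", "D4"),
                                         ax),
                 "nonpositive denominator")
  expect_true(is.na(res2$ratios[1]))
})

test_that("activated cells show a raised 752/786 ratio on synthetic data", {
  cc <- classifier_cohort()
  res <- peak_ratio_test(cc$cm$spectra, cc$cm$labels, cc$cm$axis)
  expect_gt(res$test$mean_D4, res$test$mean_D0)
  expect_lt(res$test$p_value, 0.05)
})

test_that("PCA basics: variance ordering, centering, tiny-case oracle", {
  set.seed(8)
  base <- rnorm(40)
  dirn <- rnorm(40)
  X <- t(sapply(seq(-2, 2, length.out = 9), function(a) base + a * dirn))
  pcm <- fit_pca(X, n_keep = 3)
  expect_gt(pcm$explained[1], 1 - 1e-9)
  expect_lt(max(abs(colMeans(pcm$scores))), 1e-9)
  # orthonormal loadings
  G <- crossprod(pcm$loadings)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  # 2-cell oracle: PC1 scores are +/- half the spectral distance
  Y <- rbind(rnorm(30), rnorm(30))
  p2 <- fit_pca(Y, n_keep = 1)
  expect_equal(sort(abs(p2$scores[, 1])),
               rep(sqrt(sum((Y[1, ] - Y[2, ])^2)) / 2, 2),
               tolerance = 1e-9)
  expect_error(fit_pca(Y, n_keep = 5), "n_keep")
})

test_that("PCA reconstruction with all components reproduces the input", {
  set.seed(9)
  X <- matrix(rnorm(8 * 50), 8, 50)
  pcm <- fit_pca(X, n_keep = 7)
  recon <- pcm$scores %*% t(pcm$loadings) +
    matrix(pcm$mean, 8, 50, byrow = TRUE)
  expect_lt(max(abs(recon - X)) / max(abs(X)), 1e-8)
})

test_that("per-PC tests flag planted components and hold their level under permutation", {
  cc <- classifier_cohort()
  pcm <- fit_pca(cc$cm$spectra, n_keep = 9, axis = cc$cm$axis)
  tests <- pc_score_tests(pcm, cc$cm$labels)
  expect_equal(nrow(tests), 9)
  expect_true(any(tests$significant))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  expect_error(pc_score_tests(pcm, c("D0", rep("D4", nrow(pcm$scores) - 1))),
               "at least 2 cells")
  # permutation null: ~alpha of components significant on average
  set.seed(31)
  frac <- replicate(60, {
    perm <- sample(cc$cm$labels)
    mean(pc_score_tests(pcm, perm)$significant)
  })
  expect_gt(mean(frac), 0.005)
  expect_lt(mean(frac), 0.15)
})

test_that("Fisher direction and loading spectrum behave as expected", {
  set.seed(10)
  # spherical classes: LD direction parallel to the mean difference
  S <- rbind(matrix(rnorm(200 * 3), 200, 3),
             sweep(matrix(rnorm(200 * 3), 200, 3), 2, c(4, 2, 1), "+"))
  fake_pcm <- structure(list(scores = S, n_keep = 3,
                             loadings = diag(3), mean = rep(0, 3),
                             axis = NULL), class = "pc_model")
  labels <- rep(c("D0", "D4"), each = 200)
  ld <- fit_lda(fake_pcm, labels)
  cosang <- sum(ld$coef * c(4, 2, 1)) /
    sqrt(sum(ld$coef^2) * sum(c(4, 2, 1)^2))
  expect_gt(cosang, 0.99)
  # pooled within-class variance of LD scores is 1
  v <- (var(ld$scores[1:200]) * 199 + var(ld$scores[201:400]) * 199) / 398
  expect_equal(v, 1, tolerance = 1e-9)
  # D4 projects above the threshold
  expect_gt(mean(ld$scores[201:400] > ld$threshold), 0.95)
  # 1-PC model: loading spectrum is w1 * loading
  cc <- classifier_cohort()
  pcm <- fit_pca(cc$cm$spectra, n_keep = 3, axis = cc$cm$axis)
  ld1 <- fit_lda(pcm, cc$cm$labels, pc_indices = 1)
  expect_equal(ld1$loading_spectrum, drop(pcm$loadings[, 1] * ld1$coef))
})

test_that("LD scores are invariant to reparameterizing the PC subspace", {
  set.seed(11)
  S <- rbind(matrix(rnorm(30 * 4), 30, 4),
             sweep(matrix(rnorm(30 * 4), 30, 4), 2, c(2, 1, 0, -1), "+"))
  labels <- rep(c("D0", "D4"), each = 30)
  M <- matrix(rnorm(16), 4, 4)  # invertible reparameterization (a.s.)
  mk <- function(sc) structure(list(scores = sc, n_keep = 4,
                                    loadings = diag(4), mean = rep(0, 4),
                                    axis = NULL), class = "pc_model")
  ld1 <- fit_lda(mk(S), labels)
  ld2 <- fit_lda(mk(S %*% M), labels)
  rel <- (ld1$scores - mean(ld1$scores)) / (ld2$scores - mean(ld2$scores))
  expect_lt(max(abs(abs(rel) - 1)), 1e-6)
})

test_that("LDA direction agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  cc <- classifier_cohort()
  pcm <- fit_pca(cc$cm$spectra, n_keep = 5, axis = cc$cm$axis)
  ld <- fit_lda(pcm, cc$cm$labels)
  ref <- MASS::lda(pcm$scores, grouping = cc$cm$labels)
  cosang <- abs(sum(ld$coef * ref$scaling)) /
    sqrt(sum(ld$coef^2) * sum(ref$scaling^2))
  expect_gt(cosang, 0.999)
})

test_that("leave-one-out classification is exact on separated classes and sums its confusion", {
  set.seed(12)
  X <- rbind(matrix(rnorm(10 * 40), 10, 40),
             matrix(rnorm(10 * 40, mean = 3), 10, 40))
  labels <- rep(c("D0", "D4"), each = 10)
  r <- loo_classify(X, labels, n_keep = 5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(sum(r$confusion), 20)
  r2 <- loo_classify(X, labels, n_keep = 5, strict_loo = TRUE)
  expect_equal(r2$sensitivity, 1)
  expect_error(loo_classify(X[1:12, ], c(rep("D0", 10), "D4", "D4"),
                            n_keep = 3),
               "at least 3 cells")
})

test_that("classification accuracy degrades monotonically as noise grows", {
  lib <- make_component_library()
  med_sens <- sapply(c(1, 25, 60), function(nsd) {
    sens <- sapply(1:5, function(s) {
      sim <- simulate_cohort(8, 8, lib, small_geometry(), noise_sd = nsd,
                             seed = 300 + s)
      # classify on truth-mask nucleus means to isolate the spectral effect
      X <- t(sapply(names(sim$maps), function(id) {
        mask <- sim$truth$masks[[id]]
        colMeans(map_spectra(sim$maps[[id]])[as.vector(t(mask)) == 2L, ])
      }))
      loo_classify(X, unname(sim$truth$conditions), n_keep = 5)$sensitivity
    })
    median(sens)
  })
  expect_true(med_sens[1] >= med_sens[2] && med_sens[2] >= med_sens[3])
  expect_equal(med_sens[1], 1)
})

test_that("random splits of one condition give uniform ratio-test p-values", {
  cc <- classifier_cohort()
  d0 <- cc$cm$spectra[cc$cm$labels == "D0", ]
  set.seed(13)
  ps <- replicate(120, {
    fake <- sample(rep(c("D0", "D4"), length.out = nrow(d0)))
    peak_ratio_test(d0, fake, cc$cm$axis)$test$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
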