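## Spectral discrimination of activation states: 752/786 cm^-1 peak-ratio
## test, PCA of background-corrected compartment spectra with per-component
## Welch t-tests, Fisher LDA on retained PC scores, leave-one-out
## sensitivity/specificity, and the discriminant loading projected back to
## the wavenumber axis.

#' Windowed peak intensity
#'
#' Mean intensity over the channels within `center +/- half_window` cm^-1 on
#' a (background-corrected) spectrum. No local baseline is removed.
#'
#' @param spectrum Numeric spectrum on `axis`.
#' @param axis Wavenumber axis.
#' @param center Band center, cm^-1.
#' @param half_window Half window, cm^-1 (default 4).
#' @return Scalar mean intensity.
#' @export
peak_intensity <- function(spectrum, axis, center, half_window = 4) {
  idx <- axis_window(axis, center - half_window, center + half_window)
  if (length(idx) == 0)
    stop("peak window ", center, " +/- ", half_window,
         " cm-1 contains no channels")
  mean(spectrum[idx])
}

# Welch t-test robust to zero-variance groups: identical groups give
# statistic 0 / p 1; constant but different groups give +/-Inf / p 0.
welch_test <- function(x0, x4) {
  v0 <- stats::var(x0); v4 <- stats::var(x4)
  if (v0 + v4 < 1e-300) {
    d <- mean(x4) - mean(x0)
    if (abs(d) < 1e-15) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(d) * Inf, p_value = 0))
  }
  tt <- stats::t.test(x4, x0, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Peak-ratio test between conditions
#'
#' Computes the per-cell ratio of two windowed peak intensities (defaults
#' 752 and 786 cm^-1, the nucleic-acid doublet) and compares conditions
#' with a two-sided Welch t-test. Cells with a nonpositive denominator
#' intensity are excluded with a warning and reported.
#'
#' @param spectra Matrix, cells x channels (corrected spectra).
#' @param labels Condition label per cell (`"D0"`/`"D4"`).
#' @param axis Wavenumber axis.
#' @param c1,c2 Numerator and denominator band centers, cm^-1.
#' @param half_window Half window, cm^-1.
#' @param alpha Significance level for the flag.
#' @return List: `ratios` (named per cell, NA where excluded), `excluded`
#'   ids, and `test` (statistic, p_value, group means/sizes, significant).
#' @export
peak_ratio_test <- function(spectra, labels, axis, c1 = 752, c2 = 786,
                            half_window = 4, alpha = 0.05) {
  stopifnot(nrow(spectra) == length(labels))
  i1 <- apply(spectra, 1, peak_intensity, axis = axis, center = c1,
              half_window = half_window)
  i2 <- apply(spectra, 1, peak_intensity, axis = axis, center = c2,
              half_window = half_window)
  bad <- i2 <= 0
  if (any(bad))
    warning(sum(bad), " cell(s) excluded from the peak ratio: ",
            "nonpositive denominator intensity")
  ratios <- ifelse(bad, NA_real_, i1 / i2)
  names(ratios) <- rownames(spectra)
  g0 <- ratios[labels == "D0" & !bad]
  g4 <- ratios[labels == "D4" & !bad]
  if (length(g0) < 2 || length(g4) < 2)
    stop("need at least 2 usable cells per condition")
  tt <- welch_test(g0, g4)
  list(ratios = ratios,
       excluded = rownames(spectra)[bad] %||% which(bad),
       test = list(statistic = tt$statistic, p_value = tt$p_value,
                   mean_D0 = mean(g0), mean_D4 = mean(g4),
                   n_D0 = length(g0), n_D4 = length(g4),
                   significant = tt$p_value < alpha))
}

#' Principal component analysis of cell spectra
#'
#' Mean-centered PCA (no scaling); components are ordered by explained
#' variance with the sign convention that each loading's
#' largest-magnitude element is positive.
#'
#' @param spectra Matrix, cells x channels.
#' @param n_keep Number of components to retain (default 9).
#' @param axis Optional wavenumber axis, stored for back-projection.
#' @return Object of class `pc_model`: `mean`, `loadings` (channels x
#'   n_keep), `scores` (cells x n_keep), `explained` (fraction per kept
#'   component), `sdev` (all components), `n_keep`, `axis`.
#' @export
fit_pca <- function(spectra, n_keep = 9, axis = NULL) {
  n <- nrow(spectra)
  if (n_keep > min(n - 1, ncol(spectra)))
    stop("n_keep must be <= min(cells - 1, channels)")
  pr <- stats::prcomp(spectra, center = TRUE, scale. = FALSE)
  loadings <- pr$rotation[, seq_len(n_keep), drop = FALSE]
  scores <- pr$x[, seq_len(n_keep), drop = FALSE]
  for (j in seq_len(n_keep)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(spectra)
  structure(list(mean = pr$center, loadings = loadings, scores = scores,
                 explained = pr$sdev[seq_len(n_keep)]^2 / sum(pr$sdev^2),
                 sdev = pr$sdev, n_keep = n_keep, axis = axis),
            class = "pc_model")
}

#' Project new spectra onto a fitted PC model
#'
#' @param model A `pc_model`.
#' @param spectra Matrix or vector of spectra.
#' @return Score matrix.
#' @export
project_pca <- function(model, spectra) {
  if (is.null(dim(spectra))) spectra <- rbind(spectra)
  sweep(spectra, 2, model$mean) %*% model$loadings
}

#' Per-component Welch t-tests on PC scores
#'
#' One two-sided Welch t-test per retained component between the two
#' conditions; no multiplicity correction by default (`adjust = "holm"` to
#' enable).
#'
#' @param model A `pc_model`.
#' @param labels Condition label per cell.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame: component, statistic, p_value, group means and
#'   sizes, significant flag.
#' @export
pc_score_tests <- function(model, labels, alpha = 0.05,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (min(table(labels)) < 2) stop("each condition needs at least 2 cells")
  rows <- lapply(seq_len(model$n_keep), function(j) {
    x0 <- model$scores[labels == "D0", j]
    x4 <- model$scores[labels == "D4", j]
    tt <- welch_test(x0, x4)
    data.frame(component = j, statistic = tt$statistic,
               p_value = tt$p_value, mean_D0 = mean(x0), mean_D4 = mean(x4),
               n_D0 = length(x0), n_D4 = length(x4))
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < alpha
  out
}

#' Fisher linear discriminant on PC scores
#'
#' Computes the Fisher direction `w` proportional to `S_w^-1 (mu_D4 -
#' mu_D0)` on the selected PC scores, scaled so the pooled within-class
#' variance of the LD scores is 1; the decision threshold is the midpoint of
#' the projected class means (equal priors). The discriminant is
#' back-projected to the wavenumber axis as the coefficient-weighted sum of
#' PC loadings.
#'
#' @param model A `pc_model`.
#' @param labels Condition per cell (`"D0"`/`"D4"`).
#' @param pc_indices Components to use (default all retained).
#' @return Object of class `ld_model`: `pc_indices`, `coef`, `threshold`,
#'   `scores` (per cell LD score), `loading_spectrum`, `axis`.
#' @export
fit_lda <- function(model, labels, pc_indices = NULL) {
  pc_indices <- pc_indices %||% seq_len(model$n_keep)
  if (any(pc_indices > model$n_keep))
    stop("pc_indices must be within the retained components")
  S <- model$scores[, pc_indices, drop = FALSE]
  i0 <- labels == "D0"; i4 <- labels == "D4"
  if (sum(i0) < 2 || sum(i4) < 2) stop("each class needs at least 2 cells")
  mu0 <- colMeans(S[i0, , drop = FALSE])
  mu4 <- colMeans(S[i4, , drop = FALSE])
  Sw <- ((sum(i0) - 1) * stats::cov(S[i0, , drop = FALSE]) +
           (sum(i4) - 1) * stats::cov(S[i4, , drop = FALSE])) /
    (nrow(S) - 2)
  d <- mu4 - mu0
  w <- tryCatch(solve(Sw, d), error = function(e) NULL)
  s2 <- if (is.null(w)) -1 else drop(t(w) %*% Sw %*% w)
  if (is.null(w) || !is.finite(s2) || s2 <= 0) {
    warning("singular within-class scatter; ridge 1e-8 added")
    lam <- 1e-8 * (1 + mean(diag(Sw)))
    Sw <- Sw + diag(lam, ncol(S))
    w <- solve(Sw, d)
    s2 <- drop(t(w) %*% Sw %*% w)
  }
  w <- w / sqrt(s2)
  thr <- drop((sum(w * mu0) + sum(w * mu4)) / 2)
  structure(list(pc_indices = pc_indices, coef = w, threshold = thr,
                 scores = drop(S %*% w),
                 loading_spectrum = drop(model$loadings[, pc_indices,
                                                        drop = FALSE] %*% w),
                 axis = model$axis),
            class = "ld_model")
}

#' LD scores and group calls for PC-score vectors
#'
#' @param ld An `ld_model`.
#' @param pc_scores Matrix of PC scores (columns spanning at least
#'   `max(ld$pc_indices)`) or vector.
#' @return data.frame with `ld_score` and `call` (`"D4"` above threshold).
#' @export
predict_ld <- function(ld, pc_scores) {
  if (is.null(dim(pc_scores))) pc_scores <- rbind(pc_scores)
  s <- drop(pc_scores[, ld$pc_indices, drop = FALSE] %*% ld$coef)
  data.frame(ld_score = s,
             call = ifelse(s > ld$threshold, "D4", "D0"),
             stringsAsFactors = FALSE)
}

#' Leave-one-out LDA classification of cells
#'
#' For each cell the LDA is refit on the remaining cells and the held-out
#' cell is classified by the LD threshold (D4 = positive). By default the
#' PCA is fit once on all cells and only the discriminant is refit per fold
#' (`strict_loo = TRUE` refits the PCA inside every fold and projects the
#' held-out cell onto the fold's loadings).
#'
#' @param spectra Matrix, cells x channels.
#' @param labels Condition per cell.
#' @param n_keep Retained PCs (default 9).
#' @param pc_indices Components fed to the LDA (default all retained).
#' @param strict_loo Refit PCA per fold.
#' @return Object of class `loocv_result`: `confusion` (TP, FP, TN, FN),
#'   `sensitivity`, `specificity`, `calls`, `ld_scores`.
#' @export
loo_classify <- function(spectra, labels, n_keep = 9, pc_indices = NULL,
                         strict_loo = FALSE) {
  n <- nrow(spectra)
  if (min(table(labels)) < 3) stop("need at least 3 cells per class")
  full <- if (!strict_loo) fit_pca(spectra, n_keep) else NULL
  calls <- character(n); ldsc <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(labels[tr])) < 2)
      stop("training fold with a single class")
    if (strict_loo) {
      pcm <- fit_pca(spectra[tr, , drop = FALSE], n_keep)
      ld <- fit_lda(pcm, labels[tr], pc_indices)
      sc <- project_pca(pcm, spectra[i, ])
    } else {
      pcm <- full
      pcm$scores <- full$scores[tr, , drop = FALSE]
      ld <- fit_lda(pcm, labels[tr], pc_indices)
      sc <- full$scores[i, , drop = FALSE]
    }
    pr <- predict_ld(ld, sc)
    calls[i] <- pr$call
    ldsc[i] <- pr$ld_score
  }
  tp <- sum(calls == "D4" & labels == "D4")
  fp <- sum(calls == "D4" & labels == "D0")
  tn <- sum(calls == "D0" & labels == "D0")
  fn <- sum(calls == "D0" & labels == "D4")
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 calls = calls, ld_scores = ldsc),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> sensitivity %.1f%%, specificity %.1f%% (TP %d FP %d TN %d FN %d)\n",
              100 * x$sensitivity, 100 * x$specificity,
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  invisible(x)
}

#' Collect a compartment's corrected mean spectra across retained maps
#'
#' Convenience bridge from [segment_cohort()] output to the classifier:
#' stacks one compartment's (corrected) mean spectrum per retained map.
#'
#' @param segmented Output of [segment_cohort()].
#' @param compartment `"nucleus"`, `"cytoplasm"` or `"whole_cell"`.
#' @return List: `spectra` (cells x channels, rownames map ids), `labels`,
#'   `axis`.
#' @export
compartment_matrix <- function(segmented,
                               compartment = c("nucleus", "cytoplasm",
                                               "whole_cell")) {
  compartment <- match.arg(compartment)
  keep <- segmented$qc$map_id[segmented$qc$retained]
  sp <- segmented$spectra[keep]
  X <- do.call(rbind, lapply(sp, function(cs) cs$means[[compartment]]))
  rownames(X) <- keep
  list(spectra = X,
       labels = vapply(sp, function(cs) cs$condition, character(1)),
       axis = sp[[1]]$axis)
}
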