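# Shared fixtures, built in code and cached across test files. Cohort sizes
# and grids are kept small; the acceptance tests build their own, larger
# cohorts at the sizes the acceptance surface states.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

small_geometry <- function(height = 24, width = 24)
  cell_geometry(height, width, pixel_size = 0.2,
                cell_radius = 2.2, nucleus_radius = 1.6)

# 4 + 4 cell cohort on 24x24 px grids
small_cohort <- function(noise_sd = 1) {
  cached(paste0("cohort_", noise_sd),
         simulate_cohort(4, 4, make_component_library(), small_geometry(),
                         noise_sd = noise_sd, seed = 101))
}

small_segmented <- function(noise_sd = 1) {
  cached(paste0("seg_", noise_sd), {
    sim <- small_cohort(noise_sd)
    segment_cohort(sim$maps, k = 8, seed = 1, n_init = 4, subsample = 4000)
  })
}

# 15 + 15 cell cohort for classifier-level tests
classifier_cohort <- function() {
  cached("classifier", {
    sim <- simulate_cohort(15, 15, make_component_library(),
                           small_geometry(), noise_sd = 1, seed = 202)
    seg <- segment_cohort(sim$maps, k = 10, seed = 2, n_init = 4,
                          subsample = 6000)
    cm <- compartment_matrix(seg, "nucleus")
    list(sim = sim, seg = seg, cm = cm)
  })
}

# Exhaustive-search optimum over all 2-partitions (within-cluster SS).
brute_kmeans2 <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    wss <- 0
    for (g in 0:1) {
      xs <- x[grp == g, , drop = FALSE]
      wss <- wss + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    if (is.null(best) || wss < best$wss) best <- list(wss = wss, grp = grp)
  }
  best
}

# Best-rank-r affine approximation of a target matrix (rows = samples):
# exact low-rank responses for the cross-modal exactness tests.
low_rank_targets <- function(targets, r = 2) {
  ctr <- colMeans(targets)
  sv <- svd(sweep(targets, 2, ctr))
  approx <- sv$u[, 1:r, drop = FALSE] %*% diag(sv$d[1:r], r) %*%
    t(sv$v[, 1:r, drop = FALSE])
  out <- sweep(approx, 2, ctr, "+")
  dimnames(out) <- dimnames(targets)
  out
}

# Exact (unrounded, noiseless) feature matrix for a planted transcriptome:
# samples x transcripts, affine in the targets through B_true.
exact_features <- function(tx_truth) t(tx_truth$log2_mean)
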