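## Cross-modal linear correspondence between Raman PC scores and bulk
## transcript counts: balanced random pseudo-replicate grouping of cells,
## PLS2 regression (NIPALS) of per-sample Raman PC-score vectors on
## log2(1+count) transcript features, leave-one-out prediction with LD-score
## conversion and group calls, and VIP ranking of transcripts.

#' Random balanced pseudo-replicates of cells
#'
#' Randomly partitions the cells of each condition into `n_groups` groups of
#' sizes differing by at most one (e.g. 58 cells -> 20/19/19), and averages
#' the per-cell PC-score vectors within each group. The group means are the
#' Raman "samples" matched to the bulk RNA replicates (D0-1..3, D4-1..3).
#'
#' @param scores Matrix of per-cell PC scores (cells x components), with
#'   rownames.
#' @param labels Condition per cell (`"D0"`/`"D4"`).
#' @param n_groups Groups per condition (default 3).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return Object of class `pseudo_replicates`: `assignment` (cell ->
#'   group id), `targets` (group x component mean-score matrix),
#'   `conditions` (per group), `seed`.
#' @export
make_pseudoreplicates <- function(scores, labels, n_groups = 3, seed = 1L) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("cell%03d", seq_len(nrow(scores)))
  assignment <- character(nrow(scores))
  names(assignment) <- rownames(scores)
  with_seed(seed, {
    for (cond in c("D0", "D4")) {
      idx <- which(labels == cond)
      if (length(idx) < n_groups)
        stop("fewer ", cond, " cells (", length(idx), ") than groups (",
             n_groups, ")")
      sizes <- rep(length(idx) %/% n_groups, n_groups)
      extra <- length(idx) %% n_groups
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      perm <- sample(idx)
      assignment[perm] <- rep(sprintf("%s-%d", cond, seq_len(n_groups)),
                              times = sizes)
    }
  })
  groups <- sprintf("%s-%d", rep(c("D0", "D4"), each = n_groups),
                    rep(seq_len(n_groups), 2))
  targets <- t(vapply(groups, function(g) {
    colMeans(scores[assignment == g, , drop = FALSE])
  }, numeric(ncol(scores))))
  colnames(targets) <- colnames(scores)
  structure(list(assignment = assignment, targets = targets,
                 conditions = stats::setNames(sub("-.*$", "", groups), groups),
                 seed = seed),
            class = "pseudo_replicates")
}

#' Transcript features for PLS, with training-only centering
#'
#' Transforms counts to `log2(1 + count)` per transcript and centers each
#' transcript using the *training* samples' means only; held-out samples
#' are centered with the training means, never their own.
#'
#' @param counts A [count_matrix()] or a numeric matrix (transcripts x
#'   samples); a plain matrix is taken as already-transformed features when
#'   `transform = "identity"`.
#' @param train_ids Sample ids forming the training set.
#' @param transform `"log2"` (default) or `"identity"`.
#' @return List: `features` (samples x transcripts, all samples, centered
#'   on training means), `center`, `train_ids`.
#' @export
preprocess_counts <- function(counts, train_ids,
                              transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!all(train_ids %in% colnames(m)))
    stop("unknown training sample id(s): ",
         paste(setdiff(train_ids, colnames(m)), collapse = ", "))
  f <- t(if (transform == "log2") log2(1 + m) else m)  # samples x transcripts
  center <- colMeans(f[train_ids, , drop = FALSE])
  list(features = sweep(f, 2, center), center = center,
       train_ids = train_ids)
}

#' PLS2 regression by NIPALS
#'
#' Fits a partial least squares regression with multivariate response
#' (NIPALS with deflation of both blocks), giving the coefficient matrix
#' `beta` that maps centered transcript features to centered PC-score
#' vectors. Extraction stops early (with a message in `A_used`) if the
#' feature block is exhausted before `A` components.
#'
#' @param X Feature matrix, samples x transcripts (uncentered; centering
#'   vectors are stored in the model).
#' @param Y Response matrix, samples x PC dimensions.
#' @param A Number of latent components (default 2).
#' @return Object of class `pls_model`: `W`, `Tsc`, `P`, `Q`, `beta`,
#'   `x_center`, `y_center`, `ssy` (response variance explained per
#'   component), `A`, `A_used`, `fitted`.
#' @export
fit_pls <- function(X, Y, A = 2) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(dim(Y))) Y <- cbind(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of samples")
  if (A < 0) stop("A must be >= 0")
  if (A > n - 1) stop("A must be <= samples - 1")
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center); Yc <- sweep(Y, 2, y_center)
  if (all(abs(Yc) < 1e-300)) stop("zero-variance response")
  p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, m, A)
  Tsc <- matrix(0, n, A); ssy <- numeric(A)
  Xd <- Xc; Yd <- Yc
  a_used <- 0L
  for (a in seq_len(A)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    if (sum(u^2) < 1e-24 || sum(Xd^2) < 1e-24) break
    w <- crossprod(Xd, u)
    for (iter in 1:500) {
      nw <- sqrt(sum(w^2))
      if (nw < 1e-24) break
      w <- w / nw
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / drop(crossprod(tt))
      u_new <- Yd %*% q / drop(crossprod(q))
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * (sqrt(sum(u_new^2)) + 1e-300) ||
          m == 1) { u <- u_new; break }
      u <- u_new
      w <- crossprod(Xd, u)
    }
    if (sqrt(sum(w^2)) < 1e-24) break
    tt <- Xd %*% w
    t2 <- drop(crossprod(tt))
    if (t2 < 1e-24) break
    pl <- crossprod(Xd, tt) / t2
    q <- crossprod(Yd, tt) / t2
    Xd <- Xd - tt %*% t(pl)
    Yd <- Yd - tt %*% t(q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tsc[, a] <- tt
    ssy[a] <- sum(q^2) * t2
    a_used <- a
  }
  if (a_used < A) {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Q <- Q[, seq_len(a_used), drop = FALSE]
    Tsc <- Tsc[, seq_len(a_used), drop = FALSE]
    ssy <- ssy[seq_len(a_used)]
  }
  beta <- if (a_used == 0) matrix(0, p, m) else
    W %*% solve(crossprod(P, W), t(Q))
  dimnames(beta) <- list(colnames(X), colnames(Y))
  fitted <- sweep(Xc %*% beta, 2, y_center, "+")
  structure(list(W = W, Tsc = Tsc, P = P, Q = Q, beta = beta,
                 x_center = x_center, y_center = y_center, ssy = ssy,
                 A = A, A_used = a_used, fitted = fitted),
            class = "pls_model")
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Feature matrix (samples x transcripts, uncentered).
#' @param ... Unused.
#' @return Predicted response matrix.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  sweep(sweep(newdata, 2, object$x_center) %*% object$beta, 2,
        object$y_center, "+")
}

#' Variable Importance in Projection
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * (w_ja / ||w_a||)^2) / sum_a(SSY_a))`,
#' where `p` is the number of transcripts and `SSY_a` the response variance
#' explained by latent component `a`. The mean of the squared VIP over all
#' transcripts is exactly 1.
#'
#' @param model A fitted `pls_model` with at least one component.
#' @param top_n Number of top transcripts to extract (default 20).
#' @return Object of class `vip_ranking`: `vip` (named, model order),
#'   `ranking` (data.frame sorted by decreasing VIP), `top` (top_n ids).
#' @export
vip_scores <- function(model, top_n = 20) {
  if (model$A_used < 1) stop("VIP requires at least one latent component")
  Wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  p <- nrow(model$W)
  vip <- sqrt(p * drop(Wn^2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- rownames(model$beta) %||% sprintf("x%d", seq_along(vip))
  ord <- order(vip, decreasing = TRUE)
  ranking <- data.frame(transcript = names(vip)[ord], vip = vip[ord],
                        rank = seq_along(vip), row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(vip = vip, ranking = ranking,
                 top = ranking$transcript[seq_len(min(top_n, nrow(ranking)))]),
            class = "vip_ranking")
}

#' Fraction of planted informative transcripts recovered in the top N
#'
#' @param ranking A [vip_scores()] result (or character vector of ranked
#'   ids).
#' @param truth Transcriptome truth (list with `informative`) or a
#'   character vector of informative ids.
#' @param N Top-list length (default 20).
#' @return `|top-N intersect informative| / min(N, |informative|)`.
#' @export
vip_recovery <- function(ranking, truth, N = 20) {
  ids <- if (inherits(ranking, "vip_ranking")) ranking$ranking$transcript
  else as.character(ranking)
  inf <- if (is.list(truth)) truth$informative else as.character(truth)
  top <- ids[seq_len(min(N, length(ids)))]
  length(intersect(top, inf)) / min(N, length(inf))
}

#' Leave-one-out PLS prediction of Raman PC scores from counts
#'
#' Each of the samples is held out in turn; a PLS2 model is fit on the
#' remaining samples (features centered on training means only) and the
#' held-out sample's PC-score vector is predicted from its transcript
#' features. When an `ld_model` is supplied, predictions are converted to
#' LD scores and D0/D4 group calls.
#'
#' @param counts A [count_matrix()] or feature matrix (transcripts x
#'   samples).
#' @param targets Response matrix, samples x PC dimensions, rownames
#'   matching the count columns.
#' @param A Latent components (default 2).
#' @param ld_model Optional [fit_lda()] model for LD conversion.
#' @param transform Passed to [preprocess_counts()].
#' @return List: `predictions` (data.frame sample, condition, ld_score,
#'   call, correct, residual), `predicted` (matrix of predicted PC
#'   scores).
#' @export
loo_predict <- function(counts, targets, A = 2, ld_model = NULL,
                        transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  targets <- as.matrix(targets)
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  ids <- rownames(targets)
  if (is.null(ids) || !all(ids %in% colnames(m)))
    stop("targets rownames must match count sample ids")
  if (nrow(targets) < 3) stop("need at least 3 samples")
  cond <- sub("-.*$", "", ids)
  pred <- matrix(NA_real_, nrow(targets), ncol(targets),
                 dimnames = dimnames(targets))
  for (i in seq_along(ids)) {
    tr <- ids[-i]
    if (length(unique(cond[-i])) < 2)
      stop("leave-one-out fold lost a condition")
    pp <- preprocess_counts(m, tr, transform)
    fit <- fit_pls(pp$features[tr, , drop = FALSE] , targets[tr, , drop = FALSE],
                   A = A)
    # features already centered on training means; predict() re-centers
    # with the model's x_center (~0 here), so this stays training-only
    pred[i, ] <- predict(fit, pp$features[ids[i], , drop = FALSE])
  }
  res <- data.frame(sample = ids, condition = cond,
                    residual = sqrt(rowSums((pred - targets)^2)),
                    stringsAsFactors = FALSE)
  if (!is.null(ld_model)) {
    pl <- predict_ld(ld_model, pred)
    res$ld_score <- pl$ld_score
    res$call <- pl$call
    res$correct <- res$call == res$condition
  }
  list(predictions = res, predicted = pred)
}

#' Full cross-modal analysis for one compartment
#'
#' Chains pseudo-replicate construction (or uses supplied targets), the
#' full-data PLS fit, VIP ranking, and leave-one-out prediction with group
#' calls.
#'
#' @param counts A [count_matrix()].
#' @param pc_model A [fit_pca()] model of the per-cell compartment spectra.
#' @param labels Condition per cell.
#' @param ld_model [fit_lda()] model for the group-call conversion.
#' @param n_groups Pseudo-replicates per condition (default 3).
#' @param A PLS components (default 2).
#' @param seed Seed for the pseudo-replicate partition.
#' @param top_n VIP top-list length (default 20).
#' @return List: `pseudo`, `pls` (full-data fit), `vip`, `loo`.
#' @export
crossmodal_analysis <- function(counts, pc_model, labels, ld_model,
                                n_groups = 3, A = 2, seed = 1L,
                                top_n = 20) {
  pseudo <- make_pseudoreplicates(pc_model$scores, labels, n_groups, seed)
  targets <- pseudo$targets
  mm <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!all(rownames(targets) %in% colnames(mm)))
    stop("count sample ids must match pseudo-replicate group ids (",
         paste(rownames(targets), collapse = ", "), ")")
  pp <- preprocess_counts(counts, rownames(targets))
  full <- fit_pls(pp$features[rownames(targets), , drop = FALSE], targets,
                  A = A)
  vip <- vip_scores(full, top_n = top_n)
  loo <- loo_predict(counts, targets, A = A, ld_model = ld_model)
  list(pseudo = pseudo, pls = full, vip = vip, loo = loo)
}
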