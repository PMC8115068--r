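#' Subject x voxel feature matrix for voxel-wise classification
#'
#' @param x Numeric matrix, subjects in rows, striatal voxel Ki values in
#'   columns (raw, no further pre-processing).
#' @param y Labels, +1 for non-responders, -1 for responders.
#' @param voxel_idx Optional linear voxel indices defining the (fixed)
#'   column order; used to verify compatibility when combining cohorts.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, y, voxel_idx = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("one label per subject required")
  if (anyNA(x) || any(!is.finite(x))) stop("missing values in features")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (!is.null(voxel_idx) && length(voxel_idx) != ncol(x))
    stop("voxel_idx length must equal feature count")
  structure(list(x = x, y = as.numeric(y), voxel_idx = voxel_idx),
            class = "feature_matrix")
}

#' Extract voxel-wise Ki features from a simulated or mapped cohort
#'
#' Computes a Patlak parametric map per subject ([parametric_map()]) and
#' flattens the striatal voxels (fixed mask linear-index order) into one row
#' per subject.  Controls carry no response label and are dropped; labels
#' follow the +1 = non-responder / -1 = responder convention.
#'
#' @param scans List of [subject_scan()]s.
#' @param t_star,weights Passed to [parametric_map()].
#' @return A [feature_matrix()].
#' @export
extract_feature_matrix <- function(scans, t_star = 30, weights = "uniform") {
  scans <- Filter(function(s) s$group %in% c("responder", "nonresponder"),
                  scans)
  if (!length(scans)) stop("no labelled (responder/non-responder) subjects")
  idx <- mask_region_idx(scans[[1L]]$mask, "striatum")
  rows <- lapply(scans, function(s) {
    m <- parametric_map(s, t_star = t_star, weights = weights)
    v <- m$ki[idx]
    if (anyNA(v)) stop("subject ", s$subject_id,
                       " has unfitted striatal voxels")
    v
  })
  feature_matrix(do.call(rbind, rows),
                 ifelse(vapply(scans, `[[`, "", "group") == "nonresponder",
                        1, -1),
                 voxel_idx = idx)
}

#' Combine two cohorts' feature matrices
#'
#' Row-concatenates two feature matrices after checking they use the same
#' voxel ordering.  Combining with an empty matrix is the identity.
#'
#' @param a,b [feature_matrix()] objects.
#' @return A [feature_matrix()].
#' @export
combine_cohorts <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (nrow(b$x) == 0L) return(a)
  if (nrow(a$x) == 0L) return(b)
  if (ncol(a$x) != ncol(b$x) ||
      (!is.null(a$voxel_idx) && !is.null(b$voxel_idx) &&
       !identical(a$voxel_idx, b$voxel_idx)))
    stop("feature matrices use different masks / voxel orderings")
  feature_matrix(rbind(a$x, b$x), c(a$y, b$y), a$voxel_idx)
}

#' Classifier specification
#'
#' The fixed model zoo evaluated under leave-one-out cross-validation:
#' ridge-penalised Bernoulli logistic regression and a linear SVM (both
#' linear models \eqn{f_i = W x_i + b} minimising
#' \eqn{\sum_i l(y_i, f_i) + \alpha \|W\|^2} with \eqn{\alpha = 1}), an RBF
#' SVM, a random forest (bootstrap aggregating), k-nearest-neighbours with
#' k = 2 or 3, and a Gaussian-process classifier with squared-exponential
#' kernel, probit link and Laplace approximation.  All kernel machines are
#' solved in the dual (weights expanded over training subjects), which is
#' exact for these losses and fast when subjects << voxels.
#'
#' @param family One of `"bernoulli_logistic"`, `"linear_svm"`, `"rbf_svm"`,
#'   `"random_forest"`, `"knn"`, `"gp_probit"`.
#' @param alpha Regularisation weight for the penalised linear/kernel losses
#'   (default 1).
#' @param k Neighbour count for `"knn"` (2 or 3 in the zoo; default 3).
#' @param n_trees Trees for `"random_forest"` (default 100).
#' @param kernel_scale Squared lengthscale for RBF/GP kernels; default
#'   `NULL` = number of features times the mean feature variance of the
#'   training set.
#' @return A `model_spec`; `stochastic` is `TRUE` only for the random
#'   forest.
#' @export
model_spec <- function(family = c("bernoulli_logistic", "linear_svm",
                                  "rbf_svm", "random_forest", "knn",
                                  "gp_probit"),
                       alpha = 1, k = 3L, n_trees = 100L,
                       kernel_scale = NULL) {
  family <- match.arg(family)
  if (alpha <= 0) stop("alpha must be > 0")
  if (k < 1L) stop("k must be >= 1")
  structure(list(family = family, alpha = alpha, k = as.integer(k),
                 n_trees = as.integer(n_trees), kernel_scale = kernel_scale,
                 stochastic = family == "random_forest"),
            class = "model_spec")
}

# ---- internal learners -----------------------------------------------------
# Each fit_* consumes training features/labels and returns a closure scoring
# new rows with a continuous decision value oriented to the positive class.

sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, `+`) - 2 * tcrossprod(A, B), 0)
}

kernel_matrix <- function(A, B, family, scale) {
  if (family %in% c("bernoulli_logistic", "linear_svm")) return(tcrossprod(A, B))
  exp(-sq_dist(A, B) / (2 * scale))
}

rbf_default_scale <- function(X) {
  cm <- colMeans(X)
  s <- sum(colMeans(X^2) - cm^2) * nrow(X) / max(1, nrow(X) - 1)
  if (s <= 0) 1 else s
}

kernel_scale_for <- function(X, spec) {
  if (spec$family %in% c("bernoulli_logistic", "linear_svm")) return(1)
  spec$kernel_scale %||% rbf_default_scale(X)
}

# dual kernel machine: minimise sum l(y_i, f_i) + alpha a'Ka over (a, b).
# The problem is convex, so warm starts (used by the cross-validation loops)
# change only the iteration count, never the solution.
fit_kernel_machine <- function(X, y, spec, loss, init = NULL) {
  scale <- kernel_scale_for(X, spec)
  K <- kernel_matrix(X, X, spec$family, scale)
  n <- nrow(X)
  obj <- function(p) {
    a <- p[1:n]; b <- p[n + 1L]
    f <- as.numeric(K %*% a) + b
    loss$value(y, f) + spec$alpha * sum(a * (K %*% a))
  }
  grd <- function(p) {
    a <- p[1:n]; b <- p[n + 1L]
    f <- as.numeric(K %*% a) + b
    d <- loss$dloss(y, f)
    c(as.numeric(K %*% d) + 2 * spec$alpha * as.numeric(K %*% a), sum(d))
  }
  if (is.null(init)) init <- rep(0, n + 1L)
  fit <- stats::optim(init, obj, grd, method = "L-BFGS-B",
                      control = list(maxit = 300, factr = 1e7))
  a <- fit$par[1:n]; b <- fit$par[n + 1L]
  structure(function(Xnew)
    as.numeric(kernel_matrix(Xnew, X, spec$family, scale) %*% a) + b,
    par = fit$par)
}

loss_logistic <- list(
  value = function(y, f) sum(log1p(exp(-pmin(y * f, 30))) +
                               pmax(-y * f - 30, 0)),
  dloss = function(y, f) -y / (1 + exp(pmin(pmax(y * f, -30), 30))))

loss_sqhinge <- list(
  value = function(y, f) sum(pmax(1 - y * f, 0)^2),
  dloss = function(y, f) -2 * y * pmax(1 - y * f, 0))

fit_knn <- function(X, y, spec) {
  function(Xnew) {
    d2 <- sq_dist(Xnew, X)
    apply(d2, 1L, function(d) {
      nb <- order(d)[seq_len(min(spec$k, length(d)))]
      mean(y[nb] == 1)
    })
  }
}

# Laplace-approximation GP classifier with probit likelihood
fit_gp_probit <- function(X, y, spec) {
  scale <- spec$kernel_scale %||% rbf_default_scale(X)
  n <- nrow(X)
  K <- kernel_matrix(X, X, "rbf_svm", scale) + diag(1e-6, n)
  f <- rep(0, n)
  for (it in 1:50) {
    z <- y * f
    lp <- stats::dnorm(z) / pmax(stats::pnorm(z), 1e-12)
    g <- y * lp                       # d log p(y|f) / df
    W <- lp * (z + lp)                # -d2 log p / df2  (positive)
    B <- diag(n) + sqrt(W) * t(sqrt(W) * t(K))
    L <- chol(B)
    bb <- W * f + g
    a <- bb - sqrt(W) * backsolve(L, forwardsolve(t(L), sqrt(W) * as.numeric(K %*% bb)))
    f_new <- as.numeric(K %*% a)
    if (max(abs(f_new - f)) < 1e-8) { f <- f_new; break }
    f <- f_new
  }
  z <- y * f
  g <- y * stats::dnorm(z) / pmax(stats::pnorm(z), 1e-12)
  function(Xnew)
    as.numeric(kernel_matrix(Xnew, X, "rbf_svm", scale) %*% g)
}

# compact CART random forest (gini impurity, bootstrap rows, mtry features)
fit_random_forest <- function(X, y, spec) {
  n <- nrow(X); V <- ncol(X)
  mtry <- max(1L, floor(sqrt(V)))
  grow <- function(rows, depth) {
    pos <- mean(y[rows] == 1)
    if (depth >= 8L || length(rows) < 4L || pos %in% c(0, 1))
      return(list(leaf = TRUE, prob = pos))
    feats <- sample.int(V, mtry)
    best <- NULL; best_gain <- 1e-12
    par_imp <- 2 * pos * (1 - pos)
    m <- length(rows)
    ypos <- y[rows] == 1
    for (j in feats) {
      v <- X[rows, j]
      o <- order(v)
      vs <- v[o]
      valid <- which(diff(vs) > 0)          # split between distinct values
      if (!length(valid)) next
      cpos <- cumsum(ypos[o])
      nl <- valid
      pl <- cpos[valid] / nl
      pr <- (cpos[m] - cpos[valid]) / (m - nl)
      gain <- par_imp - (nl * 2 * pl * (1 - pl) +
                           (m - nl) * 2 * pr * (1 - pr)) / m
      bi <- which.max(gain)
      if (gain[bi] > best_gain) {
        best_gain <- gain[bi]
        best <- list(j = j, cut = (vs[valid[bi]] + vs[valid[bi] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = pos))
    l <- X[rows, best$j] <= best$cut
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = grow(rows[l], depth + 1L),
         right = grow(rows[!l], depth + 1L))
  }
  trees <- lapply(seq_len(spec$n_trees), function(t)
    grow(sample.int(n, n, replace = TRUE), 0L))
  predict_tree <- function(node, xrow) {
    while (!node$leaf)
      node <- if (xrow[node$j] <= node$cut) node$left else node$right
    node$prob
  }
  function(Xnew)
    apply(Xnew, 1L, function(xr)
      mean(vapply(trees, predict_tree, numeric(1), xrow = xr)))
}

fit_model <- function(X, y, spec, init = NULL) {
  switch(spec$family,
         bernoulli_logistic = fit_kernel_machine(X, y, spec, loss_logistic,
                                                 init),
         linear_svm = fit_kernel_machine(X, y, spec, loss_sqhinge, init),
         rbf_svm = fit_kernel_machine(X, y, spec, loss_sqhinge, init),
         knn = fit_knn(X, y, spec),
         gp_probit = fit_gp_probit(X, y, spec),
         random_forest = fit_random_forest(X, y, spec))
}

is_kernel_family <- function(spec)
  spec$family %in% c("bernoulli_logistic", "linear_svm", "rbf_svm")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-out cross-validated AUC for a classifier
#'
#' Held-out AUC of a [model_spec()] classifier, fixed orientation (high
#' decision score = non-responder).  Two estimators are available:
#'
#' * `"lpo"` (default): leave-pair-out - for every (non-responder,
#'   responder) pair the model is fitted on the other N-2 subjects and the
#'   pair's held-out scores are compared; the AUC is the concordant
#'   fraction (ties half-credit).  This is the standard nearly unbiased AUC
#'   estimator for small-sample cross-validation.
#' * `"pooled"`: classic leave-one-out - each subject is scored by a model
#'   fitted on the other N-1, the N pooled scores form one ROC (computed by
#'   [roc_curve()]).  Pooled LOO scores are kept available because they
#'   yield a single curve, but their AUC is strongly pessimistic under weak
#'   signal (each fold's training set under-represents the held-out class;
#'   under a label permutation the expected AUC falls well below 0.5), which
#'   is why it is not the default.
#'
#' Held-out scores are always centred on the fold's training-score mean,
#' using training data only.  Stochastic families repeat over `seeds`
#' (default 100); deterministic families give identical results for every
#' seed by construction.
#'
#' @param spec A [model_spec()].
#' @param features A [feature_matrix()] with N >= 4 and both classes >= 2.
#' @param seeds Integer vector of RNG seeds; default `1:100` for stochastic
#'   families and `1` otherwise.
#' @param auc_method `"lpo"` (leave-pair-out, default) or `"pooled"`
#'   (pooled leave-one-out scores).
#' @return A `cv_result`: `auc` (per seed), `mean_auc`, `sd_auc`, `n_seeds`,
#'   `scores` (per-subject held-out decision scores, last seed; for `"lpo"`
#'   the mean over the subject's pair folds), `n_failed_folds`.
#' @export
loocv_evaluate <- function(spec, features, seeds = NULL,
                           auc_method = c("lpo", "pooled")) {
  stopifnot(inherits(spec, "model_spec"), inherits(features, "feature_matrix"))
  auc_method <- match.arg(auc_method)
  X <- features$x; y <- features$y
  n <- nrow(X)
  if (n < 4L || sum(y == 1) < 2L || sum(y == -1) < 2L)
    stop("need N >= 4 with at least 2 subjects per class")
  if (is.null(seeds)) seeds <- if (spec$stochastic) 1:100 else 1L
  aucs <- numeric(length(seeds))
  scores <- numeric(n)
  failed <- 0L
  # no warm starts across folds: the held-out subject's label must not be
  # able to influence its own score, even through optimiser convergence
  fit_score <- function(train, test) {
    tryCatch({
      predict_fun <- fit_model(X[train, , drop = FALSE], y[train], spec)
      predict_fun(X[test, , drop = FALSE]) -
        mean(predict_fun(X[train, , drop = FALSE]))
    }, error = function(e) rep(NA_real_, length(test)))
  }
  pos <- which(y == 1); neg <- which(y == -1)
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    if (auc_method == "pooled") {
      for (i in seq_len(n)) {
        sc <- fit_score(setdiff(seq_len(n), i), i)
        if (is.na(sc)) { failed <- failed + 1L; sc <- 0 }
        scores[i] <- sc
      }
      aucs[si] <- roc_curve(labelled_scores(scores, y == 1,
                                            positive_low = FALSE))$auc
    } else {
      concord <- 0
      npairs <- 0L
      ssum <- numeric(n); scnt <- integer(n)
      for (i in pos) for (j in neg) {
        sc <- fit_score(setdiff(seq_len(n), c(i, j)), c(i, j))
        if (anyNA(sc)) { failed <- failed + 1L; next }
        concord <- concord + (sc[1L] > sc[2L]) + 0.5 * (sc[1L] == sc[2L])
        npairs <- npairs + 1L
        ssum[c(i, j)] <- ssum[c(i, j)] + sc
        scnt[c(i, j)] <- scnt[c(i, j)] + 1L
      }
      if (npairs == 0L) stop("all pair folds failed")
      aucs[si] <- concord / npairs
      scores <- ifelse(scnt > 0L, ssum / pmax(scnt, 1L), 0)
    }
  }
  structure(list(auc = aucs, mean_auc = mean(aucs),
                 sd_auc = if (length(aucs) > 1L) stats::sd(aucs) else 0,
                 n_seeds = length(seeds), scores = scores,
                 n_failed_folds = failed, family = spec$family,
                 auc_method = auc_method),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AUC %.3f +/- %.3f (%d seed%s)\n",
              x$family, x$mean_auc, x$sd_auc, x$n_seeds,
              if (x$n_seeds > 1) "s" else ""))
  invisible(x)
}
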