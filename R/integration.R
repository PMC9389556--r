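#' PCA with per-feature contributions
#'
#' Centered (optionally unit-scaled) principal component analysis; the
#' contribution of feature f to component c is `100 * loading^2` (so
#' contributions sum to 100 per component), with the signed loading
#' retained alongside.
#'
#' @param m samples x features matrix.
#' @param scale. unit-scale features before PCA (default FALSE).
#' @param n_components number of components returned (default
#'   `min(dim(m)) - 1`).
#' @return list with scores, loadings, contributions (%), var_explained.
#' @export
pca_contributions <- function(m, scale. = FALSE, n_components = NULL) {
  if (nrow(m) < 2 || ncol(m) < 2) stop_cfg("need >= 2 samples and >= 2 features")
  if (scale. && any(apply(m, 2, stats::sd) == 0)) {
    stop_cfg("constant feature(s) present with scaling enabled")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  k <- n_components %||% min(dim(m) - c(1, 0))
  k <- min(k, ncol(pc$rotation))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       contributions = 100 * pc$rotation[, seq_len(k), drop = FALSE]^2,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

make_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# Fisher canonical discriminant axes in a (possibly reduced) space.
fisher_cva <- function(x, classes) {
  cls <- unique(classes)
  mu <- colMeans(x)
  W <- matrix(0, ncol(x), ncol(x))
  B <- matrix(0, ncol(x), ncol(x))
  for (c in cls) {
    xc <- x[classes == c, , drop = FALSE]
    d <- sweep(xc, 2, colMeans(xc))
    W <- W + crossprod(d)
    db <- colMeans(xc) - mu
    B <- B + nrow(xc) * tcrossprod(db)
  }
  W <- W + diag(1e-8, ncol(x))
  ev <- eigen(solve(W, B))
  k <- min(length(cls) - 1, ncol(x))
  axes <- Re(ev$vectors[, seq_len(k), drop = FALSE])
  list(axes = axes, eigenvalues = Re(ev$values[seq_len(k)]))
}

#' Cross-validated canonical variate analysis
#'
#' PCA reduction to `n_pcs` followed by Fisher canonical discriminant axes
#' in the reduced space, with feature loadings back-projected through the
#' PCA rotation. Per-sample variate scores are produced under stratified
#' fold-wise cross-validation: each sample is scored by a model fit without
#' it, with fold axes sign-aligned to the full-data axes.
#'
#' @param m samples x features matrix.
#' @param classes class labels (>= 2 classes, each with >= `cv_folds`
#'   members).
#' @param n_pcs PCA dimensions retained (< n_samples).
#' @param cv_folds number of folds (default 5).
#' @param seed fold seed.
#' @return list with variates_cv (samples x axes), loadings (features x
#'   axes), eigenvalues, folds.
#' @export
cva_crossvalidated <- function(m, classes, n_pcs = 10, cv_folds = 5, seed = 1L) {
  classes <- as.character(classes)
  if (length(unique(classes)) < 2) stop_cfg("need >= 2 classes")
  if (n_pcs >= nrow(m)) stop_cfg("n_pcs must be < n_samples")
  if (min(table(classes)) < cv_folds) {
    stop_cfg("each class needs >= cv_folds members")
  }
  pc <- stats::prcomp(m, center = TRUE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  full <- fisher_cva(pc$x[, seq_len(n_pcs), drop = FALSE], classes)
  loadings <- pc$rotation[, seq_len(n_pcs), drop = FALSE] %*% full$axes
  folds <- make_folds(classes, cv_folds, seed)
  variates <- matrix(NA_real_, nrow(m), ncol(full$axes))
  rownames(variates) <- rownames(m)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    pc_f <- stats::prcomp(m[tr, , drop = FALSE], center = TRUE)
    k_f <- min(n_pcs, ncol(pc_f$x))
    cva_f <- fisher_cva(pc_f$x[, seq_len(k_f), drop = FALSE], classes[tr])
    load_f <- pc_f$rotation[, seq_len(k_f), drop = FALSE] %*% cva_f$axes
    # sign-align each axis to the full-data solution
    for (a in seq_len(ncol(load_f))) {
      if (a <= ncol(loadings) &&
          sum(load_f[, a] * loadings[, a]) < 0) load_f[, a] <- -load_f[, a]
    }
    xt <- sweep(m[!tr, , drop = FALSE], 2, colMeans(m[tr, , drop = FALSE]))
    variates[!tr, seq_len(ncol(load_f))] <- xt %*% load_f
  }
  list(variates_cv = variates, loadings = loadings,
       eigenvalues = full$eigenvalues, folds = folds)
}

# Center and unit-scale block columns; zero-variance columns are centered
# only.
preprocess_block <- function(x) {
  s <- apply(x, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  scale(x, scale = s)
}

hard_threshold <- function(z, keep) {
  if (keep < length(z)) {
    cut <- sort(abs(z), decreasing = TRUE)[keep]
    z[abs(z) < cut] <- 0
    # guard against ties straddling the cutoff: keep exactly `keep` entries
    nz <- which(z != 0)
    if (length(nz) > keep) {
      ord <- nz[order(-abs(z[nz]), nz)]
      z[setdiff(nz, ord[seq_len(keep)])] <- 0
    }
  }
  nrm <- sqrt(sum(z^2))
  if (nrm > 0) z / nrm else z
}

#' Supervised multi-block sparse PLS-DA (DIABLO-style)
#'
#' Iterative block coordinate ascent maximizing the design-weighted sum of
#' covariances between block variates and the outcome-indicator variate,
#' `sum_{j<k} design[j,k] cov(X_j w_j, X_k w_k)`, with the outcome coded as
#' a dummy-indicator block. Sparsity is imposed by hard-thresholding each
#' loading to its `keep` largest absolute entries and renormalizing to unit
#' norm (the exact constrained maximizer of each block update, so the
#' objective is non-decreasing across iterations). Blocks are deflated by
#' regression on their own variates between components.
#'
#' @param blocks named list of samples x features matrices, identical row
#'   order.
#' @param y binary outcome (0/1) aligned with the block rows.
#' @param design optional (B+1) x (B+1) symmetric weight matrix in \[0,1\]
#'   with zero diagonal (last row/column = outcome block); default full
#'   design (all off-diagonal weights 1).
#' @param n_components number of components (default 2).
#' @param keep integer vector (recycled across blocks) or per-block list of
#'   per-component feature counts retained; default full width.
#' @param max_iter,tol convergence controls (default 500, 1e-6).
#' @return object of class `diablo_model`: loadings, variates, y_loadings,
#'   design, keep, objective traces, convergence flags.
#' @export
fit_diablo <- function(blocks, y, design = NULL, n_components = 2,
                       keep = NULL, max_iter = 500, tol = 1e-6) {
  B <- length(blocks)
  if (B < 1) stop_cfg("need at least one block")
  n <- nrow(blocks[[1]])
  if (!all(vapply(blocks, nrow, integer(1)) == n)) stop_cfg("blocks must share the sample axis")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(B))
  y <- as.integer(y)
  Y <- stats::model.matrix(~ 0 + factor(y, levels = c(0, 1)))
  colnames(Y) <- c("class0", "class1")
  X <- lapply(blocks, preprocess_block)
  Y <- preprocess_block(Y)
  if (is.null(design)) {
    design <- matrix(1, B + 1, B + 1)
    diag(design) <- 0
  }
  if (!isTRUE(all.equal(design, t(design))) || any(diag(design) != 0)) {
    stop_cfg("design must be symmetric with zero diagonal")
  }
  widths <- vapply(X, ncol, integer(1))
  keep_mat <- resolve_keep(keep, widths, n_components, names(blocks))

  loadings <- lapply(seq_len(B), function(j)
    matrix(0, widths[j], n_components,
           dimnames = list(colnames(X[[j]]), paste0("comp", seq_len(n_components)))))
  names(loadings) <- names(blocks)
  variates <- lapply(seq_len(B), function(j)
    matrix(0, n, n_components, dimnames = list(rownames(blocks[[j]]),
                                               paste0("comp", seq_len(n_components)))))
  names(variates) <- names(blocks)
  y_loadings <- matrix(0, ncol(Y), n_components)
  y_variates <- matrix(0, n, n_components)
  objective <- vector("list", n_components)
  converged <- logical(n_components)

  for (h in seq_len(n_components)) {
    w <- lapply(X, function(x) {
      v <- svd(x, nu = 0, nv = 1)$v[, 1]
      v / sqrt(sum(v^2))
    })
    c_y <- svd(Y, nu = 0, nv = 1)$v[, 1]
    t_list <- mapply(function(x, wj) drop(x %*% wj), X, w, SIMPLIFY = FALSE)
    t_y <- drop(Y %*% c_y)
    obj_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      w_old <- w
      for (j in seq_len(B)) {
        z <- numeric(widths[j])
        for (k in seq_len(B)) {
          if (k != j && design[j, k] > 0) z <- z + design[j, k] * crossprod(X[[j]], t_list[[k]])
        }
        if (design[j, B + 1] > 0) z <- z + design[j, B + 1] * crossprod(X[[j]], t_y)
        w[[j]] <- hard_threshold(drop(z), keep_mat[j, h])
        t_list[[j]] <- drop(X[[j]] %*% w[[j]])
      }
      zy <- numeric(ncol(Y))
      for (k in seq_len(B)) {
        if (design[B + 1, k] > 0) zy <- zy + design[B + 1, k] * crossprod(Y, t_list[[k]])
      }
      nrm <- sqrt(sum(zy^2))
      if (nrm > 0) c_y <- drop(zy) / nrm
      t_y <- drop(Y %*% c_y)
      obj <- 0
      for (j in seq_len(B)) {
        for (k in seq_len(B)) {
          if (k > j) obj <- obj + design[j, k] * sum(t_list[[j]] * t_list[[k]]) / (n - 1)
        }
        obj <- obj + design[j, B + 1] * sum(t_list[[j]] * t_y) / (n - 1)
      }
      obj_trace <- c(obj_trace, obj)
      delta <- max(vapply(seq_len(B), function(j) max(abs(w[[j]] - w_old[[j]])),
                          numeric(1)))
      if (delta < tol) { converged[h] <- TRUE; break }
    }
    if (!converged[h]) {
      warning(sprintf("component %d: no convergence after %d iterations (last delta > %g)",
                      h, max_iter, tol))
    }
    objective[[h]] <- obj_trace
    for (j in seq_len(B)) {
      loadings[[j]][, h] <- w[[j]]
      variates[[j]][, h] <- t_list[[j]]
      tj <- t_list[[j]]
      den <- sum(tj^2)
      if (den > 0) X[[j]] <- X[[j]] - tj %*% (crossprod(tj, X[[j]]) / den)
    }
    y_loadings[, h] <- c_y
    y_variates[, h] <- t_y
  }
  structure(list(loadings = loadings, variates = variates,
                 y_loadings = y_loadings, y_variates = y_variates,
                 design = design, keep = keep_mat, y = y,
                 blocks_processed = lapply(blocks, preprocess_block),
                 centers = lapply(blocks, colMeans),
                 scales = lapply(blocks, function(b) {
                   s <- apply(b, 2, stats::sd); s[s == 0 | is.na(s)] <- 1; s
                 }),
                 objective = objective, converged = converged,
                 n_components = n_components),
            class = "diablo_model")
}

resolve_keep <- function(keep, widths, n_components, block_names) {
  B <- length(widths)
  if (is.null(keep)) {
    m <- matrix(rep(widths, n_components), nrow = B)
  } else if (is.list(keep)) {
    m <- do.call(rbind, lapply(seq_len(B), function(j) rep_len(keep[[j]], n_components)))
  } else {
    m <- matrix(rep(rep_len(keep, B), n_components), nrow = B)
  }
  m <- pmin(m, widths)
  if (any(m < 1)) stop_cfg("keep must be >= 1")
  rownames(m) <- block_names
  m
}

#' @export
print.diablo_model <- function(x, ...) {
  cat(sprintf("diablo_model: %d block(s), %d component(s)\n",
              length(x$loadings), x$n_components))
  for (j in names(x$loadings)) {
    cat(sprintf("  %s: %d features, keep = %s\n", j, nrow(x$loadings[[j]]),
                paste(x$keep[j, ], collapse = "/")))
  }
  invisible(x)
}

# Project new block data onto a fitted model; returns per-block variates.
diablo_project <- function(model, blocks) {
  lapply(names(model$loadings), function(j) {
    x <- scale(blocks[[j]], center = model$centers[[j]], scale = model$scales[[j]])
    x %*% model$loadings[[j]]
  }) |> stats::setNames(names(model$loadings))
}

# Nearest-centroid classification on the block-averaged variates.
diablo_classify <- function(model, blocks_test) {
  tr <- Reduce(`+`, model$variates) / length(model$variates)
  te <- Reduce(`+`, diablo_project(model, blocks_test)) / length(model$variates)
  cents <- rbind(colMeans(tr[model$y == 0, , drop = FALSE]),
                 colMeans(tr[model$y == 1, , drop = FALSE]))
  d0 <- rowSums(sweep(te, 2, cents[1, ])^2)
  d1 <- rowSums(sweep(te, 2, cents[2, ])^2)
  as.integer(d1 < d0)
}

#' Tune component count and sparsity by stratified cross-validation
#'
#' Grid search over candidate component counts and keep values (applied to
#' every block, capped at block width); the criterion is the mean balanced
#' error rate of nearest-centroid classification on the block-averaged
#' variates across stratified folds. Ties prefer fewer components, then
#' smaller keep.
#'
#' @param blocks named list of samples x features matrices.
#' @param y binary outcome.
#' @param keep_candidates integer vector of keep values.
#' @param ncomp_candidates integer vector of component counts.
#' @param n_folds folds (default 5).
#' @param seed fold seed.
#' @param design optional design matrix passed to [fit_diablo()].
#' @return list with n_components, keep, ber, and the full `grid`.
#' @export
tune_diablo <- function(blocks, y, keep_candidates, ncomp_candidates = 1:2,
                        n_folds = 5, seed = 1L, design = NULL) {
  if (length(y) < 10) stop_cfg("need >= 10 samples to tune")
  folds <- make_folds(y, n_folds, seed)
  grid <- expand.grid(n_components = ncomp_candidates, keep = keep_candidates)
  grid$ber <- NA_real_
  for (i in seq_len(nrow(grid))) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- suppressWarnings(
        fit_diablo(lapply(blocks, function(b) b[tr, , drop = FALSE]), y[tr],
                   design = design, n_components = grid$n_components[i],
                   keep = grid$keep[i]))
      pred <- diablo_classify(fit, lapply(blocks, function(b) b[!tr, , drop = FALSE]))
      truth <- y[!tr]
      mean(c(mean(pred[truth == 0] != 0), mean(pred[truth == 1] != 1)), na.rm = TRUE)
    }, numeric(1))
    grid$ber[i] <- mean(errs)
  }
  ord <- order(grid$ber, grid$n_components, grid$keep)
  best <- grid[ord[1], ]
  list(n_components = best$n_components, keep = best$keep, ber = best$ber,
       grid = grid)
}

#' Between-block correlation edge list from the first latent component
#'
#' For the features selected on component 1 only: in "variate" mode
#' (the circos plotting convention), each feature is correlated with the
#' block-averaged first-component variate and the feature-feature
#' association for a cross-block pair is estimated as the product of the two
#' feature-variate correlations; in "raw" mode the plain Pearson correlation
#' of the two feature columns is used. Pairs with |estimate| above the
#' threshold are returned.
#'
#' @param model a `diablo_model`.
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @param method "variate" (default) or "raw".
#' @return data.frame (feature_a, block_a, feature_b, block_b, r).
#' @export
between_block_correlations <- function(model, threshold = 0.8,
                                       method = c("variate", "raw")) {
  method <- match.arg(method)
  t_avg <- Reduce(`+`, lapply(model$variates, function(v) v[, 1])) /
    length(model$variates)
  sel <- lapply(names(model$loadings), function(j) {
    feats <- rownames(model$loadings[[j]])[model$loadings[[j]][, 1] != 0]
    if (length(feats) == 0) return(NULL)
    x <- model$blocks_processed[[j]][, feats, drop = FALSE]
    list(block = j, features = feats, x = x,
         r_variate = drop(stats::cor(x, t_avg)))
  })
  sel <- Filter(Negate(is.null), sel)
  out <- list()
  if (length(sel) >= 2) {
    for (a in seq_len(length(sel) - 1)) {
      for (b in seq(a + 1, length(sel))) {
        if (method == "variate") {
          est <- outer(sel[[a]]$r_variate, sel[[b]]$r_variate)
        } else {
          est <- stats::cor(sel[[a]]$x, sel[[b]]$x)
        }
        idx <- which(abs(est) > threshold, arr.ind = TRUE)
        if (nrow(idx)) {
          out[[length(out) + 1]] <- data.frame(
            feature_a = sel[[a]]$features[idx[, 1]], block_a = sel[[a]]$block,
            feature_b = sel[[b]]$features[idx[, 2]], block_b = sel[[b]]$block,
            r = est[idx], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(feature_a = character(0), block_a = character(0),
               feature_b = character(0), block_b = character(0),
               r = numeric(0))
}

#' Bootstrap Spearman association (optionally across a panel)
#'
#' Spearman's rho with a seeded percentile bootstrap confidence interval and
#' the exact/asymptotic Spearman p-value; when `x` is a matrix, every column
#' is tested against `y` and BH adjustment is applied across the panel.
#'
#' @param x numeric vector, or samples x features matrix for a panel.
#' @param y numeric vector.
#' @param n_boot bootstrap resamples (default 1000, >= 100).
#' @param conf_level confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return data.frame (feature, type, estimate, ci_low, ci_high, p, fdr).
#' @export
spearman_bootstrap <- function(x, y, n_boot = 1000, conf_level = 0.95,
                               seed = 1L) {
  if (n_boot < 100) stop_cfg("n_boot must be >= 100")
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    rows <- lapply(seq_len(ncol(x)), function(j) {
      one_spearman(x[, j], y, n_boot, conf_level, derive_seed(seed, j),
                   colnames(x)[j] %||% paste0("f", j))
    })
    out <- do.call(rbind, rows)
  } else {
    out <- one_spearman(x, y, n_boot, conf_level, seed, "x")
  }
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

one_spearman <- function(x, y, n_boot, conf_level, seed, name) {
  if (length(x) < 5) stop_cfg("need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_cfg("constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))$p.value
  n <- length(x)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      suppressWarnings(stats::cor(x[i], y[i], method = "spearman"))
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(feature = name, type = "spearman_bootstrap", estimate = rho,
             ci_low = unname(ci[1]), ci_high = unname(ci[2]), p = p,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney location-shift association
#'
#' Hodges-Lehmann location-shift estimate of group `b` relative to group `a`
#' (positive when `b` is larger), with a distribution-free confidence
#' interval and the two-sided Mann-Whitney p (exact for combined n <= 20
#' without ties, normal approximation with tie correction otherwise).
#'
#' @param a reference group values (e.g. resistant).
#' @param b comparison group values (e.g. susceptible).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame (type, estimate, ci_low, ci_high, p, U).
#' @export
mannwhitney_estimate <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2) stop_cfg("both groups need >= 2 values")
  mw <- mw_test(b, a, conf_level)
  data.frame(type = "mannwhitney", estimate = mw$estimate,
             ci_low = mw$ci[1], ci_high = mw$ci[2], p = mw$p, U = mw$U,
             stringsAsFactors = FALSE)
}
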