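#' Build a feature matrix from a module gene set
#'
#' Transposes the (typically baseline-adjusted, genes x subjects) expression
#' matrix restricted to the module genes and attaches the binary outcome.
#'
#' @param adjusted expression matrix, genes x subjects (columns named by
#'   subject).
#' @param geneset module gene set.
#' @param labels named 0/1 outcome vector (names = subjects), or a sample
#'   table with subject_id and outcome columns.
#' @return list of class `feature_matrix`: `x` (subjects x genes), `y`
#'   (0/1 factor-coercible vector).
#' @export
build_feature_matrix <- function(adjusted, geneset, labels) {
  genes <- intersect(geneset, rownames(adjusted))
  if (length(genes) == 0) stop_cfg("gene set does not intersect the matrix")
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$outcome, labels$subject_id)
  }
  subj <- colnames(adjusted)
  if (!all(subj %in% names(labels))) stop_cfg("outcome missing for some subjects")
  y <- labels[subj]
  if (anyNA(y)) stop_cfg("outcome contains missing values")
  if (length(unique(y)) < 2) stop_cfg("both outcome classes must be present")
  x <- t(adjusted[genes, , drop = FALSE])
  structure(list(x = x, y = as.integer(y)), class = "feature_matrix")
}

#' Tune a random forest by out-of-bag error
#'
#' Grid search over `n_trees` in {250, 500, 1000, 2000} and `m_try` in
#' {sqrt(p)/2, sqrt(p), 2*sqrt(p), p/3} (rounded, deduplicated, clipped to
#' \[1, p\]); selects the minimum OOB misclassification rate, breaking ties
#' by smaller `n_trees` then smaller `m_try`. Seeded and deterministic.
#'
#' @param fm a `feature_matrix`.
#' @param n_trees_grid,m_try_grid optional custom grids.
#' @param seed integer seed.
#' @return list with n_trees, m_try, oob_error, and the full `grid`.
#' @export
tune_forest <- function(fm, n_trees_grid = c(250, 500, 1000, 2000),
                        m_try_grid = NULL, seed = 1L) {
  y <- factor(fm$y)
  if (nlevels(y) < 2 || min(table(y)) < 5) {
    stop_cfg("need >= 5 samples per class for OOB tuning")
  }
  p <- ncol(fm$x)
  if (is.null(m_try_grid)) {
    m_try_grid <- unique(pmin(pmax(round(c(sqrt(p) / 2, sqrt(p), 2 * sqrt(p), p / 3)), 1), p))
  }
  grid <- expand.grid(n_trees = n_trees_grid, m_try = m_try_grid)
  grid$oob <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- with_seed(derive_seed(seed, i), {
      randomForest::randomForest(fm$x, y, ntree = grid$n_trees[i],
                                 mtry = grid$m_try[i])
    })
    grid$oob[i] <- mean(fit$err.rate[grid$n_trees[i], "OOB"])
  }
  ord <- order(grid$oob, grid$n_trees, grid$m_try)
  best <- grid[ord[1], ]
  list(n_trees = best$n_trees, m_try = best$m_try, oob_error = best$oob,
       grid = grid)
}

#' ROC curve and AUC
#'
#' AUC by the tie-corrected Mann-Whitney identity (ties count one half); the
#' ROC curve by a descending threshold sweep over the unique scores.
#'
#' @param scores numeric prediction scores (higher = class 1).
#' @param labels 0/1 vector.
#' @return list of class `evaluation_result`: `auc`, `roc` (data.frame fpr,
#'   tpr), `scores`, `labels`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_cfg("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- t(vapply(thr, function(t) {
    pos <- scores >= t
    c(fpr = sum(pos & labels == 0) / n0, tpr = sum(pos & labels == 1) / n1)
  }, numeric(2)))
  structure(list(auc = auc, roc = as.data.frame(roc),
                 scores = scores, labels = labels),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: AUC = %.3f (%d samples)\n",
              x$auc, length(x$labels)))
  invisible(x)
}

# Stratified train/validation split; redraws (logged via attribute) until
# both classes appear in the training set.
stratified_split <- function(y, train_fraction, seed) {
  n <- length(y)
  redraws <- 0
  with_seed(seed, {
    repeat {
      train <- logical(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        n_tr <- round(train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1), length(idx) - 1)
        train[sample(idx, n_tr)] <- TRUE
      }
      if (length(unique(y[train])) == 2 && length(unique(y[!train])) == 2) break
      redraws <- redraws + 1
      if (redraws > 100) stop_cfg("could not draw a valid split")
    }
      structure(train, redraws = redraws)
  })
}

#' Train/validate a random forest on one random split
#'
#' Stratified random assignment of subjects into training and validation
#' sets, forest trained on the training set with the supplied (tuned)
#' parameters, class-1 probability scores and ROC/AUC computed on the
#' validation set only.
#'
#' @param fm a `feature_matrix`.
#' @param train_fraction training fraction (0.5, 0.6 or 0.7; default 0.5).
#' @param params list with n_trees and m_try (from [tune_forest()]).
#' @param split_seed seed controlling the split and the forest.
#' @return `evaluation_result` with a `split` element (logical training
#'   indicator).
#' @export
evaluate_split <- function(fm, train_fraction = 0.5, params, split_seed = 1L) {
  if (!train_fraction %in% c(0.5, 0.6, 0.7)) {
    stop_cfg("train_fraction must be one of 0.5, 0.6, 0.7")
  }
  train <- stratified_split(fm$y, train_fraction, split_seed)
  fit <- with_seed(derive_seed(split_seed, 13), {
    randomForest::randomForest(fm$x[train, , drop = FALSE],
                               factor(fm$y[train], levels = c(0, 1)),
                               ntree = params$n_trees, mtry = params$m_try)
  })
  scores <- stats::predict(fit, fm$x[!train, , drop = FALSE], type = "prob")[, "1"]
  out <- roc_auc(scores, fm$y[!train])
  out$split <- as.logical(train)
  out
}

#' Resampled AUC distribution over repeated random re-splits
#'
#' Repeats [evaluate_split()] `n_resamples` times with a seed sequence
#' derived from `seed`, reusing fixed tuned parameters, and summarizes the
#' AUC distribution by its median and 2.5/97.5 percentiles. Passing the same
#' `seed` reproduces the full AUC vector; passing the same seed for
#' different feature matrices over the same subjects reuses identical
#' subject-level assignments, so module comparisons share splits.
#'
#' @param fm a `feature_matrix`.
#' @param n_resamples number of re-splits (default 200).
#' @param train_fraction training fraction (default 0.5).
#' @param params list with n_trees, m_try.
#' @param seed base seed for the split sequence.
#' @param permute_labels draw a fresh label permutation for every re-split,
#'   giving the permutation null of the resampled-AUC procedure (a single
#'   fixed permutation retains its chance label-feature association across
#'   all re-splits, so its median is not centred at 0.5).
#' @return list of class `resample_distribution`: aucs, median, ci (2.5 and
#'   97.5 percentiles), n_resamples.
#' @export
resample_evaluate <- function(fm, n_resamples = 200, train_fraction = 0.5,
                              params = list(n_trees = 500, m_try = NULL),
                              seed = 1L, permute_labels = FALSE) {
  if (is.null(params$m_try)) params$m_try <- max(1, round(sqrt(ncol(fm$x))))
  aucs <- vapply(seq_len(n_resamples), function(i) {
    fmi <- fm
    if (permute_labels) {
      fmi$y <- with_seed(derive_seed(seed, 100000 + i), sample(fm$y))
    }
    evaluate_split(fmi, train_fraction, params,
                   split_seed = derive_seed(seed, i))$auc
  }, numeric(1))
  structure(list(aucs = aucs, median = stats::median(aucs),
                 ci = stats::quantile(aucs, c(0.025, 0.975)),
                 n_resamples = n_resamples),
            class = "resample_distribution")
}

#' @export
print.resample_distribution <- function(x, ...) {
  cat(sprintf("resample_distribution: %d re-splits, median AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$n_resamples, x$median, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Transfer prediction to an external cohort
#'
#' Restricts both cohorts to their gene intersection (order-aligned),
#' standardizes each gene within its own cohort (cross-platform scale
#' differences otherwise dominate), trains on the full internal cohort and
#' evaluates on the external cohort.
#'
#' @param fm_train internal `feature_matrix` (genes as columns of `x`).
#' @param external_expr external expression matrix (genes x subjects).
#' @param external_labels named 0/1 vector for the external subjects.
#' @param params list with n_trees, m_try.
#' @param seed seed for the forest.
#' @return `evaluation_result` on the external cohort, with
#'   `n_shared_genes`.
#' @export
transfer_predict <- function(fm_train, external_expr, external_labels,
                             params = list(n_trees = 500, m_try = NULL),
                             seed = 1L) {
  shared <- intersect(colnames(fm_train$x), rownames(external_expr))
  if (length(shared) < 5) {
    stop_cfg("only %d shared gene(s); need >= 5", length(shared))
  }
  std <- function(x) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    scale(x, scale = s)
  }
  x_tr <- std(fm_train$x[, shared, drop = FALSE])
  x_ex <- std(t(external_expr[shared, , drop = FALSE]))
  y_ex <- as.integer(external_labels[rownames(x_ex)])
  if (is.null(params$m_try)) params$m_try <- max(1, round(sqrt(length(shared))))
  fit <- with_seed(seed, {
    randomForest::randomForest(x_tr, factor(fm_train$y, levels = c(0, 1)),
                               ntree = params$n_trees, mtry = params$m_try)
  })
  scores <- stats::predict(fit, x_ex, type = "prob")[, "1"]
  out <- roc_auc(scores, y_ex)
  out$n_shared_genes <- length(shared)
  out
}
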