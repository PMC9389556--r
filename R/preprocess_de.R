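#' Log2 counts-per-million normalization
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)` per cell, with
#' the library size taken as the column sum of raw counts.
#'
#' @param m counts-scale expression matrix (genes x samples).
#' @param prior positive pseudo-count, default 0.5.
#' @return log2-scale matrix of the same shape.
#' @export
cpm_normalize <- function(m, prior = 0.5) {
  assert_expr_matrix(m)
  if (expr_scale(m) != "counts") stop_cfg("cpm_normalize expects a counts-scale matrix")
  if (any(m < 0)) stop_cfg("counts must be non-negative")
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop_cfg("zero library size for sample(s): %s",
             paste(colnames(m)[lib <= 0], collapse = ", "))
  }
  out <- log2(sweep(m + prior, 2, lib + 2 * prior, "/") * 1e6)
  dimnames(out) <- dimnames(m)
  set_expr_scale(out, "log2")
}

#' Baseline adjustment against matched unstimulated samples
#'
#' Subtracts, per subject, the matched CTRL sample from the sample of the
#' requested stimulus, returning one column per subject (stimulated minus
#' control). Matching is on subject + age.
#'
#' @param m log2-scale expression matrix.
#' @param s sample table with sample_id, subject_id, stimulus, age columns.
#' @param stimulus stimulus label to adjust.
#' @return genes x subjects matrix of paired differences, columns named by
#'   subject, ordered as the stimulated samples appear in `s`.
#' @export
baseline_adjust <- function(m, s, stimulus) {
  assert_expr_matrix(m)
  stim <- s[s$stimulus == stimulus, , drop = FALSE]
  ctrl <- s[s$stimulus == "CTRL", , drop = FALSE]
  if (nrow(stim) == 0) stop_cfg("no samples with stimulus '%s'", stimulus)
  key <- function(x) paste(x$subject_id, x$age, sep = "\r")
  idx <- match(key(stim), key(ctrl))
  if (anyNA(idx)) {
    stop_cfg("no matched CTRL sample for subject(s): %s",
             paste(unique(stim$subject_id[is.na(idx)]), collapse = ", "))
  }
  out <- m[, stim$sample_id, drop = FALSE] - m[, ctrl$sample_id[idx], drop = FALSE]
  colnames(out) <- stim$subject_id
  set_expr_scale(out, "log2")
}

# Inverse of the trigamma function by Newton iteration on 1/x (monotone,
# convex parametrization); used by the gamma-moment prior estimator.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment estimator of the scaled-F prior for gene-wise variances: s^2 about
# s0^2 * F(df, d0). Returns prior df d0 (possibly Inf) and prior variance s0^2.
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0 = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  t2 <- evar - trigamma(df / 2)
  if (is.finite(t2) && t2 > 0) {
    d0 <- 2 * trigamma_inverse(t2)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(d0 = d0, s0 = s0)
}

#' Empirical-Bayes moderated contrast
#'
#' Per-gene linear contrast with variance moderation: residual variances are
#' shrunk toward a common prior estimated by the gamma-moment method, the
#' moderated t uses `d_residual + d0` degrees of freedom. Paired contrasts
#' are one-sample tests on subject-wise differences; unpaired contrasts are
#' two-sample with pooled variance.
#'
#' @param m log2-scale expression matrix.
#' @param s sample table.
#' @param contrast length-2 character vector `c(A, B)`: stimulus (or group)
#'   labels compared as A minus B.
#' @param paired logical; paired mode matches samples by subject + age.
#' @param prior_df optional override of the prior degrees of freedom d0
#'   (0 recovers the ordinary t-test, Inf fully pools variances).
#' @param group_col column of `s` holding the labels (default "stimulus").
#' @return data.frame (class `contrast_result`) with gene, log2fc, mod_t, p,
#'   fdr, mean_expr; attributes `d0` and `s0`.
#' @export
fit_contrast <- function(m, s, contrast, paired = TRUE, prior_df = NULL,
                         group_col = "stimulus") {
  assert_expr_matrix(m)
  stopifnot(length(contrast) == 2)
  a <- s[s[[group_col]] == contrast[1], , drop = FALSE]
  b <- s[s[[group_col]] == contrast[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop_cfg("each arm needs >= 2 samples ('%s': %d, '%s': %d)",
             contrast[1], nrow(a), contrast[2], nrow(b))
  }
  if (paired) {
    key <- function(x) paste(x$subject_id, x$age, sep = "\r")
    idx <- match(key(a), key(b))
    if (anyNA(idx)) stop_cfg("paired contrast: unmatched subjects %s",
                             paste(a$subject_id[is.na(idx)], collapse = ", "))
    d <- m[, a$sample_id, drop = FALSE] - m[, b$sample_id[idx], drop = FALSE]
    n <- ncol(d)
    lfc <- rowMeans(d)
    s2 <- apply(d, 1, stats::var)
    df <- n - 1
    unit <- 1 / n
  } else {
    xa <- m[, a$sample_id, drop = FALSE]
    xb <- m[, b$sample_id, drop = FALSE]
    n1 <- ncol(xa); n2 <- ncol(xb)
    lfc <- rowMeans(xa) - rowMeans(xb)
    s2 <- ((n1 - 1) * apply(xa, 1, stats::var) +
             (n2 - 1) * apply(xb, 1, stats::var)) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    unit <- 1 / n1 + 1 / n2
  }
  eps <- .Machine$double.eps
  floored <- s2 < eps
  s2[floored] <- eps
  if (is.null(prior_df)) {
    pr <- estimate_variance_prior(s2, df)
  } else {
    pr <- list(d0 = prior_df, s0 = if (is.finite(prior_df) && prior_df == 0)
      NA_real_ else exp(mean(log(s2))))
  }
  d0 <- pr$d0
  s2_post <- if (is.infinite(d0)) rep(pr$s0, length(s2)) else
    if (d0 == 0) s2 else (d0 * pr$s0 + df * s2) / (d0 + df)
  mod_t <- lfc / sqrt(s2_post * unit)
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(mod_t), df = if (is.infinite(df_total)) 1e6 else df_total)
  mean_expr <- rowMeans(m)
  res <- data.frame(gene = rownames(m), log2fc = lfc, mod_t = mod_t, p = p,
                    fdr = bh_adjust(p), mean_expr = mean_expr,
                    var_floored = floored, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0") <- pr$s0
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control with monotonicity enforcement, order-preserving on the
#' input index (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in \[0,1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_cfg("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Strict thresholds: up-regulated means `fdr < fdr_max` and
#' `log2fc > lfc_min`; down-regulated analogously with `log2fc < -lfc_min`.
#' The default fold-change threshold of 1 reflects the reported DEG counts'
#' context; the stricter 1.5 is available through `lfc_min`.
#'
#' @param cr a `contrast_result` from [fit_contrast()].
#' @param lfc_min positive log2 fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.01).
#' @return list with character vectors `up` and `down`.
#' @export
select_degs <- function(cr, lfc_min = 1, fdr_max = 0.01) {
  if (lfc_min <= 0 || fdr_max <= 0) stop_cfg("thresholds must be positive")
  list(up = cr$gene[cr$fdr < fdr_max & cr$log2fc > lfc_min],
       down = cr$gene[cr$fdr < fdr_max & cr$log2fc < -lfc_min])
}

#' Select the most significantly variable genes for a stimulus response
#'
#' Ranks genes by the paired stimulated-vs-CTRL moderated-t p-value and
#' returns the `n_top` smallest; ties broken by decreasing |log2fc|, then
#' lexicographic gene id, so the selection is deterministic.
#'
#' @param m log2-scale expression matrix.
#' @param s sample table.
#' @param stimulus stimulus label contrasted against CTRL.
#' @param n_top number of genes to return.
#' @return character vector of gene ids (in selection-rank order).
#' @export
select_variable_genes <- function(m, s, stimulus, n_top) {
  if (n_top > nrow(m)) stop_cfg("n_top (%d) exceeds gene count (%d)", n_top, nrow(m))
  cr <- fit_contrast(m, s, c(stimulus, "CTRL"), paired = TRUE)
  ord <- order(cr$p, -abs(cr$log2fc), cr$gene)
  cr$gene[ord][seq_len(n_top)]
}
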