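#' Mutual information by adaptive partitioning on copula ranks
#'
#' Both vectors are rank-transformed to (0,1); the unit square is split
#' recursively into quadrants while a chi-square uniformity test over the
#' four quadrant counts rejects (p < 0.05, i.e. chi^2 > 7.8147 on 3 df) and
#' enough points remain. MI is the sum over leaf cells of
#' `(n_c/n) * log((n_c/n) / (w_x * w_y))` in nats, clamped at 0.
#'
#' @param x,y numeric vectors of equal length >= 20, non-constant.
#' @param chi_crit chi-square threshold for splitting (default
#'   `qchisq(0.95, 3)`).
#' @param min_points smallest cell that may be split (default 8).
#' @return MI estimate in nats (>= 0).
#' @export
estimate_mi <- function(x, y, chi_crit = 7.814728, min_points = 8) {
  n <- length(x)
  if (length(y) != n) stop_cfg("x and y must have equal length")
  if (n < 20) stop_cfg("need n >= 20 (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_cfg("constant vector")
  u <- (rank(x, ties.method = "average") - 0.5) / n
  v <- (rank(y, ties.method = "average") - 0.5) / n
  mi <- mi_cell(u, v, 0, 1, 0, 1, n, chi_crit, min_points)
  max(mi, 0)
}

mi_cell <- function(u, v, x1, x2, y1, y2, n, chi_crit, min_points) {
  nc <- length(u)
  if (nc == 0) return(0)
  leaf <- function() {
    (nc / n) * log((nc / n) / ((x2 - x1) * (y2 - y1)))
  }
  if (nc < min_points) return(leaf())
  xm <- (x1 + x2) / 2
  ym <- (y1 + y2) / 2
  right <- u >= xm
  top <- v >= ym
  counts <- c(sum(!right & !top), sum(right & !top),
              sum(!right & top), sum(right & top))
  e <- nc / 4
  chi2 <- sum((counts - e)^2 / e)
  if (chi2 <= chi_crit) return(leaf())
  q1 <- !right & !top; q2 <- right & !top; q3 <- !right & top; q4 <- right & top
  mi_cell(u[q1], v[q1], x1, xm, y1, ym, n, chi_crit, min_points) +
    mi_cell(u[q2], v[q2], xm, x2, y1, ym, n, chi_crit, min_points) +
    mi_cell(u[q3], v[q3], x1, xm, ym, y2, n, chi_crit, min_points) +
    mi_cell(u[q4], v[q4], xm, x2, ym, y2, n, chi_crit, min_points)
}

#' Reverse-engineer a TF-target network by mutual information
#'
#' Computes MI between every declared regulator and every other gene
#' (including other regulators), derives a pooled permutation null by
#' shuffling one member of randomly chosen pairs, and drops edges whose
#' permutation p-value is >= `alpha`.
#'
#' @param m log2-scale expression matrix (genes x samples, >= 20 samples).
#' @param tf_list gene ids declared as regulators (subset of rownames).
#' @param n_perm permutation draws for the pooled null (default 200).
#' @param alpha edge significance threshold (default 0.05).
#' @param seed seed for the permutation null.
#' @return object of class `mi_network`: `edges` data.frame (tf, target, mi,
#'   p) and `tf_list`.
#' @export
build_mi_network <- function(m, tf_list, n_perm = 200, alpha = 0.05, seed = 1L) {
  assert_expr_matrix(m)
  if (!all(tf_list %in% rownames(m))) stop_cfg("tf_list must be a subset of genes")
  if (ncol(m) < 20) stop_cfg("need >= 20 samples (got %d)", ncol(m))
  genes <- rownames(m)
  null <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_perm), function(i) {
      g1 <- m[sample(genes, 1), ]
      g2 <- sample(m[sample(genes, 1), ])
      estimate_mi(g1, g2)
    }, numeric(1))
  })
  rows <- list()
  for (tf in tf_list) {
    targets <- setdiff(genes, tf)
    mi <- vapply(targets, function(g) estimate_mi(m[tf, ], m[g, ]), numeric(1))
    p <- (1 + vapply(mi, function(v) sum(null >= v), numeric(1))) / (n_perm + 1)
    rows[[tf]] <- data.frame(tf = tf, target = targets, mi = mi, p = p,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  edges <- do.call(rbind, rows)
  edges <- edges[edges$p < alpha, , drop = FALSE]
  # de-duplicate symmetric tf-tf pairs (keep the larger MI estimate)
  both_tf <- edges$tf %in% tf_list & edges$target %in% tf_list
  if (any(both_tf)) {
    tt <- edges[both_tf, , drop = FALSE]
    key <- paste(pmin(tt$tf, tt$target), pmax(tt$tf, tt$target))
    tt <- tt[order(key, -tt$mi), , drop = FALSE]
    key <- sort(key)
    tt <- tt[!duplicated(key), , drop = FALSE]
    edges <- rbind(edges[!both_tf, , drop = FALSE], tt)
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, tf_list = tf_list), class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d edges, %d regulators\n",
              nrow(x$edges), length(x$tf_list)))
  invisible(x)
}

#' Data-processing-inequality pruning
#'
#' For every information triangle (two regulators and a common partner, all
#' three edges present), the strictly weakest edge is marked for removal when
#' its MI is below `(1 - tolerance) * min(other two MIs)`. All removals are
#' decided on the original MI values and applied at once, so the operation is
#' order-independent and idempotent.
#'
#' @param net an `mi_network`.
#' @param tolerance DPI tolerance in \[0,1\]; 0 is the classic rule, 1
#'   disables pruning.
#' @return pruned `mi_network`.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  edges <- net$edges
  if (nrow(edges) == 0 || tolerance >= 1) return(net)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  mi_map <- stats::setNames(edges$mi, key(edges$tf, edges$target))
  drop <- character(0)
  tfs <- intersect(net$tf_list, unique(c(edges$tf, edges$target)))
  partners <- function(tf) {
    c(edges$target[edges$tf == tf], edges$tf[edges$target == tf])
  }
  if (length(tfs) >= 2) {
    for (i in seq_len(length(tfs) - 1)) {
      for (j in seq(i + 1, length(tfs))) {
        k12 <- key(tfs[i], tfs[j])
        if (is.na(mi_map[k12])) next
        common <- intersect(partners(tfs[i]), partners(tfs[j]))
        common <- setdiff(common, c(tfs[i], tfs[j]))
        for (g in common) {
          k1g <- key(tfs[i], g); k2g <- key(tfs[j], g)
          mis <- c(mi_map[k12], mi_map[k1g], mi_map[k2g])
          ks <- c(k12, k1g, k2g)
          w <- which.min(mis)
          others <- mis[-w]
          if (mis[w] < (1 - tolerance) * min(others) &&
              sum(mis == mis[w]) == 1) {
            drop <- c(drop, ks[w])
          }
        }
      }
    }
  }
  if (length(drop)) {
    edges <- edges[!(key(edges$tf, edges$target) %in% drop), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, tf_list = net$tf_list), class = "mi_network")
}

#' Assemble signed, weighted regulons from a pruned MI network
#'
#' Mode = Spearman correlation between regulator and target expression
#' (clipped to \[-1,1\]); likelihood = MI scaled to the maximum within each
#' regulon. Regulons with fewer than `min_targets` targets are dropped.
#'
#' @param net a (pruned) `mi_network`.
#' @param m expression matrix used for the mode correlations.
#' @param min_targets smallest retained regulon (default 10).
#' @return object of class `regulon_set`: named list of data.frames
#'   (target, mode, likelihood).
#' @export
assemble_regulons <- function(net, m, min_targets = 10) {
  out <- list()
  for (tf in unique(net$edges$tf)) {
    sub <- net$edges[net$edges$tf == tf, , drop = FALSE]
    if (nrow(sub) < min_targets) next
    mode <- vapply(sub$target, function(g) {
      suppressWarnings(stats::cor(m[tf, ], m[g, ], method = "spearman"))
    }, numeric(1))
    mode <- pmin(pmax(mode, -1), 1)
    out[[tf]] <- data.frame(target = sub$target, mode = mode,
                            likelihood = sub$mi / max(sub$mi),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(out, class = "regulon_set")
}

#' Construct a regulon set directly from a TF-target table
#'
#' Convenience constructor for planted or user-supplied regulons (columns
#' tf, target, mode, and optionally likelihood).
#'
#' @param tab data.frame with tf, target, mode and optional likelihood/weight
#'   columns.
#' @return `regulon_set`.
#' @export
regulon_set <- function(tab) {
  lik <- tab$likelihood %||% tab$weight %||% rep(1, nrow(tab))
  out <- lapply(split(seq_len(nrow(tab)), tab$tf), function(i) {
    data.frame(target = tab$target[i], mode = tab$mode[i],
               likelihood = lik[i] / max(lik[i]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(out, class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("regulon_set: %d regulons, median size %g\n", length(x),
              stats::median(vapply(x, nrow, integer(1)))))
  invisible(x)
}

#' Two-tailed analytic rank-based enrichment (aREA) of regulons
#'
#' Signature values are rank-transformed and mapped to normal quantiles.
#' Each regulon's score combines a directional component (target quantiles
#' weighted by mode x likelihood) with a two-tail component (|extremeness|
#' quantiles weighted by (1-|mode|) x likelihood), VIPER-style: the two-tail
#' part adds only when positive, and the combined score carries the
#' directional sign. The normalizer is the exact null standard deviation of
#' the combined statistic, so NES is approximately N(0,1) under the null for
#' any mode/likelihood profile. Two-sided p from the normal; BH FDR across
#' regulons; direction labelled by `nes_threshold`.
#'
#' @param signature named numeric vector (gene-level statistic, e.g.
#'   moderated t).
#' @param regulons a `regulon_set`.
#' @param nes_threshold |NES| above which a TF is called
#'   activated/inhibited (default 2).
#' @param min_overlap smallest signature overlap scored (default 10).
#' @return data.frame (class `activity_result`): tf, n_targets, nes, p, fdr,
#'   direction.
#' @export
area_enrichment <- function(signature, regulons, nes_threshold = 2,
                            min_overlap = 10) {
  if (is.null(names(signature))) stop_cfg("signature must be a named vector")
  n <- length(signature)
  t2 <- rank(signature, ties.method = "average") / (n + 1)
  q2 <- stats::qnorm(t2)
  t1 <- pmin(pmax(2 * abs(t2 - 0.5), 1 / (n + 1)), n / (n + 1))
  q1 <- stats::qnorm(t1)
  names(q2) <- names(q1) <- names(signature)
  rows <- lapply(names(regulons), function(tf) {
    reg <- regulons[[tf]]
    reg <- reg[reg$target %in% names(signature), , drop = FALSE]
    if (nrow(reg) < min_overlap) {
      warning(sprintf("regulon '%s': %d target(s) in signature (< %d), skipped",
                      tf, nrow(reg), min_overlap))
      return(NULL)
    }
    alpha <- reg$mode * reg$likelihood
    beta <- (1 - abs(reg$mode)) * reg$likelihood
    w1 <- sqrt(sum(alpha^2)); w2 <- sqrt(sum(beta^2))
    s1 <- if (w1 > 0) sum(alpha * q2[reg$target]) / w1 else 0
    s2 <- if (w2 > 0) sum(beta * q1[reg$target]) / w2 else 0
    raw <- if (w1 == 0) s2 * w2 else sign(s1) * (abs(s1) * w1 + max(s2, 0) * w2)
    norm <- sqrt(w1^2 + 2 * w1 * w2 / pi + w2^2 / 2)
    nes <- raw / norm
    data.frame(tf = tf, n_targets = nrow(reg), nes = nes,
               p = 2 * stats::pnorm(-abs(nes)), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) stop_cfg("no regulon overlaps the signature")
  rows$fdr <- bh_adjust(rows$p)
  rows$direction <- ifelse(rows$nes > nes_threshold, "activated",
                           ifelse(rows$nes < -nes_threshold, "inhibited", "ns"))
  rownames(rows) <- NULL
  class(rows) <- c("activity_result", "data.frame")
  rows
}

#' Master-regulator analysis of a stimulation contrast
#'
#' Builds the moderated-t signature for the requested contrast with
#' [fit_contrast()], scores every regulon with [area_enrichment()], and flags
#' TFs with p < `driver_p` as putative drivers.
#'
#' @param m expression matrix.
#' @param s sample table.
#' @param contrast length-2 label vector (A vs B), as in [fit_contrast()].
#' @param regulons `regulon_set`.
#' @param paired paired contrast (default TRUE).
#' @param driver_p driver significance threshold (default 0.05).
#' @param ... passed to [area_enrichment()].
#' @return `activity_result` with an extra logical `driver` column, sorted by
#'   decreasing |NES|.
#' @export
msviper_contrast <- function(m, s, contrast, regulons, paired = TRUE,
                             driver_p = 0.05, ...) {
  cr <- fit_contrast(m, s, contrast, paired = paired)
  sig <- stats::setNames(cr$mod_t, cr$gene)
  res <- area_enrichment(sig, regulons, ...)
  res$driver <- res$p < driver_p
  res <- res[order(-abs(res$nes)), ]
  rownames(res) <- NULL
  res
}

#' Filter TF activity results by promoter-window motif support
#'
#' Retains a TF when the fraction of its regulon targets carrying the TF's
#' binding motif (user-supplied promoter-window annotation, e.g. 500 bp
#' upstream / 100 bp downstream of the TSS) is positive, or at least
#' `min_fraction` when that is > 0. TFs absent from the motif table are
#' dropped with a warning.
#'
#' @param res an `activity_result`.
#' @param regulons the `regulon_set` that produced `res`.
#' @param motifs data.frame with columns tf, gene (annotated motif targets).
#' @param min_fraction minimum annotated-target fraction (default 0: any
#'   support).
#' @return filtered `activity_result` with a `motif_fraction` column.
#' @export
filter_by_motif <- function(res, regulons, motifs, min_fraction = 0) {
  if (!all(c("tf", "gene") %in% names(motifs))) {
    stop_cfg("motif table needs columns 'tf' and 'gene'")
  }
  frac <- vapply(res$tf, function(tf) {
    if (!tf %in% motifs$tf) return(NA_real_)
    reg <- regulons[[tf]]
    if (is.null(reg)) return(NA_real_)
    mean(reg$target %in% motifs$gene[motifs$tf == tf])
  }, numeric(1))
  absent <- is.na(frac)
  if (any(absent)) {
    warning(sprintf("dropping TF(s) without motif annotation: %s",
                    paste(res$tf[absent], collapse = ", ")))
  }
  keep <- !absent & (if (min_fraction > 0) frac >= min_fraction else frac > 0)
  out <- res[keep, , drop = FALSE]
  out$motif_fraction <- frac[keep]
  rownames(out) <- NULL
  out
}

#' Per-sample regulon activity matrix
#'
#' Scores each column of a (typically baseline-adjusted) expression matrix as
#' its own signature ranked against the cohort, yielding a TF x samples NES
#' matrix suitable as a regulon-activity block for multi-omic integration.
#'
#' @param m expression matrix (genes x samples).
#' @param regulons `regulon_set`.
#' @param min_overlap smallest signature overlap scored (default 10).
#' @return matrix of NES values, TFs x samples.
#' @export
viper_activity_matrix <- function(m, regulons, min_overlap = 10) {
  assert_expr_matrix(m)
  cols <- lapply(seq_len(ncol(m)), function(j) {
    res <- suppressWarnings(
      area_enrichment(m[, j], regulons, min_overlap = min_overlap))
    stats::setNames(res$nes, res$tf)
  })
  tfs <- Reduce(union, lapply(cols, names))
  out <- vapply(cols, function(v) v[tfs], numeric(length(tfs)))
  rownames(out) <- tfs
  colnames(out) <- colnames(m)
  out
}
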