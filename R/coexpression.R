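#' Choose a soft-threshold power for scale-free topology
#'
#' For each candidate power, builds the weighted adjacency and measures the
#' scale-free fit R^2: the linear fit of log10 p(k) against log10 k over
#' connectivity bins, signed by the slope (positive when the degree
#' distribution decays). The chosen power is the smallest one reaching
#' `r2_target`; if none does, the power maximizing R^2 is returned and
#' flagged.
#'
#' @param m log2-scale expression matrix (genes x samples).
#' @param powers candidate integer powers.
#' @param r2_target scale-free fit target, default 0.8.
#' @param sign_mode "unsigned" or "signed-hybrid".
#' @param n_bins connectivity bins for the fit (default 10).
#' @return list with `power`, `reached_target`, and a `table` of power,
#'   scale_free_r2, mean_connectivity.
#' @export
pick_soft_threshold <- function(m, powers = 1:12, r2_target = 0.8,
                                sign_mode = "unsigned", n_bins = 10) {
  assert_expr_matrix(m)
  if (ncol(m) < 3) stop_cfg("need >= 3 samples")
  if (length(powers) == 0) stop_cfg("powers must be nonempty")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant gene(s) before correlation", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(m))
  base <- if (sign_mode == "unsigned") abs(r) else pmax(r, 0)
  diag(base) <- 0
  tab <- data.frame(power = powers, scale_free_r2 = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(base^powers[i])
    tab$mean_connectivity[i] <- mean(k)
    tab$scale_free_r2[i] <- scale_free_fit(k, n_bins)
  }
  hit <- which(tab$scale_free_r2 >= r2_target)
  if (length(hit)) {
    list(power = powers[hit[1]], reached_target = TRUE, table = tab)
  } else {
    list(power = powers[which.max(tab$scale_free_r2)], reached_target = FALSE,
         table = tab)
  }
}

# Signed scale-free fit index: R^2 of log10 p(k) ~ log10 k over equal-width
# bins of k, multiplied by -sign(slope) so decaying distributions score high.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = n_bins) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Build a weighted co-expression adjacency
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^power`; signed-hybrid: `cor^power` for
#' positive correlations, 0 otherwise. Pearson correlation on the supplied
#' log-scale matrix. Diagonal is set to 1 by convention and excluded from
#' connectivity sums downstream.
#'
#' @param m log2-scale expression matrix (genes x samples).
#' @param power soft-threshold power (>= 1).
#' @param sign_mode "unsigned" (default) or "signed-hybrid".
#' @param condition optional condition label stored on the network.
#' @return object of class `coexpr_network` with elements adjacency, power,
#'   sign_mode, condition.
#' @export
build_adjacency <- function(m, power = 6, sign_mode = c("unsigned", "signed-hybrid"),
                            condition = NULL) {
  assert_expr_matrix(m)
  sign_mode <- match.arg(sign_mode)
  if (power < 1) stop_cfg("power must be >= 1")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stop_cfg("zero-variance gene(s): %s",
             paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
  }
  r <- stats::cor(t(m))
  a <- if (sign_mode == "unsigned") abs(r)^power else ifelse(r > 0, r^power, 0)
  diag(a) <- 1
  structure(list(adjacency = a, power = power, sign_mode = sign_mode,
                 condition = condition), class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network: %d genes, power %d, %s%s\n",
              nrow(x$adjacency), x$power, x$sign_mode,
              if (!is.null(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the adjacency row sums excluding the diagonal; `TOM_ii = 1`.
#'
#' @param net a `coexpr_network` from [build_adjacency()].
#' @return list with `tom` (matrix) and `dissimilarity` (= 1 - tom).
#' @export
compute_tom <- function(net) {
  a <- net$adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(net$adjacency)
  list(tom = tom, dissimilarity = 1 - tom)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, followed by a
#' documented simplification of the dynamic hybrid tree cut: a static cut of
#' the dendrogram at an absolute dissimilarity height, dissolution of
#' clusters smaller than `min_module_size`, re-assignment of unassigned genes to the nearest
#' module when their mean TOM to it exceeds the module's `core_quantile`
#' intra-TOM quantile, and iterative merging of modules whose eigengenes
#' correlate above `1 - merge_height`. Modules are named M1, M2, ... by
#' decreasing size; "grey" holds unassigned genes.
#'
#' @param tom TOM matrix (from [compute_tom()]).
#' @param m expression matrix (needed for eigengene merging).
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height absolute dissimilarity height for the static cut
#'   (default 0.99).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param core_quantile intra-module TOM quantile a stray gene must exceed to
#'   be re-assigned (default 0.25).
#' @param net optional `coexpr_network`; when given, kIM/kTotal are attached.
#' @return object of class `module_partition`: labels, eigengenes,
#'   var_explained, and (optionally) kim, ktotal.
#' @export
detect_modules <- function(tom, m, min_module_size = 30, cut_height = 0.99,
                           merge_height = 0.25, core_quantile = 0.25,
                           net = NULL) {
  if (nrow(tom) != ncol(tom)) stop_cfg("TOM must be square")
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; returning all-grey partition")
    labels <- stats::setNames(rep("grey", nrow(tom)), genes)
    return(new_partition(labels, m, net))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(tree, h = min(cut_height, max(tree$height)))
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- rep("grey", length(cl))
  names(labels) <- genes

  if (length(keep)) {
    for (i in seq_along(keep)) labels[cl == keep[i]] <- paste0("tmp", i)
    # re-assign stray genes whose topological overlap with a retained module
    # is at least as strong as the module's own core
    stray <- names(labels)[labels == "grey"]
    if (length(stray)) {
      mods <- unique(labels[labels != "grey"])
      thr <- vapply(mods, function(md) {
        gm <- names(labels)[labels == md]
        sub <- tom[gm, gm]
        stats::quantile(sub[upper.tri(sub)], core_quantile)
      }, numeric(1))
      mean_tom <- vapply(mods, function(md) {
        gm <- names(labels)[labels == md]
        rowMeans(tom[stray, gm, drop = FALSE])
      }, numeric(length(stray)))
      mean_tom <- matrix(mean_tom, nrow = length(stray),
                         dimnames = list(stray, mods))
      best <- max.col(mean_tom, ties.method = "first")
      ok <- mean_tom[cbind(seq_along(stray), best)] >= thr[best]
      labels[stray[ok]] <- mods[best[ok]]
    }
    # merge modules with highly correlated eigengenes
    repeat {
      mods <- unique(labels[labels != "grey"])
      if (length(mods) < 2) break
      eg <- compute_eigengenes(m, labels)$eigengenes
      eg <- eg[mods, , drop = FALSE]
      d <- 1 - stats::cor(t(eg))
      merge_tree <- stats::hclust(stats::as.dist(d), method = "average")
      grp <- stats::cutree(merge_tree, h = merge_height)
      if (max(grp) == length(mods)) break
      for (g in unique(grp)) {
        members <- mods[grp == g]
        if (length(members) > 1) {
          labels[labels %in% members] <- members[1]
        }
      }
    }
  }
  # rename by decreasing size
  mods <- setdiff(unique(labels), "grey")
  if (length(mods)) {
    sz <- vapply(mods, function(md) sum(labels == md), integer(1))
    ord <- mods[order(-sz, mods)]
    relab <- stats::setNames(paste0("M", seq_along(ord)), ord)
    labels[labels != "grey"] <- relab[labels[labels != "grey"]]
  }
  new_partition(labels, m, net)
}

new_partition <- function(labels, m, net = NULL) {
  eg <- if (any(labels != "grey")) compute_eigengenes(m, labels) else
    list(eigengenes = NULL, var_explained = NULL)
  part <- list(labels = labels, eigengenes = eg$eigengenes,
               var_explained = eg$var_explained, kim = NULL, ktotal = NULL)
  class(part) <- "module_partition"
  if (!is.null(net)) {
    k <- intramodular_connectivity(net, labels)
    part$kim <- k$kim
    part$ktotal <- k$ktotal
  }
  part
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("module_partition:", length(x$labels), "genes\n")
  print(tab)
  invisible(x)
}

#' Module eigengenes
#'
#' First principal component of each module's standardized submatrix, scaled
#' to unit variance and sign-oriented so that its correlation with the
#' module's mean expression profile is positive. Grey (unassigned) genes are
#' skipped.
#'
#' @param m expression matrix (genes x samples).
#' @param labels named gene -> module vector.
#' @return list with `eigengenes` (modules x samples) and `var_explained`.
#' @export
compute_eigengenes <- function(m, labels) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop_cfg("no non-grey modules")
  eg <- matrix(NA_real_, nrow = length(mods), ncol = ncol(m),
               dimnames = list(mods, colnames(m)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (md in mods) {
    genes <- names(labels)[labels == md]
    if (length(genes) < 2) stop_cfg("module '%s' has < 2 genes", md)
    x <- scale(t(m[genes, , drop = FALSE]))   # samples x genes, standardized
    x[is.nan(x)] <- 0
    sv <- svd(x, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (stats::sd(e) == 0) stop_cfg("degenerate eigengene for module '%s'", md)
    e <- e / stats::sd(e)
    if (stats::cor(e, rowMeans(x)) < 0) e <- -e
    eg[md, ] <- e
    ve[md] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Intramodular and whole-network connectivity
#'
#' `kTotal_i = sum_{j != i} a_ij`; `kIM_i` restricts the sum to genes of
#' gene i's module (grey genes get their within-grey sum, flagged by the
#' module label itself).
#'
#' @param net a `coexpr_network`.
#' @param labels named gene -> module vector (subset of network genes).
#' @return list with named vectors `kim` and `ktotal`.
#' @export
intramodular_connectivity <- function(net, labels) {
  a <- net$adjacency
  genes <- names(labels)
  if (!all(genes %in% rownames(a))) stop_cfg("partition genes missing from network")
  a <- a[genes, genes]
  diag(a) <- 0
  ktotal <- rowSums(a)
  kim <- stats::setNames(numeric(length(genes)), genes)
  for (md in unique(labels)) {
    gm <- genes[labels == md]
    kim[gm] <- rowSums(a[gm, gm, drop = FALSE])
  }
  list(kim = kim, ktotal = ktotal)
}

#' Scaled connectivity profile of a module
#'
#' Scales intramodular connectivity to `k / k_max` within the module for a
#' stated condition/stratum and attaches a Monte-Carlo Lilliefors normality
#' p-value for the profile.
#'
#' @param kim named intramodular connectivity vector.
#' @param module_genes genes of the module.
#' @param stratum label recorded on the profile (e.g. "all", "sLRI+").
#' @param n_mc Monte-Carlo draws for the Lilliefors null (default 2000).
#' @param seed seed for the Lilliefors null.
#' @return list with `scaled` (named vector in \[0,1\]), `lilliefors_p`,
#'   `stratum`, `degenerate` flag.
#' @export
connectivity_density <- function(kim, module_genes, stratum = "all",
                                 n_mc = 2000, seed = 1L) {
  k <- kim[module_genes]
  if (length(k) == 0) stop_cfg("empty module")
  kmax <- max(k)
  if (kmax <= 0) stop_cfg("k_max is zero; cannot scale connectivity")
  scaled <- k / kmax
  degenerate <- stats::sd(scaled) == 0
  p <- if (degenerate) NA_real_ else
    lilliefors_test(scaled, n_mc = n_mc, seed = seed)
  list(scaled = scaled, lilliefors_p = p, stratum = stratum,
       degenerate = degenerate)
}

# Lilliefors KS statistic against a normal with estimated mean/sd.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_null <- function(n, n_mc, seed) {
  key <- paste(n, n_mc, seed, sep = "_")
  if (!is.null(.lilliefors_cache[[key]])) return(.lilliefors_cache[[key]])
  null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) lilliefors_stat(stats::rnorm(n)),
           numeric(1))
  })
  .lilliefors_cache[[key]] <- null
  null
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov statistic against a normal with estimated mean and sd;
#' the p-value comes from a seeded Monte-Carlo null distribution (cached per
#' sample size) rather than an approximation formula, so its calibration is
#' directly testable.
#'
#' @param x numeric vector, length >= 5, non-constant.
#' @param n_mc number of null draws (default 2000).
#' @param seed seed for the null draws.
#' @return p-value.
#' @export
lilliefors_test <- function(x, n_mc = 2000, seed = 1L) {
  if (length(x) < 5) stop_cfg("need n >= 5 (got %d)", length(x))
  if (stats::sd(x) == 0) stop_cfg("constant input")
  d <- lilliefors_stat(x)
  null <- lilliefors_null(length(x), n_mc, seed)
  (1 + sum(null >= d)) / (n_mc + 1)
}

#' Most connected genes of a module with their edge list
#'
#' Returns the `n_top` genes by intramodular connectivity (ties broken by
#' gene id) and the pairwise correlation edges among them, flagging strong
#' edges above `edge_threshold` in absolute value.
#'
#' @param m expression matrix (for the underlying correlations).
#' @param kim named intramodular connectivity vector.
#' @param module_genes genes of the module.
#' @param n_top number of hubs (default 20).
#' @param edge_threshold strong-edge cutoff on |r| (default 0.8).
#' @return list with `hubs` (data.frame gene, kim) and `edges` (data.frame
#'   gene_a, gene_b, r, strong).
#' @export
top_hubs <- function(m, kim, module_genes, n_top = 20, edge_threshold = 0.8) {
  if (n_top > length(module_genes)) stop_cfg("n_top exceeds module size")
  k <- kim[module_genes]
  ord <- order(-k, names(k))
  hubs <- names(k)[ord][seq_len(n_top)]
  r <- stats::cor(t(m[hubs, , drop = FALSE]))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(gene_a = hubs[idx[, 1]], gene_b = hubs[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  edges$strong <- abs(edges$r) > edge_threshold
  list(hubs = data.frame(gene = hubs, kim = k[hubs], row.names = NULL),
       edges = edges)
}

#' Permutation module preservation statistics
#'
#' For each reference module: the density statistic is the mean within-module
#' adjacency in the test data; the connectivity statistic is the Spearman
#' correlation of intramodular connectivity between reference and test data
#' over the module genes. Both are standardized against `n_perm` random gene
#' sets of equal size drawn from the shared genes (seeded), giving Z_density,
#' Z_connectivity and their mean Z_summary, plus the median rank of each
#' module across both observed statistics.
#'
#' @param m_ref,m_test expression matrices for the reference and test
#'   conditions.
#' @param labels_ref named gene -> module vector from the reference network.
#' @param power soft-threshold power used for both adjacencies (default 6).
#' @param n_perm number of permutations (>= 20, default 50).
#' @param seed seed for the permutation draws.
#' @param sign_mode adjacency sign mode.
#' @return data.frame (module, size, z_density, z_connectivity, z_summary,
#'   median_rank, n_permutations).
#' @export
module_preservation <- function(m_ref, m_test, labels_ref, power = 6,
                                n_perm = 50, seed = 1L,
                                sign_mode = "unsigned") {
  if (n_perm < 20) stop_cfg("n_perm must be >= 20 (got %d)", n_perm)
  # sorted so results are invariant to gene order of the inputs
  shared <- sort(intersect(rownames(m_ref), rownames(m_test)))
  labels_ref <- labels_ref[names(labels_ref) %in% shared]
  mods <- setdiff(unique(labels_ref), "grey")
  drop <- vapply(mods, function(md) sum(labels_ref == md) < 3, logical(1))
  if (any(drop)) {
    warning(sprintf("dropping module(s) with <3 shared genes: %s",
                    paste(mods[drop], collapse = ", ")))
    mods <- mods[!drop]
  }
  if (!length(mods)) stop_cfg("no modules with enough shared genes")
  a_ref <- build_adjacency(m_ref[shared, , drop = FALSE], power, sign_mode)$adjacency
  a_test <- build_adjacency(m_test[shared, , drop = FALSE], power, sign_mode)$adjacency
  diag(a_ref) <- 0; diag(a_test) <- 0

  stat_pair <- function(genes) {
    sub_t <- a_test[genes, genes]
    dens <- mean(sub_t[upper.tri(sub_t)])
    k_r <- rowSums(a_ref[genes, genes])
    k_t <- rowSums(sub_t)
    conn <- suppressWarnings(stats::cor(k_r, k_t, method = "spearman"))
    c(dens, if (is.na(conn)) 0 else conn)
  }

  res <- data.frame(module = mods,
                    size = vapply(mods, function(md) sum(labels_ref == md), integer(1)))
  obs <- t(vapply(mods, function(md) stat_pair(names(labels_ref)[labels_ref == md]),
                  numeric(2)))
  z <- matrix(NA_real_, nrow = length(mods), ncol = 2)
  with_seed(seed, {
    for (i in seq_along(mods)) {
      size <- res$size[i]
      null <- t(vapply(seq_len(n_perm), function(p) {
        stat_pair(sample(shared, size))
      }, numeric(2)))
      mu <- colMeans(null)
      sd0 <- pmax(apply(null, 2, stats::sd), 1e-12)
      z[i, ] <- (obs[i, ] - mu) / sd0
    }
  })
  res$z_density <- z[, 1]
  res$z_connectivity <- z[, 2]
  res$z_summary <- rowMeans(z)
  rank_d <- rank(-obs[, 1]); rank_c <- rank(-obs[, 2])
  res$median_rank <- apply(cbind(rank_d, rank_c), 1, stats::median)
  res$n_permutations <- n_perm
  rownames(res) <- NULL
  res
}

#' Cross-condition rank correlations of expression and connectivity
#'
#' Compares a gene set between two conditions: Spearman correlation of mean
#' expression ranks, and Spearman correlation of within-gene-set
#' intramodular connectivity ranks (adjacency built per condition at each
#' condition's power).
#'
#' @param m_a,m_b expression matrices for the two conditions.
#' @param geneset genes present in both matrices (>= 3).
#' @param power_a,power_b soft-threshold powers per condition (default 6).
#' @param sign_mode adjacency sign mode.
#' @return list with `rho_expression` and `rho_connectivity`.
#' @export
cross_condition_rank_correlation <- function(m_a, m_b, geneset,
                                             power_a = 6, power_b = 6,
                                             sign_mode = "unsigned") {
  geneset <- unique(geneset)
  if (length(geneset) < 3) stop_cfg("gene set must have >= 3 genes")
  if (!all(geneset %in% rownames(m_a)) || !all(geneset %in% rownames(m_b))) {
    stop_cfg("gene set not fully present in both matrices")
  }
  ea <- rowMeans(m_a[geneset, , drop = FALSE])
  eb <- rowMeans(m_b[geneset, , drop = FALSE])
  rho_e <- stats::cor(rank(ea), rank(eb), method = "spearman")
  ka <- build_adjacency(m_a[geneset, , drop = FALSE], power_a, sign_mode)$adjacency
  kb <- build_adjacency(m_b[geneset, , drop = FALSE], power_b, sign_mode)$adjacency
  diag(ka) <- 0; diag(kb) <- 0
  rho_k <- stats::cor(rank(rowSums(ka)), rank(rowSums(kb)), method = "spearman")
  list(rho_expression = rho_e, rho_connectivity = rho_k)
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric p per collection set against a fixed
#' universe, BH-adjusted across collections.
#'
#' @param geneset query gene set.
#' @param collections named list of gene sets.
#' @param universe background gene universe (superset of `geneset`).
#' @return data.frame (collection, size, overlap, p, fdr).
#' @export
overrepresentation_test <- function(geneset, collections, universe) {
  if (length(universe) == 0) stop_cfg("empty universe")
  universe <- unique(universe)
  if (!all(geneset %in% universe)) stop_cfg("geneset must be contained in universe")
  q <- unique(geneset)
  res <- data.frame(collection = names(collections),
                    size = NA_integer_, overlap = NA_integer_, p = NA_real_)
  for (i in seq_along(collections)) {
    cs <- intersect(unique(collections[[i]]), universe)
    k <- length(intersect(cs, q))
    res$size[i] <- length(cs)
    res$overlap[i] <- k
    res$p[i] <- if (length(cs) == 0) 1 else
      stats::phyper(k - 1, length(cs), length(universe) - length(cs),
                    length(q), lower.tail = FALSE)
  }
  res$fdr <- bh_adjust(res$p)
  res
}

# Shared Mann-Whitney / Hodges-Lehmann machinery: exact p for combined
# n <= 20 (no ties), normal approximation with tie correction otherwise.
mw_test <- function(a, b, conf_level = 0.95) {
  if (length(a) < 1 || length(b) < 1) stop_cfg("both groups must be nonempty")
  exact <- (length(a) + length(b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(a, b, conf.int = TRUE,
                                            conf.level = conf_level,
                                            exact = exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       estimate = unname(wt$estimate),
       ci = unname(wt$conf.int))
}

#' Mann-Whitney test of a module eigengene against a binary trait
#'
#' Exact test for combined n <= 20 (without ties), normal approximation with
#' tie correction otherwise; the location shift is the Hodges-Lehmann
#' estimate (median of pairwise differences, susceptible minus resistant)
#' with a distribution-free confidence interval.
#'
#' @param eigengene numeric vector of per-sample (or per-subject) eigengene
#'   values.
#' @param outcome 0/1 vector aligned with `eigengene`.
#' @param conf_level confidence level (default 0.95).
#' @return list with U, p, estimate, ci.
#' @export
eigengene_trait_test <- function(eigengene, outcome, conf_level = 0.95) {
  if (length(eigengene) != length(outcome)) stop_cfg("length mismatch")
  a <- eigengene[outcome == 1]
  b <- eigengene[outcome == 0]
  if (length(a) < 2 || length(b) < 2) stop_cfg("both outcome groups need >= 2 values")
  mw_test(a, b, conf_level)
}
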