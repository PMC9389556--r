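# Shared fixtures and independent oracles used across the suite.

# Small one-stimulus cohort configuration; sizes kept modest so network
# stages stay fast.
small_config <- function(seed = 1, n_subjects = 20, n_genes = 300,
                         module_size = 60, outcome_shift = 1,
                         connectivity_boost = 1, n_tfs = 0,
                         targets_per_tf = 0, stimuli = "LPS",
                         prevalence = 0.4, ...) {
  sim_config(
    n_subjects = n_subjects, prevalence = prevalence, n_genes = n_genes,
    stimuli = stimuli,
    modules = list(module_spec(module_size, stimuli[1],
                               predictive = TRUE, outcome_shift = outcome_shift,
                               connectivity_boost = connectivity_boost)),
    n_tfs = n_tfs, targets_per_tf = targets_per_tf,
    n_cytokines = 4, n_metabolites = 4, n_celltypes = 3, seed = seed, ...)
}

# Ad-hoc sample table for hand-built matrices: first half A, second half B,
# paired by position.
two_arm_samples <- function(n_per_arm, a = "LPS", b = "CTRL") {
  data.frame(
    sample_id = c(sprintf("P%02d_%s", seq_len(n_per_arm), a),
                  sprintf("P%02d_%s", seq_len(n_per_arm), b)),
    subject_id = rep(sprintf("P%02d", seq_len(n_per_arm)), 2),
    stimulus = rep(c(a, b), each = n_per_arm),
    age = "birth", stringsAsFactors = FALSE)
}

# Brute-force TOM: literal triple loop over the formula.
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Brute-force BH: explicit sort / step-up / cummin loop.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Dense two-block PLS oracle: leading singular pair of X1' X2 by power
# iteration.
oracle_two_block_pls <- function(x1, x2, n_iter = 2000) {
  m <- crossprod(scale(x1), scale(x2))
  v <- rep(1 / sqrt(ncol(m)), ncol(m))
  for (i in seq_len(n_iter)) {
    u <- m %*% v; u <- u / sqrt(sum(u^2))
    v <- crossprod(m, u); v <- v / sqrt(sum(v^2))
  }
  list(w1 = drop(u), w2 = drop(v))
}

# Up to sign, max abs deviation between two unit vectors.
vec_diff_upto_sign <- function(a, b) min(max(abs(a - b)), max(abs(a + b)))

# Trapezoidal integral of an ROC curve.
trapz_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Random MI triangle as a 3-edge mi_network (two regulators + one target).
random_triangle <- function(mis) {
  edges <- data.frame(tf = c("T1", "T1", "T2"),
                      target = c("T2", "g1", "g1"),
                      mi = mis, p = 0.001, stringsAsFactors = FALSE)
  structure(list(edges = edges, tf_list = c("T1", "T2")), class = "mi_network")
}

# Two omics blocks sharing one planted latent factor tied to the outcome.
planted_blocks <- function(seed = 84, n = 50, informative = 20) {
  set.seed(seed)
  f <- rnorm(n)
  y <- as.integer(f + rnorm(n, sd = 0.7) > 0)
  mk <- function(p, label) {
    x <- sapply(seq_len(p), function(j)
      (j <= informative) * f * runif(1, 0.7, 1) + rnorm(n))
    dimnames(x) <- list(sprintf("s%02d", 1:n), paste0(label, seq_len(p)))
    x
  }
  list(blocks = list(tr = mk(200, "t"), cy = mk(40, "c")), y = y, f = f)
}

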