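test_that("MI estimator is non-negative, symmetric and matches the Gaussian closed form", {
  set.seed(51)
  x <- rnorm(500); y <- rnorm(500)
  expect_gte(estimate_mi(x, y), 0)
  expect_equal(estimate_mi(x, y), estimate_mi(y, x))
  # self-information dominates a shuffled copy
  expect_gt(estimate_mi(x, x), estimate_mi(x, sample(x)))
  # null calibration: independent uniforms give tiny MI
  mis0 <- replicate(40, estimate_mi(runif(500), runif(500)))
  expect_gte(mean(mis0 < 0.05), 0.95)
  # closed form -0.5 log(1 - rho^2) for bivariate Gaussians
  for (rho in c(0.5, 0.9)) {
    mi <- mean(replicate(3, {
      x <- rnorm(2000)
      estimate_mi(x, rho * x + sqrt(1 - rho^2) * rnorm(2000))
    }))
    expect_lt(abs(mi - (-0.5 * log(1 - rho^2))), 0.15)
  }
  expect_error(estimate_mi(rep(1, 30), rnorm(30)), "constant")
  expect_error(estimate_mi(rnorm(10), rnorm(10)), "n >= 20")
})

test_that("MI network retains planted regulon edges and controls the null", {
  cfg <- small_config(seed = 52, n_subjects = 50, n_genes = 60, module_size = 10,
                      n_tfs = 2, targets_per_tf = 10)
  co <- generate_cohort(cfg)
  truth <- co$truth$regulons
  net <- build_mi_network(co$expr, unique(truth$tf), n_perm = 200, seed = 3)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted <- key(truth$tf, truth$target)
  kept <- key(net$edges$tf, net$edges$target)
  expect_gte(mean(planted %in% kept), 0.9)
  # independent data: edge count bounded by ~2 * alpha * n_pairs
  set.seed(53)
  ind <- matrix(rnorm(30 * 40), 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:40)))
  net0 <- build_mi_network(ind, rownames(ind)[1:3], n_perm = 200, alpha = 0.05, seed = 4)
  expect_lte(nrow(net0$edges), 2 * 0.05 * 3 * 29)
  # deterministic for a fixed seed
  net0b <- build_mi_network(ind, rownames(ind)[1:3], n_perm = 200, alpha = 0.05, seed = 4)
  expect_identical(net0$edges, net0b$edges)
  expect_error(build_mi_network(ind[, 1:10], rownames(ind)[1:2]), ">= 20")
})

test_that("DPI removes exactly the strictly weakest triangle edge and is idempotent", {
  # chain X -> Y -> Z: the weak X-Z edge is indirect
  tri <- random_triangle(c(0.5, 0.2, 0.4))  # T1-T2 = .5, T1-g1 = .2, T2-g1 = .4
  pruned <- apply_dpi(tri, tolerance = 0)
  expect_equal(nrow(pruned$edges), 2)
  expect_false(any(pruned$edges$mi == 0.2))
  # tolerance 1 disables pruning
  expect_equal(nrow(apply_dpi(tri, tolerance = 1)$edges), 3)
  # equal MIs: no strict minimum, nothing removed
  expect_equal(nrow(apply_dpi(random_triangle(c(0.3, 0.3, 0.3)))$edges), 3)
  # idempotence and the removal rule on random triangles
  set.seed(54)
  for (i in 1:200) {
    mis <- round(runif(3, 0.05, 1), 3)
    tol <- sample(c(0, 0.1, 0.3), 1)
    net <- random_triangle(mis)
    once <- apply_dpi(net, tol)
    twice <- apply_dpi(once, tol)
    expect_identical(once$edges, twice$edges)
    w <- which.min(mis)
    should_drop <- mis[w] < (1 - tol) * min(mis[-w]) && sum(mis == mis[w]) == 1
    expect_equal(nrow(once$edges), 3 - as.integer(should_drop))
    if (should_drop) expect_false(any(once$edges$mi == mis[w]))
  }
})

test_that("regulon assembly attaches modes and scaled likelihoods", {
  cfg <- small_config(seed = 55, n_subjects = 40, n_genes = 60, module_size = 10,
                      n_tfs = 1, targets_per_tf = 15,
                      tf_mode_fraction_negative = 0)
  co <- generate_cohort(cfg)
  truth <- co$truth$regulons
  net <- build_mi_network(co$expr, unique(truth$tf), n_perm = 100, seed = 6)
  regs <- assemble_regulons(net, co$expr, min_targets = 10)
  tf <- unique(truth$tf)
  expect_true(tf %in% names(regs))
  reg <- regs[[tf]]
  expect_equal(max(reg$likelihood), 1)
  expect_true(all(reg$likelihood > 0 & reg$likelihood <= 1))
  expect_true(all(reg$mode >= -1 & reg$mode <= 1))
  # planted all-activating regulon: recovered modes are positive on true targets
  on_truth <- reg$target %in% truth$target
  expect_true(all(reg$mode[on_truth] > 0))
  # min_targets filter drops small regulons
  net_small <- net
  net_small$edges <- net_small$edges[1:5, ]
  expect_length(assemble_regulons(net_small, co$expr, min_targets = 10), 0)
})

test_that("aREA is null-calibrated, antisymmetric in mode, and classifies drivers", {
  # null moments averaged over several signature draws (a single fixed
  # signature correlates the regulon scores, inflating the mean's noise)
  null_run <- function(seed) {
    set.seed(seed)
    sig <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
    tab <- do.call(rbind, lapply(1:200, function(i)
      data.frame(tf = sprintf("T%03d", i), target = sample(names(sig), 25),
                 mode = runif(25, -1, 1), likelihood = runif(25, 0.5, 1))))
    r <- area_enrichment(sig, regulon_set(tab))
    c(mean(r$nes), sd(r$nes))
  }
  mom <- vapply(201:206, null_run, numeric(2))
  expect_lt(abs(mean(mom[1, ])), 0.05)
  expect_gt(mean(mom[2, ]), 0.9); expect_lt(mean(mom[2, ]), 1.1)
  # exact antisymmetry under mode negation
  set.seed(56)
  sig <- setNames(rnorm(2000), sprintf("g%04d", 1:2000))
  tab <- do.call(rbind, lapply(1:50, function(i)
    data.frame(tf = sprintf("T%03d", i), target = sample(names(sig), 25),
               mode = runif(25, -1, 1), likelihood = runif(25, 0.5, 1))))
  res <- area_enrichment(sig, regulon_set(tab))
  tab2 <- tab; tab2$mode <- -tab2$mode
  res2 <- area_enrichment(sig, regulon_set(tab2))
  expect_equal(res$nes, -res2$nes, tolerance = 1e-12)
  # a regulon holding the top ranks with mode +1 is called activated
  top <- data.frame(tf = "UP", target = names(sort(sig, decreasing = TRUE))[1:25],
                    mode = 1, likelihood = 1)
  res3 <- area_enrichment(sig, regulon_set(top))
  expect_gt(res3$nes, 2)
  expect_identical(res3$direction, "activated")
  # skipped when the overlap is too small
  tiny <- data.frame(tf = "TINY", target = names(sig)[1:3], mode = 1, likelihood = 1)
  expect_warning(expect_error(area_enrichment(sig, regulon_set(tiny)), "overlap"),
                 "skipped")
})

test_that("contrast-signature master-regulator analysis recovers the planted driver", {
  top_rank <- 0
  for (s in 1:10) {
    cfg <- small_config(seed = 600 + s, n_subjects = 50, n_genes = 300,
                        module_size = 60, n_tfs = 1, targets_per_tf = 20)
    co <- generate_cohort(cfg)
    truth <- co$truth$regulons
    # 49 decoy regulons with random targets and modes
    decoys <- do.call(rbind, lapply(1:49, function(i) {
      set.seed(9000 + 100 * s + i)
      data.frame(tf = sprintf("D%02d", i),
                 target = sample(rownames(co$expr), 20),
                 mode = sample(c(-1, 1), 20, replace = TRUE),
                 likelihood = runif(20, 0.5, 1))
    }))
    all_regs <- regulon_set(rbind(
      truth[, c("tf", "target", "mode")] |> transform(likelihood = truth$weight),
      decoys))
    res <- msviper_contrast(co$expr, co$samples, c("LPS", "CTRL"), all_regs,
                            min_overlap = 5)
    if (which(res$tf == unique(truth$tf)) <= 3) top_rank <- top_rank + 1
  }
  expect_gte(top_rank, 9)
})

test_that("permuted contrasts flag few drivers and unresponsive regulons stay quiet", {
  cfg <- small_config(seed = 61, n_subjects = 30, n_genes = 200, module_size = 40,
                      n_tfs = 1, targets_per_tf = 15)
  co <- generate_cohort(cfg)
  # regulons of non-responsive background genes only
  bg <- setdiff(rownames(co$expr),
                c(names(co$truth$module_membership),
                  co$truth$regulons$tf, co$truth$regulons$target))
  set.seed(62)
  quiet <- do.call(rbind, lapply(1:20, function(i)
    data.frame(tf = sprintf("Q%02d", i), target = sample(bg, 12),
               mode = sample(c(-1, 1), 12, replace = TRUE), likelihood = 1)))
  res <- msviper_contrast(co$expr, co$samples, c("LPS", "CTRL"),
                          regulon_set(quiet), min_overlap = 5)
  expect_lte(mean(res$driver), 0.10)
  expect_true(all(abs(res$nes) < 3.5))
})

test_that("motif filtering applies the annotated-fraction rule", {
  res <- structure(data.frame(tf = c("A", "B", "C"), n_targets = 10,
                              nes = c(3, -2.5, 1), p = c(0.001, 0.01, 0.3),
                              fdr = c(0.003, 0.015, 0.3),
                              direction = c("activated", "inhibited", "ns"),
                              stringsAsFactors = FALSE),
                   class = c("activity_result", "data.frame"))
  regs <- regulon_set(data.frame(
    tf = rep(c("A", "B", "C"), each = 10),
    target = paste0("g", 1:30),
    mode = 1, likelihood = 1))
  motifs <- data.frame(tf = c(rep("A", 10), rep("B", 4)),
                       gene = paste0("g", c(1:10, 11:14)))
  # A fully annotated, B 4/10, C absent from the table
  expect_warning(kept <- filter_by_motif(res, regs, motifs), "C")
  expect_setequal(kept$tf, c("A", "B"))
  expect_warning(kept5 <- filter_by_motif(res, regs, motifs, min_fraction = 0.5), "C")
  expect_identical(kept5$tf, "A")   # 4/10 annotated is below 0.5
  # zero annotated targets -> dropped even at the default
  motifs_a <- motifs[motifs$tf == "A", ]
  expect_warning(kept_a <- filter_by_motif(res, regs, motifs_a), "B, C")
  expect_identical(kept_a$tf, "A")
})

test_that("per-sample activity matrix aligns TFs with samples deterministically", {
  cfg <- small_config(seed = 63, n_subjects = 15, n_genes = 120, module_size = 30,
                      n_tfs = 2, targets_per_tf = 12)
  co <- generate_cohort(cfg)
  truth <- co$truth$regulons
  regs <- regulon_set(transform(truth[, c("tf", "target", "mode")],
                                likelihood = truth$weight))
  adj <- baseline_adjust(co$expr, co$samples, "LPS")
  act <- viper_activity_matrix(adj, regs, min_overlap = 5)
  expect_equal(dim(act), c(2, 15))
  expect_identical(colnames(act), colnames(adj))
  expect_identical(act, viper_activity_matrix(adj, regs, min_overlap = 5))
})
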