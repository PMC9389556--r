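test_that("adjacency follows the power law on correlations", {
  set.seed(1)
  m <- matrix(rnorm(20 * 30), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30)))
  r <- cor(t(m))
  net <- build_adjacency(m, power = 1)
  expect_equal(unname(net$adjacency[2, 5]), abs(r[2, 5]))
  net6 <- build_adjacency(m, power = 6)
  expect_equal(unname(net6$adjacency[3, 7]), abs(r[3, 7])^6)
  expect_equal(0.5^6, 0.015625)   # the sixth-power shrinkage applied to r = 0.5
  # perfectly correlated genes keep adjacency 1 at any power
  m2 <- rbind(m, dup = 2 * m[1, ] + 3)
  expect_equal(unname(build_adjacency(m2, 6)$adjacency["dup", "g01"]), 1)
  # signed-hybrid zeroes negative correlations
  neg <- rbind(m[1:3, ], anti = -m[1, ])
  nh <- build_adjacency(neg, 2, sign_mode = "signed-hybrid")
  expect_equal(unname(nh$adjacency["anti", "g01"]), 0)
  flat <- rbind(m, zz = rep(1, 30))
  expect_error(build_adjacency(flat, 6), "zz")
  # bounds and symmetry
  expect_true(all(net6$adjacency >= 0 & net6$adjacency <= 1))
  expect_lt(max(abs(net6$adjacency - t(net6$adjacency))), 1e-10)
})

test_that("TOM equals the brute-force triple-loop oracle and hits closed forms", {
  # complete graph with all a = 1
  ones <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  net <- structure(list(adjacency = ones, power = 1, sign_mode = "unsigned"),
                   class = "coexpr_network")
  expect_true(all(abs(compute_tom(net)$tom - 1) < 1e-12))
  # two nodes connected only to each other with weight a -> TOM = a
  for (a in c(0.2, 0.7)) {
    adj <- diag(2); adj[1, 2] <- adj[2, 1] <- a
    dimnames(adj) <- list(c("x", "y"), c("x", "y"))
    net2 <- structure(list(adjacency = adj, power = 1, sign_mode = "unsigned"),
                      class = "coexpr_network")
    expect_equal(unname(compute_tom(net2)$tom[1, 2]), a, tolerance = 1e-12)
  }
  # random instances vs the oracle
  set.seed(2)
  for (i in 1:10) {
    a <- matrix(runif(400), 20); a <- (a + t(a)) / 2; diag(a) <- 1
    dimnames(a) <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20))
    netr <- structure(list(adjacency = a, power = 1, sign_mode = "unsigned"),
                      class = "coexpr_network")
    tom <- compute_tom(netr)$tom
    expect_lt(max(abs(tom - oracle_tom(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("soft-threshold choice follows the smallest-power rule", {
  # forced choice from a precomputed R2 table is the smallest reaching target
  cfg <- small_config(seed = 31, n_subjects = 30, n_genes = 150,
                      module_size = 60)
  co <- generate_cohort(cfg)
  st <- pick_soft_threshold(co$expr, powers = 1:10, r2_target = 0.8)
  expect_true(st$power %in% 1:10)
  # mean connectivity strictly decreases with power
  expect_true(all(diff(st$table$mean_connectivity) < 0))
  # smallest power at/above target, when the target is reached
  if (st$reached_target) {
    ok <- which(st$table$scale_free_r2 >= 0.8)
    expect_equal(st$power, st$table$power[ok[1]])
  }
  flat <- rbind(co$expr[1:20, ], const = rep(2, ncol(co$expr)))
  expect_warning(pick_soft_threshold(flat, powers = 1:3), "constant")
})

test_that("module detection recovers planted blocks and greys out noise", {
  # two orthogonal planted blocks
  set.seed(33)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- rbind(
    t(sapply(1:100, function(i) 2 * f1 + rnorm(n, sd = 1))),
    t(sapply(1:100, function(i) 2 * f2 + rnorm(n, sd = 1))))
  dimnames(x) <- list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:n))
  net <- build_adjacency(x, 6)
  tom <- compute_tom(net)$tom
  part <- detect_modules(tom, x, min_module_size = 30, net = net)
  truth <- rep(c("A", "B"), each = 100)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(part$labels, truth), 1.0)
  # partition invariants
  expect_true(all(part$kim <= part$ktotal + 1e-10))
  expect_true(all(part$var_explained > 0 & part$var_explained <= 1))
  expect_equal(unname(apply(part$eigengenes, 1, sd)), rep(1, 2))

  # pure noise stays almost entirely grey
  noise <- matrix(rnorm(200 * n), 200,
                  dimnames = list(sprintf("n%03d", 1:200), sprintf("s%02d", 1:n)))
  tomn <- compute_tom(build_adjacency(noise, 6))$tom
  partn <- detect_modules(tomn, noise, min_module_size = 30)
  expect_gte(mean(partn$labels == "grey"), 0.95)

  # a block smaller than min_module_size dissolves to grey
  small <- x[1:50, ]
  toms <- compute_tom(build_adjacency(small, 6))$tom
  expect_warning(parts <- detect_modules(toms, small, min_module_size = 60),
                 "grey")
  expect_true(all(parts$labels == "grey"))
})

test_that("eigengenes are unit-variance, sign-oriented and track the planted factor", {
  set.seed(34)
  n <- 40
  f <- rnorm(n)
  x <- t(sapply(1:30, function(i) runif(1, 1, 2) * f + rnorm(n, sd = 0.5)))
  dimnames(x) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:n))
  labels <- setNames(rep("M1", 30), rownames(x))
  eg <- compute_eigengenes(x, labels)
  expect_equal(sd(eg$eigengenes["M1", ]), 1)
  expect_gt(cor(eg$eigengenes["M1", ], rowMeans(scale(t(x)))), 0)
  expect_gte(abs(cor(eg$eigengenes["M1", ], f)), 0.9)
  # identical profiles give var_explained 1 and |cor| = 1 with each gene
  same <- matrix(rep(f, 3), nrow = 3, byrow = TRUE) +
    matrix(c(0, 1, 2), 3, n)
  dimnames(same) <- list(c("a", "b", "c"), sprintf("s%02d", 1:n))
  egs <- compute_eigengenes(same, setNames(rep("M1", 3), rownames(same)))
  expect_equal(unname(egs$var_explained["M1"]), 1)
  expect_equal(abs(cor(egs$eigengenes["M1", ], same["a", ])), 1)
  expect_error(compute_eigengenes(x, setNames(c("M1", rep("grey", 29)), rownames(x))),
               "< 2 genes")
})

test_that("connectivity sums split correctly between module and network", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(c("x", "y", "z"), c("x", "y", "z"))
  net <- structure(list(adjacency = a, power = 1, sign_mode = "unsigned"),
                   class = "coexpr_network")
  k <- intramodular_connectivity(net, setNames(rep("m", 3), c("x", "y", "z")))
  expect_equal(unname(k$kim), rep(1, 3))    # 2 x 0.5
  expect_equal(k$kim, k$ktotal)
  # mixed modules: kim is the within-module share
  k2 <- intramodular_connectivity(net, setNames(c("m", "m", "grey"), c("x", "y", "z")))
  expect_equal(unname(k2$kim[c("x", "y")]), c(0.5, 0.5))
  expect_equal(unname(k2$kim["z"]), 0)      # grey computed within grey
  expect_true(all(k2$kim <= k2$ktotal))
})

test_that("scaled connectivity density and its normality label behave", {
  set.seed(35)
  kim <- setNames(abs(rnorm(180, 5, 1)), sprintf("g%03d", 1:180))
  prof <- connectivity_density(kim, names(kim), stratum = "all", seed = 3)
  expect_equal(max(prof$scaled), 1)
  expect_equal(sum(prof$scaled == 1), 1)
  expect_true(all(prof$scaled >= 0 & prof$scaled <= 1))
  expect_identical(prof$stratum, "all")
  # equal connectivity everywhere is flagged degenerate
  flatk <- setNames(rep(2, 30), sprintf("g%02d", 1:30))
  expect_true(connectivity_density(flatk, names(flatk))$degenerate)
  expect_error(connectivity_density(setNames(rep(0, 10), letters[1:10]),
                                    letters[1:10]), "k_max")
  # Gaussian connectivity passes the normality check in most seeded draws
  ok <- 0
  for (i in 1:50) {
    set.seed(400 + i)
    ki <- setNames(rnorm(180, 10, 1), sprintf("g%03d", 1:180))
    if (connectivity_density(ki, names(ki), seed = 7)$lilliefors_p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("Monte-Carlo Lilliefors test is calibrated and matches the reference statistic", {
  skip_if_not_installed("nortest")
  set.seed(36)
  for (i in 1:5) {
    x <- rnorm(40 + 10 * i)
    expect_equal(ifnnet:::lilliefors_stat(x),
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  }
  # calibration near alpha under the null, strong power under exponential
  set.seed(37)
  rej <- mean(replicate(400, lilliefors_test(rnorm(100), n_mc = 2000, seed = 55) < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  pw <- mean(replicate(100, lilliefors_test(rexp(200), n_mc = 2000, seed = 56) < 0.05))
  expect_gte(pw, 0.99)
  expect_error(lilliefors_test(c(1, 2, 3, 4)), "n >= 5")
  expect_error(lilliefors_test(rep(1, 10)), "constant")
})

test_that("hub extraction ranks by connectivity and flags strong edges", {
  set.seed(38)
  n <- 50
  f <- rnorm(n)
  loads <- seq(2, 0.5, length.out = 20)
  x <- t(sapply(loads, function(l) l * f + rnorm(n, sd = 0.4)))
  dimnames(x) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n))
  net <- build_adjacency(x, 6)
  kim <- intramodular_connectivity(net, setNames(rep("m", 20), rownames(x)))$kim
  th <- top_hubs(x, kim, rownames(x), n_top = 5, edge_threshold = 0.8)
  expect_equal(nrow(th$hubs), 5)
  expect_true("g01" %in% th$hubs$gene[1:2])   # largest loading is a top hub
  expect_identical(th$edges$strong, abs(th$edges$r) > 0.8)
  full <- top_hubs(x, kim, rownames(x), n_top = 20)
  expect_setequal(full$hubs$gene, rownames(x))
  expect_error(top_hubs(x, kim, rownames(x), n_top = 21), "exceeds")
})

test_that("preservation Z separates planted modules from random gene sets", {
  cfg <- small_config(seed = 39, n_subjects = 30, n_genes = 200, module_size = 50)
  co <- generate_cohort(cfg)
  mod <- names(co$truth$module_membership)
  labels <- setNames(ifelse(rownames(co$expr) %in% mod, "M1", "grey"),
                     rownames(co$expr))
  # test = reference: the planted module is trivially preserved
  pres <- module_preservation(co$expr, co$expr, labels, n_perm = 30, seed = 2)
  expect_gt(pres$z_summary[pres$module == "M1"], 10)
  # a random gene set is not preserved beyond chance
  set.seed(40)
  zs <- replicate(8, {
    rnd <- setNames(rep("grey", nrow(co$expr)), rownames(co$expr))
    rnd[sample(rownames(co$expr), 50)] <- "R1"
    module_preservation(co$expr, co$expr, rnd, n_perm = 30, seed = 2)$z_summary
  })
  expect_gte(mean(zs > -2 & zs < 2), 0.75)
  expect_error(module_preservation(co$expr, co$expr, labels, n_perm = 10), "n_perm")
  # invariant to gene order permutations
  set.seed(41)
  ord <- sample(rownames(co$expr))
  pres2 <- module_preservation(co$expr[ord, ], co$expr, labels, n_perm = 30, seed = 2)
  expect_equal(pres$z_summary, pres2$z_summary, tolerance = 1e-10)
})

test_that("cross-condition rank correlations separate expression from wiring", {
  cfg <- small_config(seed = 43, n_subjects = 30, n_genes = 120, module_size = 60)
  co <- generate_cohort(cfg)
  mod <- names(co$truth$module_membership)
  # identical matrices give perfect correlations
  cc <- cross_condition_rank_correlation(co$expr, co$expr, mod)
  expect_equal(cc$rho_expression, 1.0)
  expect_equal(cc$rho_connectivity, 1.0)
  # doubling noise degrades wiring ranks faster than expression ranks
  set.seed(44)
  noisy <- co$expr + matrix(rnorm(length(co$expr), sd = 2), nrow(co$expr))
  cc2 <- cross_condition_rank_correlation(co$expr, noisy, mod)
  expect_gte(cc2$rho_expression, cc2$rho_connectivity)
  # independent matrices hover near zero
  set.seed(45)
  ind <- matrix(rnorm(length(co$expr)), nrow(co$expr), dimnames = dimnames(co$expr))
  cc3 <- cross_condition_rank_correlation(co$expr[mod, ], ind[mod, ], mod)
  expect_lt(abs(cc3$rho_expression), 0.3)
  expect_lt(abs(cc3$rho_connectivity), 0.3)
  expect_error(cross_condition_rank_correlation(co$expr, co$expr, mod[1:2]), ">= 3")
})

test_that("hypergeometric over-representation matches the closed form", {
  universe <- sprintf("u%02d", 1:20)
  colls <- list(hit = universe[1:5], empty = character(0))
  res <- overrepresentation_test(universe[c(1, 2, 3, 6)], colls, universe)
  expect_equal(res$p[res$collection == "hit"], 155 / 4845, tolerance = 1e-12)
  expect_equal(res$overlap[res$collection == "hit"], 3)
  expect_equal(res$p[res$collection == "empty"], 1)
  # query = universe forces maximal overlap and p = 1
  res2 <- overrepresentation_test(universe, colls["hit"], universe)
  expect_equal(res2$overlap, 5)
  expect_equal(res2$p, 1)
  expect_error(overrepresentation_test(universe[1], colls, character(0)), "universe")
})

test_that("eigengene trait test gives the exact Mann-Whitney enumeration", {
  res <- eigengene_trait_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(res$p, 0.1)    # 2/20 arrangements as extreme
  expect_equal(res$U, 0)
  # identical groups: p near 1, shift near 0
  res2 <- eigengene_trait_test(rep(c(1, 2, 3), 2), rep(c(1, 0), each = 3))
  expect_gt(res2$p, 0.9)
  expect_lt(abs(res2$estimate), 0.5)
  expect_error(eigengene_trait_test(1:5, c(1, 1, 1, 1, 1)), ">= 2")
  # power under a planted shift
  set.seed(46)
  hits <- mean(replicate(100, {
    eigengene_trait_test(c(rnorm(25, 1.2), rnorm(25)), rep(c(1, 0), each = 25))$p < 0.05
  }))
  expect_gte(hits, 0.8)
})
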