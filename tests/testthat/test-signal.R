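test_that("BM log-likelihood matches dense multivariate-normal oracles", {
  # single tip: standard normal density at the mode
  expect_equal(bm_loglik(c(A = 0), matrix(1, dimnames = list("A", "A")),
                         1, 0), -0.5 * log(2 * pi))
  # star tree: independent normals
  star <- tree_star(5)
  V <- phylo_vcv(star)
  x <- setNames(rnorm(5), star$tip.label)
  expect_equal(bm_loglik(x, V, 2, 0.3),
               sum(dnorm(x, 0.3, sqrt(2), log = TRUE)), tolerance = 1e-10)
  # general 5-tip tree vs dense linear-algebra oracle
  tr <- simulate_yule_tree(5, seed = 61)
  V <- phylo_vcv(tr)
  x <- simulate_bm_trait(tr, 1.5, 1, 2, seed = 62)
  expect_equal(bm_loglik(x, V, 1.5, 2),
               oracle_mvn_loglik(x[rownames(V)], rep(2, 5), 1.5 * V),
               tolerance = 1e-8)
  # invariant under simultaneous relabeling
  perm <- sample(5)
  expect_equal(bm_loglik(x[perm], V, 1.5, 2), bm_loglik(x, V, 1.5, 2))
})

test_that("profile likelihood equals the dense GLS likelihood at the optimum", {
  tr <- simulate_yule_tree(30, seed = 63)
  x <- simulate_bm_trait(tr, 2, 0.6, 1, seed = 64)
  ft <- fit_lambda(x, tr)
  V <- lambda_transform(phylo_vcv(tr), ft$lambda_hat)
  expect_equal(ft$loglik, bm_loglik(x, V, ft$sigma2_hat, ft$z0_hat),
               tolerance = 1e-6)
  # no lambda in [eps, 1] beats the reported optimum
  prep <- phylofd:::lambda_prep(tr)
  xt <- crossprod(prep$Q, x[prep$labels])[, 1]
  grid <- seq(1e-7, 1, length.out = 201)
  lls <- vapply(grid, phylofd:::profile_loglik, numeric(1),
                prep = prep, xt = xt)
  expect_gte(ft$loglik + 1e-6, max(lls))
})

test_that("lambda estimates agree with the standard comparative-methods fit", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(50, seed = 65)
  for (lam in c(0.3, 0.9)) {
    x <- simulate_bm_trait(tr, 1, lam, 0, seed = 66 + round(100 * lam))
    ours <- fit_lambda(x, tr)
    ref <- phytools::phylosig(tr, x, method = "lambda", test = FALSE)
    expect_equal(ours$lambda_hat, ref$lambda, tolerance = 1e-3)
    expect_equal(ours$loglik, ref$logL, tolerance = 1e-4)
  }
})

test_that("fit_lambda rejects degenerate inputs", {
  tr <- simulate_yule_tree(10, seed = 67)
  expect_error(fit_lambda(setNames(rep(1, 10), tr$tip.label), tr), "constant")
  expect_error(fit_lambda(setNames(rnorm(2), c("A", "B")), tree_cherry()),
               "at least 4 tips")
  bad <- read_newick("((A:1,B:1):1,(C:1,D:3):1);")
  expect_error(fit_lambda(setNames(rnorm(4), bad$tip.label), bad),
               "ultrametric")
})

test_that("bootstrap CI is reproducible, ordered, and hugs the eps bound for no-signal traits", {
  tr <- simulate_yule_tree(40, seed = 68)
  x <- simulate_bm_trait(tr, 1, 0.7, 0, seed = 69)
  ft <- fit_lambda(x, tr)
  ci1 <- parametric_bootstrap_ci(ft, tr, n_sim = 60, seed = 7)
  ci2 <- parametric_bootstrap_ci(ft, tr, n_sim = 60, seed = 7)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)
  expect_lte(ci1$ci_low, ci1$ci_high)
  expect_gte(ci1$ci_low, ft$eps)
  expect_lte(ci1$ci_high, 1)
  # iid (no-signal) trait: lower bound collapses to the optimizer floor
  x0 <- setNames(rnorm(40), tr$tip.label)
  f0 <- fit_lambda(x0, tr)
  b0 <- parametric_bootstrap_ci(f0, tr, n_sim = 60, seed = 8)
  expect_lt(b0$ci_low, 1e-4)
})

test_that("Moran's I matches the double-sum oracle and its exact small cases", {
  # n = 2 with the single pair weighted: I = -1 for any distinct values
  W2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(moran_i(c(3.2, -1), W2, n_perm = 9)$I, -1)
  expect_equal(moran_i(c(100, 101), W2, n_perm = 9)$I, -1)
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    W <- matrix(rbinom(n * n, 1, 0.4), n)
    W <- W * upper.tri(W); W <- W + t(W)
    if (sum(W) == 0) W[1, 2] <- W[2, 1] <- 1
    x <- rnorm(n)
    expect_equal(moran_i(x, W, n_perm = 1)$I, oracle_moran(x, W),
                 tolerance = 1e-12)
  }
  expect_error(moran_i(rep(1, 4), W2[c(1, 2, 1, 2), c(1, 2, 1, 2)]),
               "constant|symmetric")
  expect_error(moran_i(rnorm(3), matrix(0, 3, 3)), "all-zero")
})

test_that("permutation null of Moran's I is centered on -1/(n-1)", {
  set.seed(72)
  n <- 15
  W <- matrix(1, n, n); diag(W) <- 0
  W[upper.tri(W)] <- rbinom(sum(upper.tri(W)), 1, 0.5)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  x <- rnorm(n)
  xc <- x - mean(x)
  perm_I <- replicate(4000, {
    p <- sample(n)
    oracle_moran(x[p], W)
  })
  expect_lt(abs(mean(perm_I) - (-1 / (n - 1))), 0.01)
})

test_that("Moran's I agrees with the standard autocorrelation implementation", {
  # a regular (constant-row-sum) weight graph, where the reference
  # implementation's row normalization is a harmless constant rescaling
  set.seed(73)
  n <- 12
  x <- rnorm(n)
  circulant <- function(n, offsets) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in offsets) {
      j <- (i + k - 1) %% n + 1
      W[i, j] <- W[j, i] <- 1
    }
    W
  }
  for (offs in list(1, c(1, 2))) {
    Wr <- circulant(n, offs)
    refr <- ape::Moran.I(x, Wr)
    expect_equal(moran_i(x, Wr, n_perm = 9)$I, refr$observed,
                 tolerance = 1e-10)
    expect_equal(moran_i(x, Wr, method = "normal")$p_value, refr$p.value,
                 tolerance = 1e-10)
  }
})

test_that("distance classes partition all tip pairs exactly once", {
  tr <- simulate_yule_tree(61, seed = 74)
  D <- patristic_distances(tr)
  cls <- build_distance_classes(D, 8, "equal_width")
  expect_length(cls$weights, 8)
  expect_equal(sum(cls$n_pairs), 61 * 60 / 2)
  U <- Reduce(`+`, cls$weights)
  expect_equal(unname(U), unname((D > -1) - diag(61)))  # each pair once
  expect_true(all(diff(cls$bounds) > 0))
  # equal frequency on continuous (tie-free) distances: near-equal counts
  set.seed(740)
  pts <- matrix(rnorm(40 * 3), 40)
  Dc <- as.matrix(dist(pts))
  dimnames(Dc) <- list(paste0("t", 1:40), paste0("t", 1:40))
  clf <- build_distance_classes(Dc, 8, "equal_frequency")
  expect_equal(sum(clf$n_pairs), choose(40, 2))
  expect_lte(max(clf$n_pairs) - min(clf$n_pairs), 2)
  Uc <- Reduce(`+`, clf$weights)
  expect_equal(unname(Uc), unname((Dc > -1) - diag(40)))
  # on a tree's heavily tied distances the quantile edges may collapse;
  # the partition property must survive
  clt <- suppressWarnings(build_distance_classes(D, 8, "equal_frequency"))
  expect_equal(sum(clt$n_pairs), 61 * 60 / 2)
  expect_true(all(diff(clt$bounds) > 0))
  # discrete two-depth tree: only 2 of 8 equal-width classes occupied
  tr2 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_warning(cls2 <- build_distance_classes(patristic_distances(tr2), 8),
                 "distinct distances")
  expect_equal(sum(!cls2$empty), 2)
})

test_that("the correlogram flags empty classes and respects its seed", {
  tr <- simulate_two_clade_tree(20, split_frac = 0.9, seed = 75)
  x <- simulate_bm_trait(tr, 1, 1, 0, seed = 76)
  cg <- phylo_correlogram(x, tr, n_classes = 8, n_perm = 99, seed = 3)
  expect_equal(nrow(cg), 8)
  # deep two-clade split leaves intermediate classes without pairs
  expect_gte(sum(cg$empty), 3)
  expect_true(all(is.na(cg$I[cg$empty])))
  expect_true(all(!is.na(cg$I[!cg$empty])))
  expect_true(all(cg$p[!cg$empty] >= 1 / 100 & cg$p[!cg$empty] <= 1))
  cg2 <- phylo_correlogram(x, tr, n_classes = 8, n_perm = 99, seed = 3)
  expect_identical(cg, cg2)
  expect_equal(sum(cg$n_pairs), choose(20, 2))
})
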