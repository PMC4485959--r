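make_pool <- function(n_sp = 8, seed = 11) {
  set.seed(seed)
  traits <- data.frame(maxH = rnorm(n_sp, 20, 8), Wd = rnorm(n_sp, 0.5, 0.1),
                       Sm = rnorm(n_sp, 1, 2), N = rnorm(n_sp, 20, 5))
  rownames(traits) <- sprintf("sp%03d", seq_len(n_sp))
  traits
}

test_that("trait standardization gives mean-0, sample-SD-1 columns", {
  tr <- make_pool()
  Z <- standardize_traits(tr)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # two-species case: {0, 2} -> +/- 1/sqrt(2) under the sample SD
  two <- matrix(c(0, 2), 2, dimnames = list(c("a", "b"), "t"))
  expect_equal(unname(standardize_traits(two)[, 1]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # idempotent on an already standardized column
  expect_equal(standardize_traits(Z), Z, tolerance = 1e-12,
               ignore_attr = TRUE)
  const <- cbind(tr, flat = 1)
  expect_error(standardize_traits(const), "zero-variance.*flat")
})

test_that("FDis matches brute force, is zero for monocultures, and scales right", {
  tr <- make_pool()
  Z <- standardize_traits(tr, c("maxH", "Wd", "Sm"))
  expect_equal(fdis(c(sp001 = 3.2), Z), 0)
  # two species at equal abundance: FDis = half their distance
  a2 <- c(sp001 = 1, sp002 = 1)
  d12 <- sqrt(sum((Z["sp001", ] - Z["sp002", ])^2))
  expect_equal(fdis(a2, Z), d12 / 2, tolerance = 1e-12)
  # abundance-weighted 4-species case against the literal formula
  a4 <- c(sp001 = 1, sp002 = 2, sp003 = 3, sp004 = 4)
  expect_equal(fdis(a4, Z), oracle_fdis(a4, Z), tolerance = 1e-12)
  # invariance to rescaling abundances; zero-abundance species inert
  expect_equal(fdis(a4 * 17.3, Z), fdis(a4, Z), tolerance = 1e-12)
  expect_equal(fdis(c(a4, sp005 = 0), Z), fdis(a4, Z), tolerance = 1e-12)
  expect_error(fdis(c(spXXX = 1, sp001 = 1), Z), "missing traits.*spXXX")
})

test_that("PSV matches its definition, with the monoculture and star conventions", {
  tr <- simulate_yule_tree(12, seed = 21)
  C <- vcv_to_correlation(phylo_vcv(tr))
  expect_equal(psv("sp001", C), 0)                     # monoculture
  Cstar <- vcv_to_correlation(phylo_vcv(tree_star(6)))
  expect_equal(psv(LETTERS[1:5], Cstar), 1)            # star phylogeny
  # two sisters diverging at half depth: PSV = 1 - c = 0.5
  Chalf <- vcv_to_correlation(matrix(c(2, 1, 1, 2), 2,
                                     dimnames = list(c("A", "B"),
                                                     c("A", "B"))))
  expect_equal(psv(c("A", "B"), Chalf), 0.5)
  for (k in c(3, 5, 8)) {
    sp <- sample(rownames(C), k)
    expect_equal(psv(sp, C), oracle_psv(sp, C), tolerance = 1e-12)
  }
  # abundance-free: any positive abundances give the same value
  ab <- setNames(runif(4, 0.1, 9), rownames(C)[1:4])
  expect_equal(psv(ab, C), psv(names(ab), C))
  expect_error(psv("nosuch", C), "absent from tree")
})

test_that("CWM is the relative-basal-area-weighted trait mean", {
  trait <- c(a = 10, b = 20)
  expect_equal(cwm(c(a = 5), trait), 10)
  expect_equal(cwm(c(a = 1, b = 1), trait), 15)
  expect_equal(cwm(c(a = 1, b = 3), trait), 17.5)
  expect_equal(cwm(c(a = 1, b = 3, c = 0), c(trait, c = 1e6)), 17.5)
  expect_error(cwm(c(a = 1, z = 1), trait), "missing trait")
  # constant trait -> that constant, any weights
  expect_equal(cwm(c(a = 0.3, b = 2.2), c(a = 7, b = 7)), 7)
})

test_that("diversity_profile composes the single-plot computations", {
  tr <- simulate_yule_tree(10, seed = 31)
  traits <- make_pool(10, seed = 32)
  rownames(traits) <- tr$tip.label
  comm <- simulate_communities(tr$tip.label, 20, seed = 33)
  prof <- diversity_profile(comm, traits, tr)
  expect_equal(nrow(prof), 20)
  Z <- standardize_traits(traits, c("maxH", "Wd", "Sm"))
  C <- vcv_to_correlation(phylo_vcv(tr))
  for (i in c(1, 7, 20)) {
    a <- comm[i, ]
    expect_equal(prof$FDis[i], fdis(a, Z))
    expect_equal(prof$PSV[i], psv(a, C))
    expect_equal(prof$CWM_N[i], cwm(a, setNames(traits$N, rownames(traits))))
  }
  expect_true(all(prof$FDis >= 0))
  expect_true(all(prof$PSV >= 0 & prof$PSV <= 1 + 1e-12))
  # monoculture-only community: FDis and PSV identically zero
  mono <- matrix(0, 5, 10, dimnames = list(paste0("m", 1:5), tr$tip.label))
  for (i in 1:5) mono[i, i] <- runif(1, 1, 5)
  pm <- diversity_profile(mono, traits, tr)
  expect_equal(pm$FDis, rep(0, 5))
  expect_equal(pm$PSV, rep(0, 5))
  # duplicated plots give identical rows
  dup <- comm[c(1, 1), ]
  rownames(dup) <- c("p1", "p2")
  pd <- diversity_profile(dup, traits, tr)
  expect_equal(pd$FDis[1], pd$FDis[2])
  expect_equal(pd$PSV[1], pd$PSV[2])
  # label mismatch is a hard error naming the offender
  bad <- comm
  colnames(bad)[1] <- "ghost"
  expect_error(diversity_profile(bad, traits, tr), "ghost")
})

test_that("PSV agrees with the community-phylogenetics reference implementation", {
  skip_if_not_installed("picante")
  tr <- simulate_yule_tree(15, seed = 41)
  comm <- simulate_communities(tr$tip.label, 25, seed = 42)
  C <- vcv_to_correlation(phylo_vcv(tr))
  ours <- apply(comm, 1, function(a) psv(a, C))
  ref <- picante::psv(comm, tr)$PSVs
  multi <- rowSums(comm > 0) > 1
  expect_equal(unname(ours[multi]), unname(ref[multi]), tolerance = 1e-10)
})

test_that("community CSV I/O handles wide and long dialects", {
  tr <- simulate_yule_tree(6, seed = 51)
  comm <- simulate_communities(tr$tip.label, 8, max_richness = 4, seed = 52)
  wide <- withr::local_tempfile(fileext = ".csv")
  write.csv(cbind(plot = rownames(comm), as.data.frame(comm)), wide,
            row.names = FALSE)
  expect_equal(read_community_csv(wide)[rownames(comm), colnames(comm)],
               comm, tolerance = 1e-12)
  long <- withr::local_tempfile(fileext = ".csv")
  idx <- which(comm > 0, arr.ind = TRUE)
  write.csv(data.frame(plot = rownames(comm)[idx[, 1]],
                       species = colnames(comm)[idx[, 2]],
                       basal_area = comm[idx]), long, row.names = FALSE)
  M <- read_community_csv(long)
  common <- intersect(colnames(M), colnames(comm))
  expect_equal(M[rownames(comm), common], comm[, common], tolerance = 1e-12)
})
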