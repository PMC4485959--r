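# Independent brute-force oracles used across the suite. These walk the
# tree edge list / evaluate formulas directly, sharing no code path with
# the implementations they check.

# parent node and branch-length-to-parent maps for a phylo object
.parent_map <- function(tree) {
  nmax <- max(tree$edge)
  parent <- rep(NA_integer_, nmax)
  blen <- rep(NA_real_, nmax)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
    blen[tree$edge[k, 2L]] <- tree$edge.length[k]
  }
  list(parent = parent, blen = blen)
}

# ancestors of a node (node first, root last) with cumulative distances
.ancestor_chain <- function(node, pm) {
  nodes <- node
  dists <- 0
  while (!is.na(pm$parent[node])) {
    dists <- c(dists, dists[length(dists)] + pm$blen[node])
    node <- pm$parent[node]
    nodes <- c(nodes, node)
  }
  list(nodes = nodes, dists = dists)
}

# all-pairs patristic distances by explicit path enumeration
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  pm <- .parent_map(tree)
  chains <- lapply(seq_len(n), .ancestor_chain, pm = pm)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- chains[[i]]; cj <- chains[[j]]
    common <- intersect(ci$nodes, cj$nodes)
    mrca <- common[1L]  # chains run tipward->rootward, first shared is MRCA
    D[i, j] <- ci$dists[match(mrca, ci$nodes)] +
      cj$dists[match(mrca, cj$nodes)]
  }
  D
}

# shared root-to-MRCA path length per tip pair
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  pm <- .parent_map(tree)
  chains <- lapply(seq_len(n), .ancestor_chain, pm = pm)
  root_depth <- function(chain) chain$dists[length(chain$dists)]
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ci <- chains[[i]]; cj <- chains[[j]]
    mrca <- intersect(ci$nodes, cj$nodes)[1L]
    # depth of MRCA below the root = tip i's root depth minus tip->mrca dist
    V[i, j] <- root_depth(ci) - ci$dists[match(mrca, ci$nodes)]
  }
  V
}

# FDis by literal centroid-and-distance arithmetic
oracle_fdis <- function(abund, X) {
  a <- abund[abund > 0]
  if (length(a) == 1L) return(0)
  X <- X[names(a), , drop = FALSE]
  centroid <- rep(0, ncol(X))
  for (i in seq_along(a)) centroid <- centroid + a[i] * X[i, ]
  centroid <- centroid / sum(a)
  val <- 0
  for (i in seq_along(a))
    val <- val + a[i] * sqrt(sum((X[i, ] - centroid)^2))
  unname(val / sum(a))
}

# PSV by literal double loop over the correlation submatrix
oracle_psv <- function(species, C) {
  n <- length(species)
  if (n == 1L) return(0)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) tot <- tot + C[species[i], species[j]]
  }
  1 - tot / (n * (n - 1))
}

# Moran's I by literal double sum
oracle_moran <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0; S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
    S0 <- S0 + W[i, j]
  }
  (n / S0) * num / sum((x - xb)^2)
}

# dense multivariate-normal log-density via determinant + solve
oracle_mvn_loglik <- function(x, mu, Sigma) {
  n <- length(x)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  r <- x - mu
  as.numeric(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(Sigma) %*% r))
}

# small shared fixtures
tree_cherry <- function() read_newick("(A:1,B:1);")
tree_three <- function() read_newick("((A:1,B:1):1,C:2);")
tree_star <- function(n = 4, depth = 1) {
  labs <- LETTERS[seq_len(n)]
  read_newick(paste0("(", paste0(labs, ":", depth, collapse = ","), ");"))
}
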