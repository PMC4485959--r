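#' Read a chronogram from newick text or a file
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must carry a
#' branch length on every edge, have unique non-empty tip labels, and have
#' no negative branch lengths. Ultrametricity is *not* enforced here (see
#' [check_ultrametric()]); downstream functions that require a chronogram
#' check it themselves.
#'
#' @param source Path to a newick file, or a character scalar holding newick
#'   text (detected by the presence of `"("`).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  tr <- if (grepl("(", source, fixed = TRUE)) {
    ape::read.tree(text = source)
  } else {
    if (!file.exists(source)) stop("newick file not found: ", source)
    ape::read.tree(file = source)
  }
  if (is.null(tr)) stop("failed to parse newick input")
  validate_phylogeny(tr)
  tr
}

#' Write a tree as newick text (optionally to a file)
#'
#' @param tree An [ape::phylo] object.
#' @param path Optional output path; when `NULL` the newick string is
#'   returned invisibly-printable.
#' @return The newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Structural validation shared by tree I/O and the simulators.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$tip.label) || length(tree$tip.label) < 1L)
    stop("tree has no tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip labels")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; a chronogram requires them on every edge")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length))
    stop("missing branch length on at least one edge")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  invisible(tree)
}

#' Check that a tree is ultrametric (all tips equidistant from the root)
#'
#' Deviation is measured as `max(|depth_i - mean depth|) / mean depth`.
#'
#' @param tree An [ape::phylo] object.
#' @param rel_tol Relative tolerance on root-to-tip depth spread.
#' @return A list with `ultrametric` (logical) and `max_deviation` (the
#'   relative spread actually observed).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylogeny(tree)
  depths <- node_depths_to_tips(tree)
  if (length(depths) < 2L)
    return(list(ultrametric = TRUE, max_deviation = 0))
  m <- mean(depths)
  dev <- if (m > 0) max(abs(depths - m)) / m else 0
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

# Root-to-tip path length for every tip, in tip.label order.
node_depths_to_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- ape::Nnode(tree)
  depth <- numeric(n + nn)
  # edges are parent -> child; process in preorder so parents are set first
  ord <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]
    ch <- ord$edge[k, 2L]
    depth[ch] <- depth[p] + ord$edge.length[k]
  }
  stats::setNames(depth[seq_len(n)], tree$tip.label)
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree An [ape::phylo] object.
#' @return A symmetric matrix of path lengths with species as dimnames.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic variance-covariance matrix
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips i and j: the
#' covariance structure of a Brownian-motion trait on the tree. For an
#' ultrametric tree every diagonal entry equals the tree depth and
#' `V[i, j] = depth - d(i, j) / 2`.
#'
#' @param tree An [ape::phylo] object; a warning is raised for
#'   non-ultrametric input (the shared-path definition still applies).
#' @return Symmetric positive-semidefinite matrix with species dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) >= 2L && !check_ultrametric(tree)$ultrametric)
    warning("tree is not ultrametric; V computed from shared path lengths")
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Convert a phylogenetic covariance matrix to a correlation matrix
#'
#' `C[i, j] = V[i, j] / sqrt(V[i, i] * V[j, j])`; this is the matrix the PSV
#' index averages over.
#'
#' @param V Phylogenetic covariance matrix (see [phylo_vcv()]).
#' @return Correlation matrix with unit diagonal.
#' @export
vcv_to_correlation <- function(V) {
  d <- diag(V)
  if (any(d <= 0)) stop("zero or negative diagonal entry (zero-depth tip)")
  C <- V / sqrt(outer(d, d))
  diag(C) <- 1
  C
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal entries of `V` by `lambda`, leaving the
#' diagonal untouched. `lambda = 1` returns `V`; `lambda = 0` returns the
#' star-phylogeny (diagonal) structure.
#'
#' @param V Phylogenetic covariance matrix.
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

# Hard-stop label reconciliation between the tree and tabular inputs.
# `x_labels` are labels carried by traits or community data; every one must
# appear in the tree and vice versa where `both = TRUE`.
match_tip_labels <- function(tree_labels, x_labels, what = "data",
                             both = TRUE) {
  missing_in_tree <- setdiff(x_labels, tree_labels)
  if (length(missing_in_tree))
    stop(what, " species absent from tree: ",
         paste(missing_in_tree, collapse = ", "))
  if (both) {
    missing_in_x <- setdiff(tree_labels, x_labels)
    if (length(missing_in_x))
      stop("tree species absent from ", what, ": ",
           paste(missing_in_x, collapse = ", "))
  }
  invisible(TRUE)
}
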