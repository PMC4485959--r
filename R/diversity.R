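#' Standardize trait columns to zero mean and unit sample SD
#'
#' Standardization is done over the full species pool so that plot-level
#' index values are comparable across plots.
#'
#' @param traits Data frame (or matrix) of per-species trait values with
#'   species identifiers as row names, or in a `species` column.
#' @param trait_names Character vector of columns to standardize; defaults
#'   to all numeric columns.
#' @return Numeric matrix (species x traits), each column mean 0, sample
#'   SD 1.
#' @export
standardize_traits <- function(traits, trait_names = NULL) {
  M <- as_trait_matrix(traits, trait_names)
  if (nrow(M) < 2L) stop("need at least two species to standardize")
  sds <- apply(M, 2L, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero))
    stop("zero-variance trait(s): ", paste(colnames(M)[zero], collapse = ", "))
  scale(M, center = TRUE, scale = sds)[, , drop = FALSE]
}

# Coerce a trait table (data.frame with rownames or a `species` column, or a
# matrix) to a numeric matrix with species rownames, checking completeness.
as_trait_matrix <- function(traits, trait_names = NULL) {
  if (is.matrix(traits)) {
    M <- traits
  } else {
    traits <- as.data.frame(traits)
    if ("species" %in% names(traits)) {
      rn <- as.character(traits$species)
      traits <- traits[setdiff(names(traits), "species")]
      rownames(traits) <- rn
    }
    keep <- vapply(traits, is.numeric, logical(1))
    M <- as.matrix(traits[keep])
  }
  if (!is.null(trait_names)) {
    miss <- setdiff(trait_names, colnames(M))
    if (length(miss)) stop("trait(s) not found: ", paste(miss, collapse = ", "))
    M <- M[, trait_names, drop = FALSE]
  }
  if (is.null(rownames(M))) stop("trait table must identify species")
  if (anyNA(M))
    stop("missing trait values for: ",
         paste(rownames(M)[apply(is.na(M), 1L, any)], collapse = ", "))
  M
}

#' Functional dispersion (FDis) of one community
#'
#' Abundance-weighted mean distance of the species present to their
#' abundance-weighted centroid in (standardized) trait space:
#' `FDis = sum(a_i z_i) / sum(a_i)` with `z_i` the Euclidean distance of
#' species i to `c = sum(a_i x_i) / sum(a_i)`. Single-species communities
#' return 0 by convention.
#'
#' @param abundances Named numeric vector of basal areas (>= 0, at least
#'   one positive); names are species.
#' @param trait_matrix Standardized trait matrix (see
#'   [standardize_traits()]) with species rownames.
#' @return FDis value (>= 0).
#' @export
fdis <- function(abundances, trait_matrix) {
  a <- abundances[abundances > 0]
  if (length(a) == 0L || sum(a) <= 0) stop("total abundance must be positive")
  sp <- names(a)
  miss <- setdiff(sp, rownames(trait_matrix))
  if (length(miss)) stop("species missing traits: ", paste(miss, collapse = ", "))
  if (length(sp) == 1L) return(0)
  X <- trait_matrix[sp, , drop = FALSE]
  w <- a / sum(a)
  centroid <- colSums(X * w)
  z <- sqrt(rowSums(sweep(X, 2L, centroid)^2))
  sum(w * z)
}

#' Phylogenetic species variability (PSV) of one community
#'
#' For n >= 2 species, `PSV = (n * tr(C) - sum(C)) / (n * (n - 1))` over the
#' submatrix of the phylogenetic correlation matrix for the species present;
#' equivalently one minus the mean off-diagonal correlation. PSV is 1 on a
#' star phylogeny and decreases as species are more closely related.
#' Single-species communities return 0 by convention.
#'
#' @param species Character vector of species present (or a named abundance
#'   vector, thresholded at > 0).
#' @param C Phylogenetic correlation matrix (see [vcv_to_correlation()]).
#' @return PSV value in `[0, 1]` for ultrametric trees.
#' @export
psv <- function(species, C) {
  if (is.numeric(species) && !is.null(names(species)))
    species <- names(species)[species > 0]
  species <- unique(as.character(species))
  if (length(species) == 0L) stop("no species present")
  miss <- setdiff(species, rownames(C))
  if (length(miss)) stop("species absent from tree: ", paste(miss, collapse = ", "))
  n <- length(species)
  if (n == 1L) return(0)
  Cs <- C[species, species, drop = FALSE]
  (n * sum(diag(Cs)) - sum(Cs)) / (n * (n - 1))
}

#' Community-weighted mean (CWM) of a trait
#'
#' `CWM = sum(p_i t_i)` with `p_i` the relative basal area of species i.
#'
#' @param abundances Named numeric vector of basal areas.
#' @param trait Named numeric vector of trait values (raw units).
#' @return CWM in the trait's units.
#' @export
cwm <- function(abundances, trait) {
  a <- abundances[abundances > 0]
  if (length(a) == 0L || sum(a) <= 0) stop("total abundance must be positive")
  miss <- setdiff(names(a), names(trait))
  if (length(miss)) stop("species missing trait: ", paste(miss, collapse = ", "))
  tv <- trait[names(a)]
  if (anyNA(tv)) stop("missing trait values")
  sum(a / sum(a) * tv)
}

#' Per-plot diversity profile: FDis, PSV, CWM and richness
#'
#' Computes, for every plot of a community matrix, functional dispersion
#' over `fdis_traits` (traits standardized over the full species pool),
#' PSV from the chronogram, and the community-weighted mean of each trait
#' in `cwm_traits`. Monoculture plots get FDis = PSV = 0.
#'
#' @param community Plot x species matrix of basal areas (m2/ha), plot IDs
#'   as rownames.
#' @param traits Trait table (see [as_trait_matrix()] conventions).
#' @param tree Chronogram covering at least all community species.
#' @param fdis_traits Trait names entering FDis (default maxH, Wd, Sm).
#' @param cwm_traits Trait names to report as CWM (default leaf N).
#' @return Data frame with one row per plot: `plot`, `richness`, `FDis`,
#'   `PSV`, and one `CWM_<trait>` column per requested trait.
#' @export
diversity_profile <- function(community, traits, tree,
                              fdis_traits = c("maxH", "Wd", "Sm"),
                              cwm_traits = "N") {
  community <- as_community_matrix(community)
  M <- as_trait_matrix(traits)
  sp <- colnames(community)
  miss_tr <- setdiff(sp, rownames(M))
  if (length(miss_tr))
    stop("community species absent from trait table: ",
         paste(miss_tr, collapse = ", "))
  match_tip_labels(tree$tip.label, sp, what = "community", both = FALSE)
  Z <- standardize_traits(M, fdis_traits)
  C <- vcv_to_correlation(phylo_vcv(tree))
  res <- data.frame(plot = rownames(community),
                    richness = rowSums(community > 0))
  res$FDis <- apply(community, 1L, function(a) fdis(a, Z))
  res$PSV <- apply(community, 1L, function(a) psv(a, C))
  for (tn in cwm_traits) {
    tv <- stats::setNames(M[, tn], rownames(M))
    res[[paste0("CWM_", tn)]] <- apply(community, 1L, function(a) cwm(a, tv))
  }
  rownames(res) <- NULL
  res
}

# Coerce community input to a plot x species numeric matrix.
as_community_matrix <- function(community) {
  if (is.data.frame(community) &&
      all(c("plot", "species") %in% names(community))) {
    abcol <- intersect(c("basal_area", "abundance"), names(community))[1]
    if (is.na(abcol)) stop("long community table needs a basal_area column")
    community <- stats::xtabs(stats::reformulate(c("plot", "species"),
                                                 response = abcol),
                              data = community)
    community <- unclass(as.matrix(community))
    names(dimnames(community)) <- NULL
  }
  M <- as.matrix(community)
  if (!is.numeric(M)) stop("community matrix must be numeric")
  if (any(M < 0)) stop("negative basal areas")
  if (any(rowSums(M) <= 0)) {
    bad <- rownames(M)[rowSums(M) <= 0]
    stop("plot(s) with no positive abundance: ", paste(bad, collapse = ", "))
  }
  if (is.null(rownames(M))) rownames(M) <- paste0("plot", seq_len(nrow(M)))
  M
}

#' Read a community table from CSV (long or wide dialect, auto-detected)
#'
#' Long dialect has columns `plot, species, basal_area`; anything else is
#' treated as a wide plot x species matrix with plot IDs in the first
#' column.
#'
#' @param path CSV path.
#' @return Plot x species basal-area matrix.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("plot", "species") %in% names(df)))
    return(as_community_matrix(df))
  M <- as.matrix(df[-1])
  rownames(M) <- as.character(df[[1]])
  as_community_matrix(M)
}

#' Read a species trait table from CSV
#'
#' Expects a `species` column plus numeric trait columns.
#'
#' @param path CSV path.
#' @return Data frame with species rownames and trait columns.
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"species" %in% names(df)) stop("trait CSV needs a 'species' column")
  rownames(df) <- as.character(df$species)
  df$species <- NULL
  df
}
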