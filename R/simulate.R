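#' Default simulation configuration
#'
#' Bundles every parameter of the synthetic study: a 61-species Yule
#' chronogram, five continuous traits evolved under Brownian motion with
#' trait-specific signal strength lambda (spanning near-zero signal for
#' maximum height to strong signal for wood density and shade
#' tolerance), 500 inventory plots of 1-10 species with log-normal basal
#' areas, and a log-productivity response that is linear in FDis, PSV,
#' CWM of leaf N and three environmental covariates. The FDis
#' coefficient is deliberately larger than the PSV coefficient so the
#' synthetic study reproduces the asymmetry between unique functional
#' and unique phylogenetic contributions.
#'
#' @param n_species Number of tips (default 61).
#' @param birth_rate Yule birth rate (default 1; trees are rescaled to
#'   unit depth, so this only shapes node-time spacing).
#' @param traits Named list of per-trait `list(sigma2, lambda, root)`.
#' @param n_plots Number of plots (default 500).
#' @param richness_mean Mean of the truncated Poisson richness
#'   distribution on `{1..10}` (default 2.5; monocultures occur).
#' @param ba_meanlog,ba_sdlog Log-normal basal-area parameters (m2/ha).
#' @param beta Named coefficient vector for the productivity model:
#'   intercept, FDis, PSV, CWM_N, total_ba, org_depth, mat.
#' @param noise_sd Residual SD of log productivity (default 0.3).
#' @param seed Master seed (default 42).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 61, birth_rate = 1,
                       traits = list(
                         maxH  = list(sigma2 = 80,   lambda = 0.02, root = 20),
                         Wd    = list(sigma2 = 0.01, lambda = 0.79, root = 0.5),
                         Sm    = list(sigma2 = 4,    lambda = 0.23, root = 1),
                         N     = list(sigma2 = 25,   lambda = 0.65, root = 20),
                         shade = list(sigma2 = 1.5,  lambda = 0.82, root = 3)),
                       n_plots = 500, richness_mean = 2.5,
                       ba_meanlog = 1.0, ba_sdlog = 0.8,
                       beta = c(intercept = 0, FDis = 0.5, PSV = 0.2,
                                CWM_N = 0.02, total_ba = 0.02,
                                org_depth = -0.02, mat = 0.05),
                       noise_sd = 0.3, seed = 42L) {
  stopifnot(n_species >= 2, birth_rate > 0, n_plots >= 1,
            richness_mean > 0, ba_sdlog > 0, noise_sd >= 0)
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    if (tr$sigma2 <= 0 || tr$lambda < 0 || tr$lambda > 1)
      stop("invalid trait config for ", tn)
  }
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 traits = traits, n_plots = n_plots,
                 richness_mean = richness_mean, ba_meanlog = ba_meanlog,
                 ba_sdlog = ba_sdlog, beta = beta, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Yule (pure-birth) chronogram
#'
#' Pure-birth tree with exactly `n_species` tips, rescaled to unit root
#' depth and relabeled `sp001, sp002, ...`. Always ultrametric.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional seed.
#' @return An [ape::phylo] chronogram of depth 1.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(node_depths_to_tips(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Simulate a two-clade chronogram with a deep basal split
#'
#' Two Yule crowns joined by long stem branches so that the basal split
#' sits at `split_frac` of the unit depth, emulating a deep divide (such
#' as angiosperms vs gymnosperms) that leaves intermediate patristic
#' distance classes without species pairs.
#'
#' @param n_species Total number of tips.
#' @param split_frac Fraction of the depth taken by the two stems
#'   (default 0.9).
#' @param clade_frac Fraction of tips in the first clade (default 0.5).
#' @param birth_rate Speciation rate within each crown.
#' @param seed Optional seed.
#' @return An [ape::phylo] chronogram of depth 1.
#' @export
simulate_two_clade_tree <- function(n_species, split_frac = 0.9,
                                    clade_frac = 0.5, birth_rate = 1,
                                    seed = NULL) {
  stopifnot(n_species >= 4, split_frac > 0, split_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  n1 <- max(2L, round(n_species * clade_frac))
  n2 <- n_species - n1
  stopifnot(n2 >= 2)
  crown <- function(n) {
    tr <- ape::rphylo(n, birth = birth_rate, death = 0)
    tr$edge.length <- tr$edge.length / max(node_depths_to_tips(tr)) *
      (1 - split_frac)
    tr
  }
  t1 <- crown(n1); t2 <- crown(n2)
  nw <- function(tr) sub(";$", "", ape::write.tree(tr, digits = 12))
  tree <- ape::read.tree(text = sprintf("(%s:%.12f,%s:%.12f);",
                                        nw(t1), split_frac,
                                        nw(t2), split_frac))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate a trait under Brownian motion with signal strength lambda
#'
#' Draws one multivariate-normal trait vector with mean `root_state` and
#' covariance `sigma2 * lambda_transform(V, lambda)`. `lambda = 1` is
#' pure Brownian motion; `lambda = 0` yields tip values independent of
#' the phylogeny.
#'
#' @param tree Ultrametric chronogram.
#' @param sigma2 Brownian rate.
#' @param lambda Signal strength in `[0, 1]`.
#' @param root_state Trait value at the root.
#' @param seed Optional seed.
#' @param prep Optional [lambda_prep()] structure to reuse.
#' @return Named trait vector over the tips.
#' @export
simulate_bm_trait <- function(tree, sigma2, lambda = 1, root_state = 0,
                              seed = NULL, prep = NULL) {
  stopifnot(sigma2 > 0, lambda >= 0, lambda <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prep)) prep <- lambda_prep(tree)
  sdev <- sqrt(pmax(lambda * prep$d + prep$Tdepth, 0))
  z <- stats::rnorm(prep$n)
  stats::setNames(root_state + sqrt(sigma2) * (prep$Q %*% (sdev * z))[, 1L],
                  prep$labels)
}

#' Simulate plot communities with log-normal basal areas
#'
#' Each plot draws a richness from a Poisson truncated to
#' `{1, ..., max_richness}`, samples that many species without
#' replacement, and assigns each a log-normal basal area. Monocultures
#' occur whenever richness 1 has positive probability.
#'
#' @param species Character vector of available species.
#' @param n_plots Number of plots.
#' @param richness_mean Mean of the untruncated Poisson.
#' @param max_richness Upper truncation (default 10).
#' @param ba_meanlog,ba_sdlog Basal-area log-normal parameters.
#' @param seed Optional seed.
#' @return Plot x species basal-area matrix.
#' @export
simulate_communities <- function(species, n_plots, richness_mean = 2.5,
                                 max_richness = 10, ba_meanlog = 1.0,
                                 ba_sdlog = 0.8, seed = NULL) {
  stopifnot(max_richness >= 1, max_richness <= length(species))
  if (!is.null(seed)) set.seed(seed)
  support <- seq_len(max_richness)
  pr <- stats::dpois(support, richness_mean)
  pr <- pr / sum(pr)
  M <- matrix(0, n_plots, length(species),
              dimnames = list(sprintf("plot%04d", seq_len(n_plots)), species))
  rich <- sample(support, n_plots, replace = TRUE, prob = pr)
  for (i in seq_len(n_plots)) {
    sp <- sample(species, rich[i])
    M[i, sp] <- stats::rlnorm(rich[i], ba_meanlog, ba_sdlog)
  }
  M
}

#' Simulate the log-productivity response
#'
#' `y = b0 + b_FDis FDis + b_PSV PSV + b_CWM CWM_N + sum(b_cov cov) +
#' Normal(0, noise_sd^2)` over aligned plots.
#'
#' @param diversity [diversity_profile()] output (needs `FDis`, `PSV`
#'   and the CWM column named in `beta`).
#' @param covariates Data frame of plot covariates (same row order).
#' @param beta Named coefficients (see [sim_config()]).
#' @param noise_sd Residual SD.
#' @param seed Optional seed.
#' @return Numeric response vector.
#' @export
simulate_productivity <- function(diversity, covariates, beta,
                                  noise_sd = 0.3, seed = NULL) {
  stopifnot(nrow(diversity) == nrow(covariates))
  if (!is.null(seed)) set.seed(seed)
  pred <- cbind(diversity[intersect(names(beta), names(diversity))],
                covariates[intersect(names(beta), names(covariates))])
  mu <- beta[["intercept"]]
  for (nm in names(pred)) mu <- mu + beta[[nm]] * pred[[nm]]
  mu + stats::rnorm(nrow(diversity), 0, noise_sd)
}

#' Generate a complete on-disk fixture bundle
#'
#' Writes, under `dir`: `tree.nwk` (chronogram), `traits.csv` (species x
#' traits), `community.csv` (plot x species basal areas, wide),
#' `plots.csv` (plot covariates + log-productivity response) and
#' `manifest.json` (all true parameters and seeds). Regenerating from
#' the same config reproduces identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`tree`,
#'   `traits`, `community`, `plots`, `diversity`) and the file paths.
#' @export
make_fixture_bundle <- function(config = sim_config(), dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  seed <- config$seed
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             seed = derive_seed(seed, 1L))
  prep <- lambda_prep(tree)
  traits <- as.data.frame(lapply(seq_along(config$traits), function(j) {
    tr <- config$traits[[j]]
    simulate_bm_trait(tree, tr$sigma2, tr$lambda, tr$root,
                      seed = derive_seed(seed, 10L + j), prep = prep)
  }))
  names(traits) <- names(config$traits)
  rownames(traits) <- tree$tip.label
  community <- simulate_communities(tree$tip.label, config$n_plots,
                                    config$richness_mean,
                                    ba_meanlog = config$ba_meanlog,
                                    ba_sdlog = config$ba_sdlog,
                                    seed = derive_seed(seed, 20L))
  div <- diversity_profile(community, traits, tree)
  set.seed(derive_seed(seed, 30L))
  covariates <- data.frame(total_ba = rowSums(community),
                           org_depth = stats::rlnorm(config$n_plots,
                                                     log(10), 0.5),
                           mat = stats::rnorm(config$n_plots, 2, 2))
  y <- simulate_productivity(div, covariates, config$beta, config$noise_sd,
                             seed = derive_seed(seed, 40L))
  plots <- cbind(div, covariates, log_growth = y)

  paths <- list(tree = file.path(dir, "tree.nwk"),
                traits = file.path(dir, "traits.csv"),
                community = file.path(dir, "community.csv"),
                plots = file.path(dir, "plots.csv"),
                manifest = file.path(dir, "manifest.json"))
  write_newick(tree, paths$tree)
  utils::write.csv(cbind(species = rownames(traits), traits),
                   paths$traits, row.names = FALSE)
  utils::write.csv(cbind(plot = rownames(community),
                         as.data.frame(community)),
                   paths$community, row.names = FALSE)
  utils::write.csv(plots, paths$plots, row.names = FALSE)
  manifest <- list(package = "phylofd",
                   config = unclass(config),
                   derived_seeds = list(tree = derive_seed(seed, 1L),
                                        community = derive_seed(seed, 20L),
                                        covariates = derive_seed(seed, 30L),
                                        response = derive_seed(seed, 40L)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(tree = tree, traits = traits, community = community,
                 diversity = div, plots = plots, paths = paths))
}
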