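#' Brownian-motion log-likelihood of a trait on a tree
#'
#' Multivariate-normal log-density of the tip values `x` with mean
#' `z0 * 1` and covariance `sigma2 * V`. This is the likelihood that
#' Pagel's lambda profiles over after transforming `V`.
#'
#' @param x Named trait vector (names = species).
#' @param V Phylogenetic covariance matrix with matching labels.
#' @param sigma2 Brownian rate (trait units squared per unit time), > 0.
#' @param z0 Root state (trait units).
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(x, V, sigma2, z0) {
  stopifnot(sigma2 > 0)
  x <- align_trait(x, rownames(V))
  n <- length(x)
  ch <- tryCatch(chol(sigma2 * V),
                 error = function(e) stop("singular covariance matrix; ",
                                          "consider adding a small jitter"))
  r <- x - z0
  q <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2))
}

# Align a trait vector to a label order; unnamed vectors of the right
# length are taken to be in label order already.
align_trait <- function(x, labels) {
  if (is.null(names(x))) {
    if (length(x) != length(labels))
      stop("trait vector length does not match number of species")
    return(stats::setNames(as.numeric(x), labels))
  }
  match_tip_labels(labels, names(x), what = "trait")
  stats::setNames(as.numeric(x[labels]), labels)
}

# One-off spectral preparation for lambda fitting on an ultrametric tree.
# V(lambda) = lambda * (V - T I) + T I shares the eigenvectors of
# A = V - T I for every lambda, so each profile-likelihood evaluation is
# O(n) after this O(n^3) step.
lambda_prep <- function(tree, rel_tol = 1e-6) {
  validate_phylogeny(tree)
  chk <- check_ultrametric(tree, rel_tol)
  if (!chk$ultrametric)
    stop("lambda estimation requires an ultrametric tree (relative depth ",
         "spread ", format(chk$max_deviation), ")")
  V <- ape::vcv.phylo(tree)
  Tdepth <- mean(diag(V))
  A <- V
  diag(A) <- diag(A) - Tdepth
  eig <- eigen(A, symmetric = TRUE)
  n <- nrow(V)
  list(labels = rownames(V), n = n, Tdepth = Tdepth,
       Q = eig$vectors, d = eig$values,
       u = crossprod(eig$vectors, rep(1, n))[, 1L])
}

# Profile log-likelihood in lambda: z0 and sigma2 replaced by their
# conditional ML values. `xt` is Q' x.
profile_loglik <- function(lambda, prep, xt) {
  ev <- lambda * prep$d + prep$Tdepth
  if (any(ev <= 0)) return(-Inf)
  w <- 1 / ev
  u <- prep$u
  z0 <- sum(w * u * xt) / sum(w * u^2)
  r <- xt - z0 * u
  s2 <- sum(w * r^2) / prep$n
  if (s2 <= 0) return(-Inf)
  -0.5 * (prep$n * (log(2 * pi) + log(s2) + 1) + sum(log(ev)))
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' Profiles the Brownian-motion likelihood over lambda in `[eps, 1]`
#' (conditional ML root state and rate at each lambda), using a coarse
#' grid of starts followed by bounded 1-D optimization, because the
#' profile can be multimodal on small trees. A likelihood-ratio test
#' against lambda = 0 is attached as a convenience.
#'
#' @param x Named trait vector over the tips.
#' @param tree Ultrametric chronogram ([ape::phylo]).
#' @param eps Lower optimization bound for lambda (default 1e-7).
#' @param prep Optional precomputed [lambda_prep()] structure (reused by
#'   the bootstrap).
#' @return Object of class `lambda_fit`: `lambda_hat`, `sigma2_hat`,
#'   `z0_hat`, `loglik`, `lr_stat`/`p_lr` (test vs lambda = 0),
#'   `ci_low`/`ci_high`/`n_boot` (filled by
#'   [parametric_bootstrap_ci()]), `n` (tips).
#' @export
fit_lambda <- function(x, tree, eps = 1e-7, prep = NULL) {
  if (is.null(prep)) prep <- lambda_prep(tree)
  if (prep$n < 4L) stop("need at least 4 tips to estimate lambda")
  x <- align_trait(x, prep$labels)
  if (stats::sd(x) == 0) stop("trait is constant; lambda is undefined")
  xt <- crossprod(prep$Q, x)[, 1L]
  f <- function(l) profile_loglik(l, prep, xt)

  grid <- c(eps, 0.25, 0.5, 0.75, 1)
  gv <- vapply(grid, f, numeric(1))
  best <- list(lambda = grid[which.max(gv)], ll = max(gv))
  # local bounded searches bracketed around each grid start
  brackets <- cbind(pmax(eps, grid - 0.25), pmin(1, grid + 0.25))
  for (k in seq_along(grid)) {
    o <- stats::optimize(f, lower = brackets[k, 1], upper = brackets[k, 2],
                         maximum = TRUE, tol = 1e-8)
    if (o$objective > best$ll)
      best <- list(lambda = o$maximum, ll = o$objective)
  }
  lam <- min(max(best$lambda, eps), 1)

  ev <- lam * prep$d + prep$Tdepth
  w <- 1 / ev
  z0 <- sum(w * prep$u * xt) / sum(w * prep$u^2)
  s2 <- sum(w * (xt - z0 * prep$u)^2) / prep$n
  ll0 <- f(0)
  lr <- max(0, 2 * (best$ll - ll0))
  structure(list(lambda_hat = lam, sigma2_hat = s2, z0_hat = z0,
                 loglik = best$ll, lr_stat = lr,
                 p_lr = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L,
                 eps = eps, n = prep$n),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda fit (", x$n, " tips)\n", sep = "")
  cat(sprintf("  lambda = %.4f  sigma2 = %.4g  z0 = %.4g  logLik = %.3f\n",
              x$lambda_hat, x$sigma2_hat, x$z0_hat, x$loglik))
  if (x$n_boot > 0L)
    cat(sprintf("  95%% bootstrap CI: (%.4g, %.4g)  [%d simulations]\n",
                x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Parametric-bootstrap confidence interval for Pagel's lambda
#'
#' Simulates `n_sim` trait vectors from the fitted
#' `(lambda_hat, sigma2_hat, z0_hat)` model on the same tree, refits
#' lambda to each, and returns percentile bounds of the refitted
#' distribution. A replicate whose refit fails is retried once on a finer
#' grid and then dropped (with a message giving the count).
#'
#' @param fit A [fit_lambda()] result.
#' @param tree The chronogram the fit used.
#' @param n_sim Number of bootstrap simulations (default 1000).
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @param seed Integer seed; required for reproducibility.
#' @return The `lambda_fit` with `ci_low`, `ci_high`, `n_boot` filled and
#'   the refitted values in `lambda_boot`.
#' @export
parametric_bootstrap_ci <- function(fit, tree, n_sim = 1000, alpha = 0.05,
                                    seed = NULL) {
  stopifnot(inherits(fit, "lambda_fit"), n_sim >= 2)
  if (!is.null(seed)) set.seed(seed)
  prep <- lambda_prep(tree)
  sdev <- sqrt(pmax(fit$lambda_hat * prep$d + prep$Tdepth, 0))
  lam_star <- rep(NA_real_, n_sim)
  failed <- 0L
  for (b in seq_len(n_sim)) {
    z <- stats::rnorm(prep$n)
    xs <- fit$z0_hat + sqrt(fit$sigma2_hat) * (prep$Q %*% (sdev * z))[, 1L]
    names(xs) <- prep$labels
    fb <- tryCatch(fit_lambda(xs, tree, eps = fit$eps, prep = prep),
                   error = function(e) NULL)
    if (is.null(fb))  # retry once with a perturbed replicate
      fb <- tryCatch(fit_lambda(xs + stats::rnorm(prep$n, 0, 1e-8 * max(abs(xs), 1)),
                                tree, eps = fit$eps, prep = prep),
                     error = function(e) NULL)
    if (is.null(fb)) failed <- failed + 1L else lam_star[b] <- fb$lambda_hat
  }
  if (failed > 0L)
    message(failed, " bootstrap replicate(s) failed to refit and were dropped")
  lam_star <- lam_star[!is.na(lam_star)]
  ci <- stats::quantile(lam_star, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  fit$ci_low <- ci[1]
  fit$ci_high <- ci[2]
  fit$n_boot <- length(lam_star)
  fit$lambda_boot <- lam_star
  if (fit$lambda_hat < fit$ci_low || fit$lambda_hat > fit$ci_high)
    warning("point estimate outside percentile CI (Monte-Carlo noise)")
  fit
}

#' Per-trait phylogenetic-signal report
#'
#' Fits Pagel's lambda with a parametric-bootstrap CI for every trait
#' column, using seeds derived from one master seed so each trait is
#' independently reproducible.
#'
#' @param traits Trait table (species rownames or `species` column).
#' @param tree Ultrametric chronogram.
#' @param n_boot Bootstrap simulations per trait (default 1000).
#' @param seed Master seed.
#' @return Data frame: `trait, lambda_hat, ci_low, ci_high, sigma2_hat,
#'   z0_hat, loglik, n_boot`.
#' @export
signal_report <- function(traits, tree, n_boot = 1000, seed = 1L) {
  M <- as_trait_matrix(traits)
  out <- vector("list", ncol(M))
  for (j in seq_len(ncol(M))) {
    x <- stats::setNames(M[, j], rownames(M))
    ft <- fit_lambda(x, tree)
    ft <- parametric_bootstrap_ci(ft, tree, n_sim = n_boot,
                                  seed = derive_seed(seed, j))
    out[[j]] <- data.frame(trait = colnames(M)[j], lambda_hat = ft$lambda_hat,
                           ci_low = ft$ci_low, ci_high = ft$ci_high,
                           sigma2_hat = ft$sigma2_hat, z0_hat = ft$z0_hat,
                           loglik = ft$loglik, n_boot = ft$n_boot)
  }
  do.call(rbind, out)
}

#' Moran's I autocorrelation of a trait under a binary weight matrix
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with `S0 = sum(w)`. The expectation under no autocorrelation
#' is `-1 / (n - 1)`. Significance is a two-sided permutation test on
#' `|I - E[I]|` with trait values shuffled across tips (default), or the
#' classical randomization-variance normal approximation (Cliff-Ord
#' moments with kurtosis correction).
#'
#' @param x Named (or tip-ordered) trait vector.
#' @param W Symmetric zero-diagonal weight matrix (binary in the
#'   correlogram use).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation draw.
#' @param method `"permutation"` (default) or `"normal"`.
#' @return List: `I`, `expected`, `p_value`, `n_pairs` (count of positive
#'   weights above the diagonal).
#' @export
moran_i <- function(x, W, n_perm = 999, seed = NULL,
                    method = c("permutation", "normal")) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(W, t(W)))) stop("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  S0 <- sum(W)
  if (S0 <= 0) stop("all-zero weight matrix")
  if (!is.null(rownames(W))) x <- align_trait(x, rownames(W))
  x <- as.numeric(x)
  n <- length(x)
  if (n != nrow(W)) stop("trait and weight dimensions differ")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("trait is constant; Moran's I is undefined")
  I_obs <- (n / S0) * sum(xc * (W %*% xc)) / denom
  expected <- -1 / (n - 1)
  if (method == "normal") {
    S1 <- 0.5 * sum((W + t(W))^2)
    S2 <- sum((rowSums(W) + colSums(W))^2)
    kurt <- (sum(xc^4) / n) / (sum(xc^2) / n)^2
    v <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
            kurt * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - expected^2
    p <- 2 * stats::pnorm(-abs(I_obs - expected) / sqrt(v))
  } else {
    if (n_perm < 1) stop("n_perm must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    P <- replicate(n_perm, xc[sample.int(n)])
    I_perm <- (n / S0) * colSums(P * (W %*% P)) / denom
    p <- (1 + sum(abs(I_perm - expected) >= abs(I_obs - expected) - 1e-12)) /
      (1 + n_perm)
  }
  list(I = I_obs, expected = expected, p_value = p,
       n_pairs = sum(W[upper.tri(W)] > 0))
}

#' Partition patristic distances into classes with per-class weights
#'
#' Builds `n_classes` distance classes over `[0, max(D)]`, either of
#' equal width (default) or of (approximately) equal pair frequency, and
#' the binary weight matrix of each class (`w_ij = 1` iff `D[i, j]` falls
#' in the class). Classes are half-open `[lo, hi)` with the last closed,
#' so each unordered tip pair lands in exactly one class. Classes with no
#' pairs are flagged empty (with large between-clade gulfs this is
#' expected under the equal-width scheme).
#'
#' @param D Patristic distance matrix (see [patristic_distances()]).
#' @param n_classes Number of classes (default 8).
#' @param scheme `"equal_width"` or `"equal_frequency"`.
#' @return List of class `distance_classes`: `bounds` (length
#'   `n_classes + 1`), `scheme`, `weights` (list of matrices), `n_pairs`,
#'   `empty` (logical vector).
#' @export
build_distance_classes <- function(D, n_classes = 8,
                                   scheme = c("equal_width",
                                              "equal_frequency")) {
  scheme <- match.arg(scheme)
  stopifnot(n_classes >= 2)
  dvals <- D[upper.tri(D)]
  dmax <- max(dvals)
  if (dmax <= 0) stop("degenerate distance matrix (all distances zero)")
  if (n_classes > length(unique(dvals)))
    warning("more classes than distinct distances; empty classes expected")
  if (scheme == "equal_width") {
    bounds <- seq(0, dmax, length.out = n_classes + 1)
  } else {
    qs <- stats::quantile(dvals, probs = seq(0, 1, length.out = n_classes + 1),
                          names = FALSE)
    qs[1] <- 0
    qs[n_classes + 1] <- dmax
    if (anyDuplicated(qs)) {
      warning("tied quantiles collapsed; fewer than n_classes distinct classes")
      qs <- unique(qs)
    }
    bounds <- qs
  }
  k <- length(bounds) - 1L
  idx <- matrix(findInterval(D, bounds, rightmost.closed = TRUE), nrow(D),
                dimnames = dimnames(D))
  weights <- lapply(seq_len(k), function(cl) {
    W <- (idx == cl) * 1
    diag(W) <- 0
    W
  })
  n_pairs <- vapply(weights, function(W) sum(W[upper.tri(W)] > 0), integer(1))
  structure(list(bounds = bounds, scheme = scheme, weights = weights,
                 n_pairs = n_pairs, empty = n_pairs == 0L),
            class = "distance_classes")
}

#' Phylogenetic correlogram: Moran's I across patristic distance classes
#'
#' Computes Moran's I, its null expectation and a permutation p-value for
#' every non-empty distance class. Empty classes (no species pair
#' diverged within that range) are reported with `NA` statistics and
#' `empty = TRUE`.
#'
#' @param x Named trait vector over the tips.
#' @param tree Chronogram.
#' @param classes Optional [build_distance_classes()] result; built from
#'   the tree when omitted.
#' @param n_classes,scheme Passed to [build_distance_classes()] when
#'   `classes` is missing.
#' @param n_perm Permutations per class (default 999).
#' @param seed Master seed; per-class seeds are derived from it.
#' @return Data frame: `class_lo, class_hi, n_pairs, I, expected, p,
#'   empty`.
#' @export
phylo_correlogram <- function(x, tree, classes = NULL, n_classes = 8,
                              scheme = "equal_width", n_perm = 999,
                              seed = NULL) {
  D <- patristic_distances(tree)
  if (is.null(classes))
    classes <- build_distance_classes(D, n_classes, scheme)
  x <- align_trait(x, rownames(D))
  k <- length(classes$weights)
  out <- data.frame(class_lo = classes$bounds[-(k + 1L)],
                    class_hi = classes$bounds[-1L],
                    n_pairs = classes$n_pairs,
                    I = NA_real_, expected = NA_real_, p = NA_real_,
                    empty = classes$empty)
  for (cl in seq_len(k)) {
    if (classes$empty[cl]) next
    m <- moran_i(x, classes$weights[[cl]], n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, cl))
    out$I[cl] <- m$I
    out$expected[cl] <- m$expected
    out$p[cl] <- m$p_value
  }
  out
}

# Derived sub-stream seeds from one master seed, kept within 32-bit range.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 7919 + 104729 * as.double(stream)) %%
               2147483647)
}
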