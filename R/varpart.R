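#' Ordinary least squares with an explicit rank check
#'
#' Fits `y ~ 1 + X` by QR and reports R-squared. Rank deficiency is a hard
#' error naming the collinear columns, because a silent drop would corrupt
#' the adjusted-R-squared bookkeeping of the variance partition.
#'
#' @param y Response vector.
#' @param X Predictor matrix (or data frame; no intercept column).
#' @return List: `coefficients`, `fitted`, `residuals`, `r2`, `n`, `p`
#'   (predictor count, intercept excluded).
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(Xi %*% beta)
  res <- y - fitted
  sstot <- sum((y - mean(y))^2)
  list(coefficients = beta, fitted = fitted, residuals = res,
       r2 = 1 - sum(res^2) / sstot, n = n, p = ncol(X), qr = qr_x)
}

#' Ezekiel-adjusted R-squared
#'
#' `R2adj = 1 - (1 - R2) * (n - 1) / (n - p - 1)`; may be negative.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of predictors (intercept excluded).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("n must exceed p + 1 for the adjustment")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variance-partition fractions from three adjusted R-squared values
#'
#' Two-block partition identities: the unique fraction of block 1 is
#' `R2adj(both) - R2adj(X2)`, the shared fraction is
#' `R2adj(X1) + R2adj(X2) - R2adj(both)`, the unique fraction of block 2
#' is `R2adj(both) - R2adj(X1)`, and the residual is `1 - R2adj(both)`.
#'
#' @param r2adj_x1,r2adj_x2,r2adj_both Adjusted R-squared of each block
#'   alone and of their union.
#' @return Named list `frac_a` (unique X1), `frac_b` (shared), `frac_c`
#'   (unique X2), `frac_d` (residual).
#' @export
varpart_fractions <- function(r2adj_x1, r2adj_x2, r2adj_both) {
  list(frac_a = r2adj_both - r2adj_x2,
       frac_b = r2adj_x1 + r2adj_x2 - r2adj_both,
       frac_c = r2adj_both - r2adj_x1,
       frac_d = 1 - r2adj_both)
}

#' Two-block adjusted-R-squared variance partition with permutation tests
#'
#' Partitions the variance of `y` explained by predictor blocks `X1` and
#' `X2` into unique and shared adjusted-R-squared fractions, and tests
#' the two unique (testable) fractions by Freedman-Lane residual
#' permutation. The shared fraction cannot be tested. Negative fractions
#' are reported as-is.
#'
#' @param y Response vector (here, log annual aboveground biomass
#'   increment).
#' @param X1,X2 Predictor blocks (vectors or matrices), e.g. FDis and
#'   PSV.
#' @param n_perm Residual permutations (default 999, giving a minimum
#'   attainable p of 0.001).
#' @param seed Seed for the permutation draws.
#' @return Object of class `varpart_result`: the three adjusted
#'   R-squareds, fractions `frac_a/b/c/d`, `p_a`, `p_c`, `n`, `n_perm`.
#' @export
varpart_two <- function(y, X1, X2, n_perm = 999, seed = NULL) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- length(y)
  # rank-tolerant R^2: the union of overlapping blocks may be collinear,
  # in which case the projection and its rank (not the column count)
  # define the adjusted R^2
  r2_rank <- function(X) {
    qr_x <- qr(cbind(1, X))
    res <- qr.resid(qr_x, y)
    list(r2 = 1 - sum(res^2) / sum((y - mean(y))^2), p = qr_x$rank - 1L)
  }
  f1 <- r2_rank(X1)
  f2 <- r2_rank(X2)
  f12 <- r2_rank(cbind(X1, X2))
  r1 <- adjusted_r2(f1$r2, n, f1$p)
  r2 <- adjusted_r2(f2$r2, n, f2$p)
  rb <- adjusted_r2(f12$r2, n, f12$p)
  fr <- varpart_fractions(r1, r2, rb)
  p_a <- if (n_perm > 0) freedman_lane_test(y, X1, X2, n_perm = n_perm,
                                            seed = seed)$p_value else NA_real_
  p_c <- if (n_perm > 0) freedman_lane_test(y, X2, X1, n_perm = n_perm,
                                            seed = if (is.null(seed)) NULL
                                                   else derive_seed(seed, 2L)
                                            )$p_value else NA_real_
  structure(c(list(r2adj_X1 = r1, r2adj_X2 = r2, r2adj_both = rb), fr,
              list(p_a = p_a, p_c = p_c, n = n, n_perm = n_perm)),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Two-block variance partition (adjusted R-squared), n =", x$n, "\n")
  cat(sprintf("  R2adj X1 = %.4f  X2 = %.4f  both = %.4f\n",
              x$r2adj_X1, x$r2adj_X2, x$r2adj_both))
  cat(sprintf("  unique X1 [a] = %.4f (p = %s)\n", x$frac_a,
              format(x$p_a)))
  cat(sprintf("  shared   [b] = %.4f (not testable)\n", x$frac_b))
  cat(sprintf("  unique X2 [c] = %.4f (p = %s)\n", x$frac_c,
              format(x$p_c)))
  cat(sprintf("  residual [d] = %.4f\n", x$frac_d))
  invisible(x)
}

#' Freedman-Lane permutation test of a predictor block
#'
#' Tests the partial effect of `X_test` given `X_cond` by the partial F
#' statistic, comparing the observed value against the distribution
#' obtained by permuting the residuals of the reduced model
#' `y ~ X_cond`, adding them back to the reduced fitted values and
#' refitting. The p-value counts the observed statistic:
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`, so 0.001 is the floor at 999
#' permutations.
#'
#' @param y Response vector.
#' @param X_test Block whose partial effect is tested.
#' @param X_cond Conditioning block (disjoint from `X_test`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation draws.
#' @return List: `statistic` (partial F), `p_value`, `n_perm`.
#' @export
freedman_lane_test <- function(y, X_test, X_cond, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  X_test <- as.matrix(X_test); X_cond <- as.matrix(X_cond)
  n <- length(y)
  fit_red <- ols_fit(y, X_cond)
  fit_full <- ols_fit(y, cbind(X_cond, X_test))
  q <- fit_full$p - fit_red$p
  df2 <- n - fit_full$p - 1L
  partial_f <- function(rss_red, rss_full)
    ((rss_red - rss_full) / q) / (rss_full / df2)
  F_obs <- partial_f(sum(fit_red$residuals^2), sum(fit_full$residuals^2))

  if (!is.null(seed)) set.seed(seed)
  qr_red <- fit_red$qr
  qr_full <- fit_full$qr
  exceed <- 0L
  chunk <- max(1L, min(n_perm, floor(2e6 / n)))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    Ystar <- fit_red$fitted +
      matrix(fit_red$residuals[vapply(seq_len(m),
                                      function(i) sample.int(n),
                                      integer(n))], n, m)
    rss_red <- colSums(qr.resid(qr_red, Ystar)^2)
    rss_full <- colSums(qr.resid(qr_full, Ystar)^2)
    exceed <- exceed + sum(partial_f(rss_red, rss_full) >= F_obs)
    done <- done + m
  }
  list(statistic = F_obs, p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm)
}

#' Full productivity regression with per-term permutation tests
#'
#' Multiple regression of log productivity on environmental covariates,
#' community-weighted mean traits and the diversity indices (the
#' "everything in" model), with each term's partial effect tested by
#' Freedman-Lane permutation conditioned on all the others.
#'
#' @param data Plot-level data frame.
#' @param response Name of the response column (log annual aboveground
#'   biomass increment).
#' @param terms Character vector of predictor column names.
#' @param n_perm Permutations per term test (default 999).
#' @param seed Master seed; per-term seeds are derived from it.
#' @return List: `coefficients` (data frame with estimate, SE, t,
#'   permutation p), `r2`, `r2adj`, `n`.
#' @export
fit_productivity_model <- function(data, response = "log_growth",
                                   terms = c("total_ba", "org_depth", "mat",
                                             "CWM_N", "FDis", "PSV"),
                                   n_perm = 999, seed = NULL) {
  miss <- setdiff(c(response, terms), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[c(response, terms)])
  if (!all(cc)) stop("missing values in model columns")
  y <- data[[response]]
  X <- as.matrix(data[terms])
  fit <- ols_fit(y, X)
  # classical SEs from the full fit
  sigma2 <- sum(fit$residuals^2) / (fit$n - fit$p - 1)
  XtXinv <- solve(crossprod(cbind(1, X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  coefs <- data.frame(term = names(fit$coefficients),
                      estimate = unname(fit$coefficients),
                      std_error = se,
                      t_value = unname(fit$coefficients) / se,
                      p_perm = NA_real_)
  for (j in seq_along(terms)) {
    if (n_perm < 1) break
    pv <- freedman_lane_test(y, X[, terms[j], drop = FALSE],
                             X[, setdiff(terms, terms[j]), drop = FALSE],
                             n_perm = n_perm,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, j))$p_value
    coefs$p_perm[coefs$term == terms[j]] <- pv
  }
  list(coefficients = coefs, r2 = fit$r2,
       r2adj = adjusted_r2(fit$r2, fit$n, fit$p), n = fit$n)
}
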