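# Comparative inference: PGLS regression, simulation-based phylogenetic
# ANOVA, Levene-type variance comparison, Gaussian model selection over
# predictor sets, and repeatability (ICC) with bootstrap CIs.

#' Phylogenetic generalized least squares
#'
#' GLS regression of `y` on the columns of `X` with error covariance
#' proportional to `C`: `beta = (X' C^-1 X)^-1 X' C^-1 y`. Standard errors
#' use `sigma2 = e' C^-1 e / (n - p)`; t tests have `n - p` df. R-squared is
#' `1 - e' C^-1 e / e0' C^-1 e0` against the intercept-only GLS fit. With
#' `C = I` this reduces exactly to ordinary least squares.
#'
#' @param y Named numeric response (names = species).
#' @param X data.frame of predictors (rownames or a `species` column give
#'   the labels), or a numeric matrix aligned to `y`. An intercept is added.
#' @param C Phylogenetic covariance matrix with dimnames; reordered to match.
#' @return Object of class `pgls_fit`: `coefficients` (estimate, SE, t, p),
#'   `r_squared`, `residuals`, `sigma2`, `df_residual`, `n`.
#' @export
pgls <- function(y, X, C) {
  if (is.null(names(y))) stop("y must be named by species")
  labs <- names(y)
  if (is.data.frame(X)) {
    if ("species" %in% colnames(X)) {
      rownames(X) <- trimws(X$species)
      X <- X[, setdiff(colnames(X), "species"), drop = FALSE]
    }
    if (!all(labs %in% rownames(X)))
      stop("X rows do not cover all species in y")
    X <- X[labs, , drop = FALSE]
    M <- stats::model.matrix(~ ., data = X)
  } else {
    M <- cbind(`(Intercept)` = 1, as.matrix(X))
  }
  if (!all(labs %in% rownames(C))) stop("C does not cover all species in y")
  C <- C[labs, labs, drop = FALSE]
  n <- length(y); p <- ncol(M)
  if (n <= p) stop("need n > number of coefficients")
  L <- chol_safe(C)
  wy <- backsolve(L, y, transpose = TRUE)      # C^{-1/2} y
  wM <- backsolve(L, M, transpose = TRUE)
  qrW <- qr(wM)
  if (qrW$rank < p) {
    bad <- colnames(M)[qrW$pivot[(qrW$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrW, wy)
  e <- y - drop(M %*% beta)
  we <- wy - drop(wM %*% beta)
  rss <- sum(we^2)
  sigma2 <- rss / (n - p)
  XtCiX_inv <- chol2inv(qr.R(qrW))[order(qrW$pivot), order(qrW$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtCiX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  # intercept-only GLS for R^2
  w1 <- backsolve(L, rep(1, n), transpose = TRUE)
  mu0 <- sum(w1 * wy) / sum(w1^2)
  rss0 <- sum((wy - mu0 * w1)^2)
  r2 <- if (rss0 > 0) 1 - rss / rss0 else 0
  names(e) <- labs
  structure(list(
    coefficients = data.frame(estimate = beta, se = se, t = tval, p = pval,
                              row.names = colnames(M)),
    r_squared = max(0, min(1, r2)), residuals = e, sigma2 = sigma2,
    df_residual = n - p, n = n), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (n =", x$n, ")\n")
  print(round(x$coefficients, 5))
  cat(sprintf("R-squared: %.4f  residual df: %d\n", x$r_squared, x$df_residual))
  invisible(x)
}

# One-way F statistics for each column of Y given grouping g (vectorized).
f_stat_cols <- function(Y, g) {
  g <- as.factor(g)
  n <- nrow(Y); k <- nlevels(g)
  ng <- as.vector(table(g))
  Gm <- rowsum(Y, g) / ng                    # k x m group means
  grand <- colMeans(Y)
  ssb <- colSums(ng * (sweep(Gm, 2, grand))^2)
  sst <- colSums(sweep(Y, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  ifelse(msw > 0, msb / msw, Inf)
}

# Simulate nsim BM trait vectors on covariance C (rate sigma2, mean z0).
simulate_bm_null <- function(C, sigma2, z0, nsim) {
  L <- chol_safe(sigma2 * C)
  Z <- matrix(stats::rnorm(nrow(C) * nsim), nrow(C), nsim)
  z0 + crossprod(L, Z)
}

#' Simulation-based phylogenetic ANOVA
#'
#' Ordinary one-way ANOVA F for trait `x` across `groups`, with the null
#' distribution generated by simulating Brownian-motion trait evolution on
#' the tree (rate = ML BM rate of the observed data) and recomputing F with
#' group labels fixed. The simulation p-value is
#' `(1 + #\{F_null >= F_obs\}) / (nsim + 1)`.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector.
#' @param groups Named character/factor of group labels per tip.
#' @param nsim Number of null simulations.
#' @param seed Optional RNG seed.
#' @return Object of class `phylo_anova`: `f`, `df1`, `df2`, `p_parametric`,
#'   `p_simulation`, `nsim`, `degenerate`.
#' @export
phylo_anova <- function(tree, x, groups, nsim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  md <- match_tree_data(tree, x)
  tree <- md$tree; x <- md$x
  g <- as.factor(groups[names(x)])
  if (anyNA(g)) stop("groups missing for some tips")
  tb <- table(g)
  if (nlevels(g) < 2 || any(tb < 2))
    stop("need >= 2 groups each with >= 2 members")
  C <- tree_vcv(tree)
  pf <- profile_mvn(x, C)
  fobs <- f_stat_cols(matrix(x, ncol = 1), g)
  df1 <- nlevels(g) - 1; df2 <- length(x) - nlevels(g)
  degenerate <- !is.finite(fobs)
  if (degenerate)
    warning("zero within-group variance: F degenerate, simulation p floored")
  Ynull <- simulate_bm_null(C, pf$sigma2, pf$z0, nsim)
  fnull <- f_stat_cols(Ynull, g)
  psim <- if (degenerate) 1 / (nsim + 1) else (1 + sum(fnull >= fobs)) / (nsim + 1)
  structure(list(f = fobs, df1 = df1, df2 = df2,
                 p_parametric = stats::pf(fobs, df1, df2, lower.tail = FALSE),
                 p_simulation = psim, nsim = nsim, degenerate = degenerate),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F_%d,%d = %.3f, parametric p = %.4g, simulation p = %.4g (%d sims)\n",
              x$df1, x$df2, x$f, x$p_parametric, x$p_simulation, x$nsim))
  invisible(x)
}

#' Levene-type test for group differences in trait variance on a phylogeny
#'
#' Brown-Forsythe/Levene F on absolute deviations from group medians, with a
#' simulation p-value under the same BM null scheme as [phylo_anova()]
#' (the deviation statistic is recomputed on each simulated trait vector).
#'
#' @inheritParams phylo_anova
#' @export
group_variance_test <- function(tree, x, groups, nsim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  md <- match_tree_data(tree, x)
  tree <- md$tree; x <- md$x
  g <- as.factor(groups[names(x)])
  if (anyNA(g)) stop("groups missing for some tips")
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups each with >= 2 members")
  levene_f <- function(v) {
    med <- stats::ave(v, g, FUN = stats::median)
    f_stat_cols(matrix(abs(v - med), ncol = 1), g)
  }
  fobs <- levene_f(x)
  df1 <- nlevels(g) - 1; df2 <- length(x) - nlevels(g)
  C <- tree_vcv(tree)
  pf <- profile_mvn(x, C)
  Ynull <- simulate_bm_null(C, pf$sigma2, pf$z0, nsim)
  fnull <- apply(Ynull, 2, levene_f)
  degenerate <- !is.finite(fobs)
  psim <- if (degenerate) 1 / (nsim + 1) else (1 + sum(fnull >= fobs)) / (nsim + 1)
  structure(list(f = fobs, df1 = df1, df2 = df2,
                 p_parametric = stats::pf(fobs, df1, df2, lower.tail = FALSE),
                 p_simulation = psim, nsim = nsim, degenerate = degenerate),
            class = "phylo_anova")
}

#' Gaussian model selection over candidate predictor sets
#'
#' Fits a Gaussian linear model for each candidate predictor set (character
#' vector of column names; `character(0)` is the intercept-only model),
#' ranks by AICc, and attaches Akaike weights. Categorical predictors use
#' treatment contrasts with the alphabetically first level as reference.
#'
#' @param data data.frame holding response and predictors.
#' @param response Response column name.
#' @param candidate_sets List of character vectors of predictor names.
#' @return Object of class `model_selection`: `table` (predictors, k,
#'   loglik, AICc, dAICc, weight, sorted by AICc) and `fits`.
#' @export
glm_model_selection <- function(data, response, candidate_sets) {
  stopifnot(response %in% colnames(data))
  miss <- setdiff(unique(unlist(candidate_sets)), colnames(data))
  if (length(miss)) stop("predictor column(s) not in data: ",
                         paste(miss, collapse = ", "))
  n <- nrow(data)
  fits <- lapply(candidate_sets, function(ps) {
    rhs <- if (length(ps)) paste(ps, collapse = " + ") else "1"
    stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
  })
  lab <- vapply(candidate_sets, function(ps)
    if (length(ps)) paste(ps, collapse = " + ") else "(intercept)", character(1))
  names(fits) <- lab
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  k <- vapply(fits, function(f) length(stats::coef(f)) + 1, numeric(1)) # + sigma
  tab <- data.frame(predictors = lab, k = k, loglik = ll,
                    AICc = mapply(aicc, ll, k, MoreArgs = list(n = n)),
                    deviance = vapply(fits, stats::deviance, numeric(1)),
                    stringsAsFactors = FALSE)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, n = n), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection over", nrow(x$table), "candidate predictor sets (n =",
      x$n, ")\n")
  print(transform(x$table, loglik = round(loglik, 3), AICc = round(AICc, 3),
                  dAICc = round(dAICc, 3), weight = round(weight, 4),
                  deviance = round(deviance, 3)))
  invisible(x)
}

# ANOVA-based ICC point estimate for a grouped vector; returns R in [0, 1].
icc_point <- function(group, value) {
  g <- as.factor(group)
  ni <- as.vector(table(g))
  N <- length(value); a <- nlevels(g)
  msb <- sum(ni * (tapply(value, g, mean) - mean(value))^2) / (a - 1)
  msw <- sum((value - stats::ave(value, g))^2) / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)   # = n per group when balanced
  if (msw == 0) return(if (msb > 0) 1 else 0)
  r <- (msb - msw) / (msb + (k0 - 1) * msw)
  max(0, min(1, r))
}

#' Repeatability (intraclass correlation) from replicate measurements
#'
#' One-way ANOVA estimator of the intraclass correlation,
#' `R = (MSB - MSW) / (MSB + (k - 1) MSW)` (generalized k for unbalanced
#' designs), truncated to `[0, 1]` with `R = 0` when the between-group
#' variance estimate is non-positive. Confidence intervals come from
#' resampling whole groups with replacement; the likelihood-ratio test of
#' the between-group variance component uses a linear mixed model (ML)
#' against the no-group model, referred to the boundary mixture
#' `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' @param group Group (e.g. species) identifier per measurement.
#' @param value Numeric measurements.
#' @param nboot Bootstrap iterations for the CI.
#' @param ci_level Confidence level.
#' @param seed Optional RNG seed.
#' @return Object of class `repeatability`: `R`, `ci` (level, lower, upper),
#'   `lrt`, `p_value`, `n_groups`, `mean_replicates`.
#' @export
repeatability_icc <- function(group, value, nboot = 1000, ci_level = 0.95,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(group) == length(value))
  ok <- is.finite(value)
  group <- as.character(group)[ok]; value <- value[ok]
  g <- as.factor(group)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (all(table(g) < 2)) stop("all groups are singletons; replicates required")
  R <- icc_point(g, value)
  # bootstrap over groups
  by_g <- split(value, g)
  boot <- vapply(seq_len(nboot), function(i) {
    idx <- sample(length(by_g), replace = TRUE)
    vb <- by_g[idx]
    icc_point(rep(seq_along(vb), lengths(vb)), unlist(vb, use.names = FALSE))
  }, numeric(1))
  qs <- stats::quantile(boot, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                        names = FALSE)
  # boundary-mixture LRT for the variance component
  df <- data.frame(value = value, group = g)
  ll1 <- tryCatch({
    m1 <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ 1 + (1 | group), data = df, REML = FALSE)))
    as.numeric(stats::logLik(m1))
  }, error = function(e) NA_real_)
  ll0 <- as.numeric(stats::logLik(stats::lm(value ~ 1, data = df)))
  lrt <- if (is.na(ll1)) NA_real_ else max(0, 2 * (ll1 - ll0))
  p <- if (is.na(lrt)) NA_real_ else if (lrt <= 0) 1 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(R = R, ci = c(level = ci_level, lower = qs[1], upper = qs[2]),
                 lrt = lrt, p_value = p, n_groups = nlevels(g),
                 mean_replicates = mean(table(g)), nboot = nboot),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f, %d%% CI = [%.3f, %.3f], LRT p = %.3g (%d groups)\n",
              x$R, round(100 * x$ci["level"]), x$ci["lower"], x$ci["upper"],
              x$p_value, x$n_groups))
  invisible(x)
}
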