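# ML fitting of continuous trait-evolution models (BM, Pagel's lambda, OU,
# EB) by profiling the root state and rate analytically and searching the
# single shape parameter by bracketed scalar optimization.

# Cholesky with a single ridge retry for near-singular covariances.
chol_safe <- function(C, ridge = 1e-10) {
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) {
    warning("covariance near-singular; adding ridge ", ridge, " * mean(diag)")
    C <- C + diag(ridge * mean(diag(C)), nrow(C))
    L <- tryCatch(chol(C), error = function(e)
      stop("covariance singular even after ridge; check the tree/model"))
  }
  L
}

#' Multivariate-normal log-likelihood of tip data on a phylogeny
#'
#' Log density of trait vector `x` under N(z0 * 1, sigma2 * C), evaluated
#' via a Cholesky factorization (with a small ridge retry if `C` is
#' numerically singular).
#'
#' @param x Numeric vector of tip values (order aligned with `C`).
#' @param C Phylogenetic covariance matrix.
#' @param sigma2 Evolutionary rate (> 0).
#' @param z0 Root state (mean).
#' @return Log-likelihood (scalar).
#' @export
mvn_loglik <- function(x, C, sigma2, z0) {
  stopifnot(length(x) == nrow(C), sigma2 > 0, is.finite(z0))
  n <- length(x)
  L <- chol_safe(sigma2 * C)
  r <- backsolve(L, x - z0, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# Profile loglik for covariance structure C (rate and root profiled out
# analytically: GLS mean, ML variance). Returns loglik, z0, sigma2.
profile_mvn <- function(x, C) {
  n <- length(x)
  L <- chol_safe(C)
  iC1 <- backsolve(L, backsolve(L, rep(1, n), transpose = TRUE))
  z0 <- sum(iC1 * x) / sum(iC1)
  r <- backsolve(L, x - z0, transpose = TRUE)
  sigma2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(L)))
  ll <- if (sigma2 <= 0) -Inf else
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(loglik = ll, z0 = z0, sigma2 = sigma2)
}

#' Akaike information criterion with small-sample correction
#'
#' `AIC = 2k - 2 loglik`; `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1 (n = ", n, ", k = ", k, ")")
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a vector of AICc values
#'
#' `w_i = exp(-(AICc_i - min)/2)`, normalized to sum to 1.
#'
#' @param x Numeric vector of AICc (or AIC) values.
#' @export
akaike_weights <- function(x) {
  stopifnot(length(x) >= 1, any(is.finite(x)))
  d <- x - min(x, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

shape_bounds <- list(lambda = c(0, 1),
                     OU = log(c(1e-4, 1e2)),   # ln(alpha), unit-height tree
                     EB = c(-10, 0))

# Build the model covariance on the unit-height tree for a raw search value.
shape_cov <- function(C0, model, s) {
  switch(model,
    lambda = transform_covariance(C0, "lambda", list(lambda = s)),
    OU     = transform_covariance(C0, "OU", list(alpha = exp(s))),
    EB     = transform_covariance(C0, "EB", list(a = s)))
}

#' Fit a continuous trait-evolution model by maximum likelihood
#'
#' Fits one of BM, Pagel's lambda, OU, or early burst to tip data. The root
#' state and rate are profiled analytically (GLS mean; ML variance); the
#' single shape parameter is maximized by a 20-point grid pre-scan followed
#' by Brent optimization in the bracketing interval (tolerance 1e-6). The
#' tree is rescaled to unit height internally to condition the OU search;
#' estimates are reported on the original time scale.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector (tips matched/pruned via [match_tree_data()]).
#' @param model One of "BM", "lambda", "OU", "EB".
#' @param n_grid Grid points for the pre-scan.
#' @return Object of class `evo_fit`: model, sigma2, shape (named numeric or
#'   NULL for BM), z0, loglik, k, n, AIC, AICc, convergence.
#' @export
fit_model <- function(tree, x, model = c("BM", "lambda", "OU", "EB"),
                      n_grid = 20) {
  model <- match.arg(model)
  md <- match_tree_data(tree, x)
  tree <- md$tree; x <- md$x
  n <- length(x)
  if (n < 3) stop("need >= 3 matched species to fit a model")
  h <- tree_height(tree)
  if (h <= 0) stop("tree height must be positive")
  C0 <- tree_vcv(tree) / h

  if (model == "BM") {
    pf <- profile_mvn(x, C0)
    out <- list(model = "BM", shape = NULL, loglik = pf$loglik,
                z0 = pf$z0, sigma2 = pf$sigma2 / h, k = 2, n = n,
                convergence = is.finite(pf$loglik))
  } else {
    b <- shape_bounds[[model]]
    obj <- function(s) {
      pf <- tryCatch(profile_mvn(x, shape_cov(C0, model, s)),
                     error = function(e) list(loglik = -Inf))
      pf$loglik
    }
    grid <- seq(b[1], b[2], length.out = n_grid)
    ll_grid <- vapply(grid, obj, numeric(1))
    if (!any(is.finite(ll_grid)))
      stop("non-finite likelihood across the whole ", model, " parameter range")
    i <- which.max(ll_grid)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
    # keep the best of the grid, the refined optimum, and the bounds
    cand <- c(opt$maximum, grid[i], b)
    ll_cand <- c(opt$objective, ll_grid[i], obj(b[1]), obj(b[2]))
    s_hat <- cand[which.max(ll_cand)]
    pf <- profile_mvn(x, shape_cov(C0, model, s_hat))
    shape <- switch(model,
      lambda = c(lambda = s_hat),
      OU = c(alpha = exp(s_hat) / h),
      EB = c(a = s_hat / h))
    out <- list(model = model, shape = shape, loglik = pf$loglik,
                z0 = pf$z0, sigma2 = pf$sigma2 / h, k = 3, n = n,
                convergence = is.finite(pf$loglik))
  }
  out$AIC <- 2 * out$k - 2 * out$loglik
  out$AICc <- aicc(out$loglik, out$k, n)
  class(out) <- "evo_fit"
  out
}

#' @export
print.evo_fit <- function(x, ...) {
  cat("Trait-evolution model fit:", x$model, "\n")
  cat(sprintf("  n = %d, loglik = %.4f, AICc = %.4f\n", x$n, x$loglik, x$AICc))
  cat(sprintf("  sigma2 = %.6g, z0 = %.6g", x$sigma2, x$z0))
  if (!is.null(x$shape))
    cat(sprintf(", %s = %.6g", names(x$shape), x$shape))
  cat("\n")
  invisible(x)
}

#' Fit all four trait-evolution models and rank them by AICc
#'
#' @inheritParams fit_model
#' @param models Models to fit.
#' @return List with `fits` (named list of `evo_fit`) and `table`
#'   (data.frame sorted by AICc with `dAICc` and Akaike `weight`).
#' @export
fit_all_models <- function(tree, x, models = c("BM", "lambda", "OU", "EB")) {
  fits <- lapply(models, function(m) fit_model(tree, x, m))
  names(fits) <- models
  tab <- data.frame(
    model = models,
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    stringsAsFactors = FALSE)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Phylogenetic signal as Pagel's lambda, with a likelihood-ratio test
#'
#' Maximizes the lambda model and tests lambda-hat against lambda = 0 (star
#' phylogeny / no signal) with a likelihood-ratio statistic referred to
#' chi-square with 1 df. On a star tree lambda is unidentifiable; the fit is
#' returned with `degenerate = TRUE` and a warning.
#'
#' @inheritParams fit_model
#' @return List: `lambda`, `loglik`, `loglik0` (at lambda = 0), `lrt`,
#'   `p_value`, `degenerate`.
#' @export
phylo_signal_lambda <- function(tree, x) {
  md <- match_tree_data(tree, x)
  h <- tree_height(md$tree)
  C0 <- tree_vcv(md$tree) / h
  off <- C0; diag(off) <- 0
  degenerate <- max(abs(off)) < 1e-12
  if (degenerate)
    warning("star-like tree: lambda is unidentifiable (off-diagonal covariance ~ 0)")
  fit <- fit_model(md$tree, md$x, "lambda")
  ll0 <- profile_mvn(md$x, transform_covariance(C0, "lambda", list(lambda = 0)))$loglik
  lrt <- max(0, 2 * (fit$loglik - ll0))
  list(lambda = unname(fit$shape["lambda"]), loglik = fit$loglik,
       loglik0 = ll0, lrt = lrt,
       p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       degenerate = degenerate)
}
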