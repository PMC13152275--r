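# Independent brute-force oracles used to check the fast implementations.

# Phylogenetic covariance by explicit path enumeration: for every tip pair,
# the MRCA depth is the summed branch length along the shared root path.
# Deliberately avoids ape::vcv.phylo.
brute_force_vcv <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path_to_root <- function(node) {
    p <- integer(0)
    while (node != root) { p <- c(p, node); node <- parent[node] }
    c(p, root)
  }
  depth <- function(node) {
    d <- 0
    while (node != root) { d <- d + blen[node]; node <- parent[node] }
    d
  }
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    mrca <- intersect(paths[[i]], paths[[j]])[1]
    C[i, j] <- depth(mrca)
  }
  diag(C) <- vapply(seq_len(ntip), depth, numeric(1))
  C
}

# Dense multivariate-normal log density via solve() and determinant().
dense_mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  r <- x - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

# Dense GLS by explicit matrix algebra (no factorization shortcuts).
dense_gls <- function(y, M, C) {
  Ci <- solve(C)
  XtCiX <- t(M) %*% Ci %*% M
  beta <- solve(XtCiX, t(M) %*% Ci %*% y)
  e <- y - M %*% beta
  n <- length(y); p <- ncol(M)
  sigma2 <- as.numeric(t(e) %*% Ci %*% e) / (n - p)
  se <- sqrt(sigma2 * diag(solve(XtCiX)))
  list(beta = drop(beta), se = se, sigma2 = sigma2)
}

# OLS slope/intercept via raw normal equations.
normal_equations_ols <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Fast access to the package's ICC point estimator (no bootstrap/LRT),
# for replicate-heavy null simulations.
icc_point_for_test <- function(group, value) ovocond:::icc_point(group, value)
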