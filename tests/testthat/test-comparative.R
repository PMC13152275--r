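test_that("pgls with identity covariance reproduces OLS exactly", {
  set.seed(1)
  n <- 20
  sp <- paste0("s", 1:n)
  X <- data.frame(a = rnorm(n), b = runif(n), row.names = sp)
  y <- setNames(1 + 2 * X$a - 0.5 * X$b + rnorm(n), sp)
  C <- diag(n); dimnames(C) <- list(sp, sp)
  fit <- pgls(y, X, C)
  ols <- lm(y ~ a + b, data = X)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("an exact linear response gives R^2 = 1 and zero residuals", {
  sp <- paste0("s", 1:8)
  X <- data.frame(a = 1:8, row.names = sp)
  y <- setNames(3 + 2 * (1:8), sp)
  C <- diag(8); dimnames(C) <- list(sp, sp)
  fit <- pgls(y, X, C)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$residuals), rep(0, 8), tolerance = 1e-10)
})

test_that("pgls matches a dense GLS matrix-algebra oracle on a hand dataset", {
  tr <- read_newick("(((A:1,B:1):1,(C:1.5,D:0.5):0.5):1,E:3);")
  C <- tree_vcv(tr)
  y <- c(A = 1.2, B = 0.9, C = 2.1, D = 1.7, E = 3.0)
  X <- data.frame(x = c(A = 0.1, B = 0.3, C = 1.1, D = 0.8, E = 2.0))
  fit <- pgls(y, X, C)
  M <- cbind(1, X$x)
  ref <- dense_gls(y, M, C[names(y), names(y)])
  expect_equal(fit$coefficients$estimate, unname(ref$beta), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(ref$se), tolerance = 1e-8)
  # GLS orthogonality of residuals to the design
  Ci <- solve(C[names(y), names(y)])
  expect_lt(max(abs(t(M) %*% Ci %*% fit$residuals)), 1e-8)
})

test_that("pgls is invariant to reordering species rows", {
  tr <- simulate_tree(12, seed = 6)
  C <- tree_vcv(tr)
  y <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 7)
  X <- data.frame(x = rnorm(12), row.names = tr$tip.label)
  f1 <- pgls(y, X, C)
  ord <- sample(names(y))
  f2 <- pgls(y[ord], X[ord, , drop = FALSE], C)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("pgls agrees with nlme's Brownian GLS cross-check", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(25, seed = 14)
  y <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 15)
  x <- rnorm(25); names(x) <- tr$tip.label
  d <- data.frame(y = y, x = x, row.names = tr$tip.label)
  ref <- suppressWarnings(nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~ 1)))
  fit <- pgls(y, data.frame(x = x, row.names = names(x)), tree_vcv(tr))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
})

test_that("rank-deficient designs fail with the collinear column named", {
  sp <- paste0("s", 1:6)
  X <- data.frame(a = 1:6, b = 2 * (1:6), row.names = sp)
  y <- setNames(rnorm(6), sp)
  C <- diag(6); dimnames(C) <- list(sp, sp)
  expect_error(pgls(y, X, C), "collinear.*b")
})

test_that("phylogenetic ANOVA floors the simulation p under extreme separation", {
  tr <- simulate_tree(30, seed = 20)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 21)
  g <- setNames(rep(c("a", "b", "c"), each = 10), tr$tip.label)
  shift <- c(a = 0, b = 50, c = 100)  # ~10+ SD group separation
  res <- phylo_anova(tr, x + shift[g], g, nsim = 400, seed = 22)
  expect_equal(res$p_simulation, 1 / 401)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 27)
})

test_that("degenerate zero within-group variance is handled with a warning", {
  tr <- simulate_tree(8, seed = 23)
  g <- setNames(rep(c("a", "b"), each = 4), tr$tip.label)
  x <- setNames(ifelse(g == "a", 1, 2), tr$tip.label)
  expect_warning(res <- phylo_anova(tr, x, g, nsim = 99, seed = 1), "degenerate|within-group")
  expect_equal(res$p_simulation, 1 / 100)
})

test_that("simulation p agrees with the parametric p on a star tree", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:60, ":1", collapse = ","), ");"))
  set.seed(30)
  x <- setNames(rnorm(60), star$tip.label)
  g <- setNames(rep(c("a", "b", "c"), each = 20), star$tip.label)
  res <- phylo_anova(star, x, g, nsim = 4000, seed = 31)
  mc_se <- sqrt(res$p_parametric * (1 - res$p_parametric) / 4000)
  expect_lt(abs(res$p_simulation - res$p_parametric), 4 * mc_se + 1e-3)
})

test_that("variance test: identical group copies give F = 0, scaled spread is detected", {
  tr <- simulate_tree(20, seed = 33)
  g <- setNames(rep(c("a", "b"), each = 10), tr$tip.label)
  base <- rnorm(10)
  x <- setNames(c(base, base + 5), tr$tip.label)  # same spread, shifted mean
  res <- group_variance_test(tr, x, g, nsim = 99, seed = 34)
  expect_equal(res$f, 0, tolerance = 1e-10)
  # one group's spread scaled 10x
  set.seed(35)
  hits <- replicate(20, {
    x2 <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0))
    x2[g == "b"] <- mean(x2[g == "b"]) + 10 * (x2[g == "b"] - mean(x2[g == "b"]))
    group_variance_test(tr, x2, g, nsim = 199)$p_simulation <= 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("model selection: intercept-only weight, deviance nesting, signal recovery", {
  set.seed(40)
  n <- 60
  d <- data.frame(mass = rnorm(n), elevation = sample(c("low", "mid", "high"), n, TRUE),
                  noise = rnorm(n))
  d$y <- 2 * d$mass + c(low = 0, mid = -0.5, high = -1)[d$elevation] + rnorm(n, 0, 0.5)
  single <- glm_model_selection(d, "y", list(character(0)))
  expect_equal(single$table$weight, 1)
  sel <- glm_model_selection(d, "y", list(character(0), "mass", "elevation",
                                          c("mass", "elevation"),
                                          c("mass", "elevation", "noise")))
  tab <- sel$table
  # deviance is monotone non-increasing in nested supersets
  dev <- setNames(tab$deviance, tab$predictors)
  expect_lte(dev[["mass + elevation"]], dev[["mass"]])
  expect_lte(dev[["mass + elevation + noise"]], dev[["mass + elevation"]])
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$dAICc[1], 0)
  # the generating set should win most replicates
  set.seed(41)
  wins <- replicate(30, {
    d$y <- 2 * d$mass + c(low = 0, mid = -0.5, high = -1)[d$elevation] + rnorm(n, 0, 0.5)
    glm_model_selection(d, "y", list("mass", "elevation", c("mass", "elevation"),
                                     c("mass", "elevation", "noise")))$table$predictors[1]
  })
  expect_gt(mean(wins == "mass + elevation"), 0.6)
  expect_error(glm_model_selection(d, "y", list("absent_col")), "absent_col")
})

test_that("ICC: exact boundary cases and closed-form recovery", {
  # identical replicates within groups, distinct means -> R = 1
  g <- rep(1:5, each = 3)
  v <- rep(c(1, 4, 9, 2, 7), each = 3)
  res <- repeatability_icc(g, v, nboot = 50, seed = 1)
  expect_equal(res$R, 1)
  # pure noise -> R near 0 and truncation at 0 when MSB <= MSW
  set.seed(2)
  res0 <- suppressWarnings(repeatability_icc(rep(1:100, each = 3), rnorm(300),
                                             nboot = 100, seed = 3))
  expect_lte(res0$R, 0.1)
  # true ICC = 0.9: between-variance 9, within 1
  set.seed(4)
  gid <- rep(1:200, each = 3)
  v <- rnorm(200, sd = 3)[gid] + rnorm(600, sd = 1)
  res9 <- suppressWarnings(repeatability_icc(gid, v, nboot = 200, seed = 5))
  expect_lt(abs(res9$R - 0.9), 0.05)
  expect_true(res9$ci["lower"] <= res9$R && res9$R <= res9$ci["upper"])
  expect_lt(res9$p_value, 1e-6)
})

test_that("ICC is invariant to affine transforms and rejects all-singleton input", {
  set.seed(6)
  gid <- rep(1:30, each = 3)
  v <- rnorm(30, sd = 2)[gid] + rnorm(90)
  r1 <- repeatability_icc(gid, v, nboot = 10, seed = 7)$R
  r2 <- repeatability_icc(gid, 100 + 7 * v, nboot = 10, seed = 7)$R
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_error(repeatability_icc(1:10, rnorm(10)), "singleton")
})
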