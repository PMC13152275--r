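test_that("mvn_loglik matches the standard-normal case and a dense oracle", {
  # two iid standard-normal tips at the origin
  expect_equal(mvn_loglik(c(0, 0), diag(2), 1, 0), -log(2 * pi), tolerance = 1e-12)

  tr <- read_newick("((A:1,B:1):1,C:2);")
  C <- tree_vcv(tr)
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(3); s2 <- runif(1, 0.2, 3); z0 <- rnorm(1)
    expect_equal(mvn_loglik(x, C, s2, z0),
                 dense_mvn_loglik(x, rep(z0, 3), s2 * C), tolerance = 1e-8)
  }
})

test_that("loglik obeys the change-of-variables scaling identity", {
  C <- tree_vcv(simulate_tree(10, seed = 2))
  x <- simulate_trait(simulate_tree(10, seed = 2), "BM",
                      list(sigma2 = 1, z0 = 0), seed = 3)
  s <- 2.5
  expect_equal(mvn_loglik(x, C, s^2, 0),
               mvn_loglik(x / s, C, 1, 0) - length(x) * log(s),
               tolerance = 1e-10)
})

test_that("aicc follows the closed form and its domain limits", {
  expect_equal(aicc(0, 2, 108), 4 + 12 / 105)
  expect_equal(aicc(-10, 0, 50), 20)               # k = 0 -> AICc = AIC
  expect_lt(abs(aicc(0, 3, 1e5) - 6), 1e-3)         # AICc -> AIC as n grows
  expect_error(aicc(0, 3, 4), "n > k")
  # AICc >= AIC whenever defined
  expect_gte(aicc(-5, 3, 10), 2 * 3 - 2 * (-5))
})

test_that("akaike weights normalize and order correctly", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(plogis(1), plogis(-1)), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:10) {
    v <- runif(4, 0, 50)
    w <- akaike_weights(v)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(which.max(w), which.min(v))
  }
})

test_that("the lambda model never fits worse than BM (nesting)", {
  set.seed(31)
  tr <- simulate_tree(40)
  for (rep in 1:5) {
    x <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0))
    fl <- fit_model(tr, x, "lambda")
    fb <- fit_model(tr, x, "BM")
    expect_gte(fl$loglik, fb$loglik - 1e-8)
  }
})

test_that("OU loglik approaches BM loglik as alpha -> 0", {
  tr <- simulate_tree(25, seed = 8)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 9)
  C <- tree_vcv(tr)
  ll_bm <- fit_model(tr, x, "BM")$loglik
  Cou <- transform_covariance(C, "OU", list(alpha = 1e-7))
  pf <- mvn_loglik(x, Cou, fit_model(tr, x, "BM")$sigma2, fit_model(tr, x, "BM")$z0)
  expect_equal(pf, mvn_loglik(x, C, fit_model(tr, x, "BM")$sigma2,
                              fit_model(tr, x, "BM")$z0), tolerance = 1e-3)
})

test_that("fits are deterministic given the data", {
  tr <- simulate_tree(30, seed = 12)
  x <- simulate_trait(tr, "BM", list(sigma2 = 2, z0 = 1), seed = 13)
  f1 <- fit_model(tr, x, "OU"); f2 <- fit_model(tr, x, "OU")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_equal(f1$shape, f2$shape, tolerance = 1e-10)
})

test_that("lambda recovery separates phylogenetic from iid data (reduced runs)", {
  set.seed(77)
  tr <- simulate_tree(60)
  lam_bm <- replicate(20, {
    x <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0))
    unname(fit_model(tr, x, "lambda")$shape["lambda"])
  })
  lam_iid <- replicate(20, {
    x <- setNames(rnorm(60), tr$tip.label)
    unname(fit_model(tr, x, "lambda")$shape["lambda"])
  })
  expect_gt(mean(lam_bm >= 0.8), 0.7)
  expect_gt(mean(lam_iid <= 0.2), 0.7)
})

test_that("lambda estimate agrees with the phytools cross-check", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(50, seed = 101)
  x <- simulate_trait(tr, "lambda", list(sigma2 = 1, z0 = 0, lambda = 0.6),
                      seed = 102)
  mine <- phylo_signal_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda", test = FALSE)
  expect_equal(mine$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(mine$loglik, ref$logL, tolerance = 0.01)
})

test_that("model selection prefers OU for strongly mean-reverting data", {
  set.seed(55)
  tr <- simulate_tree(80)
  wins <- replicate(20, {
    x <- simulate_trait(tr, "OU", list(sigma2 = 1, z0 = 0, alpha = 2))
    fit_all_models(tr, x)$table$model[1]
  })
  expect_gt(mean(wins == "OU"), 0.5)
})

test_that("a star tree flags lambda as unidentifiable", {
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:8, ":1", collapse = ","), ");"))
  x <- setNames(rnorm(8), star$tip.label)
  expect_warning(res <- phylo_signal_lambda(star, x), "unidentifiable")
  expect_true(res$degenerate)
})

test_that("fit_model refuses undersized data", {
  tr <- read_newick("(A:1,B:1);")
  expect_error(fit_model(tr, c(A = 1, B = 2), "BM"), ">= 3")
})
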