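# Every flavor is validated against exact Shapley values of the shared
# marginal-expectation game: shap_exact by subset enumeration, and an
# independent permutation-enumeration oracle in helper-fixtures.R.

test_that("shap_exact satisfies the closed form and Shapley axioms", {
  set.seed(91)
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  bg[, 1] <- bg[, 1] - mean(bg[, 1]) # background mean of x1 exactly 0
  pf <- function(M) 2 * M[, 1]
  ex <- shap_exact(pf, c(x1 = 3, x2 = 1), bg)
  expect_equal(unname(ex$contributions["x1"]), 6, tolerance = 1e-12)
  expect_equal(unname(ex$contributions["x2"]), 0, tolerance = 1e-12)

  # efficiency on an interacting function
  pf2 <- function(M) M[, 1] * M[, 2] + M[, 1]
  x <- c(x1 = 1.5, x2 = -2)
  ex2 <- shap_exact(pf2, x, bg)
  expect_equal(ex2$base_value + sum(ex2$contributions),
               unname(pf2(matrix(x, 1, dimnames = list(NULL, names(x))))),
               tolerance = 1e-12)

  # symmetry: exchangeable features with equal values
  bg3 <- cbind(a = bg[, 1], b = bg[, 1])
  ex3 <- shap_exact(function(M) M[, 1] + M[, 2] + M[, 1] * M[, 2],
                    c(a = 2, b = 2), bg3)
  expect_equal(unname(ex3$contributions["a"]),
               unname(ex3$contributions["b"]), tolerance = 1e-12)

  expect_error(shap_exact(pf, rnorm(16), matrix(rnorm(32), 2)), "<= 15")
})

test_that("shap_exact agrees with the permutation-enumeration oracle", {
  set.seed(92)
  bg <- matrix(rnorm(8 * 4), 8, 4)
  pf <- function(M) plogis(M[, 1] - 2 * M[, 2] + M[, 3] * M[, 4])
  x <- rnorm(4)
  ex <- shap_exact(pf, x, bg)
  brute <- shapley_bruteforce(pf, x, bg)
  expect_equal(unname(ex$contributions), brute, tolerance = 1e-10)
})

test_that("linear SHAP matches the exact oracle and scales with beta", {
  set.seed(93)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  model <- list(coef = c(a = 1.2, b = -0.7, c = 0.4), intercept = 0.3)
  la <- shap_linear(model, X, colMeans(bg))
  pf <- function(M) drop(M %*% model$coef) + model$intercept
  for (i in c(1, 5)) {
    ex <- shap_exact(pf, X[i, ], bg)
    expect_equal(unname(la$contributions[i, ]), unname(ex$contributions),
                 tolerance = 1e-9)
  }
  # at the reference point every contribution vanishes
  at_mean <- shap_linear(model, matrix(colMeans(bg), 1,
                                       dimnames = list(NULL, c("a", "b", "c"))),
                         colMeans(bg))
  expect_equal(unname(at_mean$contributions[1, ]), c(0, 0, 0))
  # doubling one coefficient doubles exactly that contribution
  model2 <- model; model2$coef["b"] <- -1.4
  la2 <- shap_linear(model2, X, colMeans(bg))
  expect_equal(la2$contributions[, "b"], 2 * la$contributions[, "b"])
  expect_equal(la2$contributions[, "a"], la$contributions[, "a"])
})

test_that("tree SHAP is exact for stumps and matches enumeration", {
  toy <- toy_separable()
  # depth-1 stump: all attribution on the split feature
  stump <- fit_ensemble(toy$X, toy$y, seed = 1,
                        hyperparams = list(nrounds = 1, max_depth = 1,
                                           eta = 1, calib_folds = 2))
  ts <- shap_tree(stump, toy$X[1:5, ], toy$X)
  off_split <- which(colSums(ts$contributions != 0) == 0)
  expect_length(off_split, 1) # exactly one feature carries no mass

  set.seed(94)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(300, 1, plogis(X[, 1] - X[, 2] + X[, 1] * X[, 3]))
  ens <- fit_ensemble(X, y, seed = 2,
                      hyperparams = list(nrounds = 12, max_depth = 2,
                                         calib_folds = 2))
  bg <- X[1:16, ]
  ts2 <- shap_tree(ens, X[1:4, ], bg)
  pf <- function(M) dentshap:::cpp_boost_predict(ens$tree_model, M)
  for (i in 1:4) {
    ex <- shap_exact(pf, X[i, ], bg)
    expect_equal(unname(ts2$contributions[i, ]), unname(ex$contributions),
                 tolerance = 1e-6)
  }
  # additivity reproduces the raw margins
  expect_equal(ts2$base_value + rowSums(ts2$contributions),
               unname(pf(X[1:4, ])), tolerance = 1e-9)
  expect_error(shap_tree(list(not = "a tree"), X, bg), "booster")
})

test_that("marginal SHAP is unbiased, additive and deterministic", {
  set.seed(95)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(200, 1, plogis(X[, 1] - X[, 2]))
  ens <- fit_ensemble(X, y, seed = 3,
                      hyperparams = list(nrounds = 15, max_depth = 2,
                                         calib_folds = 2))
  pf <- function(M) predict(ens, M)
  bg <- X[1:16, ]
  ma <- shap_marginal(pf, X[1:3, ], bg, n_samples = 300, seed = 8)
  for (i in 1:3) {
    ex <- shap_exact(pf, X[i, ], bg)
    tol <- 3 * ma$se[i, ] + 1e-9
    expect_true(all(abs(ma$contributions[i, ] - ex$contributions) < tol))
  }
  # additivity is exact by the telescoping construction
  expect_equal(ma$base_value + rowSums(ma$contributions),
               unname(pf(X[1:3, ])), tolerance = 1e-12)
  # determinism
  ma2 <- shap_marginal(pf, X[1:3, ], bg, n_samples = 300, seed = 8)
  expect_identical(ma$contributions, ma2$contributions)
  expect_error(shap_marginal(pf, X[1:3, ], bg, n_samples = 5), "at least 10")
})

test_that("all flavors agree with the oracle across random small models", {
  set.seed(96)
  for (rep in 1:50) {
    d <- sample(3:6, 1)
    beta <- rnorm(d)
    X <- matrix(rnorm(8 * d), 8, d, dimnames = list(NULL, paste0("g", 1:d)))
    bg <- matrix(rnorm(10 * d), 10, d, dimnames = list(NULL, paste0("g", 1:d)))
    model <- list(coef = setNames(beta, paste0("g", 1:d)),
                  intercept = rnorm(1))
    pf <- function(M) drop(M %*% beta) + model$intercept
    i <- sample(8, 1)
    ex <- shap_exact(pf, X[i, ], bg)
    la <- shap_linear(model, X[i, , drop = FALSE], colMeans(bg))
    expect_equal(unname(la$contributions[1, ]), unname(ex$contributions),
                 tolerance = 1e-9)
    # null feature: a zeroed coefficient receives exactly zero
    expect_equal(unname(la$contributions[1, which.min(abs(beta))]),
                 unname(ex$contributions[which.min(abs(beta))]),
                 tolerance = 1e-9)
  }
})

test_that("grouped marginal SHAP attributes one-hot blocks jointly", {
  set.seed(97)
  X <- cbind(a = rnorm(100), b1 = rbinom(100, 1, 0.5))
  X <- cbind(X, b2 = 1 - X[, "b1"])
  pf <- function(M) M[, "a"] + 2 * M[, "b1"] - 2 * M[, "b2"]
  ma <- shap_marginal(pf, X[1:4, ], X, n_samples = 200, seed = 2,
                      groups = list(a = "a", b = c("b1", "b2")))
  expect_equal(colnames(ma$contributions), c("a", "b"))
  expect_equal(ma$base_value + rowSums(ma$contributions),
               unname(pf(X[1:4, ])), tolerance = 1e-12)
})

test_that("summary_ranking groups and orders by mean absolute impact", {
  contrib <- cbind(big = c(5, -5, 5), tiny = c(0.1, -0.1, 0.1),
                   school_one = c(1, 1, -1))
  attr <- dentshap:::new_attribution_matrix(contrib, 0, rowSums(contrib),
                                            contrib, "linear")
  gm <- c(big = "individual", tiny = "individual", school_one = "school")
  rk <- summary_ranking(attr, gm)
  ind <- rk[rk$group == "individual", ]
  expect_equal(ind$feature, c("big", "tiny"))
  expect_equal(ind$mean_abs_contribution, c(5, 0.1))
  expect_error(summary_ranking(attr, gm[-1]), "missing from group_map")

  # all-zero contributions keep the original feature order
  zattr <- dentshap:::new_attribution_matrix(contrib * 0, 0, c(0, 0, 0),
                                             contrib, "linear")
  zr <- summary_ranking(zattr, gm)
  expect_equal(zr$feature[zr$group == "individual"], c("big", "tiny"))
  expect_true(all(zr$mean_abs_contribution == 0))
})

test_that("collapse_attributions sums one-hot children exactly", {
  contrib <- cbind("g=a" = c(1, 2), "g=b" = c(3, -1), x = c(0.5, 0.5))
  attr <- dentshap:::new_attribution_matrix(contrib, 0.2,
                                            0.2 + rowSums(contrib),
                                            contrib, "tree")
  parent <- c("g=a" = "g", "g=b" = "g", x = "x")
  coll <- collapse_attributions(attr, parent)
  expect_equal(unname(coll$contributions[, "g"]), c(4, 1))
  expect_equal(coll$base_value + rowSums(coll$contributions),
               attr$model_outputs)
})
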