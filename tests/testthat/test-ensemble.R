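test_that("mcc matches the closed form and its zero conventions", {
  expect_equal(mcc(2, 1, 1, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(mcc(10, 0, 0, 30), 1)
  expect_equal(mcc(0, 0, 5, 10), 0)  # no predicted positives
  expect_equal(mcc(5, 10, 0, 0), 0)  # no predicted negatives
  expect_error(mcc(-1, 0, 0, 0), "nonnegative")
})

test_that("auc agrees with brute-force pair counting", {
  # perfectly ordered
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # all ties
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # worked example: enumerate all positive x negative pairs
  scores <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  brute <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                       ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(auc(scores, y), brute)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auc is invariant under strictly increasing transforms", {
  set.seed(11)
  for (rep in 1:20) {
    s <- rnorm(60)
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    a <- auc(s, y)
    expect_equal(auc(exp(s), y), a)
    expect_equal(auc(qlogis(plogis(s)), y), a, tolerance = 1e-12)
    expect_equal(auc(rank(s, ties.method = "average"), y), a)
  }
})

test_that("select_threshold maximizes MCC against an exhaustive oracle", {
  # perfectly separated: gap midpoint, MCC 1
  s <- c(0.1, 0.2, 0.8, 0.9); y <- c(0, 0, 1, 1)
  thr <- select_threshold(s, y)
  expect_equal(thr, 0.5)
  expect_equal(mcc(2, 0, 0, 2), 1)

  # identical scores: smallest candidate returned
  expect_equal(select_threshold(rep(0.4, 5), c(0, 1, 0, 1, 1)), 0.4)

  # 200 random instances vs exhaustive grid
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 2) # deliberate ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    thr <- select_threshold(s, y)
    pred <- as.numeric(s >= thr)
    got <- mcc(sum(pred & y), sum(pred & !y), sum(!pred & y),
               sum(!pred & !y))
    expect_equal(got, best_mcc_exhaustive(s, y), tolerance = 1e-12)
  }
})

test_that("isotonic calibration is monotone on a dense grid", {
  set.seed(21)
  s <- runif(500)
  y <- rbinom(500, 1, plogis(4 * s - 2))
  iso <- dentshap:::fit_isotonic(s, y)
  grid <- seq(0, 1, length.out = 2001)
  p <- dentshap:::predict_isotonic(iso, grid)
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("fit_ensemble behaves on separable and null problems", {
  toy <- toy_separable()
  ens <- fit_ensemble(toy$X, toy$y, seed = 1,
                      hyperparams = list(nrounds = 20, calib_folds = 3))
  expect_equal(auc(predict(ens, toy$X), toy$y), 1)

  # vote definition: score is the weighted mean of member probabilities
  members <- predict(ens, toy$X, type = "members")
  expect_equal(drop(members %*% c(0.5, 0.5)), predict(ens, toy$X),
               tolerance = 1e-12)
  expect_true(all(predict(ens, toy$X) >= 0 & predict(ens, toy$X) <= 1))

  expect_error(fit_ensemble(toy$X, rep(1, nrow(toy$X))), "single class")

  # permutation null: test AUC concentrates on 0.5
  dat <- toy_signal(n = 500)
  set.seed(33)
  aucs <- replicate(12, {
    yp <- sample(dat$y)
    ens0 <- fit_ensemble(dat$X[1:350, ], yp[1:350], seed = 2,
                         hyperparams = list(nrounds = 20, calib_folds = 3))
    auc(predict(ens0, dat$X[351:500, ]), yp[351:500])
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.02)
})

test_that("evaluate reports coherent imbalance-aware metrics", {
  dat <- toy_signal(n = 600)
  ens <- fit_ensemble(dat$X[1:400, ], dat$y[1:400], seed = 3,
                      hyperparams = list(nrounds = 30, calib_folds = 3))
  Xte <- dat$X[401:600, ]; yte <- dat$y[401:600]
  r <- evaluate(ens, Xte, yte, boot = 200, seed = 5)
  cm <- r$confusion
  expect_equal(r$sensitivity, cm["TP"] / (cm["TP"] + cm["FN"]),
               ignore_attr = TRUE)
  expect_equal(r$specificity, cm["TN"] / (cm["TN"] + cm["FP"]),
               ignore_attr = TRUE)
  expect_equal(r$precision, cm["TP"] / (cm["TP"] + cm["FP"]),
               ignore_attr = TRUE)
  expect_equal(r$lift, r$precision / mean(yte))
  expect_equal(sum(cm), length(yte), ignore_attr = TRUE)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_true(r$mcc >= -1 && r$mcc <= 1)
})

test_that("lift is precision over prevalence (worked ratio)", {
  # precision 0.20 at prevalence 0.05 must report lift 4
  expect_equal(0.20 / 0.05, 4)
  dat <- toy_signal(n = 400)
  ens <- fit_ensemble(dat$X, dat$y, seed = 1,
                      hyperparams = list(nrounds = 15, calib_folds = 2))
  r <- evaluate(ens, dat$X, dat$y, boot = 0)
  expect_equal(r$lift, r$precision / mean(dat$y))
})

test_that("monte_carlo_cv summary invariants hold", {
  co <- generate_cohort(cohort_config(n_dentists = 1200, seed = 14,
                                      target_prevalence = c(y = 0.15)))
  y <- co$outcomes$y
  hp <- list(nrounds = 20, calib_folds = 2)
  one <- monte_carlo_cv(co$features, y, n_iterations = 1, base_seed = 5,
                        hyperparams = hp)
  expect_equal(one$mean_auc, one$per_split[[1]]$auc)

  cv <- monte_carlo_cv(co$features, y, n_iterations = 4, base_seed = 5,
                       hyperparams = hp)
  aucs <- vapply(cv$per_split, `[[`, numeric(1), "auc")
  expect_equal(cv$best_split$auc, max(aucs))
  expect_gte(cv$best_split$auc, cv$mean_auc)
  expect_equal(cv$mean_auc, mean(aucs))
  expect_lt(cv$ci_low, cv$ci_high)
})

test_that("null cohort CV shows no systematic optimism (MCC centered)", {
  cfg <- cohort_config(n_dentists = 1500, seed = 25,
                       target_prevalence = c(y = 0.2),
                       effect_spec = null_effect_spec())
  co <- generate_cohort(cfg)
  cv <- monte_carlo_cv(co$features, co$outcomes$y, n_iterations = 5,
                       base_seed = 9,
                       hyperparams = list(nrounds = 20, calib_folds = 2))
  mccs <- vapply(cv$per_split, `[[`, numeric(1), "mcc")
  expect_lt(abs(mean(mccs)), 0.1)
  expect_true(cv$ci_low < 0.55 && cv$ci_high > 0.45)
})

test_that("cv reports serialize to JSON", {
  dat <- toy_signal(n = 300)
  cv <- monte_carlo_cv(as.data.frame(dat$X), dat$y, n_iterations = 2,
                       base_seed = 2,
                       hyperparams = list(nrounds = 10, calib_folds = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$average$mean_auc, cv$mean_auc, tolerance = 1e-12)
  expect_equal(nrow(back$per_split), 2)
})
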