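# Global feature importance: the Shapley value of each feature with respect
# to an AUC value function (SAGE with the performance metric swapped for
# AUC, to stay informative under heavy class imbalance), plus logistic
# coefficient importance and feature-inclusion curves for top-k selection.

#' AUC-based SAGE global importance
#'
#' Permutation-sampling Shapley estimator of the game
#' `v(S) = AUC(scores with features outside S marginalized, y)`.
#' Marginalization replaces out-of-coalition features with values from an
#' explicit background sample. `v(empty)` is fixed at 0.5 analytically
#' (fully marginalized scores carry no information about `y`), which makes
#' the efficiency identity `sum(values) = full_auc - 0.5` hold exactly for
#' every sampled permutation.
#'
#' Two marginalization estimators are available: `"average"` scores each
#' coalition as the mean prediction over the whole background (the exact
#' game; cost scales with background size), and `"sample"` draws one
#' background row per permutation (unbiased per step, far cheaper; the
#' estimator the pipeline uses at scale).
#'
#' @param predict_fn function(matrix) -> numeric scores.
#' @param X numeric matrix of evaluation rows.
#' @param y binary outcome aligned with `X`.
#' @param background matrix of background rows (same columns as `X`).
#' @param n_permutations sampled feature orderings (at least 2).
#' @param seed integer seed.
#' @param groups optional named list mapping group name -> column indices
#'   (or names); features enter and are marginalized as whole groups.
#'   Default: every column is its own group.
#' @param eval_cap maximum evaluation rows used for the AUC (subsampled
#'   with the seed when `nrow(X)` exceeds it).
#' @param marginal `"sample"` or `"average"` (see above).
#' @return object of class `sage_ranking`: `values`, `standard_errors`
#'   (named by group, sorted by value), `baseline_auc`, `full_auc`,
#'   `n_permutations`.
#' @export
sage_auc <- function(predict_fn, X, y, background, n_permutations = 64,
                     seed = 1L, groups = NULL, eval_cap = 2000,
                     marginal = c("sample", "average")) {
  marginal <- match.arg(marginal)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required")
  if (n_permutations < 2)
    stop("need at least 2 permutations to report standard errors")
  if (nrow(background) == 0) stop("background must be nonempty")

  if (is.null(groups)) {
    groups <- as.list(seq_len(ncol(X)))
    names(groups) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  }
  groups <- lapply(groups, function(g)
    if (is.character(g)) match(g, colnames(X)) else as.integer(g))
  G <- length(groups)

  with_seed(seed, {
    if (nrow(X) > eval_cap) {
      keep <- sample.int(nrow(X), eval_cap)
      # guard: subsample must keep both classes
      if (length(unique(y[keep])) < 2)
        keep <- c(keep, which(y == setdiff(unique(y), y[keep]))[1])
      X <- X[keep, , drop = FALSE]
      y <- y[keep]
    }
    n <- nrow(X)
    full_auc <- auc(predict_fn(X), y)

    gains <- matrix(0, n_permutations, G)
    for (t in seq_len(n_permutations)) {
      ord <- sample.int(G)
      if (marginal == "sample") {
        b <- background[sample.int(nrow(background), 1), ]
        cur <- matrix(b, n, ncol(X), byrow = TRUE)
        colnames(cur) <- colnames(X)
        prev_v <- 0.5
        for (g in ord) {
          idx <- groups[[g]]
          cur[, idx] <- X[, idx]
          v <- auc(predict_fn(cur), y)
          gains[t, g] <- v - prev_v
          prev_v <- v
        }
      } else {
        m <- nrow(background)
        hybrids <- lapply(seq_len(m), function(j) {
          h <- matrix(background[j, ], n, ncol(X), byrow = TRUE)
          colnames(h) <- colnames(X)
          h
        })
        prev_v <- 0.5
        for (g in ord) {
          idx <- groups[[g]]
          sc <- numeric(n)
          for (j in seq_len(m)) {
            hybrids[[j]][, idx] <- X[, idx]
            sc <- sc + predict_fn(hybrids[[j]])
          }
          v <- auc(sc / m, y)
          gains[t, g] <- v - prev_v
          prev_v <- v
        }
      }
    }
    values <- colMeans(gains)
    ses <- apply(gains, 2, sd) / sqrt(n_permutations)
    names(values) <- names(ses) <- names(groups)
    o <- order(values, decreasing = TRUE)
    structure(list(values = values[o], standard_errors = ses[o],
                   n_permutations = n_permutations,
                   baseline_auc = 0.5, full_auc = full_auc,
                   marginal = marginal), class = "sage_ranking")
  })
}

#' @export
print.sage_ranking <- function(x, ...) {
  cat(sprintf("AUC-SAGE ranking (%d permutations, full AUC %.3f)\n",
              x$n_permutations, x$full_auc))
  for (i in seq_along(x$values))
    cat(sprintf("  %2d. %-28s %+.4f (se %.4f)\n", i, names(x$values)[i],
                x$values[i], x$standard_errors[i]))
  invisible(x)
}

#' Logistic-coefficient global importance
#'
#' Ranks standardized-model coefficients by absolute magnitude; ties break
#' by declared column order. Warns when the design does not look
#' standardized.
#'
#' @param logistic_model list with `coef` (as from [ridge_logistic()]).
#' @param feature_names declared column order (defaults to coefficient
#'   names).
#' @param X optional design matrix used only to check standardization.
#' @return data.frame (feature, coefficient, rank) ordered by importance.
#' @export
coef_importance <- function(logistic_model, feature_names = NULL, X = NULL) {
  cf <- logistic_model$coef
  feature_names <- feature_names %||% names(cf)
  cf <- cf[feature_names]
  if (!is.null(X)) {
    mu <- colMeans(X); sdv <- apply(X, 2, sd)
    ok <- abs(mu) < 0.5 & (sdv == 0 | abs(sdv - 1) < 0.5)
    if (!all(ok))
      warning("design does not look standardized (columns: ",
              paste(feature_names[!ok], collapse = ", "), ")")
  }
  o <- order(-abs(cf), seq_along(cf)) # ties -> declared order
  data.frame(feature = feature_names[o], coefficient = unname(cf[o]),
             rank = seq_along(cf))
}

#' Feature-inclusion curve
#'
#' Refits the ensemble on the top-k raw features for each k and records the
#' held-out AUC on a single fixed 80/20 split. `k = 0` records the
#' no-feature baseline of 0.5 without fitting.
#'
#' @param features raw feature data.frame.
#' @param y binary outcome.
#' @param ranking character vector of raw feature names, most important
#'   first.
#' @param ks increasing counts, each at most `length(ranking)`.
#' @param cv_seed seed fixing the split and fits.
#' @param hyperparams ensemble hyperparameters.
#' @return object of class `inclusion_curve`: data.frame `curve` with
#'   (k, auc), plus `ranking_used`.
#' @export
inclusion_curve <- function(features, y, ranking, ks, cv_seed = 1L,
                            hyperparams = NULL) {
  stopifnot(all(diff(ks) > 0), max(ks) <= length(ranking))
  y <- as.numeric(y)
  n <- nrow(features)
  idx <- with_seed(cv_seed, sample.int(n, size = round(0.8 * n)))
  aucs <- vapply(ks, function(k) {
    if (k == 0) return(0.5)
    cols <- ranking[seq_len(k)]
    plan <- fit_preprocess(features[idx, cols, drop = FALSE])
    Xtr <- apply_preprocess(plan, features[idx, cols, drop = FALSE])
    Xte <- apply_preprocess(plan, features[-idx, cols, drop = FALSE])
    ens <- fit_ensemble(Xtr, y[idx], seed = cv_seed,
                        hyperparams = hyperparams)
    auc(predict(ens, Xte), y[-idx])
  }, numeric(1))
  structure(list(curve = data.frame(k = ks, auc = aucs),
                 ranking_used = ranking), class = "inclusion_curve")
}

#' Smallest k within tolerance of the curve maximum
#'
#' @param curve an `inclusion_curve`.
#' @param tolerance AUC slack below the maximum (default 0.005).
#' @return the selected k.
#' @export
select_top_k <- function(curve, tolerance = 0.005) {
  stopifnot(inherits(curve, "inclusion_curve"), nrow(curve$curve) > 0)
  cv <- curve$curve
  cv$k[which(cv$auc >= max(cv$auc) - tolerance)[1]]
}
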