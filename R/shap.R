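# Per-instance Shapley attributions. One removal scheme is used everywhere:
# marginal (interventional) expectation against an explicit background
# sample, so the linear, tree and model-agnostic flavors all estimate the
# same game and can be validated against the exact enumeration oracle.

#' @noRd
new_attribution_matrix <- function(contributions, base_value, model_outputs,
                                   feature_values, flavor, se = NULL) {
  structure(list(contributions = contributions, base_value = base_value,
                 model_outputs = model_outputs,
                 feature_values = feature_values, flavor = flavor, se = se),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("SHAP attribution matrix (%s): %d instances x %d features, base %.4f\n",
              x$flavor, nrow(x$contributions), ncol(x$contributions),
              x$base_value))
  invisible(x)
}

#' Exact Shapley values by subset enumeration (test oracle)
#'
#' Computes the exact Shapley values of the marginal-expectation game
#' `v(S) = mean over background rows b of predict_fn(x with features
#' outside S taken from b)`. Enumerates all `2^d` coalitions, so `d` is
#' capped at 15.
#'
#' @param predict_fn function(matrix) -> numeric.
#' @param x single explained row (numeric vector or 1-row matrix).
#' @param background matrix of background rows.
#' @return list with `contributions` (named), `base_value` and
#'   `model_output`.
#' @export
shap_exact <- function(predict_fn, x, background) {
  x <- drop(as.matrix(x))
  d <- length(x)
  if (d > 15) stop("shap_exact enumerates 2^d subsets; d must be <= 15 ",
                   "(use shap_marginal for larger models)")
  m <- nrow(background)
  nmask <- 2^d
  # v[mask+1] = mean prediction with coalition given by mask bits
  v <- numeric(nmask)
  bits <- matrix(FALSE, nmask, d)
  for (j in seq_len(d)) bits[, j] <- bitwAnd(seq_len(nmask) - 1L, 2^(j - 1)) > 0
  for (mask in seq_len(nmask)) {
    H <- background
    on <- which(bits[mask, ])
    if (length(on)) H[, on] <- matrix(x[on], m, length(on), byrow = TRUE)
    v[mask] <- mean(predict_fn(H))
  }
  fact <- factorial(0:d)
  phi <- numeric(d)
  sizes <- rowSums(bits)
  for (j in seq_len(d)) {
    without <- which(!bits[, j])
    s <- sizes[without]
    w <- fact[s + 1] * fact[d - s] / fact[d + 1]
    phi[j] <- sum(w * (v[without + 2^(j - 1)] - v[without]))
  }
  names(phi) <- names(x) %||% colnames(background)
  list(contributions = phi, base_value = v[1],
       model_output = v[nmask])
}

#' Linear SHAP for the logistic member
#'
#' On the link scale the logistic model is additive, so the attribution has
#' the closed form `beta_j * (x_ij - mean_j)` with base
#' `beta_0 + sum(beta * mean)`. With `feature_means` equal to the
#' background column means this is exactly the marginal-expectation game.
#'
#' @param logistic_model list with `coef` and `intercept`.
#' @param X explained rows.
#' @param feature_means background/reference feature means (defaults to the
#'   column means of `X`).
#' @return an `attribution_matrix` (flavor `"linear"`, link scale).
#' @export
shap_linear <- function(logistic_model, X, feature_means = colMeans(X)) {
  cf <- logistic_model$coef
  X <- X[, names(cf), drop = FALSE]
  feature_means <- feature_means[names(cf)]
  contrib <- sweep(X, 2, feature_means, "-") %*% diag(cf, length(cf))
  colnames(contrib) <- names(cf)
  base <- unname(logistic_model$intercept + sum(cf * feature_means))
  new_attribution_matrix(contrib, base, base + rowSums(contrib), X, "linear")
}

#' Interventional TreeSHAP for the boosted-tree member
#'
#' Exact Shapley values of the marginal-expectation game for a tree
#' ensemble with explicit split structure, computed by enumerating
#' root-to-leaf paths and applying closed-form coalition weights per
#' (instance, background row) pair. Attribution is on the margin (log-odds)
#' scale, before calibration.
#'
#' @param tree_model booster as stored in a `calibrated_ensemble`
#'   (`$tree_model`), or the ensemble itself.
#' @param X explained rows.
#' @param background background sample matrix.
#' @return an `attribution_matrix` (flavor `"tree"`, margin scale).
#' @export
shap_tree <- function(tree_model, X, background) {
  if (inherits(tree_model, "calibrated_ensemble"))
    tree_model <- tree_model$tree_model
  if (!is.list(tree_model) || is.null(tree_model$roots))
    stop("tree_model must be a fitted booster with explicit splits")
  X <- as.matrix(X); background <- as.matrix(background)
  res <- cpp_tree_shap(tree_model, X, background)
  contrib <- res$phi
  colnames(contrib) <- colnames(X)
  out <- cpp_boost_predict(tree_model, X)
  new_attribution_matrix(contrib, res$base, out, X, "tree")
}

#' Model-agnostic marginal SHAP by permutation sampling
#'
#' Estimates the same marginal-expectation game for an arbitrary score
#' function (by default the soft-voting ensemble's probability output).
#' Each sampled permutation walks features from a background row to the
#' explained row; marginal gains telescope, so additivity
#' `base + sum(contributions) = predict_fn(x)` holds exactly for the
#' returned averages. Per-row, per-feature Monte Carlo standard errors are
#' reported.
#'
#' @param predict_fn function(matrix) -> numeric scores.
#' @param X explained rows.
#' @param background background sample matrix.
#' @param n_samples number of sampled permutations (>= 10).
#' @param seed integer seed (same seed, same matrix).
#' @param groups optional named list mapping group name -> column indices
#'   (or names): grouped columns (e.g. the one-hot block of one
#'   categorical) enter coalitions together and receive one contribution
#'   column. Default: every column is its own group.
#' @return an `attribution_matrix` (flavor `"marginal"`) with `se`.
#' @export
shap_marginal <- function(predict_fn, X, background, n_samples = 64,
                          seed = 1L, groups = NULL) {
  if (n_samples < 10) stop("n_samples must be at least 10")
  X <- as.matrix(X); background <- as.matrix(background)
  n <- nrow(X); d <- ncol(X)
  if (is.null(groups)) {
    groups <- as.list(seq_len(d))
    names(groups) <- colnames(X) %||% paste0("V", seq_len(d))
  }
  groups <- lapply(groups, function(g)
    if (is.character(g)) match(g, colnames(X)) else as.integer(g))
  G <- length(groups)
  sum1 <- matrix(0, n, G); sum2 <- matrix(0, n, G)
  base_acc <- 0
  with_seed(seed, {
    for (t in seq_len(n_samples)) {
      ord <- sample.int(G)
      b <- background[sample.int(nrow(background), 1), ]
      cur <- matrix(b, n, d, byrow = TRUE)
      colnames(cur) <- colnames(X)
      prev <- predict_fn(cur)
      base_acc <- base_acc + prev[1] # all rows identical here
      for (g in ord) {
        idx <- groups[[g]]
        cur[, idx] <- X[, idx]
        sc <- predict_fn(cur)
        gain <- sc - prev
        sum1[, g] <- sum1[, g] + gain
        sum2[, g] <- sum2[, g] + gain^2
        prev <- sc
      }
    }
  })
  contrib <- sum1 / n_samples
  se <- sqrt(pmax(sum2 / n_samples - contrib^2, 0) / n_samples)
  colnames(contrib) <- colnames(se) <- names(groups)
  base <- base_acc / n_samples
  fv <- vapply(groups, function(idx)
    if (length(idx) == 1) X[, idx] else rowSums(X[, idx, drop = FALSE]),
    numeric(n))
  colnames(fv) <- names(groups)
  new_attribution_matrix(contrib, base, predict_fn(X), fv, "marginal", se)
}

#' Group attributions by level and rank by mean absolute impact
#'
#' @param attr an `attribution_matrix`.
#' @param group_map named character vector mapping every feature column of
#'   `attr` to a group (e.g. `"individual"` / `"school"`).
#' @return data.frame (group, feature, mean_abs_contribution, rank within
#'   group), features sorted by impact within each group.
#' @export
summary_ranking <- function(attr, group_map) {
  feats <- colnames(attr$contributions)
  missing <- setdiff(feats, names(group_map))
  if (length(missing))
    stop("features missing from group_map: ", paste(missing, collapse = ", "))
  imp <- colMeans(abs(attr$contributions))
  out <- do.call(rbind, lapply(unique(group_map[feats]), function(g) {
    f <- feats[group_map[feats] == g]
    o <- order(-imp[f], match(f, feats)) # stable: ties keep column order
    data.frame(group = g, feature = f[o],
               mean_abs_contribution = unname(imp[f][o]),
               rank = seq_along(f))
  }))
  rownames(out) <- NULL
  out
}

#' Collapse encoded-column attributions onto parent raw features
#'
#' One-hot indicator columns of one categorical variable are summed into a
#' single column so attributions can be read at the raw-feature level.
#'
#' @param attr an `attribution_matrix` over encoded columns.
#' @param parent named character vector: encoded column -> parent feature
#'   (see [encoded_parent()]).
#' @return an `attribution_matrix` over parent features.
#' @export
collapse_attributions <- function(attr, parent) {
  cols <- colnames(attr$contributions)
  p <- parent[cols]
  groups <- unique(p)
  contrib <- vapply(groups, function(g)
    rowSums(attr$contributions[, p == g, drop = FALSE]),
    numeric(nrow(attr$contributions)))
  colnames(contrib) <- groups
  fv <- attr$feature_values
  fv_parent <- vapply(groups, function(g) {
    sub <- which(p == g)
    if (length(sub) == 1) fv[, sub] else rowSums(fv[, sub, drop = FALSE])
  }, numeric(nrow(fv)))
  colnames(fv_parent) <- groups
  new_attribution_matrix(contrib, attr$base_value, attr$model_outputs,
                         fv_parent, attr$flavor)
}

#' Write an attribution matrix to CSV + JSON sidecar
#'
#' @param attr an `attribution_matrix`.
#' @param csv_path contributions CSV path.
#' @param json_path sidecar path (base value, flavor, dimensions).
#' @return invisibly, the two paths.
#' @export
write_attributions <- function(attr, csv_path, json_path) {
  write.csv(as.data.frame(attr$contributions), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(base_value = attr$base_value, flavor = attr$flavor,
         n_instances = nrow(attr$contributions),
         n_features = ncol(attr$contributions)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv_path, json_path))
}
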