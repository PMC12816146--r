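# Supervised clustering tree over SHAP attributions.
#
# Instances are partitioned recursively in attribution space: at each node,
# PCA reduces the node's SHAP rows to a few components, a seeded
# centroid-based clustering (k-means, 10 restarts) proposes partitions for
# each candidate k, and a split is accepted only when its silhouette score
# clears the gate. Leaves are labeled high / average / low by their outcome
# prevalence relative to the overall rate. Clustering model explanations
# rather than raw features yields partitions aligned with the predictive
# structure of the data.

#' Parameters of the supervised clustering tree
#'
#' @param max_components PCA component cap per node (default 3, matching
#'   3-D branch views).
#' @param variance_target cumulative variance fraction the retained
#'   components must reach (default 0.9), subject to the cap.
#' @param candidate_k candidate cluster counts per split (default `c(2,3)`).
#' @param min_silhouette silhouette gate for accepting a split (default
#'   0.4).
#' @param min_node_size smallest node eligible for splitting (default 50).
#' @param max_depth maximum tree depth (default 4; root is depth 0).
#' @param high_factor,low_factor prevalence multipliers defining the
#'   high / low leaf labels (defaults 2.0 and 0.5).
#' @param seed integer seed for the clustering restarts.
#' @return object of class `cluster_tree_params`.
#' @export
cluster_tree_params <- function(max_components = 3, variance_target = 0.9,
                                candidate_k = c(2, 3), min_silhouette = 0.4,
                                min_node_size = 50, max_depth = 4,
                                high_factor = 2.0, low_factor = 0.5,
                                seed = 1L) {
  stopifnot(min_silhouette > -1, min_silhouette < 1,
            low_factor < 1, high_factor > 1,
            all(candidate_k >= 2), max_components >= 1)
  structure(list(max_components = max_components,
                 variance_target = variance_target,
                 candidate_k = as.integer(candidate_k),
                 min_silhouette = min_silhouette,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 high_factor = high_factor, low_factor = low_factor,
                 seed = as.integer(seed)), class = "cluster_tree_params")
}

#' Mean silhouette width
#'
#' `mean((b - a) / max(a, b))` over points, where `a` is the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster (Euclidean metric). Points in singleton clusters score 0.
#'
#' @param points numeric matrix (rows = points).
#' @param labels cluster assignment (one of >= 2 distinct values).
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labs <- as.integer(factor(labels))
  k <- max(labs)
  if (k < 2) stop("silhouette requires at least 2 clusters")
  stopifnot(length(labs) == nrow(points))
  cpp_silhouette(points, labs - 1L, k)
}

#' PCA on a node's attribution rows
#'
#' Rows are centered within the node; the smallest component count whose
#' cumulative variance share reaches `variance_target` is kept, capped at
#' `max_components`. A zero-variance node yields `NULL` (it becomes a
#' leaf).
#'
#' @param attr_rows numeric matrix of SHAP rows at the node.
#' @param params a `cluster_tree_params`.
#' @return list with `basis` (loadings), `projections`,
#'   `variance_explained`; or `NULL` for a degenerate node.
#' @export
node_pca <- function(attr_rows, params) {
  attr_rows <- as.matrix(attr_rows)
  keep <- apply(attr_rows, 2, sd) > 0
  if (!any(keep)) return(NULL)
  pc <- prcomp(attr_rows[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  vshare <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(vshare) >= params$variance_target)[1]
  if (is.na(ncomp)) ncomp <- length(vshare)
  ncomp <- min(ncomp, params$max_components, ncol(pc$x))
  list(basis = pc$rotation[, seq_len(ncomp), drop = FALSE],
       projections = pc$x[, seq_len(ncomp), drop = FALSE],
       variance_explained = sum(vshare[seq_len(ncomp)]))
}

#' Propose and gate a split of one node
#'
#' For each candidate k, runs seeded k-means (10 restarts) on the node's
#' PCA projections; a k producing any cluster smaller than 3 is
#' disqualified. The k with the best silhouette wins, and the split is
#' accepted only when that silhouette reaches `min_silhouette`.
#'
#' @param projections node PCA projections.
#' @param params a `cluster_tree_params`.
#' @param node_seed seed for this node's restarts.
#' @return list with `accepted`, `labels`, `k`, `silhouette`; labels are
#'   `NULL` when no candidate qualifies.
#' @export
split_node <- function(projections, params, node_seed = params$seed) {
  best <- list(accepted = FALSE, labels = NULL, k = NA_integer_,
               silhouette = -Inf)
  for (k in params$candidate_k) {
    if (nrow(projections) <= k) next
    km <- try(with_seed(node_seed + k,
                        kmeans(projections, centers = k, nstart = 10,
                               iter.max = 50)), silent = TRUE)
    if (inherits(km, "try-error")) next
    if (min(table(km$cluster)) < 3) next
    sil <- silhouette_score(projections, km$cluster)
    if (sil > best$silhouette)
      best <- list(accepted = FALSE, labels = km$cluster, k = k,
                   silhouette = sil)
  }
  if (is.finite(best$silhouette) &&
      best$silhouette >= params$min_silhouette)
    best$accepted <- TRUE
  if (!best$accepted) best$labels <- NULL
  best
}

#' @noRd
prevalence_label <- function(prev, overall, params) {
  if (prev >= params$high_factor * overall) "high"
  else if (prev <= params$low_factor * overall) "low"
  else "average"
}

#' Build the supervised clustering tree
#'
#' Recursive PCA + gated clustering from the root (all instances) down.
#' Every leaf is labeled by its outcome prevalence relative to the overall
#' prevalence using the high/low factors.
#'
#' @param attr an `attribution_matrix` whose rows align with `y`.
#' @param y binary outcome vector.
#' @param params a `cluster_tree_params`.
#' @return root `cluster_node`: nested list with `member_indices`, `depth`,
#'   `children`, `silhouette`, `prevalence`, `label` (leaves), `leaf_id`.
#' @export
build_cluster_tree <- function(attr, y, params = cluster_tree_params()) {
  stopifnot(inherits(attr, "attribution_matrix"))
  y <- as.numeric(y)
  stopifnot(nrow(attr$contributions) == length(y))
  overall <- mean(y)
  if (overall <= 0 || overall >= 1)
    stop("overall prevalence must lie strictly in (0, 1)")
  leaf_counter <- new.env()
  leaf_counter$n <- 0L

  grow <- function(members, depth, node_seed) {
    node <- list(member_indices = members, depth = depth,
                 prevalence = mean(y[members]), silhouette = NA_real_,
                 children = list(), label = NA_character_,
                 leaf_id = NA_integer_)
    make_leaf <- function(node) {
      node$label <- prevalence_label(node$prevalence, overall, params)
      leaf_counter$n <- leaf_counter$n + 1L
      node$leaf_id <- leaf_counter$n
      node
    }
    if (depth >= params$max_depth || length(members) < params$min_node_size)
      return(make_leaf(node))
    pca <- node_pca(attr$contributions[members, , drop = FALSE], params)
    if (is.null(pca)) {
      ds_log("cluster", "zero-variance node at depth ", depth, "; leaf")
      return(make_leaf(node))
    }
    sp <- split_node(pca$projections, params, node_seed = node_seed)
    if (!sp$accepted) return(make_leaf(node))
    node$silhouette <- sp$silhouette
    node$pca_basis <- pca$basis
    node$k <- sp$k
    for (cl in sort(unique(sp$labels))) {
      child_members <- members[sp$labels == cl]
      node$children[[length(node$children) + 1]] <-
        grow(child_members, depth + 1,
             derive_seed(node_seed, 1000 * depth + cl))
    }
    node
  }
  root <- grow(seq_along(y), 0L, params$seed)
  structure(list(root = root, overall_prevalence = overall,
                 params = params, n = length(y)), class = "cluster_tree")
}

#' @noRd
collect_leaves <- function(node) {
  if (length(node$children) == 0) return(list(node))
  do.call(c, lapply(node$children, collect_leaves))
}

#' @noRd
collect_internal <- function(node) {
  if (length(node$children) == 0) return(list())
  c(list(node), do.call(c, lapply(node$children, collect_internal)))
}

#' Flat leaf assignment of a cluster tree
#'
#' @param tree a `cluster_tree`.
#' @return data.frame (instance, leaf_id, label, prevalence) covering every
#'   instance exactly once.
#' @export
leaf_assignments <- function(tree) {
  leaves <- collect_leaves(tree$root)
  out <- do.call(rbind, lapply(leaves, function(l)
    data.frame(instance = l$member_indices, leaf_id = l$leaf_id,
               label = l$label, prevalence = l$prevalence)))
  out[order(out$instance), , drop = FALSE]
}

#' @export
print.cluster_tree <- function(x, ...) {
  leaves <- collect_leaves(x$root)
  cat(sprintf("Supervised clustering tree: n = %d, overall prevalence %.4f\n",
              x$n, x$overall_prevalence))
  for (l in leaves)
    cat(sprintf("  leaf %d: n = %5d, prevalence %.4f [%s]\n", l$leaf_id,
                length(l$member_indices), l$prevalence, l$label))
  invisible(x)
}

#' Driver features of high-prevalence leaves
#'
#' For each leaf labeled high, ranks features by mean signed SHAP
#' contribution among its members (descending), with dispersion summaries.
#'
#' @param tree a `cluster_tree` built from `attr`.
#' @param attr the `attribution_matrix` the tree was built from.
#' @param top_n number of features reported per leaf.
#' @return data.frame (leaf_id, feature, mean_contribution,
#'   sd_contribution, rank); empty when no leaf is labeled high.
#' @export
summarize_high_prevalence <- function(tree, attr, top_n = 10) {
  stopifnot(nrow(attr$contributions) == tree$n)
  leaves <- Filter(function(l) identical(l$label, "high"),
                   collect_leaves(tree$root))
  if (length(leaves) == 0)
    return(data.frame(leaf_id = integer(0), feature = character(0),
                      mean_contribution = numeric(0),
                      sd_contribution = numeric(0), rank = integer(0)))
  out <- do.call(rbind, lapply(leaves, function(l) {
    sub <- attr$contributions[l$member_indices, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, sd)
    o <- order(-mu, match(colnames(sub), colnames(sub)))[seq_len(
      min(top_n, ncol(sub)))]
    data.frame(leaf_id = l$leaf_id, feature = colnames(sub)[o],
               mean_contribution = unname(mu[o]),
               sd_contribution = unname(sdv[o]),
               rank = seq_along(o))
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a cluster tree to nested JSON
#'
#' @param tree a `cluster_tree`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_cluster_tree <- function(tree, path) {
  strip <- function(node) {
    out <- list(n = length(node$member_indices),
                member_indices = node$member_indices,
                depth = node$depth, prevalence = node$prevalence)
    if (!is.na(node$silhouette)) out$silhouette <- node$silhouette
    if (!is.na(node$label)) {
      out$label <- node$label
      out$leaf_id <- node$leaf_id
    }
    if (length(node$children))
      out$children <- lapply(node$children, strip)
    out
  }
  jsonlite::write_json(
    list(overall_prevalence = tree$overall_prevalence, n = tree$n,
         params = unclass(tree$params), root = strip(tree$root)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
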