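# Plot-ready visualization data products (dependence, heatmap, force) and
# the end-to-end pipeline runner. Reports are numbers, not pixels: every
# figure-backing table is emitted as CSV/JSON so tests can assert on it.

#' SHAP dependence table
#'
#' One row per explained instance: the feature's raw value, its SHAP
#' contribution, and the value of an interaction feature. With
#' `interaction = "auto"` the interaction is the other feature whose raw
#' values have the strongest absolute Spearman correlation with the target
#' feature's contributions.
#'
#' @param attr an `attribution_matrix`.
#' @param feature explained feature name.
#' @param interaction feature name or `"auto"`.
#' @return data.frame (value, contribution, interaction_value) plus an
#'   `interaction` attribute naming the chosen feature.
#' @export
dependence_table <- function(attr, feature, interaction = "auto") {
  feats <- colnames(attr$contributions)
  if (!feature %in% feats) stop("unknown feature: ", feature)
  contrib <- attr$contributions[, feature]
  if (identical(interaction, "auto")) {
    others <- setdiff(feats, feature)
    rho <- vapply(others, function(f) {
      v <- attr$feature_values[, f]
      if (sd(v) == 0 || sd(contrib) == 0) return(0)
      abs(cor(rank(v), rank(contrib)))
    }, numeric(1))
    interaction <- others[which.max(rho)]
  } else if (!interaction %in% feats) {
    stop("unknown interaction feature: ", interaction)
  }
  out <- data.frame(value = attr$feature_values[, feature],
                    contribution = contrib,
                    interaction_value = attr$feature_values[, interaction])
  attr(out, "interaction") <- interaction
  out
}

#' SHAP heatmap layout
#'
#' Instances sorted by model output (descending), features by mean
#' absolute contribution (descending); the emitted slice is aligned to both
#' orders.
#'
#' @param attr an `attribution_matrix`.
#' @param top_features number of features kept (at most the feature count).
#' @return list with `instance_order`, `feature_order`, `matrix`.
#' @export
heatmap_layout <- function(attr, top_features = 10) {
  stopifnot(top_features <= ncol(attr$contributions))
  inst <- order(attr$model_outputs, decreasing = TRUE)
  imp <- colMeans(abs(attr$contributions))
  feat <- order(imp, decreasing = TRUE)[seq_len(top_features)]
  list(instance_order = inst,
       feature_order = colnames(attr$contributions)[feat],
       matrix = attr$contributions[inst, feat, drop = FALSE])
}

#' Force-plot decomposition of a single prediction
#'
#' @param attr an `attribution_matrix`.
#' @param instance row index.
#' @return list with `contributions` (sorted by absolute value,
#'   descending), `base_value`, `model_output`.
#' @export
force_decomposition <- function(attr, instance) {
  n <- nrow(attr$contributions)
  if (!is.numeric(instance) || instance < 1 || instance > n)
    stop("instance index out of range [1, ", n, "]")
  phi <- attr$contributions[instance, ]
  o <- order(-abs(phi), seq_along(phi))
  list(contributions = phi[o], base_value = attr$base_value,
       model_output = attr$model_outputs[instance])
}

#' End-to-end pipeline configuration
#'
#' Every stage seed derives deterministically from `base_seed`.
#'
#' @param cohort a [cohort_config()] (its seed is overridden by
#'   `base_seed`).
#' @param outcomes outcome names to analyze.
#' @param n_iterations,train_frac Monte Carlo CV settings.
#' @param hyperparams ensemble hyperparameters (NULL = defaults).
#' @param sage_permutations,sage_background SAGE budget.
#' @param shap_flavor `"marginal"`, `"tree"` or `"linear"`.
#' @param shap_samples permutation budget for marginal SHAP.
#' @param shap_background background rows for attribution.
#' @param shap_max_rows cap on explained instances (subsampled, seeded).
#' @param inclusion_ks ks of the inclusion curve (NULL for an automatic
#'   grid).
#' @param cluster a [cluster_tree_params()].
#' @param base_seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            outcomes = names(cohort$target_prevalence),
                            n_iterations = 10, train_frac = 0.8,
                            hyperparams = NULL,
                            sage_permutations = 64, sage_background = 128,
                            shap_flavor = "marginal", shap_samples = 64,
                            shap_background = 128, shap_max_rows = 4000,
                            inclusion_ks = NULL,
                            cluster = cluster_tree_params(),
                            base_seed = 1L) {
  structure(list(cohort = cohort, outcomes = outcomes,
                 n_iterations = n_iterations, train_frac = train_frac,
                 hyperparams = hyperparams,
                 sage_permutations = sage_permutations,
                 sage_background = sage_background,
                 shap_flavor = shap_flavor, shap_samples = shap_samples,
                 shap_background = shap_background,
                 shap_max_rows = shap_max_rows,
                 inclusion_ks = inclusion_ks, cluster = cluster,
                 base_seed = as.integer(base_seed)),
            class = "pipeline_config")
}

#' Reference desk-scale pipeline configuration
#'
#' The seed-fixed configuration the recovery suite runs end to end:
#' n = 20,000 dentists with the default planted effects and 10 CV
#' iterations. Boosting is scaled to 200 rounds with 3 calibration folds
#' (package defaults are 300/5) so the full run fits a single-CPU desk
#' budget; this is a compute scale-down only and does not alter the
#' simulated world.
#'
#' @param base_seed master seed.
#' @return a `pipeline_config`.
#' @export
reference_pipeline_config <- function(base_seed = 1L) {
  pipeline_config(
    cohort = cohort_config(n_dentists = 20000),
    n_iterations = 10,
    hyperparams = list(nrounds = 200L, calib_folds = 3L),
    sage_permutations = 64, sage_background = 128,
    shap_flavor = "marginal", shap_samples = 64, shap_background = 128,
    shap_max_rows = 4000,
    base_seed = base_seed)
}

#' @noRd
manifest_add <- function(manifest, stage, path) {
  manifest[[length(manifest) + 1]] <- list(
    stage = stage, file = basename(path),
    md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> Monte Carlo CV -> SAGE + inclusion curve ->
#' top-k refit -> SHAP -> supervised cluster tree -> report files, per
#' outcome. A manifest records every artifact with a content hash, so two
#' runs of the same config produce byte-identical manifests.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @return invisibly, a list with per-outcome results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  base_seed <- config$base_seed

  ds_log("pipeline", "config: seed ", base_seed, ", n = ",
         config$cohort$n_dentists, ", outcomes: ",
         paste(config$outcomes, collapse = ", "))

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(base_seed, 1)
  ds_log("simulate", "generating cohort (n = ", cohort_cfg$n_dentists, ")")
  cohort <- generate_cohort(cohort_cfg)
  paths <- write_cohort(cohort, out_dir)
  for (p in paths) manifest <- manifest_add(manifest, "simulate", p)

  results <- list()
  for (oc in config$outcomes) {
    y <- cohort$outcomes[[oc]]
    ds_log(oc, "Monte Carlo CV (", config$n_iterations, " iterations)")
    cv <- monte_carlo_cv(cohort$features, y,
                         n_iterations = config$n_iterations,
                         train_frac = config$train_frac,
                         base_seed = derive_seed(base_seed, 10),
                         hyperparams = config$hyperparams, boot = 200)
    cv_path <- file.path(out_dir, paste0(oc, "_cv.json"))
    write_cv_report(cv, cv_path)
    manifest <- manifest_add(manifest, paste0(oc, ":cv"), cv_path)

    # single fixed split for the explainability stages
    split_seed <- derive_seed(base_seed, 20)
    n <- nrow(cohort$features)
    idx <- with_seed(split_seed, sample.int(n, size = round(0.8 * n)))
    plan <- fit_preprocess(cohort$features[idx, , drop = FALSE])
    plan_path <- file.path(out_dir, paste0(oc, "_plan.json"))
    write_preprocess_plan(plan, plan_path)
    manifest <- manifest_add(manifest, paste0(oc, ":plan"), plan_path)
    Xtr <- apply_preprocess(plan, cohort$features[idx, , drop = FALSE])
    Xte <- apply_preprocess(plan, cohort$features[-idx, , drop = FALSE])
    ens <- fit_ensemble(Xtr, y[idx], seed = split_seed,
                        hyperparams = config$hyperparams)

    ds_log(oc, "SAGE (", config$sage_permutations, " permutations)")
    bg_idx <- with_seed(derive_seed(base_seed, 30),
                        sample.int(nrow(Xtr),
                                   min(config$sage_background, nrow(Xtr))))
    parent <- encoded_parent(plan)
    groups <- split(seq_along(parent), parent[colnames(Xtr)])
    sage <- sage_auc(function(M) predict(ens, M), Xte, y[-idx],
                     background = Xtr[bg_idx, , drop = FALSE],
                     n_permutations = config$sage_permutations,
                     seed = derive_seed(base_seed, 31), groups = groups)
    sage_path <- file.path(out_dir, paste0(oc, "_sage.json"))
    jsonlite::write_json(list(values = as.list(sage$values),
                              standard_errors = as.list(sage$standard_errors),
                              full_auc = sage$full_auc,
                              baseline_auc = sage$baseline_auc),
                         sage_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest <- manifest_add(manifest, paste0(oc, ":sage"), sage_path)

    ranking <- names(sage$values)
    ks <- config$inclusion_ks %||%
      unique(pmin(c(2, 4, 6, 9, 12, length(ranking)), length(ranking)))
    ds_log(oc, "inclusion curve (k = ", paste(ks, collapse = ","), ")")
    curve <- inclusion_curve(cohort$features, y, ranking, ks,
                             cv_seed = derive_seed(base_seed, 40),
                             hyperparams = config$hyperparams)
    top_k <- select_top_k(curve)
    curve_path <- file.path(out_dir, paste0(oc, "_inclusion.csv"))
    write.csv(cbind(curve$curve, selected_k = top_k), curve_path,
              row.names = FALSE)
    manifest <- manifest_add(manifest, paste0(oc, ":inclusion"), curve_path)

    ds_log(oc, "SHAP attribution (", config$shap_flavor, ")")
    Xall <- apply_preprocess(plan, cohort$features)
    keep <- if (nrow(Xall) > config$shap_max_rows)
      with_seed(derive_seed(base_seed, 50),
                sort(sample.int(nrow(Xall), config$shap_max_rows)))
    else seq_len(nrow(Xall))
    bg2 <- Xtr[with_seed(derive_seed(base_seed, 51),
                         sample.int(nrow(Xtr),
                                    min(config$shap_background, nrow(Xtr)))),
               , drop = FALSE]
    attr_parent <- switch(config$shap_flavor,
      # marginal SHAP walks parent-feature groups directly
      marginal = shap_marginal(function(M) predict(ens, M),
                               Xall[keep, , drop = FALSE], bg2,
                               n_samples = config$shap_samples,
                               seed = derive_seed(base_seed, 52),
                               groups = groups),
      tree = collapse_attributions(
        shap_tree(ens, Xall[keep, , drop = FALSE], bg2), parent),
      linear = collapse_attributions(
        shap_linear(ens$logistic_model, Xall[keep, , drop = FALSE],
                    colMeans(bg2)), parent),
      stop("unknown shap flavor: ", config$shap_flavor))
    # parent-level raw feature values for dependence plots
    for (f in colnames(attr_parent$feature_values))
      if (f %in% names(cohort$features) &&
          is.numeric(cohort$features[[f]]))
        attr_parent$feature_values[, f] <- cohort$features[[f]][keep]
    shap_csv <- file.path(out_dir, paste0(oc, "_shap.csv"))
    shap_json <- file.path(out_dir, paste0(oc, "_shap.json"))
    write_attributions(attr_parent, shap_csv, shap_json)
    manifest <- manifest_add(manifest, paste0(oc, ":shap"), shap_csv)
    manifest <- manifest_add(manifest, paste0(oc, ":shap"), shap_json)

    dep <- dependence_table(attr_parent, "debt", interaction = "race")
    dep_path <- file.path(out_dir, paste0(oc, "_dependence_debt.csv"))
    write.csv(dep, dep_path, row.names = FALSE)
    manifest <- manifest_add(manifest, paste0(oc, ":dependence"), dep_path)

    # tree-member dependence (TreeSHAP, margin scale): the linear logistic
    # member cannot represent nonlinear debt response, so curve-shaped
    # dependence reads are made on the member able to bend
    attr_tree <- collapse_attributions(
      shap_tree(ens, Xall[keep, , drop = FALSE],
                bg2[seq_len(min(64, nrow(bg2))), , drop = FALSE]), parent)
    for (f in colnames(attr_tree$feature_values))
      if (f %in% names(cohort$features) && is.numeric(cohort$features[[f]]))
        attr_tree$feature_values[, f] <- cohort$features[[f]][keep]
    dep_tree <- dependence_table(attr_tree, "debt", interaction = "race")
    dep_tree_path <- file.path(out_dir,
                               paste0(oc, "_dependence_debt_tree.csv"))
    write.csv(dep_tree, dep_tree_path, row.names = FALSE)
    manifest <- manifest_add(manifest, paste0(oc, ":dependence"),
                             dep_tree_path)

    hm <- heatmap_layout(attr_parent,
                         min(10, ncol(attr_parent$contributions)))
    hm_path <- file.path(out_dir, paste0(oc, "_heatmap.csv"))
    write.csv(hm$matrix, hm_path, row.names = FALSE)
    manifest <- manifest_add(manifest, paste0(oc, ":heatmap"), hm_path)

    ds_log(oc, "supervised cluster tree")
    cl_params <- config$cluster
    cl_params$seed <- derive_seed(base_seed, 60)
    tree <- build_cluster_tree(attr_parent, y[keep], cl_params)
    tree_path <- file.path(out_dir, paste0(oc, "_cluster_tree.json"))
    write_cluster_tree(tree, tree_path)
    manifest <- manifest_add(manifest, paste0(oc, ":cluster"), tree_path)
    assign_path <- file.path(out_dir, paste0(oc, "_leaf_assignments.csv"))
    write.csv(leaf_assignments(tree), assign_path, row.names = FALSE)
    manifest <- manifest_add(manifest, paste0(oc, ":cluster"), assign_path)
    drivers <- summarize_high_prevalence(tree, attr_parent)
    drv_path <- file.path(out_dir, paste0(oc, "_high_cluster_drivers.csv"))
    write.csv(drivers, drv_path, row.names = FALSE)
    manifest <- manifest_add(manifest, paste0(oc, ":cluster"), drv_path)

    results[[oc]] <- list(cv = cv, sage = sage, inclusion = curve,
                          top_k = top_k, attr = attr_parent,
                          attr_tree = attr_tree, attr_rows = keep,
                          tree = tree, drivers = drivers,
                          plan = plan, ensemble = ens,
                          test_idx = setdiff(seq_len(n), idx))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ds_log("pipeline", "done; manifest at ", manifest_path)
  invisible(list(cohort = cohort, results = results, manifest = manifest,
                 manifest_path = manifest_path))
}
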