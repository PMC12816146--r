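# Training-only preprocessing: missingness filter (> 60% missing), variable
# collinearity filter (|r| > 0.8), median imputation, one-hot encoding with
# an explicit "<missing>" level, and z-score standardization. All statistics
# are computed on the fitting table only, so applying a fitted plan to held
# out data leaks nothing.

#' Greedy pairwise correlation filter
#'
#' Scans columns in order; a later column whose absolute Pearson correlation
#' with any already-kept column exceeds the threshold is dropped (the
#' earlier column wins). Correlation with a zero-variance column is defined
#' as 0 and never triggers the filter.
#'
#' @param mat numeric matrix with at least 2 columns.
#' @param corr_thresh threshold in (0, 1].
#' @return list with `kept`, `dropped` (column names) and `pairs`, a
#'   data.frame of (kept, dropped, correlation) decisions.
#' @export
pairwise_correlation_filter <- function(mat, corr_thresh = 0.8) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  nms <- colnames(mat) %||% paste0("V", seq_len(ncol(mat)))
  sds <- apply(mat, 2, sd)
  kept <- character(0)
  pairs <- list()
  for (j in seq_len(ncol(mat))) {
    drop_for <- NULL
    if (sds[j] > 0) {
      for (k in kept) {
        ki <- match(k, nms)
        if (sds[ki] == 0) next
        r <- cor(mat[, j], mat[, ki])
        if (is.finite(r) && abs(r) > corr_thresh) {
          drop_for <- c(k, r)
          break
        }
      }
    }
    if (is.null(drop_for)) {
      kept <- c(kept, nms[j])
    } else {
      pairs[[length(pairs) + 1]] <-
        data.frame(kept = drop_for[1], dropped = nms[j],
                   correlation = as.numeric(drop_for[2]))
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(kept = character(0), dropped = character(0),
               correlation = numeric(0))
  list(kept = kept, dropped = setdiff(nms, kept), pairs = pairs)
}

#' Fit a preprocessing plan on a training table
#'
#' Columns with missing fraction above `missing_thresh` are dropped first;
#' collinear continuous variables (|Pearson r| above `corr_thresh` after
#' median imputation) are then filtered greedily. Medians are computed on
#' observed values only. Every categorical column gets its observed levels
#' plus an explicit `"<missing>"` level, which also absorbs unseen levels
#' at apply time. Post-encoding means/SDs are recorded for z-scoring.
#'
#' @param train data.frame of raw features (numeric and character/factor
#'   columns).
#' @param missing_thresh drop threshold on the missing fraction (default
#'   0.6).
#' @param corr_thresh drop threshold on absolute pairwise correlation
#'   (default 0.8).
#' @return object of class `preprocess_plan`.
#' @export
fit_preprocess <- function(train, missing_thresh = 0.6, corr_thresh = 0.8) {
  stopifnot(is.data.frame(train), nrow(train) > 0)
  if (missing_thresh <= 0 || missing_thresh > 1 ||
      corr_thresh <= 0 || corr_thresh > 1)
    stop("thresholds must lie in (0, 1]")

  miss_frac <- vapply(train, function(x) mean(is.na(x)), numeric(1))
  dropped_missingness <- names(train)[miss_frac > missing_thresh]
  keep <- setdiff(names(train), dropped_missingness)
  if (length(keep) == 0)
    stop("all ", ncol(train), " columns exceed the missingness threshold (",
         missing_thresh, "); nothing left to fit")
  tab <- train[keep]

  is_cont <- vapply(tab, is.numeric, logical(1))
  cont_cols <- names(tab)[is_cont]
  cat_cols <- names(tab)[!is_cont]

  medians <- vapply(cont_cols, function(cn)
    median(tab[[cn]], na.rm = TRUE), numeric(1))

  dropped_collinear <- data.frame(kept = character(0), dropped = character(0),
                                  correlation = numeric(0))
  if (length(cont_cols) >= 2) {
    imp <- vapply(cont_cols, function(cn) {
      x <- tab[[cn]]
      x[is.na(x)] <- medians[[cn]]
      x
    }, numeric(nrow(tab)))
    flt <- pairwise_correlation_filter(imp, corr_thresh)
    dropped_collinear <- flt$pairs
    cont_cols <- flt$kept
    medians <- medians[cont_cols]
  }

  category_levels <- lapply(cat_cols, function(cn) {
    lv <- sort(unique(as.character(tab[[cn]][!is.na(tab[[cn]])])))
    c(lv, "<missing>")
  })
  names(category_levels) <- cat_cols

  plan <- structure(list(dropped_missingness = dropped_missingness,
                         dropped_collinear = dropped_collinear,
                         medians = medians,
                         category_levels = category_levels,
                         column_order = c(cont_cols, cat_cols),
                         standardization = NULL),
                    class = "preprocess_plan")
  enc <- encode_table(plan, train)
  mu <- colMeans(enc)
  sdv <- apply(enc, 2, sd)
  plan$standardization <- data.frame(column = colnames(enc),
                                     mean = unname(mu), sd = unname(sdv))
  zero <- sdv == 0
  if (any(zero))
    ds_log("preprocess", "zero-variance encoded columns scaled to zero: ",
           paste(colnames(enc)[zero], collapse = ", "))
  plan
}

#' Impute + one-hot encode (no scaling)
#' @noRd
encode_table <- function(plan, table) {
  missing_cols <- setdiff(plan$column_order, names(table))
  if (length(missing_cols))
    stop("expected columns absent from table: ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(table)
  cols <- list()
  for (cn in names(plan$medians)) {
    x <- as.numeric(table[[cn]])
    x[is.na(x)] <- plan$medians[[cn]]
    cols[[cn]] <- x
  }
  for (cn in names(plan$category_levels)) {
    lv <- plan$category_levels[[cn]]
    x <- as.character(table[[cn]])
    x[is.na(x) | !(x %in% lv)] <- "<missing>"
    for (l in lv) cols[[paste0(cn, "=", l)]] <- as.numeric(x == l)
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

#' Apply a fitted preprocessing plan
#'
#' Missing continuous values are replaced by the training medians;
#' categoricals are expanded to full indicator sets (no reference level
#' dropped; unseen and missing values hit the `"<missing>"` indicator);
#' every encoded column is centered and scaled by the training statistics.
#' Zero-variance columns become all-zero columns.
#'
#' @param plan a `preprocess_plan`.
#' @param table data.frame with at least the columns the plan expects.
#' @return numeric matrix with named columns and no missing values.
#' @export
apply_preprocess <- function(plan, table) {
  stopifnot(inherits(plan, "preprocess_plan"))
  enc <- encode_table(plan, table)
  st <- plan$standardization
  enc <- enc[, st$column, drop = FALSE]
  sdv <- ifelse(st$sd == 0, Inf, st$sd) # zero-variance -> all zeros
  out <- sweep(enc, 2, st$mean, "-")
  out <- sweep(out, 2, sdv, "/")
  out
}

#' Map encoded column names back to their parent feature
#' @param plan a `preprocess_plan`.
#' @return named character vector: encoded column -> parent feature name.
#' @export
encoded_parent <- function(plan) {
  cols <- plan$standardization$column
  parent <- sub("=.*$", "", cols)
  setNames(parent, cols)
}

#' Serialize a preprocessing plan to JSON
#' @param plan a `preprocess_plan`.
#' @param path file path to write.
#' @return invisibly, `path`.
#' @export
write_preprocess_plan <- function(plan, path) {
  obj <- unclass(plan)
  obj$medians <- as.list(obj$medians) # keep names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, dataframe = "columns")
  invisible(path)
}

#' Restore a preprocessing plan from JSON
#' @param path file written by [write_preprocess_plan()].
#' @return a `preprocess_plan`.
#' @export
read_preprocess_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$medians <- unlist(raw$medians) %||% numeric(0)
  raw$category_levels <- lapply(raw$category_levels, as.character)
  raw$standardization <- as.data.frame(raw$standardization)
  structure(raw, class = "preprocess_plan")
}
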