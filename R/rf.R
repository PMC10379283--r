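#' Random-forest configuration
#'
#' @param tree_grid candidate forest sizes for the out-of-bag RMSE grid
#'   search; strictly increasing, within `[10, 10000]`. The default is a
#'   log-spaced grid over the full searched range.
#' @param variables_per_split predictors tried at each split (`mtry`);
#'   defaults to `floor(sqrt(5)) = 2`, the standard regression-forest choice.
#' @param min_node_size minimal terminal node size (regression default 5).
#' @param seed base random seed; recorded in every fit and report. Jackknife
#'   refits use `seed + i` for held-out record `i`.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(tree_grid = c(10, 25, 50, 100, 250, 500, 1000, 2500, 5000, 10000),
                      variables_per_split = 2, min_node_size = 5, seed = 1) {
  if (length(tree_grid) == 0 || any(tree_grid < 10 | tree_grid > 10000)) {
    stop("tree_grid must lie within [10, 10000]")
  }
  if (is.unsorted(tree_grid, strictly = TRUE)) stop("tree_grid must be strictly increasing")
  structure(list(tree_grid = as.integer(tree_grid),
                 variables_per_split = as.integer(variables_per_split),
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Fit a regression forest of Ho on the five predictors
#'
#' Bootstrap-resampled regression forest; the out-of-bag (OOB) RMSE is
#' computed from out-of-bag predictions only, and variable importance is the
#' impurity (variance-reduction, "Gini") importance accumulated over all
#' splits. A constant response is handled on its trivial path: OOB RMSE 0
#' and all importances 0, since there is no variance to explain.
#'
#' @param table complete-case analysis table with `ho` and the five
#'   predictor columns.
#' @param n_trees forest size.
#' @param config an [rf_config()].
#' @return An object of class `rf_fit`: `n_trees`, `oob_rmse`,
#'   `importance_raw`, `model` (the underlying ranger object, `NULL` on the
#'   constant-response path along with `constant_value`), `seed`.
#' @export
fit_forest <- function(table, n_trees, config = rf_config()) {
  vars <- canonical_predictors()
  miss <- setdiff(c("ho", vars), names(table))
  if (length(miss)) stop("analysis table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(table) < 10) stop("insufficient records: need at least 10, have ", nrow(table))
  d <- table[c("ho", vars)]
  zeros <- stats::setNames(rep(0, length(vars)), vars)
  if (stats::sd(d$ho) == 0) {
    fit <- list(n_trees = as.integer(n_trees), oob_rmse = 0,
                importance_raw = zeros, model = NULL,
                constant_value = d$ho[1], seed = config$seed)
    class(fit) <- "rf_fit"
    return(fit)
  }
  m <- ranger::ranger(ho ~ ., data = d, num.trees = n_trees,
                      mtry = config$variables_per_split,
                      min.node.size = config$min_node_size,
                      importance = "impurity",
                      seed = config$seed, num.threads = 1,
                      oob.error = TRUE)
  fit <- list(n_trees = as.integer(n_trees),
              oob_rmse = sqrt(m$prediction.error),
              importance_raw = m$variable.importance[vars],
              model = m, constant_value = NULL, seed = config$seed)
  class(fit) <- "rf_fit"
  fit
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d trees, OOB RMSE %.4g\n", x$n_trees, x$oob_rmse))
  invisible(x)
}

# predict ho for new predictor rows from an rf_fit (handles the constant path)
predict_rf <- function(fit, newdata) {
  if (is.null(fit$model)) return(rep(fit$constant_value, nrow(newdata)))
  ranger::predictions(stats::predict(fit$model, data = newdata, num.threads = 1))
}

#' Grid search over forest sizes by out-of-bag RMSE
#'
#' Fits one forest per candidate size in `config$tree_grid` (all with the
#' same seed) and returns the fit minimizing the OOB RMSE; ties go to the
#' smallest forest. The per-candidate RMSEs are attached for the run report.
#'
#' @inheritParams fit_forest
#' @return The winning `rf_fit`, with a `grid` data frame attribute
#'   (`n_trees`, `oob_rmse` per candidate).
#' @export
grid_search_trees <- function(table, config = rf_config()) {
  fits <- lapply(config$tree_grid, function(nt) fit_forest(table, nt, config))
  rmses <- vapply(fits, function(f) f$oob_rmse, numeric(1))
  best <- fits[[which.min(rmses)]]   # which.min takes the first = smallest forest
  attr(best, "grid") <- data.frame(n_trees = config$tree_grid, oob_rmse = rmses)
  best
}

#' Jackknife (leave-one-out) validation of the regression
#'
#' For each record a forest of `n_trees` trees is fit on the remaining
#' records (sampling without replacement of records: each record is held out
#' exactly once) and predicts the held-out Ho. Suited to the small
#' per-species sample sizes (< 100) for which a train/test split would be
#' wasteful. Returns the held-out predictions, their RMSE against the
#' observed values, and the R-squared and p-value of the least-squares
#' regression of observed on predicted Ho.
#'
#' @inheritParams fit_forest
#' @param n_trees forest size for every refit (typically the grid-search
#'   winner's).
#' @return List with `predictions` (one per record, in input order), `rmse`,
#'   `r2`, `p_value`, `n`.
#' @export
jackknife_validate <- function(table, config = rf_config(), n_trees = 500) {
  n <- nrow(table)
  if (n < 3) stop("need at least 3 records for jackknife validation")
  preds <- vapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    fit <- fit_forest(table[-i, , drop = FALSE], n_trees, cfg_i)
    predict_rf(fit, table[i, , drop = FALSE])
  }, numeric(1))
  obs <- table$ho
  rmse <- sqrt(mean((preds - obs)^2))
  if (stats::sd(preds) == 0 || stats::sd(obs) == 0) {
    r2 <- if (rmse == 0) 1 else 0
    p <- NA_real_
  } else {
    lmfit <- stats::lm(obs ~ preds)
    sm <- summary(lmfit)
    r2 <- sm$r.squared
    p <- unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                          lower.tail = FALSE))
  }
  list(predictions = preds, rmse = rmse, r2 = r2, p_value = p, n = n)
}

#' Max-normalize impurity importances
#'
#' Divides each raw impurity importance by the maximum, so the most
#' important predictor scores exactly 1 — the scale on which per-species
#' importance columns are reported.
#'
#' @param importance_raw named numeric vector of raw impurity decreases.
#' @return Named numeric vector in `[0, 1]` with maximum 1.
#' @export
normalize_importance <- function(importance_raw) {
  if (all(importance_raw <= 0)) stop("degenerate importance vector: no positive importance")
  importance_raw / max(importance_raw)
}
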