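#' Project predicted Ho across the predictor grid under a validity mask
#'
#' Evaluates the fitted forest at every grid cell whose five predictor values
#' are all present, then blanks cells outside the MESS validity mask, so the
#' projected surface is restricted to conditions similar to those at the
#' training localities. Because a regression forest predicts averages of
#' leaf means, every finite projected value lies within the range of the
#' training Ho.
#'
#' @param fit an `rf_fit` from [fit_forest()] or [grid_search_trees()].
#' @param stack a [predictor_stack] co-registered with the mask.
#' @param mask a `validity_mask` from [validity_mask()], or `NULL` to skip
#'   masking (the unmasked surface, useful for inspecting what the mask
#'   removes).
#' @return A list of class `projection_result`: `predicted_ho` (a
#'   [grid_layer], nodata outside the mask or where any predictor is
#'   missing), `unmasked` (the same surface before masking), `mask`, and
#'   `n_predicted` (finite cells after masking).
#' @export
project_ho <- function(fit, stack, mask = NULL) {
  if (!inherits(stack, "predictor_stack")) stop("`stack` must be a predictor_stack")
  tmpl <- stack[[1]]
  if (!is.null(mask)) {
    if (!inherits(mask, "validity_mask")) stop("`mask` must be a validity_mask")
    if (!inherits(mask$keep, "grid_layer") || !same_geometry(mask$keep, tmpl)) {
      stop("mask grid does not match the predictor stack (shape/extent)")
    }
  }
  vars <- canonical_predictors()
  q <- sapply(vars, function(v) as.vector(t(stack[[v]]$values)))
  if (is.null(dim(q))) q <- matrix(q, nrow = 1, dimnames = list(NULL, vars))
  complete <- !apply(is.na(q), 1, any)
  pred <- rep(NA_real_, nrow(q))
  if (any(complete)) {
    nd <- as.data.frame(q[complete, , drop = FALSE])
    pred[complete] <- predict_rf(fit, nd)
  }
  to_layer <- function(vec) {
    grid_layer(matrix(vec, nrow = nrow(tmpl$values), byrow = TRUE),
               tmpl$xmin, tmpl$xmax, tmpl$ymin, tmpl$ymax, nodata = -9999)
  }
  unmasked <- to_layer(pred)
  masked_vec <- pred
  if (!is.null(mask)) {
    keep <- as.vector(t(mask$keep$values)) == 1
    masked_vec[!keep | is.na(keep)] <- NA_real_
  }
  structure(list(predicted_ho = to_layer(masked_vec), unmasked = unmasked,
                 mask = mask, n_predicted = sum(!is.na(masked_vec))),
            class = "projection_result")
}
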