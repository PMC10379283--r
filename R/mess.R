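#' Univariate environmental similarity of a point to a reference sample
#'
#' The building block of the Multivariate Environmental Similarity Surface
#' (MESS). With `f` the percentage of reference values strictly below `p`,
#' the similarity is the piecewise score
#' \itemize{
#'   \item `f = 0`: `100 * (p - min) / (max - min)` (zero at the reference
#'     minimum, negative below it),
#'   \item `0 < f <= 50`: `2 f`,
#'   \item `50 < f < 100`: `2 (100 - f)`,
#'   \item `f = 100`: `100 * (max - p) / (max - min)`.
#' }
#' Scores are on a percent scale: 100 at the reference median, 0 at the
#' range limits, negative outside the reference range (extrapolation).
#'
#' @param reference numeric vector of reference values (non-degenerate:
#'   `max > min`).
#' @param p numeric vector of query values.
#' @return Numeric vector of similarity scores, one per query value.
#' @export
similarity_univariate <- function(reference, p) {
  reference <- reference[!is.na(reference)]
  if (length(reference) == 0) stop("empty reference")
  rmin <- min(reference); rmax <- max(reference)
  if (rmax <= rmin) stop("degenerate reference variable (constant)")
  sorted <- sort(reference)
  n <- length(sorted)
  # strict less-than count per query value
  f <- 100 * findInterval(p, sorted, left.open = TRUE) / n
  out <- ifelse(f == 0, 100 * (p - rmin) / (rmax - rmin),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (rmax - p) / (rmax - rmin))))
  out[is.na(p)] <- NA_real_
  out
}

# core: reference and query as numeric matrices with identical column names
mess_core <- function(ref, query) {
  vars <- colnames(ref)
  per_variable <- sapply(vars, function(v) similarity_univariate(ref[, v], query[, v]))
  if (is.null(dim(per_variable))) per_variable <- matrix(per_variable, nrow = 1,
                                                         dimnames = list(NULL, vars))
  mess <- apply(per_variable, 1, min)
  list(per_variable = per_variable, mess = mess)
}

#' Multivariate Environmental Similarity Surface
#'
#' Scores every query cell (or point) against the training localities: the
#' MESS value is the minimum of the five univariate similarities
#' ([similarity_univariate()]). Negative values flag cells where at least one
#' predictor lies outside the range seen at the training localities, i.e.
#' where a projection would be extrapolation rather than prediction.
#'
#' @param reference_table the complete-case analysis table whose predictor
#'   columns define the reference sample (the localities used to train the
#'   regression), or a plain data frame/matrix with the predictor columns.
#' @param query a [predictor_stack] (cell-wise evaluation; nodata cells stay
#'   nodata) or a data frame/matrix of query points with the same predictor
#'   columns.
#' @return An object of class `mess_result`: `mess` (a [grid_layer] or a
#'   numeric vector, matching `query`), `per_variable` (list of layers or a
#'   matrix), and `reference_summary` (per-variable min/max/n).
#' @export
compute_mess <- function(reference_table, query) {
  vars <- canonical_predictors()
  ref_df <- as.data.frame(reference_table)
  have <- intersect(vars, names(ref_df))
  if (length(have) < length(vars)) {
    stop("reference table lacks predictor column(s): ",
         paste(setdiff(vars, have), collapse = ", "))
  }
  ref <- as.matrix(ref_df[vars])
  for (v in vars) {
    rv <- ref[, v]
    if (max(rv, na.rm = TRUE) <= min(rv, na.rm = TRUE)) {
      stop("degenerate reference variable (constant): ", v)
    }
  }
  reference_summary <- data.frame(
    variable = vars,
    min = apply(ref, 2, min), max = apply(ref, 2, max),
    n = nrow(ref), row.names = NULL)

  if (inherits(query, "predictor_stack")) {
    tmpl <- query[[1]]
    q <- sapply(vars, function(v) as.vector(t(query[[v]]$values)))
    if (is.null(dim(q))) q <- matrix(q, nrow = 1, dimnames = list(NULL, vars))
    valid <- !apply(is.na(q), 1, any)
    scores <- mess_core(ref, q[valid, , drop = FALSE])
    to_layer <- function(vec_valid) {
      full <- rep(NA_real_, nrow(q))
      full[valid] <- vec_valid
      grid_layer(matrix(full, nrow = nrow(tmpl$values), byrow = TRUE),
                 tmpl$xmin, tmpl$xmax, tmpl$ymin, tmpl$ymax, nodata = tmpl$nodata)
    }
    per_variable <- lapply(vars, function(v) to_layer(scores$per_variable[, v]))
    names(per_variable) <- vars
    out <- list(mess = to_layer(scores$mess), per_variable = per_variable,
                reference_summary = reference_summary)
  } else {
    q_df <- as.data.frame(query)
    miss <- setdiff(vars, names(q_df))
    if (length(miss)) stop("query lacks predictor column(s): ",
                           paste(miss, collapse = ", "))
    scores <- mess_core(ref, as.matrix(q_df[vars]))
    out <- list(mess = scores$mess, per_variable = scores$per_variable,
                reference_summary = reference_summary)
  }
  class(out) <- "mess_result"
  out
}

mess_values <- function(result) {
  if (inherits(result$mess, "grid_layer")) as.vector(result$mess$values) else result$mess
}

#' Validity mask from a MESS result
#'
#' Cells are retained only where the MESS value strictly exceeds the median
#' of the strictly positive MESS values — a deliberately conservative rule
#' that discards not only extrapolated cells but also the less-similar half
#' of the interpolated area. `rule = "nonnegative"` exposes the milder
#' conventional rule (keep all non-extrapolated cells, `mess >= 0`) without
#' changing the default.
#'
#' @param result a `mess_result` from [compute_mess()].
#' @param rule `"median_positive"` (default) or `"nonnegative"`.
#' @return An object of class `validity_mask`: `keep` (logical grid or
#'   vector, `NA` on nodata) and `threshold` (percent).
#' @export
validity_mask <- function(result, rule = c("median_positive", "nonnegative")) {
  rule <- match.arg(rule)
  vals <- mess_values(result)
  pos <- vals[!is.na(vals) & vals > 0]
  if (rule == "median_positive") {
    if (length(pos) == 0) stop("mask undefined: all MESS non-positive")
    threshold <- stats::median(pos)
    keep_vec <- vals > threshold
  } else {
    threshold <- 0
    keep_vec <- vals >= 0
  }
  keep <- if (inherits(result$mess, "grid_layer")) {
    g <- result$mess
    g$values <- matrix(as.numeric(keep_vec), nrow = nrow(g$values))
    g$nodata <- 255
    g
  } else {
    keep_vec
  }
  structure(list(keep = keep, threshold = threshold, rule = rule),
            class = "validity_mask")
}
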