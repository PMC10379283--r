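#' PCA biplot of localities and predictor loadings
#'
#' Base-graphics biplot of the first two components: locality scores colored
#' by insularity, with variable loading arrows overlaid on a common scale.
#'
#' @param x a `pca_result` from [run_pca()].
#' @param insularity optional character vector of island/mainland flags, one
#'   per locality, used for point colors.
#' @param ... passed to [plot()].
#' @export
plot.pca_result <- function(x, insularity = NULL, ...) {
  sc <- x$scores[, 1:2, drop = FALSE]
  col <- if (is.null(insularity)) "grey30" else
    ifelse(insularity == "island", "firebrick", "steelblue")
  pct <- round(100 * x$explained[1:2], 1)
  plot(sc, col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", pct[1]),
       ylab = sprintf("PC2 (%.1f%%)", pct[2]), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  ld <- x$loadings[, 1:2, drop = FALSE]
  sf <- 0.8 * min(max(abs(sc[, 1])) / max(abs(ld[, 1])),
                  max(abs(sc[, 2])) / max(abs(ld[, 2])))
  graphics::arrows(0, 0, ld[, 1] * sf, ld[, 2] * sf,
                   length = 0.08, col = "grey40")
  graphics::text(ld[, 1] * sf * 1.08, ld[, 2] * sf * 1.08,
                 rownames(ld), cex = 0.7, col = "grey20")
  invisible(x)
}
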