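#' Synthetic study scenario
#'
#' Defines a fully reproducible synthetic counterpart of the study design:
#' five spatially smooth, weakly correlated anthropogenic-predictor fields on
#' a global lat/lon grid with contiguous nodata regions (emulating oceans and
#' unmapped areas), plus sampled localities whose observed heterozygosity is
#' a known linear function of the standardized predictors with additive
#' Gaussian noise, clipped to `[0, 1]`.
#'
#' Defaults mirror the scale of the compiled rat data: 83 localities per
#' species (the larger per-species complete-case sample), about 30% island
#' records, population density as the dominant predictor, a baseline Ho of
#' 0.5 (between the two species means of 0.45 and 0.62) and residual noise
#' of 0.05 Ho units.
#'
#' @param seed integer random seed; the whole scenario is deterministic
#'   given this seed.
#' @param nrow,ncol grid shape (default 60 x 120 at 3 degrees over the whole
#'   globe; cells must be square for ASCII-grid output).
#' @param xmin,xmax,ymin,ymax geographic extent in decimal degrees.
#' @param n_localities localities generated per species.
#' @param beta named or plain numeric vector of length 5: Ho units per
#'   standardized predictor unit, in [canonical_predictors()] order.
#' @param intercept baseline Ho.
#' @param noise_sd residual standard deviation in Ho units.
#' @param nodata_fraction fraction of cells masked as nodata, in `[0, 1)`.
#' @param island_fraction fraction of localities labelled island.
#' @param island_effect additive Ho shift for island localities.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, nrow = 60, ncol = 120,
                               xmin = -180, xmax = 180, ymin = -90, ymax = 90,
                               n_localities = 83,
                               beta = c(0.02, 0.08, 0.04, 0.01, -0.04),
                               intercept = 0.5, noise_sd = 0.05,
                               nodata_fraction = 0.3,
                               island_fraction = 0.3, island_effect = 0.05) {
  stopifnot(nrow >= 10, ncol >= 10, length(beta) == 5, noise_sd >= 0,
            nodata_fraction >= 0, nodata_fraction < 1,
            island_fraction >= 0, island_fraction <= 1)
  beta <- stats::setNames(as.numeric(beta), canonical_predictors())
  structure(list(seed = as.integer(seed), nrow = as.integer(nrow),
                 ncol = as.integer(ncol),
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 n_localities = as.integer(n_localities), beta = beta,
                 intercept = intercept, noise_sd = noise_sd,
                 nodata_fraction = nodata_fraction,
                 island_fraction = island_fraction,
                 island_effect = island_effect),
            class = "synthetic_scenario")
}

# one smooth field: sum of `bumps` Gaussian bumps with random centers/widths
gaussian_bump_field <- function(nrow, ncol, xmin, xmax, ymin, ymax, bumps = 10) {
  xc <- xmin + (seq_len(ncol) - 0.5) * (xmax - xmin) / ncol
  yc <- ymax - (seq_len(nrow) - 0.5) * (ymax - ymin) / nrow
  f <- matrix(0, nrow, ncol)
  span <- max(xmax - xmin, ymax - ymin)
  for (b in seq_len(bumps)) {
    cx <- stats::runif(1, xmin, xmax)
    cy <- stats::runif(1, ymin, ymax)
    # widths a modest fraction of the extent: large enough for smooth
    # regional structure, small enough that independent draws stay only
    # weakly cross-correlated
    w <- stats::runif(1, 0.04, 0.15) * span
    a <- stats::rnorm(1)
    dx2 <- outer(rep(1, nrow), (xc - cx)^2)
    dy2 <- outer((yc - cy)^2, rep(1, ncol))
    f <- f + a * exp(-(dx2 + dy2) / (2 * w^2))
  }
  f
}

#' Generate a synthetic predictor stack
#'
#' Each predictor is a seeded sum of 10 Gaussian bumps — smooth, like real
#' socioeconomic surfaces, so nearest-neighbour resampling and MESS behave
#' realistically — standardized to zero mean and unit variance over valid
#' cells. A `nodata_fraction` of cells is masked in spatially contiguous
#' blobs shared by all five layers (as oceans are in real global products).
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [predictor_stack].
#' @export
generate_stack <- function(scenario) {
  s <- scenario
  set.seed(s$seed)
  mask <- matrix(FALSE, s$nrow, s$ncol)
  if (s$nodata_fraction > 0) {
    blob <- gaussian_bump_field(s$nrow, s$ncol, s$xmin, s$xmax, s$ymin, s$ymax)
    mask <- blob >= stats::quantile(blob, 1 - s$nodata_fraction)
  }
  layers <- lapply(canonical_predictors(), function(nm) {
    f <- gaussian_bump_field(s$nrow, s$ncol, s$xmin, s$xmax, s$ymin, s$ymax)
    f[mask] <- NA_real_
    v <- f[!mask]
    f[!mask] <- (v - mean(v)) / stats::sd(v)
    grid_layer(f, s$xmin, s$xmax, s$ymin, s$ymax)
  })
  names(layers) <- canonical_predictors()
  predictor_stack(layers)
}

#' Generate synthetic localities with known Ho structure
#'
#' Places localities uniformly at the centers of cells valid in all five
#' layers and draws `ho = clip(intercept + sum(beta * x) +
#' island_effect * is_island + N(0, noise_sd), 0, 1)`. The generating truth
#' (`beta`, `intercept`, `noise_sd`, drawn cells) is attached for parameter
#' recovery tests.
#'
#' @param scenario a [synthetic_scenario()].
#' @param stack the matching [predictor_stack] from [generate_stack()].
#' @param species species label for the generated records.
#' @return A locality data frame (same shape as [read_localities()] output)
#'   with a `truth` attribute.
#' @export
generate_localities <- function(scenario, stack, species = "rattus") {
  s <- scenario
  tmpl <- stack[[1]]
  vars <- canonical_predictors()
  valid <- !is.na(stack[[1]]$values)
  for (nm in vars[-1]) valid <- valid & !is.na(stack[[nm]]$values)
  cells <- which(valid, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("no valid cells in the predictor stack")
  set.seed(s$seed + 1L)
  pick <- cells[sample.int(nrow(cells), s$n_localities, replace = TRUE), , drop = FALSE]
  res <- grid_res(tmpl)
  lon <- tmpl$xmin + (pick[, "col"] - 0.5) * res[["x"]]
  lat <- tmpl$ymax - (pick[, "row"] - 0.5) * res[["y"]]
  x <- sapply(vars, function(nm) stack[[nm]]$values[pick])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, vars))
  island <- stats::runif(s$n_localities) < s$island_fraction
  ho_raw <- s$intercept + as.vector(x %*% s$beta) +
    s$island_effect * island + stats::rnorm(s$n_localities, 0, s$noise_sd)
  ho <- pmin(pmax(ho_raw, 0), 1)
  records <- data.frame(
    species = species,
    study_id = sprintf("synthetic_%03d", seq_len(s$n_localities)),
    site = sprintf("site_%03d", seq_len(s$n_localities)),
    lon = lon, lat = lat, ho = ho,
    insularity = ifelse(island, "island", "mainland"),
    marker = sample(NUCLEAR_MARKERS, s$n_localities, replace = TRUE),
    stringsAsFactors = FALSE
  )
  attr(records, "truth") <- list(beta = s$beta, intercept = s$intercept,
                                 noise_sd = s$noise_sd, seed = s$seed,
                                 cells = pick)
  records
}
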