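# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests write themselves.

# A small predictor stack on [0, ncol] x [0, nrow] with 1-degree cells.
# `fill` generates each layer's matrix; `nodata` is a list of row/col index
# matrices to blank per layer (recycled if a single matrix).
tiny_stack <- function(nrow = 10, ncol = 10, seed = 1, fill = NULL, nodata = NULL) {
  set.seed(seed)
  nms <- canonical_predictors()
  layers <- lapply(seq_along(nms), function(i) {
    m <- if (is.null(fill)) matrix(stats::rnorm(nrow * ncol), nrow, ncol) else fill(i)
    if (!is.null(nodata)) {
      nd <- if (is.list(nodata)) nodata[[i]] else nodata
      if (!is.null(nd) && length(nd)) m[nd] <- NA_real_
    }
    grid_layer(m, xmin = 0, xmax = ncol, ymin = 0, ymax = nrow)
  })
  names(layers) <- nms
  predictor_stack(layers)
}

# Locality records with defaults that satisfy all parsing invariants.
make_records <- function(lon, lat, ho = 0.5, species = "rattus",
                         insularity = "mainland", marker = "microsatellite") {
  n <- max(length(lon), length(lat), length(ho))
  data.frame(species = rep_len(species, n),
             study_id = sprintf("s%02d", seq_len(n)),
             site = sprintf("site%02d", seq_len(n)),
             lon = rep_len(lon, n), lat = rep_len(lat, n),
             ho = rep_len(ho, n),
             insularity = rep_len(insularity, n),
             marker = rep_len(marker, n),
             stringsAsFactors = FALSE)
}

# An analysis table with known linear structure, no rasters involved.
make_table <- function(n = 50, beta = c(0.5, 0, 0, 0, 0), noise_sd = 0.01,
                       intercept = 0.5, seed = 1, island_fraction = 0.3) {
  set.seed(seed)
  nms <- canonical_predictors()
  x <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, nms))
  ho <- pmin(pmax(intercept + as.vector(x %*% beta) +
                    stats::rnorm(n, 0, noise_sd), 0), 1)
  cbind(make_records(lon = stats::runif(n, -170, 170),
                     lat = stats::runif(n, -80, 80), ho = ho,
                     insularity = ifelse(stats::runif(n) < island_fraction,
                                         "island", "mainland")),
        as.data.frame(x))
}

# Independent brute-force MESS oracle: explicit double loop over query rows
# and variables, counting reference values below p one by one.
mess_oracle <- function(ref, query) {
  vars <- colnames(ref)
  out <- matrix(NA_real_, nrow(query), length(vars), dimnames = list(NULL, vars))
  for (i in seq_len(nrow(query))) {
    for (v in vars) {
      r <- ref[, v]
      p <- query[i, v]
      n_below <- 0
      for (val in r) if (val < p) n_below <- n_below + 1
      f <- 100 * n_below / length(r)
      rmin <- min(r); rmax <- max(r)
      out[i, v] <-
        if (f == 0) 100 * (p - rmin) / (rmax - rmin)
        else if (f <= 50) 2 * f
        else if (f < 100) 2 * (100 - f)
        else 100 * (rmax - p) / (rmax - rmin)
    }
  }
  list(per_variable = out, mess = apply(out, 1, min))
}

write_locality_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
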