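#' Lightweight georeferenced grid layer
#'
#' In-memory container for a single-band raster on a regular WGS84
#' longitude/latitude grid. Values are stored as a numeric matrix whose first
#' row is the northernmost row of cells; missing cells are `NA` internally and
#' are written out as the layer's `nodata` sentinel.
#'
#' @param values numeric matrix, row 1 = northernmost row of cells.
#' @param xmin,xmax,ymin,ymax extent of the grid in decimal degrees
#'   (cell edges, not centers).
#' @param nodata sentinel value used on disk for missing cells; `NA` cells in
#'   `values` are the in-memory representation regardless of this sentinel.
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, xmin, xmax, ymin, ymax, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (!all(is.finite(c(xmin, xmax, ymin, ymax))) || xmax <= xmin || ymax <= ymin) {
    stop("invalid extent: require xmin < xmax and ymin < ymax")
  }
  structure(
    list(values = values, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         nodata = nodata),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %d rows x %d cols, extent [%g, %g] x [%g, %g], res %g x %g deg, %d NA cells\n",
              nrow(x$values), ncol(x$values), x$xmin, x$xmax, x$ymin, x$ymax,
              grid_res(x)["x"], grid_res(x)["y"], sum(is.na(x$values))))
  invisible(x)
}

#' Cell size of a grid layer in degrees
#' @param layer a `grid_layer`.
#' @return Named numeric vector `c(x = , y = )` in decimal degrees.
#' @export
grid_res <- function(layer) {
  c(x = (layer$xmax - layer$xmin) / ncol(layer$values),
    y = (layer$ymax - layer$ymin) / nrow(layer$values))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$xmax - b$xmax) < tol &&
    abs(a$ymin - b$ymin) < tol && abs(a$ymax - b$ymax) < tol
}

#' Read a grid layer from an ESRI ASCII grid file
#'
#' ASCII grids (`.asc`) are the plain-text raster interchange format used
#' here; they carry the extent, a square cell size and a nodata sentinel in a
#' six-line header followed by the cell values row by row from north to south.
#'
#' @param path path to an `.asc` file.
#' @return A [grid_layer] with nodata cells as `NA`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_hdr <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      seek(con, pos)
      break
    }
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d cell values, found %d", nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_layer(m,
             xmin = hdr$xllcorner, xmax = hdr$xllcorner + nc * hdr$cellsize,
             ymin = hdr$yllcorner, ymax = hdr$yllcorner + nr * hdr$cellsize,
             nodata = nodata)
}

#' Write a grid layer to an ESRI ASCII grid file
#'
#' @param layer a [grid_layer]; cells must be square (`res x == res y`).
#' @param path output path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(layer, path, digits = 10) {
  res <- grid_res(layer)
  if (abs(res["x"] - res["y"]) > 1e-9) {
    stop("ASCII grids require square cells; resample first")
  }
  m <- layer$values
  m[is.na(m)] <- layer$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", layer$xmin),
    sprintf("yllcorner %.10g", layer$ymin),
    sprintf("cellsize %.10g", res[["x"]]),
    sprintf("NODATA_value %.10g", layer$nodata)
  )
  body <- apply(m, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Nearest-neighbour resampling to a target resolution
#'
#' Produces a grid at `target_resolution` covering the source extent; every
#' output cell takes the value of the source cell whose center is nearest the
#' output cell center. Nodata is propagated, never interpolated. A point
#' equidistant between two source centers resolves to the smaller row index,
#' then the smaller column index (i.e. toward the upper-left cell).
#'
#' @param layer a [grid_layer].
#' @param target_resolution output cell size in arcminutes (2.5 arcmin = 5 km
#'   at the equator, the working resolution of the pipeline).
#' @return A resampled [grid_layer] with the same extent.
#' @export
resample_nearest <- function(layer, target_resolution = 2.5) {
  if (!inherits(layer, "grid_layer")) stop("`layer` must be a georeferenced grid_layer")
  if (!is.numeric(target_resolution) || target_resolution <= 0) {
    stop("`target_resolution` must be a positive number of arcminutes")
  }
  res_deg <- target_resolution / 60
  src_res <- grid_res(layer)
  if (abs(src_res["x"] - res_deg) < 1e-12 && abs(src_res["y"] - res_deg) < 1e-12) {
    return(layer)
  }
  nc_out <- max(1L, round((layer$xmax - layer$xmin) / res_deg))
  nr_out <- max(1L, round((layer$ymax - layer$ymin) / res_deg))
  # output cell centers
  xc <- layer$xmin + (seq_len(nc_out) - 0.5) * (layer$xmax - layer$xmin) / nc_out
  yc <- layer$ymax - (seq_len(nr_out) - 0.5) * (layer$ymax - layer$ymin) / nr_out
  # fractional 0-based index of the nearest source center; ties round down
  # (smaller index = upper/left cell)
  jx <- ceiling((xc - layer$xmin) / src_res["x"] - 0.5 - 0.5)
  iy <- ceiling((layer$ymax - yc) / src_res["y"] - 0.5 - 0.5)
  jx <- pmin(pmax(jx, 0), ncol(layer$values) - 1L) + 1L
  iy <- pmin(pmax(iy, 0), nrow(layer$values) - 1L) + 1L
  out <- layer$values[iy, jx, drop = FALSE]
  grid_layer(out, layer$xmin, layer$xmax, layer$ymin, layer$ymax,
             nodata = layer$nodata)
}

#' Canonical predictor layer names
#'
#' The five anthropogenic predictors, in their fixed order: GDP per capita
#' (2015), gridded population density (GPW v4.11, 2020), the Global Gridded
#' Relative Deprivation Index v1 (2020), travel time to the nearest city
#' (minutes) and travel time to the nearest port (minutes).
#'
#' @return Character vector of length 5.
#' @export
canonical_predictors <- function() {
  c("GDP_per_capita_2015",
    "gpw_v4_population_density_2020",
    "povmap.grdi.v1",
    "travel_time_to_cities_12_MOD",
    "travel_time_to_ports_5_MOD")
}

#' Bundle five co-registered predictor layers
#'
#' @param layers named list of five [grid_layer] objects; the names must be
#'   exactly the [canonical_predictors()], each present once, and all layers
#'   must share the same shape and extent.
#' @return An object of class `predictor_stack` (a validated named list).
#' @export
predictor_stack <- function(layers) {
  want <- canonical_predictors()
  if (!is.list(layers) || is.null(names(layers))) {
    stop("`layers` must be a named list of grid_layer objects")
  }
  missing <- setdiff(want, names(layers))
  extra <- setdiff(names(layers), want)
  if (length(missing) || length(extra)) {
    stop("predictor stack must contain exactly the five canonical layers; ",
         if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "), "; "),
         if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(names(layers))) stop("duplicated layer names")
  layers <- layers[want]
  for (nm in want) {
    if (!inherits(layers[[nm]], "grid_layer")) stop("layer is not a grid_layer: ", nm)
    if (!same_geometry(layers[[nm]], layers[[1]])) {
      stop("layer geometry mismatch: ", nm)
    }
  }
  structure(layers, class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> 5 layers, %d x %d cells\n",
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}

#' Read a predictor stack from a directory of ASCII grids
#'
#' Expects one `<canonical name>.asc` per predictor.
#'
#' @param dir directory containing the five `.asc` files.
#' @param resolution if non-`NULL`, resample every layer to this many
#'   arcminutes after reading.
#' @return A [predictor_stack].
#' @export
read_predictor_stack <- function(dir, resolution = NULL) {
  want <- canonical_predictors()
  layers <- lapply(want, function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    if (!file.exists(p)) stop("predictor raster not found: ", p)
    read_asc(p)
  })
  names(layers) <- want
  if (!is.null(resolution)) {
    layers <- lapply(layers, resample_nearest, target_resolution = resolution)
  }
  predictor_stack(layers)
}

#' Write a predictor stack as ASCII grids
#' @param stack a [predictor_stack].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_predictor_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack)) {
    write_asc(stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  invisible(dir)
}

# Row/column of the cell containing each point. Cell membership uses
# half-open pixel intervals [left, right) x (top, bottom]; longitudes exactly
# on the antimeridian wrap to -180. Out-of-grid points get NA indices.
cell_index <- function(layer, lon, lat) {
  lon <- ifelse(lon == 180 & layer$xmin <= -180 + 1e-9, -180, lon)
  res <- grid_res(layer)
  col <- floor((lon - layer$xmin) / res["x"]) + 1L
  row <- ceiling((layer$ymax - lat) / res["y"])
  bad <- col < 1L | col > ncol(layer$values) | row < 1L | row > nrow(layer$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract predictor values at localities with complete-case filtering
#'
#' Looks up, for every locality, the value of the cell containing the point in
#' each of the five layers. Localities falling outside the grid or on a nodata
#' cell in any layer are dropped (no imputation) and counted.
#'
#' @param stack a [predictor_stack].
#' @param records a locality data frame as returned by [read_localities()].
#' @return A list with `table` (the complete-case analysis table: locality
#'   metadata, `ho`, and one column per predictor), `dropped` (count) and
#'   `drop_log` (data frame of dropped localities with reasons).
#' @export
extract_at_points <- function(stack, records) {
  if (!inherits(stack, "predictor_stack")) stop("`stack` must be a predictor_stack")
  if (!is.data.frame(records) || nrow(records) == 0) stop("`records` must be a non-empty data frame")
  idx <- cell_index(stack[[1]], records$lon, records$lat)
  vals <- matrix(NA_real_, nrow = nrow(records), ncol = length(stack),
                 dimnames = list(NULL, names(stack)))
  inside <- !is.na(idx$row)
  flat <- cbind(idx$row[inside], idx$col[inside])
  for (nm in names(stack)) {
    vals[inside, nm] <- stack[[nm]]$values[flat]
  }
  keep <- inside & !apply(is.na(vals), 1, any)
  reason <- ifelse(!inside, "outside grid",
                   ifelse(!keep, "nodata in at least one layer", NA_character_))
  table <- cbind(records[keep, , drop = FALSE],
                 as.data.frame(vals[keep, , drop = FALSE]))
  rownames(table) <- NULL
  if (nrow(table) == 0) stop("no complete-case localities")
  drop_log <- data.frame(records[!keep, c("study_id", "site", "lon", "lat"), drop = FALSE],
                         reason = reason[!keep], row.names = NULL)
  list(table = table, dropped = sum(!keep), drop_log = drop_log)
}
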