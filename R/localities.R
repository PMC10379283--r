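#' Read and validate a locality table of observed heterozygosity
#'
#' One row per sampled population: species, source study, site name, WGS84
#' coordinates, observed heterozygosity (Ho) and an island/mainland flag.
#' Rows violating the record invariants are rejected (not repaired) and the
#' rejections are tallied by reason. Only nuclear markers (microsatellites,
#' SNPs, RADseq) are admitted: mitochondrial Ho is not comparable and such
#' rows are rejected at parse time.
#'
#' @param path CSV file (UTF-8, comma-separated, header row).
#' @param species_filter optional: keep only `"rattus"` or `"norvegicus"`.
#' @param columns named character vector mapping canonical column names
#'   (`species`, `study_id`, `site`, `lon`, `lat`, `ho`, `insularity`,
#'   `marker`) to the headers used in the file, for ingesting deposited
#'   tables without editing them.
#' @return A data frame of valid records with attributes `rejected` (named
#'   integer vector of rejection counts by reason) and `n_input`.
#' @export
read_localities <- function(path, species_filter = NULL, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("species", "study_id", "site", "lon", "lat", "ho",
                 "insularity", "marker")
  if (!is.null(columns)) {
    for (nm in names(columns)) {
      if (!columns[[nm]] %in% names(raw)) {
        stop("mapped column not in file: ", columns[[nm]])
      }
      names(raw)[names(raw) == columns[[nm]]] <- nm
    }
  }
  missing <- setdiff(canonical, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  validate_localities(raw[canonical], species_filter = species_filter)
}

NUCLEAR_MARKERS <- c("microsatellite", "SNP", "RADseq")

#' Validate locality records against the parsing invariants
#'
#' @param raw data frame with canonical locality columns.
#' @param species_filter optional species to keep.
#' @return Valid records; see [read_localities()].
#' @export
validate_localities <- function(raw, species_filter = NULL) {
  n_input <- nrow(raw)
  reasons <- character(n_input)
  suppressWarnings({
    raw$lon <- as.numeric(raw$lon)
    raw$lat <- as.numeric(raw$lat)
    raw$ho <- as.numeric(raw$ho)
  })
  flag <- function(cond, why) {
    hit <- cond & reasons == ""
    reasons[hit] <<- why
  }
  flag(!(raw$species %in% c("rattus", "norvegicus")), "unknown species")
  flag(!(raw$marker %in% NUCLEAR_MARKERS), "non-nuclear marker")
  flag(is.na(raw$ho) | raw$ho < 0 | raw$ho > 1, "ho out of range")
  flag(is.na(raw$lon) | raw$lon < -180 | raw$lon > 180, "lon out of range")
  flag(is.na(raw$lat) | raw$lat < -90 | raw$lat > 90, "lat out of range")
  flag(!(raw$insularity %in% c("island", "mainland")), "unknown insularity")
  ok <- reasons == ""
  records <- raw[ok, , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(species_filter)) {
    stopifnot(species_filter %in% c("rattus", "norvegicus"))
    records <- records[records$species == species_filter, , drop = FALSE]
  }
  dup <- duplicated(records[c("species", "lon", "lat")])
  if (any(dup)) {
    message(sum(dup), " duplicate (species, lon, lat) row(s) retained")
  }
  rejected <- table(reasons[!ok])
  attr(records, "rejected") <- stats::setNames(as.integer(rejected), names(rejected))
  attr(records, "n_input") <- n_input
  records
}

#' Write locality records back to CSV
#' @param records locality data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localities <- function(records, path) {
  canonical <- c("species", "study_id", "site", "lon", "lat", "ho",
                 "insularity", "marker")
  utils::write.csv(records[canonical], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Mean and standard deviation of observed heterozygosity per species
#'
#' @param records locality data frame.
#' @param species `"rattus"` or `"norvegicus"`.
#' @return List with `mean`, `sd` (sample sd, n - 1 denominator; defined as 0
#'   for a single record) and `n`.
#' @export
summarize_ho <- function(records, species) {
  ho <- records$ho[records$species == species]
  if (length(ho) == 0) stop("no records for species: ", species)
  s <- if (length(ho) == 1) 0 else stats::sd(ho)
  list(mean = mean(ho), sd = s, n = length(ho))
}
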