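#' Occurrence records as a tibble
#'
#' Occurrence sets are plain tibbles with columns `species`, `longitude`,
#' `latitude` (coordinates in the map units of the working grid). The CSV
#' interchange format is a header row `species,longitude,latitude` followed by
#' one record per line; row order is preserved and duplicates are permitted
#' before thinning.
#'
#' @param species Species name (recycled).
#' @param longitude,latitude Coordinate vectors.
#' @param source_tag Free-text provenance tag stored as an attribute.
#' @return A tibble with columns `species`, `longitude`, `latitude`.
#' @export
occurrence_set <- function(species, longitude, latitude, source_tag = "") {
  if (!all(is.finite(longitude)) || !all(is.finite(latitude))) {
    stop("occurrence coordinates must be finite", call. = FALSE)
  }
  out <- tibble::tibble(species = species, longitude = as.numeric(longitude),
                        latitude = as.numeric(latitude))
  attr(out, "source_tag") <- source_tag
  out
}

#' @rdname occurrence_set
#' @param path CSV path with header `species,longitude,latitude`.
#' @export
read_occurrences <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(tolower(header))[1:3],
                 c("species", "longitude", "latitude"))) {
    stop("occurrence CSV must have header 'species,longitude,latitude'",
         call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c("character", "character", "character"))
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad)) {
    stop(sprintf("non-numeric coordinate in occurrence CSV at data row %d",
                 bad[1]), call. = FALSE)
  }
  occurrence_set(df$species, lon, lat, source_tag = path)
}

#' @rdname occurrence_set
#' @param occ An occurrence tibble to write.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(species = occ$species,
                   longitude = sprintf("%.17g", occ$longitude),
                   latitude = sprintf("%.17g", occ$latitude))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
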