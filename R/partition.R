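#' Region partition with zone mapping
#'
#' The static geography of a study: disjoint regions (e.g. Senegalese
#' arrondissements) identified by unique labels, each with a centroid in
#' decimal degrees (WGS-84 assumed) and a many-to-one assignment to a coarser
#' zone (e.g. livelihood zones). An optional per-region urban flag supports
#' urban-resident exclusion during trajectory selection.
#'
#' @param region_id Character or integer vector of unique region labels.
#' @param lat,lon Numeric centroid coordinates in decimal degrees.
#' @param zone_id Zone label per region (many-to-one).
#' @param urban Optional logical vector; defaults to all `FALSE`.
#' @return A `region_partition`: data.frame with columns `region_id`, `lat`,
#'   `lon`, `zone_id`, `urban`, plus attributes `zones` (sorted unique zone
#'   labels) and `n_zones`.
#' @examples
#' p <- region_partition(c("A", "B", "C"), c(14, 14.5, 15), c(-16, -16, -15),
#'                       c(1, 1, 2))
#' attr(p, "n_zones")  # 2
#' @export
region_partition <- function(region_id, lat, lon, zone_id, urban = NULL) {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stop("duplicate region_id in partition: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  if (length(lat) != length(region_id) || length(lon) != length(region_id) ||
      length(zone_id) != length(region_id))
    stop("region_id, lat, lon, zone_id must have equal length")
  if (anyNA(zone_id)) stop("every region needs a zone assignment")
  if (anyNA(lat) || anyNA(lon) || any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("centroids must be valid decimal-degree coordinates")
  if (is.null(urban)) urban <- rep(FALSE, length(region_id))
  urban[is.na(urban)] <- FALSE
  zone_id <- as.character(zone_id)
  zones <- sort(unique(zone_id))
  df <- data.frame(region_id = region_id, lat = as.numeric(lat),
                   lon = as.numeric(lon), zone_id = zone_id,
                   urban = as.logical(urban), stringsAsFactors = FALSE)
  structure(df, zones = zones, n_zones = length(zones),
            class = c("region_partition", "data.frame"))
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: %d regions, %d zones, %d urban\n",
              nrow(x), attr(x, "n_zones"), sum(x$urban)))
  invisible(x)
}

#' Read a region partition from CSV
#'
#' Expected columns: `region_id,lat,lon,zone_id` and optionally `urban`
#' (0/1 or logical).
#' @param path CSV file path.
#' @return A [region_partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "lat", "lon", "zone_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("partition file missing columns: ",
                         paste(miss, collapse = ", "))
  urban <- if ("urban" %in% names(df)) as.logical(df$urban) else NULL
  region_partition(df$region_id, df$lat, df$lon, df$zone_id, urban)
}

#' Write a region partition to CSV
#' @param partition A [region_partition()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- as.data.frame(partition)
  df$urban <- as.integer(df$urban)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# zone index (1..N_Z) for each region row, in partition order
zone_index <- function(partition) {
  match(partition$zone_id, attr(partition, "zones"))
}
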