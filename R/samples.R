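## Sample tables: one row per (site, transect, zone) field plot with the six
## metal concentrations in mg/kg dry soil.

#' Validate a sample table
#'
#' Checks a data frame of per-plot metal concentrations against the package's
#' sample-table contract: columns `site`, `transect`, `zone` and the six
#' metal symbols; known zone labels; non-negative finite concentrations;
#' unique (site, transect, zone) keys. Zone labels are normalised (see
#' [normalize_zone()]), the original label is kept in `zone_label`, and
#' `distance_m` is filled in (and checked, when supplied) from the design's
#' nominal distances.
#'
#' @param df A data frame.
#' @return A validated tibble with columns `site`, `transect`, `zone`,
#'   `zone_label`, `distance_m`, then one column per metal; input row order
#'   preserved.
#' @export
as_sample_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("site", "transect", "zone")
  missing_meta <- setdiff(need, names(df))
  if (length(missing_meta)) {
    stop("Sample table is missing column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  missing_metals <- setdiff(metal_ids(), names(df))
  if (length(missing_metals)) {
    stop("Sample table is missing metal column(s): ",
         paste(missing_metals, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("Sample table has no rows", call. = FALSE)

  raw_zone <- as.character(df$zone)
  zone <- tryCatch(normalize_zone(raw_zone), error = function(e) e)
  if (inherits(zone, "error")) {
    ok <- tolower(raw_zone) %in%
      tolower(c(.zone_table$zone, names(.zone_aliases)))
    stop("Row(s) ", paste(which(!ok), collapse = ", "), ": ",
         conditionMessage(zone), call. = FALSE)
  }

  for (m in metal_ids()) {
    v <- df[[m]]
    if (!is.numeric(v)) {
      stop("Column ", m, " must be numeric (mg/kg)", call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop("Row(s) ", paste(bad, collapse = ", "),
           ": negative or non-finite concentration for ", m, call. = FALSE)
    }
  }

  dist <- zone_distance(zone)
  if ("distance_m" %in% names(df)) {
    supplied <- as.numeric(df$distance_m)
    bad <- which(!is.na(supplied) & supplied != dist)
    if (length(bad)) {
      stop("Row(s) ", paste(bad, collapse = ", "),
           ": distance_m inconsistent with zone's nominal distance",
           call. = FALSE)
    }
  }

  key <- paste(df$site, df$transect, zone, sep = "\r")
  if (anyDuplicated(key)) {
    stop("Duplicate (site, transect, zone) row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(
    site = as.character(df$site),
    transect = as.character(df$transect),
    zone = zone,
    zone_label = raw_zone,
    distance_m = dist
  )
  for (m in metal_ids()) out[[m]] <- as.numeric(df[[m]])
  out
}

#' Load a sample CSV
#'
#' Reads a delimited sample table (columns
#' `site,transect,zone,distance_m,Cd,Cr,Cu,Ni,Pb,Zn`, one header row, UTF-8,
#' decimal point) and validates it with [as_sample_table()].
#'
#' @param path CSV file path.
#' @return A validated sample tibble, row order preserved.
#' @export
#' @examples
#' tbl <- generate_transects(seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_samples(tbl, f)
#' identical(load_samples(f)$Cd, tbl$Cd)
load_samples <- function(path) {
  if (!file.exists(path)) stop("Sample file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_sample_table(df)
}

#' Write a sample table to CSV
#'
#' @param samples A sample tibble (validated with [as_sample_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- as_sample_table(samples)
  out <- samples[, c("site", "transect", "zone", "distance_m", metal_ids())]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Zone-mean concentrations per (site, zone); shared by the profile stages.
.zone_means <- function(samples) {
  samples <- as_sample_table(samples)
  samples |>
    dplyr::group_by(.data$site, .data$zone, .data$distance_m) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metal_ids()), mean),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$site, .data$distance_m, .data$zone)
}
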