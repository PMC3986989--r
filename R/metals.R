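## Canonical element and zone vocabulary shared by every module.

#' Heavy metals recognised by the package
#'
#' The six elements assessed throughout: cadmium, chromium, copper, nickel,
#' lead and zinc. All concentration tables, background sets and parameter
#' fixtures are keyed by exactly these symbols, in this order.
#'
#' @return Character vector `c("Cd", "Cr", "Cu", "Ni", "Pb", "Zn")`.
#' @export
#' @examples
#' metal_ids()
metal_ids <- function() {
  c("Cd", "Cr", "Cu", "Ni", "Pb", "Zn")
}

#' Metals treated as carcinogens in the cancer-risk pathway
#'
#' @return Character vector of the carcinogenic subset: Cd, Cr, Ni, Pb.
#' @export
carcinogen_ids <- function() {
  c("Cd", "Cr", "Ni", "Pb")
}

## Sampling-design zones: a trench at 0 m in the middle of the construction
## right-of-way, a working zone and a piling area at 10 m on either side, and
## reference plots at 20 m and 50 m on both sides. Compass-direction field
## labels (E/W or N/S) are normalised to side-agnostic labels because all
## analyses group by distance, not direction.
.zone_table <- data.frame(
  zone = c("trench", "working", "piling",
           "d20_side1", "d20_side2", "d50_side1", "d50_side2"),
  distance_m = c(0, 10, 10, 20, 20, 50, 50),
  stringsAsFactors = FALSE
)

.zone_aliases <- c(
  E20 = "d20_side1", N20 = "d20_side1",
  W20 = "d20_side2", S20 = "d20_side2",
  E50 = "d50_side1", N50 = "d50_side1",
  W50 = "d50_side2", S50 = "d50_side2"
)

#' Sampling zones of the transect design
#'
#' @return A tibble with columns `zone` (canonical label) and `distance_m`
#'   (nominal distance from the pipeline centreline, metres).
#' @export
#' @examples
#' zone_levels()
zone_levels <- function() {
  tibble::as_tibble(.zone_table)
}

#' Nominal distance of a zone
#'
#' @param zone Character vector of canonical zone labels.
#' @return Numeric vector of nominal distances in metres.
#' @export
zone_distance <- function(zone) {
  idx <- match(zone, .zone_table$zone)
  if (anyNA(idx)) {
    stop("Unknown zone label(s): ", paste(unique(zone[is.na(idx)]), collapse = ", "),
         ". Allowed: ", paste(.zone_table$zone, collapse = ", "), call. = FALSE)
  }
  .zone_table$distance_m[idx]
}

#' Normalise zone labels
#'
#' Maps field labels for the two sides of the pipeline (`E20`/`W20`,
#' `N50`/`S50`, ...) onto the side-agnostic canonical labels and validates
#' canonical labels. Matching is case-insensitive.
#'
#' @param x Character vector of zone labels.
#' @return Character vector of canonical labels (see [zone_levels()]).
#' @export
#' @examples
#' normalize_zone(c("trench", "E20", "s50"))
normalize_zone <- function(x) {
  canon <- .zone_table$zone
  lookup <- c(setNames(canon, tolower(canon)),
              setNames(unname(.zone_aliases), tolower(names(.zone_aliases))))
  out <- unname(lookup[tolower(as.character(x))])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("Unknown zone label(s): ", paste(bad, collapse = ", "),
         ". Allowed labels: ", paste(canon, collapse = ", "),
         " (or side labels ", paste(names(.zone_aliases), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}
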