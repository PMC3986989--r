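## Plain-text parameter config: INI-style sections with `key = value` pairs.
## Sections: [backgrounds.<site>], [toxicity_factors], [exposure.child],
## [exposure.adult], [exposure.shared], [tox.<metal>]. Keys absent from the
## file fall back to the packaged fixtures; numbers are written at full
## precision so a write/read round trip is exact.

.parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) {
        stop("Config entry outside any [section]: '", ln, "'", call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (is.na(num)) val else num
    } else {
      stop("Malformed config line: '", ln, "'", call. = FALSE)
    }
  }
  out
}

.fmt_num <- function(x) {
  if (is.character(x)) return(x)
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a parameter bundle to a config file
#'
#' Serialises a parameter bundle (as returned by [default_parameters()] or
#' [read_params_config()]) to the package's INI-style config format, at full
#' numeric precision so that reloading reproduces every value exactly.
#'
#' @param params List with components `backgrounds` (a [background_set()] or
#'   a named list of them keyed by site, or `NULL`), `toxicity`, `exposure`,
#'   `tox`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  lines <- character(0)
  add_section <- function(name, kv) {
    vals <- .fmt_num(unlist(kv))
    c(sprintf("[%s]", name), sprintf("%s = %s", names(vals), vals), "")
  }
  bg <- params$backgrounds
  if (!is.null(bg)) {
    if (inherits(bg, "background_set")) bg <- list(user = bg)
    for (site in names(bg)) {
      lines <- c(lines, add_section(paste0("backgrounds.", site),
                                    as.list(unclass(bg[[site]]))))
    }
  }
  if (!is.null(params$toxicity)) {
    lines <- c(lines, add_section("toxicity_factors", as.list(params$toxicity)))
  }
  if (!is.null(params$exposure)) {
    for (grp in c("child", "adult", "shared")) {
      lines <- c(lines, add_section(paste0("exposure.", grp),
                                    params$exposure[[grp]]))
    }
  }
  if (!is.null(params$tox)) {
    tox <- params$tox
    for (i in seq_len(nrow(tox))) {
      kv <- as.list(tox[i, setdiff(names(tox), "metal")])
      kv <- kv[!vapply(kv, is.na, logical(1))]
      lines <- c(lines, add_section(paste0("tox.", tox$metal[i]), kv))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter config file
#'
#' Parses the INI-style config format and merges it over the packaged
#' fixtures: any key present in the file overrides the default; absent keys
#' keep their fixture values. Toxicological values not listed for a metal are
#' treated as unavailable only if the fixture also lacks them.
#'
#' @param path Config file path.
#' @param site Optional site name selecting which `[backgrounds.<site>]`
#'   section (or packaged site) supplies `backgrounds`; defaults to the first
#'   backgrounds section in the file, if any.
#' @return A parameter bundle: list with `backgrounds`, `toxicity`,
#'   `exposure`, `tox`.
#' @export
read_params_config <- function(path, site = NULL) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  ini <- .parse_ini(path)
  params <- default_parameters()

  bg_sections <- grep("^backgrounds\\.", names(ini), value = TRUE)
  bg_sites <- sub("^backgrounds\\.", "", bg_sections)
  if (is.null(site)) {
    if (length(bg_sites)) site <- bg_sites[[1]]
  }
  if (!is.null(site)) {
    sec <- paste0("backgrounds.", site)
    if (sec %in% names(ini)) {
      vals <- unlist(ini[[sec]])
      base <- if (site %in% names(.site_backgrounds)) {
        .site_backgrounds[[site]]
      } else {
        NULL
      }
      if (!is.null(base)) vals <- unlist(modifyList(as.list(base), as.list(vals)))
      params$backgrounds <- background_set(vals, provenance = "user")
    } else {
      params$backgrounds <- default_backgrounds(site)
    }
  }

  if ("toxicity_factors" %in% names(ini)) {
    tf <- unlist(modifyList(as.list(params$toxicity), ini[["toxicity_factors"]]))
    bad <- setdiff(names(tf), metal_ids())
    if (length(bad)) stop("Unknown metal(s) in [toxicity_factors]: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    params$toxicity <- tf[metal_ids()]
  }

  for (grp in c("child", "adult", "shared")) {
    sec <- paste0("exposure.", grp)
    if (sec %in% names(ini)) {
      params$exposure[[grp]] <- modifyList(params$exposure[[grp]], ini[[sec]])
    }
  }

  tox_sections <- grep("^tox\\.", names(ini), value = TRUE)
  if (length(tox_sections)) {
    tox <- params$tox
    for (sec in tox_sections) {
      m <- sub("^tox\\.", "", sec)
      i <- match(m, tox$metal)
      if (is.na(i)) stop("Unknown metal in config section [", sec, "]",
                         call. = FALSE)
      for (key in names(ini[[sec]])) {
        if (!key %in% names(tox)) stop("Unknown toxicological key '", key,
                                       "' in [", sec, "]", call. = FALSE)
        tox[[key]][i] <- ini[[sec]][[key]]
      }
    }
    params$tox <- tox
  }
  params
}
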