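## Parameter fixtures: local geochemical backgrounds for the two survey
## sites, Grade I screening values, Hakanson toxicity factors, receptor
## exposure factors and per-metal toxicological values. All are returned as
## fresh copies so callers can modify them freely.

.site_backgrounds <- list(
  Site1 = c(Cd = 0.107, Cr = 57.5, Cu = 23,   Ni = 29.3, Pb = 16.8, Zn = 67.9),
  Site2 = c(Cd = 0.092, Cr = 64.5, Cu = 22.4, Ni = 26.5, Pb = 25.1, Zn = 71.1)
)

.grade1_screening <- c(Cd = 0.2, Cr = 90, Cu = 35, Ni = 40, Pb = 35, Zn = 100)

#' Construct a background concentration set
#'
#' A background set holds one geochemical background concentration (mg/kg dry
#' soil) per metal, used as the denominator of both the geo-accumulation
#' index and the Hakanson pollution factor.
#'
#' @param values Named numeric vector covering all of [metal_ids()], values
#'   strictly positive (mg/kg).
#' @param provenance One of `"site_local"`, `"average_shale"`, `"user"`.
#' @return A named numeric vector of class `background_set` with a
#'   `provenance` attribute, ordered as [metal_ids()].
#' @export
#' @examples
#' background_set(c(Cd = 0.1, Cr = 60, Cu = 25, Ni = 30, Pb = 20, Zn = 70), "user")
background_set <- function(values,
                           provenance = c("user", "site_local", "average_shale")) {
  provenance <- match.arg(provenance)
  values <- unlist(values)
  missing <- setdiff(metal_ids(), names(values))
  if (length(missing)) {
    stop("Background set is missing metal(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  values <- values[metal_ids()]
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Background values must be finite and > 0", call. = FALSE)
  }
  structure(values, provenance = provenance, class = "background_set")
}

#' Packaged site background sets
#'
#' Local background concentrations for the two survey sites (loess-derived
#' Site1 and sandy-loam Site2, mg/kg dry soil).
#'
#' @param site `"Site1"` or `"Site2"`.
#' @return A [background_set()] with provenance `"site_local"`.
#' @export
#' @examples
#' default_backgrounds("Site1")
default_backgrounds <- function(site) {
  if (length(site) != 1 || !site %in% names(.site_backgrounds)) {
    stop("Unknown site ", deparse(substitute(site)), "; packaged sites: ",
         paste(names(.site_backgrounds), collapse = ", "), call. = FALSE)
  }
  background_set(.site_backgrounds[[site]], provenance = "site_local")
}

#' Grade I soil-quality screening values
#'
#' National Grade I screening concentrations (mg/kg) for uncontaminated
#' natural soils; these exceed the packaged site backgrounds for every metal.
#'
#' @return Named numeric vector over [metal_ids()].
#' @export
grade1_screening_values <- function() {
  .grade1_screening[metal_ids()]
}

#' Hakanson toxicity factors
#'
#' Dimensionless toxic-response factors weighting each metal's pollution
#' factor in the potential ecological risk index: toxicity ordered
#' Cd > Cu = Ni = Pb > Cr > Zn.
#'
#' @return Named numeric vector: Cd 30, Cu/Ni/Pb 5, Cr 2, Zn 1.
#' @export
#' @examples
#' default_toxicity_factors()
default_toxicity_factors <- function() {
  c(Cd = 30, Cr = 2, Cu = 5, Ni = 5, Pb = 5, Zn = 1)[metal_ids()]
}

#' Receptor exposure parameters
#'
#' Exposure factors for the child and adult receptors plus shared site
#' factors, as used by the three-pathway dose equations:
#' \describe{
#'   \item{ABS_d}{dermal absorption fraction (unitless)}
#'   \item{AF}{soil-to-skin adherence factor (mg/cm\eqn{^2})}
#'   \item{BW}{body weight (kg)}
#'   \item{ED}{exposure duration (year)}
#'   \item{IngR}{soil ingestion rate (mg/d)}
#'   \item{SA}{exposed skin surface area (cm\eqn{^2}/event)}
#'   \item{EF}{exposure frequency (d/year)}
#'   \item{ET}{exposure time (h/d)}
#'   \item{LT}{lifetime (year)}
#'   \item{PEF}{soil-to-air particulate emission factor (m\eqn{^3}/kg)}
#' }
#' Averaging times and the age-adjusted carcinogenic factors are derived, not
#' stored: see [averaging_time()], [age_adjusted_ingestion()],
#' [age_adjusted_dermal()].
#'
#' @return A list of class `exposure_params` with components `child`, `adult`
#'   and `shared`.
#' @export
#' @examples
#' p <- default_exposure_params()
#' p$child$BW
default_exposure_params <- function() {
  structure(
    list(
      child  = list(ABS_d = 0.03,  AF = 0.2,  BW = 16.2, ED = 6,
                    IngR = 200, SA = 2800),
      adult  = list(ABS_d = 0.001, AF = 0.07, BW = 61.8, ED = 30,
                    IngR = 100, SA = 5700),
      shared = list(EF = 350, ET = 24, LT = 72, PEF = 1.36e9)
    ),
    class = "exposure_params"
  )
}

#' Averaging time in days
#'
#' Non-carcinogenic averaging time is `ED * 365` for the given receptor;
#' carcinogenic averaging time is `LT * 365` (26,280 d under defaults).
#'
#' @param p An `exposure_params` list.
#' @param receptor `"child"` or `"adult"` (ignored for `type = "ca"`).
#' @param type `"nc"` (non-carcinogenic) or `"ca"` (carcinogenic).
#' @return Averaging time in days.
#' @export
averaging_time <- function(p, receptor = c("child", "adult"),
                           type = c("nc", "ca")) {
  type <- match.arg(type)
  if (type == "ca") {
    return(p$shared$LT * 365)
  }
  receptor <- match.arg(receptor)
  p[[receptor]]$ED * 365
}

#' Per-metal toxicological parameters
#'
#' Reference doses, slope factors and absorption fractions per metal:
#' \describe{
#'   \item{RfD_ing}{chronic oral reference dose (mg/kg/d)}
#'   \item{RfC_inh}{chronic inhalation reference concentration (mg/m\eqn{^3})}
#'   \item{ABS_GI}{gastrointestinal absorption fraction (unitless)}
#'   \item{CSF_ing}{oral cancer slope factor ((mg/kg/d)\eqn{^{-1}})}
#'   \item{IUR}{inhalation unit risk ((\eqn{\mu}g/m\eqn{^3})\eqn{^{-1}})}
#' }
#' `NA` marks a route/metal combination without an established value; such
#' routes are skipped (contributing zero) by the risk calculators, never
#' raised as errors.
#'
#' @return A tibble with one row per metal.
#' @export
#' @examples
#' default_tox_params()
default_tox_params <- function() {
  tibble::tibble(
    metal   = metal_ids(),
    RfD_ing = c(1.0e-3, 3.0e-3, 4.0e-2, 2.0e-2, 3.5e-3, 3.0e-1),
    RfC_inh = c(1.0e-5, NA,     NA,     9.0e-5, NA,     NA),
    ABS_GI  = c(0.025,  0.013,  1,      0.04,   1,      1),
    CSF_ing = c(NA,     NA,     NA,     NA,     8.5e-3, NA),
    IUR     = c(1.8e-3, 1.2e-2, NA,     2.6e-4, 1.2e-5, NA)
  )
}

#' Full default parameter bundle
#'
#' Convenience constructor returning fresh copies of every packaged fixture:
#' backgrounds (if `site` is given), Hakanson toxicity factors, exposure
#' parameters and toxicological values.
#'
#' @param site `"Site1"`, `"Site2"`, or `NULL` (no packaged backgrounds; they
#'   must then come from a config file or [background_set()]).
#' @return A list with components `backgrounds` (or `NULL`), `toxicity`,
#'   `exposure`, `tox`.
#' @export
#' @examples
#' default_parameters("Site1")$backgrounds[["Pb"]]
default_parameters <- function(site = NULL) {
  backgrounds <- if (is.null(site)) NULL else default_backgrounds(site)
  list(
    backgrounds = backgrounds,
    toxicity = default_toxicity_factors(),
    exposure = default_exposure_params(),
    tox = default_tox_params()
  )
}
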