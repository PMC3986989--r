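## Three-pathway human exposure dose and risk characterisation, in the
## USDOE-RAIS / USEPA-RAGS form for soil contact:
##
## Non-carcinogenic, per receptor r (child, adult), AT_nc = ED_r * 365:
##   CDI_ing    = C * IngR_r * EF * ED_r / (BW_r * AT_nc) * 1e-6     [mg/kg/d]
##   EC_inh     = C * (1/PEF) * ET * EF * ED_r / (24 * AT_nc)        [mg/m3]
##   CDI_dermal = C * SA_r * AF_r * ABS_d,r * EF * ED_r /
##                  (BW_r * AT_nc) * 1e-6                            [mg/kg/d]
##   HQ_ing = CDI_ing / RfD_ing ; HQ_inh = EC_inh / RfC_inh ;
##   HQ_dermal = CDI_dermal / (RfD_ing * ABS_GI) ; HI = sum(HQ)
##
## Carcinogenic, lifetime-averaged (AT_ca = LT * 365), age-adjusted factors:
##   IR_adj  = ED_c*IngR_c/BW_c + (ED_a - ED_c)*IngR_a/BW_a   [mg*year/kg/d]
##   DFS_adj = ED_c*SA_c*AF_c/BW_c + (ED_a - ED_c)*SA_a*AF_a/BW_a
##   DFS_ABS = same sum with each term multiplied by its ABS_d
##   Risk_ing    = C * IR_adj  * EF / AT_ca * 1e-6 * CSF_ing
##   Risk_dermal = C * DFS_ABS * EF / AT_ca * 1e-6 * (CSF_ing / ABS_GI)
##   Risk_inh    = C * (1000/PEF) * (ET/24) * EF * ED_inh / AT_ca * IUR
##   Total Risk  = sum over carcinogens {Cd, Cr, Ni, Pb} of evaluable routes
##
## The 1e-6 kg/mg factor converts ingested/adhered soil mass once per dose;
## inhalation works in air concentration via PEF (mg/m3 against RfC for
## non-cancer, *1000 -> ug/m3 against IUR for cancer). Routes whose
## toxicological value is unavailable (NA) contribute zero and are reported
## in `skipped`, never raised as errors.

.receptors <- c("child", "adult")

#' Chronic daily intake by soil ingestion (non-carcinogenic)
#'
#' @param C Soil concentration(s), mg/kg, `>= 0`.
#' @param receptor `"child"` or `"adult"`.
#' @param p Exposure parameters ([default_exposure_params()]).
#' @return Dose in mg/kg/d.
#' @export
#' @examples
#' cdi_ingestion_nc(1, "child")
cdi_ingestion_nc <- function(C, receptor = c("child", "adult"),
                             p = default_exposure_params()) {
  receptor <- match.arg(receptor)
  r <- p[[receptor]]
  C * r$IngR * p$shared$EF * r$ED /
    (r$BW * averaging_time(p, receptor, "nc")) * 1e-6
}

#' Inhalation exposure concentration (non-carcinogenic)
#'
#' Air concentration of resuspended soil particulate; with the default
#' round-the-clock exposure time (ET = 24 h/d) the exposure duration cancels
#' against the averaging time, so child and adult receive the same value.
#'
#' @inheritParams cdi_ingestion_nc
#' @return Concentration in mg/m\eqn{^3}.
#' @export
ec_inhalation_nc <- function(C, receptor = c("child", "adult"),
                             p = default_exposure_params()) {
  receptor <- match.arg(receptor)
  r <- p[[receptor]]
  C * (1 / p$shared$PEF) * p$shared$ET * p$shared$EF * r$ED /
    (24 * averaging_time(p, receptor, "nc"))
}

#' Chronic daily dose by dermal contact (non-carcinogenic)
#'
#' @inheritParams cdi_ingestion_nc
#' @return Dose in mg/kg/d.
#' @export
cdi_dermal_nc <- function(C, receptor = c("child", "adult"),
                          p = default_exposure_params()) {
  receptor <- match.arg(receptor)
  r <- p[[receptor]]
  C * r$SA * r$AF * r$ABS_d * p$shared$EF * r$ED /
    (r$BW * averaging_time(p, receptor, "nc")) * 1e-6
}

#' Age-adjusted soil ingestion rate
#'
#' Time-weighted child-plus-adult ingestion factor for lifetime carcinogenic
#' dose: the child term over `ED_child` years plus the adult term over the
#' remaining `ED_adult - ED_child` years. Defaults evaluate to 112.9
#' (conventionally printed as 113).
#'
#' @param p Exposure parameters.
#' @return Factor in mg x year/kg/d.
#' @export
#' @examples
#' signif(age_adjusted_ingestion(), 3)
age_adjusted_ingestion <- function(p = default_exposure_params()) {
  ch <- p$child; ad <- p$adult
  ch$ED * ch$IngR / ch$BW + (ad$ED - ch$ED) * ad$IngR / ad$BW
}

#' Age-adjusted soil dermal contact factor
#'
#' Same age-span convention as [age_adjusted_ingestion()] applied to
#' `SA * AF / BW`; excludes the dermal absorption fraction (defaults evaluate
#' to 362.4). For the absorption-weighted variant used in dermal cancer dose
#' see [dermal_abs_factor()].
#'
#' @param p Exposure parameters.
#' @return Factor in mg x year/kg/d.
#' @export
age_adjusted_dermal <- function(p = default_exposure_params()) {
  ch <- p$child; ad <- p$adult
  ch$ED * ch$SA * ch$AF / ch$BW + (ad$ED - ch$ED) * ad$SA * ad$AF / ad$BW
}

#' Absorption-weighted age-adjusted dermal factor
#'
#' The dermal absorption fraction is receptor-specific, so the cancer dermal
#' dose applies it inside the age sum by default (`"within_sum"`); the
#' alternatives apply a single receptor's fraction to the plain age-adjusted
#' factor.
#'
#' @param p Exposure parameters.
#' @param mode `"within_sum"` (default), `"child"` or `"adult"`.
#' @return Factor in mg x year/kg/d.
#' @export
dermal_abs_factor <- function(p = default_exposure_params(),
                              mode = c("within_sum", "child", "adult")) {
  mode <- match.arg(mode)
  ch <- p$child; ad <- p$adult
  switch(mode,
    within_sum = ch$ED * ch$SA * ch$AF * ch$ABS_d / ch$BW +
      (ad$ED - ch$ED) * ad$SA * ad$AF * ad$ABS_d / ad$BW,
    child = age_adjusted_dermal(p) * ch$ABS_d,
    adult = age_adjusted_dermal(p) * ad$ABS_d
  )
}

#' Non-carcinogenic hazard quotients and hazard index
#'
#' Computes the three route doses for each metal, divides by the matching
#' reference value (`RfD_ing`, `RfC_inh`, or the dermal reference dose
#' `RfD_ing * ABS_GI`), and sums all evaluable hazard quotients into the
#' hazard index HI. Metal/route pairs without a reference value are skipped
#' with zero contribution.
#'
#' @param conc Named numeric vector of soil concentrations (mg/kg) covering
#'   a subset of [metal_ids()].
#' @param receptor `"child"` or `"adult"`.
#' @param p Exposure parameters.
#' @param tox Toxicological parameter table ([default_tox_params()]).
#' @return A list of class `hazard_result`: `receptor`, `HQ` (tibble
#'   `metal`, `route`, `dose`, `HQ`), `HI`, `skipped` (tibble `metal`,
#'   `route`).
#' @export
#' @examples
#' hazard_index(c(Zn = 300), "child")$HI
hazard_index <- function(conc, receptor = c("child", "adult"),
                         p = default_exposure_params(),
                         tox = default_tox_params()) {
  receptor <- match.arg(receptor)
  conc <- .check_conc(conc)
  tox <- tox[match(names(conc), tox$metal), ]
  if (all(is.na(tox$RfD_ing)) && all(is.na(tox$RfC_inh))) {
    stop("No evaluable reference values for the supplied metals",
         call. = FALSE)
  }

  rows <- list()
  skipped <- list()
  for (i in seq_along(conc)) {
    m <- names(conc)[i]
    doses <- c(ing = cdi_ingestion_nc(conc[[i]], receptor, p),
               inh = ec_inhalation_nc(conc[[i]], receptor, p),
               dermal = cdi_dermal_nc(conc[[i]], receptor, p))
    refs <- c(ing = tox$RfD_ing[i],
              inh = tox$RfC_inh[i],
              dermal = tox$RfD_ing[i] * tox$ABS_GI[i])
    for (route in names(doses)) {
      if (is.na(refs[[route]])) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(metal = m,
                                                          route = route)
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          metal = m, route = route,
          dose = unname(doses[[route]]),
          HQ = unname(doses[[route]] / refs[[route]])
        )
      }
    }
  }
  HQ <- dplyr::bind_rows(rows)
  structure(
    list(receptor = receptor, HQ = HQ, HI = sum(HQ$HQ),
         skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
           tibble::tibble(metal = character(), route = character())),
    class = "hazard_result"
  )
}

#' Incremental lifetime cancer risk
#'
#' Age-adjusted lifetime risk over the carcinogenic subset
#' ([carcinogen_ids()]): ingestion risk via the oral slope factor, dermal
#' risk via `CSF_ing / ABS_GI`, inhalation risk via the inhalation unit risk
#' applied to the lifetime-averaged air concentration in \eqn{\mu}g/m\eqn{^3}.
#' Routes without a slope factor / unit risk are skipped with zero
#' contribution.
#'
#' @param conc Named numeric vector of soil concentrations (mg/kg).
#' @param p Exposure parameters.
#' @param tox Toxicological parameter table.
#' @param ed_inh Inhalation exposure duration in years (default: the adult
#'   exposure duration).
#' @param dermal_abs Placement of the dermal absorption fraction in the
#'   age-adjusted factor; see [dermal_abs_factor()].
#' @return A list of class `cancer_result`: `risk` (tibble `metal`, `route`,
#'   `risk`), `total_risk`, `skipped`.
#' @export
#' @examples
#' cancer_risk(c(Pb = 20, Cd = 0.2))$total_risk
cancer_risk <- function(conc, p = default_exposure_params(),
                        tox = default_tox_params(),
                        ed_inh = p$adult$ED,
                        dermal_abs = c("within_sum", "child", "adult")) {
  dermal_abs <- match.arg(dermal_abs)
  conc <- .check_conc(conc)
  conc <- conc[names(conc) %in% carcinogen_ids()]
  at_ca <- averaging_time(p, type = "ca")
  ir_adj <- age_adjusted_ingestion(p)
  dfs_abs <- dermal_abs_factor(p, dermal_abs)

  rows <- list()
  skipped <- list()
  for (m in names(conc)) {
    tx <- tox[tox$metal == m, ]
    C <- conc[[m]]
    terms <- list(
      ing = if (is.na(tx$CSF_ing)) NA else
        C * ir_adj * p$shared$EF / at_ca * 1e-6 * tx$CSF_ing,
      dermal = if (is.na(tx$CSF_ing)) NA else
        C * dfs_abs * p$shared$EF / at_ca * 1e-6 * (tx$CSF_ing / tx$ABS_GI),
      inh = if (is.na(tx$IUR)) NA else
        C * (1000 / p$shared$PEF) * (p$shared$ET / 24) * p$shared$EF *
          ed_inh / at_ca * tx$IUR
    )
    for (route in names(terms)) {
      if (is.na(terms[[route]])) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(metal = m,
                                                          route = route)
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(metal = m, route = route,
                                                    risk = terms[[route]])
      }
    }
  }
  risk <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(metal = character(), route = character(), risk = numeric())
  structure(
    list(risk = risk, total_risk = sum(risk$risk),
         skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
           tibble::tibble(metal = character(), route = character())),
    class = "cancer_result"
  )
}

#' Health-risk profile by zone
#'
#' Hazard index for both receptors and total carcinogenic risk per
#' (site, zone), computed from zone-mean concentrations and ordered by
#' nominal distance.
#'
#' @param samples A sample table.
#' @param p Exposure parameters.
#' @param tox Toxicological parameter table.
#' @param ... Passed on to [cancer_risk()] (`ed_inh`, `dermal_abs`).
#' @return A tibble with columns `site`, `zone`, `distance_m`, `n`,
#'   `HI_child`, `HI_adult`, `total_risk`.
#' @export
#' @examples
#' health_profile(generate_transects(seed = 1))
health_profile <- function(samples, p = default_exposure_params(),
                           tox = default_tox_params(), ...) {
  zm <- .zone_means(samples)
  conc_rows <- as.matrix(zm[, metal_ids()])
  res <- lapply(seq_len(nrow(zm)), function(i) {
    conc <- conc_rows[i, ]
    tibble::tibble(
      HI_child = hazard_index(conc, "child", p, tox)$HI,
      HI_adult = hazard_index(conc, "adult", p, tox)$HI,
      total_risk = cancer_risk(conc, p, tox, ...)$total_risk
    )
  })
  dplyr::bind_cols(zm[, c("site", "zone", "distance_m", "n")],
                   dplyr::bind_rows(res))
}

.check_conc <- function(conc) {
  conc <- unlist(conc)
  if (is.null(names(conc)) || !all(names(conc) %in% metal_ids())) {
    stop("conc must be a named vector over the recognised metals (",
         paste(metal_ids(), collapse = ", "), ")", call. = FALSE)
  }
  if (any(is.na(conc)) || any(conc < 0)) {
    stop("Concentrations must be >= 0", call. = FALSE)
  }
  conc
}
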