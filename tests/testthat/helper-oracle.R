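# Independent factor-chain oracles: every quantity is rebuilt step by step
# from the raw factors, deliberately avoiding the package's own formula code
# paths. Used to freeze expected values and for bulk equivalence checks.

oracle_igeo <- function(C, B) {
  ratio <- C / B
  ratio <- ratio / 1.5
  log(ratio) / log(2)
}

oracle_f <- function(C, B) C * (1 / B)

oracle_ri <- function(conc, B, Tfac) {
  total <- 0
  for (m in names(conc)) {
    total <- total + Tfac[[m]] * (conc[[m]] / B[[m]])
  }
  total
}

# default Table-style factors, written out independently of the package
oracle_exposure <- function() {
  list(
    child = list(ABS_d = 0.03, AF = 0.2, BW = 16.2, ED = 6, IngR = 200,
                 SA = 2800),
    adult = list(ABS_d = 0.001, AF = 0.07, BW = 61.8, ED = 30, IngR = 100,
                 SA = 5700),
    EF = 350, ET = 24, LT = 72, PEF = 1.36e9
  )
}

oracle_cdi_ing <- function(C, rec, p = oracle_exposure()) {
  r <- p[[rec]]
  x <- C
  x <- x * r$IngR
  x <- x * p$EF
  x <- x * r$ED
  x <- x / r$BW
  x <- x / (r$ED * 365)
  x * 1e-6
}

oracle_ec_inh <- function(C, rec, p = oracle_exposure()) {
  r <- p[[rec]]
  x <- C
  x <- x / p$PEF
  x <- x * p$ET
  x <- x * p$EF
  x <- x * r$ED
  x <- x / 24
  x / (r$ED * 365)
}

oracle_cdi_dermal <- function(C, rec, p = oracle_exposure()) {
  r <- p[[rec]]
  x <- C
  x <- x * r$SA
  x <- x * r$AF
  x <- x * r$ABS_d
  x <- x * p$EF
  x <- x * r$ED
  x <- x / r$BW
  x <- x / (r$ED * 365)
  x * 1e-6
}

oracle_ir_adj <- function(p = oracle_exposure()) {
  p$child$ED * p$child$IngR / p$child$BW +
    (p$adult$ED - p$child$ED) * p$adult$IngR / p$adult$BW
}

oracle_dfs_adj <- function(p = oracle_exposure()) {
  p$child$ED * p$child$SA * p$child$AF / p$child$BW +
    (p$adult$ED - p$child$ED) * p$adult$SA * p$adult$AF / p$adult$BW
}

oracle_dfs_abs <- function(p = oracle_exposure()) {
  p$child$ED * p$child$SA * p$child$AF * p$child$ABS_d / p$child$BW +
    (p$adult$ED - p$child$ED) * p$adult$SA * p$adult$AF * p$adult$ABS_d /
      p$adult$BW
}

# Table of toxicological values, NA where no value is established
oracle_tox <- function() {
  list(
    Cd = list(RfD_ing = 1.0e-3, RfC_inh = 1.0e-5, ABS_GI = 0.025,
              CSF_ing = NA, IUR = 1.8e-3),
    Cr = list(RfD_ing = 3.0e-3, RfC_inh = NA, ABS_GI = 0.013,
              CSF_ing = NA, IUR = 1.2e-2),
    Cu = list(RfD_ing = 4.0e-2, RfC_inh = NA, ABS_GI = 1, CSF_ing = NA,
              IUR = NA),
    Ni = list(RfD_ing = 2.0e-2, RfC_inh = 9.0e-5, ABS_GI = 0.04,
              CSF_ing = NA, IUR = 2.6e-4),
    Pb = list(RfD_ing = 3.5e-3, RfC_inh = NA, ABS_GI = 1, CSF_ing = 8.5e-3,
              IUR = 1.2e-5),
    Zn = list(RfD_ing = 3.0e-1, RfC_inh = NA, ABS_GI = 1, CSF_ing = NA,
              IUR = NA)
  )
}

oracle_hi <- function(conc, rec, p = oracle_exposure(), tox = oracle_tox()) {
  total <- 0
  for (m in names(conc)) {
    tx <- tox[[m]]
    if (!is.na(tx$RfD_ing)) {
      total <- total + oracle_cdi_ing(conc[[m]], rec, p) / tx$RfD_ing
      total <- total + oracle_cdi_dermal(conc[[m]], rec, p) /
        (tx$RfD_ing * tx$ABS_GI)
    }
    if (!is.na(tx$RfC_inh)) {
      total <- total + oracle_ec_inh(conc[[m]], rec, p) / tx$RfC_inh
    }
  }
  total
}

oracle_total_risk <- function(conc, p = oracle_exposure(),
                              tox = oracle_tox(), ed_inh = 30) {
  total <- 0
  for (m in intersect(names(conc), c("Cd", "Cr", "Ni", "Pb"))) {
    tx <- tox[[m]]
    C <- conc[[m]]
    if (!is.na(tx$CSF_ing)) {
      total <- total + C * oracle_ir_adj(p) * p$EF / (p$LT * 365) * 1e-6 *
        tx$CSF_ing
      total <- total + C * oracle_dfs_abs(p) * p$EF / (p$LT * 365) * 1e-6 *
        tx$CSF_ing / tx$ABS_GI
    }
    if (!is.na(tx$IUR)) {
      total <- total + C * 1000 / p$PEF * (p$ET / 24) * p$EF * ed_inh /
        (p$LT * 365) * tx$IUR
    }
  }
  total
}

# brute-force one-way ANOVA decomposition
oracle_anova_F <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    ssw <- ssw + sum((g - mean(g))^2)
  }
  k <- length(groups)
  n <- length(all_y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# F-distribution upper tail by numeric integration of the density
oracle_f_tail <- function(f, df1, df2) {
  dens <- function(x) stats::df(x, df1, df2)
  stats::integrate(dens, lower = f, upper = Inf, rel.tol = 1e-10)$value
}

site_backgrounds_list <- function() {
  list(Site1 = default_backgrounds("Site1"),
       Site2 = default_backgrounds("Site2"))
}

# small hand-built sample table: one site, `transects` replicates, all zones
make_flat_table <- function(conc = NULL, transects = 3, site = "Site1") {
  zones <- zone_levels()$zone
  if (is.null(conc)) conc <- default_backgrounds(site)
  rows <- expand.grid(transect = paste0("T", seq_len(transects)),
                      zone = zones, stringsAsFactors = FALSE)
  df <- data.frame(site = site, transect = rows$transect, zone = rows$zone)
  for (m in metal_ids()) df[[m]] <- unname(conc[[m]])
  as_sample_table(df)
}
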