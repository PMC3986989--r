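---
title: "Methods: soil heavy-metal risk assessment along a construction corridor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil heavy-metal risk assessment along a construction corridor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

## The problem

Burying a large gas or oil pipeline through farmland concentrates heavy
machinery, welding, material stockpiles and vehicle traffic in a 28–30 m
construction right-of-way (RoW): a trench in the middle, a working zone on
one side and a piling area on the other. The package quantifies whether and
how far this activity contaminates the topsoil with six metals (Cd, Cr, Cu,
Ni, Pb, Zn), using transects perpendicular to the pipeline with plots at
0 m (trench), 10 m (working zone / piling area) and reference plots at 20 m
and 50 m on both sides. Compass side labels (E/W, N/S) are normalised to
side-agnostic labels (`d20_side1`, ...) because every analysis groups by
distance, not direction.

All concentrations are mg/kg dry soil; no moisture correction is applied
(field samples are air-dried before analysis).

## Contamination grading: geo-accumulation index

For each metal, $I_{geo} = \log_2\!\big(C/(1.5B)\big)$, with $B$ a
geochemical background and the 1.5 buffering natural background variation.
Grading follows Müller's seven classes on half-open intervals
$(k-1, k]$, with $I_{geo}\le 0$ uncontaminated and $I_{geo}>5$ extremely
contaminated; boundary values therefore belong to the lower class
(exactly 0 is class 0, exactly 1 is class 1).

Two conventions needed a decision:

* **Background choice.** The index is classically computed against average
  shale, but the package ships no shale table — the only packaged
  backgrounds are the two sites' local values, and inventing shale numbers
  would silently change every grade. `igeo_profile()` therefore uses the
  supplied background set, defaults to the site-local values, and emits a
  notice when it does so; users grading against shale pass their own
  `background_set(..., "average_shale")`.
* **Zone aggregation.** A zone's index is the mean of the per-sample
  indices over the transect replicates (log-domain mean), the
  variance-stabilising convention for a log-scale quantity. Applying the
  index to the zone-mean concentration instead is available as
  `aggregation = "mean_conc"`; the two differ by Jensen's inequality but
  rarely by a class.
* **Zero concentrations** (below detection) produce `-Inf`; they are
  flagged, excluded from the zone mean with a warning, and never propagate.

## Ecological risk: pollution factors and RI

Per metal, the pollution factor $f_i = C_i/B_i$ is weighted by a
toxic-response factor $T_i$ ({Cd 30, Cu/Ni/Pb 5, Cr 2, Zn 1}) into the
monomial risk factor $E_i = T_i f_i$, and $RI=\sum_i E_i$ is banded as
low ($\le 50$), moderate ($\le 100$), considerable ($\le 200$) or high
($>200$). These bands are the adjusted six-metal criteria rather than
Hakanson's original sediment thresholds; the package takes them as
normative. At background soil, $RI = \sum T_i = 48$, just below the
low-pollution ceiling — a useful built-in sanity check.

RI uses the site-local backgrounds by default (they are what "background
value for metals" denotes here), read independently of the
geo-accumulation background. Because RI is linear in concentrations, the
zone profile computed from zone-mean concentrations equals the mean of
per-sample RI values; `sample_ri()` also exposes the per-sample values for
zone ANOVA.

Cd dominates RI in practice: with $T_{Cd}=30$, a cadmium pollution factor
of 3.4 alone exceeds the considerable-pollution threshold of 100.

## Human health risk

Exposure follows the standard three-pathway soil model (direct ingestion,
inhalation of resuspended particulate, dermal contact) with child and adult
receptors. The dose equations are the canonical USDOE/USEPA forms; the
commented header of `R/healthrisk.R` lists each one with units. The
parameter defaults are the packaged exposure-factor table (child/adult:
ingestion 200/100 mg/d, body weight 16.2/61.8 kg, exposure duration
6/30 y, skin area 2,800/5,700 cm², adherence 0.2/0.07 mg/cm², dermal
absorption 0.03/0.001; shared: 350 d/y frequency, 24 h/d, 72 y lifetime,
particulate emission factor 1.36×10⁹ m³/kg). The adult dermal absorption
fraction of 0.001 is unusually low relative to the child's 0.03 but is used
verbatim; it makes the dermal route essentially a child's pathway.

Notable structural consequences, all property-tested:

* With 24 h/d exposure time, the non-cancer inhalation concentration is
  receptor-independent (exposure duration cancels against averaging time).
* Hazard quotients divide each dose by `RfD_ing`, `RfC_inh`, or the dermal
  reference dose `RfD_ing × ABS_GI`; HI sums them over routes and metals.
  Missing reference values (e.g. no inhalation RfC for Cr, Cu, Pb, Zn; no
  oral slope factor for Cd, Cr, Ni) make that route contribute zero, are
  recorded in `skipped`, and never raise errors.
* HI for children strictly exceeds adults for any non-zero soil
  concentration: ingestion per body weight is 12.35 vs 1.618 mg/(kg·d) and
  every dermal factor is larger for the child.
* Because Cr's gastrointestinal absorption factor is small (0.013), its
  dermal reference dose is tiny and Cr tends to dominate HI even in clean
  soil — HI contrasts between zones are therefore much flatter than RI
  contrasts.

Carcinogenic risk (Cd, Cr, Ni, Pb) is lifetime-averaged over
`LT × 365 = 26,280 d` with age-adjusted intake factors summing a child term
over `ED_child` years and an adult term over the remaining
`ED_adult − ED_child` years: `IR_adj = 6·200/16.2 + 24·100/61.8 = 112.9`
(printed conventionally as 113) and
`DFS_adj = 6·2800·0.2/16.2 + 24·5700·0.07/61.8 = 362.4`. The dermal
absorption fraction is receptor-specific, and `DFS_adj` verifiably excludes
it; the cancer dermal dose therefore applies ABS_d inside the age sum by
default (`dermal_abs_factor()` = 6.377), with `"child"`/`"adult"` variants
as bracketing alternatives. Inhalation cancer risk converts to µg/m³
against the inhalation unit risk and uses an inhalation exposure duration
defaulting to the adult's 30 years (configurable, as no single convention
exists). Lead is assessed through its slope factor and unit risk like the
other carcinogens, although modern practice would use a blood-lead model.

The 10⁻⁶ kg/mg soil-mass conversion appears exactly once in each
ingestion/dermal dose; the test suite enforces this unit coherence by
checking every dose against an independent factor-chain oracle that
multiplies the raw factors step by step.

## Zone statistics

One-way ANOVA across zones is the classical fixed-effects decomposition
(no Welch correction, matching long-standing spreadsheet/SPSS defaults),
applied per metal within each site; a pooled RoW-vs-50 m contrast is also
available because the omnibus and the contrast answer different questions
and the choice is not forced by the method. Degenerate inputs are flagged
rather than mis-reported: zero within-group variance yields an infinite-F
sentinel with p = 0; fully constant data yield `NA`.

Metal clustering uses one minus the Pearson correlation between metal
columns with average linkage — the combination matching the interpretation
of the dendrogram height as "degree of association between elements" —
with squared-Euclidean-on-z-scores and complete/Ward linkage as switchable
alternatives, since the original settings behind such dendrograms are
typically unreported. Columns are processed in a fixed canonical metal
order, making tie-breaking deterministic; trees serialise to a merge list
(JSON) and optionally Newick.

## The synthetic generator

`generate_transects()` emulates the field design (2 sites × 3 transects ×
7 plots = 42 samples) under a multiplicative model on each site's
background:

$$\log C_{m}= \log B_m + \lambda_m s(z) + \gamma Z_t\,[m \in A]
  + \nu V_{p}\,[m \in M] + \varepsilon,\qquad \varepsilon\sim N(0,\sigma^2)$$

* $s(z)$: enrichment schedule decaying from the trench outwards —
  1.0 (trench), 0.8 (working), 0.6 (piling), 0.2 (20 m), 0.0 (50 m).
* $\lambda_m$: per-metal log-enrichment scale — Cd 1.0, Pb 0.9, Cu 0.5,
  Ni 0.5, Cr 0.1, Zn 0.0. Trench cadmium then averages
  $e^{1.0}\approx 2.7\times$ background, matching roughly-twice-background
  contamination with RI in the moderate–considerable band.
* $Z_t$: one standard-normal draw per transect shared by the anthropogenic
  group $A=\{$Cd, Cu, Ni, Pb$\}$ with loading $\gamma = 0.6$ —
  construction-activity intensity varies between transects, not between
  neighbouring plots of one transect.
* $V_p$: one draw per plot shared by the mixed-origin group
  $M=\{$Cr, Zn$\}$ with loading $\nu = 0.15$ — natural/agronomic
  variability (parent material, fertilisation) unrelated to the pipeline.
  Without this second factor the model cannot express the empirical
  Cr–Zn association: their correlation would be near zero and no clustering
  convention would group them, whereas real soils show exactly this
  mixed-origin co-variation. $\nu$ is set equal to the residual noise
  scale: natural co-variation of the same order as sampling noise.
* $\sigma = 0.15$: lognormal sampling/measurement noise.

Design consequences worth knowing: because $Z_t$ is shared across the
plots of one transect, it cancels from within-transect zone contrasts
(making the RI distance ordering stable at realistic noise) while still
driving the between-column correlation that the cluster analysis detects.
The marginal distribution of any single cell across seeds is lognormal, but
pooled within-zone residuals of anthropogenic metals are a three-component
mixture (three transect draws) — normality checks in the tests are
therefore formulated across seeds, not across pooled residuals.

What the generator does **not** emulate: spatial autocorrelation beyond
the zone structure, censoring at detection limits, instrument-specific
measurement error, soil property covariates (pH, organic matter, texture),
and any temporal dynamics. Passing the pipeline's property tests on this
generator shows the methods recover a known two-source, distance-decaying
contamination structure at realistic noise; it does not validate the
exposure parameters themselves against any field population.

`estimate_enrichment()` inverts the generator's mean structure (zone mean
of $\log(C/B)$ per metal, an unbiased estimator of $\lambda_m s(z)$); the
recovery tests use 200 transects and normal-theory bounds with each
metal's full per-sample log standard deviation
($\sqrt{\sigma^2+\gamma^2}$ for anthropogenic metals,
$\sqrt{\sigma^2+\nu^2}$ for mixed-origin ones).

## Numerical and interface choices

* Classification boundaries are half-open with the boundary in the lower
  class (I_geo = 0 → class 0; RI = 50 → low); `-Inf` is a legal index input
  mapping to class 0.
* Report CSVs round to 6 significant digits; the parameter config format is
  a plain INI dialect written at full (`%.17g`) precision so write/read
  round trips are bit-exact.
* Problem sizes in the test suite are chosen to keep the full run at a few
  minutes: 100 seeds for the pipeline-level ordering/cluster properties,
  1,000 random inputs for oracle equivalence, 200 transects for parameter
  recovery.
* `run_report()` writes no timestamps, so identical inputs reproduce
  byte-identical outputs.

## Known limitations

Exposure is soil-contact only — no crop-uptake/food-chain pathway, which
field studies of farmland repeatedly flag as the dominant route; no
probabilistic (Monte Carlo) exposure assessment; no speciation or
bioavailability modelling; lead carcinogenicity via slope factor rather
than a blood-lead model; the clustering recovers association structure,
not causal source apportionment (no PMF/absolute factor scores).
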