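# soilrisk

Quantitative risk assessment of heavy-metal contamination in agricultural
soils disturbed along a linear construction corridor (a buried-pipeline
right-of-way), for environmental scientists and EIA practitioners who need
reproducible contamination grading, ecological risk indexing and human
health risk screening from transect sampling data.

The package assesses six elements — Cd, Cr, Cu, Ni, Pb, Zn — sampled along
transects perpendicular to the corridor at seven distance plots: the trench
(0 m), a working zone and a piling area (10 m, one on each side), and
reference plots at 20 m and 50 m on both sides.

## Methods at a glance

**Geo-accumulation index** per metal,

> I_geo = log2( C / (1.5 B) )

with measured concentration C and geochemical background B (mg/kg), graded
into Müller's seven classes (class 0, I_geo ≤ 0, uncontaminated … class 6,
I_geo > 5, extremely contaminated).

**Potential ecological risk index** (Hakanson),

> f_i = C_i / B_i,  E_i = T_i f_i,  RI = Σ_i E_i

with toxic-response factors T = {Cd 30, Cu/Ni/Pb 5, Cr 2, Zn 1} and
categories RI ≤ 50 low, ≤ 100 moderate, ≤ 200 considerable, > 200 high.
At background (all f = 1) RI = 48.

**Human health risk** via the three soil exposure pathways (direct
ingestion, inhalation of resuspended particulate via a particulate emission
factor, dermal contact), for child and adult receptors: chronic daily
intakes divided by route-specific reference values give hazard quotients
summed into a hazard index HI; carcinogenic risk for Cd, Cr, Ni, Pb uses
lifetime-averaged, age-adjusted intake factors (IR_adj, DFS_adj) with oral
slope factors and inhalation unit risks. Metal/route pairs without an
established toxicological value are skipped and reported, never errors.

**Zone statistics**: classical one-way ANOVA across the seven zones per
metal, and average-linkage hierarchical clustering of the metals on
correlation distance for pollution-source grouping.

**Synthetic generator**: a seeded lognormal transect simulator with
zone-dependent enrichment and a two-factor latent source structure
(anthropogenic factor on Cd/Cu/Ni/Pb, mixed-origin factor on Cr/Zn),
providing ground truth for every downstream stage.

## Worked example

```r
library(soilrisk)

s  <- generate_transects(seed = 100)     # 2 sites x 3 transects x 7 plots
bg <- list(Site1 = default_backgrounds("Site1"),
           Site2 = default_backgrounds("Site2"))

ri_profile(s, bg)[1:7, c("zone", "distance_m", "f_Cd", "E_Cd", "RI", "category")]
#>        zone distance_m   f_Cd  E_Cd    RI category
#> 1    trench          0 2.0658 61.98 86.08 moderate
#> 2    piling         10 1.5145 45.43 66.25 moderate
#> 3   working         10 1.6181 48.54 72.29 moderate
#> 4 d20_side1         20 1.0918 32.75 48.16      low
#> 5 d20_side2         20 0.9665 28.99 44.97      low
#> 6 d50_side1         50 0.8430 25.29 40.44      low
#> 7 d50_side2         50 0.6990 20.97 35.64      low
```

The trench soil carries twice the background cadmium (f_Cd = 2.07), which —
weighted by Cd's toxicity factor of 30 — contributes E_Cd = 62 of RI = 86
(moderate ecological risk); risk falls below the low-pollution threshold of
50 beyond 20 m from the pipeline.

```r
health_profile(s)[1:4, ]
#>    site    zone distance_m n HI_child HI_adult total_risk
#> 1 Site1  trench          0 3     2.43   0.0691   6.48e-07
#> 2 Site1  piling         10 3     1.95   0.0556   5.08e-07
#> 3 Site1 working         10 3     2.22   0.0646   6.51e-07
#> 4 Site1 d20_side1      20 3     1.42   0.0408   3.86e-07
```

Children's hazard index exceeds the adults' by more than an order of
magnitude (higher soil ingestion per body weight and dermal uptake), and
total carcinogenic risk stays in the 1e-7 band, below the 1e-6–1e-4
regulatory range of concern.

```r
cluster_groups(metal_clustering(s), k = 2)
#> Cd Cr Cu Ni Pb Zn
#>  1  2  1  1  1  2
```

The two-cluster cut separates the anthropogenic group (Cd, Cu, Ni, Pb —
welding, vehicle wear, oil burning) from the mixed-origin pair (Cr, Zn).

An end-to-end run writing `igeo.csv`, `ri.csv`, `health.csv`, `anova.csv`,
`dendro.json` and a run manifest:

```r
run_report(s, "report_out")
```

A thin command-line wrapper with the same stages is installed at
`inst/cli/soilrisk` (subcommands `simulate`, `igeo`, `ri`, `health`,
`stats`, `report`).

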