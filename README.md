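# nlakes

Empirical nitrogen critical loads for high-elevation lakes, from
paleolimnological and atmospheric-monitoring data.

Remote mountain lakes are ultra-oligotrophic, so even modest atmospheric
nitrogen deposition can shift their diatom communities toward nitrophilous
indicator taxa (*Asterionella formosa*, *Fragilaria crotonensis/tenera*).
The deposition level at which that shift first appears in a dated sediment
core is an **empirical critical load**. `nlakes` is for paleolimnologists
and air-quality / land-management scientists who want that whole inference
chain as tested, reproducible code rather than a one-off spreadsheet
workflow.

## What it computes

1. **Bulk deposition** from ion-exchange-resin (IER) collector extracts:
   `rate = (mass / funnel area) x 100 x (365.25 / days)` in kg ha⁻¹ yr⁻¹,
   with blank and ammonium-control corrections, site/park summaries, and
   ANOVA + Tukey HSD group comparison.
2. **Nutrient limitation** from censored water chemistry: censored records
   (`<DL`) substituted at half the detection limit, then the DIN/TP mass
   ratio classified as N-limited (≤ 1.5), possibly co-limited (1.5–3.4], or
   P-limited (> 3.4).
3. **CRS ²¹⁰Pb geochronology**: excess = total ²¹⁰Pb − ²²⁶Ra; under a
   constant rate of supply the age at depth *z* is
   *t(z) = (1/λ) ln(A(0)/A(z))* with λ = ln 2 / 22.3 yr⁻¹ and *A* the
   cumulative excess inventory. Monte-Carlo date uncertainties; validation
   against the 1963 ¹³⁷Cs fallout peak.
4. **Indicator-shift detection** in dated stratigraphies: the deepest slice
   where the indicator proportion reaches `max(2 x background, 5 %)`, dated
   with its uncertainty window.
5. **Critical load**: elevation-corrected deposition
   (`0.1 x conc[mg/L] x precip[cm]`), an exponential trend fitted by OLS on
   the log scale with or without a preindustrial anchor (0.5 kg N ha⁻¹ yr⁻¹
   at 1900), hindcast over the shift window; the window mean ± sd is the
   critical load.

Seeded generators (`gen_*`) simulate every input table with known ground
truth, so each stage has a parameter-recovery test with no external data.
See `vignettes/nlakes-methods.Rmd` for the models, conventions, and
limitations.

## Worked example

A full synthetic study at the default regime (deposition growing 0.5 → ~2
kg N ha⁻¹ yr⁻¹ over 1900–2009, diatom shift onset 1970):

```r
library(nlakes)

# 2009 surface-water chemistry shipped with the package
wc  <- read_table(system.file("extdata", "water_chem_2009.csv",
                              package = "nlakes"), "water_chem")
lim <- limitation_table(wc)
lim[lim$site %in% c("Hoh", "Lower Thornton"),
    c("site", "din", "tp", "ratio_1dp", "class")]
#>            site   din    tp ratio_1dp      class
#>  Lower Thornton 0.009 0.003       3.0 co_limited
#>             Hoh 0.006 0.007       0.9  N_limited

# date a synthetic core and find the diatom shift
core <- gen_sediment_core(core_scenario(), coring_year = 2009, seed = 2)
am   <- age_uncertainty(core$profile, 2009, n_reps = 500, seed = 1)
cs137_validate(core$profile, am)$offset_yr
#> -0.115  (CRS date at the 137Cs peak is within 0.2 yr of 1963)

dia <- gen_diatom_core(core_scenario(), core$truth, seed = 3)
sh  <- detect_shift(dia$counts, am, taxa = indicator_taxa(extended = TRUE))
sh$window
#> 1968.8 1974.3  (true onset: 1970)

# hindcast deposition over the detected window
g    <- gen_deposition_series(deposition_scenario(), seed = 4)
recs <- deposition_series(g$records)
cl_a <- estimate_critical_load(
          fit_exponential(recs, anchor = list(year = 1900, value = 0.5)),
          sh$window)
cl_u <- estimate_critical_load(fit_exponential(recs), sh$window)
c(anchored = cl_a$mean, unanchored = cl_u$mean)
#>   anchored unanchored
#>       1.33       1.31   (kg N ha-1 yr-1; closed-form truth for this
#>                          regime and window is ~1.26)
lcl95(recs$deposition)
#> 1.70  (95% lower confidence limit of 1980-2009 deposition)
```

The detected window (1968.8–1974.3) brackets the true 1970 onset, and the
hindcast critical load agrees with the regime's closed form to a few
percent. Interpreting the numbers: the critical load is the deposition the
fitted curve implies during the years the diatom community first changed;
the LCL check exploits the fact that if the shift predates the monitoring
record, every monitored year should already exceed the critical load.

A command-line front end wraps the same stages:

```sh
Rscript inst/cli/nlakes.R all --seed 4 --out run1
# run1/: deposition_summary.csv limitation.csv age_model.csv
#        proportions.csv dendrogram.nwk shifts.json critical_load.json ...
```

Applying the pipeline to real data is the same sequence with your own
`ier_columns.csv`, `water_chem.csv`, `sediment.csv`, `diatom_counts.csv`
and `deposition_series.csv` (schemas in `?read_table`). Reproducing a
published headline estimate additionally needs the external station
concentration and elevation-corrected precipitation series, supplied as a
`deposition_series.csv` with its QC flags.

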