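# retcoloc

Layer-wise quantification and colocalization of immunofluorescence in
retinal cross-sections.

Post-mortem retinal sections double-labelled for amyloid-beta (Aβ) and
a cell marker (TUBB3 for neurons, GFAP for astrocytes/activated Müller
cells, IBA-1 for microglia, or GS+GFAP for the macroglia cohort) are
analysed against manually segmented layer masks (RNFL, GCL, IPL, INL,
OPL, ONL; ITK-SNAP-style label images). `retcoloc` computes, per image
and retinal layer:

- **positive-pixel percentages** `100·|A ∩ L| / |L|` per channel,
  artifact pixels and excluded layers removed from every denominator;
- **conditional colocalization**: `p⁺ = 100·|A ∩ M ∩ L| / |M ∩ L|`
  versus `p⁻ = 100·|A ∩ Mᶜ ∩ L| / |Mᶜ ∩ L|` — equal under the
  "Aβ randomly placed" null, `p⁺ > p⁻` when Aβ is enriched in the
  marker footprint;
- **coverage by microglia**: `100·|A ∩ M ∩ L| / |A ∩ L|`;
- the **macroglia partition** GS∩GFAP / GS-only / GFAP-only as
  percentages of the inner (RNFL+GCL+IPL) and outer (INL+OPL+ONL)
  layer groups, pooled by counts.

Image-level values are averaged into one *data point* per donor ×
region (central / mid-peripheral) × layer, screened with an iterated
modified z-score outlier rule (0.6745·|x−median|/MAD > 3.5, n ≥ 3),
and compared AD vs control per geo-layer with a **two-sided exact
tie-aware Wilcoxon rank-sum test**; within-group colocalization uses
the **exact Wilcoxon signed-rank test** on paired `p⁺ − p⁻`
differences. A synthetic-retina generator with a known joint pixel law
(marginals `p_red`, `p_green` and enrichment ratio
`ρ = P(A⁺|M⁺)/P(A⁺|M⁻)`, solved so the marginals are preserved for any
ρ) provides ground truth for end-to-end validation.

## Worked example

Simulate the default study design (5 AD + 7 control donors, 2
cross-sections each, 2 images per region, IBA-1 cohort) and run the
full analysis in memory:

```r
library(retcoloc)
library(dplyr)

sc  <- default_scenario("IBA-1")
sim <- simulate_cohort(sc)
res <- analyze_records(sim$records)

res$fraction_comparisons |>
  filter(role == "amyloid", region == "mid-peripheral") |>
  select(layer, mean_ad, se_ad, mean_control, se_control, p_value, stars)
#>   layer mean_ad  se_ad mean_control se_control p_value stars
#> 1   GCL   4.808 0.0667        2.156     0.1381 0.01667     *
#> 2   INL   3.485 0.1606        1.591     0.0442 0.00253    **
#> 3   IPL   3.766 0.2237        1.893     0.0714 0.00126    **
#> 4   ONL   0.877 0.0407        0.905     0.0273 0.59524
#> 5   OPL   4.112 0.3045        1.789     0.1083 0.00253    **
#> 6  RNFL   2.296 0.1440        1.921     0.0998 0.10606
```

The scenario doubles the amyloid fraction in the AD mid-peripheral
GCL/IPL/INL/OPL only, and exactly those four geo-layers are flagged
(`mean_*` are group means of donor data points in %, `se_*` their
standard errors, p-values from the exact rank-sum test). The
colocalization summary shows the microglia pattern built into the
scenario — strong Aβ–IBA-1 enrichment in controls (ρ = 3), blunted in
AD (ρ = 1.5, and with 5 donors the exact paired test cannot fall below
p = 0.0625):

```r
res$coloc_summary
#>   group   n_keys n_p05 n_p01 n_p001
#> 1 AD          12     0     0      0
#> 2 control     12    12     0      0
```

`plot_layer_profile()` and `plot_coloc_profile()` draw the
corresponding star-annotated bar figures. Disk-based workflows
(`write_dataset()`, `run_simulate()`, `run_analyze()` with a YAML
config, or the `inst/cli/retcoloc` wrapper) produce the same tables as
CSV plus a JSON-lines audit log of thresholds and exclusions.

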