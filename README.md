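# dfmcyto

Flow-cytometry demultiplexing and absolute quantification for
**differential fluorescent marking (DFM)** of bacteria.

DFM labels strains with three fluorescent proteins — mCherry, sYFP2 and
mTagBFP — singly and pairwise, creating six presence/absence barcodes
(R, Y, B, RY, RB, YB). A three-laser cytometer (405/488/561 nm) then
resolves a mixed community, such as a six-member synthetic community
(SynCom) colonising plant roots, into per-strain identities without
sequencing or plating. `dfmcyto` is for microbiome and synthetic-biology
researchers who want that analysis as tested, scriptable code:

- **Gating** (`gate_chain()`): Bacteria → Singlets (FSC > 0,
  aspect-ratio of SSC > 0.4) → colour populations (Red: "561-611/31"
  > 550 FI; Yellow: "488-528/46" > 500 FI; Blue: "405-456/51" > 450 FI,
  all strict) → six exclusive Combined populations. Triple-positive and
  all-negative singlets are reported as `Unassigned`, never silently
  reclassified.
- **Quantification** (`events_to_emL()`, `emL_to_egr()`,
  `subtract_background()`, `to_relative()`): gated counts →
  events·mL⁻¹ (emL = count / analysed volume, with volume = flow rate ×
  time if not recorded; default 3.66 µL·min⁻¹) → events·g root⁻¹
  (egr = emL × harvest volume / root mass; default 25 mL), minus the
  mean uninoculated-plant background per (plant, population), clamped
  at zero.
- **Simulation** (`simulate_events()`, `simulate_mixture()`,
  `simulate_root_background()`): seed-deterministic events with Gaussian
  spectral spillover, log-normal expression noise and autofluorescence,
  doublets and debris — calibrated so the published detection bounds
  (≥ 90% colour detection, ≤ 1.7% unlabelled false positives, ≥ 95%
  combined-population accuracy) hold with margin.
- **Growth fitness** (`simulate_growth_curve()`, `estimate_mgt()`): mean
  generation time MGT = ln 2 / µ from a sliding log-linear window with
  an R² guard.
- **Assembly statistics** (`summarise_series()`, `correlate_strains()`):
  mean ± SEM time series and replicate-paired Pearson correlations.
- **Tn7 junction calling** (`make_junction()`, `call_att()`,
  `summarise_offsets()`): the distance from the *glmS* stop codon to the
  attB insertion point (canonically 25 ± 1 bp) and the 5-bp target-site
  duplication, from junction reads.
- **Pipeline** (`run_pipeline()`, `dfm_cli()`): strictly validated JSON
  config, tidy CSV outputs, JSON run report, byte-reproducible.

## Worked example

Simulate an equal six-strain mixture, demultiplex it, and quantify one
root sample:

```r
library(dfmcyto)

mix <- simulate_mixture(dfm_strains(), rep(1/6, 6), 60000, seed = 3841)
lab <- gate_chain(mix)
sum(lab$in_singlets)
#> [1] 55775

round(100 * table(lab$combined[lab$in_singlets]) / sum(lab$in_singlets), 2)
#>          R          Y          B         RY         RB         YB Unassigned
#>      16.25      16.70      16.39      16.43      17.12      16.80       0.32

sc <- score_assignments(lab, mix$truth)
round(100 * sc$per_class_accuracy, 1)
#>    B    R   RB   RY    Y   YB
#> 99.9 98.2 99.9 98.4 98.6 99.9
```

Each combined population receives ~1/6 of the singlets (multinomial
noise around 16.7%), and every strain is assigned its own label for
≥ 98% of its singlets. Converting to absolute abundance for a sample
acquired 10 min at 3.66 µL·min⁻¹ from a 0.5 g root washed in 25 mL:

```r
meta <- sample_meta("pea_7dpi_r1", timepoint = 7,
                    acquisition_time_min = 10, root_mass_g = 0.5)
abundance_table(lab, meta)[, c("population", "count", "emL", "egr")]
#>   population count    emL      egr
#> 1          R  9063 247623 12381148
#> 2          Y  9312 254426 12721311
#> 3          B  9142 249781 12489071
#> 4         RY  9163 250355 12517760
#> 5         RB  9546 260820 13040984
#> 6         YB  9369 255984 12799180
#> 7 Unassigned   180   4918   245902
```

Mean generation time from a noise-free growth curve generated at
MGT = 3.4 h:

```r
estimate_mgt(simulate_growth_curve(mgt = 3.4, noise_sd = 0))$mgt
#> [1] 3.418946
```

The whole pipeline, from the bundled demo config:

```r
cfg <- system.file("extdata", "oxcom6.json", package = "dfmcyto")
res <- run_pipeline(cfg, out_dir = "demo_run")
```

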