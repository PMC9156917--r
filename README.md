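# clinemap

Geographic cline analysis of Mendelian colour polymorphism from
dominance-scored occurrence records.

Warning-coloured species are often polymorphic, and the geography of that
polymorphism — where alleles are fixed, where they mix, and how wide the
transitions are — reflects the balance between selection (e.g. predator
learning against rare morphs) and dispersal. `clinemap` is for researchers
who have georeferenced records of individuals scored only into **dominant**
and **recessive** phenotype classes at one or more loci (heterozygotes
indistinguishable from dominant homozygotes), typically pooled from museum
collections, fieldwork and citizen-science photographs. It provides the full
chain:

1. **records** — read/validate record CSVs (source, coordinates, per-locus
   class calls, missing allowed);
2. **gridding** — aggregate into 4°/2° grid cells; estimate the recessive
   allele frequency per cell under Hardy–Weinberg equilibrium,
   `q̂ = sqrt(n_rec / n_scored)`; classify cells as near-fixed (> 0.95),
   polymorphic (0.05–0.95) or near-absent (< 0.05); compare sources by
   per-cell regression;
3. **geodesy** — project cells onto great-circle transects using
   cross-track and along-track distances on the mean-radius sphere, with a
   450 km corridor;
4. **cline** — fit the hybrid-zone sigmoid
   `f(x) = 1 / (1 + exp(−4(x − c)/w))` with optional exponential tails and
   frequency scaling (`p(x) = pmin + (pmax − pmin) f(x)`); six models
   (scaling ∈ {none, fixed, free} × tails ∈ {none, both}) compared by
   AICc; posteriors by Metropolis MCMC (3 chains, 10⁴ burn-in + 10⁵
   generations, adaptive proposals during burn-in only) giving centre/width
   credible intervals, the fuzzy-cline envelope, and centre offsets between
   loci;
5. **envassoc** — test morph-frequency association with abiotic covariates
   (bio01 temperature, bio20 radiation, bio12 precipitation, bio28 soil
   moisture) via weighted screens, VIFs, and GLS over all 16 covariate
   subsets with exponential spatial correlation
   `Σij = σ² √(vi vj) exp(−dij/ρ)` and variance weights `vi = 1/ni`;
6. **synthdata** — a generator of synthetic record datasets with known
   clinal truth, hotspot sampling bias, two record sources and realistic
   missingness, so the whole pipeline is testable without any download.

## Worked example

Simulate a 20 000-record world whose locus-A and locus-C clines are centred
1500 km apart, then recover that offset through the full pipeline:

```r
library(clinemap)

world <- world_spec(n_records = 20000, seed = 106)
ds    <- sample_records(world)
summarize_sources(ds)
#>     source n_records A_scored B_scored C_scored
#> 1 research     13546    13546    13546    13546
#> 2  citizen      6454     6454     3199     6454
#> 3    total     20000    20000    16745    20000
```

About half of the citizen records carry no B-locus call (background colour
is not scorable from underside photographs). Grid and summarise:

```r
grid <- build_grid(ds, grid_spec(4))
grid
#> frequency_grid: 120 occupied 4-degree cells, 20000 records
round(fixation_summary(grid, "B", min_n = 5)$percent, 1)
#> near_absent polymorphic  near_fixed
#>        38.2        19.1        42.7
```

Fit both clines along the generating axis and measure their offset:

```r
axis  <- world$loci$A$axis        # a 'transect' object (~3892 km)
fit_a <- fit_cline(grid, axis, "A", model = cline_model_spec())
fit_a
#> cline_fit: locus A along 'synthetic-axis' (27 cells)
#>   model: scaling = none, tails = none; orientation increasing
#>   centre: 963 km (95% CI 954-971)
#>   width:  485 km (95% CI 464-506)

fit_c <- fit_cline(grid, axis, "C", model = cline_model_spec())
off   <- centre_offset(fit_a, fit_c)
off$offset_km
#> [1] 1503.972
```

The generating centres were 1000 and 2500 km: the pipeline recovers the
1500 km offset to within a few km (the ~40 km centre shifts reflect the
hotspot sampling geometry, which both loci share, so the offset is
accurate). `fit_cline(..., model = "select")` instead ranks all six model
specifications by AICc; `write_cline_fit()` exports the report as JSON and
the credible envelope as CSV.

A YAML-driven command-line front-end wraps the same functions:

```sh
Rscript inst/cli/clinemap run-all --config config.yaml --seed 1
```

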