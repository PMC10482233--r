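# pseudospace

Latent pseudotime for spatially profiled lymphoid-tissue microregions, and
transfer of the resulting gene signature to lymphoma cohorts.

## The problem

Digital spatial profiling measures probe-count transcriptomes for a small
number of segmented microregions (ROIs) of reactive lymphoid tissue:
germinal-center dark zone (DZ), light zone (LZ), and peri-/inter-follicular
areas (Peri). These zones are snapshots of a continuous biological
progression. `pseudospace` is for analysts who want to:

1. estimate that progression as a one-dimensional **pseudotime** over the
   ROIs, from bulk-style expression, via a Bayesian one-factor model
   ($y_{gj} = \mu_g + c_g z_j + \varepsilon_{gj}$ with
   $\varepsilon_{gj} \sim \mathcal N(0, \tau_g^{-1})$) fitted by
   coordinate-ascent variational inference, oriented DZ → Peri;
2. derive the **pseudotime signature**: genes whose Spearman correlation
   $\hat\rho_i$ with pseudotime survives Bonferroni control of the
   family-wise error rate at 5%, split into positively and negatively
   correlated sets;
3. project external DLBCL cohorts onto the trajectory through the
   correlation-weighted score
   $\mathrm{score}_j = \sum_{i=1}^{n} \hat\rho_i\, x_{ij}$
   and cut each cohort into low / intermediate / high **tertile groups**;
4. quantify what the groups capture: cell-of-origin and genetic-subtype
   composition (Jaccard index, Fisher exact tests) and survival
   differences (Kaplan-Meier, log-rank, proportional-hazards diagnostics,
   multivariate Cox with COO and IPI).

Seeded generators (`simulate_spatial()`, `simulate_cohort()`) plant known
trajectories, enrichments and hazards, so the whole pipeline is testable
without any external download. See the methods vignette
(`vignettes/spatial-pseudotime-methods.Rmd`) for the model, the numerical
choices, and what the simulations do and do not emulate.

## Worked example

```r
library(pseudospace)

# spatial stage: 15 ROIs, 400-gene panel with planted trends
sim  <- simulate_spatial(n_per_zone = 5, n_genes = 400,
                         frac_pos = 0.1, frac_neg = 0.15,
                         effect_size = 2, seed = 42)
norm <- q3_normalize(sim$data)
fit  <- orient_pseudotime(fit_pseudotime(norm))
fit
#> <pseudotime_fit> 15 samples, 400 genes; 29 CAVI iterations (converged)
#> final ELBO: -6684.81; oriented DZ -> Peri

head(tidy(fit), 4)
#> # A tibble: 4 x 4
#>   roi_id zone       z   z_sd
#>   <chr>  <chr>  <dbl>  <dbl>
#> 1 DZ_1   DZ    -0.243 0.0343
#> 2 DZ_2   DZ    -0.259 0.0343
#> 3 DZ_3   DZ    -0.580 0.0343
#> 4 DZ_4   DZ    -0.309 0.0343

sig <- bonferroni_select(correlate_genes(norm, fit$z), alpha = 0.05)
sig
#> <pseudotime_signature> 36/400 genes selected at FWER 0.05 (17 positive, 19 negative)
```

The fitted pseudotime `z` orders the ROIs (negative = DZ-like start,
positive = Peri-like apex; `z_sd` is its posterior uncertainty), and 36 of
the 400 panel genes track it strongly enough to clear the Bonferroni gate.
Scoring a cohort with that signature:

```r
cs <- simulate_cohort(sig, n_patients = 300, seed = 7)
sc <- pseudotime_score(cs$data, sig)
sc
#> <scored_cohort> 300 patients scored with 36 signature genes (0 missing)
#> # A tibble: 300 x 3
#>   patient_id score group
#> 1 P0001       47.0 high
#> 2 P0002      -33.3 low
#> ...

fisher_association(unclass(table(cs$data$patients$coo, sc$group)))
#> Fisher exact test (monte_carlo): p = 1e-05

d <- merge(as.data.frame(sc), cs$data$patients, by = "patient_id")
logrank_test(d, os_time, os_event, group)
#> statistic 20.7, df 2, p 3.2e-05 (n = 300)

tidy(cox_multivariate(d, os_time, os_event, group, coo, ipi))
#> # A tibble: 6 x 6
#>   term              estimate    hr conf_low conf_high   p_value
#> 1 groupintermediate   -0.217 0.805    0.584     1.11  0.184
#> 2 grouphigh           -0.755 0.470    0.332     0.665 0.0000211
#> ...
```

The tertile groups carry the planted structure: the COO mix differs across
groups (Fisher p = 1e-05), survival separates (log-rank p = 3.2e-05), and
in the multivariate Cox — references: low pseudotime, GCB, low IPI — the
high-pseudotime group keeps an independent effect (HR 0.47 vs low) while
the noise covariates sit near 1. `autoplot()` methods (pseudotime fits,
scored cohorts, KM curves), `plot_trajectory()` and
`plot_signature_heatmap()` draw the standard displays, and
`run_pipeline()` chains every stage from TSV/GEO inputs to a hashed
artifact manifest.

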