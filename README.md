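# glycontact

Quantitative analysis of glycan–protein CH–π recognition, for structural
glycobiologists and lectin engineers. Lectins read glycans largely through
CH–π interactions — pyranose C–H bonds stacking on the π face of Trp, Tyr
and Phe side chains — and `glycontact` provides the four quantitative
stages such a study needs:

1. **CH–π contact statistics** over multi-model PDB trajectories. For each
   (glycan C–H hydrogen *i*, aromatic ring center *j*) pair the smooth
   contact score is the rational switching function

   c(r_ij) = (1 − (r_ij/r₀)ⁿ) / (1 − (r_ij/r₀)ᵐ),  r₀ = 0.3 nm, n = 6, m = 12,

   and a residue's per-frame coordination number is the sum over pairs
   (both Trp rings contribute). Time series, means, and integer-contact
   distributions follow.
2. **Interaction-frequency networks**: per (protein residue, glycan
   residue) pair, the fraction of frames with minimum heavy-atom distance
   ≤ 0.45 nm — the quantity edge thickness is proportional to in
   interaction diagrams.
3. **1:1 binding isotherms**: K_D estimation from titration curves using
   the exact mass-action (ligand-depletion) solution
   f_b = ((L+T+K_D) − √((L+T+K_D)² − 4LT)) / 2T with the labeled target T
   fixed (default 50 nM), replicates sharing K_D, and fold-change
   comparison between protein variants.
4. **Proximity-labeling enrichment**: deterministic minimum imputation,
   per-protein fold change and two-tailed Student's t-test, and the
   compound filter FC > 5 & p < 0.01 & ≥2 unique peptides in ≥2
   replicates, with BH FDR reported alongside.

Seeded synthetic-data generators (two-state contact trajectories, noisy
titrations, two-channel quantification tables with left-censored
missingness) give every stage a ground truth to be tested against, with no
external downloads. See the methods vignette
(`vignettes/glycan-chpi-methods.Rmd`) for the models, assumptions and
design decisions.

## Worked example

```r
library(glycontact)

# a 2000-frame two-state trajectory: 70% bound at 0.3 nm, 30% unbound at 1.0 nm
sim <- generate_two_state_trajectory(n_frames = 2000, occupancy = 0.7, seed = 42)
series <- contact_timeseries(sim$trajectory, "A:23")   # the Phe-like residue
mean_contacts(series)
#> 0.321            # generator expectation 0.348; a bound frame scores c(0.3) = 0.5
contact_distribution(series, 0.1)$integer_counts
#>    0    1
#> 1394  606        # frames rounding to 0 vs 1 contacts out of 2000

interaction_frequencies(sim$trajectory)$edges
#>   protein_residue glycan_residue frequency mean_min_distance_nm
#> 1        A:23:PHE        G:1:NAG     0.573            0.6676853

# K_D fitting: 3 noisy replicates generated at the depletion isotherm
g <- generate_titration(kd = 1.52, target_conc_uM = 0.05, noise_sd = 2,
                        n_replicates = 3, seed = 42)
fit_kd(g$curve, target_conc_uM = 0.05)$kd_uM
#> 1.455            # true value 1.52 uM

# fold change between variant and reference dissociation constants
fold_change(141.64, 1.52)
#> $ratio 93.18421  $ratio_rounded 93.2  $direction "weaker"

# enrichment filter on a 1000-protein table (60 truly enriched at FC 8)
qt <- generate_quant_table(seed = 42)
res <- apply_filters(protein_stats(impute_min(qt$table)), qt$table)
length(res$enriched_set)
#> 53               # 88.3% of the designated set, zero background calls
```

The interpretation: the contact statistic recovers the designed occupancy
(0.7 × 0.5 ≈ 0.35 expected mean contacts, within sampling error of the
dwell-correlated chain); the isotherm fit recovers the generating K_D
within noise; the filter reclaims the designated enriched proteins except
those losing signal to detection-limit censoring or sparse peptide draws.

Multi-stage runs with a manifest (inputs hashed, seed and parameters
recorded) are available through `run_pipeline()` or the thin CLI wrapper
`inst/scripts/glycontact.R`.

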