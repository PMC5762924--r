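# paleotrait

Trait-based analysis of late-Quaternary plant communities from sedimentary
ancient DNA (sedaDNA) metabarcoding.

## The scientific problem

Permafrost sediments preserve plant DNA across the last ~50,000 years.
Metabarcoding such archives yields a samples × MOTUs read-count table — a
quantitative record of northern high-latitude vegetation through the
pre-LGM (> 25 ka BP), LGM (25–15 ka BP) and post-LGM (< 15 ka BP) climatic
periods. Attaching mutualist traits to each MOTU — mycorrhizal type
(AM/ECM/ERM/NM) and status (OM/FM/NM), symbiotic N-fixation, pollination
mode — plus growth form turns that floristic record into a record of how
the *mutualist structure* of vegetation tracked climate. `paleotrait` is a
package for ecologists working with such data: it implements the full
analysis chain with explicit contracts, deterministic seeds and a
synthetic-data generator so every statistical component is testable.

The core quantities and models:

- **Community-weighted trait shares.** For sample *j* and trait category
  *c*, the read-weighted share is Σ_{i∈c} y_ij / Σ_i y_ij (MOTU-weighted
  uses presence instead of reads). Period estimates average per-sample
  shares; 95% CIs come from a stratified bootstrap (resampling samples
  within periods, 2.5/97.5 percentiles).
- **PERMANOVA** on Bray–Curtis distances d = Σ|x−y| / Σ(x+y): Gower
  centering G = C(−½ D∘D)C, sequential sums of squares via nested hat
  matrices SS_k = tr(H_k G) − tr(H_{k−1} G), pseudo-F tested by joint
  relabeling of D, plus pairwise contrasts with compact letters.
- **OMI niche ordination**: each MOTU's marginality m_i = Σ_j p_ij z_j in
  the standardized period space; OMI_i = ‖m_i‖², with the exact
  decomposition inertia = OMI + tolerance + residual tolerance, a Monte
  Carlo test of the mean OMI, Euclidean PERMANOVA models of traits on the
  species scores, and Dunn's rank tests per axis.
- **Spatial diagnostics**: Mantel correlograms on residual (period-removed)
  community distances, multi-scale variance decomposition
  γ_total = γ_explained + γ_residual + cross per distance class, and a
  simulation-based estimate of PERMANOVA type-I inflation under a spatial
  Gaussian process.
- **Phylogenetics**: grafting MOTUs onto a backbone supertree at the
  lowest containing taxonomic rank, and GLS with co-estimated Pagel's λ
  (V(λ) scales shared branch lengths off-diagonally; ML over [0, 1]).
- **Sensitivity**: random trait-database errors at 1–20% rates
  (ERM and N-fixation protected as phylogenetically conserved), share
  correlations and re-fit niche models across 1000 replicates.

## Worked example

```r
library(paleotrait)

cfg <- sim_config(n_samples_per_period = c(30, 15, 15), n_motus = 60,
                  overdispersion = 5, seed = 42)
ds <- filter_dataset(simulate_dataset(cfg))
ds
#> paleo_dataset: 60 samples x 60 MOTUs, 965625 reads
#>   periods: pre-LGM=30, LGM=15, post-LGM=15
#>   phylogeny: 60 tips

comp <- sample_trait_shares(ds$read_matrix, ds$traits, "myc_type", "reads")
bootstrap_ci(comp, ds$samples, B = 1000, seed = 1)
#> stratified bootstrap (B = 1000, level = 0.95) for myc_type shares (reads-weighted)
#>   pre-LGM :
#>     AM           0.62 [0.61, 0.63]
#>     ECM          0.08 [0.07, 0.09]
#>     ERM          0.04 [0.03, 0.04]
#>     NM           0.26 [0.25, 0.27]
#>   LGM :
#>     AM           0.33 [0.32, 0.35]
#>     ...
#>   post-LGM :
#>     AM           0.11 [0.10, 0.11]
#>     ...

permanova(bray_curtis(unclass(comp)),
          data.frame(period = ds$samples$period), n_perm = 999, seed = 1)
#> PERMANOVA (sequential SS,  999 permutations)
#>          Df SumOfSqs     R2     F     p
#> period    2   3.0230 0.9569 632.5 0.001
#> Residual 57   0.1362 0.0431    NA    NA
#> Total    59   3.1590 1.0000    NA    NA

om <- omi_analysis(ds$read_matrix, ds$samples$period)
om
#> OMI ordination: 60 MOTUs, 3 periods, 2 non-null axes
#>   eigenvalues: 0.4398, 0.1003
#>   u-weighted mean OMI: 0.5401
omi_randtest(ds$read_matrix, ds$samples$period, n_perm = 999, seed = 1)
#> OMI randomization test: mean OMI = 0.5401, p = 0.029 (999 permutations)
```

Reading the output: the generator was asked for a strong period signal, so
AM host plants dominate the pre-LGM reads (62%) and collapse toward the
post-LGM (11%) while NM plants rise — the period factor explains 96% of
the Bray–Curtis variation in mycorrhizal-type composition, and MOTUs sit
significantly farther from the study centroid in period space than random
relabelings allow (mean OMI 0.54, p ≈ 0.03). Axis 1 of `om` separates the
post-LGM (negative scores) from earlier periods, axis 2 the LGM from the
rest.

The whole chain (filter → composition → PERMANOVA → OMI → spatial → phylo
→ sensitivity) runs end-to-end with `run_all(config)`, which writes CSV
outputs and a checksummed `manifest.json` for reproducibility.

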