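---
title: "Methods: trait-based analysis of late-Quaternary sedaDNA communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based analysis of late-Quaternary sedaDNA communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Sedimentary ancient DNA (sedaDNA) metabarcoding of permafrost deposits
yields read-count tables of molecular operational taxonomic units (MOTUs)
for plant communities spanning the last glacial cycle. Attaching mutualist
traits to those MOTUs — mycorrhizal type (AM, ECM, ERM, NM) and status
(obligate OM, facultative FM, NM), symbiotic nitrogen fixation, pollination
mode — and growth form turns a floristic record into a record of how the
*interaction structure* of vegetation changed between the pre-LGM
(> 25 ka BP), LGM (25–15 ka BP) and post-LGM (< 15 ka BP) climatic periods.
`paleotrait` implements that analysis chain as reusable, tested components:
dataset filtering, trait-table merging, community-weighted composition with
bootstrap intervals, PERMANOVA, OMI niche ordination, spatial diagnostics,
phylogenetic models, and a trait-error sensitivity simulation, together
with a synthetic-data generator that emulates the statistical structure of
such data so every stage can be validated without the original
supplementary tables.

## Data model and filtering

A dataset bundles a samples × MOTUs integer read matrix, per-sample
metadata (site, coordinates, age in ka BP, derived climatic period) and a
per-MOTU trait table. Period assignment is a total, monotone step function
of age; the LGM interval is stated in the literature as "25 to 15 ka BP"
without closure, so we fix `(15, 25]` for the LGM and `[0, 15]` for the
post-LGM — a convention, made explicit because nothing in the record pins
down samples dated exactly to a boundary.

Trait values are whitespace-trimmed and case-insensitively matched to a
canonical vocabulary at ingest; missing cells become the explicit
`undefined` level rather than being dropped silently. Two hard invariants
are enforced everywhere: NM is a level of both mycorrhizal traits and must
agree whenever both are defined, and (in generated data) no N-fixer is
non-mycorrhizal, matching the observed absence of NM taxa among fixers.

`merge_trait_sources()` combines partial trait compilations
most-recent-first, on the rationale that newer databases cover, update and
correct older ones; a conflict that leaves NM type/status inconsistent is a
validation error naming the MOTUs rather than a silent overwrite.

`filter_dataset()` applies, in a fixed order, (1) the rare-MOTU rule
(total reads < 5, the omission threshold of the source data set), (2)
removal of MOTUs undefined for any of the five traits, (3) removal of
samples left empty. On the published pipeline the order is immaterial
because rare filtering happened upstream; we fix it for determinism. The
operation is idempotent and reports all removal counts.

## Composition and uncertainty

Read-weighted trait shares are community-weighted means with read counts
as the abundance proxy: the share of a category in a sample is its read
total over the sample's reads. MOTU-weighted shares use presence
(reads > 0) instead. Period-level estimates are the unweighted mean of
per-sample shares, re-normalized — samples are the replication unit, which
matches the bootstrap: confidence intervals resample sample ids with
replacement *within* each climatic period and take raw 2.5/97.5 percentiles
(linear-interpolation definition, no BCa). `B = 1000` by default; the
source text's bootstrap count is literally missing from the available
methods text, and 1000 matches the stated replicate count of its
sensitivity analysis. A pooled-reads period aggregation is available behind
a flag but is not the default, since it would weight samples by sequencing
depth, which is a laboratory artefact.

## PERMANOVA

`permanova()` implements the distance-based partitioning directly: Gower
centering `G = C(-D∘D/2)C`, sequential (Type I) sums of squares through
nested hat matrices (`SS_k = tr(H_k G) − tr(H_{k−1} G)`), pseudo-F, and
permutation p-values by joint row/column relabeling of the distance matrix,
with ties counted as at least as extreme and a floor of `1/(n_perm + 1)`.
`n_perm = 999` by default (the convention of the reference implementation;
no count is stated in the source). Permutation is free — the study reports
no blocking structure. Under Euclidean distance the one-factor pseudo-F
equals the classical ANOVA F exactly, which the test suite verifies to
1e-9, and the term table matches `vegan::adonis2(by = "terms")` to the same
tolerance; `vegan` serves only as a cross-check, never as the
implementation. Exhaustive enumeration over all `n!` relabelings is
available for small n, where the hand-worked two-group example
({0,1} vs {3,4}) gives SS 9/10, F = 18 and an exact p of 1/3.

Pairwise period contrasts run the same machinery on each pair's
sub-matrix and are summarized as a compact letter display (insert-absorb
algorithm); pairwise p-values are unadjusted by default with Holm available,
and α = 0.05, both documented choices where the source is silent.

## OMI niche ordination

The outlying mean index places each MOTU at its read-weighted average
position in a standardized environment space and measures the squared
distance of that position from the study centroid. The environment table
is the period dummy coding, centered and standardized with uniform sample
weights 1/n (the convention of the classical implementation; the source is
silent), so a three-level factor spans a rank-2 space and exactly two
non-null axes exist. Species profiles are `p_ij = y_ij / y_i+`, species
weights are read-mass fractions, and per MOTU the total profile inertia
decomposes exactly into `omi + tol + rtol` (marginality, tolerance along
the marginality direction, residual tolerance); the ordination eigenvalues
sum to the weight-averaged OMI. Both identities are asserted at 1e-9.

Two conventions are ours and documented: axis signs are fixed so the
post-LGM sample centroid is negative on axis 1 and the LGM centroid
negative on axis 2 (matching the axis reading "post-LGM = more negative");
and the Monte Carlo test permutes the sample-to-period assignment as one
global row permutation of the environment table, preserving the among-MOTU
covariance of the community table, with `p = (#{perm ≥ obs} + 1)/(n_perm + 1)`.
A documented alternative (per-species profile shuffling) was rejected
because it destroys the community covariance that the statistic shares
across species. One practical caveat the simulation work made clear: with
heavily overdispersed read tables the permutation distribution of the mean
OMI is heavy-tailed (profile concentration, not period signal, dominates),
so the randomization test has limited power at the skew typical of raw
metabarcoding data — the calibration tests confirm its level is correct
regardless.

Trait–niche models use the species scores (Euclidean distance) as the
PERMANOVA response in three designs: each trait alone; growth form first,
trait second; and growth form plus non-confounded mutualist traits first,
focal trait last. Mycorrhizal type and status are strongly associated and
partially confounded, so they never enter the same model; when the focal
trait is pollination or N-fixation, status (the stronger of the pair in
this record) represents the mycorrhizal block among covariates — a choice
the source leaves open. Growth form itself is only tested univariately.
Per-axis category contrasts use Dunn's rank test with mid-rank ties and
the standard tie correction; residuals of parametric fits on such scores
are not normal, which is why a rank test is used at all.

## Spatial diagnostics

Geographic distances are haversine on a 6371.0 km sphere. The Mantel
correlogram computes, per distance class (default breaks 0, 200, 500,
1000, 2000, ∞ km, anchored to the reported short-range positive and
long-range negative autocorrelation), the sign-flipped correlation between
the class indicator and ecological distances over all pairs, so positive r
means within-class similarity; p-values come from joint relabelings with a
progressive Holm adjustment (class k adjusted within classes 1..k). The
ecological input is the *residual* distance structure after projecting the
period effect out of the Gower-centered matrix and re-expressing it as
pairwise distances — our reading of the "residual matrix from db-RDA"
construction, implemented with the same Gower machinery as PERMANOVA.

The multi-scale decomposition computes, per distance class, the
multivariate semivariance of the total, period-fitted and residual trait
composition; the cross term `γ_total − γ_explained − γ_residual` is the
scale-dependence diagnostic, near zero everywhere under a
scale-independent trait–climate relationship. With one global class it
reduces exactly to the between/within variance partition.

The influence of autocorrelation on PERMANOVA's type-I error is estimated
by simulation (the source's own translation from variance underestimation
to error rates is unspecified): null multivariate responses are drawn from
a Gaussian process with exponential covariance `sill·exp(−d/range)` plus
unit nugget at the observed coordinates, and the rejection fraction at
α = 0.05 is reported with a binomial interval. With sill 0 the test sits at
its nominal level; autocorrelation spatially aligned with the period
layout inflates it.

## Phylogeny and PGLS

`graft_motus()` places MOTUs on an ultrametric backbone species tree:
single-species MOTUs relabel their tip; others attach at the MRCA of the
backbone members of the lowest rank (genus, tribe, subfamily, family)
containing all component taxa, with pendant length equal to the attachment
node's height so tips stay contemporaneous — branch-length handling is not
stated in the source, and keeping the tree ultrametric is the conservative
choice. MRCA generalizes "the node representing the rank" to
non-monophyletic backbones; a rank with a single backbone member attaches
at the midpoint of that member's terminal branch. Unplaceable MOTUs are an
error list, never a silent drop. Redundant backbone species are pruned
afterwards; at the published attachment counts (26 species-level + 75
genus + 7 tribe + 5 subfamily + 18 family) the result is a 131-tip MOTU
phylogeny, which is also what `scripts/acceptance.R` recomputes.

`pgls_lambda()` fits GLS with Pagel's λ scaling the off-diagonal shared
branch lengths, by ML (not REML) over λ ∈ [0, 1] with a bounded 1-D search
(tolerance 1e-6, boundary values checked explicitly). On a star phylogeny
λ is unidentifiable and is reported at the lower bound with a flag; the
fit then equals OLS exactly. The test suite recovers λ = 1 and λ = 0 from
simulated 200-tip trees and matches `nlme::gls` with the Pagel correlation
structure on the same data. `category_niche_means()` contrasts arithmetic
category means of an OMI axis with the GLS cell means under the estimated
λ; for phylogenetically clustered traits the phylogenetic standard errors
are systematically wider — the precision cost of acknowledging
non-independence.

## Sensitivity to trait-database error

Trait compilations carry misclassification (an estimated 10% for
mycorrhizal assignments). `perturb_traits()` injects errors at a given
rate into the susceptible traits — mycorrhizal status, mycorrhizal type
excluding ERM, pollination — selecting exactly `round(rate · S)` MOTUs per
trait uniformly without replacement and redrawing each selected category
uniformly from the permitted alternatives. ERM and N-fixation are treated
as phylogenetically conserved and are never altered, on either side of a
swap. The source does not say how the NM type/status linkage survives
perturbation; our coupling rule (type→NM forces status NM; type out of NM
redraws status from OM/FM; status→NM — never offered to ERM taxa — forces
type NM; status out of NM redraws type from AM/ECM) restores consistency
deterministically, and these coupled edits are reported separately from
the `round(rate · S)` direct reassignments, which the perturbation audits
exactly. Whether the original perturbed traits jointly or independently is
not fully specified; we perturb independently per trait per replicate.

`sensitivity_curve()` Pearson-correlates the flattened per-sample
read-weighted shares of all five traits between original and perturbed
tables ("correlated" is not attributed to a coefficient in the source;
Pearson on shares is the plain reading); medians are non-increasing in the
rate. `sensitivity_model_rerun()` re-fits the most conservative niche
model (status after growth form and non-confounded traits) per replicate
and reports median R² and p; the ordination itself does not depend on
traits, so species scores are held fixed.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the statistics consume, not
sequences or taphonomy. Defaults are the study conditions: 216 samples
(145/32/39 across pre-LGM/LGM/post-LGM) from 21 sites, 131 MOTUs, trait
marginals equal to the published counts over 131, and trait–trait
correlation induced by conditioning mycorrhizal type on growth form (woody
taxa biased toward ECM/ERM, obligate status biased toward ECM/ERM taxa,
graminoids wind-pollinated) — the sign pattern of the observed
associations, with no attempt to match the V values exactly. Counts are
Dirichlet-multinomial: expected period profiles are lognormal baseline
MOTU weights times exponentiated per-trait period effects (log-fold
shifts, defaults chosen to mirror the qualitative record: AM/forb/OM
decline toward the post-LGM, ECM/NM/woody/wind increase, N-fixers dip in
the LGM), and per-sample profiles are drawn with concentration
`0.3 · n_motus · π` — concentration 0.3 reproduces the heavy skew of
metabarcoding read tables. Sequencing depths are lognormal
(meanlog 8.9, sdlog 1.5, giving a mean depth near the study's
~23,000 reads per sample); site effects follow an exponential-covariance
Gaussian process (range 500 km, sill 0.25 — a moderate level consistent
with the weak autocorrelation reported) and tilt MOTU weights along a
random loading vector. An optional `target_shares` calibration rescales
one category's weights per period so its expected read share hits a
requested value exactly, which gives tests an analytic oracle.

The `truth` record carries the expected profiles and analytic per-period
trait shares; these are exact when the spatial sill is 0, which is how the
coverage tests use them. What passing tests on this generator do *not*
show: robustness to taxonomic mis-assignment, PCR/primer bias, DNA damage,
or non-exponential spatial structure — none of which the generator
emulates.

## Problem sizes and numerical choices

The test suite checks permutation-test calibration with 500 null
simulations per test (PERMANOVA, OMI randomization, Mantel class test;
rejection within [0.03, 0.07] at α = 0.05, n ≈ 20 per simulation with 99
permutations), bootstrap coverage with 200 generated datasets of 40
samples per period (coverage within [90%, 99%] at the nominal 95%), and λ
recovery with 100 replicates of 200-tip trees per scenario — sizes chosen
to make Monte Carlo error small relative to the asserted bands while
keeping the suite quick on one CPU. Ties in permuted statistics count as
at least as extreme (conservative); eigenvalues below 1e-10 are treated as
null axes; degenerate Cholesky factorizations are penalized during λ
optimization rather than crashing it; and all stochastic components take
explicit seeds, with pipeline stages sub-seeded as `seed + stage index`.

## Known limitations

The published headline numbers (the real record's Tables and proportions)
require the original supplementary data, which this package does not ship;
everything numeric here is validated on synthetic data plus the
self-contained arithmetic of the printed counts. The OMI randomization
test is level-correct but weak under extreme read skew. The db-RDA
residual construction and the type-I translation of the spatial analysis
are declared interpretations of tersely described methods. PGLS is
per-axis (matching "scores along individual axes"); no joint multivariate
phylogenetic model is attempted, and no Ornstein–Uhlenbeck alternative is
offered.
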