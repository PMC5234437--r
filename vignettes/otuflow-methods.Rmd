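---
title: "Methods and design choices in otuflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in otuflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

otuflow implements the downstream half of an amplicon workflow: it consumes
an OTU count table, a sample mapping file and a phylogenetic tree, and
produces normalized tables, diversity summaries, phylogenetic
beta-diversity with ordination and significance tests, per-rank taxonomic
compositions, gated nonparametric group comparisons, and CLR-based
correlations. This vignette explains the statistical choices, the defaults
and their units, what the synthetic generator does and does not emulate,
and the numerical conventions.

## Normalization

The default normalization is deterministic proportion rescaling: every
count is divided by its library size and multiplied by the smallest library
size in the table, `n_ij = c_ij · min_k S_k / S_j`. Unlike rarefaction this
introduces no random variance and discards no reads; within-sample
proportions are preserved exactly and every normalized sample sums to the
minimum depth. Normalized values are deliberately kept as reals: the
alpha-diversity step applies a 0.5-count detection floor, and rounding
first would apply a second, hidden threshold.

Classical rarefaction (`rarefy()`) is provided for compatibility. It
subsamples reads **without** replacement (multivariate hypergeometric), so
each rarefied count can never exceed the original and its expectation is
`depth · c_ij / S_j`. The rarefaction depth is a required argument rather
than defaulting to the minimum library size, making the information loss an
explicit decision.

`depth_report()` flags samples whose depth is at or below 1/10 of the
median depth — the classic symptom of a failed library (e.g. 2,000 reads
among ~20,000-read libraries) — but never removes them: deciding what is a
failed sample, or a negative control that should not enter the analysis,
is the analyst's responsibility. The boundary is inclusive so that the
canonical 2,000-vs-20,000 example is flagged.

## Alpha-diversity

Richness counts OTUs strictly above a floor of 0.5 normalized counts
(default): depth rescaling can produce fractional counts below half a read
that carry no evidence of presence. The same floored community is used for
the Shannon index `H = −Σ p_i ln p_i` (natural log, nats) and the Simpson
index `D = Σ p_i²`, so all indices describe one community; `--floor 0`
disables the filter. Raw indices are converted to effective numbers of
species (Hill numbers): `exp(H)` and the inverse Simpson `1/D`. Effective
numbers are linear in the intuitive sense — a community twice as diverse
has twice the effective number — and obey the ordering
`richness ≥ exp(H) ≥ 1/D`. The inverse Simpson `1/D` was chosen over the
Gini–Simpson complement `1/(1−D)` because only `1/D` is the order-2 Hill
number with the doubling property; the tests verify that doubling a
community doubles both effective numbers.

## Generalized UniFrac

For two samples A and B the distance is

```
d^(α)(A,B) = Σ_i b_i (p_Ai + p_Bi)^α · |p_Ai − p_Bi| / (p_Ai + p_Bi)
           ÷ Σ_i b_i (p_Ai + p_Bi)^α
```

where the sum runs over tree branches `i` with length `b_i`, and `p_Ai` is
the summed proportion in A of all leaves below branch `i`. Branches with
`p_Ai + p_Bi = 0` are skipped in both sums (the limit value of the
summand). α interpolates between sensitivity to rare lineages (α → 0) and
to dominant ones (α = 1, the abundance-weighted normalized form); the
default α = 0.5 is the balanced compromise. The implementation builds a
branch-by-leaf incidence matrix once and computes all pairs from branch
proportion vectors; the test suite checks it against an independent
brute-force loop over every branch (50 random tree/table fixtures, four α
values, tolerance 1e-10) and against hand-enumerated three-leaf cases
(1 for fully disjoint lineages, `2/(2+√2)` for sister taxa at α = 0.5).

Trees must cover every OTU in the table; leaves missing from the table are
treated as zero abundance, while OTUs missing from the tree are a hard
error (silently dropping them would bias the distances) unless pruning is
explicitly requested and logged. Unrooted input is midpoint-rooted
deterministically.

## Ordination, PERMANOVA, clustering

PCoA is classical scaling: eigendecomposition of the double-centred
`−½D²`. Negative eigenvalues, which generalized UniFrac can produce, are
reported but not corrected (no Cailliez/Lingoes); their axes are dropped.

NMDS minimizes Kruskal stress-1 via `vegan::monoMDS` (global model,
tied ranks averaged), with a multi-start strategy owned by the package:
the first start is the PCoA configuration, the remaining `n_starts − 1`
(default 19) are random, all under one seed, and the lowest-stress
solution is returned with a convergence flag — non-convergence warns,
never passes silently. NMDS runs on the generalized UniFrac matrix.

PERMANOVA partitions the total sum of squared dissimilarities
(`SS_T = Σ_{i<j} d²_ij / n`, within-group analogues per group) into
among- and within-group components and tests
`F = (SS_A/(k−1)) / (SS_W/(n−k))` by uniformly permuting sample labels;
`p = (1 + #{F* ≥ F}) / (n_perm + 1)`, never below `1/(n_perm+1)`. The
default 999 permutations follows the convention of the R ecosystem's
`adonis`; the implementation here is cross-checked in the tests against
`vegan::adonis2` (identical F and R²) and against exhaustive enumeration
of all label assignments on a 3+3 fixture (exact p = 0.1). Pairwise
PERMANOVA runs the same test per group pair and BH-adjusts across pairs.

Hierarchical clustering uses Ward's criterion on squared dissimilarities
(`ward.D2`), the variant that actually minimizes within-cluster variance;
dendrograms serialize to Newick.

## Taxonomic binning

Lineages are positional: the split taxonomy string is indexed as
kingdom–genus (depth 6), with short lineages padded by `Unknown`. At a
given rank every OTU maps to exactly one bin — its lineage prefix with
empty ranks replaced by `Unknown` — so OTUs unclassified at the rank but
with different known roots (`Bacteria;Firmicutes;Unknown` vs
`Bacteria;Bacteroidetes;Unknown`) never merge, and binning is an exact
partition: per-sample bin sums equal the input sums, and binning at genus
then re-binning at phylum equals binning at phylum directly. The stacked
composition plot may merge bins below a display cutoff (default 0.5% grand
mean) into "Other", but only in the figure — output tables are never
collapsed.

## Serial group comparisons

The cascade for relative-abundance variables, in order:

1. **Abundance cutoff** (default 0.5%): values strictly below are set to
   0 — at typical depths such values are within technical noise (see the
   replicate-CV analysis below). Values equal to the cutoff are kept.
2. **Zeros become missing.** A zero is "not detected", not a measured
   abundance; retaining zeros as values lets them dominate the rank tests
   and mask differences among the samples where the taxon actually occurs.
   The package's tests include a three-OTU construction — each OTU elevated
   in a disjoint subset of one group — where the rank test on zeros-retained
   data is null and the same test on detected-only values separates the
   groups.
3. **Prevalence gate** (default 0.30, strict `>`): tested only if some
   group has the variable in more than 30% of its samples — with two groups
   of 10 that means at least 4 positives in one group. Sparse variables
   yield unstable rank statistics and un-interpretable significance.
4. **Median gate** (default 1%, strict `>`, computed over detected
   values): a significant shift from 0.25% to 0.70% median abundance is
   rarely worth interpreting at the community level.

Tested variables get a tie-corrected Kruskal–Wallis test (chi-square
p-value, k−1 df), pairwise Mann–Whitney tests when there are more than two
groups (exact two-sided p when the smaller side has ≤ 8 observations and
no ties, else normal approximation with continuity and tie correction),
and Fisher's exact test on the groups × present/absent table (exact up to
2 groups or n ≤ 40, Monte-Carlo with ≥ 1e5 draws beyond). BH correction is
applied within each family — Kruskal–Wallis across variables, Mann–Whitney
across all variable × pair tests pooled (the more conservative choice),
Fisher across variables — with m equal to the number of non-missing
p-values. Gates apply only to relative-abundance variables;
alpha-diversity and numeric meta-variables pass through the same tests
ungated (`gated = FALSE`).

## Correlations

Relative abundances are compositional: if one taxon's absolute abundance
rises, every other proportion falls, generating correlations with no
biological meaning. Taxonomic variables are therefore CLR-transformed,
`clr_i = ln(p_i / g)`, with the geometric mean `g` computed per sample over
the detected taxa only (after the 0.5% cutoff and zero-masking), re-closed
to sum 1 — consistent with treating zeros as missing rather than imputing a
pseudocount (a `pseudocount` argument offers the conventional alternative).
Taxa detected in fewer than 30% of all samples are excluded; this
boundary is inclusive (9 of 30 samples qualifies), unlike the strict group
prevalence gate, and the discrepancy is deliberate and documented. After
standardization (mean 0, sd 1 over non-missing values), Pearson r is
computed on pairwise-complete observations with a t-distribution p-value
(n−2 df; r undefined below 2 observations, p withheld below 3), and BH
correction spans all pairs computed in the invocation. Every record
carries `n_obs`, because after zero-masking two correlations in the same
table can rest on very different evidence.

A property test documents what CLR does and does not fix: with one taxon
varying and all others constant in absolute abundance, raw-proportion
Pearson shows strong spurious negative correlations between the varying
taxon and the constant ones (and spurious positive ones among the constant
taxa, which co-move through the shared denominator); after CLR,
constant-taxon pairs are centred on zero. A residual `−ln(a_varying)/D`
term means CLR attenuates rather than eliminates the driver's imprint —
with D = 40 taxa it is small, but CLR is not a license to interpret weak
correlations involving dominant taxa.

## Synthetic data

The generator states a world resembling the template experiments: groups
of 10 samples (default 2 groups), 100 OTUs, library depth
negative-binomial with mean 20,000 reads (size 10), composition drawn per
sample from a Dirichlet over a geometric rank-abundance base (ratio 0.93,
total concentration 50 — an uneven community where the top OTU holds ~7%
and a long tail falls below the detection thresholds, which is what makes
the filter gates meaningful). Group effects multiply chosen OTUs' expected
proportions and re-close. The tree is a pure-birth (Yule) tree rescaled to
unit height; taxonomy is derived by cutting that tree at heights 0.8,
0.65, 0.5, 0.35, 0.2 (phylum–genus), so taxonomy is perfectly nested and
consistent with the phylogeny. Technical replicates share one true
composition with Dirichlet overdispersion `1/noise` (default
`noise = 0.002`, mild between-library variability) plus multinomial
counting noise; under this model alone the coefficient of variation of
relative abundances falls with mean abundance, reproducing the qualitative
abundance-vs-CV relationship that motivates the 0.5% cutoff.

What the generator does **not** emulate: chimeras and spurious OTUs,
taxonomy misannotation (taxonomy here is always consistent with the tree),
run- and batch-level structure in replicates, correlated taxa (beyond
closure), and absolute-abundance dynamics. A green test therefore
establishes algorithmic correctness and statistical calibration under the
stated model, not robustness to real-data pathologies.

## Numerical conventions and degenerate inputs

* Boundary conventions: abundance cutoff keeps values equal to it;
  prevalence and median gates are strict; the correlation prevalence
  filter and the depth flag are inclusive.
* All randomized procedures (rarefaction, NMDS starts, permutations,
  simulation) take explicit integer seeds; identical seeds give
  bit-identical results, and the CLI writes every parameter and seed to a
  run log.
* Zero-total samples are hard errors in normalization and UniFrac; samples
  with no detected taxon are dropped from CLR with a warning; zero-variance
  variables are dropped from standardization with a warning; an empty
  tested set is a logged, empty result — not an error.
* p-values from permutation tests use the `(1 + exceedances)/(n + 1)`
  estimator; exact-test switchovers (Mann–Whitney n ≤ 8, Fisher n ≤ 40)
  are implementation choices surfaced in the results.

## Known limitations

* No BIOM input, no variance-stabilizing count models, no
  Chao1/ACE-style richness estimation, no network inference — out of
  scope by design.
* Negative PCoA eigenvalues are reported but uncorrected.
* The Fisher test for more than two groups is the overall groups × 2
  table; pairwise 2×2 prevalence tests are not run by default.
* The published banded replicate-CV summary of the 10-library repeat
  experiment can only be recomputed from its supplementary OTU table,
  which is not redistributable here; the corresponding acceptance check
  runs when that file is supplied and fails otherwise.
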