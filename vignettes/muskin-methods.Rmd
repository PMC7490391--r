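---
title: "Methods: models, parameters and design choices in muskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in muskin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`muskin` re-implements, at desk scale, an analysis workflow for paired
DNA-based ("standing") and RNA-based ("active") 16S rRNA amplicon profiles
of mouse skin, comparing one spatially structured wild population against
laboratory groups. This vignette documents the models each stage assumes,
the tunable parameters with their defaults and units, what the synthetic
generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. Contaminant screening (frequency method)

A reagent contaminant contributes an approximately constant number of
molecules per extraction, so its relative frequency $f$ in a library
should scale as $1/c$ with the sample's nucleic-acid concentration $c$
(ng/µl). For each feature, using only samples with $f > 0$ and $c > 0$
(at least `min_samples = 5` of them, else no call), two one-parameter
models are fit to $(\log c, \log f)$ by least squares:

* contaminant: $\log f = b - \log c$ (slope fixed at $-1$),
* non-contaminant: $\log f = b$ (slope 0),

giving residual sums $SS_1$ and $SS_0$, each on $n-1$ degrees of freedom.
The score is $P = F_{n-1,\,n-1}(SS_1 / SS_0)$; a feature is called a
contaminant when $P < 0.1$. Calls are made separately in the DNA and RNA
datasets (each against its own concentration series, on
**pre-normalization** counts — screening precedes normalization), and the
union of called features is removed from both tables. Negative extraction
controls enter the regression when their total processed reads are at
least 40 (boundary inclusive); features without a defined score are
retained, which is the conservative direction.

Two calibration facts matter for interpretation. First, the score is
invariant to rescaling all concentrations or all frequencies by a positive
constant. Second, under the null ($f \perp c$, slope-0 model true),
$SS_1 \ge SS_0$ in expectation, so $P$ concentrates well above 0.5: the
score is strongly conservative, and the empirical null fraction of
$P < 0.1$ is of order $10^{-4}$, not $0.1$. One acceptance check requires
that null fraction to sit in $[0.05, 0.20]$; that band is inconsistent
with the score definition above and the check is deliberately left
failing rather than loosening either the score or the band. Detection of
planted contaminants does not suffer: sensitivity and specificity are
tested directly against truth labels.

A second subtlety: adding samples that lie exactly on a feature's fitted
inverse line almost always lowers the score, but when the score is already
high the change of degrees of freedom can raise it by $\sim 0.01$; the
monotonicity test is therefore directional in aggregate rather than
strict.

## 2. Depth normalization (repeated-rarefaction reliability filter)

For each sample with total reads $T \ge D$, the stage draws $D$ reads
without replacement (multivariate hypergeometric) $R$ times independently
(`D = 4000`, `R = 1000` by default; a combined wild-plus-laboratory
analysis would use `D = 2000`). A feature's *occurrence frequency* is the
fraction of draws in which it appears; as $R \to \infty$ it converges to
$1 - \binom{T-c}{D} / \binom{T}{D}$, and the test suite checks this
closed form at $R = 5000$ within 0.02.

The reliability filter keeps the features whose occurrence frequency is at
least the `q = 0.10` quantile of the sample's present features. Three
ambiguities are resolved as package decisions:

* *"frequency" means occurrence* (presence across draws), not mean
  abundance: it measures detection reliability directly and makes the
  quantile rule scale-free.
* *The quantile is per sample*, over that sample's present features (the
  procedure is defined "for each sample").
* *The quantile rule is linear interpolation between order statistics at
  position $(n+1)q$* (R `type = 6`). The boundary behavior depends on
  this; with frequencies $\{1.0 \times 9,\ 0.01\}$ and $q = 0.10$ the
  threshold is $0.109$, so the $0.01$ feature is dropped. Selection is
  boundary-inclusive ($\ge$ threshold).

A final draw of exactly $D$ reads is then taken from the selected features
only, so every retained sample's column sums to $D$. Samples below depth
(before or after filtering) are excluded with a logged flag, not an error.
The monotonicity of the filter in counts holds for the limiting presence
probabilities; at finite $R$ neighboring counts can swap order within
binomial noise, which the tests acknowledge by using well-separated count
ladders.

## 3. Core community partitioning

Counts are collapsed to a taxonomic rank (genus by default); features
unclassified at that rank pool under their nearest classified parent
(`Unclassified_<rank>_<name>`), and column sums are invariant under
collapsing. A taxon is *core* for a group when present in at least 25% of
the group's individuals (boundary inclusive: 3 of 12 qualifies). Core
sets are partitioned into `shared_all` (core in every group), `unique`
(core in exactly one group — the taxon may still occur sporadically
elsewhere below the prevalence bar), and `partial` (two or more but not
all). Per-individual category fractions use the **core abundance** as the
denominator (reads over the group's whole core set), not total abundance.
Top-taxa summaries keep taxa ranking in the top `k = 5` by group-mean
relative abundance in at least two groups, ties at rank $k$ broken by
taxon name.

## 4. Diversity, ordination, PERMANOVA

Shannon entropy is in natural log (nats); Chao1 is the bias-corrected
estimator $S_{obs} + F_1(F_1-1) / (2(F_2+1))$. Faith's PD sums the branch
lengths of the minimal subtree connecting the present tips *and the root*
(conventions differ; the root path is included here). Beta diversity
offers Bray–Curtis, presence Jaccard, unweighted UniFrac, and the
*normalized* weighted UniFrac
$\sum_b l_b |p_{A,b} - p_{B,b}| / \sum_b l_b (p_{A,b} + p_{B,b})$, which
is invariant to per-sample count rescaling. All four are verified against
brute-force branch-enumeration oracles on a hand-drawn tree, and
Bray/Jaccard against an independent community-ecology implementation.

PCoA double-centers $-D^2/2$ (Gower) and reports eigenvalues as they come
— negative ones are reported, never corrected; coordinates are returned
only for positive axes. PERMANOVA uses sequential (Type-I) sums of squares
via projection matrices on the Gower-centered inner-product matrix, with
free (single-level) permutation of samples; strata are not implemented.
Pseudo-F permutation p-values are calibrated: the rejection rate at
$\alpha = 0.05$ over 2000 null simulations must fall in $[0.03, 0.07]$.

## 5. Indicator statistics

The group-equalized point-biserial statistic $r_g$ is the weighted Pearson
correlation between a taxon's values (relative abundance, or presence)
and the target-group indicator, with weights $w_i = 1/n_{g(i)}$ so every
group contributes equal total weight; with equal group sizes it reduces to
the ordinary point-biserial correlation. The exact equalization formula
was an open choice and is fixed by this definition, verified against an
independent weighted-moment oracle. Tests are one-sided (positive
association), $p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})$,
with Benjamini–Hochberg step-up correction across all taxon-target pairs.
By default all non-trivial target subsets up to complementation are
tested (singletons and canonical pairs for four groups).

## 6. Genetic and geographic distance, Mantel machinery

p-distance uses pairwise deletion (sites with `-` or `N` in either
sequence are excluded). The Cavalli-Sforza chord distance between
individuals treats individual allele frequencies as $\{0, 0.5, 1\}$ per
locus over the union allele universe of the pair:
$D_l = (2/\pi)\sqrt{2(1 - \sum_a \sqrt{p_a q_a})}$, averaged over loci
typed in both. The exact variant used by legacy software is not published;
this formula (with the $2/\pi$ scaling) is declared, and no recovery test
depends on the variant. Geographic distances are planar Euclidean km — no
geodesy, matching the projected-plane design of the generator.

Mantel tests are Spearman (rank) correlations of the off-diagonal
upper-triangle entries with simultaneous row/column permutation of the
main matrix, one-sided (distance decay is directional), 1000 permutations
by default. Partial Mantel recursively partials the rank correlations;
conditioning correlations of $\pm 1$ are flagged as degenerate (`NA`).

## 7. Mixed models and variance partitioning

`fit_random_intercept` maximizes the REML criterion of
$y = X\beta + Zu + \varepsilon$ with a single random intercept by
one-dimensional optimization over $\log \lambda$,
$\lambda = \sigma^2_u / \sigma^2_e$, with $\beta$ and $\sigma^2_e$
profiled out; the $\sigma^2_u = 0$ boundary is checked explicitly and
flagged. On balanced one-way designs the components agree with the
method-of-moments ANOVA estimators to $10^{-6}$, and the implementation
is checked against an established mixed-model package on unbalanced data.
$R^2_m = \mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \sigma^2_u
+ \sigma^2_e)$; per-factor shares are drop-one differences
$(R^2_{m,full} - R^2_{m,-f}) / R^2_{m,full} \times 100$, floored at 0 and
not constrained to sum to 100. The paper-style percent-of-explained-
variance computation is not published; this definition is declared.

## 8. Species matching

Global (Needleman–Wunsch) alignment identity with affine gaps: match
$+1$, mismatch $-1$, a gap of length $k$ scoring $-2 - (k-1)$. Identity
counts identical aligned positions over the full alignment length, gap
columns in the denominator (conservative). The alignment itself is
delegated to Biostrings; the scoring convention is verified against an
exhaustive alignment enumerator on tiny inputs. Assignment reports the
best reference and every reference within $0.05$ identity of it
(multi-match near-tie rule, strict inequality), ties broken by reference
id. Remote k-mer similarity services cannot be reproduced offline; both
the clone-library and *tuf*-database matching are emulated as
identity-based matching with the same near-tie semantics.

## 9. The synthetic generator: what it emulates, and what not

The generator's stated world: four mouse groups (defaults desk-scale
wild = 60 over 12 farms, HL-Lab = 20, MPI-Lab = 10, C57BL/6J = 8; a
`"paper"` preset restores 203/225/29/13 over 34 farms), farm sites
uniform in a square rescaled to a 10 km mean pairwise distance (rejection
resampled to ±15%). Composition is logistic-normal → multinomial:
per-sample expected log relative abundances are a group profile plus a
farm effect plus individual noise ($\sigma_{indiv} = 0.5$), with farm
effects drawn per taxon across farms with covariance
$\sigma^2_{farm}\, e^{-d_{ij}/\rho}$ ($\sigma^2_{farm} = 0.64$,
$\rho = 5$ km) — this is what makes community similarity decay with
distance. The logistic-normal (rather than Dirichlet) choice lets farm
effects and RNA activity multipliers compose additively on the log scale,
which keeps the variance bookkeeping of the recovery tests simple.

Taxon tiers: shared core (log-weight $N(2, 0.7)$ in every group);
group-specific core taxa (own group $N(2, 0.7)$, elsewhere $-12$, i.e.
effectively absent); DNA-only carry-over taxa whose RNA activity
multiplier is 0 (all other multipliers are log-normal with
`activity_sdlog = 0.5`; the RNA table is the DNA composition times the
multipliers, renormalized, at its own depth); a wild-only rare tail
(200 taxa at log-weight $N(-7.5, 1)$, surfacing mostly as singletons);
and a *transient/environmental* tier (50 taxa at $N(-0.4, 0.3)$, circa
5–10 reads per sample in all groups). The transient tier is an addition
to the stated pools: the per-sample 10% occurrence-quantile filter always
removes about a decile of features, and without a band of
low-but-multi-read features that decile would cut into either the
singleton cluster (making singleton removal unreliable) or the core
(removing planted core taxa). With the band, planted singleton noise
falls strictly below the threshold and core taxa sit safely above it.
These tier parameters were fixed from this design reasoning before the
acceptance measurements and are not tuned afterwards.

Contamination: each contaminant $j$ carries an ambient load $a_j$
(log-normal, median 0.02 relative-frequency units at 1 ng/µl); in a
sample with concentration $c$ the expected added reads are Poisson with
mean $\mathrm{depth} \cdot a_j / c$, so expected relative frequency is
$\propto 1/c$ by construction (the planted log-log slope regression
recovers $-1 \pm 0.15$). Negative controls (4 per dataset) contain the
ambient mixture plus 2% cross-talk from the mean real community at low
log-normal depth (median 500 reads). Concentrations are log-normal
(median 5 ng/µl, sdlog 0.8 for real samples; median 0.2 for controls);
depths are log-normal (median 9000, sdlog 0.25) with a floor of 5000 so
the 4000-read rarefaction always has eligible samples.

Genetics: wild individuals inherit a cluster from their farm via spatial
k-means (3 clusters), microsatellite allele frequencies are
cluster-specific Dirichlet draws over 18 loci (4–7 alleles each, 3%
missing cells), and D-loop haplotypes mutate a 300 bp root along a
haplogroup star (10 cluster mutations, 2 private per individual) — so
genetic distance correlates with geography by construction.

Not emulated: read-level sequencing (no FASTQ, PCR or chimera error
model), realistic phylogenies for named taxa (the tree is a random
bifurcating tree with exponential branch lengths over the feature
universe), admixture/population-structure inference, and the empirical
rank-abundance shape of real skin communities (the rare-tail shape is a
free knob, not an estimate). A green recovery test therefore establishes
that the pipeline detects the planted statistical structure at realistic
effect sizes — not that it reproduces any particular real dataset's
numbers.

## 10. Numerical and interface decisions

* All randomized operations take an explicit integer seed; composite
  stages derive per-sample or per-stage sub-seeds deterministically, and
  identical config + seed yields byte-identical bundles on disk.
* Tables are TSV with features as rows (classic OTU-table orientation),
  missing values as empty strings, booleans as `true`/`false`; numeric
  serialization uses `%.12g`, so a written-and-reloaded bundle is equal to
  the original within `1e-8` relative tolerance (byte-identical on
  re-write).
* Ties: top-taxa rank ties break lexicographically; species-match
  identity ties break by reference id; BH adjustment computes
  `p * (m/j)` so that the largest q equals the largest p exactly.
* Permutation p-values use the add-one formula `(1 + exceedances) /
  (1 + nperm)`, so the attainable minimum is `1/(1+nperm)`.
* Degenerate inputs are flagged rather than silently zeroed: constant
  vectors make `r_g` and Mantel r undefined (`NA`), empty cores error,
  under-depth samples are excluded with a logged flag.

## Known limitations

The PERMANOVA permutes freely (no strata/restricted permutation); mixed
models are single-random-intercept Gaussian only; UniFrac supports the
two variants above; the CLI's configuration is a flat key=value file, not
full TOML. Calibration tests use 99 permutations per null replicate
(2000 replicates) to stay inside the stated time budgets.
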