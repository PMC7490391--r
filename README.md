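# muskin

Desk-scale analysis pipeline for **wild versus laboratory mouse skin
microbiota**, built around paired DNA-based ("standing") and RNA-based
("active") 16S rRNA amplicon profiles of the same samples.

Skin is a low-biomass habitat: reagent contamination, unreliable
low-count features and uneven sequencing depth can dominate naive
analyses, and wild populations add spatial structure (farms, geography,
host genetics) that laboratory studies never face. `muskin` implements
the full chain an ecologist needs to handle this:

1. **Contaminant screening (frequency method).** A reagent contaminant's
   relative frequency varies inversely with the sample's nucleic-acid
   concentration. Per feature, two one-parameter log-log models are
   compared — contaminant `log f = b − log c` (slope −1) vs
   non-contaminant `log f = b` — and the residual ratio is scored through
   the F(n−1, n−1) CDF; features with score < 0.1 in either the DNA or
   RNA dataset are removed from both (union rule). Negative controls with
   ≥ 40 processed reads enter the regression.
2. **Repeated-rarefaction reliability filter.** Per sample, 1000
   independent draws of 4000 reads without replacement; features whose
   occurrence frequency across draws falls below the 10% quantile of the
   sample's present features are discarded, then one final 4000-read draw
   is taken from the survivors.
3. **Core community partitioning.** Core = present in ≥ 25% of a group's
   individuals; core sets partition into shared-by-all, unique and
   partial taxa, with per-individual core-abundance fractions.
4. **Diversity & ordination.** Shannon (nats), bias-corrected Chao1,
   Faith's PD, Bray–Curtis / Jaccard / unweighted / normalized weighted
   UniFrac, PCoA, and sequential-SS PERMANOVA with permutation p-values.
5. **Indicator statistics.** Group-equalized point-biserial correlation
   (weights 1/n_g), one-sided permutation p-values,
   Benjamini–Hochberg correction.
6. **Distance decay & drivers.** p-distance, individual-level
   Cavalli-Sforza chord distance over microsatellites, Euclidean
   geographic distance, Spearman Mantel and partial Mantel tests, and
   REML random-intercept mixed models with marginal-R² variance
   partitioning.
7. **Species matching.** Global-alignment identity of short variants
   against longer references, reporting every reference within 0.05
   identity of the best (near-tie multi-match rule).

A first-class **synthetic-data generator** plants all of this structure —
contaminants with 1/concentration frequency, group cores, DNA-only
carry-over taxa, a wild rare biosphere, spatially autocorrelated farm
effects (covariance σ²·exp(−d/ρ)), spatially clustered genetics — with
truth labels, so every stage is tested by recovery rather than by
fixtures. See `vignettes/muskin-methods.Rmd` for models, parameters and
design decisions.

## Worked example

```r
library(muskin)

b  <- simulate_bundle(sim_config(), seed = 1)      # 4 groups, 98 mice + 8 controls
sc <- screen_and_filter(b$dna, b$rna, b$metadata, threshold = 0.1)
length(sc$union)                                   # 20  (all 20 planted contaminants)

nt <- normalize_table(sc$dna, D = 4000, R = 1000, seed = 1)
all(colSums(nt$table$counts) == 4000)              # TRUE, 98 samples retained
range(nt$report$excluded_read_fraction)            # 0.0011 ... 0.0043

coll   <- collapse_taxonomy(nt$table, b$taxonomy, "genus")
md     <- b$metadata[!(b$metadata$is_negative_control %in% TRUE), ]
groups <- split(md$sample_id, md$group)
part   <- partition_core(lapply(groups, function(s) core_set(coll, s)))
lengths(part$unique)                               # C57BL/6J 8, HL-Lab 12, MPI-Lab 10, wild 30
category_fraction(coll, groups$wild, part, "wild")$mean
#> shared_all    partial     unique
#>      0.468      0.001      0.531

pm <- permanova(beta_diversity(nt$table, "bray_curtis"),
                data.frame(group = md$group[match(nt$table$sample_ids, md$sample_id)]),
                nperm = 999, seed = 1)
pm[1, c("R2", "p")]                                # group R2 = 0.476, p = 0.001

wild <- intersect(groups$wild, coll$sample_ids)
bc   <- beta_diversity(feature_table(nt$table$counts[, wild], "DNA"), "bray_curtis")
geo  <- geographic_distance(md[md$sample_id %in% wild, ])
mantel(bc, geo, nperm = 999, seed = 1)
#> Mantel (Spearman): r = 0.5223, p = 0.001 (999 permutations)

cs <- cavalli_sforza_matrix(b$genotypes)           # microsatellites
pd <- p_distance_matrix(b$dloop)                   # mitochondrial D-loop
partial_mantel(geo, bc, list(cs[wild, wild], pd[wild, wild]),
               nperm = 999, seed = 1)
#> Mantel (Spearman): r = 0.2103, p = 0.001 (999 permutations)
#>   conditioned on: C1, C2
```

Reading the output: the screen recovers exactly the planted contaminant
set; normalization discards only 0.1–0.4% of reads while equalizing depth;
the wild group carries the largest unique core (30 genera, 53% of its
core reads); group membership explains 48% of Bray–Curtis variation; and
wild community similarity decays with geographic distance (r = 0.52),
attenuating to r = 0.21 once host population structure (chord distance,
D-loop p-distance) is partialled out — the planted farm covariance
(σ²_farm = 0.64, ρ = 5 km) seen through the pipeline.

## Command line

```sh
muskin simulate  --seed 1 --config sim.toml --out-dir bundle/
muskin decontam  --in-dir bundle/ --out-dir dec/ --threshold 0.1 --min-reads 40
muskin normalize --in-dir dec/ --out-dir norm/ --depth 4000 --draws 1000 --quantile 0.10 --seed 1
muskin core      --in-dir bundle/ --level genus --prevalence 0.25 --out-dir core/
muskin diversity --in-dir bundle/ --out-dir div/ --nperm 999
muskin indicators --in-dir bundle/ --mode abundance --nperm 999 --out-dir ind/
muskin drivers mantel --main geo.tsv --response bray.tsv --conditions cs.tsv,pd.tsv --nperm 1000
muskin match-species --queries asvs.fasta --refs clones.fasta --labels species.tsv --delta 0.05
```

(`inst/exec/muskin` is an Rscript wrapper around `muskin::muskin_cli()`;
logs go to stderr.)

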