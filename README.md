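# asvref

Build and evaluate ASV-resolved full-length 16S rRNA gene reference
databases, and profile the microbial communities of wastewater treatment
plants (WWTPs) with them.

Microbial community profiling at genus and species resolution needs a
reference database that (i) contains a high-identity (≥ 99%) reference for
essentially every abundant organism in the ecosystem and (ii) carries a
complete seven-rank taxonomy, including placeholder names for the many
environmental lineages that have no validly published name. `asvref`
implements that workflow end to end for the activated-sludge ecosystem
model:

* **FL-ASV resolution** — full-length (27F–1391R) reads are oriented,
  primer-trimmed and exactly dereplicated; a full-length amplicon sequence
  variant (FL-ASV) is accepted when at least two identical reads support
  it. FL-ASVs are merged append-only into a versioned database with stable
  `FLASV<k>` identifiers and exported in SINTAX, QIIME and DADA2 dialects.
* **Identity-threshold taxonomy** — each FL-ASV is mapped exhaustively
  against a typed reference set; rank names are inherited from the top hit
  while the percent identity *i* satisfies *i* ≥ *t(r)* for the rank
  thresholds *t* = (phylum 75.0, class 78.5, order 82.0, family 86.5,
  genus 94.5, species 98.7). Ranks below the last satisfied threshold are
  filled by de novo placeholder taxa (`midas_g_123` style) minted by greedy
  threshold clustering scoped within the parent taxon, and the sequence /
  taxonomy novelty per rank is tabulated.
* **Database evaluation** — a SINTAX-style bootstrap k-mer classifier
  (8-mers, 32 drawn per bootstrap, 100 bootstraps, confidence cutoff 0.8)
  plus high-identity coverage: the share of ASVs at ≥ 0.01% relative
  abundance with a ≥ 99%-identity hit, summarised per sample with
  1.5 × IQR box statistics.
* **Community profiling** — rank aggregation, replicate collapsing, core
  taxa (> 0.1% relative abundance in > 80 / 50 / 20% of plants → strict /
  general / loose core), conditionally rare-or-abundant taxa (CRAT: not
  core, > 1% in ≥ 1 plant), cumulative tier abundances per process type,
  V1–V3 vs V4 primer-bias categories (twofold rule with a ≥ 0.001%
  floor), and metadata binning.
* **Ecological statistics** — rarefaction to 10,000 reads, observed
  richness and inverse Simpson, Bray–Curtis and Sørensen (presence
  threshold 0.01%) dissimilarities, Haversine distances (radius
  6,378.137 km), Mantel tests (Spearman, 999 permutations), single-factor
  PERMANOVA with R² = SS_between/SS_total, PCoA, distance-decay regressions
  with a 2,500 km breakpoint, and Kruskal–Wallis with Dunn's post hoc test.
* **Synthetic worlds** — a seeded generator (`synth_config()`,
  `make_reference_world()`, `make_plants()`, `sample_communities()`,
  `simulate_reads()`) that emits full-length and short-read data with known
  ground truth: realized identities to the typed references, planted core
  tiers, planted primer mismatches, and regional species pools that induce
  distance decay. Every downstream stage is testable against this ground
  truth without any external data.

The sequence kernel (semi-global identity with affine gaps and an
exhaustive, deterministic top-hit search) is implemented in C++ and is
checked against an independent brute-force dynamic-programming oracle in
the test suite.

## Worked example

Build a reference database from simulated full-length reads, assign
taxonomy, and profile the simulated short-read communities (about two
minutes; the taxonomy step maps every FL-ASV against the typed set
exhaustively):

```r
library(asvref)
cfg    <- synth_config(seed = 42, n_extra_per_species = 0, low_depth_frac = 0)
world  <- make_reference_world(cfg)
plants <- make_plants(cfg)
comm   <- sample_communities(world, plants, cfg)

fl    <- simulate_reads(comm, world, "FL", depth = 5000)
flasv <- resolve_flasvs(fl$reads)                  # >= 2 identical reads
db    <- merge_into_database(new_refdb(), flasv$seq, label = "demo run")
db
#> <refdb> 78 FL-ASVs, version 844cf624985e16e35ecd37d11d82b8a7

tax <- assign_taxonomy(setNames(db$flasv$seq, db$flasv$id),
                       world$typed_seqs, world$typed_taxonomy)
novelty_table(tax)[, c("rank", "threshold", "novel_sequences",
                       "novel_sequences_pct", "denovo_taxa")]
#>      rank threshold novel_sequences novel_sequences_pct denovo_taxa
#> 1  phylum      75.0               0                0.00           0
#> 2   class      78.5               0                0.00           0
#> 3   order      82.0               0                0.00           0
#> 4  family      86.5               0                0.00           0
#> 5   genus      94.5              15               19.23           8
#> 6 species      98.7              39               50.00          39

reads <- simulate_reads(comm, world, "V1V3")
genus <- aggregate_by_rank(reads$counts, reads$asv_taxonomy, "genus")
rel   <- relative_abundance(rarefy(genus, 10000, seed = 42))
core  <- core_crat_assign(plant_collapse(rel))
table(core$tier)
#>    CRAT general   loose   other  strict
#>       9       9      10      14       6
```

The novelty table reads as in reference-database reports: 39 of the 78
FL-ASVs (50.00%) have no ≥ 98.7%-identity relative in the typed set, so
they receive de novo species placeholders; at half that database 19.23%
even lack a genus-level relative. The core table recovers exactly the
community structure the generator planted (6 strict-core genera, 9 CRAT
genera, and so on). A single orchestrated run over all stages, with a JSON
manifest of parameters, seed and output hashes, is available as
`run_pipeline(run_config(synth_config(...)))`.

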