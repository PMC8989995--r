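---
title: "Methods and design of asvref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of asvref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `asvref`: how full-length 16S rRNA reference databases are built and
given a threshold-based taxonomy, how databases and communities are
evaluated, and what the synthetic-data generator does and does not emulate.

## Reference database model

A full-length amplicon sequence variant (FL-ASV) is an exact sequence
between the 27F and 1391R primer binding sites supported by at least two
identical reads (`resolve_flasvs()`, `min_copies = 2`). Requiring two
identical observations suppresses sequences that exist only because of
residual error; it also means genuinely rare variants are deliberately
missed — sensitivity is traded for reference quality.

Databases are append-only (`merge_into_database()`): a sequence already
present verbatim keeps its `FLASV<k>` identifier forever, and new unique
sequences take the next sequential identifiers. "Unique" means exact string
identity after normalization (uppercase, U→T); near-identical sequences are
distinct FL-ASVs by design, because the ASV concept is exact-variant based.
Versions are content hashes of the ordered sequence set, and a provenance
log records every merge, so any database state is reproducible from its
merge history. Chimera-freedom is an assumption on the input (full-length
protocols achieve it upstream via unique molecular identifiers); no chimera
checker is implemented.

Three export dialects are written and re-imported losslessly: SINTAX
(`>FLASV1;tax=d:...,p:...,...;`), QIIME (FASTA plus a two-column TSV with
`d__...; p__...`), and DADA2 (semicolon-joined lineage as the FASTA
header). The DADA2 dialect carries no record identifiers, so re-import
regenerates them sequentially in file order. Taxon names containing the
dialect delimiters (`,`, `;`, tab) are rejected at export rather than
escaped.

The read-tag library normalisation formula
`C_seq = peak_molarity × 0.0124 × (215 − peak_size) + 10.332`
(pmol/l, bp) is exposed as `effective_seq_concentration()`. Zero molarity
is a valid input (the formula returns its 10.332 intercept); negative
molarity and non-positive or >1,500 bp sizes are errors.

## Pairwise identity and top-hit mapping

The alignment kernel (`global_identity()`, Rcpp) performs global
Needleman–Wunsch alignment with affine gaps: match +1, mismatch −1, a gap
of length *k* costs 2 + (*k* − 1). Identity is the number of matching
columns divided by the number of alignment columns, with terminal gap runs
excluded from the columns, so a short amplicon aligned inside a full-length
reference is scored on its aligned core. Two conventions deserve emphasis:

* **Terminal gaps are penalized in the score** (like the defaults of the
  common mapping tools), although they are excluded from the identity
  denominator. Scoring them free instead would let a chance one- or
  two-base suffix/prefix overlap between unrelated sequences outscore the
  honest full alignment and report a perfect identity — which would
  corrupt any ≥ 99%-identity coverage evaluation. For near-full-length
  pairs the two schemes coincide, because the optimal alignment has no
  terminal gaps.
* **Canonical alignment by value, not position.** Among equal-scoring
  alignments the reported one maximizes matching columns and then
  minimizes alignment columns. Because this choice depends only on
  (score, matches, columns) and never on cell positions, the identity is
  provably symmetric in its two arguments. Identity is therefore a
  well-defined function of the unordered sequence pair, which the test
  suite asserts and which an independent brute-force oracle reproduces
  exactly.

`top_hit()` is exhaustive — every query is aligned against every
reference, with no heuristic termination or pre-filtering — and ties at
the maximal identity go to the smallest reference identifier, with the tie
multiplicity reported. Greedy 97% OTU clustering (`cluster_otus()`) visits
sequences in decreasing abundance order and joins the first centroid at
identity ≥ 0.97; no chimera step is applied.

Identity conventions differ between tools, and assignments whose best
identity falls within a fraction of a percent of a rank threshold can
change under another convention. The convention above is fixed, documented
and oracle-checked, but results at the 98.7%/99% boundaries should be read
with that caveat.

## Threshold taxonomy and de novo placeholders

`assign_inherited()` maps each sequence to its closest typed reference and
inherits rank names from the top downward while 100 × identity ≥
threshold, with thresholds phylum 75.0, class 78.5, order 82.0, family
86.5, genus 94.5, species 98.7 (domain is always inherited). The boundary
convention is: inherit at ≥ threshold, novel strictly below — matching the
"< 98.7%" style in which such thresholds are usually printed. Inheritance
is monotone by construction: a rank can only be assigned if all its
ancestors are.

`mint_denovo()` then fills the open ranks top-down. At each rank,
unassigned sequences are greedily clustered at that rank's threshold
(first-come centroid, database order — chosen for determinism and
identifier stability), and each new cluster receives the next
`midas_<r>_<n>` placeholder. Clustering is scoped within the parent taxon,
which enforces that the resulting taxonomy is a tree: a de novo genus
cannot appear under two families. A consequence of per-parent scoping is
that two sequences more similar than a rank's threshold but placed under
different parents will not share a placeholder at that rank; this mirrors
the behaviour of naive threshold taxonomy generators and is one known
source of artifacts for lineages with unusual evolutionary rates.

`novelty_table()` reports, per rank, the number and percentage of
sequences whose best identity is strictly below the rank threshold, and
the number and percentage of de novo taxa among the distinct taxa observed
at that rank. Percentages are rounded to two decimals. The taxa
denominator is the number of distinct names in the database at that rank;
published tables do not always state their denominator, so percentages on
other databases may be defined slightly differently.

## Bootstrap k-mer classification and database evaluation

`classify()` is a SINTAX-style naive bootstrap classifier. Per bootstrap,
32 k-mers (k = 8) are drawn uniformly **without replacement** from the
query's **distinct** k-mer set, the reference sharing the most of them
wins, and ties among equally good references are broken **uniformly at
random** (seeded). Per-rank confidence is the vote fraction of the modal
name; the reported label is truncated at the first rank whose confidence
falls below the cutoff, with the cutoff itself retained (a confidence of
exactly 0.8 is reported at the default cutoff 0.8, 0.79 is not). The
original tool's internals are under-documented, so these choices are a
documented dialect: drawing without replacement from distinct k-mers makes
the two-identical-references case analytically predictable (species
confidence → 0.5, genus confidence 1), and random tie-breaking is what
makes that case behave correctly at all — a deterministic tie rule would
always report one of the two species with full confidence.

Database evaluation filters each sample to ASVs at ≥ 0.01% relative
abundance (relative to all reads of the sample, including unclassifiable
ones) and reports per sample: coverage (share of kept ASVs with a ≥ 99%
top-hit identity) and genus/species classification rates (share of kept
ASVs with a name at that rank after confidence truncation; placeholder
names count as classified). The filter is applied before mapping; this
does not change the ratio's definition, only the compute. Aggregates are
mean, SD, median, quartiles and whiskers at 1.5 × IQR (min and max of the
values inside the fences). Coverage and both rates are monotone
non-decreasing in database content, which the tests assert.

## Community profiling conventions

Counts are features × samples; each sample maps to a plant, and plant
profiles are the mean of their replicates' relative abundances. Plants,
not samples, are the occupancy denominator. All profile boundaries are
strict inequalities, following the usual "> 0.1%" phrasing: a taxon is
present in a plant when its relative abundance exceeds 0.1%; strict /
general / loose core requires occupancy > 0.8 / 0.5 / 0.2; CRAT taxa are
non-core taxa exceeding 1% in at least one plant. Core tiers are assigned
before CRAT, so the two are disjoint by construction. ASVs unclassified at
the aggregation rank are pooled into an explicit `unclassified` feature
that stays in every denominator but is never a core/CRAT candidate, and
cumulative tier shares per plant group therefore always sum to 100%.

Primer-bias comparison keeps genera at ≥ 0.001% mean relative abundance in
either primer set and categorizes by the V1–V3 : V4 ratio with the twofold
rule (≥ 2 / ≤ 0.5 / neutral). Zero means are replaced by a pseudo-abundance
ε = 10⁻⁶ (as a fraction), so a genus seen by only one primer set is
"preferential", not undefined. Temperature and industrial-load bins follow
the printed ranges exactly, with out-of-range values labelled `unbinned`
rather than clamped.

Samples with fewer than 10,000 reads are discarded by `rarefy()`, which
subsamples the rest to exactly 10,000 without replacement
(`vegan::rrarefy`). Alpha diversity is observed richness and inverse
Simpson; beta diversity is Bray–Curtis on relative abundances and Sørensen
on presence/absence after thresholding at 0.01% relative abundance, both
via `vegan::vegdist`. Geographic distances use the Haversine formula with
radius 6,378.137 km (the default of the `geosphere` tool this field
usually cites). Mantel tests use Spearman correlation and 999 permutations
with the add-one p-value estimator; PERMANOVA is `vegan::adonis2` with
R² = SS_between / SS_total, and the tests verify it against a direct
sum-of-squares partition computed from the distance matrix. Distance-decay
regressions are ordinary least squares of community similarity
(1 − dissimilarity) on untransformed kilometres, fitted separately within
and beyond a 2,500 km breakpoint; no functional form beyond a straight
line per stratum is assumed, since none is standard. Dunn's post hoc test
(rank z-statistics with tie correction, Bonferroni-adjusted, significance
at adjusted p < 0.01) is implemented directly, as no installed package
provides it.

## The synthetic world generator

The generator exists so that every stage can be tested against known
ground truth. It emulates the study design of a global WWTP amplicon
survey: a taxonomy tree of sequences, hundreds of plants with metadata in
realistic categorical frequencies, duplicate biological samples per plant,
full-length reads with duplicates and singleton noise, and V1–V3/V4
short-read ASV tables.

**Sequences.** A random 1,300 bp root centroid carries fixed primer-site
instances (27F, 534R, 515F, 806R, 1391R) at realistic relative positions;
descending the rank tree mutates a binomially sampled number of positions
per rank (defaults 0.10, 0.05, 0.04, 0.03, 0.025, 0.014 from phylum to
species), with primer sites protected so that primer bias is planted, not
accidental. Mutations are substitutions only, so realized identities are
exact and cheap to audit; an optional indel mode exists for variants but
is excluded from the ground-truth guarantees. The default divergence
schedule keeps species, genus and family bands separated under the
inheritance thresholds; deeper ranks are deliberately over-dispersed
(sister classes look phylum-novel), which the validator allows — it
errors only when a schedule fails to *separate* ranks, the case that would
make ground truth incoherent. Because the real 515F and 534R primers
target overlapping gene regions, their site instances are engineered to
mismatch each other (515F instantiated as Y→T, M→C, plus a fixed guard
triplet before the 534 site); otherwise in-silico extraction would find
spurious cross-primer sites within its two-mismatch tolerance.

**Ground truth identities.** The realized closest-relative identity of
every sequence is recomputed from the emitted sequences at build time. The
authoritative definition is the exhaustive-mapping identity under the
package's alignment convention (`identity_method = "alignment"`), matching
how such identities are measured in practice; a Hamming-fraction column is
always recorded for substitution-only worlds. The two coincide at
within-species divergences but the alignment identity can exceed the
Hamming fraction for distant relatives, where gapped alignments recover
additional matching columns — precisely the convention-sensitivity the
alignment section warns about. Alignment-based ground truth is optional
because it is the one expensive step.

**Communities.** Core tiers are planted at the genus level: genus weights
per plant are an occupancy Bernoulli (defaults 0.95 / 0.68 / 0.35 for
strict/general/loose core, 0.08 for "other") times a log-normal abundance
draw (σ = 0.2), a process-type multiplier for genera with a planted
process affinity, and a regional-pool weighting; species split their genus
weight by a per-genus Dirichlet draw. CRAT genera sit at a low baseline
(~0.03% share) everywhere and spike (~3% share) with probability 0.08 per
plant. These values are chosen so that every planted abundance is at least
a factor of two away from the 0.1% and 1% decision boundaries: at 10,000
reads per sample with duplicate samples, the probability that read
sampling flips any presence/absence or CRAT indicator is negligible, which
is what makes *exact* tier recovery a fair requirement. The recorded
ground-truth tier is the core/CRAT definition applied to the noiseless
plant-truth table — the realized planted structure — so recovery tests
check that the sampling + aggregation + assignment path reproduces it
exactly, not that binomial occupancy draws happened to land on their
expectations.

**Primer bias and distance decay.** Planted primer mismatches multiply a
taxon's detection weight by 2^(−m) — the simplest mechanism that produces
twofold detection categories — and are placed on strict-core genera so the
effect is observable everywhere. The default mismatch load is asymmetric
(four V1–V3-biased genera versus one V4-biased), reflecting the lower
theoretical coverage of the V1–V3 primer pair; renormalisation then puts
the expected V1–V3 : V4 ratio of the one-mismatch V4 genus slightly above
2 rather than exactly at the category boundary, so its detection is a
decidable event rather than a coin flip. Regional pools implement distance
decay through immigration-like preferential occupancy (loose-core and
rare genera are more often present, and core genera more abundant, in
their home pool); pool centres sit ~1,900 km apart along a latitude band
so that pairs below the 2,500 km breakpoint mix same-pool and
neighbour-pool comparisons while pairs beyond it are all cross-pool.

**What the generator does not emulate.** No 16S secondary structure, rate
heterogeneity across sites, chimeras, quality scores, or a realistic
species-abundance distribution — the log-normal is a modelling choice, not
an empirical claim. Passing the recovery tests therefore demonstrates that
the pipeline's bookkeeping and decision rules are exact under controlled
noise, not that the method's statistical behaviour on real communities has
been validated.

## Problem sizes in the test suite

The suite exercises: a 576-sequence world (96 species plus five variants
each, 12 typed references) for exact threshold-taxonomy recovery; 20
seeded 60-plant worlds for exact core/CRAT recovery; 200 random pairs and
a 50 × 50 query–reference grid against the brute-force alignment oracle;
200 null replicates (Mantel) and 500 (Kruskal–Wallis) for type-I error
calibration against binomial 95% bounds; and 100 seeded 20-plant worlds
for primer-bias detection. These sizes are the package's choices for a
thorough single-machine run; all are plain parameters of the test code.

## Known limitations

* Exact dereplication only: near-identical FL-ASVs are separate records,
  and merging never collapses them.
* The classifier dialect (subsampling, tie handling) approximates, but is
  not byte-identical to, the original SINTAX implementation.
* De novo placeholder names are stable only for a fixed database order;
  inserting sequences mid-database would renumber downstream placeholders
  (databases are therefore append-only).
* Identity values within a fraction of a percent of a rank threshold are
  convention-sensitive (see the alignment section).
* PCoA reports negative eigenvalues for non-Euclidean dissimilarities
  rather than applying a correction.
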