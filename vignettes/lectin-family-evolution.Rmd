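---
title: "Methods: lectin gene-family evolution and expression divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lectin gene-family evolution and expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinfam)
```

This vignette documents the models and procedures implemented in
`lectinfam`, the parameters that matter, the design choices made where the
underlying methodology left them open, and what the synthetic-data tests do
and do not demonstrate about real genomes.

## The analysis model

The package treats a lectin superfamily survey as seven linked stages.

**Family classification.** Genes are assigned to one of twelve
carbohydrate-binding-domain families from a per-domain hit table (the
tabular layout of hmmscan per-domain output). Hits above an e-value cutoff
of 1.0 are discarded; each gene takes the family of its best-e-value lectin
domain. Multiple hits to the same domain (hololectins) collapse to one
membership; hits to non-lectin domains (kinases, F-boxes, glycoside
hydrolases) are recorded as accessory domains, marking chimerolectins. The
phloem lectin and EEA families have no public profile accession, so the
catalog names custom profiles (`PHLOEM_CUSTOM`, `EUL_CUSTOM`). Members
whose best hit covers less than 70% of the domain model are flagged
`partial`: such genes usually lack the sugar-binding region and behave like
pseudogenes, so downstream evolutionary counts exclude them by default. The
70% bound (inclusive) is a reproducible surrogate for what was originally a
manual curation step; it is a package decision, exposed as
`min_model_coverage`.

**Tandem clusters.** Two same-family genes are tandem neighbours when they
are at most `max_gene_gap = 10` genes apart — measured as the difference of
per-chromosome gene ranks, counting *all* annotated genes in the GFF3 — and
their starts lie within `max_bp` (100 kb for a compact, Arabidopsis-like
genome; 350 kb for large soybean/rice-like genomes). Clusters chain
rank-adjacent members transitively, so a long array qualifies even though
its total span exceeds the cap: the pairwise reading is the only one
consistent with arrays of ~19 genes spanning hundreds of kb. Because gene
starts are monotone in rank, chained adjacency equals the connected
components of the all-pairs predicate, which is what the test oracle
computes. Distance is start-to-start (unambiguous under nesting); rank ties
are broken by end coordinate, then identifier, so clustering is
reproducible.

**Segmental duplications.** Given a catalogued block list (two paired
intervals per block), tandem arrays are first collapsed to their lowest-rank
representative — gene-family copy counts treat an array as one copy. A
representative pair is segmental when the two genes (or any members of
their arrays) lie in the two intervals of one block and share a family; all
members of a collapsed array then inherit the segmental status, since
published gene-level summaries count genes, not representatives. Where no
block is catalogued, `infer_block_from_flanks()` compares the 50-kb
neighbourhoods of a candidate pair: a block is inferred when at least
`min_extra_anchors = 2` homologous gene pairs (besides the lectin pair)
connect the windows with consistent order — the longest strictly monotone
(co-linear or fully reversed) run of anchor positions. The anchor count is
a package default; no specific number was prescribed.

**Retrogenes.** Candidates are single-exon lectins whose protein aligns to
a multi-exon lectin over at least 70% of the query at e-value at most
1e-8; the best-e-value qualifying homolog is designated parental. Flanks
are then scanned, strand-oriented, for the two sequence hallmarks of
retroposition: a target-site duplication (direct repeat of 4–20 bp within
100 bp of the insertion boundaries, exact by default) and a 3' poly(A)
tract (>= 8 bp at >= 80% adenine within 200 bp downstream, scored purity
first, then length, then earliest position). Numeric hallmark definitions
are package decisions — the original identification was manual — and all
are configurable. Calls carry an evidence tier (`homology_only`, `+polyA`,
`+TSD`, `+both`); homology-only calls are retained because hallmarks erode
by substitution and indel over evolutionary time. A retrogene sitting
inside a tandem cluster is reported by `retro_tandem_expansion()` as a
retro-then-tandem expansion. With exact matching and `min_len = 4`, a TSD
"hit" in ~100-bp windows is expected by chance (about 37 random 4-mer
matches per window pair), so short-TSD evidence is corroborative, not
probative; the erosion-tier tests therefore use stricter scanner settings.

**TE overlap.** Each gene's relationship to provided TE annotations
(BED6, superfamilies MULE/CACTA/hAT/Helitron) is classified within 50-kb
windows by a fixed most-specific-first priority: gene inside a TE, TE
inside an intron, TE over exon sequence, TE in the flank, else none. The
priority order is a package decision; the source categories carried no
explicit precedence.

**Ancestral units and birth rates.** Gene trees with species-resolved
leaves are reconciled against the species tree
`((soybean, Arabidopsis), rice)` by LCA mapping: each node maps to the
smallest species-tree clade containing its leaf species; a node whose
mapping equals a child's is a duplication, otherwise a speciation. For a
species subset, the ancestral-unit count N_anc is the number of speciation
nodes mapped to the subset's root after pruning to the subset's leaves.
This is the parsimony-minimal, loss-blind count — a lower bound, matching
the "at least" phrasing used for published rates. Unrooted input trees are
midpoint-rooted by default (outgroup rooting by flag); multifurcations are
resolved deterministically, which can only lower, never raise, the count.
The birth rate is

$$r = 100 \cdot \frac{(N_{extant} - N_{anc})/N_{anc}}{T}$$

genes per 100 MY per ancestral gene. T defaults to 150 MY, the upper bound
of the 140–150 MYA monocot–dicot divergence estimate, which reproduces the
published worked rates (13.3 / 10.9 / 4.4 for 105 / 87 / 38 extant B-lectin
genes over 5 ancestral units); it is configurable in [140, 150].

**Expression.** A gene is regulated under a contrast when its
pseudocount-adjusted mean fold change reaches 2 (up) or 1/2 (down) *and* a
two-sided equal-variance Student t-test on replicate signals gives
p < 0.05. "Student's t-test" is read as the classical equal-variance test
(Welch by flag). No multiple-testing correction is applied by default, to
mirror the original analysis; Benjamini–Hochberg is available behind a
flag. Tag-count (MPSS-style) matrices are normalized to tags-per-million
first; without replicates, fold-only calls are flagged untested rather
than given fabricated p-values. Stress summaries combine per-contrast
regulated sets into biotic/abiotic unions with the inclusion–exclusion
identity asserted on every reported union. Tissue specificity — stated
qualitatively in the source as preferential expression in one or two
tissues — is operationalized as: expressed (mean > 5) in 1–2 tissues and
those tissues carrying >= 90% of total signal; both thresholds are package
decisions. A tandem cluster or block pair is expression-divergent when any
contrast shows two distinct member statuses; members without expression
data are excluded and reported, and groups with fewer than two informative
members are not callable.

## The synthetic-data generator

Real genome annotations for this superfamily are not redistributable at
package scale, so testing rests on `simulate_dataset()`, which generates
the full input suite (GFF3, genomic FASTA, TE BED, Newick trees, homology
and domain tables, blocks, expression matrices) with a ground-truth
manifest.

*Evolution.* Each family starts from `n_anc` ancestral genes (defaults: 5,
3, 4 for three simulated families) that evolve independently along the
three lineages under a pure-birth process. The split rate is calibrated so
the expected extant count is exactly `n_anc * (1 + rT/100)` — the linear
model the birth-rate estimator inverts — and default rates follow the
published per-lineage B-lectin values (13.3 / 4.4 / 10.9) plus moderate
values for the smaller families. Pure birth (no loss) is deliberate: it
makes the true root-lineage count exact, so `count_ancestral_units()` has
a known answer; loss would only push the estimate below truth, in the
documented "at least" direction. The dicot split is placed at the root
(both splits at 150 MY), matching the single-calibration rate arithmetic.

*Placement.* Genes are grouped into placement units — tandem arrays
(members at most 3 filler genes apart), segmental source windows (parent
plus two dedicated fillers each side), destination copies (copied fillers
around the new gene, on a different chromosome), singles — and the units
are assembled onto chromosomes with filler runs stretched so that
same-family genes from different units are always more than 10 genes
apart. That spacing is the operational meaning of "dispersed" and makes
the mechanism labels unambiguous by construction. Two event relabelings
keep truth clean: a segmental event whose parent is already in a tandem
array becomes dispersed (so each planted block contains exactly one lectin
per side), and a retro event whose parent is itself intronless becomes
dispersed (intron loss cannot be observed). Nested tandem-within-block
cases still arise — later tandem copies of a block-resident gene — and
both the truth flags and the detector treat the whole array as
block-resident.

*Sequence and hallmarks.* Chromosome sequence is uniform random
nucleotide; retrogene insertions get an exact direct repeat (4–15 bp)
written into both flanks and a poly(A) run (8–30 bp) downstream,
reverse-complemented for minus-strand genes; an erosion rate can mutate
planted hallmark bases. Homology tables are fabricated from true paralogy
(coverage U(0.75, 1), e-value 10^-U(10, 60)) with decoy pairs failing the
70% / 1e-8 filter by construction; no alignment tool is involved, which is
why sequence realism is limited to the hallmark strings.

*Expression.* Baselines are log-normal (meanlog 5, sdlog 0.7 — signals in
the hundreds, so the pseudocount of 1 is negligible); a 30% DE fraction
per contrast receives folds from {2, 4, 8}, planted on the
pseudocount-adjusted scale so the planted fold is exactly what the 2-fold
rule measures at zero noise; replicate noise is multiplicative log-normal
with CV 0.2 at n = 3. Tissue panels plant specificity by zeroing signal
outside 1–2 tissues.

What passing these tests shows: the detectors recover exactly what they
are defined to detect, at realistic family sizes and genome geometry, and
every numeric convention (coordinates, ranks, thresholds, tie-breaks) is
internally consistent. What they do not show: robustness to annotation
error, fragmented assemblies, alignment noise in real homology searches,
sequence-level hallmark degeneracy, or probe-to-gene mapping artifacts in
real expression data — none of which the generator emulates.

## Numerical choices and degenerate inputs

- Internal coordinates are 0-based half-open everywhere; GFF3 converts at
  the boundary, BED passes through. One representative (most-exon) mRNA per
  gene.
- Rank ties (identical starts) break by end then identifier; cluster
  membership is invariant to input order.
- `detect_polyA` scores purity first, then length, then earliest start —
  the ordering that makes a clean A-run beat a longer diluted window.
  `detect_tsd` takes the longest repeat, ties broken by summed distance to
  the boundaries, then upstream proximity.
- Empty inputs return empty, typed tables; a flank clipped to nothing
  returns `NULL`; `estimate_birth_rate()` refuses N_anc = 0 (a family
  absent from the ancestor has no defined per-ancestral-gene rate).
- Equal-variance t-tests on zero-variance replicates fall back to an exact
  equal/unequal decision rather than NaN.

## Problem sizes

The test suite and acceptance script run everything at desk scale, chosen
as the smallest sizes that exercise the claims: the default synthetic
dataset (~390 lectins, ~3,300 genes, ~10 Mb of sequence across three
genomes), exhaustive reconciliation checks over all rooted gene-tree shapes
to 4 leaves with full species labelings (thinned at 5 leaves, random at
6–8), 100 random placements for the tandem-closure oracle, 500-bp flanks
for the scanner oracles, and 600 genes x 5 contrasts for expression
recovery. Birth-rate recovery uses two replicate families of 50 ancestral
genes at r = 10 so the pooled estimator's standard error (~0.6) sits well
inside the 20% band.

## Known limitations

- Ancestral-unit counts are lower bounds; lineage loss and rooting errors
  bias them downward, and the rate estimator inherits that bias (rates are
  "at least").
- Flank-anchor block inference is seeded by lectin pairs only; it is not a
  genome-wide synteny caller and does not date duplications.
- The 2-fold + t-test rule at n = 3 replicates has limited power near the
  fold threshold: with CV 0.2 noise a true 2.5-fold change is missed ~9% of
  the time by the fold filter alone, so recovery of borderline effects
  should be expected to sit near, not at, 90%.
- TSD evidence with the permissive 4-bp minimum is noisy by construction;
  treat short-TSD tiers as corroborative.
- Expression divergence between paralogs conflates regulatory divergence
  with platform noise when members sit near detection thresholds; the
  package reports member-level statuses so such cases can be inspected.
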