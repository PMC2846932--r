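# lectinfam

Genome-wide analysis of plant lectin gene-family evolution and expression
divergence, as an R package.

Plant lectins — carbohydrate-binding proteins spanning twelve domain-defined
families (B_lectin, Lectin_legB, Jacalin, Phloem, Lectin_C, Chitin_bind_1,
Ricin_B_Lectin, Gal_lectin, Gal_binding_Lectin, Calreticulin, EEA, LysM) —
form one of the most dynamically expanding gene superfamilies in higher
plants. `lectinfam` is for comparative genomicists who want to reconstruct
how such a superfamily expanded across genomes (here modelled on a
soybean / rice / Arabidopsis comparison) and what that expansion did to
stress-response expression. It provides:

- **Family classification** from profile-HMM domain-hit tables (e-value
  cutoff 1.0), with pseudogene-like members flagged by partial domain
  coverage.
- **Tandem cluster detection** under the three-part criterion: same family,
  at most 10 genes apart, within 100 kb (compact genomes) or 350 kb (large
  genomes), chained over rank-adjacent members.
- **Segmental duplication assignment** from catalogued block lists, plus
  flank-anchor block inference from 50-kb neighbourhoods, with tandem
  arrays collapsed to single copies and block status inherited by array
  members.
- **Retrogene detection**: single-exon genes matching multi-exon paralogs
  (>= 70% query coverage, e-value <= 1e-8), with target-site-duplication and
  poly(A)-tract scanners over strand-oriented genomic flanks.
- **Transposable-element overlap classes** within 50-kb windows
  (gene-within-TE, TE-in-intron, TE-over-exons, TE-in-flank).
- **Ancestral-unit (MRCA) counting** on species-labelled gene trees by LCA
  reconciliation, and **birth-rate estimation**:

  `rate = 100 * ((N_extant - N_anc) / N_anc) / T` genes per 100 MY per
  ancestral gene, with T the monocot–dicot divergence (140–150 MY, default
  150).

- **Expression analysis** under the 2-fold + Student t-test rule, stress-set
  summaries by inclusion–exclusion, tissue-specificity calls, and
  expression-divergence classification of tandem clusters and segmental
  blocks.
- A seeded **synthetic-genome generator** (`simulate_dataset()`,
  `emit_dataset()`) producing GFF3/FASTA/BED/Newick/TSV inputs with a full
  ground-truth manifest, so the entire pipeline is testable without genome
  downloads.

## Worked example

The flagship family in the three-genome comparison is B_lectin: 105 soybean,
87 rice and 38 Arabidopsis members trace back to 5 lineages in their common
ancestor, which under a 150-MY calibration gives sharply lineage-specific
birth rates:

```r
library(lectinfam)
estimate_birth_rate(105, 5, 150)  # soybean lineage
#> birth rate: 13.3 genes per 100 MY per ancestral gene (N_extant=105, N_anc=5, T=150 MY)
estimate_birth_rate(87, 5, 150)   # rice lineage
#> birth rate: 10.9 genes per 100 MY per ancestral gene (N_extant=87, N_anc=5, T=150 MY)
estimate_birth_rate(38, 5, 150)   # Arabidopsis lineage
#> birth rate: 4.4 genes per 100 MY per ancestral gene (N_extant=38, N_anc=5, T=150 MY)
```

All three rates are far above the ~1 gene / 100 MY / ancestral gene typical
of eukaryotic families, the signature of rapid birth-and-death evolution.

An end-to-end run on a synthetic dataset:

```r
ds <- simulate_dataset(sim_config(seed = 1))
dir <- emit_dataset(ds, tempfile())
res <- run_pipeline(analysis_config(dir))
generate_report(res)
```

The report prints per-family membership counts, expansion-mechanism
partitions (tandem / segmental / both / other), ancestral-unit counts with
birth rates (for the seed-1 dataset, B_lectin: N_anc = 5 in both the
two-dicot and the three-species ancestor, recovered exactly from the
simulated trees), retrogene calls with hallmark tiers, and
stress-regulation summaries with the inclusion–exclusion identity shown,
e.g. `union 91 = 58 + 62 - 29 overlap` for two biotic contrasts.

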