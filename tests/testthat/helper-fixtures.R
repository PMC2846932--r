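# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# full default-condition synthetic dataset (seed fixed for the suite)
shared_dataset <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- simulate_dataset(sim_config(seed = 1))
  .fixture_cache$ds
}

# the same dataset emitted to disk
shared_dataset_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    d <- file.path(tempdir(), "lectinfam_shared_ds")
    emit_dataset(shared_dataset(), d)
    .fixture_cache$dir <- d
  }
  .fixture_cache$dir
}

# species max_bp profiles matching the default config
test_profiles <- function()
  data.frame(species = c("soybean", "Arabidopsis", "rice"),
             max_bp = c(350000, 100000, 350000), stringsAsFactors = FALSE)

# run tandem + segmental detection against the manifest (all lectins)
detect_mechanisms <- function(ds) {
  man <- ds$manifest
  prof <- test_profiles()
  out <- list()
  for (sp in unique(man$species)) {
    ann <- ds$placed$annotation[[sp]]
    msp <- man[man$species == sp, ]
    cl <- list()
    for (fam in unique(msp$family)) {
      cc <- find_tandem_clusters(msp$gene_id[msp$family == fam], ann, 10,
                                 prof$max_bp[prof$species == sp], family = fam)
      if (nrow(cc)) cl[[length(cl) + 1]] <- cc
    }
    clu <- if (length(cl)) do.call(rbind, cl) else
      find_tandem_clusters(character(), ann)
    reps <- collapse_tandem_arrays(msp$gene_id, clu)
    blocks <- ds$placed$blocks[ds$placed$blocks$species == sp, ]
    sb <- assign_segmental_from_blocks(reps, blocks,
                                       msp[, c("gene_id", "family")], ann, clu)
    cls <- classify_expansion(msp$gene_id, clu, sb$segmental_genes)
    cls$species <- sp
    out[[sp]] <- list(clusters = clu, segmental = sb, classes = cls)
  }
  out
}

# a small hand-built annotation: one chromosome, genes at given starts
toy_annotation <- function(starts, ends = starts + 1000, strand = "+",
                           chrom_len = max(ends) + 60000, species = "toy",
                           chromosome = "chr1", n_exons = 2) {
  n <- length(starts)
  ids <- sprintf("g%02d", seq_len(n))
  strand <- rep(strand, length.out = n)
  n_exons <- rep(n_exons, length.out = n)
  genes <- data.frame(gene_id = ids, chromosome = chromosome,
                      start = starts, end = ends, strand = strand,
                      n_exons = n_exons, rank = NA_integer_,
                      stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- n_exons[i]
    w <- (ends[i] - starts[i]) %/% (2 * k - 1)
    es <- starts[i] + (seq_len(k) - 1) * 2 * w
    data.frame(gene_id = ids[i], chromosome = chromosome, start = es,
               end = pmin(es + w, ends[i]), strand = strand[i],
               stringsAsFactors = FALSE)
  }))
  ann <- lectinfam:::new_genome_annotation(
    species, genes, ex, stats::setNames(chrom_len, chromosome))
  compute_gene_ranks(ann)
}

# random nucleotide string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
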