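#' Construct a genomic interval
#'
#' Intervals are 0-based, half-open (`start` inclusive, `end` exclusive), the
#' convention used internally for every base-pair distance in the package
#' (tandem spacing caps, 50-kb flank windows, TE overlap windows). GFF3 input
#' is converted at the reading boundary; BED passes through unchanged.
#'
#' @param chromosome Chromosome identifier.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @return A one-row `data.frame` with columns chromosome, start, end, strand.
#' @export
interval <- function(chromosome, start, end, strand = "*") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval requires start < end")
  stopifnot(all(strand %in% c("+", "-", "*")))
  data.frame(chromosome = as.character(chromosome), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Length of an interval in base pairs
#' @param x A data.frame with `start`/`end` columns.
#' @return Numeric vector of lengths (`end - start`).
#' @export
interval_length <- function(x) x$end - x$start

new_genome_annotation <- function(species, genes, exons, chrom_lengths) {
  stopifnot(!anyDuplicated(genes$gene_id))
  structure(list(species = species, genes = genes, exons = exons,
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: species '%s', %d genes on %d chromosomes\n",
              x$species, nrow(x$genes), length(x$chrom_lengths)))
  invisible(x)
}

validate_annotation <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_ids in annotation")
  len <- ann$chrom_lengths[g$chromosome]
  bad <- which(is.na(len) | g$end > len | g$start < 0)
  if (length(bad))
    stop("genes outside chromosome bounds: ",
         paste(utils::head(g$gene_id[bad], 5), collapse = ", "))
  # every exon inside its gene locus
  ex <- merge(ann$exons, g[, c("gene_id", "start", "end")],
              by = "gene_id", suffixes = c("", ".gene"))
  if (any(ex$start < ex$start.gene | ex$end > ex$end.gene))
    stop("exon outside gene locus")
  invisible(ann)
}

#' Read a GFF3 genome annotation
#'
#' Parses gene/mRNA/exon features, keeps one representative transcript per
#' gene (the mRNA with the most exons, i.e. the longest model; ties broken by
#' mRNA identifier), and converts 1-based inclusive GFF3 coordinates to the
#' internal 0-based half-open convention. Chromosome lengths are taken from
#' `##sequence-region` pragmas when present, otherwise from the rightmost
#' feature per chromosome.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label; defaults to the file's basename.
#' @return A `genome_annotation` object (no ranks assigned yet; see
#'   [compute_gene_ranks()]).
#' @export
read_gff3 <- function(path, species = NULL) {
  if (is.null(species))
    species <- sub("\\.gff3?$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  getid <- function(x) vapply(x, function(v) if (length(v)) v[[1]] else NA_character_, "")
  df$parent <- if ("Parent" %in% names(df)) getid(df$Parent) else NA_character_

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  exons <- df[df$type == "exon", ]
  if (!nrow(genes)) stop("no gene features in ", path)

  # pick representative mRNA per gene: most exons, then id
  exn <- table(exons$parent)
  mrnas$n_exons <- as.integer(exn[mrnas$ID])
  mrnas$n_exons[is.na(mrnas$n_exons)] <- 0L
  mrnas <- mrnas[order(mrnas$parent, -mrnas$n_exons, mrnas$ID), ]
  rep_mrna <- mrnas[!duplicated(mrnas$parent), ]

  keep_ex <- exons[exons$parent %in% rep_mrna$ID, ]
  mrna_gene <- stats::setNames(rep_mrna$parent, rep_mrna$ID)
  gene_strand <- stats::setNames(genes$strand, genes$ID)

  gdf <- data.frame(gene_id = genes$ID, chromosome = genes$seqnames,
                    start = genes$start - 1, end = genes$end,
                    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*"),
                    stringsAsFactors = FALSE)
  edf <- data.frame(gene_id = unname(mrna_gene[keep_ex$parent]),
                    chromosome = keep_ex$seqnames,
                    start = keep_ex$start - 1, end = keep_ex$end,
                    strand = keep_ex$strand, stringsAsFactors = FALSE)
  edf <- edf[order(edf$gene_id, edf$start), ]
  nex <- table(edf$gene_id)
  gdf$n_exons <- as.integer(nex[gdf$gene_id])
  gdf$n_exons[is.na(gdf$n_exons)] <- 1L  # gene without annotated mRNA: single-exon locus
  gdf$rank <- NA_integer_

  # chromosome lengths: sequence-region pragmas, else max end seen
  lens <- tapply(gdf$end, gdf$chromosome, max)
  prag <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(prag)) {
    pp <- strsplit(trimws(prag), "\\s+")
    for (p in pp) if (length(p) >= 4) lens[p[2]] <- as.numeric(p[4])
  }
  ann <- new_genome_annotation(species, gdf, edf, unlist(as.list(lens)))
  validate_annotation(ann)
}

#' Write a genome annotation as GFF3
#'
#' Emits gene/mRNA/exon features (one mRNA per gene), converting internal
#' 0-based half-open coordinates back to 1-based inclusive GFF3.
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes[order(ann$genes$chromosome, ann$genes$start, ann$genes$end,
                       ann$genes$gene_id), ]
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(ann$chrom_lengths),
                     as.integer(ann$chrom_lengths)))
  ex_by_gene <- split(ann$exons, ann$exons$gene_id)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    st <- if (gi$strand == "*") "." else gi$strand
    lines <- c(lines,
      sprintf("%s\tlectinfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gi$chromosome, gi$start + 1, gi$end, st, gi$gene_id),
      sprintf("%s\tlectinfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              gi$chromosome, gi$start + 1, gi$end, st, gi$gene_id, gi$gene_id))
    ex <- ex_by_gene[[gi$gene_id]]
    if (is.null(ex))
      ex <- gi[, c("chromosome", "start", "end", "strand")]
    ex <- ex[order(ex$start), ]
    lines <- c(lines,
      sprintf("%s\tlectinfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              gi$chromosome, ex$start + 1, ex$end, st, gi$gene_id,
              seq_len(nrow(ex)), gi$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assign chromosome ranks to genes
#'
#' Per chromosome, genes sorted by start (ties broken by end, then gene_id)
#' receive ranks 0..n-1. The rank difference between two genes is the "genes
#' apart" distance used by the tandem-duplication criterion.
#'
#' @param ann A `genome_annotation`.
#' @return The annotation with the `rank` column filled.
#' @export
compute_gene_ranks <- function(ann) {
  g <- ann$genes
  o <- order(g$chromosome, g$start, g$end, g$gene_id)
  g <- g[o, ]
  g$rank <- stats::ave(seq_len(nrow(g)), g$chromosome,
                       FUN = function(i) seq_along(i) - 1L)
  ann$genes <- g
  ann
}

#' Extract a flanking window next to a gene
#'
#' Strand-aware: for a `+` (or unknown) strand gene, upstream lies to the
#' left of the locus; for `-` strand, to the right. Windows are clipped to
#' `[0, chromosome length]`.
#'
#' @param ann A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @param side `"upstream"` or `"downstream"`.
#' @param width_bp Window width in bp (> 0).
#' @return A one-row interval data.frame, or `NULL` when the clipped window
#'   is empty (gene abuts the chromosome edge).
#' @export
extract_flank <- function(ann, gene_id, side = c("upstream", "downstream"),
                          width_bp) {
  side <- match.arg(side)
  if (width_bp <= 0) stop("width_bp must be positive")
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (!nrow(g)) stop("unknown gene: ", gene_id)
  clen <- ann$chrom_lengths[[g$chromosome]]
  left <- (side == "upstream") == (g$strand != "-")
  if (left) {
    s <- max(0, g$start - width_bp); e <- g$start
  } else {
    s <- g$end; e <- min(clen, g$end + width_bp)
  }
  if (s >= e) return(NULL)
  interval(g$chromosome, s, e, g$strand)
}

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write sequences to a FASTA file (wrapped at 60 columns)
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a BED file of annotated features
#'
#' BED is already 0-based half-open, matching the internal convention; the
#' name field carries the feature label (e.g. TE superfamily).
#'
#' @param path BED path (3-6 columns).
#' @return data.frame with chromosome, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  data.frame(chromosome = as.character(df$seqnames),
             start = df$start - 1, end = df$end,
             name = if ("name" %in% names(df)) df$name else NA_character_,
             score = if ("score" %in% names(df)) df$score else 0,
             strand = as.character(df$strand), stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#' @param df data.frame with chromosome, start, end and optional name,
#'   score, strand columns (internal 0-based half-open, written unchanged).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) ifelse(df$strand == "*", ".", df$strand) else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", df$chromosome,
                     as.integer(df$start), as.integer(df$end),
                     name, score, strand), path)
  invisible(path)
}

#' Read / write a TSV table with a header row
#' @param path File path.
#' @return data.frame (`read_tsv_table`) or `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
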