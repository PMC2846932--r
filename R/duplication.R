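#' Find tandem duplication clusters of a gene family
#'
#' Two same-family genes on one chromosome are tandem neighbours when they
#' are at most `max_gene_gap` genes apart (difference of chromosome ranks)
#' and their starts lie within `max_bp`. Clusters are the maximal chains of
#' rank-consecutive family members satisfying both gaps — equivalently the
#' connected components of the pairwise predicate, since gene starts are
#' monotone in rank. Singletons are not clusters.
#'
#' @param family_genes Character vector of member gene_ids (one family).
#' @param ann A ranked `genome_annotation` (see [compute_gene_ranks()]).
#' @param max_gene_gap Maximum rank difference (default 10).
#' @param max_bp Maximum start-to-start distance in bp: 100000 for a compact
#'   genome (Arabidopsis-like), 350000 for soybean/rice-like genomes.
#' @param family Family label stored on the clusters.
#' @return data.frame with one row per cluster: cluster_id, family,
#'   chromosome, members (comma-joined in rank order), n_members, span_start,
#'   span_end.
#' @export
find_tandem_clusters <- function(family_genes, ann, max_gene_gap = 10,
                                 max_bp = 350000, family = NA_character_) {
  g <- ann$genes[ann$genes$gene_id %in% family_genes, , drop = FALSE]
  if (nrow(g) && anyNA(g$rank)) stop("gene ranks not computed; run compute_gene_ranks()")
  out <- list()
  for (chr in unique(g$chromosome)) {
    gc <- g[g$chromosome == chr, ]
    gc <- gc[order(gc$rank), ]
    if (nrow(gc) < 2) next
    link <- diff(gc$rank) <= max_gene_gap & diff(gc$start) <= max_bp
    comp <- cumsum(c(TRUE, !link))
    for (id in unique(comp)) {
      m <- gc[comp == id, ]
      if (nrow(m) < 2) next
      out[[length(out) + 1]] <- data.frame(
        family = family, chromosome = chr,
        members = paste(m$gene_id, collapse = ","), n_members = nrow(m),
        span_start = min(m$start), span_end = max(m$end),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(family = character(), chromosome = character(),
               members = character(), n_members = integer(),
               span_start = numeric(), span_end = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chromosome, res$span_start), , drop = FALSE]
  res$cluster_id <- if (nrow(res)) sprintf("TC%03d", seq_len(nrow(res))) else character()
  res[, c("cluster_id", "family", "chromosome", "members", "n_members",
          "span_start", "span_end")]
}

cluster_member_list <- function(clusters)
  strsplit(clusters$members, ",", fixed = TRUE)

#' Collapse tandem arrays to single representatives
#'
#' For gene-copy counting, a tandem array counts as one copy: each cluster is
#' replaced by its lowest-rank member; non-clustered genes pass through.
#'
#' @param genes Character vector of gene_ids under analysis.
#' @param clusters Cluster table from [find_tandem_clusters()] (members
#'   already rank-ordered).
#' @return Character vector of representative gene_ids.
#' @export
collapse_tandem_arrays <- function(genes, clusters) {
  members <- cluster_member_list(clusters)
  reps <- vapply(members, `[`, "", 1)
  drop <- setdiff(unlist(members), reps)
  union(setdiff(genes, drop), intersect(reps, genes))
}

#' Read a segmental duplication block list
#'
#' File columns (block_id, chrA, startA, endA, chrB, startB, endB) use
#' 1-based inclusive coordinates at the boundary and are converted to the
#' internal 0-based half-open convention.
#'
#' @param path TSV path.
#' @return data.frame of block pairs with a `provenance = "given"` column.
#' @export
read_blocks <- function(path) {
  b <- read_tsv_table(path)
  need <- c("block_id", "chrA", "startA", "endA", "chrB", "startB", "endB")
  stopifnot(all(need %in% names(b)))
  b$startA <- b$startA - 1; b$startB <- b$startB - 1
  b$provenance <- "given"
  b
}

genes_in_window <- function(ann, chr, start, end) {
  g <- ann$genes
  g$gene_id[g$chromosome == chr & g$start < end & g$end > start]
}

#' Mark segmentally duplicated gene pairs from known blocks
#'
#' A representative pair (g, g') is segmental when g lies in interval A and
#' g' in interval B of one block (or vice versa) and both belong to the same
#' family. Members of a collapsed tandem array inherit the array
#' representative's segmental status, since gene-level summaries count
#' genes, not representatives.
#'
#' @param representatives Gene_ids after [collapse_tandem_arrays()].
#' @param blocks Block table from [read_blocks()] (internal coordinates).
#' @param assignments Family assignments (gene_id, family).
#' @param ann A `genome_annotation`.
#' @param clusters Cluster table, used to propagate status to array members.
#' @return list(pairs = data.frame(block_id, gene_a, gene_b, family),
#'   segmental_genes = character vector incl. inherited array members).
#' @export
assign_segmental_from_blocks <- function(representatives, blocks, assignments,
                                         ann, clusters = NULL) {
  fam <- stats::setNames(assignments$family, assignments$gene_id)
  # map every analyzed gene to its representative: a collapsed array lies in
  # a block when any of its members does
  rep_of <- stats::setNames(assignments$gene_id, assignments$gene_id)
  if (!is.null(clusters) && nrow(clusters)) {
    for (m in cluster_member_list(clusters))
      rep_of[m] <- intersect(representatives, m)[1]
  }
  reps_in <- function(chr, s, e) {
    g <- intersect(genes_in_window(ann, chr, s, e), names(rep_of))
    unique(stats::na.omit(rep_of[g]))
  }
  pairs <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ga <- reps_in(b$chrA, b$startA, b$endA)
    gb <- reps_in(b$chrB, b$startB, b$endB)
    if (!length(ga) || !length(gb)) next
    for (a in ga) for (bb in gb) {
      if (a != bb && !is.na(fam[a]) && !is.na(fam[bb]) && fam[a] == fam[bb])
        pairs[[length(pairs) + 1]] <- data.frame(
          block_id = b$block_id, gene_a = a, gene_b = bb,
          family = unname(fam[a]), stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(block_id = character(), gene_a = character(),
               gene_b = character(), family = character(),
               stringsAsFactors = FALSE)
  seg <- unique(c(pairs$gene_a, pairs$gene_b))
  if (!is.null(clusters) && nrow(clusters)) {
    for (m in cluster_member_list(clusters))
      if (any(m %in% seg)) seg <- union(seg, m)
  }
  list(pairs = pairs, segmental_genes = seg)
}

#' Infer a segmental block from flanking-gene homology
#'
#' For a candidate duplicated lectin pair without a catalogued block, the
#' 50-kb windows around each gene are compared: if, besides the lectin pair
#' itself, at least `min_extra_anchors` homologous gene pairs connect the two
#' neighbourhoods with consistent relative order (co-linear or fully
#' reversed), an inferred block spanning the outermost anchors is returned.
#' Order consistency is assessed as the longest monotone (increasing or
#' decreasing) run of anchor positions in window B when anchors are sorted
#' by position in window A.
#'
#' @param gene_a,gene_b The candidate pair's gene_ids.
#' @param ann A `genome_annotation`.
#' @param homology data.frame with columns qseqid, sseqid (any extra columns
#'   ignored) listing homologous gene pairs.
#' @param flank_bp Window half-width around each gene (default 50000).
#' @param min_extra_anchors Minimum anchors besides the lectin pair
#'   (default 2).
#' @return One-row block data.frame (provenance `"inferred"`), or `NULL`
#'   when no block is supported (overlapping windows, too few anchors, or
#'   inconsistent anchor order).
#' @export
infer_block_from_flanks <- function(gene_a, gene_b, ann, homology,
                                    flank_bp = 50000, min_extra_anchors = 2) {
  g <- ann$genes
  a <- g[g$gene_id == gene_a, ]; b <- g[g$gene_id == gene_b, ]
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  wa <- c(max(0, a$start - flank_bp), min(ann$chrom_lengths[[a$chromosome]], a$end + flank_bp))
  wb <- c(max(0, b$start - flank_bp), min(ann$chrom_lengths[[b$chromosome]], b$end + flank_bp))
  if (a$chromosome == b$chromosome && wa[1] < wb[2] && wb[1] < wa[2])
    return(NULL)  # self-overlap: the two windows are not independent
  ga <- setdiff(genes_in_window(ann, a$chromosome, wa[1], wa[2]), c(gene_a, gene_b))
  gb <- setdiff(genes_in_window(ann, b$chromosome, wb[1], wb[2]), c(gene_a, gene_b))
  hom <- homology[(homology$qseqid %in% ga & homology$sseqid %in% gb) |
                  (homology$qseqid %in% gb & homology$sseqid %in% ga), ,
                  drop = FALSE]
  if (!nrow(hom)) return(NULL)  # no anchors
  anc_a <- ifelse(hom$qseqid %in% ga, hom$qseqid, hom$sseqid)
  anc_b <- ifelse(hom$qseqid %in% ga, hom$sseqid, hom$qseqid)
  anc <- unique(data.frame(a = anc_a, b = anc_b, stringsAsFactors = FALSE))
  pos <- stats::setNames(g$start, g$gene_id)
  anc <- anc[order(pos[anc$a]), , drop = FALSE]
  bpos <- rank(pos[anc$b], ties.method = "first")
  n_ok <- max(longest_monotone_run(bpos), longest_monotone_run(rev(bpos)))
  if (n_ok < min_extra_anchors) return(NULL)  # order not consistent
  sa <- c(pos[anc$a], a$start); ea <- c(g$end[match(anc$a, g$gene_id)], a$end)
  sb <- c(pos[anc$b], b$start); eb <- c(g$end[match(anc$b, g$gene_id)], b$end)
  data.frame(block_id = paste0("INF_", gene_a, "_", gene_b),
             chrA = a$chromosome, startA = min(sa), endA = max(ea),
             chrB = b$chromosome, startB = min(sb), endB = max(eb),
             n_anchors = nrow(anc), provenance = "inferred",
             stringsAsFactors = FALSE)
}

# length of the longest increasing subsequence (strict) of x
longest_monotone_run <- function(x) {
  if (!length(x)) return(0L)
  best <- integer(length(x))
  for (i in seq_along(x)) {
    prev <- best[which(x[seq_len(i - 1)] < x[i])]
    best[i] <- 1L + if (length(prev)) max(prev) else 0L
  }
  max(best)
}

#' Classify each gene's expansion mechanism
#'
#' Partition by duplication evidence: `tandem` (in a cluster only),
#' `segmental` (in a block pair only), `both`, or `other` (dispersed or
#' single-copy; includes retrogenes, which are called separately).
#'
#' @param genes Character vector of analyzed gene_ids.
#' @param clusters Cluster table from [find_tandem_clusters()].
#' @param segmental_genes Character vector from
#'   [assign_segmental_from_blocks()].
#' @return data.frame(gene_id, class).
#' @export
classify_expansion <- function(genes, clusters, segmental_genes) {
  in_tan <- genes %in% unlist(cluster_member_list(clusters))
  in_seg <- genes %in% segmental_genes
  cls <- ifelse(in_tan & in_seg, "both",
         ifelse(in_tan, "tandem", ifelse(in_seg, "segmental", "other")))
  data.frame(gene_id = genes, class = cls, stringsAsFactors = FALSE)
}

#' Summarize expansion mechanisms per family
#'
#' Counts and integer-rounded percentages of tandem / segmental / both /
#' other members against family totals. `pct_tandem_any` counts genes in any
#' tandem evidence (tandem + both) and `pct_segmental_any` likewise.
#'
#' @param classes data.frame from [classify_expansion()].
#' @param assignments Family assignments (gene_id, family).
#' @return data.frame, one row per family plus a `total` row.
#' @export
expansion_summary <- function(classes, assignments) {
  fam <- stats::setNames(assignments$family, assignments$gene_id)
  classes$family <- unname(fam[classes$gene_id])
  one <- function(df, label) {
    n <- nrow(df)
    cnt <- function(k) sum(df$class == k)
    data.frame(family = label, n_total = n, n_tandem = cnt("tandem"),
               n_segmental = cnt("segmental"), n_both = cnt("both"),
               n_other = cnt("other"),
               pct_tandem_any = round(100 * (cnt("tandem") + cnt("both")) / max(n, 1)),
               pct_segmental_any = round(100 * (cnt("segmental") + cnt("both")) / max(n, 1)),
               pct_other = round(100 * cnt("other") / max(n, 1)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(split(classes, classes$family), function(d) one(d, d$family[1]))
  rbind(do.call(rbind, rows), one(classes, "total"))
}
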