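#' Classify a gene's relationship to transposable-element annotations
#'
#' Within a window of `flank_bp` either side of the gene, each TE is tested
#' against a fixed most-specific-first priority: the gene lying entirely
#' inside a TE (`gene_within_te`), a TE entirely inside an intron
#' (`te_within_intron`), a TE overlapping exon sequence
#' (`te_within_exon_region`), a TE anywhere in the flank windows
#' (`te_in_flank`), else `none`. The highest-priority class over all TEs is
#' reported with its element; ties within a class go to the element nearest
#' the gene start.
#'
#' @param ann A `genome_annotation`.
#' @param gene_id Gene to classify.
#' @param te data.frame of TE annotations: chromosome, start, end, name
#'   (element id), superfamily (MULE/CACTA/hAT/Helitron/other) — as produced
#'   by [read_bed()] with `name` holding `element_id:superfamily`.
#' @param flank_bp Flank window width (default 50000).
#' @return data.frame(gene_id, class, element_id, superfamily).
#' @export
classify_te_overlap <- function(ann, gene_id, te, flank_bp = 50000) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  stopifnot(nrow(g) == 1)
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) ex <- g[, c("gene_id", "chromosome", "start", "end")]
  ex <- ex[order(ex$start), ]
  # introns: gaps between consecutive exons
  introns <- if (nrow(ex) > 1)
    data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1]) else
    data.frame(start = numeric(), end = numeric())
  clen <- ann$chrom_lengths[[g$chromosome]]
  win <- c(max(0, g$start - flank_bp), min(clen, g$end + flank_bp))
  cand <- te[te$chromosome == g$chromosome & te$start < win[2] &
             te$end > win[1], , drop = FALSE]
  class_of <- function(t) {
    if (t$start <= g$start && t$end >= g$end) return("gene_within_te")
    if (nrow(introns) &&
        any(t$start >= introns$start & t$end <= introns$end))
      return("te_within_intron")
    if (any(t$start < ex$end & t$end > ex$start))
      return("te_within_exon_region")
    "te_in_flank"
  }
  lv <- c("gene_within_te", "te_within_intron", "te_within_exon_region",
          "te_in_flank")
  if (nrow(cand)) {
    cls <- vapply(seq_len(nrow(cand)), function(i) class_of(cand[i, ]), "")
    pri <- match(cls, lv)
    dist <- abs((cand$start + cand$end) / 2 - (g$start + g$end) / 2)
    o <- order(pri, dist)[1]
    return(data.frame(gene_id = gene_id, class = cls[o],
                      element_id = cand$name[o],
                      superfamily = te_superfamily(cand$name[o]),
                      stringsAsFactors = FALSE))
  }
  data.frame(gene_id = gene_id, class = "none", element_id = NA_character_,
             superfamily = NA_character_, stringsAsFactors = FALSE)
}

te_superfamily <- function(name) {
  part <- sub("^[^:]*:?", "", name)
  ifelse(part %in% c("MULE", "CACTA", "hAT", "Helitron"), part, "other")
}

#' TE overlap classes for every gene of an annotation subset
#' @param ann A `genome_annotation`.
#' @param gene_ids Genes to classify (default: all).
#' @param te TE annotation data.frame (see [classify_te_overlap()]).
#' @param flank_bp Flank window width.
#' @return data.frame, one row per gene.
#' @export
te_overlap_table <- function(ann, te, gene_ids = ann$genes$gene_id,
                             flank_bp = 50000) {
  do.call(rbind, lapply(gene_ids, classify_te_overlap, ann = ann, te = te,
                        flank_bp = flank_bp))
}
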