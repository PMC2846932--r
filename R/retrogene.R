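#' Read an all-vs-all protein homology table
#'
#' 12-column BLAST tabular dialect (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore), headerless. Query
#' coverage requires a sidecar of protein lengths.
#'
#' @param path Table path.
#' @param protein_lengths Optional named vector (gene_id -> aa length); when
#'   given, a `qcov` column (aligned query fraction) is added.
#' @return data.frame of homology hits.
#' @export
read_homology_table <- function(path, protein_lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  h <- utils::read.delim(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(h) != 12) stop("expected 12-column BLAST tabular input")
  names(h) <- cols
  if (!is.null(protein_lengths))
    h$qcov <- (h$qend - h$qstart + 1) / unname(protein_lengths[h$qseqid])
  h
}

#' Find retrogene candidate pairs
#'
#' A retrogene candidate is a single-exon lectin gene whose protein matches a
#' multi-exon lectin gene over at least `min_cov` of the query protein at
#' e-value at most `max_e`. The best-e-value qualifying multi-exon homolog is
#' designated the parental gene.
#'
#' @param ann A `genome_annotation` (provides exon counts).
#' @param assignments Family assignments (restricts to lectin genes).
#' @param homology Homology table with a `qcov` column (see
#'   [read_homology_table()]).
#' @param min_cov Minimum aligned query fraction (default 0.70).
#' @param max_e Maximum e-value (default 1e-8).
#' @return data.frame(retrogene, parent, evalue, qcov, pident), one row per
#'   single-exon query with a qualifying parent.
#' @export
find_retro_candidates <- function(ann, assignments, homology,
                                  min_cov = 0.70, max_e = 1e-8) {
  nex <- stats::setNames(ann$genes$n_exons, ann$genes$gene_id)
  lectins <- assignments$gene_id
  single <- lectins[nex[lectins] == 1L]
  multi <- lectins[nex[lectins] >= 2L]
  h <- homology[homology$qseqid %in% single & homology$sseqid %in% multi &
                homology$qcov >= min_cov & homology$evalue <= max_e, ,
                drop = FALSE]
  if (!nrow(h))
    return(data.frame(retrogene = character(), parent = character(),
                      evalue = numeric(), qcov = numeric(), pident = numeric(),
                      stringsAsFactors = FALSE))
  h <- h[order(h$qseqid, h$evalue, -h$bitscore, h$sseqid), ]
  best <- h[!duplicated(h$qseqid), ]
  data.frame(retrogene = best$qseqid, parent = best$sseqid,
             evalue = best$evalue, qcov = best$qcov, pident = best$pident,
             stringsAsFactors = FALSE)
}

#' Scan a downstream flank for a poly(A) tract
#'
#' Finds the best-scoring substring of the first `window` bases with length
#' at least `min_run` and adenine fraction at least `min_purity`: highest
#' purity first, then longest, then earliest start. The flank must be
#' oriented 5'->3' on the gene's coding strand, so a genuine retrogene
#' tract reads as a run of A.
#'
#' @param downstream_seq Character scalar (ACGT).
#' @param window Bases scanned from the gene end (default 200).
#' @param min_run Minimum tract length (default 8).
#' @param min_purity Minimum A fraction (default 0.8).
#' @return list(start, length, purity) with 1-based `start` offset into the
#'   flank, or `NULL` when no qualifying tract exists.
#' @export
detect_polyA <- function(downstream_seq, window = 200, min_run = 8,
                         min_purity = 0.8) {
  s <- toupper(substr(downstream_seq, 1, window))
  n <- nchar(s)
  if (n < min_run) return(NULL)
  isA <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == "A")
  cs <- c(0L, cumsum(isA))
  best <- NULL
  for (len in seq(n, min_run)) {
    starts <- seq_len(n - len + 1)
    frac <- (cs[starts + len] - cs[starts]) / len
    ok <- which(frac >= min_purity)
    if (!length(ok)) next
    i <- ok[which.max(frac[ok])]
    # purity beats length; length beats start (lengths scan high to low,
    # so on purity ties the incumbent longer hit is kept)
    if (is.null(best) || frac[i] > best$purity + 1e-12)
      best <- list(start = i, length = len, purity = frac[i])
  }
  best
}

#' Scan flanks for a target-site duplication (direct repeat)
#'
#' Searches the `search_bp` bases of the upstream flank nearest the gene and
#' the first `search_bp` bases of the downstream flank for the longest
#' direct repeat of length `min_len`..`max_len` with at most `max_mismatch`
#' mismatches; among equal-length matches the pair closest to the gene
#' boundaries wins (summed distance, then upstream proximity).
#'
#' Flanks must be oriented 5'->3' on the gene's strand with the upstream
#' string ending at the gene start and the downstream string beginning at
#' the gene end.
#'
#' @param upstream_seq,downstream_seq Character scalars.
#' @param min_len,max_len Repeat length bounds (default 4-20).
#' @param max_mismatch Mismatches tolerated (default 0, exact repeats).
#' @param search_bp Window near each boundary searched (default 100).
#' @return list(repeat_seq, length, up_offset, down_offset, mismatches)
#'   where `up_offset` is the distance from the repeat's end to the upstream
#'   boundary and `down_offset` the distance from the downstream boundary to
#'   the repeat's start; or `NULL`.
#' @export
detect_tsd <- function(upstream_seq, downstream_seq, min_len = 4,
                       max_len = 20, max_mismatch = 0, search_bp = 100) {
  up <- toupper(upstream_seq); down <- toupper(downstream_seq)
  nu <- nchar(up)
  up_tail <- substr(up, max(1, nu - search_bp + 1), nu)
  down_head <- substr(down, 1, search_bp)
  ntail <- nchar(up_tail); nhead <- nchar(down_head)
  top_len <- min(max_len, ntail, nhead)
  if (top_len < min_len) return(NULL)
  for (len in seq(top_len, min_len)) {
    ustarts <- seq_len(ntail - len + 1)
    dstarts <- seq_len(nhead - len + 1)
    usub <- substring(up_tail, ustarts, ustarts + len - 1)
    dsub <- substring(down_head, dstarts, dstarts + len - 1)
    if (max_mismatch == 0) {
      hit_idx <- which(outer(usub, dsub, `==`), arr.ind = TRUE)
      mm <- rep(0L, nrow(hit_idx))
    } else {
      um <- do.call(rbind, strsplit(usub, "", fixed = TRUE))
      dm <- do.call(rbind, strsplit(dsub, "", fixed = TRUE))
      mmat <- matrix(0L, length(usub), length(dsub))
      for (k in seq_len(len))
        mmat <- mmat + outer(um[, k], dm[, k], `!=`)
      hit_idx <- which(mmat <= max_mismatch, arr.ind = TRUE)
      mm <- mmat[hit_idx]
    }
    if (nrow(hit_idx)) {
      iu <- unname(hit_idx[, 1]); id <- unname(hit_idx[, 2])
      up_off <- ntail - (iu + len - 1)  # bases between repeat end and gene start
      down_off <- id - 1                # bases between gene end and repeat start
      score <- up_off + down_off
      o <- order(score, up_off, down_off)[1]
      return(list(repeat_seq = usub[iu[o]], length = len,
                  up_offset = up_off[o], down_offset = down_off[o],
                  mismatches = as.integer(mm[o])))
    }
  }
  NULL
}

#' Call retrogenes with hallmark evidence tiers
#'
#' Each candidate pair is annotated with the retrogene hallmarks found in
#' its genomic flanks: a target-site duplication (TSD) and/or a poly(A)
#' tract. Homology-only calls are retained but flagged, since hallmarks
#' erode by substitution and indel over time.
#'
#' @param candidates data.frame from [find_retro_candidates()].
#' @param ann A `genome_annotation`.
#' @param genome Named character vector of chromosome sequences.
#' @param flank_bp Flank width extracted around each retrogene (default 500).
#' @param polyA_args,tsd_args Lists of scanner parameter overrides.
#' @return data.frame(retrogene, parent, evalue, qcov, has_tsd, has_polyA,
#'   tier) with tier in homology_only / +polyA / +TSD / +both.
#' @export
call_retrogenes <- function(candidates, ann, genome, flank_bp = 500,
                            polyA_args = list(), tsd_args = list()) {
  n <- nrow(candidates)
  has_tsd <- logical(n); has_pa <- logical(n)
  for (i in seq_len(n)) {
    fl <- gene_flank_seqs(ann, genome, candidates$retrogene[i], flank_bp)
    pa <- do.call(detect_polyA, c(list(fl$downstream), polyA_args))
    ts <- do.call(detect_tsd, c(list(fl$upstream, fl$downstream), tsd_args))
    has_pa[i] <- !is.null(pa); has_tsd[i] <- !is.null(ts)
  }
  tier <- ifelse(has_tsd & has_pa, "+both",
          ifelse(has_tsd, "+TSD", ifelse(has_pa, "+polyA", "homology_only")))
  cbind(candidates,
        data.frame(has_tsd = has_tsd, has_polyA = has_pa, tier = tier,
                   stringsAsFactors = FALSE))
}

# strand-oriented flank sequences: upstream ends at the gene start,
# downstream begins at the gene end, both read 5'->3' on the gene's strand
gene_flank_seqs <- function(ann, genome, gene_id, flank_bp) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  stopifnot(nrow(g) == 1)
  chrseq <- genome[[g$chromosome]]
  clen <- nchar(chrseq)
  left <- substr(chrseq, max(1, g$start - flank_bp + 1), g$start)
  right <- substr(chrseq, g$end + 1, min(clen, g$end + flank_bp))
  if (g$strand == "-") {
    list(upstream = revcomp(right), downstream = revcomp(left))
  } else {
    list(upstream = left, downstream = right)
  }
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Retrogenes that seeded tandem arrays
#'
#' Reports the retrogene calls whose gene sits inside a tandem cluster —
#' retroposition followed by tandem duplication, a two-step expansion route.
#'
#' @param calls data.frame from [call_retrogenes()].
#' @param clusters Cluster table from [find_tandem_clusters()].
#' @return data.frame(retrogene, cluster_id, n_comembers, comembers).
#' @export
retro_tandem_expansion <- function(calls, clusters) {
  out <- list()
  members <- cluster_member_list(clusters)
  for (i in seq_len(nrow(calls))) {
    rg <- calls$retrogene[i]
    for (j in seq_along(members)) {
      if (rg %in% members[[j]]) {
        co <- setdiff(members[[j]], rg)
        out[[length(out) + 1]] <- data.frame(
          retrogene = rg, cluster_id = clusters$cluster_id[j],
          n_comembers = length(co), comembers = paste(co, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(retrogene = character(), cluster_id = character(),
               n_comembers = integer(), comembers = character(),
               stringsAsFactors = FALSE)
}
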