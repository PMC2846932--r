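#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has genes in rows (first column `gene_id`) and samples in
#' columns; the sidecar TSV has columns sample, condition, replicate, tissue,
#' category (biotic/abiotic/control/tissue).
#'
#' @param matrix_path,meta_path File paths.
#' @param platform `"microarray"` (replicated signals) or `"tag_count"`
#'   (MPSS-style counts, normalized to tags-per-million before fold tests).
#' @return list of class `expression_set`: `signal` (numeric matrix), `meta`
#'   (data.frame), `platform`.
#' @export
read_expression <- function(matrix_path, meta_path, platform = c("microarray", "tag_count")) {
  platform <- match.arg(platform)
  m <- read_tsv_table(matrix_path)
  meta <- read_tsv_table(meta_path)
  sig <- as.matrix(m[, -1, drop = FALSE])
  rownames(sig) <- m[[1]]
  stopifnot(all(colnames(sig) %in% meta$sample), all(is.finite(sig)), all(sig >= 0))
  meta <- meta[match(colnames(sig), meta$sample), ]
  if (platform == "tag_count")
    sig <- sweep(sig, 2, colSums(sig), "/") * 1e6
  structure(list(signal = sig, meta = meta, platform = platform),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set (%s): %d genes x %d samples, conditions {%s}\n",
              x$platform, nrow(x$signal), ncol(x$signal),
              paste(unique(x$meta$condition), collapse = ", ")))
  invisible(x)
}

#' Call differential expression for one stress contrast
#'
#' A gene is regulated when its pseudocount-adjusted mean fold change
#' (stress over control) reaches `min_fold` (up) or `1/min_fold` (down) AND
#' a two-sided two-sample Student t-test on the replicate signals gives
#' p < `alpha`. With fewer than two replicates on either side no test is
#' possible: the fold-only status is reported with `tested = FALSE`. No
#' multiple-testing correction is applied by default; `fdr = TRUE` switches
#' the p-value column to Benjamini-Hochberg-adjusted values before
#' thresholding.
#'
#' @param es An `expression_set`.
#' @param control,stress Condition labels in the metadata.
#' @param contrast Name stored on the calls (default `stress`).
#' @param min_fold Fold-change threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @param welch Use the unequal-variance (Welch) test instead of the
#'   classical equal-variance test (default FALSE).
#' @param fdr Apply BH correction across genes (default FALSE).
#' @return data.frame(gene_id, contrast, fold, p, status, tested) with
#'   status in up/down/ns.
#' @export
call_differential <- function(es, control, stress, contrast = stress,
                              min_fold = 2.0, alpha = 0.05, pseudocount = 1.0,
                              welch = FALSE, fdr = FALSE) {
  cc <- which(es$meta$condition == control)
  ss <- which(es$meta$condition == stress)
  if (!length(cc) || !length(ss))
    stop("contrast error: condition not present in matrix: ",
         if (!length(cc)) control else stress)
  sig <- es$signal
  fold <- (rowMeans(sig[, ss, drop = FALSE]) + pseudocount) /
          (rowMeans(sig[, cc, drop = FALSE]) + pseudocount)
  tested <- length(cc) >= 2 && length(ss) >= 2
  p <- rep(NA_real_, nrow(sig))
  if (tested) {
    p <- apply(sig, 1, function(x) {
      if (stats::sd(x[cc]) == 0 && stats::sd(x[ss]) == 0)
        return(if (mean(x[cc]) == mean(x[ss])) 1 else 0)
      stats::t.test(x[ss], x[cc], var.equal = !welch)$p.value
    })
    if (fdr) p <- stats::p.adjust(p, method = "BH")
  }
  sig_ok <- if (tested) p < alpha else TRUE
  status <- ifelse(fold >= min_fold & sig_ok, "up",
            ifelse(fold <= 1 / min_fold & sig_ok, "down", "ns"))
  data.frame(gene_id = rownames(sig), contrast = contrast, fold = fold,
             p = p, status = status, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Size of a set union by inclusion-exclusion
#' @param n_a,n_b Set sizes.
#' @param n_ab Intersection size.
#' @return `n_a + n_b - n_ab`.
#' @export
union_size <- function(n_a, n_b, n_ab) n_a + n_b - n_ab

#' Integer-rounded percentage
#' @param n Count.
#' @param total Denominator.
#' @return `round(100 * n / total)`.
#' @export
pct_of <- function(n, total) round(100 * n / total)

#' Summarize stress-regulated gene sets with inclusion-exclusion
#'
#' Combines per-contrast differential-expression calls into biotic and
#' abiotic regulated sets (unions over the category's contrasts), their
#' overlap, and the any-stress union, with integer-rounded percentages of
#' the analyzed total.
#'
#' @param calls data.frame of calls (rbind of [call_differential()] outputs).
#' @param contrast_categories Named vector contrast -> category
#'   (`"biotic"`/`"abiotic"`).
#' @param total Denominator for percentages (default: number of distinct
#'   genes in `calls`).
#' @return list of class `stress_summary` with per-contrast counts, set
#'   sizes (biotic, abiotic, overlap, any) and percentages.
#' @export
summarize_stress_sets <- function(calls, contrast_categories, total = NULL) {
  reg <- calls[calls$status %in% c("up", "down"), ]
  sets <- split(reg$gene_id, reg$contrast)
  sets <- lapply(sets, unique)
  if (is.null(total)) total <- length(unique(calls$gene_id))
  cat_of <- contrast_categories
  union_of <- function(category) {
    cs <- names(cat_of)[cat_of == category]
    unique(unlist(sets[intersect(names(sets), cs)]))
  }
  biotic <- union_of("biotic"); abiotic <- union_of("abiotic")
  both <- intersect(biotic, abiotic)
  any_set <- union(biotic, abiotic)
  stopifnot(length(any_set) ==
            union_size(length(biotic), length(abiotic), length(both)))
  structure(list(
    per_contrast = vapply(sets, length, 1L),
    n_biotic = length(biotic), n_abiotic = length(abiotic),
    n_overlap = length(both), n_any = length(any_set), total = total,
    pct_biotic = pct_of(length(biotic), total),
    pct_abiotic = pct_of(length(abiotic), total),
    pct_any = pct_of(length(any_set), total),
    genes = list(biotic = biotic, abiotic = abiotic, any = any_set)),
    class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  cat(sprintf(
    "stress regulation: biotic %d (%d%%), abiotic %d (%d%%), overlap %d, any %d (%d%%) of %d genes\n",
    x$n_biotic, x$pct_biotic, x$n_abiotic, x$pct_abiotic, x$n_overlap,
    x$n_any, x$pct_any, x$total))
  invisible(x)
}

#' Call tissue-specific expression
#'
#' A gene is tissue-specific when it is expressed (mean signal above
#' `theta`) in at least one and at most `max_tissues` tissues AND its top
#' `max_tissues` tissues carry at least `min_share` of its total signal —
#' operationalizing "preferentially expressed in only one or two tissues".
#'
#' @param es An `expression_set` whose metadata `tissue` column labels the
#'   samples (>= 3 distinct tissues required).
#' @param theta Expression threshold (default 5).
#' @param max_tissues Maximum expressed tissues (default 2).
#' @param min_share Minimum signal share of the top tissues (default 0.9).
#' @return data.frame(gene_id, n_expressed, top_share, specific).
#' @export
call_tissue_specific <- function(es, theta = 5.0, max_tissues = 2,
                                 min_share = 0.9) {
  tis <- es$meta$tissue
  stopifnot(length(unique(tis)) >= 3)
  means <- t(apply(es$signal, 1, function(x) tapply(x, tis, mean)))
  n_exp <- rowSums(means > theta)
  top_share <- apply(means, 1, function(m) {
    tot <- sum(m)
    if (tot == 0) return(0)
    sum(sort(m, decreasing = TRUE)[seq_len(max_tissues)]) / tot
  })
  data.frame(gene_id = rownames(es$signal), n_expressed = n_exp,
             top_share = top_share,
             specific = n_exp >= 1 & n_exp <= max_tissues &
                        top_share >= min_share,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression divergence of a duplicated gene group
#'
#' A tandem cluster (or segmental block pair) is divergent when, under at
#' least one stress contrast, its members do not all share the same
#' regulation status — i.e. some member responds while a co-member does not,
#' or they respond in opposite directions. Members without expression data
#' are excluded and reported; groups with fewer than two informative members
#' are not callable (`NA`).
#'
#' @param members Character vector of member gene_ids.
#' @param calls data.frame of per-contrast calls covering the members.
#' @return list(divergent, n_informative, excluded, contrasts_divergent).
#' @export
cluster_divergence <- function(members, calls) {
  have <- intersect(members, unique(calls$gene_id))
  excluded <- setdiff(members, have)
  if (length(have) < 2)
    return(list(divergent = NA, n_informative = length(have),
                excluded = excluded, contrasts_divergent = character()))
  sub <- calls[calls$gene_id %in% have, ]
  div <- vapply(split(sub$status, sub$contrast),
                function(s) length(unique(s)) > 1, TRUE)
  list(divergent = any(div), n_informative = length(have),
       excluded = excluded, contrasts_divergent = names(div)[div])
}

#' Fractions of divergent clusters and blocks per family
#'
#' @param flags data.frame with columns group_id, family, type
#'   (`"cluster"`/`"block"`), divergent (logical; NA rows dropped).
#' @return data.frame per (type, family) plus per-type totals: n, n_divergent,
#'   pct_divergent (integer-rounded).
#' @export
divergence_summary <- function(flags) {
  flags <- flags[!is.na(flags$divergent), , drop = FALSE]
  one <- function(df, type, fam)
    data.frame(type = type, family = fam, n = nrow(df),
               n_divergent = sum(df$divergent),
               pct_divergent = pct_of(sum(df$divergent), nrow(df)),
               stringsAsFactors = FALSE)
  out <- list()
  for (tp in unique(flags$type)) {
    sub <- flags[flags$type == tp, ]
    for (fm in unique(sub$family))
      out[[length(out) + 1]] <- one(sub[sub$family == fm, ], tp, fm)
    out[[length(out) + 1]] <- one(sub, tp, "total")
  }
  do.call(rbind, out)
}
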