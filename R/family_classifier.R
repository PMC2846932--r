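#' The twelve-family lectin domain catalog
#'
#' Maps carbohydrate-binding domain models to lectin families, one domain per
#' family. The phloem lectin and EEA families have no standard profile
#' accession, so they use custom profile names (`PHLOEM_CUSTOM`,
#' `EUL_CUSTOM`). Model lengths are representative profile lengths used to
#' compute coverage fractions on synthetic hit tables; a user-supplied
#' catalog (TSV with columns domain, family, model_len) overrides them.
#'
#' @param path Optional TSV catalog to read instead of the built-in one.
#' @return data.frame with columns domain, family, model_len.
#' @export
lectin_family_catalog <- function(path = NULL) {
  if (!is.null(path)) {
    cat <- read_tsv_table(path)
    stopifnot(all(c("domain", "family", "model_len") %in% names(cat)))
    if (anyDuplicated(cat$domain)) stop("catalog maps a domain to two families")
    return(cat)
  }
  data.frame(
    domain = c("B_lectin", "Lectin_legB", "Jacalin", "PHLOEM_CUSTOM",
               "Lectin_C", "Chitin_bind_1", "Ricin_B_lectin", "Gal_Lectin",
               "Gal-bind_lectin", "Calreticulin", "EUL_CUSTOM", "LysM"),
    family = c("B_lectin", "Lectin_legB", "Jacalin", "Phloem", "Lectin_C",
               "Chitin_bind_1", "Ricin_B_Lectin", "Gal_lectin",
               "Gal_binding_Lectin", "Calreticulin", "EEA", "LysM"),
    model_len = c(115L, 230L, 140L, 200L, 110L, 40L, 125L, 90L, 135L,
                  320L, 150L, 45L),
    stringsAsFactors = FALSE)
}

#' Names of the twelve lectin families
#' @return Character vector of family names.
#' @export
lectin_families <- function() lectin_family_catalog()$family

#' Read a per-domain hit table
#'
#' The table mirrors hmmscan per-domain output: one row per (gene, domain)
#' alignment with columns gene_id, domain, evalue, ali_from, ali_to,
#' hmm_from, hmm_to, model_len (1-based inclusive alignment coordinates).
#' Hits above the e-value cutoff are dropped and the fraction of the profile
#' model covered by the alignment is computed.
#'
#' @param path TSV path.
#' @param evalue_cutoff Maximum e-value retained (default 1.0).
#' @return data.frame of surviving hits with a `model_coverage` column.
#' @export
read_domain_table <- function(path, evalue_cutoff = 1.0) {
  h <- read_tsv_table(path)
  need <- c("gene_id", "domain", "evalue", "ali_from", "ali_to",
            "hmm_from", "hmm_to", "model_len")
  stopifnot(all(need %in% names(h)))
  if (any(h$evalue < 0)) stop("negative e-value in domain table")
  if (any(h$ali_from < 1 | h$hmm_from < 1 | h$ali_to < h$ali_from |
          h$hmm_to < h$hmm_from))
    stop("invalid alignment coordinates in domain table")
  h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
  h$model_coverage <- (h$hmm_to - h$hmm_from + 1) / h$model_len
  h
}

#' Assign genes to lectin families from domain hits
#'
#' Each gene with at least one hit to a catalog domain is assigned the family
#' of its best-e-value lectin hit. Multiple hits to the same domain
#' (hololectins, tandem domain repeats) collapse into one assignment. Hits to
#' domains not in the catalog (kinases, F-boxes, glycoside hydrolases...) are
#' recorded in `other_domains`, marking chimerolectins. A gene hitting two
#' distinct lectin families — not part of the family model — is assigned by
#' best e-value and flagged in the `conflict` column with a warning.
#'
#' @param hits data.frame from [read_domain_table()].
#' @param catalog Family catalog (default [lectin_family_catalog()]).
#' @param min_model_coverage Profile coverage below which a member is flagged
#'   `partial` (pseudogene-like, default 0.7; the bound is inclusive).
#' @return data.frame with one row per assigned gene: gene_id, family,
#'   best_evalue, model_coverage, completeness, other_domains (comma-joined),
#'   conflict.
#' @export
assign_families <- function(hits, catalog = lectin_family_catalog(),
                            min_model_coverage = 0.7) {
  fam_of <- stats::setNames(catalog$family, catalog$domain)
  hits$family <- unname(fam_of[hits$domain])
  lec <- hits[!is.na(hits$family), , drop = FALSE]
  oth <- hits[is.na(hits$family), , drop = FALSE]
  if (!nrow(lec))
    return(data.frame(gene_id = character(), family = character(),
                      best_evalue = numeric(), model_coverage = numeric(),
                      completeness = character(), other_domains = character(),
                      conflict = logical(), stringsAsFactors = FALSE))
  # deterministic best hit per gene: e-value, then coverage desc, then domain
  lec <- lec[order(lec$gene_id, lec$evalue, -lec$model_coverage, lec$domain), ]
  best <- lec[!duplicated(lec$gene_id), ]
  nfam <- tapply(lec$family, lec$gene_id, function(f) length(unique(f)))
  best$conflict <- unname(nfam[best$gene_id] > 1)
  if (any(best$conflict))
    warning("gene(s) hit two distinct lectin families, assigned by best ",
            "e-value: ", paste(best$gene_id[best$conflict], collapse = ", "))
  other <- vapply(best$gene_id, function(g) {
    d <- sort(unique(oth$domain[oth$gene_id == g]))
    paste(d, collapse = ",")
  }, "")
  data.frame(gene_id = best$gene_id, family = best$family,
             best_evalue = best$evalue, model_coverage = best$model_coverage,
             completeness = ifelse(best$model_coverage >= min_model_coverage,
                                   "complete", "partial"),
             other_domains = unname(other), conflict = best$conflict,
             stringsAsFactors = FALSE)
}

#' Re-flag completeness of family assignments
#'
#' A member whose best hit covers less than `min_model_coverage` of the
#' domain profile is flagged `partial`: such members usually lack the
#' sugar-binding region and are treated as pseudogene-like, excluded from
#' the evolutionary counts by default. The bound is inclusive (coverage
#' exactly at the threshold is `complete`).
#'
#' @param assignments data.frame from [assign_families()].
#' @param min_model_coverage Coverage threshold (default 0.7).
#' @return The assignments with `completeness` recomputed.
#' @export
flag_partial <- function(assignments, min_model_coverage = 0.7) {
  assignments$completeness <-
    ifelse(assignments$model_coverage >= min_model_coverage,
           "complete", "partial")
  assignments
}

#' Per-species, per-family membership counts
#'
#' @param assignments data.frame from [assign_families()], optionally with a
#'   `species` column (a single label is assumed otherwise).
#' @return data.frame with species, family, n_complete, n_partial, n_total;
#'   every catalog family appears (zero rows included).
#' @export
summarize_families <- function(assignments) {
  fams <- lectin_families()
  if (!nrow(assignments))
    return(data.frame(species = character(), family = character(),
                      n_complete = integer(), n_partial = integer(),
                      n_total = integer(), stringsAsFactors = FALSE))
  sp <- if ("species" %in% names(assignments)) assignments$species else "all"
  out <- expand.grid(species = unique(sp), family = fams,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(sp, assignments$family)
  cc <- table(key[assignments$completeness == "complete"])
  pp <- table(key[assignments$completeness == "partial"])
  k <- paste(out$species, out$family)
  out$n_complete <- as.integer(ifelse(is.na(cc[k]), 0L, cc[k]))
  out$n_partial <- as.integer(ifelse(is.na(pp[k]), 0L, pp[k]))
  out$n_total <- out$n_complete + out$n_partial
  out
}
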