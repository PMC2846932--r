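#' Analysis configuration for a dataset directory
#'
#' Collects every threshold of the analysis in one place, with the values
#' used throughout: tandem criteria (<= 10 genes apart, species bp cap),
#' 50-kb flanks, retrogene homology filter (70% coverage, e-value 1e-8),
#' domain e-value cutoff 1.0, partial-coverage bound 0.7, the 2-fold /
#' alpha 0.05 expression rule, and the 150-MY divergence calibration.
#'
#' @param dir Dataset directory (as written by [emit_dataset()]).
#' @param species_profiles data.frame(species, max_bp, prefix); `max_bp` is
#'   the tandem span cap (100000 compact genome, 350000 large genome).
#' @param max_gene_gap,flank_bp,retro_min_cov,retro_max_e,domain_cutoff,
#'   partial_coverage,min_fold,alpha,T_my Thresholds (see Details).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(dir,
                            species_profiles = data.frame(
                              species = c("soybean", "Arabidopsis", "rice"),
                              max_bp = c(350000, 100000, 350000),
                              prefix = c("soy", "ara", "ric"),
                              stringsAsFactors = FALSE),
                            max_gene_gap = 10, flank_bp = 50000,
                            retro_min_cov = 0.70, retro_max_e = 1e-8,
                            domain_cutoff = 1.0, partial_coverage = 0.7,
                            min_fold = 2.0, alpha = 0.05, T_my = 150) {
  stopifnot(max_gene_gap > 0, flank_bp > 0, retro_min_cov > 0,
            retro_max_e > 0, min_fold > 0, alpha > 0, T_my >= 140, T_my <= 150)
  structure(list(dir = dir, species_profiles = species_profiles,
                 max_gene_gap = max_gene_gap, flank_bp = flank_bp,
                 retro_min_cov = retro_min_cov, retro_max_e = retro_max_e,
                 domain_cutoff = domain_cutoff,
                 partial_coverage = partial_coverage,
                 min_fold = min_fold, alpha = alpha, T_my = T_my),
            class = "analysis_config")
}

#' Run the analysis pipeline on an emitted dataset directory
#'
#' Stages run in dependency order (classify, tandem, segmental, ancestry,
#' retro, te, express); each writes its TSV artifact into `out_dir` and the
#' results are also returned in memory. Requesting a stage whose upstream
#' artifact is absent raises a dependency error naming the stage.
#'
#' @param config An `analysis_config`.
#' @param stages Character vector of stages, or `"all"`.
#' @param out_dir Artifact directory (default `<dir>/results`).
#' @return Named list of stage results, invisibly classed
#'   `pipeline_result`.
#' @export
run_pipeline <- function(config, stages = "all",
                         out_dir = file.path(config$dir, "results")) {
  all_stages <- c("classify", "tandem", "segmental", "ancestry", "retro",
                  "te", "express")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  deps <- list(tandem = "classify", segmental = "tandem", retro = "tandem",
               express = "classify")
  for (s in stages) {
    for (d in deps[[s]])
      if (!d %in% stages)
        stop("dependency error: stage '", s, "' requires stage '", d, "'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir <- config$dir
  res <- list()
  prof <- config$species_profiles
  anns <- list()
  for (i in seq_len(nrow(prof))) {
    sp <- prof$species[i]
    p <- file.path(dir, paste0(sp, ".gff3"))
    if (file.exists(p))
      anns[[sp]] <- compute_gene_ranks(read_gff3(p, species = sp))
  }
  if ("classify" %in% stages) {
    hits <- read_domain_table(file.path(dir, "domains.tsv"),
                              evalue_cutoff = config$domain_cutoff)
    asn <- assign_families(hits, min_model_coverage = config$partial_coverage)
    asn$species <- species_of_gene(asn$gene_id, anns)
    res$classify <- asn
    write_tsv_table(asn, file.path(out_dir, "families.tsv"))
    write_tsv_table(summarize_families(asn),
                    file.path(out_dir, "family_summary.tsv"))
  }
  if ("tandem" %in% stages) {
    asn <- res$classify[res$classify$completeness == "complete", ]
    cl <- list()
    for (sp in names(anns)) {
      max_bp <- prof$max_bp[prof$species == sp]
      for (fam in unique(asn$family)) {
        ids <- asn$gene_id[asn$family == fam & asn$species == sp]
        cc <- find_tandem_clusters(ids, anns[[sp]], config$max_gene_gap,
                                   max_bp, family = fam)
        if (nrow(cc)) { cc$species <- sp; cl[[length(cl) + 1]] <- cc }
      }
    }
    clusters <- if (length(cl)) do.call(rbind, cl) else NULL
    if (!is.null(clusters))
      clusters$cluster_id <- sprintf("TC%03d", seq_len(nrow(clusters)))
    res$tandem <- clusters
    write_tsv_table(clusters %||% data.frame(), file.path(out_dir, "clusters.tsv"))
  }
  if ("segmental" %in% stages) {
    bp <- file.path(dir, "blocks.tsv")
    if (!file.exists(bp)) stop("dependency error: stage 'segmental' needs blocks.tsv")
    blocks <- read_blocks(bp)
    asn <- res$classify[res$classify$completeness == "complete", ]
    seg <- list(); classes <- list()
    for (sp in names(anns)) {
      ids <- asn$gene_id[asn$species == sp]
      clu <- res$tandem[res$tandem$species == sp, , drop = FALSE]
      if (is.null(res$tandem)) clu <- empty_clusters()
      reps <- collapse_tandem_arrays(ids, clu)
      sb <- assign_segmental_from_blocks(reps, blocks, asn, anns[[sp]], clu)
      cls <- classify_expansion(ids, clu, sb$segmental_genes)
      cls$species <- sp
      seg[[sp]] <- sb
      classes[[sp]] <- cls
    }
    res$segmental <- seg
    res$expansion <- do.call(rbind, classes)
    write_tsv_table(res$expansion, file.path(out_dir, "expansion_classes.tsv"))
    write_tsv_table(expansion_summary(res$expansion,
                                      res$classify[, c("gene_id", "family")]),
                    file.path(out_dir, "expansion_summary.tsv"))
  }
  if ("ancestry" %in% stages) {
    tf <- list.files(dir, pattern = "^tree_.*\\.nwk$", full.names = TRUE)
    st <- default_species_tree()
    rows <- list()
    for (f in tf) {
      fam <- sub("^tree_(.*)\\.nwk$", "\\1", basename(f))
      gt <- read_newick_species(f)
      subs <- list(dicots = c("soybean", "Arabidopsis"),
                   all = c("soybean", "Arabidopsis", "rice"))
      for (nm in names(subs)) {
        au <- count_ancestral_units(gt, st, subs[[nm]])
        for (sp in subs[[nm]]) {
          nx <- sum(gt$species == sp)
          rate <- if (au$n_anc >= 1)
            estimate_birth_rate(nx, au$n_anc, config$T_my)$rate else NA_real_
          rows[[length(rows) + 1]] <- data.frame(
            family = fam, subset = nm, species = sp, N_extant = nx,
            N_anc = au$n_anc, T_my = config$T_my, rate = round(rate, 1),
            stringsAsFactors = FALSE)
        }
      }
    }
    res$ancestry <- do.call(rbind, rows)
    write_tsv_table(res$ancestry, file.path(out_dir, "birth_rates.tsv"))
  }
  if ("retro" %in% stages) {
    plen <- read_tsv_table(file.path(dir, "protein_lengths.tsv"))
    hom <- read_homology_table(file.path(dir, "homology.tsv"),
                               stats::setNames(plen$length, plen$gene_id))
    asn <- res$classify
    calls <- list()
    for (sp in names(anns)) {
      fa <- file.path(dir, paste0(sp, ".fa"))
      genome <- if (file.exists(fa)) read_fasta(fa) else NULL
      cand <- find_retro_candidates(anns[[sp]], asn[asn$species == sp, ], hom,
                                    config$retro_min_cov, config$retro_max_e)
      out <- if (!is.null(genome) && nrow(cand))
        call_retrogenes(cand, anns[[sp]], genome) else
        cbind(cand, data.frame(has_tsd = logical(0), has_polyA = logical(0),
                               tier = character(0)))
      if (nrow(out)) { out$species <- sp; calls[[sp]] <- out }
    }
    res$retro <- if (length(calls)) do.call(rbind, calls) else NULL
    write_tsv_table(res$retro %||% data.frame(), file.path(out_dir, "retrogenes.tsv"))
  }
  if ("te" %in% stages) {
    te_rows <- list()
    asn <- res$classify
    for (sp in names(anns)) {
      bed <- file.path(dir, paste0(sp, "_te.bed"))
      if (!file.exists(bed)) next
      te <- read_bed(bed)
      ids <- if (!is.null(asn)) asn$gene_id[asn$species == sp] else
        anns[[sp]]$genes$gene_id
      tt <- te_overlap_table(anns[[sp]], te, ids, config$flank_bp)
      tt$species <- sp
      te_rows[[sp]] <- tt
    }
    res$te <- do.call(rbind, te_rows)
    write_tsv_table(res$te, file.path(out_dir, "te_overlap.tsv"))
  }
  if ("express" %in% stages) {
    ex_rows <- list()
    for (sp in names(anns)) {
      mp <- file.path(dir, paste0(sp, "_stress_expr.tsv"))
      if (!file.exists(mp)) next
      es <- read_expression(mp, file.path(dir, paste0(sp, "_stress_meta.tsv")))
      contr <- unique(es$meta$condition[es$meta$condition != "control"])
      cats <- stats::setNames(
        es$meta$category[match(contr, es$meta$condition)], contr)
      calls <- do.call(rbind, lapply(contr, function(cn)
        call_differential(es, "control", cn, min_fold = config$min_fold,
                          alpha = config$alpha)))
      calls$species <- sp
      ex_rows[[sp]] <- list(calls = calls, categories = cats,
                            summary = summarize_stress_sets(calls, cats))
    }
    res$express <- ex_rows
    if (length(ex_rows))
      write_tsv_table(do.call(rbind, lapply(ex_rows, `[[`, "calls")),
                      file.path(out_dir, "de_calls.tsv"))
  }
  res$annotations <- anns
  invisible(structure(res, class = "pipeline_result"))
}

empty_clusters <- function()
  data.frame(cluster_id = character(), family = character(),
             chromosome = character(), members = character(),
             n_members = integer(), span_start = numeric(),
             span_end = numeric(), species = character(),
             stringsAsFactors = FALSE)

species_of_gene <- function(gene_ids, anns) {
  sp <- rep(NA_character_, length(gene_ids))
  for (s in names(anns)) {
    sp[gene_ids %in% anns[[s]]$genes$gene_id] <- s
  }
  sp
}

#' Consolidated text report of a pipeline run
#'
#' Assembles family counts, ancestral-unit/birth-rate tables, expansion
#' mechanism breakdowns, stress-regulation set sizes (with the
#' inclusion-exclusion identity shown) and divergence fractions into a
#' plain-text report. Sections whose artifacts are absent print an explicit
#' "no data" line.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
generate_report <- function(result) {
  ln <- c("Lectin gene-family analysis report",
          strrep("=", 40))
  sec <- function(title, body) c("", title, strrep("-", nchar(title)), body)
  if (!is.null(result$classify)) {
    fs <- summarize_families(result$classify)
    fs <- fs[fs$n_total > 0, ]
    ln <- c(ln, sec("Family membership",
      sprintf("%-12s %-20s complete=%d partial=%d total=%d", fs$species,
              fs$family, fs$n_complete, fs$n_partial, fs$n_total)))
  } else ln <- c(ln, sec("Family membership", "no data"))
  if (!is.null(result$expansion)) {
    es <- expansion_summary(result$expansion,
                            result$classify[, c("gene_id", "family")])
    ln <- c(ln, sec("Expansion mechanisms",
      sprintf("%-20s n=%d tandem=%d segmental=%d both=%d other=%d (%d%% other)",
              es$family, es$n_total, es$n_tandem, es$n_segmental, es$n_both,
              es$n_other, es$pct_other)))
  } else ln <- c(ln, sec("Expansion mechanisms", "no data"))
  if (!is.null(result$ancestry)) {
    a <- result$ancestry
    ln <- c(ln, sec("Ancestral units and birth rates",
      sprintf("%-14s %-8s %-12s N_extant=%-4d N_anc=%-3d rate=%.1f/100MY",
              a$family, a$subset, a$species, a$N_extant, a$N_anc, a$rate)))
  } else ln <- c(ln, sec("Ancestral units and birth rates", "no data"))
  if (!is.null(result$retro)) {
    ln <- c(ln, sec("Retrogenes",
      if (nrow(result$retro))
        sprintf("%s <- parent %s [%s]", result$retro$retrogene,
                result$retro$parent, result$retro$tier) else "none detected"))
  } else ln <- c(ln, sec("Retrogenes", "no data"))
  if (!is.null(result$express) && length(result$express)) {
    for (sp in names(result$express)) {
      s <- result$express[[sp]]$summary
      ln <- c(ln, sec(paste("Stress regulation:", sp), c(
        sprintf("biotic %d (%d%%), abiotic %d (%d%%) of %d genes",
                s$n_biotic, s$pct_biotic, s$n_abiotic, s$pct_abiotic, s$total),
        sprintf("union %d = %d + %d - %d overlap (%d%%)",
                s$n_any, s$n_biotic, s$n_abiotic, s$n_overlap, s$pct_any))))
    }
  } else ln <- c(ln, sec("Stress regulation", "no data"))
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
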