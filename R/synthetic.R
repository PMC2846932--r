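#' Simulation configuration for synthetic lectin genomes
#'
#' The defaults describe a three-genome study system: two large genomes
#' (soybean/rice-like, 350-kb tandem span cap) and one compact genome
#' (Arabidopsis-like, 100-kb cap); a handful of lectin families expanding
#' from small ancestral complements under a pure-birth process whose rate is
#' expressed in genes per 100 MY per ancestral gene over a 150-MY divergence;
#' and a mechanism mix dominated by tandem and segmental duplication with a
#' small retroposition component. All randomness flows from the single seed.
#'
#' @param seed Integer seed driving every draw.
#' @param species Species names (first two dicot-like sisters, third the
#'   outgroup, matching [default_species_tree()] when defaults are kept).
#' @param prefixes Gene-id prefixes per species.
#' @param T_my Divergence time in MY.
#' @param families data.frame(family, n_anc) of simulated families.
#' @param rates Matrix of birth rates [family x species], genes per 100 MY
#'   per ancestral gene.
#' @param mechanism_mix Named probabilities (tandem, segmental, retro;
#'   remainder dispersed) applied to each duplication event.
#' @param tandem_gap_max Max filler genes between inserted tandem copies.
#' @param tsd_len,polyA_len Length ranges (min, max) of planted retrogene
#'   hallmarks.
#' @param hallmark_erosion Per-base mutation probability applied to planted
#'   hallmarks (0 = intact).
#' @param n_chr,filler_per_chr Genome shape per species.
#' @param p_partial Fraction of lectin genes given partial-coverage domain
#'   hits (pseudogene-like members).
#' @param p_chimero Fraction given an extra non-lectin (Kinase) domain hit.
#' @param n_te Planted transposable elements per species.
#' @param expression List of expression parameters: contrasts (named
#'   category vector), n_rep, cv, de_fraction, folds, baseline_meanlog,
#'   baseline_sdlog, n_tissues, tissue_specific_fraction.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       species = c("soybean", "Arabidopsis", "rice"),
                       prefixes = c(soybean = "soy", Arabidopsis = "ara", rice = "ric"),
                       T_my = 150,
                       families = data.frame(
                         family = c("B_lectin", "Jacalin", "Lectin_legB"),
                         n_anc = c(5L, 3L, 4L), stringsAsFactors = FALSE),
                       rates = rbind(B_lectin = c(soybean = 13.3, Arabidopsis = 4.4, rice = 10.9),
                                     Jacalin = c(4, 8, 6),
                                     Lectin_legB = c(2, 2, 2)),
                       mechanism_mix = c(tandem = 0.45, segmental = 0.25, retro = 0.05),
                       tandem_gap_max = 3,
                       tsd_len = c(4L, 15L), polyA_len = c(8L, 30L),
                       hallmark_erosion = 0,
                       n_chr = 5, filler_per_chr = 60,
                       p_partial = 0.1, p_chimero = 0.15, n_te = 24,
                       expression = list(
                         contrasts = c(Mg = "biotic", Xoo = "biotic",
                                       cold = "abiotic", drought = "abiotic",
                                       salt = "abiotic"),
                         n_rep = 3, cv = 0.2, de_fraction = 0.3,
                         folds = c(2, 4, 8), baseline_meanlog = 5,
                         baseline_sdlog = 0.7, n_tissues = 6,
                         tissue_specific_fraction = 0.1)) {
  stopifnot(sum(mechanism_mix) <= 1, all(mechanism_mix >= 0),
            all(rates >= 0), all(families$n_anc >= 1),
            nrow(rates) == nrow(families),
            ncol(rates) == length(species), T_my > 0)
  colnames(rates) <- species
  rownames(rates) <- families$family
  structure(list(seed = seed, species = species, prefixes = prefixes,
                 T_my = T_my, families = families, rates = rates,
                 mechanism_mix = mechanism_mix, tandem_gap_max = tandem_gap_max,
                 tsd_len = tsd_len, polyA_len = polyA_len,
                 hallmark_erosion = hallmark_erosion,
                 n_chr = n_chr, filler_per_chr = filler_per_chr,
                 p_partial = p_partial, p_chimero = p_chimero, n_te = n_te,
                 expression = expression),
            class = "sim_config")
}

# pure-birth (Yule) simulation for one ancestral gene over time T;
# rate r (genes/100 MY/ancestral gene) is converted to the per-lineage
# split rate lambda with e^(lambda T) = 1 + r T / 100, so the expected
# extant count is exactly the linear birth-rate parameterization
yule_unit <- function(r, T_my) {
  lambda <- log(1 + r * T_my / 100) / T_my
  events <- list()
  n <- 1L; t <- 0
  if (lambda > 0) repeat {
    t <- t + stats::rexp(1, n * lambda)
    if (t > T_my) break
    p <- sample.int(n, 1)
    n <- n + 1L
    events[[length(events) + 1L]] <- c(p, n)
  }
  list(n = n, events = events)
}

# topology of a recorded duplication history as a Newick fragment over
# leaf labels `ids` (one per extant lineage)
yule_newick <- function(events, ids) {
  mk <- function() new.env(parent = emptyenv())
  root <- mk(); root$leaf <- 1L
  tip <- list(root)
  for (e in events) {
    nd <- tip[[e[1]]]
    a <- mk(); a$leaf <- e[1]
    b <- mk(); b$leaf <- e[2]
    nd$leaf <- NULL; nd$l <- a; nd$r <- b
    tip[[e[1]]] <- a; tip[[e[2]]] <- b
  }
  ser <- function(nd) {
    if (!is.null(nd$leaf)) return(ids[nd$leaf])
    paste0("(", ser(nd$l), ",", ser(nd$r), ")")
  }
  ser(root)
}

#' Simulate lectin family evolution along the species tree
#'
#' Each ancestral gene of each family evolves independently in every lineage
#' under a pure-birth process calibrated so the expected extant count is
#' `n_anc * (1 + r * T / 100)` — the linear birth-rate model the estimator
#' inverts. Every duplication event is tagged with a mechanism drawn from
#' the mix; the true per-family gene trees join the three within-lineage
#' duplication histories of each ancestral unit at speciation nodes, and the
#' units by a caterpillar of root duplications.
#'
#' @param config A `sim_config`. Note: the caller controls the RNG state
#'   (see [simulate_dataset()], which seeds once for the whole dataset).
#' @return list with `genes` (data.frame gene_id, species, family, unit,
#'   mechanism, parent, birth_order) and `trees` (named list family ->
#'   Newick string).
#' @export
simulate_family_evolution <- function(config) {
  mech_p <- config$mechanism_mix
  mechs <- c(names(mech_p), "dispersed")
  probs <- c(unname(mech_p), 1 - sum(mech_p))
  all_genes <- list()
  trees <- list()
  for (fi in seq_len(nrow(config$families))) {
    fam <- config$families$family[fi]
    unit_frags <- character(0)
    for (u in seq_len(config$families$n_anc[fi])) {
      sp_frags <- character(length(config$species))
      for (si in seq_along(config$species)) {
        sp <- config$species[si]
        r <- config$rates[fam, sp]
        yu <- yule_unit(r, config$T_my)
        ids <- sprintf("%s_%s_u%d_g%02d", config$prefixes[[sp]], fam, u,
                       seq_len(yu$n))
        mech <- c("ancestral",
                  sample(mechs, length(yu$events), replace = TRUE, prob = probs))
        parent <- c(NA_character_,
                    vapply(yu$events, function(e) ids[e[1]], ""))
        all_genes[[length(all_genes) + 1L]] <- data.frame(
          gene_id = ids, species = sp, family = fam, unit = u,
          mechanism = mech, parent = parent,
          birth_order = seq_len(yu$n), stringsAsFactors = FALSE)
        sp_frags[si] <- yule_newick(yu$events, ids)
      }
      # ((dicot1, dicot2), outgroup): speciation nodes of this unit
      unit_frags[u] <- sprintf("((%s,%s),%s)", sp_frags[1], sp_frags[2],
                               sp_frags[3])
    }
    tree <- unit_frags[1]
    for (u in seq_along(unit_frags)[-1])
      tree <- sprintf("(%s,%s)", tree, unit_frags[u])
    trees[[fam]] <- paste0(tree, ";")
  }
  list(genes = do.call(rbind, all_genes), trees = trees)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Place simulated genes on a synthetic genome
#'
#' Builds one genome per species constructively. Genes are grouped into
#' placement units: tandem arrays (a root gene plus its tandem descendants,
#' members separated by at most `tandem_gap_max` filler genes), segmental
#' source windows (the parent gene with two dedicated filler genes on each
#' side), segmental destination copies (copies of the source fillers around
#' the new gene and, when the new gene later founded an array, that whole
#' array), and single genes. Units are shuffled onto chromosomes with
#' filler runs drawn between them; runs are lengthened wherever needed so
#' that genes of the same family from different units are always more than
#' 10 genes apart — the synthetic meaning of "dispersed". Destination units
#' always land on a different chromosome than their source. Coordinates are
#' then laid out with random intergenic gaps and exon/intron structures,
#' random nucleotide sequence is generated, and retrogene hallmarks
#' (TSD + poly(A)) are written into retrogene flanks.
#'
#' Two event relabelings keep ground truth unambiguous: a segmental event
#' whose parent sits in a tandem array becomes dispersed (planted blocks
#' then contain exactly one lectin per side), and a retro event whose
#' parent is itself intronless becomes dispersed (the intron-loss criterion
#' cannot apply). The returned `genes` table carries final mechanism labels
#' plus the derived truth flags `in_tandem` and `in_block`.
#'
#' @param evo Output of [simulate_family_evolution()].
#' @param config A `sim_config`.
#' @return list with per-species `annotation` (ranked `genome_annotation`),
#'   `genome` (named chromosome sequences), `blocks` (true block table,
#'   internal coordinates), `te` (planted TE table with true classes),
#'   `genes` (manifest), and `retro_hallmarks`.
#' @export
place_genes_on_genome <- function(evo, config) {
  genes <- evo$genes
  genes$in_tandem <- FALSE
  genes$in_block <- FALSE
  genes$array_root <- genes$gene_id
  all_blocks <- list(); all_te <- list(); all_hall <- list()
  anns <- list(); genomes <- list()
  min_family_gap <- 11L  # same-family genes from different units: > 10 apart
  for (sp in config$species) {
    pre <- config$prefixes[[sp]]
    gsp <- genes[genes$species == sp, ]
    gsp <- gsp[order(gsp$family, gsp$unit, gsp$birth_order), ]
    rownames(gsp) <- gsp$gene_id
    # --- mechanism relabelings (see Details) ---
    tandem_parents <- unique(gsp$parent[gsp$mechanism == "tandem"])
    arrayed <- gsp$mechanism == "tandem" | gsp$gene_id %in% tandem_parents
    names(arrayed) <- gsp$gene_id
    demote_seg <- gsp$mechanism == "segmental" & arrayed[gsp$parent] %in% TRUE
    gsp$mechanism[demote_seg] <- "dispersed"
    # retro needs a spliced template: process in birth order so the parent's
    # final exon count (retro = 1) is known
    for (i in which(gsp$mechanism == "retro")) {
      if (gsp[gsp$parent[i], "mechanism"] == "retro")
        gsp$mechanism[i] <- "dispersed"
    }
    # --- array grouping ---
    root <- gsp$gene_id
    repeat {
      idx <- match(root, gsp$gene_id)
      climb <- gsp$mechanism[idx] == "tandem"
      if (!any(climb)) break
      root[climb] <- gsp$parent[idx[climb]]
    }
    gsp$array_root <- root
    seg_children <- gsp$gene_id[gsp$mechanism == "segmental"]
    seg_parents <- unique(gsp$parent[gsp$mechanism == "segmental"])
    # --- build placement units ---
    fill_n <- 0L
    new_fill <- function(k) {
      if (k == 0) return(character(0))
      ids <- sprintf("%s_fill_%04d", pre, fill_n + seq_len(k))
      fill_n <<- fill_n + k
      n_ex[ids] <<- sample(1:3, k, replace = TRUE)
      ids
    }
    fam_of <- stats::setNames(gsp$family, gsp$gene_id)
    n_ex <- stats::setNames(ifelse(gsp$mechanism == "retro", 1L, 2L),
                            gsp$gene_id)
    # an array unit: members in adjacency order with 0..gap_max fillers
    # interleaved; the root sits where its birth position fell
    array_entries <- function(members) {
      ord <- members[1]
      for (m in members[-1]) {
        p <- gsp$parent[gsp$gene_id == m]
        at <- which(ord == p)
        if (!length(at)) at <- length(ord)
        if (stats::runif(1) < 0.5)
          ord <- append(ord, m, after = at) else
          ord <- append(ord, m, after = at - 1L)
      }
      out <- character(0)
      for (k in seq_along(ord)) {
        out <- c(out, ord[k])
        if (k < length(ord)) {
          nf <- sample(0:config$tandem_gap_max, 1)
          if (nf > 0) out <- c(out, new_fill(nf))
        }
      }
      out
    }
    units <- list()   # each: list(id, entries, families, kind)
    unit_of_gene <- character(0)
    roots <- unique(gsp$array_root)
    for (r in roots) {
      members <- gsp$gene_id[gsp$array_root == r]
      members <- members[order(gsp[members, "birth_order"])]
      if (r %in% seg_children) next  # embedded in its dest unit below
      ent <- if (length(members) > 1) array_entries(members) else members
      if (r %in% seg_parents) {
        w <- c(new_fill(2), ent, new_fill(2))  # dedicated source window
        ent <- w
      }
      uid <- paste0("u_", r)
      units[[uid]] <- list(id = uid, entries = ent, kind = "plain",
                           src_of = NULL)
      unit_of_gene[members] <- uid
    }
    # destination units for segmental children (in birth order so chained
    # segmental events see their parent's unit)
    for (gch in seg_children[order(gsp[seg_children, "birth_order"])]) {
      p <- gsp$parent[gsp$gene_id == gch]
      pu <- units[[unit_of_gene[[p]]]]
      pe <- pu$entries
      pidx <- which(pe == p)
      left <- pe[seq_len(pidx - 1)]
      left <- utils::tail(left[!(left %in% gsp$gene_id)], 2)
      right <- pe[-seq_len(pidx)]
      right <- utils::head(right[!(right %in% gsp$gene_id)], 2)
      src_ids <- c(left, p, right)
      members <- gsp$gene_id[gsp$array_root == gch]
      members <- members[order(gsp[members, "birth_order"])]
      core <- if (length(members) > 1) array_entries(members) else gch
      lcopy <- paste0(left, "_sd_", gch)
      rcopy <- paste0(right, "_sd_", gch)
      for (k in seq_along(c(lcopy, rcopy)))
        n_ex[c(lcopy, rcopy)[k]] <- n_ex[[c(left, right)[k]]]
      ent <- c(lcopy, core, rcopy)
      uid <- paste0("u_", gch)
      units[[uid]] <- list(id = uid, entries = ent, kind = "dest",
                           src_of = list(parent = p, child = gch,
                                         src_ids = src_ids,
                                         dst_ids = c(lcopy, gch, rcopy),
                                         parent_unit = unit_of_gene[[p]]))
      unit_of_gene[members] <- uid
    }
    # filler exon counts for all fillers created so far + dest copies
    fids <- setdiff(unlist(lapply(units, `[[`, "entries")), gsp$gene_id)
    miss <- setdiff(fids, names(n_ex))
    n_ex[miss] <- sample(1:3, length(miss), replace = TRUE)
    # --- assign units to chromosomes (dest != parent's chromosome) ---
    chrs <- sprintf("%s_chr%d", pre, seq_len(config$n_chr))
    uids <- names(units)
    chr_of <- stats::setNames(sample(chrs, length(uids), replace = TRUE), uids)
    for (uid in uids) {
      so <- units[[uid]]$src_of
      if (!is.null(so)) {
        pchr <- chr_of[[so$parent_unit]]
        chr_of[[uid]] <- sample(setdiff(chrs, pchr), 1)
      }
    }
    # --- assemble chromosomes with same-family spacing ---
    entries <- stats::setNames(vector("list", length(chrs)), chrs)
    for (chr in chrs) {
      mine <- sample(uids[chr_of == chr])
      ent <- new_fill(sample(3:6, 1))
      last_fam_idx <- numeric(0)
      for (uid in mine) {
        ue <- units[[uid]]$entries
        gpos <- which(ue %in% gsp$gene_id)
        run <- sample(2:6, 1)
        for (f in unique(fam_of[ue[gpos]])) {
          fg <- gpos[fam_of[ue[gpos]] == f]
          if (!is.na(last_fam_idx[f] %||% NA)) {
            need <- min_family_gap - (length(ent) + run + min(fg) - 1 -
                                        last_fam_idx[[f]])
            if (need > 0) run <- run + need
          }
        }
        ent <- c(ent, new_fill(run), ue)
        off <- length(ent) - length(ue)
        for (f in unique(fam_of[ue[gpos]]))
          last_fam_idx[f] <- off + max(gpos[fam_of[ue[gpos]] == f])
      }
      pad <- max(0L, config$filler_per_chr - sum(!(ent %in% gsp$gene_id)))
      ent <- c(ent, new_fill(sample(3:6, 1) + pad))
      entries[[chr]] <- ent
    }
    allf <- setdiff(unlist(entries), names(n_ex))
    n_ex[allf] <- sample(1:3, length(allf), replace = TRUE)
    # --- coordinate layout ---
    gene_rows <- list(); exon_rows <- list(); chrom_len <- numeric(0)
    for (chr in chrs) {
      pos <- 5000
      for (id in entries[[chr]]) {
        pos <- pos + round(stats::runif(1, 1500, 4000))
        ne <- n_ex[[id]]
        elens <- round(stats::runif(ne, 300, 800))
        ilens <- if (ne > 1) round(stats::runif(ne - 1, 150, 400)) else numeric(0)
        strand <- sample(c("+", "-"), 1)
        estart <- pos + cumsum(c(0, elens[-ne] + ilens))
        eend <- estart + elens
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = id, chromosome = chr, start = pos, end = max(eend),
          strand = strand, n_exons = ne, rank = NA_integer_,
          stringsAsFactors = FALSE)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          gene_id = id, chromosome = chr, start = estart, end = eend,
          strand = strand, stringsAsFactors = FALSE)
        pos <- max(eend)
      }
      chrom_len[chr] <- pos + 30000
    }
    gdf <- do.call(rbind, gene_rows)
    edf <- do.call(rbind, exon_rows)
    ann <- new_genome_annotation(sp, gdf, edf, chrom_len)
    ann <- compute_gene_ranks(ann)
    # --- sequence + retro hallmarks ---
    genome <- vapply(chrs, function(chr)
      paste(sample(c("A", "C", "G", "T"), chrom_len[chr], replace = TRUE),
            collapse = ""), "")
    retro_ids <- gsp$gene_id[gsp$mechanism == "retro"]
    for (rid in retro_ids) {
      gg <- ann$genes[ann$genes$gene_id == rid, ]
      hl <- plant_retro_hallmarks(genome[[gg$chromosome]], gg$start, gg$end,
                                  gg$strand, config)
      genome[[gg$chromosome]] <- hl$seq
      all_hall[[length(all_hall) + 1L]] <- data.frame(
        gene_id = rid, species = sp, tsd_len = hl$tsd_len,
        polyA_len = hl$polyA_len, stringsAsFactors = FALSE)
    }
    # --- block intervals from final entry positions ---
    pos_of <- stats::setNames(gdf$start, gdf$gene_id)
    end_of <- stats::setNames(gdf$end, gdf$gene_id)
    chr_of_gene <- stats::setNames(gdf$chromosome, gdf$gene_id)
    bi <- 0L
    for (uid in uids) {
      so <- units[[uid]]$src_of
      if (is.null(so)) next
      bi <- bi + 1L
      dst_span <- units[[uid]]$entries
      all_blocks[[length(all_blocks) + 1L]] <- data.frame(
        block_id = sprintf("%s_blk%02d", pre, bi),
        chrA = chr_of_gene[[so$parent]],
        startA = min(pos_of[so$src_ids]), endA = max(end_of[so$src_ids]),
        chrB = chr_of_gene[[so$child]],
        startB = min(pos_of[dst_span]), endB = max(end_of[dst_span]),
        species = sp, lectin_a = so$parent, lectin_b = so$child,
        anchors_a = paste(setdiff(so$src_ids, so$parent), collapse = ","),
        anchors_b = paste(setdiff(so$dst_ids, so$child), collapse = ","),
        provenance = "given", stringsAsFactors = FALSE)
      genes$in_block[genes$gene_id %in% c(so$parent, so$child)] <- TRUE
    }
    all_te[[length(all_te) + 1L]] <- plant_te_elements(ann, config)
    anns[[sp]] <- ann
    genomes[[sp]] <- genome
    genes$mechanism[match(gsp$gene_id, genes$gene_id)] <- gsp$mechanism
    genes$array_root[match(gsp$gene_id, genes$gene_id)] <- gsp$array_root
  }
  # truth flags
  tab <- table(genes$array_root)
  in_arr <- genes$array_root %in% names(tab)[tab > 1]
  genes$in_tandem <- in_arr
  # arrays containing a block-resident gene are block-resident throughout
  blk_roots <- unique(genes$array_root[genes$in_block & in_arr])
  genes$in_block <- genes$in_block | (in_arr & genes$array_root %in% blk_roots)
  list(annotation = anns, genome = genomes,
       blocks = if (length(all_blocks)) do.call(rbind, all_blocks) else NULL,
       te = do.call(rbind, all_te), genes = genes,
       retro_hallmarks = if (length(all_hall)) do.call(rbind, all_hall) else NULL)
}

# write `repl` into `s` at 1-based [at, at+nchar(repl)-1]
str_write <- function(s, at, repl) {
  if (at < 1 || at + nchar(repl) - 1 > nchar(s)) return(s)
  paste0(substr(s, 1, at - 1), repl, substr(s, at + nchar(repl), nchar(s)))
}

erode <- function(s, p) {
  if (p <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < p
  ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Plant retrogene hallmarks around an inserted gene
#'
#' Writes an identical direct repeat (target-site duplication) into both
#' flanks and a poly(A) run downstream of the gene, strand-aware: on the
#' minus strand the hallmarks are written reverse-complemented on the plus
#' strand of the assembly so they read correctly in gene orientation.
#' `hallmark_erosion` in the config mutates planted bases at that rate.
#'
#' @param chrseq Chromosome sequence (character scalar).
#' @param start,end Gene interval (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param config A `sim_config` (uses tsd_len, polyA_len, hallmark_erosion).
#' @return list(seq = modified chromosome, tsd_len, polyA_len, tsd_seq).
#' @export
plant_retro_hallmarks <- function(chrseq, start, end, strand, config) {
  tl <- sample(config$tsd_len[1]:config$tsd_len[2], 1)
  pl <- sample(config$polyA_len[1]:config$polyA_len[2], 1)
  tsd <- paste(sample(c("A", "C", "G", "T"), tl, replace = TRUE), collapse = "")
  polyA <- strrep("A", pl)
  er <- config$hallmark_erosion
  tsd_up <- erode(tsd, er); tsd_down <- erode(tsd, er)
  polyA_e <- erode(polyA, er)
  if (strand != "-") {
    chrseq <- str_write(chrseq, start - 3 - tl + 1, tsd_up)        # upstream copy
    chrseq <- str_write(chrseq, end + 6, polyA_e)                  # poly(A)
    chrseq <- str_write(chrseq, end + 6 + pl + 3, tsd_down)        # downstream copy
  } else {
    chrseq <- str_write(chrseq, end + 4, revcomp(tsd_up))
    chrseq <- str_write(chrseq, start - 5 - pl + 1, revcomp(polyA_e))
    chrseq <- str_write(chrseq, start - 5 - pl - 3 - tl + 1, revcomp(tsd_down))
  }
  list(seq = chrseq, tsd_len = tl, polyA_len = pl, tsd_seq = tsd)
}

# plant TEs with known overlap classes against target lectin genes
plant_te_elements <- function(ann, config) {
  g <- ann$genes
  lect <- g[grepl("_u\\d+_g", g$gene_id), ]
  n <- min(config$n_te, nrow(lect))
  targets <- lect[sample.int(nrow(lect), n), ]
  sfams <- c("MULE", "CACTA", "hAT", "Helitron")
  rows <- list()
  for (i in seq_len(n)) {
    t <- targets[i, ]
    cls <- sample(c("gene_within_te", "te_within_intron",
                    "te_within_exon_region", "te_in_flank"), 1)
    ex <- ann$exons[ann$exons$gene_id == t$gene_id, ]
    ex <- ex[order(ex$start), ]
    if (cls == "te_within_intron" && nrow(ex) < 2) cls <- "te_in_flank"
    iv <- switch(cls,
      gene_within_te = c(max(0, t$start - round(stats::runif(1, 200, 1000))),
                         t$end + round(stats::runif(1, 200, 1000))),
      te_within_intron = {
        is <- ex$end[1]; ie <- ex$start[2]
        c(is + 10, is + 10 + round(stats::runif(1, 50, max(51, ie - is - 30))))
      },
      te_within_exon_region = c(round((ex$start[1] + ex$end[1]) / 2),
                                ex$end[1] + 200),
      te_in_flank = {
        s <- t$end + round(stats::runif(1, 5000, 25000))
        c(s, s + 500)
      })
    rows[[i]] <- data.frame(
      chromosome = t$chromosome, start = iv[1], end = iv[2],
      name = sprintf("TE%s_%03d:%s", substr(t$chromosome, 1, 3), i,
                     sample(sfams, 1)),
      score = 0, strand = "+", target_gene = t$gene_id, true_class = cls,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Fabricate an all-vs-all homology table from true paralogy
#'
#' True duplication pairs (child vs parent, plus segmental filler anchors)
#' receive query coverage ~ U(0.75, 1) and e-value 10^-U(10, 60); decoy
#' pairs — random same-species gene pairs, including single-exon fillers
#' against multi-exon lectins — receive coverage < 0.7 or e-value > 1e-8,
#' so none survives the retrogene homology filter. Entries are symmetric.
#'
#' @param placed Output of [place_genes_on_genome()].
#' @param config A `sim_config`.
#' @param n_decoys Decoy pairs per species (default 150).
#' @return list(homology = 12-column data.frame, protein_lengths = named
#'   vector of fabricated protein lengths for every gene).
#' @export
synthesize_homology_table <- function(placed, config, n_decoys = 150) {
  genes <- placed$genes
  rows <- list()
  plens <- numeric(0)
  for (sp in config$species) {
    ann <- placed$annotation[[sp]]
    ex <- placed$annotation[[sp]]$exons
    exbp <- tapply(ex$end - ex$start, ex$gene_id, sum)
    pl <- pmax(round(exbp / 3), 50)
    plens <- c(plens, stats::setNames(as.numeric(pl), names(pl)))
  }
  add_pair <- function(q, s, cov, ev, pid) {
    qlen <- plens[[q]]
    qend <- max(1, round(cov * qlen))
    rows[[length(rows) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = pid, length = qend, mismatch = 0L,
      gapopen = 0L, qstart = 1L, qend = qend, sstart = 1L, send = qend,
      evalue = ev, bitscore = round(200 - log10(ev + 1e-300)),
      stringsAsFactors = FALSE)
  }
  true_pair <- function(q, s) {
    add_pair(q, s, stats::runif(1, 0.75, 1), 10^-stats::runif(1, 10, 60),
             round(stats::runif(1, 70, 99), 1))
  }
  dup <- genes[!is.na(genes$parent), ]
  for (i in seq_len(nrow(dup))) {
    true_pair(dup$gene_id[i], dup$parent[i])
    true_pair(dup$parent[i], dup$gene_id[i])
  }
  if (!is.null(placed$blocks)) for (i in seq_len(nrow(placed$blocks))) {
    aa <- strsplit(placed$blocks$anchors_a[i], ",")[[1]]
    bb <- strsplit(placed$blocks$anchors_b[i], ",")[[1]]
    for (k in seq_along(aa)) { true_pair(aa[k], bb[k]); true_pair(bb[k], aa[k]) }
  }
  for (sp in config$species) {
    ids <- placed$annotation[[sp]]$genes$gene_id
    nd <- min(n_decoys, floor(length(ids) / 2))
    q <- sample(ids, nd); s <- sample(ids, nd)
    keep <- q != s
    q <- q[keep]; s <- s[keep]
    for (k in seq_along(q)) {
      if (k %% 2 == 0)
        add_pair(q[k], s[k], stats::runif(1, 0.2, 0.65),
                 10^-stats::runif(1, 10, 40), round(stats::runif(1, 40, 70), 1))
      else
        add_pair(q[k], s[k], stats::runif(1, 0.75, 1),
                 10^-stats::runif(1, 0, 7.5), round(stats::runif(1, 30, 60), 1))
    }
  }
  list(homology = do.call(rbind, rows), protein_lengths = plens)
}

#' Fabricate a domain-hit table with known family truth
#'
#' Every lectin gene receives a hit to its family's domain profile
#' (e-value 10^-U(20, 80)); a `p_partial` fraction gets partial model
#' coverage (pseudogene-like members) and a `p_chimero` fraction an extra
#' Kinase domain hit. Hit order is shuffled.
#'
#' @param placed Output of [place_genes_on_genome()].
#' @param config A `sim_config`.
#' @return data.frame in [read_domain_table()] layout plus the truth columns
#'   used by the manifest (true_partial).
#' @export
synthesize_domain_table <- function(placed, config) {
  cat <- lectin_family_catalog()
  dom_of <- stats::setNames(cat$domain, cat$family)
  mlen <- stats::setNames(cat$model_len, cat$domain)
  genes <- placed$genes
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    dom <- dom_of[[g$family]]
    L <- mlen[[dom]]
    partial <- stats::runif(1) < config$p_partial
    hmm_to <- if (partial) round(L * stats::runif(1, 0.2, 0.6)) else L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, domain = dom,
      evalue = 10^-stats::runif(1, 20, 80),
      ali_from = 1L, ali_to = hmm_to, hmm_from = 1L, hmm_to = hmm_to,
      model_len = L, true_partial = partial, stringsAsFactors = FALSE)
    if (stats::runif(1) < config$p_chimero)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, domain = "Pkinase",
        evalue = 10^-stats::runif(1, 10, 50),
        ali_from = 1L, ali_to = 250L, hmm_from = 1L, hmm_to = 250L,
        model_len = 260L, true_partial = FALSE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df[sample.int(nrow(df)), ]
}

#' Simulate stress and tissue expression with known truth
#'
#' Baseline signals are log-normal; per (gene, contrast), a `de_fraction`
#' of genes is regulated with a sampled fold (up or down); replicate noise
#' is multiplicative log-normal with the configured CV. A separate
#' one-sample-per-tissue matrix plants tissue-specific genes expressed in
#' 1-2 tissues and near-zero elsewhere.
#'
#' @param gene_ids Genes to simulate (one species' lectins, typically).
#' @param config A `sim_config`.
#' @return list(stress = `expression_set`, tissue = `expression_set`,
#'   truth = data.frame(gene_id, contrast, true_status), tissue_truth =
#'   data.frame(gene_id, specific)).
#' @export
simulate_expression <- function(gene_ids, config) {
  ec <- config$expression
  contrasts <- names(ec$contrasts)
  n <- length(gene_ids)
  base <- stats::rlnorm(n, ec$baseline_meanlog, ec$baseline_sdlog)
  sdlog <- sqrt(log(1 + ec$cv^2))
  conds <- c("control", contrasts)
  cols <- list(); meta <- list()
  truth <- list()
  status <- matrix("ns", n, length(contrasts),
                   dimnames = list(gene_ids, contrasts))
  mult <- matrix(1, n, length(contrasts))
  for (j in seq_along(contrasts)) {
    de <- stats::runif(n) < ec$de_fraction
    up <- stats::runif(n) < 0.5
    fold <- ec$folds[sample.int(length(ec$folds), n, replace = TRUE)]
    mult[de & up, j] <- fold[de & up]
    mult[de & !up, j] <- 1 / fold[de & !up]
    status[de & up, j] <- "up"; status[de & !up, j] <- "down"
    truth[[j]] <- data.frame(gene_id = gene_ids, contrast = contrasts[j],
                             true_status = status[, j],
                             stringsAsFactors = FALSE)
  }
  noise <- function() stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  for (cond in conds) {
    m <- if (cond == "control") rep(1, n) else mult[, match(cond, contrasts)]
    # plant the effect on the pseudocount-adjusted fold scale, so the
    # planted fold is exactly what the 2-fold rule measures at zero noise
    cond_mean <- pmax(0, m * (base + 1) - 1)
    for (r in seq_len(ec$n_rep)) {
      sample_id <- sprintf("%s_r%d", cond, r)
      cols[[sample_id]] <- cond_mean * noise()
      meta[[sample_id]] <- data.frame(
        sample = sample_id, condition = cond, replicate = r, tissue = NA,
        category = if (cond == "control") "control" else
          unname(ec$contrasts[cond]), stringsAsFactors = FALSE)
    }
  }
  sig <- do.call(cbind, cols)
  rownames(sig) <- gene_ids
  stress <- structure(list(signal = sig, meta = do.call(rbind, meta),
                           platform = "microarray"), class = "expression_set")
  # tissue panel
  nt <- ec$n_tissues
  spec <- stats::runif(n) < ec$tissue_specific_fraction
  tsig <- matrix(stats::rlnorm(n * nt, ec$baseline_meanlog, ec$baseline_sdlog),
                 n, nt, dimnames = list(gene_ids, sprintf("T%d", seq_len(nt))))
  for (i in which(spec)) {
    k <- sample(1:2, 1)
    keep <- sample.int(nt, k)
    tsig[i, -keep] <- stats::runif(nt - k, 0, 0.5)
  }
  tmeta <- data.frame(sample = colnames(tsig), condition = "tissue_panel",
                      replicate = 1, tissue = colnames(tsig),
                      category = "tissue", stringsAsFactors = FALSE)
  tissue <- structure(list(signal = tsig, meta = tmeta,
                           platform = "microarray"), class = "expression_set")
  list(stress = stress, tissue = tissue,
       truth = do.call(rbind, truth),
       tissue_truth = data.frame(gene_id = gene_ids, specific = spec,
                                 stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG once from the config and runs evolution, placement,
#' homology/domain fabrication, and expression simulation for every
#' species, returning all in-memory objects plus the ground-truth manifest.
#'
#' @param config A `sim_config`.
#' @return list of class `lectin_dataset` with elements config, evo,
#'   placed, homology, protein_lengths, domains, expression (per species),
#'   manifest.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  evo <- simulate_family_evolution(config)
  placed <- place_genes_on_genome(evo, config)
  hom <- synthesize_homology_table(placed, config)
  dom <- synthesize_domain_table(placed, config)
  expr <- list()
  for (sp in config$species) {
    ids <- placed$genes$gene_id[placed$genes$species == sp]
    expr[[sp]] <- simulate_expression(ids, config)
  }
  manifest <- placed$genes
  lec_dom <- dom[dom$domain %in% lectin_family_catalog()$domain, ]
  manifest$true_partial <-
    lec_dom$true_partial[match(manifest$gene_id, lec_dom$gene_id)]
  structure(list(config = config, evo = evo, placed = placed,
                 homology = hom$homology, protein_lengths = hom$protein_lengths,
                 domains = dom, expression = expr, manifest = manifest),
            class = "lectin_dataset")
}

#' @export
print.lectin_dataset <- function(x, ...) {
  cat(sprintf("lectin_dataset: %d lectin genes across %d species (seed %d)\n",
              nrow(x$manifest), length(x$config$species), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits, per species: GFF3 annotation, genome FASTA, TE BED; plus global
#' Newick gene trees, 12-column homology table with protein-length sidecar,
#' domain-hit TSV, block list TSV (1-based inclusive at the file boundary),
#' expression matrices with metadata sidecars, the ground-truth manifest
#' TSV, and a JSON run-metadata file. Deterministic given the config seed.
#'
#' @param ds A `lectin_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- ds$config
  for (sp in cfg$species) {
    write_gff3(ds$placed$annotation[[sp]], file.path(dir, paste0(sp, ".gff3")))
    write_fasta(ds$placed$genome[[sp]], file.path(dir, paste0(sp, ".fa")))
    te <- ds$placed$te[ds$placed$te$chromosome %in%
                       names(ds$placed$annotation[[sp]]$chrom_lengths), ]
    write_bed(te, file.path(dir, paste0(sp, "_te.bed")))
    ex <- ds$expression[[sp]]
    for (panel in c("stress", "tissue")) {
      sig <- ex[[panel]]$signal
      write_tsv_table(data.frame(gene_id = rownames(sig), sig,
                                 check.names = FALSE),
                      file.path(dir, sprintf("%s_%s_expr.tsv", sp, panel)))
      write_tsv_table(ex[[panel]]$meta,
                      file.path(dir, sprintf("%s_%s_meta.tsv", sp, panel)))
    }
  }
  for (fam in names(ds$evo$trees))
    writeLines(ds$evo$trees[[fam]], file.path(dir, paste0("tree_", fam, ".nwk")))
  utils::write.table(ds$homology, file.path(dir, "homology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_table(data.frame(gene_id = names(ds$protein_lengths),
                             length = unname(ds$protein_lengths)),
                  file.path(dir, "protein_lengths.tsv"))
  write_tsv_table(ds$domains[, !(names(ds$domains) == "true_partial")],
                  file.path(dir, "domains.tsv"))
  if (!is.null(ds$placed$blocks)) {
    b <- ds$placed$blocks
    fb <- data.frame(block_id = b$block_id, chrA = b$chrA,
                     startA = b$startA + 1, endA = b$endA,
                     chrB = b$chrB, startB = b$startB + 1, endB = b$endB,
                     stringsAsFactors = FALSE)
    write_tsv_table(fb, file.path(dir, "blocks.tsv"))
  }
  write_tsv_table(ds$manifest, file.path(dir, "manifest.tsv"))
  meta <- list(seed = cfg$seed, species = cfg$species,
               families = cfg$families$family, T_my = cfg$T_my,
               mechanism_mix = as.list(cfg$mechanism_mix))
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
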