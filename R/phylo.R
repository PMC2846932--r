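#' Default species tree
#'
#' Rooted topology over the three analyzed genomes: the two dicots (soybean,
#' Arabidopsis) sister to each other, rice as the monocot outgroup.
#'
#' @return An `ape::phylo` tree.
#' @export
default_species_tree <- function()
  ape::read.tree(text = "((soybean,Arabidopsis),rice);")

#' Default gene-id prefix rules for species resolution
#' @return Named character vector mapping gene_id prefix to species.
#' @export
default_species_map <- function()
  c(Glyma = "soybean", LOC_Os = "rice", AT = "Arabidopsis",
    soy = "soybean", ara = "Arabidopsis", ric = "rice")

resolve_species <- function(labels, species_map) {
  vapply(labels, function(lab) {
    if (grepl("|", lab, fixed = TRUE))
      return(sub("^.*\\|", "", lab))
    hits <- names(species_map)[startsWith(lab, names(species_map))]
    if (!length(hits)) return(NA_character_)
    unname(species_map[hits[which.max(nchar(hits))]])
  }, "")
}

#' Read a species-labelled gene tree from Newick
#'
#' Leaf species are resolved from gene-id prefixes via `species_map` (e.g.
#' `Glyma` -> soybean) or from an explicit `id|species` suffix. Unrooted
#' trees are midpoint-rooted by default (supply `root_outgroup` to root on an
#' outgroup leaf instead). Multifurcations are resolved into an arbitrary but
#' deterministic binary tree (zero-length branches, input child order), which
#' can only lower, never raise, the ancestral-unit count.
#'
#' @param path Newick file path, or a Newick string via `text`.
#' @param species_map Named prefix->species vector.
#' @param text Newick string (alternative to `path`).
#' @param root_outgroup Optional leaf label to root on.
#' @return list of class `labeled_gene_tree`: `tree` (rooted binary phylo),
#'   `species` (named vector leaf -> species).
#' @export
read_newick_species <- function(path = NULL, species_map = default_species_map(),
                                text = NULL, root_outgroup = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  sp <- resolve_species(tr$tip.label, species_map)
  if (anyNA(sp))
    stop("cannot resolve species for leaves: ",
         paste(tr$tip.label[is.na(sp)], collapse = ", "))
  if (!is.null(root_outgroup)) {
    tr <- ape::root(tr, outgroup = root_outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tr)) {
    tr <- midpoint_root(tr)
  }
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  structure(list(tree = tr, species = stats::setNames(sp, tr$tip.label)),
            class = "labeled_gene_tree")
}

#' @export
print.labeled_gene_tree <- function(x, ...) {
  cat(sprintf("labeled_gene_tree: %d leaves, species {%s}\n",
              length(x$tree$tip.label),
              paste(sort(unique(x$species)), collapse = ", ")))
  invisible(x)
}

# midpoint rooting (longest leaf-to-leaf path); trees without branch
# lengths get unit lengths first so the midpoint is well defined
midpoint_root <- function(tr) {
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  phangorn::midpoint(tr)
}

#' LCA reconciliation map of a gene tree onto a species tree
#'
#' Each gene-tree node is mapped to the lowest species-tree node whose clade
#' contains all species below it; an internal node whose mapping equals one
#' of its children's mappings is a duplication, otherwise a speciation.
#'
#' @param gtree A `labeled_gene_tree`.
#' @param species_tree An `ape::phylo` species tree.
#' @return data.frame with one row per gene-tree node: node, st_node (species
#'   tree node index), st_clade (comma-joined species set), event
#'   (`leaf`/`speciation`/`duplication`).
#' @export
lca_species_map <- function(gtree, species_tree = default_species_tree()) {
  tr <- gtree$tree
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  st_ntip <- length(species_tree$tip.label)
  # species-tree clades as species-name sets, per species-tree node
  st_clades <- vector("list", st_ntip + species_tree$Nnode)
  for (i in seq_len(st_ntip)) st_clades[[i]] <- species_tree$tip.label[i]
  st_post <- ape::reorder.phylo(species_tree, "postorder")$edge
  for (k in seq_len(nrow(st_post))) {
    p <- st_post[k, 1]; c <- st_post[k, 2]
    st_clades[[p]] <- sort(union(st_clades[[p]], st_clades[[c]]))
  }
  map_to_st <- function(spset) {
    sizes <- vapply(st_clades, length, 1L)
    ok <- vapply(st_clades, function(cl) all(spset %in% cl), TRUE)
    which(ok)[which.min(sizes[ok])]
  }
  # gene-tree species sets by postorder union
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- unname(gtree$species[tr$tip.label[i]])
  post <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1]; c <- post[k, 2]
    sets[[p]] <- sort(union(sets[[p]], sets[[c]]))
  }
  st_node <- vapply(seq_len(nnode), function(i) map_to_st(sets[[i]]), 1L)
  event <- rep("leaf", nnode)
  for (v in (ntip + 1):nnode) {
    ch <- tr$edge[tr$edge[, 1] == v, 2]
    event[v] <- if (any(st_node[ch] == st_node[v])) "duplication" else "speciation"
  }
  data.frame(node = seq_len(nnode), st_node = st_node,
             st_clade = vapply(st_node, function(i)
               paste(st_clades[[i]], collapse = ","), ""),
             event = event, stringsAsFactors = FALSE)
}

#' Count ancestral gene lineages (MRCA units) for a species subset
#'
#' The gene tree is pruned to leaves of `species_subset`; with R the root of
#' the species tree restricted to the subset, the ancestral-unit count is the
#' number of speciation nodes mapped to R under LCA reconciliation — the
#' parsimony-minimal (loss-blind) number of gene lineages present in the
#' species' most recent common ancestor. Trees whose surviving leaves all
#' come from one species yield 0.
#'
#' @param gtree A `labeled_gene_tree`.
#' @param species_tree Species tree (default [default_species_tree()]).
#' @param species_subset Character vector of >= 2 species.
#' @return list of class `ancestral_units`: `n_anc`, `species_subset`,
#'   `n_leaves` (per-species leaf counts after pruning).
#' @export
count_ancestral_units <- function(gtree, species_tree = default_species_tree(),
                                  species_subset) {
  if (missing(species_subset) || length(species_subset) < 2)
    stop("species_subset must name at least two species")
  stopifnot(all(species_subset %in% species_tree$tip.label))
  keep <- names(gtree$species)[gtree$species %in% species_subset]
  res <- function(n) structure(
    list(n_anc = n, species_subset = sort(species_subset),
         n_leaves = table(factor(gtree$species[keep], levels = species_subset))),
    class = "ancestral_units")
  if (length(keep) < 2 || length(unique(gtree$species[keep])) < 2)
    return(res(0L))
  tr <- ape::keep.tip(gtree$tree, keep)
  sub <- structure(list(tree = tr,
                        species = gtree$species[tr$tip.label]),
                   class = "labeled_gene_tree")
  st <- if (length(species_subset) < length(species_tree$tip.label))
    ape::keep.tip(species_tree, species_subset) else species_tree
  m <- lca_species_map(sub, st)
  root_clade <- paste(sort(species_subset), collapse = ",")
  res(sum(m$event == "speciation" & m$st_clade == root_clade))
}

#' @export
print.ancestral_units <- function(x, ...) {
  cat(sprintf("ancestral units: %d lineage(s) in the MRCA of {%s}\n",
              x$n_anc, paste(x$species_subset, collapse = ", ")))
  invisible(x)
}

#' Estimate the gene birth rate of a family lineage
#'
#' The rate of surviving gene births per ancestral gene per 100 million
#' years: `rate = 100 * ((N_extant - N_anc) / N_anc) / T_my`. With N_anc
#' ancestral lineages at the species split T_my ago growing to N_extant
#' extant members, this is the net per-ancestral-gene gain normalized to a
#' 100-MY clock — a lower bound, since lost and pseudogenized copies are
#' invisible.
#'
#' @param N_extant Extant family size in the lineage.
#' @param N_anc Ancestral-unit count (>= 1).
#' @param T_my Divergence time in MY (default 150, the upper bound of the
#'   monocot-dicot split estimate of 140-150 MYA).
#' @param family,lineage Optional labels carried on the result.
#' @return Object of class `birth_rate` with fields N_extant, N_anc, T_my,
#'   rate (genes per 100 MY per ancestral gene, unrounded).
#' @export
estimate_birth_rate <- function(N_extant, N_anc, T_my = 150,
                                family = NA_character_, lineage = NA_character_) {
  if (N_anc < 1) stop("undefined birth rate: family absent from the ancestor (N_anc = 0)")
  if (T_my <= 0) stop("divergence time must be positive")
  structure(list(family = family, lineage = lineage,
                 N_extant = N_extant, N_anc = N_anc, T_my = T_my,
                 rate = 100 * ((N_extant - N_anc) / N_anc) / T_my),
            class = "birth_rate")
}

#' @export
print.birth_rate <- function(x, ...) {
  cat(sprintf(
    "birth rate: %.1f genes per 100 MY per ancestral gene (N_extant=%d, N_anc=%d, T=%g MY)\n",
    x$rate, x$N_extant, x$N_anc, x$T_my))
  invisible(x)
}

#' @export
coef.birth_rate <- function(object, ...) c(rate = object$rate)
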