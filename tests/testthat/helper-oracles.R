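# Independent brute-force oracles shared by unit and acceptance tests.

# brute-force oracle: connected components of the pairwise tandem predicate
closure_clusters <- function(ids, ann, max_gap, max_bp) {
  g <- ann$genes[match(ids, ann$genes$gene_id), ]
  n <- length(ids)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- g$chromosome[i] == g$chromosome[j] &&
      abs(g$rank[i] - g$rank[j]) <= max_gap &&
      abs(g$start[i] - g$start[j]) <= max_bp
    if (ok) comp[comp == comp[j]] <- comp[i]
  }
  split(ids, comp)
}


# -- independent oracle -------------------------------------------------
# Counts MRCA gene lineages by direct species-set logic: for each internal
# node compute the set of species below it by explicit recursion over the
# edge matrix; a node "covers the root" when its species set is contained in
# no single child clade of the restricted species tree; the count is the
# number of covering nodes none of whose children also cover.
oracle_units <- function(tree, species, subset) {
  keep <- names(species)[species %in% subset]
  if (length(keep) < 2 || length(unique(species[keep])) < 2) return(0L)
  tr <- ape::keep.tip(tree, keep)
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  kids <- lapply(seq_len(nn), function(v) tr$edge[tr$edge[, 1] == v, 2])
  spset <- function(v) {
    if (v <= ntip) return(unname(species[tr$tip.label[v]]))
    sort(unique(unlist(lapply(kids[[v]], spset))))
  }
  # restricted species tree children clades (hand-listed for <= 3 species)
  subset <- sort(subset)
  child_clades <- if (length(subset) == 3)
    list(sort(c("soybean", "Arabidopsis")), "rice") else
    as.list(subset)
  covers <- vapply(seq_len(nn), function(v) {
    s <- spset(v)
    !any(vapply(child_clades, function(cl) all(s %in% cl), TRUE))
  }, TRUE)
  sum(vapply((ntip + 1):nn, function(v)
    covers[v] && !any(covers[kids[[v]]]), TRUE))
}

gt <- function(newick) read_newick_species(text = newick)

enum_trees <- function(labels) {
  if (length(labels) == 1) return(labels)
  rest <- labels[-1]
  out <- character(0)
  for (m in 0:(2^length(rest) - 1)) {
    pick <- which(bitwAnd(m, 2^(seq_along(rest) - 1)) > 0)
    right <- if (length(pick)) rest[-pick] else rest
    if (!length(right)) next
    left <- c(labels[1], rest[pick])
    for (l in enum_trees(left)) for (r in enum_trees(right))
      out <- c(out, sprintf("(%s,%s)", l, r))
  }
  out
}


# brute-force scanners used as oracles -----------------------------------
brute_polyA <- function(seq, window, min_run, min_purity) {
  s <- toupper(substr(seq, 1, window))
  ch <- strsplit(s, "")[[1]]
  best <- NULL
  n <- length(ch)
  for (i in seq_len(n)) {
    na <- 0
    for (j in i:n) {
      if (ch[j] == "A") na <- na + 1
      len <- j - i + 1
      if (len >= min_run && na / len >= min_purity) {
        pu <- na / len
        if (is.null(best) || pu > best$purity + 1e-12 ||
            (abs(pu - best$purity) < 1e-12 &&
             (len > best$length ||
              (len == best$length && i < best$start))))
          best <- list(start = i, length = len, purity = pu)
      }
    }
  }
  best
}

brute_tsd <- function(up, down, min_len, max_len, search_bp) {
  nu <- nchar(up)
  ut <- substr(up, max(1, nu - search_bp + 1), nu)
  dh <- substr(down, 1, search_bp)
  best <- NULL
  for (len in min_len:min(max_len, nchar(ut), nchar(dh))) {
    for (i in seq_len(nchar(ut) - len + 1)) {
      for (j in seq_len(nchar(dh) - len + 1)) {
        if (substr(ut, i, i + len - 1) == substr(dh, j, j + len - 1)) {
          cand <- list(repeat_seq = substr(ut, i, i + len - 1), length = len,
                       up_offset = nchar(ut) - (i + len - 1),
                       down_offset = j - 1)
          csum <- cand$up_offset + cand$down_offset
          bsum <- if (is.null(best)) Inf else best$up_offset + best$down_offset
          if (is.null(best) || cand$length > best$length ||
              (cand$length == best$length &&
               (csum < bsum ||
                (csum == bsum && cand$up_offset < best$up_offset))))
            best <- cand
        }
      }
    }
  }
  best
}

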