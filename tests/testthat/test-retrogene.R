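test_that("retro candidates respect the coverage and e-value filter", {
  ann <- toy_annotation(starts = c(1000, 50000, 90000),
                        n_exons = c(1, 2, 1), chrom_len = 2e5)
  asn <- data.frame(gene_id = c("g01", "g02", "g03"), family = "Jacalin",
                    stringsAsFactors = FALSE)
  hom <- data.frame(qseqid = c("g01", "g03"), sseqid = c("g02", "g02"),
                    pident = 90, length = 100, mismatch = 0, gapopen = 0,
                    qstart = 1, qend = 100, sstart = 1, send = 100,
                    evalue = c(1e-12, 1e-12), bitscore = 200,
                    qcov = c(0.80, 0.69), stringsAsFactors = FALSE)
  got <- find_retro_candidates(ann, asn, hom)
  expect_equal(got$retrogene, "g01")      # g03 fails min_cov = 0.70
  expect_equal(got$parent, "g02")
  # coverage 0.69 rejected even with perfect e-value
  expect_false("g03" %in% got$retrogene)
  # shuffled input gives the identical candidate set
  set.seed(8)
  got2 <- find_retro_candidates(ann, asn, hom[sample(nrow(hom)), ])
  expect_identical(got, got2)
})

test_that("poly(A) scanning matches the brute-force substring oracle", {
  hit <- detect_polyA(paste0(strrep("C", 10), strrep("A", 10), strrep("G", 40)))
  expect_equal(hit$start, 11)
  expect_equal(hit$length, 10)
  expect_equal(hit$purity, 1.0)
  expect_null(detect_polyA(strrep("ACGT", 50)))
  h2 <- detect_polyA(paste0("AAAAGAAAAA", strrep("C", 50)))
  expect_equal(h2$length, 10)
  expect_equal(h2$purity, 0.9)

  set.seed(41)
  for (rep in 1:5) {
    s <- rand_dna(500)
    got <- detect_polyA(s, window = 500, min_run = 6, min_purity = 0.8)
    want <- brute_polyA(s, 500, 6, 0.8)
    expect_equal(got, want)
  }
})

test_that("TSD scanning matches the brute-force oracle with boundary ties", {
  up <- paste0(rand_dna(0), strrep("AC", 20), "GATCGA")
  down <- paste0("GATCGA", strrep("GT", 20))
  hit <- detect_tsd(up, down)
  expect_equal(hit$repeat_seq, "GATCGA")
  expect_equal(hit$length, 6)
  expect_equal(c(hit$up_offset, hit$down_offset), c(0, 0))

  # flanks built from disjoint dinucleotide alphabets share no 4-mer
  expect_null(detect_tsd(strrep("AC", 30), strrep("GT", 30)))

  # equal-length candidates: the pair nearest the boundaries wins
  up2 <- paste0("TTTTGGCC", strrep("AC", 10), "TTTTGG")
  down2 <- paste0("CCTTTTGG", strrep("GT", 10))
  tie <- detect_tsd(up2, down2, min_len = 6, max_len = 6)
  oracle <- brute_tsd(up2, down2, 6, 6, 100)
  expect_equal(tie[c("repeat_seq", "up_offset", "down_offset")],
               oracle[c("repeat_seq", "up_offset", "down_offset")])

  set.seed(42)
  for (rep in 1:4) {
    u <- rand_dna(500); d <- rand_dna(500)
    got <- detect_tsd(u, d, min_len = 5, max_len = 15, search_bp = 50)
    want <- brute_tsd(u, d, 5, 15, 50)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$length, want$length)
      expect_equal(got$up_offset + got$down_offset,
                   want$up_offset + want$down_offset)
    }
  }
})

test_that("hallmark planting yields detectable TSD and poly(A) on both strands", {
  cfg <- sim_config(seed = 2)
  cfg$tsd_len <- c(10L, 12L)   # long enough to stand out from background
  set.seed(2)
  for (strand in c("+", "-")) {
    chr <- rand_dna(4000)
    hl <- plant_retro_hallmarks(chr, 1500, 2500, strand, cfg)
    ann <- local({
      g <- data.frame(gene_id = "r1", chromosome = "c", start = 1500,
                      end = 2500, strand = strand, n_exons = 1,
                      rank = 0L, stringsAsFactors = FALSE)
      lectinfam:::new_genome_annotation(
        "toy", g, g[, c("gene_id", "chromosome", "start", "end", "strand")],
        c(c = 4000))
    })
    fl <- lectinfam:::gene_flank_seqs(ann, c(c = hl$seq), "r1", 500)
    pa <- detect_polyA(fl$downstream)
    ts <- detect_tsd(fl$upstream, fl$downstream, min_len = 8)
    expect_false(is.null(pa), info = strand)
    expect_gte(pa$length, hl$polyA_len)
    expect_false(is.null(ts), info = strand)
    expect_gte(ts$length, 8)
  }
})

test_that("evidence tiers degrade when a hallmark is absent", {
  # fully controlled chromosome: AC-tiling upstream, GT-tiling downstream,
  # so the only shared k-mers and A-runs are the planted hallmarks
  tsd <- "GATCGATCGA"
  polyA <- strrep("A", 15)
  set.seed(12)
  gene_seq <- rand_dna(600)
  build <- function(tsd_up, tsd_down, pa) {
    bg <- substr(strrep("AC", 600), 1, 1200 - nchar(tsd_up) - 3)
    paste0(bg, tsd_up, "CCC",                           # [1..1200] upstream
           gene_seq,                                    # (1200,1800] gene
           "GGGGG", pa, "CCC", tsd_down,
           strrep("GT", 120))
  }
  full <- build(tsd, tsd, polyA)
  no_pa <- build(tsd, tsd, strrep("GT", 8))             # poly(A) erased
  no_tsd <- build(strrep("C", 10), strrep("G", 10), polyA)
  mk_ann <- function(len) {
    g <- data.frame(gene_id = "r1", chromosome = "c", start = 1200,
                    end = 1800, strand = "+", n_exons = 1, rank = 0L,
                    stringsAsFactors = FALSE)
    lectinfam:::new_genome_annotation(
      "toy", g, g[, c("gene_id", "chromosome", "start", "end", "strand")],
      c(c = len))
  }
  cand <- data.frame(retrogene = "r1", parent = "p1", evalue = 1e-20,
                     qcov = 0.9, pident = 95, stringsAsFactors = FALSE)
  tier_of <- function(seq) {
    call_retrogenes(cand, mk_ann(nchar(seq)), c(c = seq), flank_bp = 300,
                    tsd_args = list(min_len = 8, search_bp = 60))$tier
  }
  expect_equal(tier_of(full), "+both")
  expect_equal(tier_of(no_pa), "+TSD")
  expect_equal(tier_of(no_tsd), "+polyA")
})

test_that("planted retrogenes are recovered genome-wide with full hallmarks", {
  ds <- shared_dataset()
  man <- ds$manifest
  hom <- ds$homology
  hom$qcov <- (hom$qend - hom$qstart + 1) / ds$protein_lengths[hom$qseqid]
  hits <- 0; planted_total <- 0
  for (sp in unique(man$species)) {
    msp <- man[man$species == sp, ]
    cand <- find_retro_candidates(ds$placed$annotation[[sp]],
                                  msp[, c("gene_id", "family")], hom)
    calls <- call_retrogenes(cand, ds$placed$annotation[[sp]],
                             ds$placed$genome[[sp]])
    planted <- msp$gene_id[msp$mechanism == "retro"]
    planted_total <- planted_total + length(planted)
    hits <- hits + sum(planted %in% calls$retrogene[calls$has_tsd &
                                                    calls$has_polyA])
    # no non-planted gene ever becomes a candidate
    expect_true(all(calls$retrogene %in% planted))
  }
  expect_gte(hits / planted_total, 0.95)
})

test_that("retro-seeded tandem arrays are reported with their co-members", {
  clusters <- data.frame(cluster_id = c("TC1", "TC2"), family = "B_lectin",
                         chromosome = "c1",
                         members = c("r1,x1,x2,x3", "y1,y2"),
                         n_members = c(4, 2), span_start = 0, span_end = 1,
                         stringsAsFactors = FALSE)
  calls <- data.frame(retrogene = c("r1", "r9"), parent = c("p1", "p9"),
                      stringsAsFactors = FALSE)
  got <- retro_tandem_expansion(calls, clusters)
  expect_equal(nrow(got), 1)
  expect_equal(got$n_comembers, 3)
  expect_setequal(strsplit(got$comembers, ",")[[1]], c("x1", "x2", "x3"))

  # manifest oracle: every planted retro gene that founded an array shows up
  ds <- shared_dataset()
  det <- detect_mechanisms(ds)
  man <- ds$manifest
  retro_roots <- man$gene_id[man$mechanism == "retro" & man$in_tandem]
  found <- character(0)
  for (sp in names(det)) {
    calls <- data.frame(
      retrogene = man$gene_id[man$species == sp & man$mechanism == "retro"],
      stringsAsFactors = FALSE)
    got <- retro_tandem_expansion(calls, det[[sp]]$clusters)
    found <- c(found, got$retrogene)
  }
  expect_setequal(found, retro_roots)
})
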