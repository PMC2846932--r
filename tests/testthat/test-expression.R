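mk_es <- function(ctrl, stress, contrast = "salt") {
  n <- length(ctrl)
  sig <- rbind(g1 = c(ctrl, stress))
  samples <- c(sprintf("control_r%d", seq_len(n)),
               sprintf("%s_r%d", contrast, seq_along(stress)))
  colnames(sig) <- samples
  meta <- data.frame(sample = samples,
                     condition = rep(c("control", contrast),
                                     c(n, length(stress))),
                     replicate = c(seq_len(n), seq_along(stress)),
                     tissue = NA, category = "abiotic",
                     stringsAsFactors = FALSE)
  structure(list(signal = sig, meta = meta, platform = "microarray"),
            class = "expression_set")
}

test_that("the 2-fold + t-test rule calls regulation as hand-computed", {
  ns <- call_differential(mk_es(c(10, 10, 10), c(10, 10, 10)), "control", "salt")
  expect_equal(ns$fold, 1.0)
  expect_equal(ns$status, "ns")

  # hand-computed equal-variance t: control (10,10,10), stress (25,20,27)
  up <- call_differential(mk_es(c(10, 10, 10), c(25, 20, 27)), "control", "salt")
  expect_equal(up$fold, (mean(c(25, 20, 27)) + 1) / 11, tolerance = 1e-12)
  x <- c(25, 20, 27); y <- c(10, 10, 10)
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * stats::pt(-abs(tstat), df = 4)
  expect_equal(up$p, p_hand, tolerance = 1e-12)
  expect_lt(up$p, 0.05)
  expect_equal(up$status, "up")

  # high-variance replicates: fold 3 but p large -> ns
  hv <- call_differential(mk_es(c(2, 30, 1), c(60, 2, 40)), "control", "salt")
  expect_gt(hv$fold, 2)
  expect_gt(hv$p, 0.05)
  expect_equal(hv$status, "ns")

  expect_error(call_differential(mk_es(c(1, 1), c(2, 2)), "control", "frost"),
               "contrast error")
})

test_that("swapping control and stress maps up to down and inverts fold", {
  set.seed(14)
  ctrl <- stats::rlnorm(3, 4, 0.1); str <- stats::rlnorm(3, 5, 0.1)
  a <- call_differential(mk_es(ctrl, str), "control", "salt")
  b <- call_differential(mk_es(ctrl, str), "salt", "control",
                         contrast = "swap")
  expect_equal(a$fold, 1 / b$fold, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(unname(c(a$status, b$status)), c("up", "down"))
})

test_that("degenerate thresholds call every unequal-mean gene", {
  es <- mk_es(c(10, 11, 9), c(12, 13, 12))
  got <- call_differential(es, "control", "salt", min_fold = 1, alpha = 1)
  expect_true(got$status != "ns")
})

test_that("stress-set summaries obey inclusion-exclusion", {
  # synthetic sets with a known overlap structure
  mk_calls <- function(ids, contrast)
    data.frame(gene_id = ids, contrast = contrast, fold = 3, p = 0.01,
               status = "up", tested = TRUE, stringsAsFactors = FALSE)
  g <- sprintf("r%03d", 1:200)
  calls <- rbind(mk_calls(g[1:58], "Mg"), mk_calls(g[30:91], "Xoo"),
                 mk_calls(g[80:140], "cold"))
  cats <- c(Mg = "biotic", Xoo = "biotic", cold = "abiotic")
  s <- summarize_stress_sets(calls, cats, total = 267)
  expect_equal(s$n_biotic, union_size(58, 62, 29))
  expect_equal(s$n_any, s$n_biotic + s$n_abiotic - s$n_overlap)
  # disjoint sets: union = sum
  calls2 <- rbind(mk_calls(g[1:10], "Mg"), mk_calls(g[11:30], "Xoo"))
  s2 <- summarize_stress_sets(calls2, cats, total = 100)
  expect_equal(s2$n_biotic, 30)
})

test_that("tissue specificity requires few expressed tissues and signal share", {
  sig <- rbind(spec = c(100, 0, 0, 0, 0, 0),
               flat = rep(10, 6),
               broad = c(50, 40, 6, 0, 0, 0))
  colnames(sig) <- sprintf("T%d", 1:6)
  meta <- data.frame(sample = colnames(sig), condition = "tissue",
                     replicate = 1, tissue = colnames(sig),
                     category = "tissue", stringsAsFactors = FALSE)
  es <- structure(list(signal = sig, meta = meta, platform = "microarray"),
                  class = "expression_set")
  got <- call_tissue_specific(es)
  sp <- stats::setNames(got$specific, got$gene_id)
  expect_true(sp[["spec"]])
  expect_false(sp[["flat"]])
  expect_false(sp[["broad"]])   # three tissues above theta
})

test_that("divergence of duplicate groups follows the any-contrast rule", {
  mk <- function(g, contrast, status)
    data.frame(gene_id = g, contrast = contrast, status = status,
               stringsAsFactors = FALSE)
  calls <- rbind(mk("a", "salt", "up"), mk("b", "salt", "ns"),
                 mk("a", "cold", "ns"), mk("b", "cold", "ns"))
  expect_true(cluster_divergence(c("a", "b"), calls)$divergent)
  allns <- rbind(mk("a", "salt", "ns"), mk("b", "salt", "ns"))
  expect_false(cluster_divergence(c("a", "b"), allns)$divergent)
  # members without data are excluded and reported
  d <- cluster_divergence(c("a", "b", "zz"), calls)
  expect_equal(d$excluded, "zz")

  # exhaustive enumeration: 3 members x 2 contrasts, all status matrices
  sts <- c("up", "down", "ns")
  grids <- expand.grid(rep(list(sts), 6), stringsAsFactors = FALSE)
  for (i in seq(1, nrow(grids), by = 7)) {
    v <- unlist(grids[i, ])
    calls <- rbind(mk(c("a", "b", "c"), "s1", v[1:3]),
                   mk(c("a", "b", "c"), "s2", v[4:6]))
    want <- length(unique(v[1:3])) > 1 || length(unique(v[4:6])) > 1
    expect_equal(cluster_divergence(c("a", "b", "c"), calls)$divergent, want)
  }
})

test_that("divergence fractions use integer-rounded percentages", {
  flags <- data.frame(group_id = sprintf("c%d", 1:42), family = "B_lectin",
                      type = "cluster",
                      divergent = c(rep(TRUE, 29), rep(FALSE, 13)),
                      stringsAsFactors = FALSE)
  s <- divergence_summary(flags)
  expect_equal(s$pct_divergent[s$family == "total"], 69)
  none <- divergence_summary(data.frame(group_id = "x", family = "f",
                                        type = "cluster", divergent = FALSE))
  expect_equal(none$pct_divergent[none$family == "total"], 0)
})

test_that("tag-count platforms are normalized to tags-per-million", {
  m <- data.frame(gene_id = c("g1", "g2"), s1 = c(10, 90), s2 = c(30, 70))
  meta <- data.frame(sample = c("s1", "s2"), condition = c("control", "salt"),
                     replicate = 1, tissue = NA, category = "abiotic")
  fm <- tempfile(); fx <- tempfile()
  write_tsv_table(m, fm); write_tsv_table(meta, fx)
  es <- read_expression(fm, fx, platform = "tag_count")
  expect_equal(colSums(es$signal), c(s1 = 1e6, s2 = 1e6))
  # single replicate: fold-only path flagged untested
  calls <- call_differential(es, "control", "salt")
  expect_false(any(calls$tested))
})
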