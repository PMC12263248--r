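# compact constructor for hit rows
hit <- function(q, s, bits, pident = 90, len = 285, evalue = 1e-50) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = 10L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue, bitscore = bits)
}

toy_coords <- function(genes, chrom = "chr1") {
  data.frame(gene = genes, chrom = chrom,
             start = (seq_along(genes) - 1L) * 1000L,
             end = (seq_along(genes) - 1L) * 1000L + 900L)
}

test_that("E-value filtering keeps the boundary and preserves order", {
  h <- rbind(hit("a1", "b1", 500, evalue = 1e-8),
             hit("a2", "b2", 500, evalue = 1e-7),
             hit("a3", "b3", 500, evalue = 1e-6))
  f <- filter_hits(h, 1e-7)
  expect_equal(f$qseqid, c("a1", "a2"))  # 1e-8 and the 1e-7 boundary pass
  expect_equal(nrow(filter_hits(h[0, ], 1e-7)), 0L)
  expect_error(filter_hits(h, -1), "positive")
})

test_that("reciprocal best hits use the lexicographic ranking", {
  # a1's hits tie on bit score; alignment rate 0.9 beats 0.8
  la <- data.frame(gene = "a1", length = 300L)
  lb <- data.frame(gene = c("b1", "b2"), length = c(300L, 300L))
  ab <- rbind(hit("a1", "b1", 500, len = 270),
              hit("a1", "b2", 500, len = 240))
  ba <- rbind(hit("b1", "a1", 500, len = 270),
              hit("b2", "a1", 450, len = 270))
  p <- reciprocal_best_hits(ab, ba, la, lb)
  expect_equal(p, data.frame(a = "a1", b = "b1"))
  # non-reciprocal: a1 -> b1 best, but b1 -> a2 best: no pair with b1
  ab2 <- hit("a1", "b1", 500)
  ba2 <- hit("b1", "a2", 500)
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2)), 0L)
  # full tie on all three keys drops the query
  ab3 <- rbind(hit("a1", "b1", 500), hit("a1", "b2", 500))
  expect_message(p3 <- reciprocal_best_hits(ab3, ba2), "tied")
  expect_equal(nrow(p3), 0L)
})

test_that("RBH is symmetric under swapping the two species", {
  set.seed(171)
  g <- simulate_synteny_genomes(30, paralog_rate = 0.3, seed = 172)
  h <- g$hits[["plac2"]]
  p1 <- reciprocal_best_hits(h$ab, h$ba)
  p2 <- reciprocal_best_hits(h$ba, h$ab)
  expect_setequal(paste(p1$a, p1$b), paste(p2$b, p2$a))
})

test_that("synteny filter keeps colinear pairs and drops relocated genes", {
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  pairs <- data.frame(a = a, b = b)
  ca <- toy_coords(a)
  cb <- toy_coords(b)
  kept <- synteny_filter(pairs, ca, cb)
  expect_equal(kept$a, paste0("a", 2:4))  # strict: ends not evaluable
  kept_p <- synteny_filter(pairs, ca, cb, end_policy = "permissive")
  expect_equal(kept_p$a, a)               # one-sided ends evaluate fine
  # relocate b3 to another scaffold: (a3,b3) fails, neighbours too (their
  # flank no longer matches), but distant pairs survive
  cb2 <- cb
  cb2$chrom[cb2$gene == "b3"] <- "chr9"
  kept2 <- synteny_filter(pairs, ca, cb2, end_policy = "permissive")
  expect_false("a3" %in% kept2$a)
  expect_true("a1" %in% kept2$a)
})

test_that("synteny filter tolerates local inversions (orientation-agnostic)", {
  a <- paste0("a", 1:5)
  pairs <- data.frame(a = a, b = paste0("b", 1:5))
  ca <- toy_coords(a)
  cb <- toy_coords(paste0("b", 5:1))  # whole block reversed
  kept <- synteny_filter(pairs, ca, cb)
  expect_equal(kept$a, paste0("a", 2:4))
})

test_that("absent coordinates drop the pair with a message", {
  pairs <- data.frame(a = c("a1", "a2"), b = c("b1", "b2"))
  ca <- toy_coords(c("a1", "a2"))
  cb <- toy_coords("b1")
  expect_message(kept <- synteny_filter(pairs, ca, cb, end_policy = "permissive"),
                 "absent")
  expect_false("a2" %in% kept$a)
})

test_that("merging intersects species, orders by coordinates, and drops
           duplicate claims", {
  ref <- toy_coords(c("r3", "r1", "r2"))  # deliberately shuffled rows
  ref$start <- c(2000L, 0L, 1000L)
  pw <- list(
    sp1 = data.frame(a = c("r1", "r2", "r3"), b = c("x1", "x2", "x3")),
    sp2 = data.frame(a = c("r1", "r3"), b = c("y1", "y3")))
  m <- merge_orthologues(pw, ref)
  expect_equal(m$ref_gene, c("r1", "r3"))  # r2 missing from sp2; coord order
  expect_equal(m$sp1, c("x1", "x3"))
  # duplicate partner claim removes both rows
  pw2 <- list(sp1 = data.frame(a = c("r1", "r2"), b = c("x1", "x1")),
              sp2 = data.frame(a = c("r1", "r2"), b = c("y1", "y2")))
  expect_message(m2 <- merge_orthologues(pw2, ref), "one-to-one")
  expect_equal(nrow(m2), 0L)
})

run_orthology <- function(g, evalue = 1e-7, end_policy = "permissive") {
  ref <- g$reference
  pw <- list()
  for (sp in setdiff(names(g$coords), ref)) {
    h <- g$hits[[sp]]
    rbh <- reciprocal_best_hits(filter_hits(h$ab, evalue),
                                filter_hits(h$ba, evalue),
                                g$lengths[[ref]], g$lengths[[sp]])
    pw[[sp]] <- synteny_filter(rbh, g$coords[[ref]], g$coords[[sp]],
                               end_policy = end_policy)
  }
  merge_orthologues(pw, g$coords[[ref]], ref)
}

test_that("unperturbed synthetic genomes are recovered exactly; decoys never
           survive (precision 1)", {
  g <- simulate_synteny_genomes(40, seed = 181)
  m <- run_orthology(g)
  expect_equal(nrow(m), 40L)
  for (sp in setdiff(names(g$coords), g$reference)) {
    truth <- g$truth[g$truth$species == sp, ]
    expect_identical(m[[sp]], truth$partner[match(m$ref_gene,
                                                  truth$ref_gene)])
  }
  g2 <- simulate_synteny_genomes(40, paralog_rate = 0.2, seed = 182)
  m2 <- run_orthology(g2)
  truth2 <- g2$truth[g2$truth$species == "plac2", ]
  called <- m2[["plac2"]]
  expect_true(all(called == truth2$partner[match(m2$ref_gene,
                                                 truth2$ref_gene)]))
})

test_that("a rearranged block breaks synteny at its boundaries", {
  g <- simulate_synteny_genomes(12, rearrangement_events = 1L, seed = 183)
  m <- run_orthology(g)
  # the moved block's boundary genes lose a matching flank somewhere
  expect_lt(nrow(m), 12L)
  expect_gt(nrow(m), 0L)
})

test_that("tightening the E-value cutoff never adds pairs (monotone)", {
  g <- simulate_synteny_genomes(30, paralog_rate = 0.4, seed = 184)
  h <- g$hits[["nonplac2"]]
  prev <- NULL
  for (cut in c(1e-4, 1e-7, 1e-20, 1e-45)) {
    p <- reciprocal_best_hits(filter_hits(h$ab, cut), filter_hits(h$ba, cut))
    if (!is.null(prev))
      expect_true(all(paste(p$a, p$b) %in% prev))
    prev <- paste(p$a, p$b)
  }
})

test_that("gene ids carry no hidden semantics (bijective relabelling)", {
  g <- simulate_synteny_genomes(20, seed = 185)
  h <- g$hits[["outgroup"]]
  p <- reciprocal_best_hits(h$ab, h$ba)
  relab <- function(x) paste0("Z", rev(sprintf("%03d", seq_len(1000))))[
    match(x, unique(c(h$ab$qseqid, h$ab$sseqid)))]
  h2 <- h
  h2$ab$qseqid <- relab(h$ab$qseqid); h2$ab$sseqid <- relab(h$ab$sseqid)
  h2$ba$qseqid <- relab(h$ba$qseqid); h2$ba$sseqid <- relab(h$ba$sseqid)
  p2 <- reciprocal_best_hits(h2$ab, h2$ba)
  expect_setequal(paste(relab(p$a), relab(p$b)), paste(p2$a, p2$b))
})
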