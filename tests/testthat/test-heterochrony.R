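toy_design <- pair_design("P", "N")

test_that("fold change is the pseudocounted ratio", {
  expect_equal(fold_change(8, 2, 0), 4)
  expect_equal(fold_change(8, 0, 0.01), 801)
  expect_equal(fold_change(3, 3, 0.5), 1)
  expect_true(is.na(fold_change(NA, 1)))
  # converges to the exact ratio as the pseudocount vanishes
  expect_equal(fold_change(6, 3, 1e-12), 2, tolerance = 1e-9)
  expect_error(fold_change(1, 1, -0.1), "non-negative")
})

test_that("neoteny filter applies all four criteria, boundaries inclusive", {
  g <- c("pass", "fail_egg", "boundary_fc", "fail_within", "fail_late")
  mt <- means_table(
    P.late = setNames(c(8, 8, 8, 8, 1.9), g),
    P.egg  = setNames(c(1.5, 0.9, 1.0, 1.5, 1.5), g),
    N.late = setNames(c(1, 1, 2, 1, 0.2), g),
    N.egg  = setNames(c(6, 6, 4, 1.8, 6), g))
  th <- thresholds(pseudocount = 1e-9)  # keep boundary ratios exact
  cs <- neoteny_candidates(mt, toy_design, th)
  expect_setequal(cs$gene, c("pass", "boundary_fc"))
  # exact boundaries: FC 4.0 and 2.0 pass, egg mean 1.0 passes
  ev <- attr(cs, "evaluation")
  b <- ev[ev$gene == "boundary_fc", ]
  expect_equal(b$fc_between, 4, tolerance = 1e-6)
  expect_equal(b$fc_within, 2, tolerance = 1e-6)
  expect_equal(b$plac_egg, 1.0)
  # single-criterion failures excluded for the right reason
  expect_false(attr(cs, "evaluation")[ev$gene == "fail_egg", "pass_egg_min"])
  expect_false(ev[ev$gene == "fail_within", "pass_fc_within"])
  expect_false(ev[ev$gene == "fail_late", "pass_late_min"])
})

test_that("genes with missing stage means are excluded, not guessed", {
  mt <- means_table(P.late = c(g1 = 8, g2 = NA), P.egg = c(g1 = 2, g2 = 2),
                    N.late = c(g1 = 1, g2 = 1), N.egg = c(g1 = 6, g2 = 6))
  expect_message(cs <- neoteny_candidates(mt, toy_design), "missing")
  expect_equal(attr(cs, "excluded"), "g2")
  expect_error(neoteny_candidates(mt, pair_design("X", "N")), "X")
})

test_that("hypermorphosis rules require the derived direction against the
           ancestor", {
  g <- c("up", "down", "up_blocked", "down_blocked", "flat")
  mt <- means_table(
    P.late = setNames(c(10, 0.5, 10, 0.5, 3), g),
    N.late = setNames(c(2, 4, 2, 4, 3), g))
  anc <- setNames(c("0", "1", "1", "0", "0"), g)
  cs <- hypermorphosis_candidates(mt, anc, toy_design,
                                  thresholds(pseudocount = 1e-9))
  expect_equal(cs$class[cs$gene == "up"], "derived_up")     # FC 5, anc off
  expect_equal(cs$class[cs$gene == "down"], "derived_down") # FC 8, anc on
  expect_false("up_blocked" %in% cs$gene)   # ancestor already expressed
  expect_false("down_blocked" %in% cs$gene) # ancestor already silent
  expect_false("flat" %in% cs$gene)
})

test_that("ambiguous ancestral states are skipped and the classes are
           mutually exclusive for any input", {
  set.seed(201)
  n <- 200
  g <- sprintf("g%03d", 1:n)
  mt <- means_table(P.late = setNames(rlnorm(n, 1, 2), g),
                    N.late = setNames(rlnorm(n, 1, 2), g))
  anc <- setNames(sample(c("0", "1", "ambiguous"), n, TRUE), g)
  expect_message(cs <- hypermorphosis_candidates(mt, anc, toy_design),
                 "ambiguous")
  expect_false(any(anc[cs$gene] == "ambiguous"))
  expect_equal(anyDuplicated(cs$gene), 0L)
  up <- cs$gene[cs$class == "derived_up"]
  down <- cs$gene[cs$class == "derived_down"]
  expect_length(intersect(up, down), 0L)
})

test_that("raising any threshold never enlarges a candidate set and
           classification is gene-order invariant", {
  set.seed(202)
  n <- 300
  g <- sprintf("g%03d", 1:n)
  mt <- means_table(P.late = setNames(rlnorm(n, 1, 1.5), g),
                    P.egg = setNames(rlnorm(n, 0.5, 1.5), g),
                    N.late = setNames(rlnorm(n, 0, 1.5), g),
                    N.egg = setNames(rlnorm(n, 1, 1.5), g))
  base <- neoteny_candidates(mt, toy_design, thresholds())
  for (tighter in list(thresholds(fc_between = 6), thresholds(fc_within = 3),
                       thresholds(fpkm_late_min = 4),
                       thresholds(fpkm_egg_min = 2))) {
    cs <- neoteny_candidates(mt, toy_design, tighter)
    expect_true(all(cs$gene %in% base$gene))
  }
  perm <- mt[sample(nrow(mt)), ]
  expect_setequal(neoteny_candidates(perm, toy_design)$gene, base$gene)
})

test_that("overlap summary counts exclusive and shared regions", {
  s1 <- data.frame(gene = c("a", "b", "c"), class = "neoteny")
  s2 <- data.frame(gene = c("b", "c", "d"), class = "neoteny")
  ov <- overlap_summary(list(p1 = s1, p2 = s2))
  expect_equal(ov$count[ov$region == "p1&p2"], 2L)
  expect_equal(ov$count[ov$region == "p1"], 1L)
  expect_equal(ov$count[ov$region == "p2"], 1L)
  # disjoint and identical sets
  ov2 <- overlap_summary(list(p1 = s1, p2 = data.frame(
    gene = c("x", "y", "z", "w", "v"), class = "neoteny")))
  expect_false("p1&p2" %in% ov2$region)
  ov3 <- overlap_summary(list(p1 = s1, p2 = s1))
  expect_equal(ov3$count[ov3$region == "p1&p2"], 3L)
  expect_error(overlap_summary(list(s1)), ">= 2")
})

test_that("matrotrophy index is the regression-endpoint mass ratio", {
  expect_equal(matrotrophy_index(0:10, rep(2, 11)), 1, ignore_attr = TRUE)
  expect_equal(matrotrophy_index(0:10, seq(1, 0.7, length.out = 11)), 0.7, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(matrotrophy_index(0:10, seq(1, 8, length.out = 11)), 8, ignore_attr = TRUE,
               tolerance = 1e-10)
  # noisy observations still estimate the slope-implied ratio
  set.seed(203)
  mi <- matrotrophy_index(rep(0:10, 2),
                          rep(seq(1, 8, length.out = 11), 2) *
                            exp(rnorm(22, 0, 0.05)))
  expect_gt(mi, 6); expect_lt(mi, 10)
  expect_error(matrotrophy_index(c(1, 1), c(2, 3)), "distinct")
  expect_error(matrotrophy_index(0:1, c(1, -1)), "positive")
  # steep decline can predict negative mass at the far endpoint
  expect_error(matrotrophy_index(0:10, pmax(seq(1, -0.8, length.out = 11),
                                            0.01)), "non-positive")
})
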