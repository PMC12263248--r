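test_that("FPKM follows the standard formula", {
  expect_equal(compute_fpkm(matrix(100), 1000, 1e6)[1, 1], 100)
  expect_equal(compute_fpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  cm <- matrix(rpois(20, 50), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  f1 <- compute_fpkm(cm, rep(500, 5), rep(2e6, 4))
  f2 <- compute_fpkm(cm, rep(500, 5), rep(4e6, 4))
  expect_equal(f1, 2 * f2)  # doubling totals halves every FPKM
  expect_error(compute_fpkm(cm, c(500, 0, 500, 500, 500), rep(1e6, 4)),
               "g2")
})

test_that("size factors are median ratios: scaling a sample by c gives
           factor c", {
  set.seed(191)
  m <- matrix(rlnorm(200 * 4, 2, 1), 200, 4,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  m2 <- m
  m2[, 2] <- m[, 2] * 2
  f0 <- size_factors(m)
  f2 <- size_factors(m2)
  # factors are defined relative to the geometric-mean reference: the
  # scaled sample's factor rises by c relative to the untouched samples
  expect_equal(unname((f2[2] / f2[1]) / (f0[2] / f0[1])), 2,
               tolerance = 1e-10)
  # identical samples: all factors exactly 1
  mi <- matrix(rep(rlnorm(50, 1, 1), 3), 50, 3,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:3)))
  expect_equal(unname(size_factors(mi)), rep(1, 3), tolerance = 1e-12)
})

test_that("one exactly doubled sample normalizes back onto the others", {
  set.seed(192)
  base <- rlnorm(100, 2, 1)
  m <- cbind(s1 = base, s2 = base, s3 = 2 * base)
  rownames(m) <- paste0("g", 1:100)
  n <- normalize_within_species(m)
  f <- attr(n, "size_factors")
  expect_equal(unname(f), c(2^(-1 / 3), 2^(-1 / 3), 2^(2 / 3)),
               tolerance = 1e-10)
  expect_equal(n[, "s3"], n[, "s1"], tolerance = 1e-10)
})

test_that("size factors agree with the median-of-ratios reference
           implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(193)
  m <- matrix(round(rlnorm(300 * 6, 4, 1)), 300, 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  f_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  f <- size_factors(m)
  # same construction up to the geometric-mean reference convention
  expect_equal(unname(f / exp(mean(log(f)))),
               unname(f_ref / exp(mean(log(f_ref)))), tolerance = 1e-8)
})

test_that("normalization is within-species: merging species changes
           nothing", {
  set.seed(194)
  m <- matrix(rlnorm(400, 2, 1), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  md <- data.frame(sample = paste0("s", 1:4),
                   species = c("A", "A", "B", "B"))
  joint <- normalize_within_species(m, md)
  solo <- cbind(normalize_within_species(m[, 1:2]),
                normalize_within_species(m[, 3:4]))
  expect_equal(unclass(joint), solo, ignore_attr = TRUE)
  expect_error(normalize_within_species(m[1:5, ]), "fewer than 10")
})

test_that("binarization boundary is inclusive and missing survives", {
  m <- matrix(c(2.0, 1.999, NA, 0), 2, 2)
  b <- binarize(m)
  expect_equal(b[1, 1], 1L)   # FPKM exactly 2.0 codes expressed
  expect_equal(b[2, 1], 0L)   # 1.999 codes not expressed
  expect_true(is.na(b[1, 2]))
  expect_equal(b[2, 2], 0L)
  # idempotent under re-application (0/1 with threshold <= 1 maps to itself)
  expect_equal(binarize(b, 1), b)
  # monotone: raising a value never flips 1 -> 0
  m2 <- m; m2[2, 1] <- 5
  expect_true(all(binarize(m2) >= b, na.rm = TRUE))
})

test_that("stage means average replicates and skip missing values", {
  m <- matrix(c(1, 3, NA, 2, 4, 6), 1, 6)
  rownames(m) <- "g1"
  colnames(m) <- paste0("s", 1:6)
  md <- data.frame(sample = paste0("s", 1:6), species = "A",
                   stage = rep(c("egg", "late"), each = 3))
  sm <- stage_means(m, md)
  expect_equal(sm$mean_fpkm[sm$stage == "egg"], 2)   # (1+3)/2, NA excluded
  expect_equal(sm$mean_fpkm[sm$stage == "late"], 4)
  # single replicate equals itself; all-missing group is NA
  m2 <- matrix(c(5, NA), 1, 2, dimnames = list("g1", c("a", "b")))
  md2 <- data.frame(sample = c("a", "b"), species = "A",
                    stage = c("egg", "late"))
  sm2 <- stage_means(m2, md2)
  expect_equal(sm2$mean_fpkm[sm2$stage == "egg"], 5)
  expect_true(is.na(sm2$mean_fpkm[sm2$stage == "late"]))
})

test_that("per-species consensus takes the replicate majority, ties to
           missing", {
  bin <- matrix(c(1L, 1L, 0L,  1L, 0L, NA,  0L, 0L, 0L), 3, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  md <- data.frame(sample = paste0("s", 1:3), species = "A", stage = "egg")
  st <- stage_consensus_binary(bin, md, "egg")
  expect_equal(unname(st["A", ]), c(1L, NA, 0L))
})

test_that("PCA reproduces the covariance eigendecomposition", {
  set.seed(195)
  m <- matrix(rlnorm(5 * 4, 1, 1), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  p <- expression_pca(m, n_components = 3, log_transform = FALSE)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1))
  expect_equal(unname(p$variance_fraction),
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  for (k in 1:3)
    expect_equal(abs(unname(p$scores[, k])), abs(unname(x %*% ev$vectors[, k]))[, 1],
                 tolerance = 1e-8)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
})

test_that("PCA drops genes with missing values and handles degenerate
           inputs", {
  m <- matrix(c(1, 2, NA, 4, 1, 2, 3, 4), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_message(p <- expression_pca(m, 1), "dropped")
  expect_equal(p$n_genes_used, 3L)
  # identical samples: zero variance, all scores zero
  mi <- matrix(rep(c(1, 5, 2), 2), 3, 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  pi_ <- expression_pca(mi, 1)
  expect_equal(unname(pi_$scores[, 1]), c(0, 0), tolerance = 1e-12)
  expect_error(expression_pca(mi[, 1, drop = FALSE]), ">= 2 samples")
  # gene-order permutation leaves scores unchanged up to sign
  set.seed(196)
  mm <- matrix(rlnorm(40), 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  p1 <- expression_pca(mm, 2)
  p2 <- expression_pca(mm[sample(10), ], 2)
  for (k in 1:2)
    expect_equal(abs(unname(p1$scores[, k])), abs(unname(p2$scores[, k])),
                 tolerance = 1e-8)
})

test_that("logistic PCA: monotone objective, block separation, rank
           guard, missing exclusion", {
  Y <- matrix(0L, 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  Y[1:10, 1:3] <- 1L
  Y[11:20, 4:6] <- 1L
  lp <- logistic_pca(Y, rank = 1)
  expect_true(all(diff(lp$objective) >= -1e-8))
  s <- lp$scores[, 1]
  expect_true(all(sign(s[1:3]) == sign(s[1])) &&
                all(sign(s[4:6]) == -sign(s[1])))
  # constant matrix: offset absorbs everything, scores near zero
  Yc <- matrix(1L, 15, 5)
  lpc <- logistic_pca(Yc, rank = 1)
  expect_lt(max(abs(lpc$scores)), 1e-6)
  expect_error(logistic_pca(Y, rank = 6), "rank")
  # missing entries are excluded from the objective, not imputed
  Ym <- Y; Ym[1, 1] <- NA
  lpm <- logistic_pca(Ym, rank = 1)
  expect_true(all(diff(lpm$objective) >= -1e-8))
})
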