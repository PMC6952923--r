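test_that("SMEL is an exact scalar multiple of the score", {
  v <- scoreVS("AA")
  expect_identical(scoreValues(smel(v, 0)), c(0, 0, 0))
  expect_equal(scoreValues(smel(v, 3)), 2 * scoreValues(smel(v, 1.5)),
               tolerance = 1e-14)
  expect_equal(scoreValues(smel(v, 1.5)),
               1.5 * sqrt(2) * c(0.417, 0.514, 0.228), tolerance = 1e-12)
  expect_error(smel(v, Inf), "finite")
})

test_that("pairwise regression reproduces exact proportional data", {
  t <- 1:10
  r <- suppressWarnings(pairwiseRegression(t, 2 * t, throughOrigin = TRUE))
  expect_equal(slopeEstimate(r), 2, tolerance = 1e-12)
  expect_equal(slopeSE(r), 0, tolerance = 1e-12)
  expect_equal(r@r2, 1, tolerance = 1e-12)

  r <- pairwiseRegression(t, -t + 0.001 * rnorm(10))
  expect_equal(slopeEstimate(r), -1, tolerance = 1e-2)
  expect_equal(signedFit(r), -r@r2, tolerance = 1e-12)
  expect_lt(signedFit(r), -0.99)
})

test_that("regression inputs are validated", {
  expect_error(pairwiseRegression(1:2, 1:2), "3 points")
  expect_error(pairwiseRegression(rep(1, 5), 1:5), "zero-variance")
  expect_error(pairwiseRegression(1:5, 1:5, axisPair = "x-z"))
})

test_that("OLS slope, SE, p and r2 match closed-form formulas", {
  set.seed(21)
  for (rep in 1:8) {
    a <- rnorm(20, sd = 3)
    b <- 1.7 * a + rnorm(20)
    for (origin in c(FALSE, TRUE)) {
      r <- pairwiseRegression(a, b, throughOrigin = origin)
      o <- bruteOLS(a, b, throughOrigin = origin)
      expect_equal(slopeEstimate(r), o$slope, tolerance = 1e-10)
      expect_equal(slopeSE(r), o$se, tolerance = 1e-10)
      expect_equal(pValue(r), o$p, tolerance = 1e-10)
      expect_equal(r@r2, o$r2, tolerance = 1e-10)
    }
  }
})

test_that("slope intervals compare by k-sigma overlap with nesting", {
  mk <- function(slope, se) methods::new(
    "AxisRegression", axisPair = "x-y", slope = slope, se = se,
    pValue = 0.01, r2 = 1, signedFit = sign(slope), n = 10L,
    throughOrigin = TRUE)
  r1 <- mk(1, 0.01); r2 <- mk(2, 0.01)
  for (k in 1:3) expect_false(compareSlopes(r1, r1, k))
  expect_true(compareSlopes(r1, r2, 2))

  set.seed(22)
  for (rep in 1:20) {
    a <- mk(rnorm(1), runif(1, 0, 0.5))
    b <- mk(rnorm(1), runif(1, 0, 0.5))
    sig <- vapply(1:3, function(k) compareSlopes(a, b, k), logical(1))
    # significance is monotone non-increasing in k
    expect_true(all(diff(sig) <= 0))
    if (sig[3]) expect_true(sig[2] && sig[1])
  }

  r3 <- methods::new("AxisRegression", axisPair = "y-z", slope = 1,
                     se = 0.1, pValue = 0.01, r2 = 1, signedFit = 1,
                     n = 10L, throughOrigin = TRUE)
  expect_error(compareSlopes(r1, r3, 2), "axis pairs differ")
})

test_that("regression tables report NA on degenerate Structure A axes", {
  set.seed(23)
  seqs <- setNames(vapply(1:6, function(i) randomSeq(8), character(1)),
                   paste0("m", 1:6))
  sc <- suppressWarnings(scoreTable(seqs, methods = c("EV_C", "EV_S"),
                                    structures = c("A", "B")))
  rt <- regressionTable(sc)
  for (m in c("EV_C", "EV_S")) {
    a <- rt[rt$method == m & rt$structure == "A", ]
    expect_true(all(is.na(a$slope[a$axis_pair %in% c("y-z", "z-x")])))
    expect_false(is.na(a$slope[a$axis_pair == "x-y"]))
    b <- rt[rt$method == m & rt$structure == "B", ]
    expect_true(all(!is.na(b$slope)))
  }
})

test_that("unique-only regression mode collapses duplicate score rows", {
  sc <- data.frame(id = paste0("m", 1:6), sequence = "x", method = "VS",
                   structure = NA_character_,
                   v1 = c(1, 2, 3, 1, 2, 4), v2 = c(2, 4, 6, 2, 4, 9),
                   v3 = c(1, 2, 3, 1, 2, 5))
  rtAll <- regressionTable(sc)
  rtUni <- regressionTable(sc, uniqueOnly = TRUE)
  expect_identical(rtAll$n[1], 6L)
  expect_identical(rtUni$n[1], 4L)
})

test_that("single-x-value SMEL recovers the score-space slope exactly", {
  set.seed(24)
  v1 <- runif(12, 1, 3); v2 <- 1.8 * v1 + rnorm(12, sd = 0.05)
  scoreSlope <- sum(v1 * v2) / sum(v1^2)
  x <- rep(2.5, 12)
  r <- pairwiseRegression(v1 * x, v2 * x, throughOrigin = TRUE)
  expect_equal(slopeEstimate(r), scoreSlope, tolerance = 1e-12)
})

test_that("disease discrimination marks o / x / NA correctly", {
  set.seed(25)
  sm <- syntheticSmelTable(c(D1 = 2, D2 = 3), n = 20, noise = 1e-4)
  dd <- suppressWarnings(diseaseDiscrimination(sm, k = 2))
  xy <- dd$decisions[dd$decisions$axis_pair == "x-y", ]
  expect_identical(xy$mark, "o")

  # one disease duplicated under two labels: never significant
  dup <- syntheticSmelTable(c(D1 = 2, D2 = 2), n = 20, noise = 0)
  for (k in 1:3) {
    dd <- suppressWarnings(diseaseDiscrimination(dup, k = k))
    expect_true(all(dd$decisions$mark[!is.na(dd$decisions$mark)] == "x"))
  }

  # Structure A field scores: y-z and z-x are undefined
  sm$s3 <- 0
  sm$method <- "EV_S"; sm$structure <- "A"
  dd <- suppressWarnings(diseaseDiscrimination(sm, k = 2))
  marks <- dd$decisions
  expect_true(all(is.na(marks$mark[marks$axis_pair %in% c("y-z", "z-x")])))
  expect_false(anyNA(marks$mark[marks$axis_pair == "x-y"]))
})

test_that("the descending-gap outlier rule matches its fixtures", {
  r <- filterFCOutliers(c(1000, 10, 9, 8))
  expect_identical(r$removed, 1000)
  expect_identical(r$kept, c(10, 9, 8))

  r <- filterFCOutliers(c(4, 3, 2))
  expect_identical(r$removed, numeric(0))
  expect_identical(r$kept, c(4, 3, 2))

  r <- filterFCOutliers(c(100, 40, 3, 2))
  expect_identical(r$removed, c(100, 40))
  expect_identical(r$kept, c(3, 2))

  # unsorted input: rule applies to the sorted values
  r <- filterFCOutliers(c(10, 1000, 8, 9))
  expect_identical(r$removed, 1000)

  expect_error(filterFCOutliers(c(2, -1)), "positive")
  expect_error(filterFCOutliers(c(2, 0)), "positive")
})

test_that("the outlier filter is idempotent", {
  set.seed(26)
  for (rep in 1:10) {
    fc <- 2^rnorm(30)
    fc[1:2] <- fc[1:2] * 500
    kept <- filterFCOutliers(fc)$kept
    again <- filterFCOutliers(kept)
    expect_identical(again$removed, numeric(0))
    expect_identical(again$kept, kept)
  }
})

test_that("scanAll mode also removes values above a buried gap", {
  # leading scan stops immediately (1000 < 2*600); scanAll sees the 600/10
  # gap below and removes everything above it
  r1 <- filterFCOutliers(c(1000, 600, 10))
  expect_identical(r1$removed, numeric(0))
  r2 <- filterFCOutliers(c(1000, 600, 10), scanAll = TRUE)
  expect_identical(sort(r2$removed), c(600, 1000))
  expect_identical(r2$kept, 10)
})

test_that("expression completion derives the missing column", {
  df <- data.frame(mirna_id = c("a", "b"), disease = "AD",
                   fc = c(2, NA), log2fc = c(NA, 1))
  out <- completeExpression(df)
  expect_equal(out$log2fc, c(1, 1), tolerance = 1e-12)
  expect_equal(out$fc, c(2, 2), tolerance = 1e-12)

  bad <- data.frame(mirna_id = "a", disease = "AD", fc = NA, log2fc = NA)
  expect_error(completeExpression(bad), "neither fc nor log2fc: 1")
})

test_that("smelTable multiplies each disease record by its expression", {
  seqs <- c(m1 = "GCAU", m2 = "AUGC", m3 = "GGCC")
  sc <- scoreTable(seqs, methods = "VS")
  expr <- data.frame(mirna_id = c("m1", "m2", "m3", "m1"),
                     disease = c("AD", "AD", "AD", "TB"),
                     fc = c(2, 4, 1, 8), log2fc = NA)
  sm <- smelTable(sc, expr, expressionType = "log2fc")
  expect_identical(nrow(sm), 4L)
  v <- sc[sc$id == "m1", c("v1", "v2", "v3")]
  row <- sm[sm$id == "m1" & sm$disease == "TB", ]
  expect_equal(unname(unlist(row[, c("s1", "s2", "s3")])),
               3 * unname(unlist(v)), tolerance = 1e-12)
  expect_warning(
    smelTable(sc, data.frame(mirna_id = c("m1", "zz"), disease = "AD",
                             fc = 2, log2fc = NA)),
    "dropped")
})
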