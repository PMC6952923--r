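test_that("VS is the per-site Euclidean norm", {
  expect_equal(scoreValues(scoreVS("A")), c(0.417, 0.514, 0.228),
               tolerance = 1e-12)
  expect_equal(scoreValues(scoreVS("AA")),
               sqrt(2) * c(0.417, 0.514, 0.228), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:10) {
    s <- randomSeq(sample(3:25, 1))
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_identical(scoreValues(scoreVS(perm)), scoreValues(scoreVS(s)))
    expect_true(all(scoreValues(scoreVS(s)) >= 0))
  }
})

test_that("Sum is the per-site charge total, linear and order-free", {
  expect_equal(scoreValues(scoreSum("AU")), c(-0.089, -0.106, -0.243),
               tolerance = 1e-12)
  expect_equal(scoreValues(scoreSum(strrep("A", 7))),
               7 * c(0.417, -0.514, 0.228), tolerance = 1e-12)
  set.seed(6)
  s <- randomSeq(15)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(scoreValues(scoreSum(perm)), scoreValues(scoreSum(s)),
               tolerance = 1e-14)
})

test_that("field at a point matches the brute-force triple loop", {
  set.seed(9)
  for (rep in 1:12) {
    st <- buildStructure(randomSeq(sample(2:8, 1)),
                         sample(c("A", "B", "C"), 1))
    p <- runif(3, -20, 20)
    f <- fieldAtPoint(st, p)
    o <- bruteField(st, p)
    expect_equal(f, o, tolerance = 1e-10)
  }
})

test_that("field decays in the far zone and cancels by symmetry", {
  st <- buildStructure("GCAU", "B")
  near <- sqrt(sum(fieldAtPoint(st, c(1, 2, 3))^2))
  far <- sqrt(sum(fieldAtPoint(st, c(1e6, 0, 0))^2))
  expect_lt(far, 1e-9 * near)

  # 4-fold rotational symmetry of a homopolymer cancels the centre field
  stA <- buildStructure("AAAA", "A")
  expect_equal(scoreValues(scoreEVC(stA)), c(0, 0, 0), tolerance = 1e-12)
})

test_that("EV_C is the field at the torus centre", {
  set.seed(10)
  st <- buildStructure(randomSeq(6), "C")
  expect_equal(scoreValues(scoreEVC(st)), fieldAtPoint(st, c(0, 0, 0)),
               tolerance = 1e-14)
})

test_that("EV_S matches the brute-force quadruple loop", {
  st <- buildStructure("GCAU", "B")
  expect_equal(scoreValues(suppressWarnings(scoreEVS(st))),
               bruteEVS(st), tolerance = 1e-10)
  set.seed(12)
  for (label in c("A", "C")) {
    st <- buildStructure(randomSeq(5), label)
    expect_equal(scoreValues(suppressWarnings(scoreEVS(st))),
                 bruteEVS(st), tolerance = 1e-10)
  }
})

test_that("Structure A field scores have an exactly null third component", {
  set.seed(13)
  for (rep in 1:5) {
    st <- buildStructure(randomSeq(sample(4:12, 1)), "A")
    evc <- scoreValues(scoreEVC(st))
    evs <- scoreValues(suppressWarnings(scoreEVS(st)))
    expect_lt(abs(evc[3]), 1e-12 * max(sqrt(sum(evc^2)), 1e-300))
    expect_lt(abs(evs[3]), 1e-12 * max(sqrt(sum(evs^2)), 1e-300))
  }
})

test_that("lattice-summed field of a symmetric homopolymer cancels", {
  st <- buildStructure("AAAA", "A")
  L <- buildLattice(st)
  total <- scoreValues(suppressWarnings(scoreEVS(st, L)))
  # scale: sum of per-point field magnitudes
  pts <- latticePoints(L)
  scale <- sum(apply(pts, 1, function(p)
    sqrt(sum(suppressWarnings(fieldAtPoint(st, p))^2))))
  expect_lt(sqrt(sum(total^2)), 1e-10 * scale)
})

test_that("field scores carry positional information that VS/Sum discard", {
  s <- "GGCAUU"
  perm <- "UGCGUA"  # same multiset of bases, different order
  expect_identical(scoreValues(scoreVS(perm)), scoreValues(scoreVS(s)))
  stS <- buildStructure(s, "B"); stP <- buildStructure(perm, "B")
  evs <- scoreValues(suppressWarnings(scoreEVS(stS)))
  evp <- scoreValues(suppressWarnings(scoreEVS(stP)))
  expect_gt(max(abs(evs - evp)), 1e-6)
})

test_that("duplicate counting keeps duplicate + unique = total", {
  r <- duplicateAnalysis(rbind(c(1, 2, 3), c(1, 2, 3), c(4, 5, 6)))
  expect_identical(r, list(nDuplicate = 2L, nUnique = 1L, pctUnique = 33L))

  distinct <- cbind(1:10, 2:11, 3:12)
  r <- duplicateAnalysis(distinct)
  expect_identical(r, list(nDuplicate = 0L, nUnique = 10L,
                           pctUnique = 100L))

  set.seed(14)
  for (rep in 1:10) {
    m <- matrix(sample(1:3, 60, replace = TRUE), ncol = 3)
    r <- duplicateAnalysis(m)
    expect_identical(r$nDuplicate + r$nUnique, nrow(m))
  }
  expect_error(duplicateAnalysis(matrix(numeric(), ncol = 3)), "nonempty")

  # rounding glues floating-point noise onto true duplicates
  r <- duplicateAnalysis(rbind(c(1, 2, 3), c(1 + 1e-14, 2, 3)))
  expect_identical(r$nDuplicate, 2L)
})

test_that("identical sequences score identically under every method", {
  sc <- suppressWarnings(
    scoreTable(c(a = "GCAU", b = "GCAU"), structures = "B"))
  for (m in unique(sc$method)) {
    sub <- sc[sc$method == m, c("v1", "v2", "v3")]
    expect_identical(unname(unlist(sub[1, ])), unname(unlist(sub[2, ])))
  }
})

test_that("duplicate summary mirrors the per-method row arithmetic", {
  set.seed(15)
  seqs <- c(vapply(1:8, function(i) randomSeq(6), character(1)),
            GCAU1 = "GCAU", GCAU2 = "GCAU")
  names(seqs)[1:8] <- paste0("s", 1:8)
  sc <- suppressWarnings(scoreTable(seqs, structures = c("A", "B")))
  ds <- duplicateSummary(sc)
  expect_true(all(ds$nDuplicate + ds$nUnique == length(seqs)))
  seqRow <- ds[ds$method == "sequence", ]
  expect_gte(seqRow$nDuplicate, 2L)
})
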