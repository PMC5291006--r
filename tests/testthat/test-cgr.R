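test_that("weighted expansion matches the published worked examples", {
  ex <- expandAmbiguous("tamcg")
  expect_identical(ex$string, c("taacg", "taccg"))
  expect_equal(ex$weight, c(0.5, 0.5))

  ex <- expandAmbiguous("tavcg")
  expect_identical(ex$string, c("taacg", "taccg", "tagcg"))
  expect_equal(ex$weight, rep(1 / 3, 3))

  ex <- expandAmbiguous("acgta")
  expect_identical(ex$string, "acgta")
  expect_equal(ex$weight, 1.0)
})

test_that("expansion is the full Cartesian product with uniform weights", {
  ex <- expandAmbiguous("nn")
  expect_identical(nrow(ex), 16L)
  expect_equal(ex$weight, rep(1 / 16, 16))
  expect_identical(sort(ex$string), bruteExpand("nn"))

  withr::local_seed(4)
  for (i in 1:20) {
    s <- randomIupacSymbols(5, ambProb = 0.4)
    ex <- expandAmbiguous(s)
    expect_identical(sort(ex$string), bruteExpand(s))
    expect_equal(sum(ex$weight), 1.0)
    expect_true(all(ex$weight == ex$weight[1]))
  }
  expect_error(expandAmbiguous("nnnnnnn"), "cap")
})

test_that("substring addressing follows the quadrant recursion", {
  expect_equal(unname(substringPosition("aaaaa")), c(0, 0))
  expect_equal(unname(substringPosition("ttttt")), c(31, 31))
  expect_equal(unname(substringPosition("ca")), c(0, 2))
  # level-1 corners of the base layout
  expect_equal(unname(substringPosition("a")), c(0, 0))
  expect_equal(unname(substringPosition("c")), c(0, 1))
  expect_equal(unname(substringPosition("g")), c(1, 0))
  expect_equal(unname(substringPosition("t")), c(1, 1))
  expect_error(substringPosition("an"), "expand")
})

test_that("addresses are unique and fill the matrix", {
  kmers <- do.call(paste0, expand.grid(rep(list(c("a", "c", "g", "t")), 3)))
  pos <- t(vapply(kmers, substringPosition, c(row = 0, col = 0)))
  expect_identical(nrow(unique(pos)), 64L)
  expect_true(all(pos >= 0 & pos < 8))
})

test_that("CGR matrix equals brute-force k-mer counting on pure sequences", {
  m <- cgrValues(cgrMatrix("aaaa", 2))
  expect_equal(m[1, 1], 3)
  expect_equal(sum(m), 3)

  m <- cgrValues(cgrMatrix("acgtacgt", 1))
  expect_equal(as.vector(m), rep(2, 4))

  withr::local_seed(9)
  for (i in 1:10) {
    s <- paste(sample(c("a", "c", "g", "t"), 300, replace = TRUE),
               collapse = "")
    L <- sample(2:5, 1)
    m <- cgrValues(cgrMatrix(s, L))
    counts <- bruteKmerCounts(s, L)
    for (kmer in names(counts)) {
      p <- substringPosition(kmer)
      expect_identical(m[p[1] + 1, p[2] + 1], as.numeric(counts[[kmer]]))
    }
    expect_equal(sum(m), 300 - L + 1)
  }
})

test_that("ambiguous windows spread fractional mass at the expanded cells", {
  m <- cgrValues(cgrMatrix("tamcg", 5))
  p1 <- substringPosition("taacg")
  p2 <- substringPosition("taccg")
  expect_equal(m[p1[1] + 1, p1[2] + 1], 0.5)
  expect_equal(m[p2[1] + 1, p2[2] + 1], 0.5)
  expect_equal(sum(m), 1.0)
})

test_that("mass is conserved on random IUPAC sequences", {
  withr::local_seed(21)
  for (i in 1:40) {
    n <- sample(50:500, 1)
    L <- sample(c(3, 5, 7), 1)
    s <- ntSequence(randomIupacSymbols(n, ambProb = 0.02))
    expect_equal(sum(cgrValues(cgrMatrix(s, L))), n - L + 1,
                 tolerance = 1e-9)
  }
})

test_that("circular windowing adds exactly the wraparound mass", {
  s <- ntSequence("acgtacgt")
  expect_equal(sum(cgrValues(cgrMatrix(s, 3, circular = TRUE))), 8)
  expect_equal(sum(cgrValues(cgrMatrix(s, 3, circular = FALSE))), 6)
})

test_that("marginalizing the last symbol recovers the (L-1)-mer counts", {
  withr::local_seed(33)
  s <- paste(sample(c("a", "c", "g", "t"), 400, replace = TRUE), collapse = "")
  for (L in c(3, 5)) {
    mL <- cgrValues(cgrMatrix(s, L))
    mPrev <- cgrValues(cgrMatrix(s, L - 1))
    counts <- bruteKmerCounts(s, L - 1)
    for (w in names(counts)) {
      childSum <- sum(vapply(c("a", "c", "g", "t"), function(x) {
        p <- substringPosition(paste0(w, x))
        mL[p[1] + 1, p[2] + 1]
      }, numeric(1)))
      pw <- substringPosition(w)
      expect_lte(abs(childSum - mPrev[pw[1] + 1, pw[2] + 1]), 1)
    }
  }
})

test_that("a CpG-free sequence empties every cell whose k-mer contains cg", {
  ref <- randomSequence(20000, forbiddenDinucleotides = "cg", seed = 5)
  m <- cgrValues(cgrMatrix(ref, 4))
  kmers <- do.call(paste0, expand.grid(rep(list(c("a", "c", "g", "t")), 4)))
  for (kmer in kmers[grepl("cg", kmers)]) {
    p <- substringPosition(kmer)
    expect_identical(m[p[1] + 1, p[2] + 1], 0)
  }
  # and the pattern is non-trivial: plenty of occupied cells remain
  expect_gt(sum(m > 0), 100)
})

test_that("frame length is validated", {
  expect_error(cgrMatrix("acgt", 0), "\\[1, 12\\]")
  expect_error(cgrMatrix("acgt", 13), "\\[1, 12\\]")
  expect_error(cgrMatrix("acg", 4), "exceeds")
})

test_that("mutation report splits ambiguous composition fractionally", {
  ref <- ntSequence("acgt")
  rep0 <- mutationReport(ref, NULL)
  expect_equal(unname(baseCounts(rep0)), c(1, 1, 1, 1))
  expect_identical(nrow(mutationCalls(rep0, "homoplasmic")), 0L)

  ct <- callTable(2, "c", "m")
  rep1 <- mutationReport(ref, ct)
  expect_equal(baseCounts(rep1),
               c(a = 1.5, c = 0.5, g = 1, t = 1))
  het <- mutationCalls(rep1, "heteroplasmic")
  expect_identical(het$position, 2L)
  expect_identical(het$call, "m")

  ct2 <- callTable(c(1, 4), c("a", "t"), c("g", "c"))
  rep2 <- mutationReport(ref, ct2)
  expect_identical(nrow(mutationCalls(rep2, "homoplasmic")), 2L)
  expect_identical(nrow(mutationCalls(rep2, "heteroplasmic")), 0L)
  expect_equal(sum(baseCounts(rep2)), 4)
})
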