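test_that("min-max normalization maps onto [0, 1] with declared edge cases", {
  expect_equal(normalizeMatrix(matrix(c(0, 4, 2, 8), 2, 2)),
               matrix(c(0, 0.5, 0.25, 1), 2, 2))
  expect_equal(normalizeMatrix(matrix(3, 4, 4)), matrix(1, 4, 4))
  expect_error(normalizeMatrix(matrix(0, 4, 4)), "all-zero")

  withr::local_seed(2)
  m <- matrix(runif(64, 1, 9), 8, 8)
  nm <- normalizeMatrix(m)
  expect_equal(min(nm), 0)
  expect_equal(max(nm), 1)
})

test_that("sigmoid preprocessing is the logistic threshold", {
  img <- matrix(0.7, 3, 3)
  expect_equal(sigmoidPreprocess(img, k = 7, sigma = 0.7),
               matrix(0.5, 3, 3))

  expect_equal(sigmoidPreprocess(matrix(0, 1, 2), k = 7, sigma = 0.7)[1],
               1 / (1 + exp(4.9)))

  # large k approaches binarization at level sigma
  img <- matrix(c(0.2, 0.69, 0.71, 0.95), 2, 2)
  hard <- sigmoidPreprocess(img, k = 1e4, sigma = 0.7)
  expect_equal(as.vector(hard), c(0, 0, 1, 1), tolerance = 1e-6)

  expect_error(sigmoidPreprocess(img, k = -1), "positive")
  expect_error(sigmoidPreprocess(img, k = 7, sigma = 0), "positive")
})

test_that("box-mass distributions enumerate every stride-1 placement", {
  d <- boxMassDistribution(matrix(1, 4, 4), 2)
  expect_identical(length(boxMasses(d)), 9L)
  expect_true(all(boxMasses(d) == 4))

  px <- matrix(0, 8, 8)
  px[4, 4] <- 1
  d <- boxMassDistribution(px, 2)
  expect_identical(length(boxMasses(d)), 49L)
  expect_equal(sum(boxMasses(d) == 1), 4)
  expect_equal(sum(boxMasses(d) == 0), 45)

  d <- boxMassDistribution(px, 8)
  expect_identical(length(boxMasses(d)), 1L)
  expect_equal(boxMasses(d), sum(px))

  expect_error(boxMassDistribution(px, 9), "out of range")
})

test_that("lacunarity values match hand-computed cases", {
  expect_equal(lacunarityAt(boxMassDistribution(matrix(0.6, 10, 10), 3)), 1)

  px <- matrix(0, 8, 8)
  px[4, 4] <- 1
  expect_equal(lacunarityAt(boxMassDistribution(px, 2)), 49 / 4)

  expect_error(lacunarityAt(boxMassDistribution(matrix(0, 5, 5), 2)),
               "undefined")
})

test_that("summed-area implementation equals the naive double-loop oracle", {
  withr::local_seed(14)
  for (i in 1:8) {
    px <- matrix(runif(32 * 32), 32, 32)
    for (b in c(2, 3, 7, 13)) {
      expect_equal(sort(boxMasses(boxMassDistribution(px, b))),
                   sort(naiveBoxMasses(px, b)), tolerance = 1e-12)
      expect_equal(lacunarityAt(boxMassDistribution(px, b)),
                   naiveLacunarity(px, b), tolerance = 1e-10)
    }
  }
})

test_that("Bernoulli images match the i.i.d. closed form 1 + (1-p)/(p b^2)", {
  # moderate size here; the full 512^2 three-p sweep runs in the
  # acceptance suite
  withr::local_seed(8)
  img <- bernoulliImage(256, 256, 0.5, seed = 81)
  lam <- lacunarityAt(boxMassDistribution(img, 3))
  expect_equal(lam, 1 + 0.5 / (0.5 * 9), tolerance = 0.01)
})

test_that("the lacunarity curve behaves as theory demands", {
  expect_true(all(lambdaValues(lacunarityCurve(matrix(2, 16, 16),
                                               bMin = 2, bMax = 8)) == 1))

  withr::local_seed(77)
  px <- matrix(runif(24 * 24), 24, 24)
  cv <- lacunarityCurve(px, bMin = 2, bMax = 24)
  expect_gte(min(lambdaValues(cv)), 1)
  expect_equal(lambdaValues(cv)[length(cv)], 1)  # single full-size box
  expect_identical(boxSizes(cv), 2:24)

  expect_error(lacunarityCurve(px, bMin = 5, bMax = 5), "bMin < bMax")
  expect_error(lacunarityCurve(px, bMin = 2, bMax = 30), "bMin < bMax")
})

test_that("a Sierpinski carpet yields a decaying, hyperbola-like curve", {
  img <- sierpinskiCarpet(4)  # 81 x 81
  cv <- lacunarityCurve(img, bMin = 2, bMax = 27)
  lam <- lambdaValues(cv)
  expect_gte(min(lam), 1)
  # non-increasing over the fitted range (small numeric slack)
  expect_true(all(diff(lam) <= 1e-9))
  # log(Lambda - asymptote) vs log b roughly linear with negative slope
  fit <- fitHyperbola(cv)
  expect_gt(coef(fit)["alpha"], 0)
  expect_gt(rSquared(fit), 0.95)
})

test_that("lacunarity is invariant under the dihedral group of the square", {
  withr::local_seed(19)
  px <- matrix(runif(20 * 20), 20, 20)
  rot90 <- function(m) t(m)[, nrow(m):1]
  variants <- list(px, rot90(px), rot90(rot90(px)), rot90(rot90(rot90(px))),
                   px[nrow(px):1, ], px[, ncol(px):1], t(px))
  base <- vapply(2:10, function(b) lacunarityAt(boxMassDistribution(px, b)),
                 numeric(1))
  for (v in variants[-1]) {
    lam <- vapply(2:10, function(b) lacunarityAt(boxMassDistribution(v, b)),
                  numeric(1))
    expect_equal(lam, base, tolerance = 1e-12)
  }
})
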