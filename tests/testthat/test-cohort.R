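# exact sample with prescribed mean and SD (z-score then rescale)
exactSample <- function(n, mean, sd, seed) {
  set.seed(seed)
  x <- rnorm(n)
  mean + sd * (x - mean(x)) / sd(x)
}

test_that("one-tail pooled t-test matches closed-form and t.test identities", {
  a <- exactSample(14, 75.4, 5.1, 1)
  b <- exactSample(14, 73.1, 5.1, 2)
  res <- tTestOneTail(a, b)
  tClosed <- (75.4 - 73.1) / (5.1 * sqrt(2 / 14))
  expect_equal(res$t, tClosed, tolerance = 1e-10)
  expect_equal(res$df, 26)
  expect_equal(res$p, pt(tClosed, 26, lower.tail = FALSE), tolerance = 1e-12)

  # one-tail p is half the two-tailed p for the same data
  two <- t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(res$p, two / 2, tolerance = 1e-12)

  # swapping groups flips direction but not magnitude
  res2 <- tTestOneTail(b, a)
  expect_equal(abs(res2$t), abs(res$t))
  expect_equal(res2$p, res$p)
})

test_that("identical groups give t = 0, p = 0.5", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  res <- tTestOneTail(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)
})

test_that("well-separated tight groups give a vanishing p", {
  a <- c(10, 10.001, 9.999, 10.0005)
  res <- tTestOneTail(a + 100, a)
  expect_lt(res$p, 1e-6)
})

test_that("degenerate variance is handled per contract", {
  expect_error(tTestOneTail(c(2, 2), c(2, 2)), "zero pooled variance")
  res <- tTestOneTail(c(5, 5), c(2, 2))
  expect_identical(res$t, Inf)
  expect_identical(res$p, 0)
  expect_error(tTestOneTail(1, c(1, 2)), "at least 2")
})

test_that("median-cutoff classification produces exact confusion counts", {
  df <- data.frame(subjectId = paste0("s", 1:4),
                   group = c("pos", "pos", "neg", "neg"),
                   beta = c(1, 2, 3, 4))
  cmp <- classifyByCutoff(df, cutoff = "median", positiveGroup = "pos")
  expect_equal(betaCutoff(cmp), 2.5)
  expect_identical(confusionCounts(cmp),
                   c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))

  # ties at the cutoff count as positive
  dfTie <- data.frame(subjectId = paste0("s", 1:4),
                      group = c("pos", "pos", "neg", "neg"),
                      beta = c(2, 2, 2, 2))
  cmpTie <- classifyByCutoff(dfTie, cutoff = "median", positiveGroup = "pos")
  expect_identical(confusionCounts(cmpTie),
                   c(tp = 2L, fp = 2L, tn = 0L, fn = 0L))
})

test_that("infinite cutoffs label everyone one way", {
  df <- data.frame(subjectId = paste0("s", 1:6),
                   group = rep(c("pos", "neg"), 3),
                   beta = rnorm(6))
  all.pos <- confusionCounts(classifyByCutoff(df, Inf, "pos"))
  expect_identical(unname(all.pos[c("tn", "fn")]), c(0L, 0L))
  expect_identical(sum(all.pos), 6L)
  all.neg <- confusionCounts(classifyByCutoff(df, -Inf, "pos"))
  expect_identical(unname(all.neg[c("tp", "fp")]), c(0L, 0L))
})

test_that("classification rejects invalid input", {
  one <- data.frame(subjectId = "s1", group = "pos", beta = 1)
  expect_error(classifyByCutoff(one), "at least 2")
  same <- data.frame(subjectId = c("s1", "s2"), group = "pos", beta = 1:2)
  expect_error(classifyByCutoff(same), "two groups")
})

test_that("a group-shifted beta distribution is detected with good sensitivity", {
  # positives shifted down by 0.1 against noise sd 0.08, n = 14 + 14
  withr::local_seed(301)
  sens <- replicate(100, {
    beta <- c(rnorm(14, 1.68 - 0.1, 0.08), rnorm(14, 1.68, 0.08))
    df <- data.frame(subjectId = paste0("s", 1:28),
                     group = rep(c("AD", "CTR"), each = 14),
                     beta = beta)
    cmp <- classifyByCutoff(df, "median", positiveGroup = "AD")
    confusionCounts(cmp)["tp"] / 14
  })
  expect_gte(mean(sens), 0.6)
})
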