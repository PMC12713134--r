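# Triplet classification, non-repetitive fraction, run lengths, and
# cumulative distribution averaging.

test_that("triplet windows classify by first-vs-third syllable identity", {
  expect_identical(classifyTriplets(c(5, 6, 9)), 1L)
  expect_identical(classifyTriplets(c(12, 1, 12)), 0L)
  expect_identical(classifyTriplets(c(1, 2, 1, 2, 1)), c(0L, 0L, 0L))
  expect_identical(classifyTriplets(c(3, 7, 4, 7)), c(1L, 0L))
  expect_error(classifyTriplets(c(1, 2)), "T >= 3")
})

test_that("classification is invariant under syllable relabeling", {
  set.seed(42)
  for (i in 1:20) {
    e <- randomValidSequence(60, 8)
    perm <- sample(0:7)
    expect_identical(classifyTriplets(e), classifyTriplets(perm[e + 1]))
  }
})

test_that("non-repetitive fraction is the mean indicator", {
  expect_equal(nonrepetitiveFraction(c(1, 1, 1, 1)), 1)
  expect_equal(nonrepetitiveFraction(c(0, 0)), 0)
  expect_equal(nonrepetitiveFraction(c(1, 0, 1, 0)), 0.5)
  expect_error(nonrepetitiveFraction(integer(0)), "empty")
  b <- c(1L, 0L, 0L, 1L, 1L)
  expect_equal(nonrepetitiveFraction(b) * length(b), sum(b))
})

test_that("run lengths are maximal constant blocks, in order", {
  rl <- runLengths(c(1, 1, 0, 0, 0, 1))
  expect_identical(rl$repetitive, 3L)
  expect_identical(rl$nonrepetitive, c(2L, 1L))
  rl0 <- runLengths(rep(0L, 7))
  expect_identical(rl0$repetitive, 7L)
  expect_length(rl0$nonrepetitive, 0)
  expect_error(runLengths(integer(0)), "empty")
})

test_that("run lengths partition and reconstruct the indicator vector", {
  set.seed(7)
  for (i in 1:200) {
    b <- sample(0:1, sample(1:60, 1), replace = TRUE)
    rl <- runLengths(b)
    expect_equal(sum(rl$repetitive) + sum(rl$nonrepetitive), length(b))
    # reconstruct: interleave the two lists in recorded order
    r <- rle(b)
    expect_identical(as.integer(r$lengths[r$values == 0]), rl$repetitive)
    expect_identical(as.integer(r$lengths[r$values == 1]), rl$nonrepetitive)
    rebuilt <- inverse.rle(list(
      lengths = r$lengths,
      values = r$values))
    expect_identical(rebuilt, b)
  }
})

test_that("alternation profile ties indicators, fraction and runs together", {
  # triplets of (1,2,1,2,5,6): 1-2-1 -> 0, 2-1-2 -> 0, 1-2-5 -> 1, 2-5-6 -> 1
  s <- syllableSequence(c(1, 2, 1, 2, 5, 6), animalId = "a1",
                        group = "g", timepoint = "tp")
  p <- alternationProfile(s)
  expect_identical(indicators(p), c(0L, 0L, 1L, 1L))
  expect_equal(profileFraction(p), 0.5)
  expect_identical(repetitiveRuns(p), 2L)
  expect_identical(nonrepetitiveRuns(p), 2L)
  expect_identical(animalId(p), "a1")
})

test_that("empirical cumulative distributions count in percent", {
  cd <- cumulativeDistribution(c(1, 1, 2))
  expect_equal(cd$value, c(1, 2))
  expect_equal(cd$cum_percent, c(100 * 2 / 3, 100))
  expect_equal(cd$cum_percent[nrow(cd)], 100)
  expect_error(cumulativeDistribution(numeric(0)), "empty")
})

test_that("averaging step CDFs on the union grid", {
  cd <- cumulativeDistribution(c(2, 4, 4, 9))
  avg <- averageDistributions(list(cd, cd))
  expect_equal(avg$value, cd$value)
  expect_equal(avg$cum_percent, cd$cum_percent)
  a <- cumulativeDistribution(1)
  b <- cumulativeDistribution(3)
  avg2 <- averageDistributions(list(a, b))
  expect_equal(avg2$value, c(1, 3))
  expect_equal(avg2$cum_percent, c(50, 100))
})

test_that("with no return bias the repetitive fraction matches chance 1/(n-1)", {
  n <- 9
  cfg <- cohortConfig(nSyllables = n, seqLength = 1500,
                      nAnimalsPerGroup = 2, returnBias = 0, controlBias = 0,
                      groupSpecificIds = integer(0), racingIds = integer(0),
                      racingBoost = 1, lengthFactor = 1,
                      timepoints = "tp", seed = 1)
  fr <- vapply(1:25, function(i) {
    s <- simulateSequence(cfg, cfg@groups[1], seed = 3000 + i)
    1 - nonrepetitiveFraction(classifyTriplets(s))
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 1 / (n - 1)), 3 * se + 1e-12)
})

test_that("cohort alternation tables are consistent with profiles", {
  cfg <- cohortConfig(seqLength = 120, nAnimalsPerGroup = 2, seed = 8,
                      timepoints = c("1.5w", "12w"))
  cohort <- simulateCohort(cfg)
  alt <- cohortAlternation(cohort)
  expect_equal(nrow(alt$profiles), length(cohort))
  expect_equal(alt$profiles$percent_repetitive,
               100 * (1 - alt$profiles$f))
  # run lengths per animal sum to T - 2
  sums <- tapply(alt$runs$length, alt$runs$animal_id, sum)
  expect_equal(as.numeric(sums[alt$profiles$animal_id]),
               alt$profiles$T - 2)
})
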