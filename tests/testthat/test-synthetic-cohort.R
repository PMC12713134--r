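# Generator contract: no self-repeats, vocabulary restriction, determinism,
# and the analytic repetitive-triplet fraction rho + (1 - rho)/(n - 1).

analyticCfg <- function(rho, n = 11, Tn = 2000, seed = 1) {
  cohortConfig(nSyllables = n, seqLength = Tn, nAnimalsPerGroup = 2,
               returnBias = rho, controlBias = 0,
               groupSpecificIds = integer(0), racingIds = integer(0),
               racingBoost = 1, lengthFactor = 1,
               timepoints = c("t1", "t2"), seed = seed)
}

caseGroup <- function(cfg) cfg@groups[2]

test_that("sequences respect the no-self-repeat and id-range invariants", {
  cfg <- cohortConfig(seqLength = 300, nAnimalsPerGroup = 3, seed = 11)
  cohort <- simulateCohort(cfg)
  expect_length(cohort, 2 * 3 * 3)
  for (s in cohort) {
    e <- emissions(s)
    expect_true(all(e[-1] != e[-length(e)]))
    expect_true(all(e >= 0 & e < cfg@nSyllables))
  }
  expect_false(anyDuplicated(vapply(cohort, animalId, character(1))) > 0)
})

test_that("identical configs reproduce identical cohorts; seeds differ per animal", {
  cfg <- cohortConfig(seqLength = 100, nAnimalsPerGroup = 2, seed = 5)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(lapply(c1, emissions), lapply(c2, emissions))
  s1 <- animalSeed(5, "naive", "12w", 1)
  s2 <- animalSeed(5, "naive", "12w", 2)
  s3 <- animalSeed(5, "epileptic", "12w", 1)
  expect_true(length(unique(c(s1, s2, s3))) == 3)
  expect_true(all(c(s1, s2, s3) < 2^31))
})

test_that("group-specific syllables appear only in the case group", {
  cfg <- cohortConfig(seqLength = 400, nAnimalsPerGroup = 4, seed = 3)
  cohort <- simulateCohort(cfg)
  for (s in cohort) {
    if (groupLabel(s) != caseGroup(cfg))
      expect_length(intersect(emissions(s), cfg@groupSpecificIds), 0)
  }
  caseEmis <- unlist(lapply(cohort[vapply(cohort, groupLabel, character(1)) ==
                                   caseGroup(cfg)], emissions))
  expect_setequal(intersect(caseEmis, cfg@groupSpecificIds),
                  cfg@groupSpecificIds)
})

test_that("return bias 1 forces a strict two-syllable oscillation", {
  cfg <- analyticCfg(1, Tn = 50)
  s <- emissions(simulateSequence(cfg, caseGroup(cfg), seed = 9,
                                  timepoint = "t2"))
  expect_true(all(s[-(1:2)] == s[seq_len(48)]))
  expect_length(unique(s), 2)
})

test_that("sedentary length factor shortens only the case group's final timepoint", {
  cfg <- cohortConfig(seqLength = 200, nAnimalsPerGroup = 1,
                      lengthFactor = 0.5, seed = 2)
  cohort <- simulateCohort(cfg)
  man <- cohortManifest(cohort)
  short <- man$T == 100
  expect_true(all(man$group[short] == caseGroup(cfg)))
  expect_true(all(man$timepoint[short] == "20w"))
  expect_true(all(man$T[!short] == 200))
})

test_that("vocabulary below two syllables is rejected", {
  cfg <- cohortConfig(nSyllables = 3, groupSpecificIds = 1:2,
                      racingIds = integer(0), seqLength = 10,
                      lengthFactor = 1)
  expect_error(simulateSequence(cfg, cfg@groups[1], seed = 1),
               "fewer than 2")
})

test_that("with zero return bias, P(S[t] == S[t+2]) approaches 1/(n-1)", {
  cfg <- analyticCfg(0, n = 11, Tn = 200000)
  s <- emissions(simulateSequence(cfg, caseGroup(cfg), seed = 101,
                                  timepoint = "t2"))
  frac <- mean(s[seq_len(length(s) - 2)] == s[-(1:2)])
  expect_equal(frac, 1 / 10, tolerance = 0.005 / (1 / 10))
  expect_lt(abs(frac - 0.1), 0.005)
})

test_that("repetitive-triplet fraction recovers rho + (1-rho)/(n-1)", {
  nAnimals <- 20
  Tn <- 2500
  for (rho in c(0, 0.2, 0.4)) {
    cfg <- analyticCfg(rho, n = 11, Tn = Tn)
    fr <- vapply(seq_len(nAnimals), function(i) {
      s <- simulateSequence(cfg, caseGroup(cfg), seed = 1000 + i,
                            timepoint = "t2")
      1 - nonrepetitiveFraction(classifyTriplets(s))
    }, numeric(1))
    expected <- rho + (1 - rho) / 10
    se <- sd(fr) / sqrt(nAnimals)
    expect_lt(abs(mean(fr) - expected), 3 * se + 1e-12)
  }
})

test_that("cohort-mean repetitive fraction is nondecreasing in the return bias", {
  rhos <- seq(0, 0.9, by = 0.1)
  means <- vapply(rhos, function(rho) {
    cfg <- analyticCfg(rho, n = 11, Tn = 2000)
    mean(vapply(1:20, function(i) {
      s <- simulateSequence(cfg, caseGroup(cfg), seed = 400 + i,
                            timepoint = "t2")
      1 - nonrepetitiveFraction(classifyTriplets(s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -0.01))
  expect_gt(means[10], means[1])
})

test_that("racing boost raises racing usage only where applied", {
  cfg <- cohortConfig(seqLength = 800, nAnimalsPerGroup = 6, seed = 21)
  cohort <- simulateCohort(cfg)
  labels <- data.frame(syllable_id = 0:36,
                       behavior_name = "x",
                       is_racing = 0:36 %in% cfg@racingIds)
  man <- cohortManifest(cohort)
  tot <- vapply(cohort, function(s)
    racingUsageTotal(usageFromSequence(s), labels), numeric(1))
  caseChronic <- man$group == caseGroup(cfg) & man$timepoint != "1.5w"
  control <- man$group == cfg@groups[1]
  expect_gt(mean(tot[caseChronic]), 2 * mean(tot[control]))
})
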