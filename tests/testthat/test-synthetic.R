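test_that("single-regime simulation is degenerate as expected", {
  # one state: recipe builds a single block covering all nodes
  spec <- syntheticSpec(nNodes = 8, nTimepoints = 200, nStates = 1,
                        r = 0.3, stayProb = c(A = 0.9, B = 0.9),
                        groupSizes = c(A = 2, B = 2))
  set.seed(1)
  s <- simulateSubject(spec, "A")
  expect_identical(unique(s@statePath), 1L)
  expect_identical(length(s@statePath), 200L)
})

test_that("identity covariances give near-zero node correlations", {
  spec <- syntheticSpec(nNodes = 6, nTimepoints = 4000, nStates = 2,
                        r = c(0, 0), smoothSd = 0,
                        stayProb = c(A = 0.95, B = 0.95),
                        groupSizes = c(A = 1, B = 1))
  set.seed(2)
  s <- simulateSubject(spec, "A")
  cc <- cor(seriesValues(s@series))
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(4000))
})

test_that("regime switch rate matches the stay probability", {
  spec <- syntheticSpec(nNodes = 4, nTimepoints = 2000, nStates = 3,
                        r = c(0.1, 0.3, 0.5),
                        stayProb = c(A = 0.9, B = 0.5),
                        groupSizes = c(A = 1, B = 1))
  set.seed(3)
  s <- simulateSubject(spec, "A")
  switches <- sum(diff(s@statePath) != 0)  # direct tally of the state path
  frac <- switches / (length(s@statePath) - 1)
  # binomial sampling band around 0.1 (4 sd)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / 1999))
})

test_that("single-state empirical covariance recovers the specified matrix", {
  S <- blockStateCovariances(10, 1, r = 0.5)[[1]]
  spec <- syntheticSpec(nNodes = 10, nTimepoints = 5000, nStates = 1,
                        r = 0.5, smoothSd = 0,
                        stayProb = c(A = 0.9, B = 0.9),
                        groupSizes = c(A = 1, B = 1))
  set.seed(4)
  s <- simulateSubject(spec, "A")
  emp <- cov(seriesValues(s@series))
  relFrob <- norm(emp - S, "F") / norm(S, "F")
  expect_lt(relFrob, 0.1)

  # temporal smoothing preserves the marginal covariance (looser band:
  # autocorrelation cuts the effective sample size)
  spec2 <- syntheticSpec(nNodes = 10, nTimepoints = 5000, nStates = 1,
                         r = 0.5, smoothSd = 2,
                         stayProb = c(A = 0.9, B = 0.9),
                         groupSizes = c(A = 1, B = 1))
  set.seed(5)
  s2 <- simulateSubject(spec2, "A")
  expect_lt(norm(cov(seriesValues(s2@series)) - S, "F") / norm(S, "F"), 0.25)
})

test_that("invalid specs and groups are rejected with clear messages", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(syntheticSpec(nNodes = 2, nStates = 1,
                             stateCovariances = list(bad),
                             groupSizes = c(A = 1, B = 1)),
               "state 1.*positive-semidefinite")
  expect_error(syntheticSpec(stayProb = c(A = 1, B = 0.9)), "stayProb")
  expect_error(syntheticSpec(groupSizes = c(A = 0, B = 2)), ">= 1")
  spec <- tinySpec()
  expect_error(simulateSubject(spec, "C"), "unknown group 'C'")
})

test_that("cohorts honor group sizes and are seed-deterministic", {
  spec <- tinySpec(groupSizes = c(A = 3, B = 2), nTimepoints = 100)
  co <- simulateCohort(spec, seed = 9)
  expect_identical(nrow(cohortTable(co)), 5L)
  expect_identical(sum(cohortTable(co)$group == "A"), 3L)

  co2 <- simulateCohort(spec, seed = 9)
  expect_identical(cohortTable(co), cohortTable(co2))
  expect_identical(seriesValues(cohortSubjects(co)[[4]]@series),
                   seriesValues(cohortSubjects(co2)[[4]]@series))
  expect_identical(cohortSubjects(co)[[2]]@statePath,
                   cohortSubjects(co2)[[2]]@statePath)

  co3 <- simulateCohort(spec, seed = 10)
  expect_false(identical(cohortTable(co)$age_years,
                         cohortTable(co3)$age_years))
})

test_that("covariates follow the per-group distributions", {
  spec <- syntheticSpec(nNodes = 4, nTimepoints = 10, smoothSd = 0,
                        groupSizes = c(A = 200, B = 200),
                        nStates = 1, r = 0,
                        stayProb = c(A = 0.9, B = 0.9))
  co <- simulateCohort(spec, seed = 11)
  tab <- cohortTable(co)
  expect_equal(mean(tab$age_years[tab$group == "A"]), 27.9,
               tolerance = 3 * 2.4 / sqrt(200) / 27.9)
  expect_equal(mean(tab$brain_volume_ml[tab$group == "B"]), 1063.8,
               tolerance = 3 * 36.27 / sqrt(200) / 1063.8)
})

test_that("slower switching yields longer mean trough durations downstream", {
  # Monte-Carlo sign test over replicate cohorts at reduced scale
  spec <- syntheticSpec(nNodes = 20, nTimepoints = 600,
                        groupSizes = c(A = 8, B = 8),
                        stayProb = c(A = 0.97, B = 0.93))
  wins <- 0L
  nRep <- 10L
  for (r in seq_len(nRep)) {
    co <- simulateCohort(spec, seed = 100 + r)
    s <- summarizeCohort(co, list(troughCriterion(0)))
    tab <- merge(cohortTable(co), s, by = "subject_id")
    dA <- mean(tab$mean_duration_s[tab$group == "A"], na.rm = TRUE)
    dB <- mean(tab$mean_duration_s[tab$group == "B"], na.rm = TRUE)
    wins <- wins + (dA > dB)
  }
  expect_gte(wins, 8L)
})

test_that("mean trough duration is monotone in the stay probability", {
  durs <- vapply(c(0.90, 0.95, 0.99), function(sp) {
    spec <- syntheticSpec(nNodes = 20, nTimepoints = 800,
                          groupSizes = c(A = 6, B = 1),
                          stayProb = c(A = sp, B = sp))
    co <- simulateCohort(spec, seed = 77)
    s <- summarizeCohort(co, list(troughCriterion(0.02)))
    mean(s$mean_duration_s[s$subject_id %in%
                             cohortTable(co)$subject_id[
                               cohortTable(co)$group == "A"]], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(durs) > 0))
})
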