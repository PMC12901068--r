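mkRss <- function(x, tr = 0.72) new("RssSeries", values = x, trSeconds = tr,
                                    nEdges = 10L, label = "test")

test_that("base detection matches hand-checkable series", {
  res <- detectBaseExtrema(mkRss(c(3, 1, 2, 1, 3), tr = 1))
  expect_identical(troughIndices(res), c(2L, 4L))
  expect_identical(peakIndices(res), 3L)
  expect_equal(peakHeights(res), 2)
  expect_equal(troughDurations(res), 2)

  # strictly monotone series: no local minima
  mono <- detectBaseExtrema(mkRss(1:10 * 1.0))
  expect_identical(nTroughs(mono), 0L)
  expect_length(troughDurations(mono), 0)

  # exact ties disqualify a strict trough
  tie <- detectBaseExtrema(mkRss(c(3, 1, 1, 3, 0, 3)))
  expect_identical(troughIndices(tie), 5L)

  expect_error(detectBaseExtrema(mkRss(c(1, 2))), "short")
})

test_that("base detection agrees with the exhaustive neighbour-scan oracle", {
  set.seed(101)
  for (rep in 1:200) {
    rss <- randomRssSeries(sample(20:500, 1))
    res <- detectBaseExtrema(rss)
    x <- seriesValues(rss)
    expect_identical(troughIndices(res), oracleTroughs(x))
    expect_identical(peakIndices(res), oraclePeaks(x, troughIndices(res)))
  }
})

test_that("theta = 0 returns the base result unchanged in both modes", {
  rss <- randomRssSeries(200)
  base <- detectBaseExtrema(rss)
  for (mode in c("adjacent-sample", "adjacent-peak")) {
    out <- applyMagnitudeCriterion(base, rss, troughCriterion(0, mode))
    expect_identical(troughIndices(out), troughIndices(base))
    expect_identical(peakIndices(out), peakIndices(base))
  }
})

test_that("the percent boundary is inclusive in adjacent-sample mode", {
  rss <- mkRss(c(3, 2.97, 3, 1, 3))  # keeps a deep anchor trough at 4
  base <- detectBaseExtrema(rss)
  expect_identical(troughIndices(base), c(2L, 4L))
  # 2.97 is exactly 1% below 3: retained at theta = 0.01, removed at 0.02
  kept <- applyMagnitudeCriterion(base, rss, troughCriterion(0.01))
  expect_true(2L %in% troughIndices(kept))
  gone <- applyMagnitudeCriterion(base, rss, troughCriterion(0.02))
  expect_false(2L %in% troughIndices(gone))
  # exactly representable boundary too: 3 == 0.75 * 4
  rss2 <- mkRss(c(4, 3, 4, 1, 4))
  base2 <- detectBaseExtrema(rss2)
  expect_true(2L %in% troughIndices(
    applyMagnitudeCriterion(base2, rss2, troughCriterion(0.25))))
})

test_that("adjacent-peak pruning matches the exhaustive subset oracle", {
  set.seed(202)
  tested <- 0L
  while (tested < 60L) {
    rss <- randomRssSeries(sample(15:30, 1))
    x <- seriesValues(rss)
    base <- detectBaseExtrema(rss)
    if (nTroughs(base) < 1L || nTroughs(base) > 12L) next
    theta <- sample(c(0.01, 0.02, 0.05, 0.1), 1)
    out <- applyMagnitudeCriterion(base, rss,
                                   troughCriterion(theta, "adjacent-peak"))
    best <- oracleMaxValidSubsets(x, troughIndices(base), theta)
    # the pruned set must be a maximum-cardinality valid subset
    expect_true(oracleSubsetValid(x, troughIndices(out), theta))
    expect_identical(length(troughIndices(out)), length(best[[1]]))
    if (length(best) == 1L)
      expect_identical(troughIndices(out), as.integer(best[[1]]))
    tested <- tested + 1L
  }
})

test_that("trough durations and peak heights are recomputed consistently", {
  set.seed(303)
  rss <- randomRssSeries(400, tr = 0.72)
  res <- detectBaseExtrema(rss)
  tr <- troughIndices(res)
  expect_equal(troughDurations(res), diff(tr) * 0.72)
  # telescoping sum
  expect_equal(sum(troughDurations(res)), (max(tr) - min(tr)) * 0.72)
  # heights are interval maxima, absolute y values
  x <- seriesValues(rss)
  for (i in seq_len(length(tr) - 1L))
    expect_equal(peakHeights(res)[i], max(x[(tr[i] + 1):(tr[i + 1] - 1)]))
  # TR override
  expect_equal(troughDurations(res, trSeconds = 2), diff(tr) * 2)
})

test_that("peak height uses the absolute value, not depth above troughs", {
  # equal vs unequal flanking troughs give the same height
  a <- detectBaseExtrema(mkRss(c(5, 1, 4, 1, 5)))
  b <- detectBaseExtrema(mkRss(c(5, 3, 4, 1, 5)))
  expect_equal(peakHeights(a), 4)
  expect_equal(peakHeights(b), 4)
})

test_that("subject summaries compute per-subject means and flags", {
  s <- summarizeSubject(mkRss(c(5, 1, 2, 1, 4, 1, 5), tr = 1),
                        troughCriterion(0), "s1")
  expect_identical(s$n_troughs, 3L)
  expect_equal(s$mean_duration_s, 2)
  expect_equal(s$mean_peak_height, 3)
  expect_true(s$analyzable)

  # fewer than 2 troughs: flagged, means undefined
  s2 <- summarizeSubject(mkRss(c(3, 1, 3)), troughCriterion(0), "s2")
  expect_false(s2$analyzable)
  expect_true(is.na(s2$mean_duration_s))

  # telescoping identity for the mean duration
  set.seed(404)
  rss <- randomRssSeries(300, tr = 0.72)
  s3 <- summarizeSubject(rss, troughCriterion(0), "s3")
  tr <- troughIndices(detectBaseExtrema(rss))
  expect_equal(s3$mean_duration_s,
               (max(tr) - min(tr)) * 0.72 / (length(tr) - 1))
})

test_that("troughs and peaks strictly alternate", {
  set.seed(505)
  for (rep in 1:50) {
    rss <- randomRssSeries(200)
    for (cr in list(troughCriterion(0), troughCriterion(0.03),
                    troughCriterion(0.03, "adjacent-peak"))) {
      res <- detectExtrema(rss, cr)
      tr <- troughIndices(res)
      pk <- peakIndices(res)
      if (length(tr) >= 2L) {
        inter <- sort(c(tr, pk))
        # alternating: trough, peak, trough, peak, ..., trough
        expect_identical(inter[seq(1, length(inter), by = 2)], tr)
        expect_identical(inter[seq(2, length(inter), by = 2)], pk)
      }
    }
  }
})

test_that("trough count and mean duration are monotone in theta", {
  set.seed(606)
  thetas <- c(0, 0.01, 0.02, 0.05)
  for (rep in 1:20) {
    rss <- randomRssSeries(500)
    for (mode in c("adjacent-sample", "adjacent-peak")) {
      counts <- durs <- numeric(0)
      for (th in thetas) {
        s <- summarizeSubject(rss, troughCriterion(th, mode), "x")
        counts <- c(counts, s$n_troughs)
        durs <- c(durs, s$mean_duration_s)
      }
      expect_true(all(diff(counts) <= 0))
      d <- durs[!is.na(durs)]
      expect_true(all(diff(d) >= 0))
    }
  }
})

test_that("adjacent-sample trough sets are nested across theta", {
  set.seed(707)
  for (rep in 1:30) {
    rss <- randomRssSeries(300)
    base <- detectBaseExtrema(rss)
    t1 <- troughIndices(applyMagnitudeCriterion(base, rss, troughCriterion(0.01)))
    t2 <- troughIndices(applyMagnitudeCriterion(base, rss, troughCriterion(0.02)))
    t5 <- troughIndices(applyMagnitudeCriterion(base, rss, troughCriterion(0.05)))
    expect_true(all(t5 %in% t2))
    expect_true(all(t2 %in% t1))
    expect_true(all(t1 %in% troughIndices(base)))
  }
})

test_that("extrema indices are invariant to positive rescaling of the RSS", {
  set.seed(808)
  for (const in c(0.001, 7, 1e4)) {
    rss <- randomRssSeries(300)
    scaled <- new("RssSeries", values = const * seriesValues(rss),
                  trSeconds = trSeconds(rss), nEdges = 10L, label = "scaled")
    for (cr in list(troughCriterion(0.02), troughCriterion(0.02, "adjacent-peak"))) {
      expect_identical(troughIndices(detectExtrema(rss, cr)),
                       troughIndices(detectExtrema(scaled, cr)))
      expect_identical(peakIndices(detectExtrema(rss, cr)),
                       peakIndices(detectExtrema(scaled, cr)))
    }
  }
})

test_that("mismatched base and series are rejected", {
  rss <- mkRss(c(3, 1, 3, 1, 3))
  other <- mkRss(c(1, 5, 1, 5, 1))
  base <- detectBaseExtrema(rss)
  expect_error(applyMagnitudeCriterion(base, other, troughCriterion(0.01)),
               "not local minima")
  shorter <- mkRss(c(3, 1, 3))
  expect_error(applyMagnitudeCriterion(base, shorter, troughCriterion(0.01)),
               "length mismatch")
})
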