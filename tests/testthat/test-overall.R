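makeResult <- function(null, obs = NULL, dt = 4, theta = 0.05) {
  # wrap a runs x time null-statistic matrix as a TanovaResult
  nRuns <- nrow(null); tp <- ncol(null)
  if (is.null(obs)) obs <- null[1, ]
  p <- sapply(seq_len(tp), function(t)
    (1 + sum(null[, t] >= obs[t])) / (nRuns + 1))
  new("TanovaResult", observed = matrix(obs, tp, 1,
                                        dimnames = list(NULL, "e")),
      p = matrix(p, tp, 1, dimnames = list(NULL, "e")),
      null = array(null, c(nRuns, tp, 1)),
      time = (seq_len(tp) - 1) * dt, effects = "e", statistic = "dgfp",
      cfg = randConfig(nRuns = nRuns, pThreshold = theta, seed = 1))
}

test_that("null p-matrix ranks runs against the other runs plus the observed", {
  set.seed(42)
  null <- matrix(runif(100 * 1), 100, 1)
  res <- makeResult(null, obs = 0.5)
  P <- suppressWarnings(nullPMatrix(res, "e"))
  expect_equal(dim(P), c(100L, 1L))
  # run with the largest statistic: nothing else reaches it
  expect_equal(P[which.max(null[, 1]), 1], 1 / 101)
  # all runs equal: ties count as >=, p = 1 for every run
  resT <- makeResult(matrix(1, 50, 2))
  PT <- suppressWarnings(nullPMatrix(resT, "e"))
  expect_true(all(PT == 1))
  # continuous null statistics give the uniform grid of ranks: the runs
  # occupy 200 of the 201 descending ranks of {runs, observed}
  set.seed(1)
  resU <- makeResult(matrix(rnorm(200), 200, 1), obs = rnorm(1))
  PU <- nullPMatrix(resU, "e")
  ranks <- round(PU[, 1] * 201)
  expect_equal(length(unique(ranks)), 200L)
  expect_true(all(ranks %in% 1:201))
  expect_warning(nullPMatrix(makeResult(matrix(runif(10), 10, 1)), "e"),
                 "unstable")
})

test_that("count, duration and Fisher statistics match their definitions", {
  expect_equal(countStatistic(c(0.01, 0.2, 0.04), 0.05), 2)
  expect_equal(countStatistic(rep(1, 7), 0.05), 0)
  expect_equal(countStatistic(rep(0.01, 9), 0.05), 9)
  expect_equal(durationStatistic(c(0.01, 0.01, 0.2, 0.04), 0.05, 4), 8)
  expect_equal(durationStatistic(rep(0.5, 5), 0.05, 4), 0)
  expect_equal(durationStatistic(rep(0.01, 250), 0.05, 4), 1000)
  expect_equal(fisherStatistic(rep(1, 5)), 0)
  expect_equal(fisherStatistic(exp(-1)), 2)
  set.seed(2)
  p <- runif(20)
  expect_equal(fisherStatistic(p), -2 * sum(log(p)), tolerance = 1e-12)
  expect_error(fisherStatistic(c(0.5, 0)), "p > 0")
})

test_that("adding a sub-threshold point never decreases count or Fisher", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(5:30, 1))
    p2 <- c(p, runif(1, 0, 0.049))
    expect_gte(countStatistic(p2, 0.05), countStatistic(p, 0.05))
    expect_gte(fisherStatistic(p2), fisherStatistic(p))
  }
})

test_that("an observed statistic beyond every null run gives the extreme rank", {
  set.seed(4)
  null <- matrix(runif(99 * 10), 99, 10)
  obs <- rep(2, 10)   # larger than every null statistic at every time point
  res <- makeResult(null, obs)
  for (kind in c("count", "duration", "fisher")) {
    o <- overallTest(res, "e", kind = kind, theta = 0.05)
    expect_equal(o@p, 1 / 100)
  }
})

test_that("the duration threshold is the (1 - theta) null quantile and monotone", {
  set.seed(5)
  null <- matrix(runif(200 * 30), 200, 30)
  res <- makeResult(null)
  thr <- sapply(c(0.01, 0.05, 0.1, 0.2), function(lv)
    overallTest(res, "e", "duration", level = lv)@durationThresholdMs)
  expect_true(all(diff(thr) <= 0))
  o <- overallTest(res, "e", "duration", theta = 0.05)
  durs <- o@nullSamples
  expect_equal(o@durationThresholdMs,
               as.numeric(quantile(durs, 0.95, type = 1)))
})

test_that("count, duration and Fisher recycle the identical permutations", {
  ds <- randomDataset(5, 2, 12, 6, seed = 6)
  res <- tanova(ds, twoLevelDesign(), randConfig(nRuns = 99, seed = 7))
  o1 <- overallTest(res, "cond", "count")
  o2 <- overallTest(res, "cond", "duration")
  o3 <- overallTest(res, "cond", "fisher")
  # all derive from the same retained null: rerunning gives identical output
  res2 <- tanova(ds, twoLevelDesign(), randConfig(nRuns = 99, seed = 7))
  expect_identical(res@null, res2@null)
  expect_identical(overallTest(res2, "cond", "count")@p, o1@p)
  expect_identical(overallTest(res2, "cond", "duration")@nullSamples,
                   o2@nullSamples)
  expect_identical(overallTest(res2, "cond", "fisher")@observed, o3@observed)
  expect_error(overallTest(res, "nope", "count"), "not in result")
})
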