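test_that("dGFP closed forms and direct-formula oracle", {
  expect_equal(dgfp(matrix(c(1, -1, -1, 1), 2, byrow = TRUE)), sqrt(2))
  expect_equal(dgfp(matrix(c(1, -1, 1, -1), 2, byrow = TRUE)), 0)
  set.seed(1)
  m <- matrix(rnorm(12), 3, 4)           # 3 levels x 4 channels
  direct <- sqrt(sum(sweep(m, 2, colMeans(m))^2) / 4)
  expect_equal(dgfp(m), direct, tolerance = 1e-12)
  expect_error(dgfp(matrix(1:4, 1)), "2 levels")
})

test_that("identical conditions give dGFP 0 and p = 1 everywhere", {
  base <- array(rnorm(5 * 6 * 4), c(5, 6, 4, 1))
  arr <- array(NA_real_, c(5, 6, 4, 2))
  arr[, , , 1] <- base; arr[, , , 2] <- base
  ds <- averageReference(erpDataset(arr, dtMs = 4, conditionTags = c("A", "B")))
  res <- tanova(ds, twoLevelDesign(), randConfig(nRuns = 99, seed = 1))
  expect_equal(as.numeric(res@observed), rep(0, 5))
  expect_equal(as.numeric(res@p), rep(1, 5))
})

test_that("a large fixed topographic difference is detected throughout", {
  set.seed(2)
  eff <- averageReference(c(rep(3, 6), rep(-3, 6)))
  arr <- array(rnorm(8 * 12 * 12 * 2, sd = 0.5), c(8, 12, 12, 2))
  arr[, , , 2] <- arr[, , , 2] + rep(eff, each = 8)
  ds <- averageReference(erpDataset(arr, dtMs = 4, conditionTags = c("A", "B")))
  res <- tanova(ds, twoLevelDesign(), randConfig(nRuns = 999, seed = 3))
  expect_true(all(res@p <= 0.002))
})

test_that("randomization p matches the exhaustive swap enumeration", {
  ds <- randomDataset(4, 2, 4, 6, seed = 4)
  pExact <- exactTanovaP(ds)
  nRuns <- 20000
  res <- tanova(ds, twoLevelDesign(), randConfig(nRuns = nRuns, seed = 5))
  se <- sqrt(pExact * (1 - pExact) / nRuns)
  expect_true(all(abs(res@p[, 1] - pExact) < 3 * se + 1 / nRuns))
})

test_that("dGFP is invariant to common channel permutations and subject order", {
  ds <- randomDataset(5, 2, 6, 8, seed = 6)
  des <- twoLevelDesign()
  r1 <- tanova(ds, des, randConfig(nRuns = 9, seed = 1))
  chperm <- sample(8)
  ds2 <- ds; ds2@data <- ds@data[, chperm, , , drop = FALSE]
  ds2@channelLabels <- ds@channelLabels[chperm]
  r2 <- tanova(ds2, des, randConfig(nRuns = 9, seed = 1))
  expect_equal(r1@observed, r2@observed)
  sperm <- sample(5)
  ds3 <- ds; ds3@data <- ds@data[, , sperm, , drop = FALSE]
  ds3@subjectIds <- ds@subjectIds[sperm]
  r3 <- tanova(ds3, des, randConfig(nRuns = 9, seed = 1))
  expect_equal(r1@observed, r3@observed)
})

test_that("with normalization, per-condition rescaling of any subject is ignored", {
  ds <- randomDataset(4, 2, 5, 6, seed = 7)
  des <- twoLevelDesign()
  cfg <- randConfig(nRuns = 29, seed = 2, normalize = TRUE)
  r1 <- tanova(ds, des, cfg)
  ds2 <- ds
  ds2@data[, , 2, 1] <- ds2@data[, , 2, 1] * 3.7   # positive rescale
  r2 <- tanova(ds2, des, cfg)
  expect_equal(r1@observed, r2@observed, tolerance = 1e-12)
  expect_equal(r1@p, r2@p)
})

test_that("GFP test isolates quantitative effects from topographic ones", {
  # conditions are scaled copies (x2) per subject: no topographic difference
  set.seed(8)
  base <- array(rnorm(6 * 10 * 10), c(6, 10, 10, 1))
  arr <- array(NA_real_, c(6, 10, 10, 2))
  arr[, , , 1] <- base
  arr[, , , 2] <- base * 2
  ds <- averageReference(erpDataset(arr, dtMs = 4, conditionTags = c("A", "B")))
  des <- twoLevelDesign()
  g <- gfpTest(ds, des, randConfig(nRuns = 199, seed = 9))
  expect_true(all(g@p <= 0.01))
  tn <- tanova(ds, des, randConfig(nRuns = 199, seed = 9, normalize = TRUE))
  expect_equal(as.numeric(tn@observed), rep(0, 6), tolerance = 1e-10)
  expect_equal(as.numeric(tn@p), rep(1, 6))
  # identical level-mean GFPs give statistic 0
  expect_equal(dgfp(matrix(c(1, 1), 2, 1)), 0)
})

test_that("window tests reproduce single-sample p and sharpen stationary effects", {
  ds <- randomDataset(5, 2, 8, 6, seed = 10)
  des <- twoLevelDesign()
  cfg <- randConfig(nRuns = 199, seed = 11)
  full <- tanova(ds, des, cfg)
  t3 <- sampleTimes(ds)[3]
  w <- windowAverageTest(ds, des, c(t3, t3), cfg)
  expect_equal(w@p[1, 1], full@p[3, 1])
  expect_equal(w@observed[1, 1], full@observed[3, 1])
  expect_error(windowAverageTest(ds, des, c(100, 50), cfg), "from <= to")
  # stationary effect: whole-epoch averaging raises SNR
  set.seed(12)
  eff <- averageReference(c(rep(1, 3), rep(-1, 3)))
  arr <- array(rnorm(10 * 6 * 10 * 2), c(10, 6, 10, 2))
  arr[, , , 2] <- arr[, , , 2] + rep(eff, each = 10)
  dsE <- averageReference(erpDataset(arr, dtMs = 4,
                                     conditionTags = c("A", "B")))
  fullE <- tanova(dsE, des, cfg)
  wE <- windowAverageTest(dsE, des, range(sampleTimes(dsE)), cfg)
  expect_lte(wE@p[1, 1], stats::median(fullE@p[, 1]))
})

test_that("PCA projection spans the informative plane", {
  set.seed(13)
  m1 <- averageReference(rnorm(8)); m2 <- averageReference(rnorm(8))
  pr <- pcaProjection(rbind(m1, m2))
  expect_equal(pr$coords[1, ], -pr$coords[2, ], tolerance = 1e-9)
  expect_gt(abs(stats::cor(pr$components[1, ], m1 - m2)), 1 - 1e-9)
  same <- pcaProjection(matrix(rep(m1, 4), 4, byrow = TRUE))
  expect_lt(max(abs(same$coords)), 1e-9)
  # projection contracts distances
  maps <- matrix(rnorm(6 * 8), 6)
  pr2 <- pcaProjection(maps)
  dFull <- as.matrix(dist(maps))
  dProj <- as.matrix(dist(pr2$coords))
  expect_true(all(dProj <= dFull + 1e-9))
})

test_that("power is monotone in simulated effect amplitude", {
  des <- twoLevelDesign()
  amps <- c(0, 0.5, 1, 2, 4)
  medp <- sapply(amps, function(a) {
    ps <- sapply(1:8, function(i) {
      set.seed(1000 + 17 * i + round(100 * a))
      eff <- averageReference(c(rep(a, 4), rep(-a, 4)))
      arr <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2))
      arr[, , , 2] <- arr[, , , 2] + rep(eff, each = 4)
      ds <- averageReference(erpDataset(arr, dtMs = 4,
                                        conditionTags = c("A", "B")))
      stats::median(tanova(ds, des, randConfig(nRuns = 99, seed = i))@p[, 1])
    })
    mean(ps)
  })
  expect_true(all(diff(medp) <= 0.05))   # non-increasing up to MC noise
})
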