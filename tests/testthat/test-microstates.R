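orthoTemplates <- function(k, nch, seed = 1) {
  set.seed(seed)
  makeTemplates(k, nch)
}

# noise-free alternation between templates
altMaps <- function(templ, reps = 10, amps = NULL) {
  k <- nrow(templ)
  if (is.null(amps)) amps <- rep(1, k * reps)
  idx <- rep(seq_len(k), reps)
  templ[idx, , drop = FALSE] * amps
}

test_that("k-means recovers noise-free templates exactly", {
  templ <- orthoTemplates(2, 10)
  maps <- altMaps(templ, 10)
  set.seed(2)
  model <- clusterKmeans(maps, 2, nRestarts = 5)
  C <- abs(cor(t(templates(model)), t(templ)))
  expect_true(all(apply(C, 2, max) > 1 - 1e-9))
  expect_error(clusterKmeans(maps, 1), "k must be >= 2")
})

test_that("explained variance is nested in k", {
  set.seed(3)
  templ <- orthoTemplates(4, 12, seed = 3)
  maps <- altMaps(templ, 8) + matrix(rnorm(32 * 12, sd = 0.2), 32)
  set.seed(4)
  ev2 <- explainedVariance(maps, clusterKmeans(maps, 2, nRestarts = 10))
  ev3 <- explainedVariance(maps, clusterKmeans(maps, 3, nRestarts = 10))
  expect_gte(ev3, ev2 - 1e-9)
})

test_that("AAHC is deterministic, recovers templates, and rivals k-means", {
  templ <- orthoTemplates(2, 10, seed = 5)
  maps <- altMaps(templ, 10)
  m1 <- clusterAahc(maps, 2)
  m2 <- clusterAahc(maps, 2)
  expect_identical(templates(m1), templates(m2))
  C <- abs(cor(t(templates(m1)), t(templ)))
  expect_true(all(apply(C, 2, max) > 1 - 1e-9))
  # 4-template synthetic data: AAHC explains nearly as much as k-means
  set.seed(6)
  templ4 <- orthoTemplates(4, 16, seed = 6)
  maps4 <- altMaps(templ4, 12, amps = runif(48, 0.5, 2)) +
    matrix(rnorm(48 * 16, sd = 0.2), 48)
  evA <- explainedVariance(maps4, clusterAahc(maps4, 4))
  set.seed(7)
  evK <- explainedVariance(maps4, clusterKmeans(maps4, 4, nRestarts = 20))
  expect_gt(evA, evK - 0.05)
})

test_that("assignment follows spatial correlation and the polarity mode", {
  templ <- orthoTemplates(3, 8, seed = 8)
  model <- new("MicrostateModel", templates = templ,
               polarityMode = "sensitive")
  expect_equal(assignMaps(templ[2, , drop = FALSE], model), 2L)
  modelI <- new("MicrostateModel", templates = templ, polarityMode = "ignore")
  expect_equal(assignMaps(-templ[2, , drop = FALSE], modelI), 2L)
  neg <- assignMaps(-templ[2, , drop = FALSE], model)
  expect_true(neg != 2L || ncol(templ) == 0)  # negation correlates -1 with 2
  expect_warning(z <- assignMaps(matrix(0, 1, 8), model), "zero map")
  expect_equal(z, 1L)
  expect_error(assignMaps(matrix(0, 1, 5), model), "channel count")
})

test_that("label smoothing dissolves short segments into better neighbours", {
  templ <- orthoTemplates(2, 10, seed = 9)
  model <- new("MicrostateModel", templates = templ,
               polarityMode = "sensitive")
  maps <- templ[c(1, 1, 1, 1, 1), ]
  expect_equal(smoothLabels(c(1, 1, 2, 1, 1), maps, model, 8, 4),
               rep(1L, 5))
  # long segments untouched (idempotence)
  labs <- c(1, 1, 1, 2, 2, 2)
  maps2 <- templ[labs, ]
  expect_equal(smoothLabels(labs, maps2, model, 8, 4), labs)
  # alternating single samples collapse to one surviving class
  alt <- rep(c(1L, 2L), 6)
  mapsAlt <- templ[alt, ]
  sm <- smoothLabels(alt, mapsAlt, model, 8, 4)
  expect_equal(length(rle(sm)$lengths), 1L)
})

test_that("explained variance matches its definition and edge cases", {
  templ <- orthoTemplates(3, 10, seed = 10)
  model <- new("MicrostateModel", templates = templ,
               polarityMode = "sensitive")
  maps <- altMaps(templ, 4, amps = runif(12, 0.5, 3))
  expect_equal(explainedVariance(maps, model), 1, tolerance = 1e-10)
  # labels orthogonal to the data explain nothing
  labs <- assignMaps(maps, model)
  wrong <- (labs %% 3L) + 1L
  expect_equal(explainedVariance(maps, model, wrong), 0, tolerance = 1e-10)
  # direct formula on random data
  set.seed(11)
  rmaps <- matrix(rnorm(80), 8, 10)
  rlabs <- assignMaps(rmaps, model)
  g <- gfp(rmaps)
  cc <- sapply(seq_len(8), function(t)
    cor(rmaps[t, ], templ[rlabs[t], ]))
  expect_equal(explainedVariance(rmaps, model, rlabs),
               sum((g * cc)^2) / sum(g^2), tolerance = 1e-10)
  expect_error(explainedVariance(matrix(0, 3, 10), model), "all-zero")
  # sign flips of templates are immaterial when polarity is ignored
  modelI <- new("MicrostateModel", templates = templ, polarityMode = "ignore")
  modelF <- new("MicrostateModel", templates = templ * c(-1, 1, -1),
                polarityMode = "ignore")
  expect_equal(explainedVariance(rmaps, modelI), explainedVariance(rmaps, modelF),
               tolerance = 1e-10)
})

test_that("quantifier arithmetic is exact for a uniform-GFP class", {
  labels <- c(rep(2L, 10), rep(1L, 10), rep(2L, 10))
  q <- microstateQuantifiers(labels, rep(1, 30), 2, dtMs = 4)
  # class 1 occupies samples 10..19 (0-based) at dt 4 ms
  expect_equal(q$onset_ms[1], 40)
  expect_equal(q$offset_ms[1], 76)
  expect_equal(q$duration_ms[1], 40)
  expect_equal(q$auc[1], 40)
  expect_equal(q$cog_ms[1], 58)
  expect_equal(q$mean_gfp[1], 1)
  expect_true(all(q$present))
  # absent class policy
  q2 <- microstateQuantifiers(rep(1L, 10), rep(1, 10), 2, dtMs = 4)
  expect_false(q2$present[2])
  expect_equal(q2$duration_ms[2], 0)
  expect_true(is.na(q2$onset_ms[2]))
  # disjoint segments of one class pool within the window
  q3 <- microstateQuantifiers(labels, rep(1, 30), 2, dtMs = 4)
  expect_equal(q3$duration_ms[2], 80)
  # window restriction isolates one appearance
  q4 <- microstateQuantifiers(labels, rep(1, 30), 2, dtMs = 4,
                              window = c(0, 36))
  expect_equal(q4$duration_ms[2], 40)
})

test_that("summed class-wise explained GFP never exceeds the total GFP", {
  set.seed(12)
  templ <- orthoTemplates(3, 12, seed = 12)
  maps <- altMaps(templ, 6) + matrix(rnorm(18 * 12, sd = 0.3), 18)
  model <- new("MicrostateModel", templates = templ,
               polarityMode = "sensitive")
  labs <- assignMaps(maps, model)
  g <- gfp(maps)
  explained <- abs(sapply(seq_len(nrow(maps)), function(t)
    g[t] * cor(maps[t, ], templ[labs[t], ])))
  expect_true(all(explained <= g + 1e-12))
})

test_that("cross-validation finds the true number of classes and is reproducible", {
  spec <- syntheticSpec(nSubjects = 8, nChannels = 16, nTimepoints = 60,
                        nClasses = 3, conditionTags = c("A", "B"),
                        noiseSd = 0.5, subjectLatencySd = 5, seed = 13)
  ds <- generateDataset(spec)
  cv <- crossValidateK(ds, kRange = 2:5, nSplits = 3, nRestarts = 5,
                       seed = 14)
  expect_true(all(diff(cv@learningEv) >= -1e-9))
  expect_gt(cv@testEv[2] - cv@testEv[1], 0.05)   # k 2 -> 3 helps
  expect_lt(cv@testEv[3] - cv@testEv[2], 0.01)   # k 3 -> 4 does not
  cv2 <- crossValidateK(ds, kRange = 2:5, nSplits = 3, nRestarts = 5,
                        seed = 14)
  expect_identical(cv@testEv, cv2@testEv)
  expect_error(crossValidateK(randomDataset(3, 2, 10, 6, seed = 1)),
               "at least 4")
})

test_that("quantifier randomization statistics behave under null and effect", {
  # identical conditions: observed variances 0, p = 1
  set.seed(15)
  base <- array(rnorm(20 * 10 * 6), c(20, 10, 6, 1))
  arr <- array(NA_real_, c(20, 10, 6, 2))
  arr[, , , 1] <- base; arr[, , , 2] <- base
  ds <- averageReference(erpDataset(arr, dtMs = 4,
                                    conditionTags = c("A", "B")))
  templ <- orthoTemplates(3, 10, seed = 16)
  model <- new("MicrostateModel", templates = templ,
               polarityMode = "sensitive")
  st <- microstateTest(ds, twoLevelDesign(), model,
                       cfg = randConfig(nRuns = 29, seed = 17))
  expect_true(all(st@observed[, "duration_ms", 1] == 0 |
                    is.na(st@observed[, "duration_ms", 1])))
  expect_true(all(st@p == 1 | is.na(st@p)))
})
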