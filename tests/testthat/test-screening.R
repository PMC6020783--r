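test_that("baseline correction subtracts the window mean per channel", {
  arr <- array(5, c(10, 4, 2, 1))
  ds <- erpDataset(arr, dtMs = 4, conditionTags = "A")
  out <- baselineCorrect(ds, c(0, 36))
  expect_equal(max(abs(out@data)), 0)
  # already zero-mean-in-window data unchanged
  ds2 <- randomDataset(2, 1, 10, 4, seed = 1)
  ds2 <- baselineCorrect(ds2, c(0, 36))
  expect_equal(baselineCorrect(ds2, c(0, 36))@data, ds2@data)
  # single-sample window subtracts that sample
  ds3 <- randomDataset(2, 1, 10, 4, seed = 2)
  out3 <- baselineCorrect(ds3, c(8, 8))
  expect_equal(out3@data[3, , , ], ds3@data[3, , , ] * 0)
})

test_that("band-pass keeps in-band sinusoids and the notch removes its target", {
  fs <- 250; dt <- 1000 / fs
  t <- (0:499) / fs
  amp <- function(x, f) {
    # FFT amplitude oracle at frequency f
    n <- length(x)
    2 * Mod(stats::fft(x))[round(f * n / fs) + 1] / n
  }
  mk <- function(freq) {
    arr <- array(rep(sin(2 * pi * freq * t), 4), c(500, 4, 1, 1))
    erpDataset(arr, dtMs = dt, conditionTags = "A")
  }
  ds5 <- applyFilter(mk(5), lowCut = 1, highCut = 30)
  expect_gt(amp(ds5@data[, 1, 1, 1], 5), 0.95)
  ds50 <- applyFilter(mk(50), notch = 50)
  expect_lt(amp(ds50@data[, 1, 1, 1], 50), 0.1)
  # undo restores bit-identical data; specs are recorded
  ds <- mk(10)
  dsf <- applyFilter(ds, lowCut = 2, highCut = 40, notch = 50)
  expect_identical(undoFilter(dsf)@data, ds@data)
  expect_equal(filterSpecs(dsf)[[1]]$low_cut_hz, 2)
  expect_error(applyFilter(ds, highCut = 200), "Nyquist")
})

test_that("subject similarity is the correlation of vectorized data", {
  ds <- randomDataset(4, 2, 6, 5, seed = 3)
  ds@data[, , 2, ] <- ds@data[, , 1, ]           # identical subjects
  ds@data[, , 3, ] <- -ds@data[, , 1, ]          # negated subject
  s <- subjectSimilarity(ds)
  expect_equal(diag(s), rep(1, 4), ignore_attr = TRUE)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], -1)
  direct <- cor(as.numeric(ds@data[, , 1, ]), as.numeric(ds@data[, , 4, ]))
  expect_equal(s[1, 4], direct, tolerance = 1e-12)
  dsz <- ds; dsz@data[, , 2, ] <- 3   # constant vector
  expect_error(subjectSimilarity(dsz), "S02")
})

test_that("MDS reproduces rank-2 correlation structure and orders distances", {
  # three subjects with an exact 1-D structure
  set.seed(4)
  base <- rnorm(60)
  dir <- rnorm(60)
  V <- rbind(base, base + 0.5 * dir, base + 1.5 * dir)
  r <- cor(t(V))
  emb <- mdsEmbed(r)
  d <- sqrt(2 * (1 - r))
  dhat <- as.matrix(dist(emb@coords))
  expect_equal(dhat, as.matrix(stats::as.dist(d)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(emb@coords))), 1e-10)
  # identical subjects coincide
  r2 <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3)
  emb2 <- mdsEmbed(r2)
  expect_lt(sqrt(sum((emb2@coords[1, ] - emb2@coords[2, ])^2)), 1e-6)
  # distances decrease monotonically with correlation
  ds <- randomDataset(8, 2, 10, 6, seed = 5)
  s <- subjectSimilarity(ds)
  e <- mdsEmbed(s)
  dd <- as.matrix(dist(e@coords))
  i <- lower.tri(s)
  expect_lt(cor(s[i], dd[i], method = "spearman"), -0.5)
})

test_that("outlier auto-select flags planted outliers and spares clean clouds", {
  set.seed(6)
  # tight Gaussian cloud of 16 points: nothing flagged
  cloud <- matrix(rnorm(32), 16, 2)
  expect_length(flagOutliers(cloud, 0.05), 0)
  expect_error(flagOutliers(matrix(rnorm(8), 4, 2)), "at least 5")
  # one point 20 SD away is flagged nearly always
  hits <- 0L
  for (i in 1:100) {
    X <- rbind(matrix(rnorm(30), 15, 2), c(20, 0))
    fl <- flagOutliers(X, 0.05)
    if (16L %in% fl) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("false-flag rate of the auto-select is near alpha", {
  set.seed(7)
  flags <- replicate(400, length(flagOutliers(matrix(rnorm(32), 16, 2),
                                              0.05)) > 0)
  ci <- stats::binom.test(sum(flags), 400)$conf.int
  expect_lt(ci[1], 0.05)   # 5% inside (or above) the CI; test is slightly
  expect_gt(ci[2], 0.015)  # conservative by its Bonferroni construction
})

test_that("the screening table carries coordinates, distances and flags", {
  ds <- randomDataset(8, 2, 10, 6, seed = 8)
  tab <- screenSubjects(ds)
  expect_equal(nrow(tab), 8L)
  expect_named(tab, c("id", "mds_x", "mds_y", "mahalanobis", "flagged"))
  expect_true(all(!tab$flagged))
})
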