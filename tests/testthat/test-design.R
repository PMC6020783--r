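test_that("a 2 x 2 within design enumerates main effects and the interaction", {
  des <- erpDesign(list(expectancy = c(C1 = 1, C2 = 1, F1 = 2, F2 = 2),
                        day = c(C1 = 1, C2 = 2, F1 = 1, F2 = 2)),
                   conditionTags = c("C1", "C2", "F1", "F2"))
  expect_setequal(designEffects(des), c("expectancy", "day", "expectancy:day"))
  one <- erpDesign(list(f = c(a = 1, b = 2, c = 3)),
                   conditionTags = c("a", "b", "c"))
  expect_equal(designEffects(one), "f")
})

test_that("invalid designs are rejected", {
  # missing cell combination -> not fully crossed
  expect_error(erpDesign(list(f1 = c(A = 1, B = 1, C = 2),
                              f2 = c(A = 1, B = 2, C = 1)),
                         conditionTags = c("A", "B", "C")),
               "fully crossed|orthogonal")
  expect_error(erpDesign(list(f1 = c(A = 1)), conditionTags = c("A", "B")),
               "unassigned")
  expect_error(erpDesign(list(), conditionTags = "A"), "at least one factor")
})

test_that("between factor adds group effects and must cover all subjects", {
  des <- erpDesign(list(cond = c(A = 1, B = 2)), conditionTags = c("A", "B"),
                   betweenFactor = c(S1 = "g1", S2 = "g1", S3 = "g2",
                                     S4 = "g2"))
  expect_setequal(designEffects(des), c("cond", "group", "group:cond"))
  ds <- randomDataset(4, 2, 5, 6, seed = 1)
  expect_error(tanova(randomDataset(5, 2, 3, 4, seed = 2), des,
                      randConfig(nRuns = 5)), "cover")
})

test_that("effect cell means match direct averaging and zero out for identical data", {
  # hand-built 2-subject, 2-condition grid: oracle is direct arithmetic
  s1a <- matrix(c(1, -1, 2, -2), 2, byrow = TRUE)
  s1b <- matrix(c(3, -3, 0, 0), 2, byrow = TRUE)
  s2a <- matrix(c(5, -5, 2, -2), 2, byrow = TRUE)
  s2b <- matrix(c(1, -1, 4, -4), 2, byrow = TRUE)
  ds <- tinyDataset(list(S1 = list(A = s1a, B = s1b),
                         S2 = list(A = s2a, B = s2b)))
  des <- twoLevelDesign()
  cm <- effectCellMeans(ds, des, "cond")
  expect_equal(cm$levelMeans[, , 1], (s1a + s2a) / 2)
  expect_equal(cm$levelMeans[, , 2], (s1b + s2b) / 2)
  expect_equal(cm$overallMean, (s1a + s1b + s2a + s2b) / 4)
  # identical conditions: all deviations vanish
  dsEq <- tinyDataset(list(S1 = list(A = s1a, B = s1a),
                           S2 = list(A = s2a, B = s2a)))
  expect_equal(max(abs(effectCellMeans(dsEq, des, "cond")$deviations)), 0)
  # single subject: level mean equals that subject's data
  ds1 <- tinyDataset(list(S1 = list(A = s1a, B = s1b)))
  expect_equal(effectCellMeans(ds1, des, "cond")$levelMeans[, , 2], s1b)
})

test_that("cell means are invariant to subject ordering", {
  ds <- randomDataset(5, 4, 3, 6, seed = 11)
  des <- erpDesign(list(f1 = c(A = 1, B = 1, C = 2, D = 2),
                        f2 = c(A = 1, B = 2, C = 1, D = 2)),
                   conditionTags = LETTERS[1:4])
  cm1 <- effectCellMeans(ds, des, "f1:f2")
  perm <- c(3, 1, 5, 2, 4)
  ds2 <- ds
  ds2@data <- ds@data[, , perm, ]
  ds2@subjectIds <- ds@subjectIds[perm]
  cm2 <- effectCellMeans(ds2, des, "f1:f2")
  expect_equal(cm1$deviations, cm2$deviations)
})

test_that("interaction residuals are doubly centered for balanced designs", {
  ds <- randomDataset(6, 4, 4, 8, seed = 12)
  des <- erpDesign(list(f1 = c(A = 1, B = 1, C = 2, D = 2),
                        f2 = c(A = 1, B = 2, C = 1, D = 2)),
                   conditionTags = LETTERS[1:4])
  dev <- effectCellMeans(ds, des, "f1:f2")$deviations
  grid <- array(dev, c(dim(dev)[1:2], 2, 2))
  expect_lt(max(abs(apply(grid, c(1, 2, 3), sum))), 1e-10)
  expect_lt(max(abs(apply(grid, c(1, 2, 4), sum))), 1e-10)
  # raw interaction deviations do not double-center in general
  devRaw <- effectCellMeans(ds, des, "f1:f2", residualize = FALSE)$deviations
  gridRaw <- array(devRaw, c(dim(devRaw)[1:2], 2, 2))
  expect_gt(max(abs(apply(gridRaw, c(1, 2, 3), sum))), 1e-6)
})

test_that("within permutations are uniform over the permutation group", {
  des <- erpDesign(list(f = c(a = 1, b = 2, c = 3)),
                   conditionTags = c("a", "b", "c"))
  set.seed(99)
  draws <- replicate(10000, paste(
    permuteDesign(des, "S1", scope = "within")$condPerm[1, ], collapse = ""))
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("permutation scopes conserve labels and respect the design", {
  des <- erpDesign(list(cond = c(A = 1, B = 2)), conditionTags = c("A", "B"),
                   betweenFactor = c(S1 = "A", S2 = "A", S3 = "B"))
  set.seed(5)
  pa <- permuteDesign(des, c("S1", "S2", "S3"), scope = "between")
  groups <- c("A", "A", "B")[pa$groupPerm]
  expect_setequal(groups, c("A", "A", "B"))
  expect_equal(sort(table(groups)), sort(table(c("A", "A", "B"))),
               ignore_attr = TRUE)
  # each subject's within permutation is a bijection
  pw <- permuteDesign(des, c("S1", "S2", "S3"), scope = "within")
  for (s in 1:3) expect_setequal(pw$condPerm[s, ], 1:2)
  desNoGroup <- twoLevelDesign()
  expect_error(permuteDesign(desNoGroup, "S1", scope = "between"),
               "between-subject factor")
  # fixed seed reproduces the identical permutation stream
  set.seed(123); a <- replicate(5, permuteDesign(des, paste0("S", 1:3), "both"),
                                simplify = FALSE)
  set.seed(123); b <- replicate(5, permuteDesign(des, paste0("S", 1:3), "both"),
                                simplify = FALSE)
  expect_identical(a, b)
})

test_that("single-subject two-condition permutations are identity or swap equally", {
  des <- twoLevelDesign()
  set.seed(7)
  swaps <- replicate(10000,
    permuteDesign(des, "S1", scope = "within")$condPerm[1, 1] == 2L)
  expect_gt(stats::binom.test(sum(swaps), 10000, 0.5)$p.value, 0.001)
})

test_that("rank-scaled single factors use a centered linear contrast", {
  set.seed(21)
  ds <- randomDataset(4, 3, 5, 6, seed = 21)
  des <- erpDesign(list(dose = c(A = 1, B = 2, C = 3)),
                   conditionTags = LETTERS[1:3],
                   factorTypes = c(dose = "rank"))
  cm <- effectCellMeans(ds, des, "dose")
  w <- c(-1, 0, 1)
  lev <- sapply(1:3, function(co) apply(ds@data[, , , co], c(1, 2), mean),
                simplify = "array")
  contrast <- lev[, , 1] * w[1] + lev[, , 2] * w[2] + lev[, , 3] * w[3]
  expect_equal(dgfp(cm), sqrt(rowSums(contrast^2) / 6), tolerance = 1e-12)
})
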