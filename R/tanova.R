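# Topographic analysis of variance: per-time-point randomization test on the
# GFP of difference maps between factor levels, plus its GFP-test twin and the
# PCA state-space display.

# scope needed to randomize an effect
.effectScope <- function(info) {
  if (info$group && length(info$within)) "both"
  else if (info$group) "between"
  else "within"
}

# fast path shared by tanova() and gfpTest(): X is (tp*nch) x (ns*nc) with
# subject varying fastest along columns
.tanovaEngine <- function(X, tp, nch, ns, nc, design, effects, cfg,
                          residualize = TRUE, groups = NULL,
                          condTags = design@conditionTags) {
  .checkConditionCoverage(design, condTags)
  infos <- lapply(effects, .effectInfo, design = design)
  identityPerm <- matrix(rep(seq_len(nc), each = ns), ns, nc)
  obs <- matrix(NA_real_, tp, length(effects),
                dimnames = list(NULL, effects))
  for (e in seq_along(effects)) {
    dev <- .effectDeviations(X, ns, nc, design, infos[[e]], identityPerm,
                             groups, NULL, residualize, condTags)
    obs[, e] <- sqrt(rowSums(matrix(dev^2, tp)) / nch)
  }
  nRuns <- as.integer(cfg@nRuns)
  null <- array(NA_real_, c(nRuns, tp, length(effects)))
  needBetween <- any(vapply(infos, function(i) i$group, logical(1L)))
  for (r in seq_len(nRuns)) {
    condPerm <- t(vapply(seq_len(ns), function(s) sample.int(nc), integer(nc)))
    groupPerm <- if (needBetween) sample.int(ns) else NULL
    for (e in seq_along(effects)) {
      cp <- if (infos[[e]]$group && !length(infos[[e]]$within))
        identityPerm else condPerm
      gp <- if (infos[[e]]$group) groupPerm else NULL
      dev <- .effectDeviations(X, ns, nc, design, infos[[e]], cp, groups, gp,
                               residualize, condTags)
      null[r, , e] <- sqrt(rowSums(matrix(dev^2, tp)) / nch)
    }
  }
  p <- matrix(NA_real_, tp, length(effects), dimnames = list(NULL, effects))
  for (e in seq_along(effects)) {
    b <- colSums(null[, , e, drop = FALSE][, , 1L] >=
                   matrix(obs[, e], nRuns, tp, byrow = TRUE))
    p[, e] <- if (cfg@legacyP) b / nRuns else (1 + b) / (nRuns + 1)
  }
  list(observed = obs, p = p, null = null)
}

#' Topographic analysis of variance
#'
#' For every effect of the design and every time point, tests the GFP of the
#' difference maps between factor-level mean maps (dGFP, see [dgfp()]) against
#' its distribution under random reassignment: factor levels are shuffled
#' independently within each subject (and group labels across subjects for
#' between effects), the dGFP is recomputed, and the p-value is the add-one
#' proportion of runs reaching the observed value. One shared permutation
#' stream serves all effects, so the retained null distribution can be
#' recycled by the overall statistics.
#'
#' With `cfg@normalize` every subject x condition map is divided by its GFP
#' first, so significant results reflect purely topographic (qualitative)
#' differences; pair with [gfpTest()] for the quantitative counterpart.
#'
#' @param ds an average-referenced, complete [ErpDataset-class].
#' @param design an [ErpDesign-class].
#' @param cfg a [RandConfig-class].
#' @param effects subset of `designEffects(design)` (default all).
#' @param interaction `"residualized"` (both marginal main-effect patterns
#'   subtracted before dGFP) or `"raw"` cell deviations.
#' @return a [TanovaResult-class].
#' @export
tanova <- function(ds, design, cfg = randConfig(),
                   effects = designEffects(design),
                   interaction = c("residualized", "raw")) {
  interaction <- match.arg(interaction)
  a <- ds@data
  if (cfg@normalize) a <- .normalizeArray(a)
  d <- dim(a)
  X <- matrix(a, nrow = d[1L] * d[2L])
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  groups <- .designGroups(design, ds@subjectIds)
  res <- .tanovaEngine(X, d[1L], d[2L], d[3L], d[4L], design, effects, cfg,
                       residualize = interaction == "residualized",
                       groups = groups, condTags = ds@conditionTags)
  new("TanovaResult", observed = res$observed, p = res$p, null = res$null,
      time = sampleTimes(ds), effects = effects, statistic = "dgfp",
      cfg = cfg)
}

#' GFP randomization test
#'
#' The quantitative twin of [tanova()]: the identical permutation machinery
#' applied to the scalar GFP of each subject x condition map, i.e. the scaling
#' factor removed by normalization. A significant GFP test without a
#' normalized-TANOVA effect indicates a pure strength (quantitative)
#' difference in the active sources.
#'
#' @inheritParams tanova
#' @return a [TanovaResult-class] with `statistic = "gfp"`.
#' @export
gfpTest <- function(ds, design, cfg = randConfig(),
                    effects = designEffects(design),
                    interaction = c("residualized", "raw")) {
  interaction <- match.arg(interaction)
  d <- dim(ds@data)
  mu <- apply(ds@data, c(1L, 3L, 4L), mean)
  g <- sqrt(apply((ds@data - aperm(
    array(mu, c(d[c(1L, 3L, 4L)], d[2L])), c(1L, 4L, 2L, 3L)))^2,
    c(1L, 3L, 4L), mean))                       # tp x ns x nc of map GFPs
  X <- matrix(g, nrow = d[1L])
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  groups <- .designGroups(design, ds@subjectIds)
  res <- .tanovaEngine(X, d[1L], 1L, d[3L], d[4L], design, effects, cfg,
                       residualize = interaction == "residualized",
                       groups = groups, condTags = ds@conditionTags)
  new("TanovaResult", observed = res$observed, p = res$p, null = res$null,
      time = sampleTimes(ds), effects = effects, statistic = "gfp", cfg = cfg)
}

#' TANOVA on window-averaged maps
#'
#' Maps are averaged across an analysis window before the identical test,
#' yielding a single p-value per effect: the a-priori-window form of the
#' TANOVA (or of the GFP test with `statistic = "gfp"`).
#'
#' @inheritParams tanova
#' @param window `c(from, to)` in ms, inclusive.
#' @param statistic `"dgfp"` or `"gfp"`.
#' @return a [TanovaResult-class] with a single time point (the window
#'   center).
#' @export
windowAverageTest <- function(ds, design, window, cfg = randConfig(),
                              effects = designEffects(design),
                              statistic = c("dgfp", "gfp"),
                              interaction = c("residualized", "raw")) {
  statistic <- match.arg(statistic)
  idx <- windowSamples(ds, window)
  a <- ds@data
  if (statistic == "dgfp" && cfg@normalize) a <- .normalizeArray(a)
  avg <- apply(a[idx, , , , drop = FALSE], c(2L, 3L, 4L), mean)
  d2 <- c(1L, dim(avg))
  ds2 <- ds
  ds2@data <- array(avg, d2)
  ds2@t0 <- mean(sampleTimes(ds)[idx])
  cfg2 <- cfg
  cfg2@normalize <- FALSE   # normalization already applied to the full maps
  if (statistic == "gfp") gfpTest(ds2, design, cfg2, effects, interaction)
  else tanova(ds2, design, cfg2, effects, interaction)
}

#' PCA state-space projection of a set of mean maps
#'
#' Rotates the n-channel state space so that its projection onto two
#' dimensions is maximally informative about the relationships among a set of
#' maps: coordinates are the scores of the first two principal components, and
#' the component maps themselves are returned for axis display.
#'
#' @param maps numeric matrix, one map per row.
#' @return list with `coords` (maps x 2 scores), `components` (2 x channel
#'   eigenvector maps) and `varExplained` (fraction per component).
#' @export
pcaProjection <- function(maps) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 2L) stop("need at least 2 maps")
  pc <- stats::prcomp(maps, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, 0)
  comps <- t(pc$rotation[, seq_len(k), drop = FALSE])
  ev <- pc$sdev^2
  list(coords = coords, components = comps,
       varExplained = ev[seq_len(k)] / max(sum(ev), .Machine$double.eps))
}
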