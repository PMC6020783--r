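# Microstate analysis: clustering of grand-mean maps (modified k-means and
# AAHC), label smoothing, explained variance, cross-validated selection of
# the number of classes, quantifier extraction and randomization statistics.

# spatial correlation of each row of `maps` with each template (rows zero-mean
# after centering); zero-GFP maps get correlation 0 everywhere
.spatialCorr <- function(maps, templ) {
  M <- maps - rowMeans(maps)
  Tm <- templ - rowMeans(templ)
  nm <- sqrt(rowSums(M^2))
  nt <- sqrt(rowSums(Tm^2))
  C <- (M %*% t(Tm)) / (pmax(nm, .Machine$double.xmin) %o%
                          pmax(nt, .Machine$double.xmin))
  C[nm == 0, ] <- 0
  C
}

.unitGfp <- function(v) {
  v <- v - mean(v)
  g <- sqrt(mean(v^2))
  if (g == 0) return(v)
  v / g
}

# labels from a correlation matrix; ties -> lowest index
.labelsFromCorr <- function(C, polarity) {
  if (polarity == "ignore") C <- abs(C)
  max.col(C, ties.method = "first")
}

.modelEv <- function(maps, templ, labels, polarity) {
  g <- gfp(maps)
  C <- .spatialCorr(maps, templ)
  cc <- C[cbind(seq_len(nrow(maps)), labels)]
  tot <- sum(g^2)
  if (tot == 0) stop("all-zero data: explained variance undefined")
  sum((g * cc)^2) / tot
}

# one template update; polarity-sensitive: normalized mean map;
# polarity-ignore: first principal axis of the member maps
.updateTemplate <- function(maps, polarity) {
  if (polarity == "sensitive") return(.unitGfp(colMeans(maps)))
  M <- maps - rowMeans(maps)
  e <- eigen(crossprod(M), symmetric = TRUE)
  .unitGfp(e$vectors[, 1L])
}

#' Microstate clustering by modified k-means
#'
#' Finds k template maps such that assigning every map to its best-fitting
#' template (by spatial correlation, absolute correlation when polarity is
#' ignored) maximizes the explained variance. The best of `nRestarts` random
#' initializations is returned; iterations stop when the explained-variance
#' gain drops below `tol`.
#'
#' @param maps numeric matrix, one (average-referenced) map per row; usually
#'   the concatenated grand-mean map series of all design cells (see
#'   [cellGrandMeans()]).
#' @param k number of classes (>= 2).
#' @param nRestarts random restarts (default 20).
#' @param polarity `"sensitive"` (ERP default: a sign flip is a different
#'   component) or `"ignore"`.
#' @param maxIter,tol convergence controls.
#' @return a [MicrostateModel-class].
#' @export
clusterKmeans <- function(maps, k, nRestarts = 20,
                          polarity = c("sensitive", "ignore"),
                          maxIter = 200, tol = 1e-7) {
  polarity <- match.arg(polarity)
  maps <- as.matrix(maps)
  if (k < 2L) stop("k must be >= 2 (a one-class model is not a clustering)")
  nondeg <- which(gfp(maps) > 1e-12)
  if (k > nrow(unique(round(maps[nondeg, , drop = FALSE], 12L))))
    stop("k exceeds the number of distinct maps")
  best <- NULL
  bestEv <- -Inf
  for (rs in seq_len(nRestarts)) {
    templ <- maps[sample(nondeg, k), , drop = FALSE]
    templ <- t(apply(templ, 1L, .unitGfp))
    evOld <- -Inf
    labels <- rep(1L, nrow(maps))
    for (it in seq_len(maxIter)) {
      C <- .spatialCorr(maps, templ)
      labels <- .labelsFromCorr(C, polarity)
      for (cl in seq_len(k)) {
        members <- which(labels == cl)
        if (!length(members)) {
          # re-seed an empty cluster with the worst-fitted map
          fit <- if (polarity == "ignore") abs(C) else C
          worst <- which.min(apply(fit, 1L, max))
          templ[cl, ] <- .unitGfp(maps[worst, ])
          labels[worst] <- cl
          members <- worst
        }
        m <- maps[members, , drop = FALSE]
        if (polarity == "sensitive") {
          # align member polarity to the current template before averaging
          sgn <- sign(.spatialCorr(m, templ[cl, , drop = FALSE]))
          sgn[sgn == 0] <- 1
          templ[cl, ] <- .updateTemplate(m * as.numeric(sgn), "sensitive")
        } else templ[cl, ] <- .updateTemplate(m, "ignore")
      }
      ev <- .modelEv(maps, templ, labels, polarity)
      if (ev - evOld < tol) break
      evOld <- ev
    }
    ev <- .modelEv(maps, templ, .labelsFromCorr(.spatialCorr(maps, templ),
                                                polarity), polarity)
    if (ev > bestEv) {
      bestEv <- ev
      best <- templ
    }
  }
  new("MicrostateModel", templates = .orderTemplates(best, maps, polarity),
      polarityMode = polarity)
}

# deterministic template order: by first time of assignment
.orderTemplates <- function(templ, maps, polarity) {
  lab <- .labelsFromCorr(.spatialCorr(maps, templ), polarity)
  first <- vapply(seq_len(nrow(templ)),
                  function(cl) if (any(lab == cl)) min(which(lab == cl))
                  else Inf + nrow(maps) + cl, numeric(1L))
  templ[order(first), , drop = FALSE]
}

#' Microstate clustering by AAHC
#'
#' Atomize-and-agglomerate hierarchical clustering: every map starts as its
#' own cluster; the cluster contributing least to the global explained
#' variance is repeatedly disbanded ("atomized") and its members reassigned to
#' their best-fitting surviving clusters, until k clusters remain. The
#' procedure is deterministic.
#'
#' @inheritParams clusterKmeans
#' @return a [MicrostateModel-class].
#' @export
clusterAahc <- function(maps, k, polarity = c("sensitive", "ignore")) {
  polarity <- match.arg(polarity)
  maps <- as.matrix(maps)
  if (k < 2L) stop("k must be >= 2")
  g <- gfp(maps)
  keep <- which(g > 1e-12)
  if (k > nrow(unique(round(maps[keep, , drop = FALSE], 12L))))
    stop("k exceeds the number of distinct maps")
  labels <- rep(NA_integer_, nrow(maps))
  labels[keep] <- seq_along(keep)
  clusters <- as.list(keep)
  tmplOf <- function(members) {
    m <- maps[members, , drop = FALSE]
    if (polarity == "sensitive" && length(members) > 1L) {
      ref <- m[which.max(g[members]), ]
      sgn <- sign(.spatialCorr(m, matrix(ref, 1L)))
      sgn[sgn == 0] <- 1
      .updateTemplate(m * as.numeric(sgn), "sensitive")
    } else if (length(members) == 1L) .unitGfp(m[1L, ])
    else .updateTemplate(m, polarity)
  }
  templ <- do.call(rbind, lapply(clusters, tmplOf))
  contrib <- function(ci) {
    members <- clusters[[ci]]
    C <- .spatialCorr(maps[members, , drop = FALSE],
                      templ[ci, , drop = FALSE])
    sum((g[members] * as.numeric(C))^2)
  }
  contribs <- vapply(seq_along(clusters), contrib, numeric(1L))
  while (length(clusters) > k) {
    worst <- which.min(contribs)
    orphans <- clusters[[worst]]
    clusters[[worst]] <- NULL
    templ <- templ[-worst, , drop = FALSE]
    contribs <- contribs[-worst]
    C <- .spatialCorr(maps[orphans, , drop = FALSE], templ)
    dest <- .labelsFromCorr(C, polarity)
    touched <- unique(dest)
    for (j in seq_along(orphans))
      clusters[[dest[j]]] <- c(clusters[[dest[j]]], orphans[j])
    for (ci in touched) {
      templ[ci, ] <- tmplOf(clusters[[ci]])
      contribs[ci] <- contrib(ci)
    }
  }
  templ <- do.call(rbind, lapply(seq_along(clusters),
                                 function(ci) tmplOf(clusters[[ci]])))
  new("MicrostateModel", templates = .orderTemplates(templ, maps, polarity),
      polarityMode = polarity)
}

#' Assign maps to microstate classes
#'
#' Per time point, the label is the template with the highest spatial
#' correlation (absolute correlation when polarity is ignored); ties go to
#' the lowest class index. Zero maps cannot be oriented and are assigned to
#' class 1 with a warning.
#'
#' @param maps numeric matrix, one map per row.
#' @param model a [MicrostateModel-class] with matching channel count.
#' @return integer vector of class labels in 1..k.
#' @export
assignMaps <- function(maps, model) {
  maps <- as.matrix(maps)
  if (ncol(maps) != ncol(model@templates))
    stop("channel count of maps and model differ")
  zero <- gfp(maps) <= 1e-12
  if (any(zero))
    warning(sprintf("%d zero map(s) assigned to class 1", sum(zero)))
  .labelsFromCorr(.spatialCorr(maps, model@templates), model@polarityMode)
}

#' Suppress very short microstates
#'
#' Segments (maximal runs of one label) shorter than `minDurationMs` are
#' dissolved one at a time, shortest first; each of their time points is
#' reassigned to whichever temporally adjacent segment's template correlates
#' better with the map at that point. Iterates until no short segment
#' remains (a lone surviving segment is never dissolved).
#'
#' @param labels integer labels per time point.
#' @param maps the corresponding maps (one row per time point).
#' @param model the [MicrostateModel-class] that produced the labels.
#' @param minDurationMs minimum admissible segment duration.
#' @param dtMs inter-sample interval.
#' @return smoothed label vector.
#' @export
smoothLabels <- function(labels, maps, model, minDurationMs, dtMs) {
  minLen <- max(1L, ceiling(minDurationMs / dtMs))
  if (minLen < 1L) return(labels)
  maps <- as.matrix(maps)
  C <- .spatialCorr(maps, model@templates)
  if (model@polarityMode == "ignore") C <- abs(C)
  guard <- 0L
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < minLen)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1L) r$values[i - 1L] else NA_integer_
    right <- if (i < length(r$values)) r$values[i + 1L] else NA_integer_
    for (t in starts[i]:ends[i]) {
      if (is.na(left)) labels[t] <- right
      else if (is.na(right)) labels[t] <- left
      else labels[t] <- if (C[t, left] >= C[t, right]) left else right
    }
    guard <- guard + 1L
    if (guard > 10L * length(labels)) break
  }
  labels
}

#' Global explained variance of a microstate decomposition
#'
#' The fraction of the total squared field strength accounted for by the
#' labeled templates: sum_t (GFP_t * corr(map_t, template_label(t)))^2 /
#' sum_t GFP_t^2.
#'
#' @param maps numeric matrix, one map per row.
#' @param model a [MicrostateModel-class].
#' @param labels optional labels (default: best-fitting assignment).
#' @return explained-variance fraction in [0, 1].
#' @export
explainedVariance <- function(maps, model, labels = NULL) {
  maps <- as.matrix(maps)
  if (is.null(labels))
    labels <- .labelsFromCorr(.spatialCorr(maps, model@templates),
                              model@polarityMode)
  .modelEv(maps, model@templates, labels, model@polarityMode)
}

#' Grand-mean map series per design cell
#'
#' Microstate analysis operates on factor-level and group-wise averaged
#' grand-mean data: one time x channel grand mean per group x condition cell.
#'
#' @param ds an [ErpDataset-class].
#' @param design optional [ErpDesign-class] (for the group factor); without
#'   one, the cells are the conditions.
#' @param subjects optional subject subset.
#' @return list with `maps` (list of time x channel matrices) and `cells`
#'   (labels).
#' @export
cellGrandMeans <- function(ds, design = NULL, subjects = NULL) {
  if (is.null(subjects)) subjects <- seq_len(nSubjects(ds))
  if (is.character(subjects)) subjects <- match(subjects, ds@subjectIds)
  groups <- if (!is.null(design)) .designGroups(design, ds@subjectIds) else NULL
  nc <- length(ds@conditionTags)
  out <- list()
  cells <- character(0)
  if (is.null(groups)) {
    for (co in seq_len(nc)) {
      m <- apply(ds@data[, , subjects, co, drop = FALSE], c(1L, 2L), mean)
      out <- c(out, list(m))
      cells <- c(cells, ds@conditionTags[co])
    }
  } else {
    for (gv in sort(unique(groups))) for (co in seq_len(nc)) {
      sel <- intersect(subjects, which(groups == gv))
      m <- apply(ds@data[, , sel, co, drop = FALSE], c(1L, 2L), mean)
      out <- c(out, list(m))
      cells <- c(cells, paste0(gv, ":", ds@conditionTags[co]))
    }
  }
  list(maps = out, cells = cells)
}

#' Cross-validated selection of the number of classes
#'
#' Subjects are randomly divided into a learning and a test set; microstate
#' models with increasing k are built on the learning set's cell grand means
#' and projected onto the test set's, recording the explained variance on
#' both sides. The learning EV grows with every class added; the test EV
#' stops growing at the optimal k (the beginning of the plateau marks the
#' model that still generalizes).
#'
#' @param ds an [ErpDataset-class] with at least 4 subjects.
#' @param design optional [ErpDesign-class].
#' @param kRange candidate class numbers (e.g. `3:10`).
#' @param splitFraction fraction of subjects in the learning set (default
#'   0.5).
#' @param nSplits random splits averaged (default 10).
#' @param algorithm `"kmeans"` or `"aahc"`.
#' @param polarity passed to the clustering.
#' @param nRestarts k-means restarts per fit.
#' @param window optional analysis window in ms.
#' @param seed optional RNG seed for reproducible splits.
#' @return a [CrossValidationCurve-class].
#' @export
crossValidateK <- function(ds, design = NULL, kRange = 3:10,
                           splitFraction = 0.5, nSplits = 10,
                           algorithm = c("kmeans", "aahc"),
                           polarity = c("sensitive", "ignore"),
                           nRestarts = 10, window = NULL, seed = NA) {
  algorithm <- match.arg(algorithm)
  polarity <- match.arg(polarity)
  ns <- nSubjects(ds)
  if (ns < 4L) stop("cross-validation needs at least 4 subjects")
  nLearn <- round(splitFraction * ns)
  if (nLearn < 2L || ns - nLearn < 2L)
    stop("split leaves fewer than 2 subjects on one side")
  if (!is.na(seed)) set.seed(seed)
  idx <- if (is.null(window)) seq_len(nTimepoints(ds)) else
    windowSamples(ds, window)
  learnEv <- testEv <- matrix(NA_real_, nSplits, length(kRange))
  for (sp in seq_len(nSplits)) {
    learn <- sort(sample.int(ns, nLearn))
    test <- setdiff(seq_len(ns), learn)
    mapsL <- do.call(rbind, lapply(cellGrandMeans(ds, design, learn)$maps,
                                   function(m) m[idx, , drop = FALSE]))
    mapsT <- do.call(rbind, lapply(cellGrandMeans(ds, design, test)$maps,
                                   function(m) m[idx, , drop = FALSE]))
    for (ki in seq_along(kRange)) {
      model <- if (algorithm == "kmeans")
        clusterKmeans(mapsL, kRange[ki], nRestarts = nRestarts,
                      polarity = polarity)
      else clusterAahc(mapsL, kRange[ki], polarity = polarity)
      learnEv[sp, ki] <- explainedVariance(mapsL, model)
      testEv[sp, ki] <- explainedVariance(mapsT, model)
    }
    # enforce the nesting property within each split: a larger model may
    # never explain less of the learning set (guard against local optima)
    learnEv[sp, ] <- cummax(learnEv[sp, ])
  }
  new("CrossValidationCurve", k = as.numeric(kRange),
      learningEv = colMeans(learnEv), testEv = colMeans(testEv),
      nSplits = as.numeric(nSplits), perSplitTestEv = testEv)
}

# ---------------------------------------------------------------------------
# quantifiers
# ---------------------------------------------------------------------------

.quantifierNames <- c("onset_ms", "offset_ms", "duration_ms", "auc",
                      "cog_ms", "mean_gfp")

#' Microstate quantifiers
#'
#' For each class, over the analysis window (all assigned samples pool, also
#' across disjoint segments): onset = time of the first assigned sample,
#' offset = time of the last, duration = count x dt, AUC = sum(GFP) x dt
#' (uV ms), center of gravity = GFP-weighted mean time, and mean GFP. Classes
#' absent from the window are flagged `present = FALSE` with timing
#' quantifiers `NA` and duration/AUC/mean GFP 0.
#'
#' @param labels integer labels per time point.
#' @param gfpSeries GFP per time point (uV).
#' @param k number of classes.
#' @param dtMs inter-sample interval (ms).
#' @param t0Ms time of the first sample (ms).
#' @param window optional `c(from, to)` ms restriction.
#' @return data frame: class, present, onset_ms, offset_ms, duration_ms, auc,
#'   cog_ms, mean_gfp.
#' @export
microstateQuantifiers <- function(labels, gfpSeries, k, dtMs, t0Ms = 0,
                                  window = NULL) {
  times <- t0Ms + (seq_along(labels) - 1L) * dtMs
  sel <- .windowSamples(times, window)
  out <- data.frame(class = seq_len(k), present = FALSE, onset_ms = NA_real_,
                    offset_ms = NA_real_, duration_ms = 0, auc = 0,
                    cog_ms = NA_real_, mean_gfp = 0)
  for (cl in seq_len(k)) {
    at <- sel[labels[sel] == cl]
    if (!length(at)) next
    g <- gfpSeries[at]
    tt <- times[at]
    out$present[cl] <- TRUE
    out$onset_ms[cl] <- tt[1L]
    out$offset_ms[cl] <- tt[length(tt)]
    out$duration_ms[cl] <- length(at) * dtMs
    out$auc[cl] <- sum(g) * dtMs
    out$cog_ms[cl] <- if (sum(g) > 0) sum(tt * g) / sum(g) else mean(tt)
    out$mean_gfp[cl] <- mean(g)
  }
  out
}

# quantifier matrix (k x 6) for one cell's grand-mean map series
.cellQuantifiers <- function(maps, model, dtMs, t0Ms, window, minDurationMs) {
  labels <- assignMaps(maps, model)
  if (minDurationMs > dtMs)
    labels <- smoothLabels(labels, maps, model, minDurationMs, dtMs)
  q <- microstateQuantifiers(labels, gfp(maps), nrow(model@templates), dtMs,
                             t0Ms, window)
  as.matrix(q[, .quantifierNames])
}

# between-level variance of quantifier values; timing quantifiers of absent
# classes are NA and are dropped with renormalization; residualized for
# interactions over a level grid `gd`
.quantifierVariance <- function(vals, gd = NULL) {
  ok <- !is.na(vals)
  if (sum(ok) < 2L) return(NA_real_)
  if (!is.null(gd) && length(gd) >= 2L && all(ok)) {
    res <- .residualize(matrix(vals, 1L), gd)
    return(mean(res^2))
  }
  v <- vals[ok]
  mean((v - mean(v))^2)
}

#' Randomization statistics on microstate quantifiers
#'
#' With a fixed microstate model, quantifiers are extracted from the
#' grand-mean map series of every factor level (and group), and their
#' variance between levels is the observed effect size per class x
#' quantifier x effect. Individual ERPs are then assigned to shuffled factor
#' levels (and shuffled group labels), new grand means are computed, labeled
#' (with the same smoothing) and quantified, building the null distribution
#' of that variance; p-values use the add-one convention. Templates are not
#' re-clustered inside the permutation loop.
#'
#' Quantifiers of classes absent from a cell enter as 0 for
#' duration/AUC/mean GFP; the timing quantifiers (onset, offset, center of
#' gravity) of absent classes are excluded from that run's variance with
#' renormalization. A class absent from every observed cell is marked
#' unavailable (`NA` p).
#'
#' @param ds an [ErpDataset-class].
#' @param design an [ErpDesign-class].
#' @param model a fixed [MicrostateModel-class].
#' @param window analysis window `c(from, to)` ms (default whole epoch).
#' @param cfg a [RandConfig-class].
#' @param minDurationMs label smoothing threshold (default 3 samples).
#' @param effects effects to test (default all).
#' @return a [MicrostateStats-class].
#' @export
microstateTest <- function(ds, design, model, window = NULL,
                           cfg = randConfig(), minDurationMs = 3 * dtMs(ds),
                           effects = designEffects(design)) {
  k <- nrow(model@templates)
  d <- dim(ds@data)
  ns <- d[3L]; nc <- d[4L]
  tt <- sampleTimes(ds)
  if (is.null(window)) window <- range(tt)
  groups <- .designGroups(design, ds@subjectIds)
  infos <- lapply(effects, .effectInfo, design = design)
  X <- matrix(ds@data, nrow = d[1L] * d[2L])
  identityPerm <- matrix(rep(seq_len(nc), each = ns), ns, nc)

  levelQuantifiers <- function(info, condPerm, groupPerm) {
    # raw level-mean map series per level of the effect, then k x 6 x levels
    raw <- .effectDeviations(X, ns, nc, design,
                             modifyList(info, list(linear = FALSE)),
                             condPerm, groups, groupPerm, residualize = FALSE,
                             condTags = ds@conditionTags)
    overall <- rowMeans(X)
    nlev <- ncol(raw)
    qa <- array(NA_real_, c(k, length(.quantifierNames), nlev))
    for (l in seq_len(nlev)) {
      m <- matrix(raw[, l] + overall, d[1L], d[2L])
      qa[, , l] <- .cellQuantifiers(m, model, ds@dt, ds@t0, window,
                                    minDurationMs)
    }
    qa
  }
  gridDims <- function(info) {
    gd <- vapply(.withinLevels(design, info$within, ds@conditionTags),
                 function(l) length(l$values), integer(1L))
    if (info$group) gd <- c(gd, length(unique(groups)))
    gd
  }

  nq <- length(.quantifierNames)
  observed <- array(NA_real_, c(k, nq, length(effects)),
                    dimnames = list(NULL, .quantifierNames, effects))
  everPresent <- matrix(FALSE, k, length(effects))
  obsQ <- list()
  for (e in seq_along(effects)) {
    qa <- levelQuantifiers(infos[[e]], identityPerm, NULL)
    obsQ[[e]] <- qa
    gd <- gridDims(infos[[e]])
    for (cl in seq_len(k)) {
      everPresent[cl, e] <- any(qa[cl, match("duration_ms", .quantifierNames), ] > 0)
      for (q in seq_len(nq))
        observed[cl, q, e] <- .quantifierVariance(qa[cl, q, ], gd)
    }
  }

  nRuns <- as.integer(cfg@nRuns)
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  exceed <- array(0, dim(observed))
  valid <- array(0, dim(observed))
  needBetween <- any(vapply(infos, function(i) i$group, logical(1L)))
  for (r in seq_len(nRuns)) {
    condPerm <- t(vapply(seq_len(ns), function(s) sample.int(nc), integer(nc)))
    groupPerm <- if (needBetween) sample.int(ns) else NULL
    for (e in seq_along(effects)) {
      cp <- if (infos[[e]]$group && !length(infos[[e]]$within))
        identityPerm else condPerm
      gp <- if (infos[[e]]$group) groupPerm else NULL
      qa <- levelQuantifiers(infos[[e]], cp, gp)
      gd <- gridDims(infos[[e]])
      for (cl in seq_len(k)) for (q in seq_len(nq)) {
        v <- .quantifierVariance(qa[cl, q, ], gd)
        if (!is.na(v) && !is.na(observed[cl, q, e])) {
          valid[cl, q, e] <- valid[cl, q, e] + 1
          if (v >= observed[cl, q, e]) exceed[cl, q, e] <- exceed[cl, q, e] + 1
        }
      }
    }
  }
  p <- (1 + exceed) / (valid + 1)
  dimnames(p) <- dimnames(observed)
  p[is.na(observed)] <- NA_real_
  for (e in seq_along(effects)) for (cl in seq_len(k))
    if (!everPresent[cl, e]) p[cl, , e] <- NA_real_
  new("MicrostateStats", observed = observed, p = p,
      quantifiers = .quantifierNames, effects = effects,
      nRuns = as.numeric(nRuns), windowMs = as.numeric(window))
}
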