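# Experimental designs and the permutations that define every null
# distribution.

#' Define an experimental design
#'
#' Up to two orthogonal within-subject factors (each assigning every condition
#' a level code) and an optional between-subject group factor. All testable
#' effects are enumerated: every within main effect, the within x within
#' interaction, the group effect, and group x within interactions. A single
#' within factor may be declared `rank` or `interval` scaled, in which case
#' its test statistic is a linear contrast across the centered level values.
#'
#' @param withinFactors named list; each element a named numeric vector
#'   mapping condition tags to level codes, e.g.
#'   `list(expectancy = c(C1 = 1, C2 = 1, F1 = 2, F2 = 2))`.
#' @param conditionTags all condition tags of the dataset.
#' @param betweenFactor optional named character vector, subject id -> group.
#' @param factorTypes optional named character vector per within factor,
#'   `"categorical"` (default), `"rank"` or `"interval"`.
#' @return an [ErpDesign-class].
#' @export
erpDesign <- function(withinFactors = list(), conditionTags,
                      betweenFactor = NULL, factorTypes = NULL) {
  fn <- names(withinFactors)
  if (length(withinFactors) && is.null(fn))
    stop("withinFactors must be a named list")
  types <- stats::setNames(rep("categorical", length(fn)), fn)
  if (!is.null(factorTypes)) types[names(factorTypes)] <- factorTypes
  for (f in fn) {
    miss <- setdiff(conditionTags, names(withinFactors[[f]]))
    if (length(miss))
      stop(sprintf("factor '%s' leaves condition(s) %s unassigned", f,
                   paste(miss, collapse = ", ")))
  }
  effects <- fn
  if (length(fn) == 2L) effects <- c(effects, paste(fn, collapse = ":"))
  if (!is.null(betweenFactor)) {
    betweenFactor <- stats::setNames(as.character(betweenFactor),
                                     names(betweenFactor))
    effects <- c(effects, "group", if (length(fn)) paste0("group:", fn),
                 if (length(fn) == 2L) paste0("group:", paste(fn, collapse = ":")))
  }
  if (!length(effects)) stop("a design needs at least one factor")
  new("ErpDesign", withinFactors = withinFactors, factorTypes = types,
      betweenFactor = betweenFactor, conditionTags = as.character(conditionTags),
      effects = effects)
}

# every dataset condition must have a level on every factor
.checkConditionCoverage <- function(design, condTags) {
  for (f in names(design@withinFactors)) {
    lev <- design@withinFactors[[f]]
    miss <- setdiff(condTags, names(lev))
    if (length(miss))
      stop(sprintf("design factor '%s' does not cover condition(s): %s", f,
                   paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

# group labels aligned with a dataset's subjects
.designGroups <- function(design, subjectIds) {
  if (is.null(design@betweenFactor)) return(NULL)
  g <- design@betweenFactor[subjectIds]
  if (anyNA(g))
    stop("between factor does not cover subject(s): ",
         paste(subjectIds[is.na(g)], collapse = ", "))
  unname(g)
}

#' Draw a random permuted assignment
#'
#' One randomization run's reassignment: an independent uniform permutation of
#' each subject's condition labels (`within` scope), a uniform permutation of
#' the group labels across subjects (`between` scope), or both. The identity
#' assignment is the observed data.
#'
#' @param design an [ErpDesign-class].
#' @param subjectIds the dataset's subjects (the between factor must cover
#'   them when between scope is requested).
#' @param scope `"within"`, `"between"` or `"both"`.
#' @return list with `condPerm` (subject x condition matrix: data condition j
#'   of subject s is treated as condition `condPerm[s, j]`) and `groupPerm`
#'   (permutation of subjects applied to the group labels, or `NULL`).
#' @export
permuteDesign <- function(design, subjectIds,
                          scope = c("within", "between", "both")) {
  scope <- match.arg(scope)
  ns <- length(subjectIds)
  nc <- length(design@conditionTags)
  condPerm <- matrix(rep(seq_len(nc), each = ns), ns, nc)
  groupPerm <- NULL
  if (scope %in% c("within", "both"))
    condPerm <- t(vapply(seq_len(ns), function(s) sample.int(nc),
                         integer(nc)))
  if (scope %in% c("between", "both")) {
    if (is.null(design@betweenFactor))
      stop("between scope requires a between-subject factor")
    groupPerm <- sample.int(ns)
  }
  list(condPerm = condPerm, groupPerm = groupPerm)
}

# ---------------------------------------------------------------------------
# effect machinery
# ---------------------------------------------------------------------------

# parse an effect id into its ingredients
.effectInfo <- function(design, effect) {
  if (!effect %in% design@effects)
    stop(sprintf("effect '%s' is not part of the design (%s)", effect,
                 paste(design@effects, collapse = ", ")))
  parts <- strsplit(effect, ":", fixed = TRUE)[[1L]]
  group <- "group" %in% parts
  within <- setdiff(parts, "group")
  linear <- length(within) == 1L && !group &&
    design@factorTypes[[within]] != "categorical"
  list(within = within, group = group, linear = linear)
}

# per-condition level index for each involved within factor (conditions in
# dataset order); list of integer vectors plus level value tables
.withinLevels <- function(design, within, conditionTags) {
  lapply(within, function(f) {
    lev <- design@withinFactors[[f]][conditionTags]
    vals <- sort(unique(lev))
    list(index = match(lev, vals), values = vals)
  })
}

# inclusion-exclusion centering of a (cells-grid) matrix M (rows = anything,
# cols = cells laid out as an array of dim `gd`); full factorial residual
.residualize <- function(M, gd) {
  nf <- length(gd)
  if (nf == 1L) return(M - rowMeans(M))
  res <- M
  for (sz in (nf - 1L):0L) {
    combs <- utils::combn(nf, sz, simplify = FALSE)
    for (keep in combs) {
      sign <- (-1)^(nf - sz)
      A <- array(M, c(nrow(M), gd))
      margin <- c(1L, keep + 1L)
      mm <- apply(A, margin, mean)
      big <- array(0, c(nrow(M), gd))
      # broadcast margin mean back over the collapsed factors
      perm <- c(margin, setdiff(seq_len(nf + 1L), margin))
      bb <- array(mm, c(dim(A)[margin], dim(A)[setdiff(seq_len(nf + 1L), margin)]))
      big <- aperm(bb, order(perm))
      res <- res + sign * matrix(big, nrow(M))
    }
  }
  res
}

# Deviation maps entering dGFP for one effect, given data columns X
# ((tp*nch) x (ns*nc), subject fastest) and an assignment. Returns a matrix
# (tp*nch) x ncells of deviations from the relevant mean structure.
.effectDeviations <- function(X, ns, nc, design, info, condPerm, groups,
                              groupPerm = NULL, residualize = TRUE,
                              condTags = design@conditionTags) {
  levels <- .withinLevels(design, info$within, condTags)
  # level index of each data column under the assignment
  colSubject <- rep(seq_len(ns), nc)
  colCond <- rep(seq_len(nc), each = ns)
  assigned <- condPerm[cbind(colSubject, colCond)]
  idx <- lapply(levels, function(l) l$index[assigned])
  gd <- vapply(levels, function(l) length(l$values), integer(1L))
  if (info$group) {
    g <- groups
    if (!is.null(groupPerm)) g <- groups[groupPerm]
    gvals <- sort(unique(groups))
    idx <- c(idx, list(match(g, gvals)[colSubject]))
    gd <- c(gd, length(gvals))
  }
  cell <- idx[[1L]]
  if (length(idx) > 1L)
    for (j in 2L:length(idx)) cell <- cell + (idx[[j]] - 1L) * prod(gd[1:(j - 1L)])
  ncells <- prod(gd)
  W <- matrix(0, ns * nc, ncells)
  W[cbind(seq_len(ns * nc), cell)] <- 1
  cnt <- colSums(W)
  if (any(cnt == 0L)) stop("empty design cell; the grid must be fully crossed")
  W <- sweep(W, 2L, cnt, "/")
  M <- X %*% W
  if (info$linear) {
    w <- levels[[1L]]$values - mean(levels[[1L]]$values)
    return(M %*% matrix(w, ncol = 1L))
  }
  if (length(gd) >= 2L && residualize) return(.residualize(M, gd))
  M - rowMeans(M)   # single factor, or raw multi-factor: deviation from mean
}

#' Cell means of an effect
#'
#' Marginal mean map series per level for a main effect, per-group means for
#' the between effect, and cell-combination means for interactions (with both
#' marginal main-effect patterns subtracted when `residualize = TRUE`, so the
#' interaction is not contaminated by main effects).
#'
#' @param ds an [ErpDataset-class].
#' @param design an [ErpDesign-class].
#' @param effect one of `designEffects(design)`.
#' @param assignment a permuted assignment from [permuteDesign()], or `NULL`
#'   for the identity (observed data).
#' @param normalize divide each subject x condition map by its GFP first.
#' @param residualize subtract marginal patterns for interactions.
#' @return list with `levelMeans` (time x channel x cell array), `overallMean`
#'   (time x channel), `deviations` (same shape as `levelMeans`; what enters
#'   [dgfp()]), and `cells` labels.
#' @export
effectCellMeans <- function(ds, design, effect, assignment = NULL,
                            normalize = FALSE, residualize = TRUE) {
  info <- .effectInfo(design, effect)
  a <- ds@data
  if (normalize) a <- .normalizeArray(a)
  d <- dim(a)
  ns <- d[3L]; nc <- d[4L]
  X <- matrix(a, nrow = d[1L] * d[2L])
  if (is.null(assignment))
    assignment <- list(condPerm = matrix(rep(seq_len(nc), each = ns), ns, nc),
                       groupPerm = NULL)
  groups <- .designGroups(design, ds@subjectIds)
  if (info$group && is.null(groups))
    stop("effect involves groups but the design has no between factor")
  .checkConditionCoverage(design, ds@conditionTags)
  dev <- .effectDeviations(X, ns, nc, design, info, assignment$condPerm,
                           groups, assignment$groupPerm, residualize,
                           condTags = ds@conditionTags)
  # the raw (non-residualized, non-contrast) cell means, for reporting
  rawInfo <- info; rawInfo$linear <- FALSE
  raw <- .effectDeviations(X, ns, nc, design, rawInfo, assignment$condPerm,
                           groups, assignment$groupPerm, residualize = FALSE,
                           condTags = ds@conditionTags)
  overall <- matrix(rowMeans(X), d[1L], d[2L])
  lm <- array(raw + as.vector(overall), c(d[1L], d[2L], ncol(raw)))
  list(levelMeans = lm, overallMean = overall,
       deviations = array(dev, c(d[1L], d[2L], ncol(dev))),
       cells = paste0("cell", seq_len(ncol(raw))), linear = info$linear)
}

#' Effect size of map differences (dGFP)
#'
#' The root-mean-square deviation, across channels, of the factor-level mean
#' maps from their grand mean, summed over levels: the global quantifier of
#' topographic difference tested by the TANOVA.
#'
#' @param cm cell means from [effectCellMeans()], or a levels x channels
#'   matrix of mean maps.
#' @return scalar (or per-time-point vector for cell-mean series), in uV.
#' @export
dgfp <- function(cm) {
  if (is.matrix(cm)) {
    if (nrow(cm) < 2L) stop("dGFP needs at least 2 levels")
    dev <- sweep(cm, 2L, colMeans(cm))
    return(sqrt(sum(dev^2) / ncol(cm)))
  }
  dev <- cm$deviations
  d <- dim(dev)
  if (d[3L] < 2L && !isTRUE(cm$linear)) stop("dGFP needs at least 2 levels")
  sqrt(rowSums(matrix(dev^2, d[1L])) / d[2L])
}
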