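#' @import methods
NULL

# ---------------------------------------------------------------------------
# Montage
# ---------------------------------------------------------------------------

#' Electrode montage
#'
#' Channel labels and 3-D head-centered electrode positions used to interpret
#' a scalp map spatially. Units of the coordinates are arbitrary; only the
#' relative geometry matters for display.
#'
#' @slot labels character vector of unique channel names.
#' @slot positions numeric matrix with one row per channel and columns x, y, z.
#' @export
setClass("Montage",
         slots = c(labels = "character", positions = "matrix"))

setValidity("Montage", function(object) {
  n <- length(object@labels)
  if (anyDuplicated(object@labels))
    return("channel labels must be unique")
  if (!is.numeric(object@positions) || nrow(object@positions) != n ||
      ncol(object@positions) != 3L)
    return("positions must be a numeric n x 3 matrix (one row per channel)")
  if (!all(is.finite(object@positions)))
    return("positions must be finite")
  TRUE
})

#' Construct a montage
#'
#' @param labels channel names; generated as `Ch1`, `Ch2`, ... when missing.
#' @param positions numeric matrix of 3-D positions, one row per channel.
#' @return A [Montage-class] object.
#' @export
montage <- function(positions, labels = NULL) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(positions)))
  new("Montage", labels = as.character(labels), positions = positions)
}

# ---------------------------------------------------------------------------
# ErpDataset
# ---------------------------------------------------------------------------

#' Multi-subject, multi-condition ERP dataset
#'
#' The central data container: a complete subject x condition grid of averaged
#' ERP matrices sharing one time axis and one channel set, stored as a 4-D
#' array (time x channel x subject x condition, microvolts). All cells must be
#' present (complete-case design).
#'
#' @slot data numeric 4-D array, time x channel x subject x condition.
#' @slot dt inter-sample interval in ms (> 0).
#' @slot t0 time of the first sample in ms; stimulus onset is 0.
#' @slot subjectIds,conditionTags axis labels.
#' @slot channelLabels per-channel names.
#' @slot montage a [Montage-class] or `NULL`.
#' @slot averageReferenced `TRUE` once every map has zero channel mean.
#' @slot filterLog list of filter settings applied so far ("Filter Specs").
#' @slot original the pre-filter array when the last filter was undoable.
#' @export
setClass("ErpDataset",
         slots = c(data = "array", dt = "numeric", t0 = "numeric",
                   subjectIds = "character", conditionTags = "character",
                   channelLabels = "character", montage = "ANY",
                   averageReferenced = "logical", filterLog = "list",
                   original = "ANY"))

setValidity("ErpDataset", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4-D array (time x channel x subject x condition)")
  if (!all(is.finite(object@data)))
    return("data must be finite (no missing cells are supported)")
  if (length(object@dt) != 1L || object@dt <= 0)
    return("dt must be a single positive number (ms)")
  if (length(object@subjectIds) != d[3L])
    return("subjectIds length must match the subject dimension")
  if (length(object@conditionTags) != d[4L])
    return("conditionTags length must match the condition dimension")
  if (length(object@channelLabels) != d[2L])
    return("channelLabels length must match the channel dimension")
  if (anyDuplicated(object@subjectIds)) return("subjectIds must be unique")
  if (anyDuplicated(object@conditionTags)) return("conditionTags must be unique")
  if (!is.null(object@montage)) {
    if (!is(object@montage, "Montage")) return("montage must be a Montage or NULL")
    if (length(object@montage@labels) != d[2L])
      return(sprintf("montage has %d channels but data has %d",
                     length(object@montage@labels), d[2L]))
  }
  TRUE
})

#' Construct an ERP dataset
#'
#' @param data either a 4-D array (time x channel x subject x condition) or a
#'   list of per-subject lists of time x channel matrices.
#' @param dtMs inter-sample interval in ms.
#' @param t0Ms time of the first sample in ms (default 0 = stimulus onset).
#' @param subjectIds,conditionTags axis labels; defaults are generated.
#' @param montage optional [Montage-class]; channel count must match.
#' @param averageReferenced set `TRUE` if the data are already average
#'   referenced; use [averageReference()] to enforce it.
#' @return An [ErpDataset-class].
#' @export
erpDataset <- function(data, dtMs, t0Ms = 0,
                       subjectIds = NULL, conditionTags = NULL,
                       montage = NULL, averageReferenced = FALSE) {
  if (is.list(data)) {
    ns <- length(data)
    nc <- length(data[[1L]])
    m1 <- as.matrix(data[[1L]][[1L]])
    arr <- array(NA_real_, c(nrow(m1), ncol(m1), ns, nc))
    for (s in seq_len(ns)) for (co in seq_len(nc)) {
      m <- as.matrix(data[[s]][[co]])
      if (!identical(dim(m), dim(m1)))
        stop("all cells must have identical dimensions")
      arr[, , s, co] <- m
    }
    if (is.null(subjectIds)) subjectIds <- names(data)
    if (is.null(conditionTags)) conditionTags <- names(data[[1L]])
    data <- arr
  }
  d <- dim(data)
  if (is.null(subjectIds)) subjectIds <- sprintf("S%02d", seq_len(d[3L]))
  if (is.null(conditionTags)) conditionTags <- paste0("C", seq_len(d[4L]))
  channelLabels <- if (!is.null(montage)) montage@labels else
    paste0("Ch", seq_len(d[2L]))
  new("ErpDataset", data = data, dt = as.numeric(dtMs), t0 = as.numeric(t0Ms),
      subjectIds = as.character(subjectIds),
      conditionTags = as.character(conditionTags),
      channelLabels = channelLabels, montage = montage,
      averageReferenced = averageReferenced, filterLog = list(),
      original = NULL)
}

# ---------------------------------------------------------------------------
# ErpDesign
# ---------------------------------------------------------------------------

#' Experimental design
#'
#' Assignment of conditions to the levels of up to two orthogonal
#' within-subject factors, plus an optional between-subject group factor.
#' The design enumerates every testable effect: each within main effect, the
#' within x within interaction, the group effect and group x within
#' interactions.
#'
#' @slot withinFactors named list; each element is a named numeric vector
#'   mapping every condition tag to a level code.
#' @slot factorTypes per-factor measurement scale, `"categorical"`, `"rank"`
#'   or `"interval"`; non-categorical single factors are tested with a linear
#'   contrast across levels.
#' @slot betweenFactor named character vector (subject id -> group) or `NULL`.
#' @slot conditionTags the condition tags covered by the design.
#' @slot effects enumerated effect identifiers.
#' @export
setClass("ErpDesign",
         slots = c(withinFactors = "list", factorTypes = "character",
                   betweenFactor = "ANY", conditionTags = "character",
                   effects = "character"))

setValidity("ErpDesign", function(object) {
  nf <- length(object@withinFactors)
  if (nf > 2L) return("at most two within-subject factors are supported")
  for (f in names(object@withinFactors)) {
    lev <- object@withinFactors[[f]]
    if (!all(object@conditionTags %in% names(lev)))
      return(sprintf("factor '%s' does not assign a level to every condition", f))
  }
  if (nf == 2L) {
    l1 <- object@withinFactors[[1L]][object@conditionTags]
    l2 <- object@withinFactors[[2L]][object@conditionTags]
    tab <- table(l1, l2)
    if (any(tab == 0L) || length(unique(as.vector(tab))) != 1L)
      return("two within-subject factors must form a fully crossed (orthogonal) grid")
  }
  if (!is.null(object@betweenFactor) && length(object@betweenFactor) < 1L)
    return("betweenFactor must be NULL or a named subject -> group vector")
  TRUE
})

# ---------------------------------------------------------------------------
# RandConfig
# ---------------------------------------------------------------------------

#' Randomization settings
#'
#' Shared settings for all randomization tests: number of runs, significance
#' threshold, per-map GFP normalization, and the seed that makes a run
#' reproducible. Five thousand runs is the publication standard; one thousand
#' gives an accurate estimate at the 5\% level.
#'
#' @slot nRuns number of randomization runs.
#' @slot pThreshold significance threshold in (0, 1).
#' @slot normalize divide each map by its GFP before topographic tests.
#' @slot seed integer seed; `NA` leaves the RNG stream untouched.
#' @slot legacyP if `TRUE`, p = b/n (the literal percentage of runs reaching
#'   the observed value) instead of the default add-one (1+b)/(n+1).
#' @export
setClass("RandConfig",
         slots = c(nRuns = "numeric", pThreshold = "numeric",
                   normalize = "logical", seed = "numeric",
                   legacyP = "logical"))

setValidity("RandConfig", function(object) {
  if (object@nRuns < 1) return("nRuns must be >= 1")
  if (object@pThreshold <= 0 || object@pThreshold >= 1)
    return("pThreshold must be in (0, 1)")
  TRUE
})

#' @param nRuns,pThreshold,normalize,seed,legacyP see [RandConfig-class].
#' @return a [RandConfig-class] object.
#' @rdname RandConfig-class
#' @export
randConfig <- function(nRuns = 5000, pThreshold = 0.05, normalize = FALSE,
                       seed = NA, legacyP = FALSE) {
  new("RandConfig", nRuns = as.numeric(nRuns), pThreshold = pThreshold,
      normalize = normalize, seed = as.numeric(seed), legacyP = legacyP)
}

# ---------------------------------------------------------------------------
# Result containers
# ---------------------------------------------------------------------------

#' Topographic consistency test result
#'
#' @slot observedGfp matrix (time x condition) of grand-mean GFP values (uV).
#' @slot p matrix (time x condition) of randomization p-values.
#' @slot time sample times in ms.
#' @slot nRuns,threshold settings used.
#' @export
setClass("TctResult",
         slots = c(observedGfp = "matrix", p = "matrix", time = "numeric",
                   nRuns = "numeric", threshold = "numeric"))

#' TANOVA / GFP-test result
#'
#' Per-effect, per-time-point observed statistic and p-value plus the full
#' permutation null, which the overall statistics re-use run by run.
#'
#' @slot observed matrix (time x effect) of observed dGFP (or GFP statistic).
#' @slot p matrix (time x effect) of p-values.
#' @slot null array (run x time x effect) of null statistic samples.
#' @slot time sample times (ms).
#' @slot effects effect identifiers.
#' @slot statistic `"dgfp"` or `"gfp"`.
#' @slot cfg the [RandConfig-class] used.
#' @export
setClass("TanovaResult",
         slots = c(observed = "matrix", p = "matrix", null = "array",
                   time = "numeric", effects = "character",
                   statistic = "character", cfg = "RandConfig"))

#' Overall (multiple testing over time) result
#'
#' @slot effect,kind which effect and which statistic (`count`, `duration`,
#'   `fisher`).
#' @slot observed observed statistic on the p-value series.
#' @slot nullSamples per-run null statistics.
#' @slot p overall p-value.
#' @slot durationThresholdMs for `kind = "duration"`, the shortest run length
#'   significant at the threshold; `NA` otherwise.
#' @slot theta the sub-threshold criterion used.
#' @export
setClass("OverallResult",
         slots = c(effect = "character", kind = "character",
                   observed = "numeric", nullSamples = "numeric",
                   p = "numeric", durationThresholdMs = "numeric",
                   theta = "numeric"))

#' Channel-wise t-map result
#'
#' @slot t per-channel t statistic (`Inf` sentinel where the variance is 0).
#' @slot meanA,meanB window-averaged mean maps of the two selections.
#' @slot df degrees of freedom (n-1 paired, n1+n2-2 unpaired).
#' @slot paired whether a paired test was used.
#' @slot contrastP TANOVA p of the same contrast over the same window.
#' @slot channels channel labels.
#' @export
setClass("TMapResult",
         slots = c(t = "numeric", meanA = "numeric", meanB = "numeric",
                   df = "numeric", paired = "logical", contrastP = "numeric",
                   channels = "character"))

#' MDS embedding of subject similarity
#'
#' @slot coords subject x 2 coordinates, centered at the origin.
#' @slot stress residual misfit between embedded and target distances.
#' @export
setClass("MdsEmbedding",
         slots = c(coords = "matrix", stress = "numeric"))

#' Microstate model
#'
#' @slot templates k x channel matrix of unit-GFP, zero-mean template maps.
#' @slot polarityMode `"sensitive"` (a sign flip is a different component,
#'   the ERP default) or `"ignore"`.
#' @export
setClass("MicrostateModel",
         slots = c(templates = "matrix", polarityMode = "character"))

setValidity("MicrostateModel", function(object) {
  if (nrow(object@templates) < 2L) return("a model needs k >= 2 templates")
  g <- apply(object@templates, 1L, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(abs(g - 1) > 1e-6)) return("templates must have unit GFP")
  if (!object@polarityMode %in% c("sensitive", "ignore"))
    return("polarityMode must be 'sensitive' or 'ignore'")
  TRUE
})

#' Cross-validation curve for the number of microstate classes
#'
#' @slot k candidate class numbers.
#' @slot learningEv,testEv mean explained-variance fractions per k.
#' @slot nSplits number of random learning/test splits averaged.
#' @slot perSplitTestEv splits x k matrix of test explained variances.
#' @export
setClass("CrossValidationCurve",
         slots = c(k = "numeric", learningEv = "numeric", testEv = "numeric",
                   nSplits = "numeric", perSplitTestEv = "matrix"))

#' Microstate quantifier randomization statistics
#'
#' @slot observed array class x quantifier x effect of observed between-level
#'   variances.
#' @slot p matching array of p-values (`NA` where a class was absent from all
#'   observed cells).
#' @slot quantifiers quantifier names.
#' @slot effects effect identifiers.
#' @slot nRuns runs used.
#' @slot windowMs analysis window.
#' @export
setClass("MicrostateStats",
         slots = c(observed = "array", p = "array", quantifiers = "character",
                   effects = "character", nRuns = "numeric",
                   windowMs = "numeric"))

#' Synthetic dataset specification
#'
#' Describes an average-referenced multichannel ERP study built from a small
#' set of orthonormal source maps activated in sequence, with per-condition
#' topographic (rotation), amplitude (scale) and latency effects, per-subject
#' amplitude/latency variability, and spatially uncorrelated plus optionally
#' spatially correlated noise. Defaults emulate the kind of N400 study the
#' statistics were designed for: 16 subjects, 74 channels, 250 samples at
#' 4 ms (0-1000 ms), four conditions in a 2 x 2 within-subject design.
#'
#' @slot nSubjects,nChannels,nTimepoints,dtMs,t0Ms geometry of the recording.
#' @slot conditionTags condition labels.
#' @slot nClasses number of source maps in the default sequence.
#' @slot amplitude peak source amplitude (uV).
#' @slot rampMs cosine on/off ramp of each activation envelope.
#' @slot sequence `NULL` for the default sequential activation, or a named
#'   list (per condition) of data frames with columns `class`, `onsetMs`,
#'   `offsetMs`, `amplitude`.
#' @slot templates optional user-supplied k x channel template matrix.
#' @slot conditionScale,conditionRotationDeg,conditionShiftMs named per
#'   condition; amplitude scaling, rotation of the `rotationClass` template
#'   within the plane spanned by it and an extra orthogonal map, and latency
#'   shift (ms).
#' @slot rotationClass which template the rotation effect applies to.
#' @slot noiseSd per-channel independent Gaussian noise SD (uV).
#' @slot correlatedNoiseSd SD of spatially correlated noise expressed through
#'   three fixed random basis maps (uV).
#' @slot subjectAmpSd relative SD of per-subject amplitude scaling.
#' @slot subjectLatencySd SD of per-subject latency jitter (ms), shifting the
#'   whole response.
#' @slot boundaryJitterSd SD of independent per-subject, per-condition,
#'   per-activation onset/offset jitter (ms): individual variability in
#'   component timing beyond a global shift.
#' @slot groups optional per-subject group labels (between factor).
#' @slot seed RNG seed; identical spec + seed gives a bit-identical dataset.
#' @export
setClass("SyntheticSpec",
         slots = c(nSubjects = "numeric", nChannels = "numeric",
                   nTimepoints = "numeric", dtMs = "numeric", t0Ms = "numeric",
                   conditionTags = "character", nClasses = "numeric",
                   amplitude = "numeric", rampMs = "numeric",
                   sequence = "ANY", templates = "ANY",
                   conditionScale = "numeric",
                   conditionRotationDeg = "numeric",
                   conditionShiftMs = "numeric", rotationClass = "numeric",
                   noiseSd = "numeric", correlatedNoiseSd = "numeric",
                   subjectAmpSd = "numeric", subjectLatencySd = "numeric",
                   boundaryJitterSd = "numeric", groups = "ANY",
                   seed = "numeric"))
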