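# Accessor generics for the data containers. Slot access from user code is
# discouraged; these are the supported surface.

#' @rdname ErpDataset-class
#' @param x,object an object.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname ErpDataset-class
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
#' @rdname ErpDataset-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname ErpDataset-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname ErpDataset-class
#' @export
setGeneric("conditionTags", function(x) standardGeneric("conditionTags"))
#' @rdname ErpDataset-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname ErpDataset-class
#' @export
setGeneric("dtMs", function(x) standardGeneric("dtMs"))
#' @rdname ErpDataset-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname ErpDataset-class
#' @export
setGeneric("getMontage", function(x) standardGeneric("getMontage"))
#' @rdname ErpDataset-class
#' @export
setGeneric("isAverageReferenced", function(x) standardGeneric("isAverageReferenced"))

#' @rdname ErpDesign-class
#' @param x an object.
#' @export
setGeneric("designEffects", function(x) standardGeneric("designEffects"))

#' Extract one cell's time x channel matrix
#'
#' @param x an [ErpDataset-class].
#' @param subject subject id or index.
#' @param condition condition tag or index.
#' @return numeric time x channel matrix (uV).
#' @export
setGeneric("erpMatrix", function(x, subject, condition)
  standardGeneric("erpMatrix"))

#' Average reference data
#'
#' Subtracts, at every time point, the mean across channels, centering each
#' scalp map at the origin of the state space. Idempotent; preserves all
#' pairwise channel differences. Strongly recommended for all ERP analyses
#' here, since GFP and dGFP presuppose it.
#'
#' @param x a time x channel matrix or an [ErpDataset-class].
#' @return the same type, average referenced.
#' @export
setGeneric("averageReference", function(x) standardGeneric("averageReference"))

#' @rdname MicrostateModel-class
#' @param x an object.
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))
#' @rdname MicrostateModel-class
#' @export
setGeneric("polarityMode", function(x) standardGeneric("polarityMode"))
#' @rdname MicrostateModel-class
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

# --- methods -----------------------------------------------------------------

#' @rdname ErpDataset-class
setMethod("nChannels", "ErpDataset", function(x) dim(x@data)[2L])
#' @rdname ErpDataset-class
setMethod("nTimepoints", "ErpDataset", function(x) dim(x@data)[1L])
#' @rdname ErpDataset-class
setMethod("nSubjects", "ErpDataset", function(x) dim(x@data)[3L])
#' @rdname ErpDataset-class
setMethod("subjectIds", "ErpDataset", function(x) x@subjectIds)
#' @rdname ErpDataset-class
setMethod("conditionTags", "ErpDataset", function(x) x@conditionTags)
#' @rdname ErpDataset-class
setMethod("channelLabels", "ErpDataset", function(x) x@channelLabels)
#' @rdname ErpDataset-class
setMethod("dtMs", "ErpDataset", function(x) x@dt)
#' @rdname ErpDataset-class
setMethod("sampleTimes", "ErpDataset", function(x)
  x@t0 + (seq_len(dim(x@data)[1L]) - 1L) * x@dt)
#' @rdname ErpDataset-class
setMethod("getMontage", "ErpDataset", function(x) x@montage)
#' @rdname ErpDataset-class
setMethod("isAverageReferenced", "ErpDataset", function(x) x@averageReferenced)

#' @rdname Montage-class
setMethod("nChannels", "Montage", function(x) length(x@labels))
#' @rdname Montage-class
setMethod("channelLabels", "Montage", function(x) x@labels)

#' @rdname ErpDesign-class
setMethod("designEffects", "ErpDesign", function(x) x@effects)

setMethod("erpMatrix", "ErpDataset", function(x, subject, condition) {
  if (is.character(subject)) subject <- match(subject, x@subjectIds)
  if (is.character(condition)) condition <- match(condition, x@conditionTags)
  if (is.na(subject) || is.na(condition))
    stop("unknown subject or condition")
  m <- x@data[, , subject, condition, drop = FALSE]
  dim(m) <- dim(x@data)[1:2]
  dimnames(m) <- list(NULL, x@channelLabels)
  m
})

#' @rdname MicrostateModel-class
setMethod("templates", "MicrostateModel", function(x) x@templates)
#' @rdname MicrostateModel-class
setMethod("polarityMode", "MicrostateModel", function(x) x@polarityMode)
#' @rdname MicrostateModel-class
setMethod("nClasses", "MicrostateModel", function(x) nrow(x@templates))

# --- show methods ------------------------------------------------------------

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage with %d channels: %s%s\n", length(object@labels),
              paste(utils::head(object@labels, 6L), collapse = ", "),
              if (length(object@labels) > 6L) ", ..." else ""))
})

setMethod("show", "ErpDataset", function(object) {
  d <- dim(object@data)
  tt <- object@t0 + c(0, (d[1L] - 1L) * object@dt)
  cat(sprintf(
    "ErpDataset: %d subjects x %d conditions, %d time points x %d channels\n",
    d[3L], d[4L], d[1L], d[2L]))
  cat(sprintf("  time %g..%g ms (dt = %g ms); average referenced: %s\n",
              tt[1L], tt[2L], object@dt, object@averageReferenced))
  cat(sprintf("  conditions: %s\n", paste(object@conditionTags, collapse = ", ")))
  if (length(object@filterLog))
    cat(sprintf("  filters applied: %d (see filterSpecs())\n",
                length(object@filterLog)))
})

setMethod("show", "ErpDesign", function(object) {
  cat("ErpDesign\n")
  for (f in names(object@withinFactors)) {
    lev <- object@withinFactors[[f]][object@conditionTags]
    cat(sprintf("  within factor '%s' (%s): %s\n", f,
                object@factorTypes[[f]],
                paste(sprintf("%s=%g", object@conditionTags, lev),
                      collapse = ", ")))
  }
  if (!is.null(object@betweenFactor))
    cat(sprintf("  between factor: groups {%s}\n",
                paste(unique(object@betweenFactor), collapse = ", ")))
  cat(sprintf("  effects: %s\n", paste(object@effects, collapse = ", ")))
})

setMethod("show", "RandConfig", function(object) {
  cat(sprintf(
    "RandConfig: %d runs, p-threshold %g, normalize %s, seed %s%s\n",
    object@nRuns, object@pThreshold, object@normalize,
    ifelse(is.na(object@seed), "unset", format(object@seed)),
    if (object@legacyP) ", legacy p = b/n" else ""))
})

setMethod("show", "TctResult", function(object) {
  cat(sprintf("TctResult: %d time points x %d conditions (%d runs)\n",
              nrow(object@p), ncol(object@p), object@nRuns))
  sig <- colMeans(object@p < object@threshold)
  cat(sprintf("  fraction of time significant at %g: %s\n", object@threshold,
              paste(sprintf("%s=%.2f", colnames(object@p), sig),
                    collapse = ", ")))
})

setMethod("show", "TanovaResult", function(object) {
  cat(sprintf("%s result: %d time points, effects: %s (%d runs)\n",
              ifelse(object@statistic == "gfp", "GFP test", "TANOVA"),
              nrow(object@p), paste(object@effects, collapse = ", "),
              object@cfg@nRuns))
  sig <- colMeans(object@p < object@cfg@pThreshold)
  cat(sprintf("  fraction of time significant at %g: %s\n",
              object@cfg@pThreshold,
              paste(sprintf("%s=%.2f", object@effects, sig), collapse = ", ")))
})

setMethod("show", "OverallResult", function(object) {
  cat(sprintf("Overall %s statistic for effect '%s': observed %g, p = %.4g\n",
              object@kind, object@effect, object@observed, object@p))
  if (!is.na(object@durationThresholdMs))
    cat(sprintf("  duration threshold: %g ms\n", object@durationThresholdMs))
})

setMethod("show", "TMapResult", function(object) {
  cat(sprintf("TMapResult: %d channels, %s t-test, df = %g, contrast p = %.4g\n",
              length(object@t), ifelse(object@paired, "paired", "unpaired"),
              object@df, object@contrastP))
  i <- which.max(abs(object@t))
  cat(sprintf("  largest |t| = %.3f at %s\n", abs(object@t[i]),
              object@channels[i]))
})

setMethod("show", "MdsEmbedding", function(object) {
  cat(sprintf("MdsEmbedding: %d subjects in %d dimensions, stress %.4f\n",
              nrow(object@coords), ncol(object@coords), object@stress))
})

setMethod("show", "MicrostateModel", function(object) {
  cat(sprintf("MicrostateModel: %d classes x %d channels, polarity-%s\n",
              nrow(object@templates), ncol(object@templates),
              object@polarityMode))
})

setMethod("show", "CrossValidationCurve", function(object) {
  cat(sprintf("CrossValidationCurve over k = %s (%d splits)\n",
              paste(range(object@k), collapse = ".."), object@nSplits))
  cat("  k        :", sprintf("%6d", object@k), "\n")
  cat("  learn EV :", sprintf("%6.3f", object@learningEv), "\n")
  cat("  test  EV :", sprintf("%6.3f", object@testEv), "\n")
})

setMethod("show", "MicrostateStats", function(object) {
  cat(sprintf(
    "MicrostateStats: %d classes x %d quantifiers x %d effects (%d runs)\n",
    dim(object@p)[1L], dim(object@p)[2L], dim(object@p)[3L], object@nRuns))
  cat(sprintf("  window %g..%g ms; %d tests with p < 0.05\n",
              object@windowMs[1L], object@windowMs[2L],
              sum(object@p < 0.05, na.rm = TRUE)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d subjects, %d conditions, %d x %d samples, seed %g\n",
    object@nSubjects, length(object@conditionTags), object@nTimepoints,
    object@nChannels, object@seed))
})
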