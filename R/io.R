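# ASCII I/O: time x channel matrices, xyz electrode files, dataset archives.

#' Read one ASCII ERP matrix
#'
#' Reads a whitespace-delimited numeric rectangle organized as time x channel
#' (one row per sample). Files organized as channel x time can be transposed
#' while importing.
#'
#' @param path file path.
#' @param transpose transpose after reading (input was channel x time).
#' @return numeric time x channel matrix.
#' @export
readErpMatrix <- function(path, transpose = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("'%s' contains no data", path))
  toks <- strsplit(trimws(lines), "[ \t]+")
  nc <- length(toks[[1L]])
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != nc)
      stop(sprintf("ragged rows in '%s': line %d has %d fields, line 1 has %d",
                   path, i, length(toks[[i]]), nc))
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    row <- (bad - 1L) %/% nc + 1L
    col <- (bad - 1L) %% nc + 1L
    stop(sprintf("non-numeric value '%s' in '%s' at line %d, field %d",
                 toks[[row]][col], path, row, col))
  }
  m <- matrix(vals, nrow = length(toks), ncol = nc, byrow = TRUE)
  if (transpose) m <- t(m)
  m
}

#' Read an electrode coordinate (xyz) file
#'
#' Accepts both dialects: an optional first line holding the channel count,
#' followed by one line per channel with three coordinates and an optional
#' label. The dialect is autodetected from the first line's token count.
#' Labels are auto-generated when absent.
#'
#' @param path file path.
#' @return a [Montage-class].
#' @export
readMontage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- length(toks[[1L]]) < 3L
  if (header) {
    n <- suppressWarnings(as.integer(toks[[1L]][1L]))
    toks <- toks[-1L]
    if (is.na(n) || n != length(toks))
      stop(sprintf("montage header announces %s channels but %d lines follow",
                   lines[1L], length(toks)))
  }
  pos <- matrix(NA_real_, length(toks), 3L)
  labels <- character(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    xyz <- suppressWarnings(as.numeric(tk[1:3]))
    if (length(tk) < 3L || anyNA(xyz))
      stop(sprintf("montage line %d is not 'x y z [label]'",
                   i + as.integer(header)))
    pos[i, ] <- xyz
    labels[i] <- if (length(tk) >= 4L) tk[4L] else paste0("Ch", i)
  }
  montage(pos, labels)
}

#' Write an electrode coordinate file
#'
#' @param m a [Montage-class].
#' @param path output path; written with a channel-count header line.
#' @export
writeMontage <- function(m, path) {
  writeLines(c(as.character(length(m@labels)),
               sprintf("%.6f %.6f %.6f %s", m@positions[, 1L],
                       m@positions[, 2L], m@positions[, 3L], m@labels)),
             path)
  invisible(path)
}

#' Import a folder of per-subject, per-condition ASCII files
#'
#' One file is required per subject and condition; file names carry a subject
#' identifier and a condition tag at fixed positions (e.g. `S01_C1.asc`). The
#' search expression identifies all subjects for one condition with `*`
#' standing for the subject part; files for the remaining conditions are found
#' by substituting the condition tag.
#'
#' @param folder directory with the data files.
#' @param searchExpression glob such as `"*_C1.asc"`; must contain `*` (the
#'   subject capture) and exactly one of the condition tags.
#' @param conditionTags condition labels, e.g. `c("C1","C2","F1","F2")`.
#' @param transpose transpose each file while importing (channel x time input).
#' @param doAverageReference re-compute every matrix to average reference
#'   (recommended for all analyses here).
#' @param montage optional [Montage-class] or path to an xyz file.
#' @return an [ErpDataset-class]; a message reports frames and channels.
#' @export
importErpDataset <- function(folder, searchExpression, conditionTags,
                             transpose = FALSE, doAverageReference = TRUE,
                             montage = NULL) {
  hit <- conditionTags[vapply(conditionTags, grepl, logical(1L),
                              x = searchExpression, fixed = TRUE)]
  if (length(hit) < 1L)
    stop("searchExpression must contain one of the condition tags")
  tag0 <- hit[which.max(nchar(hit))]   # prefer the longest embedded tag
  files0 <- Sys.glob(file.path(folder, searchExpression))
  if (!length(files0))
    stop(sprintf("no files match '%s' in '%s'", searchExpression, folder))
  # recover the subject part captured by '*'
  rx <- utils::glob2rx(searchExpression)
  rx <- sub("\\.\\*", "(.*)", rx)       # first '*' becomes a capture
  subjects <- sort(unique(sub(rx, "\\1", basename(files0))))
  grid <- expand.grid(subject = subjects, condition = conditionTags,
                      stringsAsFactors = FALSE)
  fname <- function(s, co) {
    f <- sub("*", s, searchExpression, fixed = TRUE)
    sub(tag0, co, f, fixed = TRUE)
  }
  paths <- file.path(folder, mapply(fname, grid$subject, grid$condition))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing subject x condition file(s): ",
         paste(sprintf("(%s, %s)", grid$subject[missing],
                       grid$condition[missing]), collapse = ", "))
  mats <- lapply(paths, readErpMatrix, transpose = transpose)
  dims <- vapply(mats, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    bad <- which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])[1L]
    stop(sprintf("inconsistent dimensions: '%s' is %d x %d but '%s' is %d x %d",
                 basename(paths[1L]), dims[1L, 1L], dims[2L, 1L],
                 basename(paths[bad]), dims[1L, bad], dims[2L, bad]))
  }
  arr <- array(NA_real_, c(dims[1L, 1L], dims[2L, 1L], length(subjects),
                           length(conditionTags)))
  for (i in seq_len(nrow(grid))) {
    s <- match(grid$subject[i], subjects)
    co <- match(grid$condition[i], conditionTags)
    arr[, , s, co] <- mats[[i]]
  }
  if (is.character(montage)) montage <- readMontage(montage)
  ds <- erpDataset(arr, dtMs = 1, subjectIds = subjects,
                   conditionTags = conditionTags, montage = montage)
  if (doAverageReference) ds <- averageReference(ds)
  message(sprintf("imported %d subjects x %d conditions: %d frames, %d channels",
                  length(subjects), length(conditionTags), dims[1L, 1L],
                  dims[2L, 1L]))
  ds
}

# ---------------------------------------------------------------------------
# archival export/import: directory of ASCII matrices + plain-text manifest
# ---------------------------------------------------------------------------

#' Export a dataset as an archival folder
#'
#' Writes one ASCII time x channel matrix per subject x condition (named
#' `<subject>_<condition>.asc`, values at 1e-6 precision), the montage as an
#' xyz file, and a plain-text key-value manifest with the sampling
#' information, so a dataset round-trips bit-exactly at the documented
#' precision.
#'
#' @param ds an [ErpDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportErpDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(nSubjects(ds))) for (co in seq_len(length(ds@conditionTags))) {
    m <- ds@data[, , s, co]
    con <- file.path(dir, sprintf("%s_%s.asc", ds@subjectIds[s],
                                  ds@conditionTags[co]))
    utils::write.table(format(m, digits = 15, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(ds@montage)) writeMontage(ds@montage, file.path(dir, "montage.xyz"))
  man <- c(sprintf("dt_ms=%.10g", ds@dt), sprintf("t0_ms=%.10g", ds@t0),
           sprintf("subjects=%s", paste(ds@subjectIds, collapse = ",")),
           sprintf("conditions=%s", paste(ds@conditionTags, collapse = ",")),
           sprintf("average_referenced=%d", as.integer(ds@averageReferenced)))
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Load a dataset archive written by [exportErpDataset()]
#'
#' @param dir archive directory.
#' @return an [ErpDataset-class].
#' @export
loadErpArchive <- function(dir) {
  man <- readLines(file.path(dir, "manifest.txt"))
  kv <- strsplit(man, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  subjects <- strsplit(vals[["subjects"]], ",")[[1L]]
  conds <- strsplit(vals[["conditions"]], ",")[[1L]]
  mont <- NULL
  if (file.exists(file.path(dir, "montage.xyz")))
    mont <- readMontage(file.path(dir, "montage.xyz"))
  mats <- list()
  for (s in subjects) {
    mats[[s]] <- list()
    for (co in conds)
      mats[[s]][[co]] <- readErpMatrix(file.path(dir, sprintf("%s_%s.asc", s, co)))
  }
  erpDataset(mats, dtMs = as.numeric(vals[["dt_ms"]]),
             t0Ms = as.numeric(vals[["t0_ms"]]),
             subjectIds = subjects, conditionTags = conds, montage = mont,
             averageReferenced = vals[["average_referenced"]] == "1")
}

#' Per-condition data inspection summary
#'
#' Butterfly extrema and grand-mean GFP per condition, the quick sanity check
#' that imported data are represented correctly (scaling, polarity, time
#' axis).
#'
#' @param ds an [ErpDataset-class].
#' @return data frame: condition, min/max voltage (uV), peak grand-mean GFP
#'   and its latency (ms).
#' @export
inspectDataset <- function(ds) {
  tt <- sampleTimes(ds)
  out <- lapply(seq_along(ds@conditionTags), function(co) {
    gm <- grandMean(ds, conditionWeights =
                      as.numeric(seq_along(ds@conditionTags) == co))
    g <- gfp(gm)
    data.frame(condition = ds@conditionTags[co],
               min_uv = min(ds@data[, , , co]),
               max_uv = max(ds@data[, , , co]),
               peak_gfp_uv = max(g), peak_gfp_ms = tt[which.max(g)])
  })
  do.call(rbind, out)
}

#' Grand-mean GFP curves per condition
#'
#' @param ds an [ErpDataset-class].
#' @return data frame with columns `time_ms` and one GFP column per condition.
#' @export
gfpCurves <- function(ds) {
  out <- data.frame(time_ms = sampleTimes(ds))
  for (co in seq_along(ds@conditionTags))
    out[[ds@conditionTags[co]]] <- gfp(grandMean(
      ds, conditionWeights = as.numeric(seq_along(ds@conditionTags) == co)))
  out
}
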