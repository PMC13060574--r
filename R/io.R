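# Delimited-text I/O for time series, connectivity matrices, network maps and
# labels. Canonical on-disk layout for a time-series matrix is ROI rows x time
# columns, tab-separated, '.' decimal, no header and no index column.

.parseNumericMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (length(unique(nc)) != 1L)
    stop(sprintf("ragged rows in %s: row 1 has %d columns, row %d has %d",
                 path, nc[1L], which(nc != nc[1L])[1L], nc[nc != nc[1L]][1L]))
  m <- suppressWarnings(matrix(as.numeric(unlist(cells)), length(lines),
                               nc[1L], byrow = TRUE))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite cell at row %d, column %d of %s",
                 bad[1L, 1L], bad[1L, 2L], path))
  }
  m
}

#' Load an ROI time-series matrix from delimited text
#'
#' Reads a single subject's matrix. `layout = "roi_rows"` expects one ROI per
#' row (the canonical layout); `"roi_cols"` transposes after reading.
#'
#' @param path TSV file path.
#' @param layout `"roi_rows"` or `"roi_cols"`.
#' @param trSeconds optional repetition time.
#' @return An [RoiTimeSeriesBatch-class] with S = 1.
#' @export
loadTimeSeries <- function(path, layout = c("roi_rows", "roi_cols"),
                           trSeconds = NA_real_) {
  layout <- match.arg(layout)
  m <- .parseNumericMatrix(path)
  if (layout == "roi_cols") m <- t(m)
  b <- roiTimeSeriesBatch(m, subjectIds = sub("\\.[^.]*$", "", basename(path)),
                          trSeconds = trSeconds)
  b
}

#' Write an ROI time-series matrix as TSV
#'
#' @param mat `[N, T]` numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(mat, path) {
  writeLines(apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             path)
  invisible(path)
}

#' Z-score every (subject, ROI) row
#'
#' Standardizes each ROI time series to zero mean and unit standard deviation.
#' The population (1/T) standard deviation is the default; rows with zero
#' variance are mapped to all zeros and flagged in `constantRows`.
#'
#' @param batch an [RoiTimeSeriesBatch-class].
#' @param sdType `"population"` (1/T) or `"sample"` (1/(T-1)).
#' @return The standardized batch.
#' @export
standardizeBatch <- function(batch, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  x <- batch@data
  d <- dim(x)
  if (d[3L] < 2L) stop("standardization needs at least 2 time points")
  flagged <- NULL
  for (s in seq_len(d[1L])) {
    m <- x[s, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, d[2L], d[3L])
    mu <- rowMeans(m)
    mc <- m - mu
    ss <- rowSums(mc * mc)
    denom <- if (sdType == "population") d[3L] else d[3L] - 1L
    sdv <- sqrt(ss / denom)
    const <- sdv < 1e-12
    sdv[const] <- 1
    mc <- mc / sdv
    mc[const, ] <- 0
    x[s, , ] <- mc
    if (any(const)) flagged <- rbind(flagged, cbind(s, which(const)))
  }
  out <- batch
  out@data <- x
  out@standardized <- TRUE
  if (!is.null(flagged)) {
    colnames(flagged) <- c("subject", "roi")
    out@constantRows <- flagged
  }
  out
}

#' Write / read a square connectivity matrix as named TSV
#'
#' Full-precision TSV with a header row and a leading column of ROI names;
#' a write/read round trip reproduces values to better than 1e-12.
#'
#' @param mat square numeric matrix.
#' @param roiNames character names, one per ROI.
#' @param path file path.
#' @return `writeConnectivity` returns `path`; `readConnectivity` returns a
#'   named square matrix.
#' @export
writeConnectivity <- function(mat, roiNames = NULL, path) {
  if (nrow(mat) != ncol(mat)) stop("connectivity matrix must be square")
  if (is.null(roiNames)) roiNames <- rownames(mat) %||% sprintf("roi%03d", seq_len(nrow(mat)))
  if (length(roiNames) != nrow(mat))
    stop("roiNames length (", length(roiNames), ") must match matrix order (",
         nrow(mat), ")")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("roi", roiNames), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(roiNames[i], sprintf("%.17g", mat[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeConnectivity
#' @export
readConnectivity <- function(path) {
  d <- read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("connectivity matrix on disk is not square")
  m
}

#' Write / read an ROI to network map as two-column TSV
#'
#' Columns `roi_name` and `network_id`; an optional third column
#' `network_name` is written when names are available.
#'
#' @param map a [NetworkMap-class].
#' @param path file path.
#' @param roiNames optional ROI names.
#' @return `readNetworkMap` returns a [NetworkMap-class].
#' @export
writeNetworkMap <- function(map, path, roiNames = NULL) {
  n <- length(map@roiToNetwork)
  if (is.null(roiNames)) roiNames <- sprintf("roi%03d", seq_len(n))
  df <- data.frame(roi_name = roiNames, network_id = map@roiToNetwork,
                   network_name = map@networkNames[map@roiToNetwork])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetworkMap
#' @export
readNetworkMap <- function(path) {
  df <- read.delim(path)
  nm <- if ("network_name" %in% names(df)) {
    vapply(seq_len(max(df$network_id)), function(k) {
      v <- unique(df$network_name[df$network_id == k])
      if (length(v)) v[1L] else sprintf("network%d", k)
    }, "")
  } else NULL
  networkMap(df$network_id, nm)
}

#' Write a fixture cohort to a directory
#'
#' Lays out the canonical on-disk cohort: one TSV per subject under
#' `timeseries/`, `labels.tsv`, `network_map.tsv` and a JSON manifest holding
#' the generating specification and the true effect edges.
#'
#' @param cohort a list as returned by [generateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  b <- cohort$batch
  ids <- subjectIds(b)
  for (s in seq_len(nSubjects(b))) {
    writeTimeSeries(b@data[s, , ], file.path(dir, "timeseries", paste0(ids[s], ".tsv")))
  }
  write.table(data.frame(subject_id = ids, label = cohort$labels),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeNetworkMap(cohort$map, file.path(dir, "network_map.tsv"))
  eff <- which(cohort$trueDiffMask & upper.tri(cohort$trueDiffMask), arr.ind = TRUE)
  spec <- unclass(cohort$spec)
  spec$effectEdges <- NULL
  manifest <- list(spec = spec,
                   effect_edges = if (nrow(eff))
                     data.frame(i = eff[, 1L], j = eff[, 2L]) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @return A list with `batch`, `labels`, `map` and (when present) `manifest`.
#' @export
loadCohort <- function(dir) {
  lab <- read.delim(file.path(dir, "labels.tsv"))
  mats <- lapply(lab$subject_id, function(id) {
    .parseNumericMatrix(file.path(dir, "timeseries", paste0(id, ".tsv")))
  })
  d1 <- dim(mats[[1L]])
  ok <- vapply(mats, function(m) identical(dim(m), d1), TRUE)
  if (!all(ok)) stop("subjects disagree on [N, T] dimensions")
  arr <- array(0, c(length(mats), d1[1L], d1[2L]))
  for (s in seq_along(mats)) arr[s, , ] <- mats[[s]]
  manifestPath <- file.path(dir, "manifest.json")
  list(batch = roiTimeSeriesBatch(arr, subjectIds = lab$subject_id),
       labels = as.integer(lab$label),
       map = readNetworkMap(file.path(dir, "network_map.tsv")),
       manifest = if (file.exists(manifestPath))
         jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL)
}

#' Validate a binary label vector
#'
#' @param labels integer vector with values in {0, 1}.
#' @param requireBoth require both classes present.
#' @return The labels as integers.
#' @export
checkLabels <- function(labels, requireBoth = TRUE) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  if (requireBoth && length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}
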