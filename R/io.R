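#' Read a nodal time-series table
#'
#' Reads a timepoints x nodes text matrix with a header row of node labels.
#' The delimiter is auto-detected between tab and comma. Rows are
#' timepoints, columns nodes.
#'
#' @param path file path.
#' @param trSeconds repetition time in seconds to attach (default 0.72).
#' @return a \code{\linkS4class{NodalTimeSeries}}.
#' @export
readNodalTimeSeries <- function(path, trSeconds = 0.72) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  labels <- strsplit(header, sep, fixed = TRUE)[[1L]]
  if (anyDuplicated(labels))
    stop("duplicate node label(s) in header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  widths <- lengths(strsplit(readLines(path), sep, fixed = TRUE))
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged table: line %d has %d fields, expected %d",
                 which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L]))
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, fill = FALSE)
  bad <- which(!vapply(dt, is.numeric, logical(1L)))
  if (length(bad)) {
    col <- dt[[bad[1L]]]
    line <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
    stop(sprintf("non-numeric value in column '%s' (data line %d)",
                 names(dt)[bad[1L]], if (is.na(line)) 1L else line))
  }
  NodalTimeSeries(as.matrix(dt), trSeconds = trSeconds)
}

#' Write a nodal time-series table
#'
#' Tab-separated, one row per timepoint, header row of node labels; the
#' round trip through \code{\link{readNodalTimeSeries}} preserves values to
#' full double precision.
#'
#' @param series a \code{\linkS4class{NodalTimeSeries}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNodalTimeSeries <- function(series, path) {
  stopifnot(is(series, "NodalTimeSeries"))
  df <- as.data.frame(series@values)
  # %.17g keeps the full double-precision round trip
  df[] <- lapply(df, function(x) sub("e", "E", sprintf("%.17g", x)))
  data.table::fwrite(df, path, sep = "\t", col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Read a node-subset file
#'
#' Plain text, one node label per line; blank lines and lines starting with
#' \code{#} are ignored.
#'
#' @param path file path.
#' @return character vector of node labels.
#' @export
readNodeSubset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x))
    stop("duplicate node label(s) in subset file: ",
         paste(unique(x[duplicated(x)]), collapse = ", "))
  x
}

#' Concatenate scan runs
#'
#' Row-wise concatenation of several runs of the same parcellation, in the
#' given order. Concatenation happens on the raw series, before z-scoring;
#' z-scoring the concatenated series is not the same as z-scoring each run
#' (run-specific means/scales are preserved here and removed jointly later).
#'
#' @param runs list of \code{\linkS4class{NodalTimeSeries}} sharing node
#'   labels and TR.
#' @return a single \code{\linkS4class{NodalTimeSeries}}.
#' @export
concatenateRuns <- function(runs) {
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, is, logical(1L), "NodalTimeSeries")))
  if (length(runs) == 1L) return(runs[[1L]])
  lab <- nodeLabels(runs[[1L]])
  tr <- trSeconds(runs[[1L]])
  for (r in runs[-1L]) {
    if (!identical(nodeLabels(r), lab)) stop("runs differ in node labels")
    if (!identical(trSeconds(r), tr)) stop("runs differ in TR")
  }
  NodalTimeSeries(do.call(rbind, lapply(runs, seriesValues)),
                  trSeconds = tr)
}

#' Write a simulated cohort to disk
#'
#' One TSV per subject plus a cohort CSV (subject_id, group, age_years,
#' brain_volume_ml, series_path) and the spec's scalar parameters as JSON.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return path of the cohort CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort@subjects, function(s) {
    p <- file.path(dir, paste0(s@subjectId, ".tsv"))
    writeNodalTimeSeries(s@series, p)
    basename(p)
  }, character(1L))
  tab <- cohort@table
  tab$series_path <- paths
  csv <- file.path(dir, "cohort.csv")
  data.table::fwrite(tab, csv)
  spec <- cohort@spec
  jsonlite::write_json(
    list(n_nodes = spec@nNodes, n_timepoints = spec@nTimepoints,
         tr_seconds = spec@trSeconds, n_states = spec@nStates,
         stay_prob = as.list(spec@stayProb), smooth_sd = spec@smoothSd,
         group_sizes = as.list(spec@groupSizes), seed = spec@seed),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a cohort directory
#'
#' @param dir directory written by \code{\link{writeCohort}} (or laid out the
#'   same way: \code{cohort.csv} plus one series file per subject).
#' @param trSeconds TR attached to each series.
#' @return list: \code{table} (data.frame) and \code{series} (named list of
#'   \code{\linkS4class{NodalTimeSeries}}).
#' @export
readCohort <- function(dir, trSeconds = 0.72) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stop("no cohort.csv in ", dir)
  tab <- data.table::fread(csv, data.table = FALSE)
  series <- lapply(tab$series_path, function(p)
    readNodalTimeSeries(file.path(dir, p), trSeconds = trSeconds))
  names(series) <- tab$subject_id
  list(table = tab, series = series)
}
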