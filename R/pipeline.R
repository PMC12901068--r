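#' Pipeline configuration
#'
#' @param trSeconds repetition time in seconds.
#' @param thetas magnitude-criterion fractions, each in [0, 0.5).
#' @param mode criterion mode, \code{"adjacent-sample"} or
#'   \code{"adjacent-peak"}.
#' @param nodeSubset optional character vector of node labels defining a
#'   subnetwork (e.g. a default-mode-network node list); the pipeline then
#'   analyzes the subnetwork RSS alongside nothing else (one scope per run).
#' @param label scope label for reporting.
#' @return validated list of class \code{"cofluxConfig"}.
#' @export
pipelineConfig <- function(trSeconds = 0.72,
                           thetas = c(0, 0.01, 0.02, 0.05),
                           mode = c("adjacent-sample", "adjacent-peak"),
                           nodeSubset = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (trSeconds <= 0) stop("'trSeconds' must be positive")
  if (any(thetas < 0 | thetas >= 0.5)) stop("each theta must lie in [0, 0.5)")
  structure(list(trSeconds = trSeconds, thetas = thetas, mode = mode,
                 nodeSubset = nodeSubset,
                 label = if (is.null(label)) {
                   if (is.null(nodeSubset)) "whole-brain" else "subset"
                 } else label),
            class = "cofluxConfig")
}

.subjectSeriesList <- function(x) {
  if (is(x, "SyntheticCohort"))
    return(stats::setNames(lapply(x@subjects, slot, "series"),
                           vapply(x@subjects, slot, character(1L),
                                  "subjectId")))
  stopifnot(is.list(x), !is.null(names(x)))
  x
}

#' Per-subject summaries for a whole cohort
#'
#' For each subject: z-score the nodal series, form the RSS co-fluctuation
#' trace (optionally restricted to a node subset), and summarize troughs and
#' peaks under each criterion.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}, or a named list of
#'   \code{\linkS4class{NodalTimeSeries}} keyed by subject id.
#' @param criteria list of \code{\linkS4class{TroughCriterion}} objects.
#' @param nodeSubset optional node-label subset (within-subset edges only).
#' @param label scope label stored on each row.
#' @return data.frame, one row per subject x criterion (columns as in
#'   \code{\link{summarizeSubject}}).
#' @examples
#' co <- simulateCohort(syntheticSpec(groupSizes = c(A = 2, B = 2),
#'                                    nTimepoints = 150), seed = 3)
#' head(summarizeCohort(co, list(troughCriterion(0))))
#' @export
summarizeCohort <- function(cohort, criteria = list(troughCriterion(0)),
                            nodeSubset = NULL, label = NULL) {
  series <- .subjectSeriesList(cohort)
  rows <- lapply(names(series), function(id) {
    z <- zscoreNodes(series[[id]])
    rss <- computeRSS(z, nodeSubset = nodeSubset, label = label)
    base <- detectBaseExtrema(rss)
    do.call(rbind, lapply(criteria, function(cr) {
      res <- applyMagnitudeCriterion(base, rss, cr)
      k <- length(res@troughIndices)
      data.frame(subject_id = id, label = rss@label, theta = cr@theta,
                 mode = cr@mode, n_troughs = k,
                 n_peaks = length(res@peakIndices),
                 mean_duration_s = if (k >= 2L) mean(res@durationsSeconds)
                                   else NA_real_,
                 mean_peak_height = if (k >= 2L) mean(res@peakHeights)
                                    else NA_real_,
                 analyzable = k >= 2L, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Group models over all criteria and outcomes
#'
#' Joins per-subject summaries with the covariate table and fits one
#' group-effect model (age and brain volume as covariates) per combination
#' of scope label, criterion and outcome. Subjects flagged unanalyzable for
#' a criterion are excluded from that fit and counted.
#'
#' @param summaries data.frame from \code{\link{summarizeCohort}}.
#' @param covariates data.frame with subject_id, group, age_years,
#'   brain_volume_ml.
#' @param outcomes outcome columns to model.
#' @return data.frame, one row per label x theta x mode x outcome: F, df,
#'   p, adjusted means and SEs per group, and exclusion counts.
#' @export
cohortAncova <- function(summaries, covariates,
                         outcomes = c("mean_duration_s",
                                      "mean_peak_height")) {
  tab <- merge(summaries, covariates, by = "subject_id")
  if (nrow(tab) != nrow(summaries))
    stop("some summary rows have no covariate row (subject_id mismatch)")
  combos <- unique(tab[, c("label", "theta", "mode")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- merge(tab, combos[i, , drop = FALSE],
                 by = c("label", "theta", "mode"))
    do.call(rbind, lapply(outcomes, function(oc) {
      fit <- ancovaGroupEffect(sub, outcome = oc)
      m <- fit@adjustedMeans
      out <- data.frame(label = combos$label[i], theta = combos$theta[i],
                        mode = combos$mode[i], outcome = oc,
                        f = fit@fStatistic, df1 = fit@dfNum,
                        df2 = fit@dfDen, p = fit@pValue,
                        n_analyzed = fit@nObs,
                        n_excluded = sum(!sub$analyzable |
                                         is.na(sub[[oc]])),
                        stringsAsFactors = FALSE)
      for (g in seq_len(nrow(m))) {
        out[[paste0("adj_mean_", m$group[g])]] <- m$adjusted_mean[g]
        out[[paste0("se_", m$group[g])]] <- m$se[g]
      }
      out
    }))
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on a cohort directory
#'
#' Reads a cohort written by \code{\link{writeCohort}} (or an equivalent
#' layout), computes per-subject RSS extrema summaries under every
#' configured criterion, fits the group models, and (when \code{outDir} is
#' given) writes \code{summaries.csv}, \code{results.csv} and a
#' \code{manifest.json} recording subject counts, exclusions and any
#' per-subject failures. Failing subjects are logged and skipped, not fatal.
#'
#' @param cohortDir directory containing \code{cohort.csv} and series files.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory.
#' @return list: \code{summaries}, \code{results}, \code{manifest}.
#' @export
runPipeline <- function(cohortDir, config = pipelineConfig(),
                        outDir = NULL) {
  stopifnot(inherits(config, "cofluxConfig"))
  co <- readCohort(cohortDir, trSeconds = config$trSeconds)
  criteria <- lapply(config$thetas, troughCriterion, mode = config$mode)
  failures <- character(0)
  summaries <- NULL
  for (id in names(co$series)) {
    row <- tryCatch(
      summarizeCohort(co$series[id], criteria = criteria,
                      nodeSubset = config$nodeSubset,
                      label = config$label),
      error = function(e) {
        warning(sprintf("subject %s failed: %s", id, conditionMessage(e)))
        NULL
      })
    if (is.null(row)) failures <- c(failures, id) else
      summaries <- rbind(summaries, row)
  }
  if (is.null(summaries)) stop("every subject failed; nothing to analyze")
  results <- cohortAncova(summaries, co$table)
  manifest <- list(
    n_subjects = nrow(co$table),
    n_analyzed = length(unique(summaries$subject_id)),
    n_failed = length(failures),
    failed_subjects = failures,
    n_excluded_rows = sum(!summaries$analyzable),
    thetas = config$thetas, mode = config$mode, label = config$label,
    tr_seconds = config$trSeconds)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(summaries, file.path(outDir, "summaries.csv"))
    data.table::fwrite(results, file.path(outDir, "results.csv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(summaries = summaries, results = results, manifest = manifest)
}

#' Plot an RSS trace with its extrema
#'
#' Base-graphics trace of the co-fluctuation amplitude over time, marking
#' troughs and peaks.
#'
#' @param rss an \code{\linkS4class{RssSeries}}.
#' @param result optional \code{\linkS4class{ExtremaResult}} to overlay.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotRss <- function(rss, result = NULL, ...) {
  stopifnot(is(rss, "RssSeries"))
  tt <- (seq_along(rss@values) - 1L) * rss@trSeconds
  plot(tt, rss@values, type = "l", xlab = "time (s)",
       ylab = "RSS co-fluctuation amplitude", main = rss@label, ...)
  if (!is.null(result)) {
    points(tt[result@troughIndices], rss@values[result@troughIndices],
           pch = 25, bg = "steelblue")
    points(tt[result@peakIndices], result@peakHeights, pch = 24,
           bg = "firebrick")
  }
  invisible(NULL)
}
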