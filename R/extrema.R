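#' Build a trough criterion
#'
#' @param theta fraction in [0, 0.5). 0 is the base rule (any strict local
#'   minimum); 0.01, 0.02, 0.05 require a trough to be at least 1/2/5 percent
#'   lower than its reference values. The percent test is boundary-inclusive:
#'   a trough survives when \code{rss[trough] <= (1 - theta) * reference},
#'   evaluated with a 1e-12 relative tolerance so that values sitting exactly
#'   on the boundary in decimal (e.g. 2.97 against 0.99 * 3) are kept despite
#'   binary floating-point representation of \code{1 - theta}.
#' @param mode \code{"adjacent-sample"} (references are the two neighbouring
#'   samples; the default, matching the literal reading of the rule) or
#'   \code{"adjacent-peak"} (references are the flanking peaks of the
#'   alternating trough/peak sequence, pruned iteratively).
#' @return a \code{\linkS4class{TroughCriterion}}.
#' @examples
#' troughCriterion(0.02)
#' @export
troughCriterion <- function(theta = 0, mode = c("adjacent-sample",
                                                "adjacent-peak")) {
  new("TroughCriterion", theta = as.numeric(theta), mode = match.arg(mode))
}

setMethod("show", "TroughCriterion", function(object) {
  cat(sprintf("TroughCriterion: theta = %g (%s)\n", object@theta, object@mode))
})

## boundary-inclusive percent comparisons use a relative tolerance so the
## documented <= convention survives binary representation of (1 - theta)
.boundaryTol <- 1e-12

## peak = earliest index attaining the max of the open interval between
## consecutive troughs
.peaksBetween <- function(x, troughs) {
  k <- length(troughs)
  if (k < 2L) return(integer(0))
  vapply(seq_len(k - 1L), function(i) {
    iv <- (troughs[i] + 1L):(troughs[i + 1L] - 1L)
    iv[which.max(x[iv])]
  }, integer(1L))
}

.extremaResult <- function(x, troughs, criterion, trSec) {
  peaks <- .peaksBetween(x, troughs)
  new("ExtremaResult",
      troughIndices = as.integer(troughs), peakIndices = peaks,
      peakHeights = x[peaks], durationsSeconds = diff(troughs) * trSec,
      criterion = criterion, trSeconds = trSec,
      nTimepoints = length(x))
}

#' Detect base troughs and peaks
#'
#' A trough is a strict local minimum of the RSS trace: a value lower than
#' the values directly before and after it (ties disqualify). The peak
#' between two consecutive troughs is the highest value in the open interval
#' (earliest index on ties). The first and last timepoints are never
#' extrema, and partial intervals before the first / after the last trough
#' contribute neither peaks nor durations.
#'
#' @param rss an \code{\linkS4class{RssSeries}} (length >= 3).
#' @return an \code{\linkS4class{ExtremaResult}} with criterion theta = 0.
#' @examples
#' rss <- new("RssSeries", values = c(3, 1, 2, 1, 3), trSeconds = 0.72,
#'            nEdges = 10L, label = "demo")
#' troughIndices(detectBaseExtrema(rss))  # 2 and 4
#' @export
detectBaseExtrema <- function(rss) {
  stopifnot(is(rss, "RssSeries"))
  x <- rss@values
  if (length(x) < 3L) stop("RSS series too short: need at least 3 timepoints")
  w <- 2L:(length(x) - 1L)
  troughs <- w[x[w] < x[w - 1L] & x[w] < x[w + 1L]]
  .extremaResult(x, troughs, troughCriterion(0), rss@trSeconds)
}

## flanking-peak validity under the boundary-inclusive percent rule; troughs
## with no flanking peak on either side (single-trough case) are vacuously valid
.adjacentPeakViolations <- function(x, troughs, theta) {
  k <- length(troughs)
  if (k == 0L) return(list(viol = integer(0), ratio = numeric(0)))
  pv <- x[.peaksBetween(x, troughs)]
  ratio <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    fl <- c(if (i > 1L) pv[i - 1L], if (i < k) pv[i])
    if (length(fl)) ratio[i] <- x[troughs[i]] / min(fl)
  }
  list(viol = which(!is.na(ratio) &
                    ratio > (1 - theta) * (1 + .boundaryTol)),
       ratio = ratio)
}

#' Apply a percent-magnitude trough criterion
#'
#' Prunes the base trough set so every surviving trough is at least
#' \code{theta} lower (proportionally, boundary-inclusive) than its reference
#' values, then recomputes the peaks between surviving troughs.
#'
#' \code{adjacent-sample} mode keeps trough t iff
#' \code{rss[t] <= (1 - theta) * rss[t - 1]} and
#' \code{rss[t] <= (1 - theta) * rss[t + 1]} — a single pass, so the trough
#' sets are nested across increasing theta.
#'
#' \code{adjacent-peak} mode works on the alternating trough/peak sequence:
#' while any trough is less than \code{theta} below the lower of its flanking
#' peaks, the shallowest such trough (largest trough/peak ratio) is removed
#' and its two segments merged (the higher flanking peak survives); removals
#' only raise the remaining flanking peaks, so already-valid troughs stay
#' valid.
#'
#' @param base the base \code{\linkS4class{ExtremaResult}} from
#'   \code{\link{detectBaseExtrema}} on the same series.
#' @param rss the \code{\linkS4class{RssSeries}} the base result came from.
#' @param criterion a \code{\linkS4class{TroughCriterion}}.
#' @return an \code{\linkS4class{ExtremaResult}} under \code{criterion};
#'   \code{theta = 0} returns \code{base} unchanged.
#' @examples
#' rss <- new("RssSeries", values = c(3, 2.97, 3, 1, 3), trSeconds = 1,
#'            nEdges = 10L, label = "demo")
#' b <- detectBaseExtrema(rss)
#' nTroughs(applyMagnitudeCriterion(b, rss, troughCriterion(0.02)))
#' @export
applyMagnitudeCriterion <- function(base, rss, criterion) {
  stopifnot(is(base, "ExtremaResult"), is(rss, "RssSeries"),
            is(criterion, "TroughCriterion"))
  x <- rss@values
  if (base@nTimepoints != length(x))
    stop("'base' was not produced from this RSS series (length mismatch)")
  bt <- base@troughIndices
  if (length(bt) && !all(x[bt] < x[bt - 1L] & x[bt] < x[bt + 1L]))
    stop("'base' does not match the RSS series: stored troughs are not local minima")
  theta <- criterion@theta
  if (theta == 0) {
    return(new("ExtremaResult", troughIndices = base@troughIndices,
               peakIndices = base@peakIndices, peakHeights = base@peakHeights,
               durationsSeconds = base@durationsSeconds, criterion = criterion,
               trSeconds = base@trSeconds, nTimepoints = base@nTimepoints))
  }
  troughs <- base@troughIndices
  if (criterion@mode == "adjacent-sample") {
    thr <- (1 - theta) * (1 + .boundaryTol)
    keep <- x[troughs] <= thr * x[troughs - 1L] &
            x[troughs] <= thr * x[troughs + 1L]
    troughs <- troughs[keep]
  } else {
    repeat {
      v <- .adjacentPeakViolations(x, troughs, theta)
      if (!length(v$viol)) break
      drop <- v$viol[which.max(v$ratio[v$viol])]
      troughs <- troughs[-drop]
    }
  }
  .extremaResult(x, troughs, criterion, base@trSeconds)
}

#' Detect extrema under a criterion
#'
#' Convenience wrapper: base detection followed by
#' \code{\link{applyMagnitudeCriterion}}.
#'
#' @inheritParams applyMagnitudeCriterion
#' @param rss an \code{\linkS4class{RssSeries}}.
#' @return an \code{\linkS4class{ExtremaResult}}.
#' @export
detectExtrema <- function(rss, criterion = troughCriterion(0)) {
  applyMagnitudeCriterion(detectBaseExtrema(rss), rss, criterion)
}

setMethod("show", "ExtremaResult", function(object) {
  cat(sprintf("ExtremaResult: %d troughs, %d peaks (theta = %g, %s) over %d timepoints\n",
              length(object@troughIndices), length(object@peakIndices),
              object@criterion@theta, object@criterion@mode,
              object@nTimepoints))
})

#' Trough-to-trough durations
#'
#' @param result an \code{\linkS4class{ExtremaResult}}.
#' @param trSeconds optional TR override; defaults to the TR stored on the
#'   result.
#' @return numeric vector of consecutive trough-to-trough intervals in
#'   seconds (empty with fewer than 2 troughs).
#' @export
troughDurations <- function(result, trSeconds = NULL) {
  stopifnot(is(result, "ExtremaResult"))
  if (is.null(trSeconds)) return(result@durationsSeconds)
  diff(result@troughIndices) * trSeconds
}

#' Peak heights
#'
#' The RSS value at each peak — the absolute y-axis value, not a height
#' relative to the flanking troughs.
#'
#' @param result an \code{\linkS4class{ExtremaResult}}.
#' @return numeric vector of peak RSS values.
#' @export
peakHeights <- function(result) {
  stopifnot(is(result, "ExtremaResult"))
  result@peakHeights
}

#' Per-subject extrema summary
#'
#' Runs trough/peak detection on one RSS trace under one criterion and
#' returns the subject-level outcomes used in group analyses: mean
#' trough-to-trough duration (seconds) and mean peak height. Subjects with
#' fewer than 2 troughs have undefined means; they are flagged
#' (\code{analyzable = FALSE}), never silently dropped.
#'
#' @param rss an \code{\linkS4class{RssSeries}}.
#' @param criterion a \code{\linkS4class{TroughCriterion}}.
#' @param subjectId subject identifier.
#' @param label scope label; defaults to the label on \code{rss}.
#' @return one-row data.frame: subject_id, label, theta, mode, n_troughs,
#'   n_peaks, mean_duration_s, mean_peak_height, analyzable.
#' @examples
#' rss <- new("RssSeries", values = c(3, 1, 2, 1, 4, 1, 3), trSeconds = 1,
#'            nEdges = 10L, label = "demo")
#' summarizeSubject(rss, troughCriterion(0), "s1")
#' @export
summarizeSubject <- function(rss, criterion = troughCriterion(0),
                             subjectId, label = NULL) {
  res <- detectExtrema(rss, criterion)
  k <- length(res@troughIndices)
  data.frame(
    subject_id = as.character(subjectId),
    label = if (is.null(label)) rss@label else label,
    theta = criterion@theta,
    mode = criterion@mode,
    n_troughs = k,
    n_peaks = length(res@peakIndices),
    mean_duration_s = if (k >= 2L) mean(res@durationsSeconds) else NA_real_,
    mean_peak_height = if (k >= 2L) mean(res@peakHeights) else NA_real_,
    analyzable = k >= 2L,
    stringsAsFactors = FALSE)
}
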