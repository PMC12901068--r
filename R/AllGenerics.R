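#' Accessor generics
#'
#' Small accessor family shared by the co-fluctuation containers:
#' \code{seriesValues} returns the numeric payload (matrix or vector),
#' \code{trSeconds} the repetition time, \code{nodeLabels} the node labels,
#' \code{nTimepoints}/\code{nNodes}/\code{nEdges} the obvious counts, and
#' \code{edgePairs} the two-column (i, j) pair matrix of an edge ordering.
#'
#' @param x a package object.
#' @return the accessed component.
#' @examples
#' ei <- buildEdgeIndex(4)
#' nEdges(ei)
#' head(edgePairs(ei))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname accessors
#' @export
setGeneric("edgePairs", function(x) standardGeneric("edgePairs"))

#' @rdname accessors
#' @export
setMethod("seriesValues", "NodalTimeSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("seriesValues", "EdgeTimeSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("seriesValues", "RssSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("seriesValues", "EfcMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("trSeconds", "NodalTimeSeries", function(x) x@trSeconds)
#' @rdname accessors
#' @export
setMethod("trSeconds", "EdgeTimeSeries", function(x) x@trSeconds)
#' @rdname accessors
#' @export
setMethod("trSeconds", "RssSeries", function(x) x@trSeconds)

#' @rdname accessors
#' @export
setMethod("nodeLabels", "NodalTimeSeries", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("nTimepoints", "NodalTimeSeries", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nTimepoints", "RssSeries", function(x) length(x@values))

#' @rdname accessors
#' @export
setMethod("nNodes", "NodalTimeSeries", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("nNodes", "EdgeIndex", function(x) x@nNodes)

#' @rdname accessors
#' @export
setMethod("nEdges", "EdgeIndex", function(x) nrow(x@pairs))
#' @rdname accessors
#' @export
setMethod("nEdges", "EdgeTimeSeries", function(x) nrow(x@edgeIndex@pairs))
#' @rdname accessors
#' @export
setMethod("nEdges", "RssSeries", function(x) x@nEdges)

#' @rdname accessors
#' @export
setMethod("edgePairs", "EdgeIndex", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("edgePairs", "EdgeTimeSeries", function(x) x@edgeIndex@pairs)

#' Trough and peak accessors
#'
#' @param x an \code{\linkS4class{ExtremaResult}}.
#' @return \code{troughIndices}/\code{peakIndices}: integer timepoint indices
#'   (1-based); \code{nTroughs}: the trough count.
#' @name extrema-accessors
NULL

#' @rdname extrema-accessors
#' @export
setGeneric("troughIndices", function(x) standardGeneric("troughIndices"))
#' @rdname extrema-accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))
#' @rdname extrema-accessors
#' @export
setGeneric("nTroughs", function(x) standardGeneric("nTroughs"))

#' @rdname extrema-accessors
#' @export
setMethod("troughIndices", "ExtremaResult", function(x) x@troughIndices)
#' @rdname extrema-accessors
#' @export
setMethod("peakIndices", "ExtremaResult", function(x) x@peakIndices)
#' @rdname extrema-accessors
#' @export
setMethod("nTroughs", "ExtremaResult", function(x) length(x@troughIndices))

#' @rdname accessors
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
#' @rdname accessors
#' @export
setMethod("cohortTable", "SyntheticCohort", function(x) x@table)
#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))
#' @rdname accessors
#' @export
setMethod("cohortSubjects", "SyntheticCohort", function(x) x@subjects)
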