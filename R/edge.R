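#' Construct a nodal time-series object
#'
#' @param values numeric matrix, timepoints in rows and nodes in columns.
#'   Column names are used as node labels; when absent, labels
#'   \code{node_001, ...} are generated.
#' @param trSeconds repetition time (TR) in seconds.
#' @param nodeLabels optional character vector overriding the column names.
#' @param zscored set \code{TRUE} only for data already standardized per node.
#'
#' @return a \code{\linkS4class{NodalTimeSeries}}.
#' @examples
#' x <- NodalTimeSeries(matrix(rnorm(30), 10, 3), trSeconds = 0.72)
#' nTimepoints(x)
#' @export
NodalTimeSeries <- function(values, trSeconds, nodeLabels = NULL,
                            zscored = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(nodeLabels)) colnames(values) <- nodeLabels
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("node_%03d", seq_len(ncol(values)))
  new("NodalTimeSeries", values = values, trSeconds = as.numeric(trSeconds),
      zscored = isTRUE(zscored))
}

setMethod("show", "NodalTimeSeries", function(object) {
  cat(sprintf("NodalTimeSeries: %d timepoints x %d nodes, TR = %g s%s\n",
              nrow(object@values), ncol(object@values), object@trSeconds,
              if (object@zscored) " (z-scored)" else ""))
})

#' Z-score each node's time series
#'
#' Standardizes every column to mean 0 and unit standard deviation, using the
#' sample (n - 1) denominator. This is the first step of the edge
#' time-series construction; the same convention is used wherever the package
#' relates edge products to Pearson correlations.
#'
#' @param series a \code{\linkS4class{NodalTimeSeries}}.
#' @return a z-scored \code{\linkS4class{NodalTimeSeries}}.
#' @examples
#' z <- zscoreNodes(NodalTimeSeries(matrix(rnorm(40), 20, 2), 0.72))
#' colMeans(seriesValues(z))  # ~0
#' @export
zscoreNodes <- function(series) {
  stopifnot(is(series, "NodalTimeSeries"))
  v <- series@values
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(v)[sds == 0]
    stop("cannot z-score constant node column(s): ",
         paste(bad, collapse = ", "))
  }
  z <- scale(v, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  colnames(z) <- colnames(v)
  new("NodalTimeSeries", values = z, trSeconds = series@trSeconds,
      zscored = TRUE)
}

#' Enumerate all node pairs
#'
#' Builds the canonical edge ordering: every unordered pair (i, j) with
#' i < j, sorted lexicographically. For the 268-node parcellation used in
#' whole-brain analyses this yields 35,778 edges.
#'
#' @param nNodes number of nodes (>= 2).
#' @return an \code{\linkS4class{EdgeIndex}}.
#' @examples
#' nEdges(buildEdgeIndex(268))  # 35778
#' @export
buildEdgeIndex <- function(nNodes) {
  nNodes <- as.integer(nNodes)
  if (length(nNodes) != 1L || is.na(nNodes) || nNodes < 2L)
    stop("'nNodes' must be a single integer >= 2")
  i <- rep.int(seq_len(nNodes - 1L), times = (nNodes - 1L):1L)
  j <- sequence((nNodes - 1L):1L) + i
  new("EdgeIndex", pairs = cbind(i = i, j = j), nNodes = nNodes)
}

setMethod("show", "EdgeIndex", function(object) {
  cat(sprintf("EdgeIndex: %d nodes, %d edges (i < j, lexicographic)\n",
              object@nNodes, nrow(object@pairs)))
})

.requireZscored <- function(series, caller) {
  if (!series@zscored)
    stop(caller, "() expects a z-scored series; run zscoreNodes() first")
}

#' Compute edge time series
#'
#' For each node pair (i, j) forms the per-timepoint product
#' z_i(t) * z_j(t) of the z-scored signals. The time average of an edge
#' column equals (up to the n/(n-1) factor of the sample-sd convention) the
#' Pearson correlation of the two nodes, so the edge time series is an exact
#' temporal unwrapping of functional connectivity.
#'
#' @param zseries z-scored \code{\linkS4class{NodalTimeSeries}}.
#' @param edgeIndex optional \code{\linkS4class{EdgeIndex}}; built from the
#'   node count when omitted. Must match the node count.
#' @return an \code{\linkS4class{EdgeTimeSeries}}; columns are labelled
#'   \code{"<node_i>~<node_j>"}.
#' @examples
#' z <- zscoreNodes(NodalTimeSeries(matrix(rnorm(50), 10, 5), 0.72))
#' ets <- computeETS(z)
#' dim(seriesValues(ets))  # 10 x 10
#' @export
computeETS <- function(zseries, edgeIndex = NULL) {
  stopifnot(is(zseries, "NodalTimeSeries"))
  .requireZscored(zseries, "computeETS")
  n <- ncol(zseries@values)
  if (is.null(edgeIndex)) edgeIndex <- buildEdgeIndex(n)
  if (edgeIndex@nNodes != n)
    stop(sprintf("edge index is for %d nodes but the series has %d",
                 edgeIndex@nNodes, n))
  z <- zseries@values
  p <- edgeIndex@pairs
  ets <- z[, p[, 1L], drop = FALSE] * z[, p[, 2L], drop = FALSE]
  colnames(ets) <- paste(colnames(z)[p[, 1L]], colnames(z)[p[, 2L]],
                         sep = "~")
  new("EdgeTimeSeries", values = ets, edgeIndex = edgeIndex,
      trSeconds = zseries@trSeconds)
}

#' Root-sum-square co-fluctuation amplitude
#'
#' Collapses all edge time series into a single amplitude trace:
#' RSS(t) = sqrt( sum over i<j of (z_i(t) z_j(t))^2 ). With a node subset
#' (e.g. a default-mode-network node list) only within-subset pairs
#' contribute. By default the algebraic identity
#' RSS(t)^2 = ((sum_i z_i^2)^2 - sum_i z_i^4) / 2 is used, which avoids
#' materializing the edge matrix; \code{explicitEdges = TRUE} forces the
#' direct edge-by-edge accumulation (the oracle path).
#'
#' @param zseries z-scored \code{\linkS4class{NodalTimeSeries}}.
#' @param nodeSubset optional character vector of node labels (or integer
#'   indices) restricting the edge set to within-subset pairs; at least 2.
#' @param explicitEdges logical; force the explicit edge enumeration.
#' @param label scope label stored on the result; defaults to
#'   \code{"whole-brain"}, or \code{"subset"} when \code{nodeSubset} is given.
#' @return an \code{\linkS4class{RssSeries}}.
#' @examples
#' z <- zscoreNodes(NodalTimeSeries(matrix(rnorm(200), 50, 4), 0.72))
#' rss <- computeRSS(z)
#' head(seriesValues(rss))
#' @export
computeRSS <- function(zseries, nodeSubset = NULL, explicitEdges = FALSE,
                       label = NULL) {
  stopifnot(is(zseries, "NodalTimeSeries"))
  .requireZscored(zseries, "computeRSS")
  z <- zseries@values
  if (!is.null(nodeSubset)) {
    if (is.numeric(nodeSubset)) {
      if (any(nodeSubset < 1 | nodeSubset > ncol(z)))
        stop("node subset indices out of range")
      cols <- as.integer(nodeSubset)
    } else {
      missing <- setdiff(nodeSubset, colnames(z))
      if (length(missing))
        stop("unknown node label(s) in subset: ",
             paste(missing, collapse = ", "))
      cols <- match(nodeSubset, colnames(z))
    }
    if (length(cols) < 2L) stop("node subset must contain at least 2 nodes")
    z <- z[, cols, drop = FALSE]
    if (is.null(label)) label <- "subset"
  }
  if (is.null(label)) label <- "whole-brain"
  n <- ncol(z)
  if (explicitEdges) {
    ss <- numeric(nrow(z))
    for (i in seq_len(n - 1L)) {
      prod2 <- (z[, i] * z[, (i + 1L):n, drop = FALSE])^2
      ss <- ss + rowSums(prod2)
    }
  } else {
    s2 <- rowSums(z^2)
    s4 <- rowSums(z^4)
    ss <- (s2^2 - s4) / 2
  }
  ss[ss < 0] <- 0  # guard against tiny negative rounding
  new("RssSeries", values = sqrt(ss), trSeconds = zseries@trSeconds,
      nEdges = as.integer(n * (n - 1L) / 2L), label = label)
}

setMethod("show", "RssSeries", function(object) {
  cat(sprintf("RssSeries [%s]: %d timepoints over %d edges, TR = %g s\n",
              object@label, length(object@values), object@nEdges,
              object@trSeconds))
})

#' Edge functional connectivity matrix
#'
#' Pearson-correlates every pair of edge time series. Constant edge columns
#' (undefined correlation) are excluded with a warning and recorded in the
#' \code{excluded} slot; the matrix then covers the remaining edges.
#'
#' @param ets an \code{\linkS4class{EdgeTimeSeries}} with >= 3 timepoints.
#' @return an \code{\linkS4class{EfcMatrix}}.
#' @examples
#' z <- zscoreNodes(NodalTimeSeries(matrix(rnorm(200), 50, 4), 0.72))
#' efc <- computeEFC(computeETS(z))
#' range(seriesValues(efc))
#' @export
computeEFC <- function(ets) {
  stopifnot(is(ets, "EdgeTimeSeries"))
  v <- ets@values
  if (nrow(v) < 3L) stop("need at least 3 timepoints to correlate edges")
  sds <- apply(v, 2L, stats::sd)
  excluded <- which(sds == 0)
  if (length(excluded)) {
    warning(sprintf("excluding %d constant edge column(s) from the eFC matrix: %s",
                    length(excluded),
                    paste(colnames(v)[excluded], collapse = ", ")))
    v <- v[, -excluded, drop = FALSE]
  }
  cc <- stats::cor(v)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  new("EfcMatrix", values = cc, edgeIndex = ets@edgeIndex,
      excluded = as.integer(excluded))
}

setMethod("show", "EfcMatrix", function(object) {
  cat(sprintf("EfcMatrix: %d x %d edge correlations (%d excluded as constant)\n",
              nrow(object@values), ncol(object@values),
              length(object@excluded)))
})
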