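#' @import methods
NULL

#' Nodal BOLD time series
#'
#' Container for a parcellated resting-state recording: a timepoints x nodes
#' numeric matrix, the repetition time (TR) in seconds, and node labels
#' carried as column names.
#'
#' @slot values numeric matrix, timepoints in rows, nodes in columns; column
#'   names are the node labels.
#' @slot trSeconds length-one positive numeric, repetition time in seconds.
#' @slot zscored logical scalar; \code{TRUE} once each column has been
#'   standardized by \code{\link{zscoreNodes}}.
#'
#' @seealso \code{\link{NodalTimeSeries}} for the user constructor.
#' @export
setClass("NodalTimeSeries",
         representation(values = "matrix", trSeconds = "numeric",
                        zscored = "logical"),
         prototype(zscored = FALSE))

setValidity("NodalTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (anyNA(v)) return("'values' must not contain missing values")
  if (nrow(v) < 3L) return("need at least 3 timepoints")
  if (ncol(v) < 2L) return("need at least 2 nodes")
  lab <- colnames(v)
  if (is.null(lab) || any(!nzchar(lab)))
    return("columns must carry non-empty node labels")
  if (anyDuplicated(lab))
    return(sprintf("duplicate node label(s): %s",
                   paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    return("'trSeconds' must be a single positive number")
  if (length(object@zscored) != 1L) return("'zscored' must be a scalar")
  TRUE
})

#' Canonical edge (node-pair) index
#'
#' All unordered node pairs (i, j) with i < j, in lexicographic order; the
#' shared edge ordering used by edge time series, eFC matrices and RSS traces.
#'
#' @slot pairs integer matrix with two columns (i, j), one row per edge.
#' @slot nNodes integer scalar, number of nodes indexed.
#'
#' @seealso \code{\link{buildEdgeIndex}}
#' @export
setClass("EdgeIndex", representation(pairs = "matrix", nNodes = "integer"))

setValidity("EdgeIndex", function(object) {
  p <- object@pairs
  n <- object@nNodes
  if (length(n) != 1L || n < 2L) return("'nNodes' must be a single count >= 2")
  if (!is.integer(p) || ncol(p) != 2L) return("'pairs' must be a 2-column integer matrix")
  if (nrow(p) != n * (n - 1L) / 2L)
    return(sprintf("expected %d pairs for %d nodes, got %d",
                   n * (n - 1L) / 2L, n, nrow(p)))
  if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
  if (any(p < 1L) || any(p > n)) return("pair indices out of range")
  o <- order(p[, 1L], p[, 2L])
  if (!identical(o, seq_len(nrow(p)))) return("pairs must be in lexicographic order")
  if (anyDuplicated(p)) return("duplicate pairs")
  TRUE
})

#' Edge time series
#'
#' Timepoints x edges matrix of per-timepoint products of z-scored node
#' signals, with the \code{\linkS4class{EdgeIndex}} giving the node pair
#' behind each column.
#'
#' @slot values numeric matrix, timepoints x edges.
#' @slot edgeIndex \code{\linkS4class{EdgeIndex}}.
#' @slot trSeconds repetition time in seconds.
#'
#' @seealso \code{\link{computeETS}}
#' @export
setClass("EdgeTimeSeries",
         representation(values = "matrix", edgeIndex = "EdgeIndex",
                        trSeconds = "numeric"))

setValidity("EdgeTimeSeries", function(object) {
  if (ncol(object@values) != nrow(object@edgeIndex@pairs))
    return("column count must equal the number of indexed edges")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("'trSeconds' must be a single positive number")
  TRUE
})

#' Root-sum-square co-fluctuation amplitude trace
#'
#' One nonnegative amplitude value per timepoint: the root sum square over
#' all included edge time series, i.e. a single whole-brain (or subnetwork)
#' co-fluctuation magnitude series.
#'
#' @slot values nonnegative numeric vector, one value per timepoint.
#' @slot trSeconds repetition time in seconds.
#' @slot nEdges number of edges the RSS was taken over.
#' @slot label scope label, e.g. \code{"whole-brain"} or a subnetwork name.
#'
#' @seealso \code{\link{computeRSS}}
#' @export
setClass("RssSeries",
         representation(values = "numeric", trSeconds = "numeric",
                        nEdges = "integer", label = "character"))

setValidity("RssSeries", function(object) {
  if (anyNA(object@values) || any(object@values < 0))
    return("RSS values must be nonnegative and non-missing")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("'trSeconds' must be a single positive number")
  if (length(object@nEdges) != 1L || object@nEdges < 1L)
    return("'nEdges' must be a single positive count")
  if (length(object@label) != 1L) return("'label' must be a single string")
  TRUE
})

#' Edge functional connectivity matrix
#'
#' Pearson correlations among edge time series: a symmetric edges x edges
#' matrix with unit diagonal describing how node-pair co-fluctuations track
#' one another.
#'
#' @slot values numeric edges x edges matrix.
#' @slot edgeIndex \code{\linkS4class{EdgeIndex}} for the rows/columns.
#' @slot excluded integer vector of edge columns excluded as constant.
#'
#' @seealso \code{\link{computeEFC}}
#' @export
setClass("EfcMatrix",
         representation(values = "matrix", edgeIndex = "EdgeIndex",
                        excluded = "integer"))

setValidity("EfcMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("eFC matrix must be square")
  if (max(abs(v - t(v))) > 1e-12) return("eFC matrix must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-12) return("diagonal must be 1")
  if (any(v < -1 - 1e-12) || any(v > 1 + 1e-12))
    return("entries must lie in [-1, 1]")
  TRUE
})

#' Trough magnitude criterion
#'
#' The rule deciding which strict local minima of an RSS trace count as
#' troughs. \code{theta = 0} is the base rule (any strict local minimum);
#' \code{theta} of 0.01/0.02/0.05 requires a trough to be at least 1/2/5
#' percent lower than its reference values. \code{mode} selects the
#' reference: the two adjacent samples (\code{"adjacent-sample"}) or the two
#' flanking peaks (\code{"adjacent-peak"}).
#'
#' @slot theta fraction in [0, 0.5).
#' @slot mode \code{"adjacent-sample"} or \code{"adjacent-peak"}.
#'
#' @seealso \code{\link{troughCriterion}}
#' @export
setClass("TroughCriterion",
         representation(theta = "numeric", mode = "character"))

setValidity("TroughCriterion", function(object) {
  if (length(object@theta) != 1L || is.na(object@theta) ||
      object@theta < 0 || object@theta >= 0.5)
    return("'theta' must be a single fraction in [0, 0.5)")
  if (length(object@mode) != 1L ||
      !object@mode %in% c("adjacent-sample", "adjacent-peak"))
    return("'mode' must be \"adjacent-sample\" or \"adjacent-peak\"")
  TRUE
})

#' Detected troughs and peaks of an RSS trace
#'
#' Trough timepoint indices (1-based), the single peak between each
#' consecutive trough pair with its height, and trough-to-trough durations in
#' seconds, under a given \code{\linkS4class{TroughCriterion}}.
#'
#' @slot troughIndices strictly increasing integer vector.
#' @slot peakIndices integer vector, one peak between each trough pair.
#' @slot peakHeights RSS values at the peaks.
#' @slot durationsSeconds trough-to-trough intervals times TR.
#' @slot criterion the \code{\linkS4class{TroughCriterion}} applied.
#' @slot trSeconds repetition time in seconds.
#' @slot nTimepoints length of the source RSS trace.
#'
#' @seealso \code{\link{detectBaseExtrema}}, \code{\link{applyMagnitudeCriterion}}
#' @export
setClass("ExtremaResult",
         representation(troughIndices = "integer", peakIndices = "integer",
                        peakHeights = "numeric", durationsSeconds = "numeric",
                        criterion = "TroughCriterion", trSeconds = "numeric",
                        nTimepoints = "integer"))

setValidity("ExtremaResult", function(object) {
  tr <- object@troughIndices
  if (is.unsorted(tr, strictly = TRUE)) return("troughs must be strictly increasing")
  if (length(tr) && (tr[1L] <= 1L || tr[length(tr)] >= object@nTimepoints))
    return("first/last timepoints can never be troughs")
  npk <- max(0L, length(tr) - 1L)
  if (length(object@peakIndices) != npk)
    return("need exactly one peak between each consecutive trough pair")
  if (length(object@peakHeights) != npk) return("one height per peak")
  if (length(object@durationsSeconds) != npk)
    return("durations count must be max(0, troughs - 1)")
  if (npk && any(object@peakIndices <= tr[-length(tr)] |
                 object@peakIndices >= tr[-1L]))
    return("each peak must lie strictly between its flanking troughs")
  TRUE
})

#' Specification of a synthetic two-group cohort
#'
#' Parameters of the regime-switching generator: cohort layout, Markov
#' stay-probabilities per group, per-state node covariance matrices, the
#' temporal smoothness of the latent node noise, and per-group covariate
#' distributions (age in years, total brain volume in ml).
#'
#' @slot nNodes,nTimepoints,nStates integer scalars.
#' @slot trSeconds repetition time in seconds.
#' @slot stayProb named numeric, per-group probability of remaining in the
#'   current covariance regime at each timepoint.
#' @slot stateCovariances list of node x node positive-semidefinite matrices.
#' @slot smoothSd standard deviation (in samples) of the Gaussian kernel that
#'   smooths the latent node noise; 0 disables smoothing.
#' @slot groupSizes named integer, subjects per group.
#' @slot ageMeanSd,volumeMeanSd named lists of c(mean, sd) per group.
#' @slot seed integer default seed used by \code{\link{simulateCohort}}.
#'
#' @seealso \code{\link{syntheticSpec}}, \code{\link{simulateCohort}}
#' @export
setClass("SyntheticSpec",
         representation(nNodes = "integer", nTimepoints = "integer",
                        trSeconds = "numeric", nStates = "integer",
                        stayProb = "numeric", stateCovariances = "list",
                        smoothSd = "numeric", groupSizes = "integer",
                        ageMeanSd = "list", volumeMeanSd = "list",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nNodes < 2L) return("'nNodes' must be >= 2")
  if (object@nTimepoints < 3L) return("'nTimepoints' must be >= 3")
  if (object@nStates < 1L) return("'nStates' must be >= 1")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("'trSeconds' must be a single positive number")
  g <- names(object@groupSizes)
  if (is.null(g) || anyDuplicated(g)) return("'groupSizes' must carry unique group names")
  if (any(object@groupSizes < 1L)) return("every group size must be >= 1")
  if (!setequal(names(object@stayProb), g))
    return("'stayProb' must be named by the same groups as 'groupSizes'")
  if (any(object@stayProb <= 0) || any(object@stayProb >= 1))
    return("each 'stayProb' must lie strictly in (0, 1)")
  if (length(object@stateCovariances) != object@nStates)
    return("need one covariance matrix per state")
  for (k in seq_along(object@stateCovariances)) {
    S <- object@stateCovariances[[k]]
    if (!is.matrix(S) || nrow(S) != object@nNodes || ncol(S) != object@nNodes)
      return(sprintf("state %d covariance has wrong dimensions", k))
    if (max(abs(S - t(S))) > 1e-10)
      return(sprintf("state %d covariance is not symmetric", k))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      return(sprintf("state %d covariance is not positive-semidefinite", k))
  }
  if (object@smoothSd < 0) return("'smoothSd' must be >= 0")
  for (nm in c("ageMeanSd", "volumeMeanSd")) {
    x <- slot(object, nm)
    if (!setequal(names(x), g)) return(sprintf("'%s' must be named by group", nm))
    if (any(vapply(x, function(v) length(v) != 2L || v[2L] < 0, logical(1L))))
      return(sprintf("each '%s' entry must be c(mean, sd) with sd >= 0", nm))
  }
  TRUE
})

#' One simulated participant
#'
#' @slot subjectId character scalar.
#' @slot group group label.
#' @slot age years.
#' @slot brainVolume total brain volume, ml.
#' @slot series \code{\linkS4class{NodalTimeSeries}} of simulated BOLD-like data.
#' @slot statePath integer vector, hidden covariance regime at each timepoint
#'   (ground truth for the generator's Markov chain).
#'
#' @seealso \code{\link{simulateSubject}}
#' @export
setClass("SyntheticSubject",
         representation(subjectId = "character", group = "character",
                        age = "numeric", brainVolume = "numeric",
                        series = "NodalTimeSeries", statePath = "integer"))

setValidity("SyntheticSubject", function(object) {
  if (length(object@statePath) != nrow(object@series@values))
    return("state path length must equal the number of timepoints")
  TRUE
})

#' A simulated cohort
#'
#' @slot subjects list of \code{\linkS4class{SyntheticSubject}}.
#' @slot table data.frame with one row per subject: subject_id, group,
#'   age_years, brain_volume_ml.
#' @slot spec the generating \code{\linkS4class{SyntheticSpec}}.
#'
#' @seealso \code{\link{simulateCohort}}
#' @export
setClass("SyntheticCohort",
         representation(subjects = "list", table = "data.frame",
                        spec = "SyntheticSpec"))

#' Fitted group-effect model
#'
#' Result of the ordinary-least-squares model
#' \code{outcome ~ group + age + brain volume}: the partial F test for the
#' group term, its p-value, coefficients, and covariate-adjusted group means
#' (model predictions at grand-mean covariates) with standard errors.
#'
#' @slot fStatistic F statistic for the group term (1 numerator df).
#' @slot dfNum,dfDen numerator and denominator degrees of freedom.
#' @slot pValue two-sided p from the F distribution.
#' @slot tStatistic t statistic of the group contrast (F = t^2).
#' @slot coefficients named vector: intercept, group contrast, age and volume
#'   slopes.
#' @slot adjustedMeans data.frame: group, n, adjusted_mean, se.
#' @slot outcome name of the modelled outcome column.
#' @slot nObs number of rows analyzed.
#'
#' @seealso \code{\link{ancovaGroupEffect}}, \code{\link{adjustedGroupMeans}}
#' @export
setClass("AncovaResult",
         representation(fStatistic = "numeric", dfNum = "integer",
                        dfDen = "integer", pValue = "numeric",
                        tStatistic = "numeric", coefficients = "numeric",
                        adjustedMeans = "data.frame", outcome = "character",
                        nObs = "integer"))

setValidity("AncovaResult", function(object) {
  if (object@fStatistic < 0) return("F must be nonnegative")
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0, 1]")
  if (object@dfNum != 1L) return("group term has a single df")
  if (object@dfDen != object@nObs - 4L)
    return("denominator df must be n - 4 (intercept + group + 2 covariates)")
  if (abs(object@fStatistic - object@tStatistic^2) >
      1e-8 * max(1, object@fStatistic))
    return("F must equal the squared group-contrast t statistic")
  TRUE
})
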