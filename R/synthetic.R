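#' Block covariance recipe for regime states
#'
#' Builds one node x node covariance matrix per hidden state. The nodes are
#' split into \code{nStates} contiguous blocks of (near-)equal size; in state
#' k the within-block correlation of block k is raised to \code{r[k]}, all
#' other entries stay 0 (unit variances throughout). Giving each state a
#' different \code{r[k]} makes the regimes differ in co-fluctuation
#' amplitude, so that regime switches show up as excursions of the RSS
#' trace — with a common \code{r} the states are exchangeable and the RSS
#' amplitude carries no regime information.
#'
#' @param nNodes number of nodes.
#' @param nStates number of states/blocks.
#' @param r within-block correlation per state, recycled to length
#'   \code{nStates}; each in [0, 1).
#' @return list of \code{nStates} covariance matrices.
#' @examples
#' covs <- blockStateCovariances(6, 2, r = c(0.1, 0.6))
#' covs[[2]]
#' @export
blockStateCovariances <- function(nNodes, nStates, r = c(0.05, 0.6)) {
  if (any(r < 0 | r >= 1)) stop("'r' must lie in [0, 1)")
  r <- rep_len(r, nStates)
  if (nNodes < nStates) stop("need at least one node per state block")
  blocks <- split(seq_len(nNodes), sort(rep_len(seq_len(nStates), nNodes)))
  lapply(seq_len(nStates), function(k) {
    S <- diag(nNodes)
    b <- blocks[[k]]
    S[b, b] <- r[k]
    diag(S) <- 1
    S
  })
}

#' Specify a synthetic two-group cohort
#'
#' Defines the generative model: per subject, a hidden Markov chain over
#' \code{nStates} covariance regimes (per-timepoint probability
#' \code{stayProb[group]} of staying; switches go to a uniformly random
#' different state; the initial state is uniform), latent node noise that is
#' white across nodes and temporally smoothed by a unit-variance Gaussian FIR
#' kernel (\code{smoothSd} samples, emulating the smoothness of
#' bandpass-filtered BOLD), and observed series
#' y(t) = chol(Sigma_state(t))' e(t). Age and total brain volume are drawn
#' per group from independent normals.
#'
#' Defaults give a small, fast cohort (20 nodes) whose two groups differ only
#' in switching rate (0.97 vs 0.93), with covariate distributions echoing a
#' large young-adult sample: ages ~27.9 (SD 2.4) vs 29.5 (SD 3.5) years and
#' brain volumes ~1215 (SD 45) vs 1064 (SD 36) ml.
#'
#' @param nNodes,nTimepoints series dimensions.
#' @param trSeconds repetition time in seconds (default 0.72).
#' @param nStates number of covariance regimes.
#' @param stayProb named numeric, one stay-probability in (0,1) per group.
#' @param stateCovariances optional list of PSD node x node matrices; built
#'   with \code{\link{blockStateCovariances}(nNodes, nStates, r)} when absent.
#' @param r per-state within-block correlation for the default recipe.
#' @param smoothSd Gaussian kernel SD in samples (0 = temporally white).
#' @param groupSizes named integer vector of subjects per group.
#' @param ageMeanSd,volumeMeanSd named lists of c(mean, sd) per group.
#' @param seed default seed used by \code{\link{simulateCohort}}.
#' @return a validated \code{\linkS4class{SyntheticSpec}}.
#' @examples
#' spec <- syntheticSpec(groupSizes = c(A = 3, B = 2), nTimepoints = 200)
#' spec
#' @export
syntheticSpec <- function(nNodes = 20, nTimepoints = 1200, trSeconds = 0.72,
                          nStates = 2, stayProb = c(A = 0.97, B = 0.93),
                          stateCovariances = NULL, r = c(0.05, 0.6),
                          smoothSd = 2,
                          groupSizes = c(A = 30, B = 30),
                          ageMeanSd = list(A = c(27.9, 2.4),
                                           B = c(29.5, 3.5)),
                          volumeMeanSd = list(A = c(1215.13, 44.89),
                                              B = c(1063.80, 36.27)),
                          seed = 1L) {
  if (is.null(stateCovariances))
    stateCovariances <- blockStateCovariances(nNodes, nStates, r)
  new("SyntheticSpec",
      nNodes = as.integer(nNodes), nTimepoints = as.integer(nTimepoints),
      trSeconds = as.numeric(trSeconds), nStates = as.integer(nStates),
      stayProb = stayProb, stateCovariances = stateCovariances,
      smoothSd = as.numeric(smoothSd),
      groupSizes = stats::setNames(as.integer(groupSizes),
                                   names(groupSizes)),
      ageMeanSd = ageMeanSd, volumeMeanSd = volumeMeanSd,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  g <- names(object@groupSizes)
  cat(sprintf("SyntheticSpec: %d nodes x %d timepoints (TR %g s), %d states\n",
              object@nNodes, object@nTimepoints, object@trSeconds,
              object@nStates))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d, stay=%.3g)", g, object@groupSizes,
                            object@stayProb[g]), collapse = ", ")))
  cat(sprintf("  latent smoothing SD: %g samples\n", object@smoothSd))
})

## square root factors (chol when PD, eigen fallback for PSD-singular)
.stateFactors <- function(spec) {
  lapply(seq_len(spec@nStates), function(k) {
    S <- spec@stateCovariances[[k]]
    U <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(U)) {
      e <- eigen(S, symmetric = TRUE)
      if (min(e$values) < -1e-8 * max(abs(e$values)))
        stop(sprintf("state %d covariance is not positive-semidefinite", k))
      U <- t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
    }
    U
  })
}

.simulateStatePath <- function(nTimepoints, nStates, stayProb) {
  s <- integer(nTimepoints)
  s[1L] <- sample.int(nStates, 1L)
  if (nStates == 1L) return(rep(1L, nTimepoints))
  stay <- stats::runif(nTimepoints - 1L) < stayProb
  for (t in 2:nTimepoints) {
    s[t] <- if (stay[t - 1L]) s[t - 1L] else {
      cand <- sample.int(nStates - 1L, 1L)
      if (cand >= s[t - 1L]) cand + 1L else cand
    }
  }
  s
}

## unit-variance Gaussian FIR smoothing; extra lead-in/out rows give exact
## stationarity at the edges
.smoothedNoise <- function(nTimepoints, nNodes, smoothSd) {
  if (smoothSd <= 0) return(matrix(stats::rnorm(nTimepoints * nNodes),
                                   nTimepoints, nNodes))
  half <- ceiling(4 * smoothSd)
  h <- stats::dnorm(seq(-half, half), sd = smoothSd)
  h <- h / sqrt(sum(h^2))
  eta <- matrix(stats::rnorm((nTimepoints + 2L * half) * nNodes),
                nTimepoints + 2L * half, nNodes)
  sm <- stats::filter(eta, h, method = "convolution", sides = 2L)
  matrix(sm[(half + 1L):(half + nTimepoints), , drop = FALSE],
         nTimepoints, nNodes)
}

#' Simulate one subject
#'
#' Draws a hidden regime path and a nodal time series under
#' \code{spec}, plus age and brain-volume covariates for the given group.
#' Uses the current RNG state; seed via \code{set.seed} or
#' \code{\link{simulateCohort}} for reproducibility.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @param group one of the groups named in \code{spec}.
#' @param subjectId identifier for the subject (default "sub1").
#' @return a \code{\linkS4class{SyntheticSubject}}; the realized regime path
#'   is kept in \code{@statePath} as ground truth.
#' @examples
#' set.seed(7)
#' s <- simulateSubject(syntheticSpec(nTimepoints = 100), "A")
#' table(s@statePath)
#' @export
simulateSubject <- function(spec, group, subjectId = "sub1") {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (!group %in% names(spec@groupSizes))
    stop(sprintf("unknown group '%s'; spec defines: %s", group,
                 paste(names(spec@groupSizes), collapse = ", ")))
  Us <- .stateFactors(spec)
  s <- .simulateStatePath(spec@nTimepoints, spec@nStates,
                          spec@stayProb[[group]])
  E <- .smoothedNoise(spec@nTimepoints, spec@nNodes, spec@smoothSd)
  Y <- matrix(0, spec@nTimepoints, spec@nNodes)
  for (k in seq_len(spec@nStates)) {
    idx <- which(s == k)
    if (length(idx)) Y[idx, ] <- E[idx, , drop = FALSE] %*% Us[[k]]
  }
  colnames(Y) <- sprintf("node_%03d", seq_len(spec@nNodes))
  age <- stats::rnorm(1L, spec@ageMeanSd[[group]][1L],
                      spec@ageMeanSd[[group]][2L])
  vol <- stats::rnorm(1L, spec@volumeMeanSd[[group]][1L],
                      spec@volumeMeanSd[[group]][2L])
  new("SyntheticSubject", subjectId = as.character(subjectId),
      group = as.character(group), age = age, brainVolume = vol,
      series = NodalTimeSeries(Y, spec@trSeconds), statePath = s)
}

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject %s [group %s]: age %.1f y, volume %.1f ml, %d timepoints x %d nodes\n",
              object@subjectId, object@group, object@age, object@brainVolume,
              nrow(object@series@values), ncol(object@series@values)))
})

#' Simulate a full cohort
#'
#' Generates \code{groupSizes[g]} subjects per group under \code{spec},
#' reproducibly: the same spec and seed give an identical cohort.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @param seed integer seed; defaults to the seed stored in \code{spec}.
#' @return a \code{\linkS4class{SyntheticCohort}}; \code{cohortTable(x)}
#'   gives the subject-level covariate table.
#' @examples
#' co <- simulateCohort(syntheticSpec(groupSizes = c(A = 3, B = 2),
#'                                    nTimepoints = 120), seed = 5)
#' cohortTable(co)
#' @export
simulateCohort <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  set.seed(as.integer(seed))
  groups <- rep(names(spec@groupSizes), times = spec@groupSizes)
  ids <- sprintf("sub%03d", seq_along(groups))
  subjects <- mapply(function(g, id) simulateSubject(spec, g, id),
                     groups, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  tab <- data.frame(
    subject_id = ids,
    group = groups,
    age_years = vapply(subjects, slot, numeric(1L), "age"),
    brain_volume_ml = vapply(subjects, slot, numeric(1L), "brainVolume"),
    stringsAsFactors = FALSE)
  new("SyntheticCohort", subjects = subjects, table = tab, spec = spec)
}

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects (%s)\n",
              length(object@subjects),
              paste(sprintf("%s: %d", names(table(object@table$group)),
                            table(object@table$group)), collapse = ", ")))
})
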