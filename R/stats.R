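.checkCohortTable <- function(table, outcome) {
  needed <- c("group", "age_years", "brain_volume_ml", outcome)
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  table <- table[!is.na(table[[outcome]]), , drop = FALSE]
  lev <- sort(unique(as.character(table$group)))
  if (length(lev) != 2L)
    stop(sprintf("need exactly two group levels, found %d (%s)",
                 length(lev), paste(lev, collapse = ", ")))
  if (any(table(table$group) == 0L)) stop("one group is empty")
  if (nrow(table) < 5L)
    stop("need at least 5 analyzable rows (4 parameters + 1)")
  for (cv in c("age_years", "brain_volume_ml"))
    if (stats::sd(table[[cv]]) == 0)
      stop(sprintf("covariate '%s' is constant: design matrix rank-deficient", cv))
  list(table = table, levels = lev)
}

#' Group effect with age and brain-volume covariates
#'
#' Fits the ordinary-least-squares model
#' \code{outcome ~ group + age + brain volume} (group coded 0/1 with the
#' alphabetically first level as reference) and tests the group term with a
#' partial F test: F = (SSR_reduced - SSR_full) / (SSR_full / (n - 4)),
#' where the reduced model drops only the group indicator. This equals the
#' squared t statistic of the group contrast; the two-sided p-value comes
#' from the F(1, n - 4) distribution. Rows with a missing outcome are
#' excluded before fitting.
#'
#' @param table data.frame with columns \code{group} (two levels),
#'   \code{age_years}, \code{brain_volume_ml} and the outcome column.
#' @param outcome name of the outcome column (default
#'   \code{"mean_duration_s"}).
#' @return an \code{\linkS4class{AncovaResult}}.
#' @examples
#' tab <- data.frame(group = rep(c("A", "B"), each = 6),
#'                   age_years = rnorm(12, 28, 3),
#'                   brain_volume_ml = rnorm(12, 1100, 50),
#'                   mean_duration_s = rnorm(12, 10))
#' ancovaGroupEffect(tab)
#' @export
ancovaGroupEffect <- function(table, outcome = "mean_duration_s") {
  chk <- .checkCohortTable(table, outcome)
  tab <- chk$table
  lev <- chk$levels
  tab$.g <- as.integer(as.character(tab$group) == lev[2L])
  form <- stats::reformulate(c(".g", "age_years", "brain_volume_ml"),
                             response = outcome)
  full <- stats::lm(form, data = tab)
  if (full$rank < 4L)
    stop("design matrix rank-deficient; check the covariate columns")
  reduced <- stats::lm(stats::reformulate(c("age_years", "brain_volume_ml"),
                                          response = outcome), data = tab)
  n <- nrow(tab)
  dfDen <- n - 4L
  ssrFull <- sum(stats::residuals(full)^2)
  ssrRed <- sum(stats::residuals(reduced)^2)
  y <- tab[[outcome]]
  scale <- max(1e-300, sum((y - mean(y))^2))
  if (ssrFull <= 1e-12 * scale && ssrRed <= 1e-12 * scale) {
    # outcome (near-)constant given covariates: the group term adds nothing
    f <- 0
    tstat <- 0
  } else if (ssrFull <= 1e-12 * scale) {
    # perfectly separated degenerate fit: floor the residual SS to keep the
    # statistic finite rather than emitting Inf
    f <- (ssrRed - ssrFull) / ((1e-12 * scale) / dfDen)
    tstat <- sign(stats::coef(full)[".g"]) * sqrt(f)
  } else {
    f <- max(0, (ssrRed - ssrFull) / (ssrFull / dfDen))
    tstat <- summary(full)$coefficients[".g", "t value"]
  }
  tstat <- unname(tstat)
  cf <- stats::coef(full)
  names(cf) <- c("intercept", "group_contrast", "age_slope", "volume_slope")
  res <- new("AncovaResult",
             fStatistic = f, dfNum = 1L, dfDen = dfDen,
             pValue = stats::pf(f, 1, dfDen, lower.tail = FALSE),
             tStatistic = tstat, coefficients = cf,
             adjustedMeans = .adjustedMeans(full, tab, lev),
             outcome = outcome, nObs = as.integer(n))
  validObject(res)
  res
}

## model predictions at grand-mean covariates, SE from the coefficient
## covariance of the prediction contrast
.adjustedMeans <- function(fit, tab, lev) {
  X <- rbind(c(1, 0, mean(tab$age_years), mean(tab$brain_volume_ml)),
             c(1, 1, mean(tab$age_years), mean(tab$brain_volume_ml)))
  est <- drop(X %*% stats::coef(fit))
  se <- sqrt(diag(X %*% stats::vcov(fit) %*% t(X)))
  data.frame(group = lev, n = as.integer(table(tab$group)[lev]),
             adjusted_mean = est, se = se, stringsAsFactors = FALSE)
}

setMethod("show", "AncovaResult", function(object) {
  cat(sprintf("ANCOVA on '%s': F(%d,%d) = %.3f, p = %.4g\n",
              object@outcome, object@dfNum, object@dfDen,
              object@fStatistic, object@pValue))
  m <- object@adjustedMeans
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s (n=%d): adjusted mean %.4g (SE %.3g)\n",
                m$group[i], m$n[i], m$adjusted_mean[i], m$se[i]))
})

#' Covariate-adjusted group means
#'
#' Estimated marginal means: each group's model prediction with age and
#' brain volume fixed at their grand means, with standard errors from the
#' coefficient covariance. Recomputed from the table so a mismatched
#' table/fit pair is detected.
#'
#' @param table the cohort table the fit came from.
#' @param fit an \code{\linkS4class{AncovaResult}}.
#' @return data.frame: group, n, adjusted_mean, se.
#' @export
adjustedGroupMeans <- function(table, fit) {
  stopifnot(is(fit, "AncovaResult"))
  chk <- .checkCohortTable(table, fit@outcome)
  if (nrow(chk$table) != fit@nObs ||
      !identical(chk$levels, fit@adjustedMeans$group))
    stop("'table' does not match the table this fit was computed from")
  tab <- chk$table
  tab$.g <- as.integer(as.character(tab$group) == chk$levels[2L])
  full <- stats::lm(stats::reformulate(c(".g", "age_years",
                                         "brain_volume_ml"),
                                       response = fit@outcome), data = tab)
  if (max(abs(stats::coef(full) - unname(fit@coefficients))) >
      1e-8 * max(1, abs(fit@coefficients)))
    stop("'table' does not reproduce the fitted coefficients")
  .adjustedMeans(full, tab, chk$levels)
}

## one full simulate -> RSS -> extrema -> ANCOVA pass; shared by the
## error-rate sweeps and the end-to-end recovery analyses
.simulateAndTest <- function(spec, seed, criterion, outcome) {
  co <- simulateCohort(spec, seed = seed)
  summ <- summarizeCohort(co, criteria = list(criterion))
  tab <- merge(cohortTable(co), summ, by = "subject_id")
  ancovaGroupEffect(tab, outcome = outcome)
}

#' Null rejection-rate sweep
#'
#' Simulates replicate cohorts whose groups have identical dynamics (both
#' groups get the first group's stay-probability), runs the full pipeline
#' (simulate, RSS, extrema, summary, ANCOVA) on each, and reports the
#' fraction of replicates rejecting at level \code{alpha}. Covariates keep
#' their per-group distributions, so the sweep also exercises covariate
#' adjustment under group-shifted covariates.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}; its stay-probabilities
#'   are equalized internally.
#' @param nReplicates number of replicate cohorts (warning below 20).
#' @param alpha rejection level.
#' @param criterion \code{\linkS4class{TroughCriterion}} for the outcome.
#' @param outcome outcome column to test.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return list: \code{rejectionRate}, \code{pValues}, \code{alpha},
#'   \code{nReplicates}.
#' @export
typeOneErrorSweep <- function(spec, nReplicates = 100, alpha = 0.05,
                              criterion = troughCriterion(0),
                              outcome = "mean_duration_s", seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (nReplicates < 20) warning("fewer than 20 replicates: rate estimate unstable")
  nullSpec <- spec
  nullSpec@stayProb[] <- spec@stayProb[[1L]]
  p <- vapply(seq_len(nReplicates), function(r) {
    .simulateAndTest(nullSpec, seed = seed + r, criterion, outcome)@pValue
  }, numeric(1L))
  list(rejectionRate = mean(p < alpha), pValues = p, alpha = alpha,
       nReplicates = nReplicates)
}

#' End-to-end group-difference recovery
#'
#' Runs the full pipeline on replicate cohorts simulated under \code{spec}
#' (groups differing in stay-probability) and records, per replicate, the
#' ANCOVA p-value and the sign of the adjusted-mean difference. The headline
#' check: the slower-switching group should show the longer adjusted mean
#' trough duration.
#'
#' @inheritParams typeOneErrorSweep
#' @param spec a \code{\linkS4class{SyntheticSpec}} with unequal
#'   stay-probabilities.
#' @return data.frame with one row per replicate: seed, f, p,
#'   adj_mean_<group> columns, and \code{slower_group_longer} (logical).
#' @export
recoverySweep <- function(spec, nReplicates = 20, alpha = 0.05,
                          criterion = troughCriterion(0),
                          outcome = "mean_duration_s", seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  slower <- names(which.max(spec@stayProb))
  rows <- lapply(seq_len(nReplicates), function(r) {
    fit <- .simulateAndTest(spec, seed = seed + r, criterion, outcome)
    m <- fit@adjustedMeans
    means <- stats::setNames(m$adjusted_mean, paste0("adj_mean_", m$group))
    cbind(data.frame(seed = seed + r, f = fit@fStatistic, p = fit@pValue),
          as.data.frame(as.list(means)),
          data.frame(slower_group_longer =
                       m$adjusted_mean[m$group == slower] ==
                       max(m$adjusted_mean)))
  })
  do.call(rbind, rows)
}
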