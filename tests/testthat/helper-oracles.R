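# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: plain loops and direct formulas.

# explicit edge-by-edge RSS via a double loop over all pairs
oracleRss <- function(z) {
  n <- ncol(z)
  acc <- numeric(nrow(z))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      acc <- acc + (z[, i] * z[, j])^2
  sqrt(acc)
}

# exhaustive neighbour scan for strict local minima
oracleTroughs <- function(x) {
  out <- integer(0)
  for (t in 2:(length(x) - 1L))
    if (x[t] < x[t - 1L] && x[t] < x[t + 1L]) out <- c(out, t)
  out
}

# peak = earliest argmax of each open inter-trough interval
oraclePeaks <- function(x, troughs) {
  if (length(troughs) < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(length(troughs) - 1L)) {
    iv <- (troughs[i] + 1L):(troughs[i + 1L] - 1L)
    out <- c(out, iv[which.max(x[iv])])
  }
  out
}

# validity of a trough subset under the boundary-inclusive flanking-peak rule
oracleSubsetValid <- function(x, sub, theta, tol = 1e-12) {
  k <- length(sub)
  if (k == 0L) return(TRUE)
  pv <- x[oraclePeaks(x, sub)]
  for (i in seq_len(k)) {
    fl <- c(if (i > 1L) pv[i - 1L], if (i < k) pv[i])
    if (length(fl) && x[sub[i]] > (1 - theta) * (1 + tol) * min(fl))
      return(FALSE)
  }
  TRUE
}

# all maximum-cardinality valid subsets of the base troughs (exhaustive)
oracleMaxValidSubsets <- function(x, baseTroughs, theta) {
  k <- length(baseTroughs)
  best <- list()
  bestSize <- -1L
  for (m in 0:(2^k - 1L)) {
    sub <- baseTroughs[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0]
    if (length(sub) < bestSize) next
    if (oracleSubsetValid(x, sub, theta)) {
      if (length(sub) > bestSize) {
        best <- list(sub)
        bestSize <- length(sub)
      } else best <- c(best, list(sub))
    }
  }
  best
}

# from-scratch normal-equations ANCOVA: outcome ~ 1 + group(0/1) + age + vol
oracleAncova <- function(tab, outcome) {
  tab <- tab[!is.na(tab[[outcome]]), , drop = FALSE]
  lev <- sort(unique(as.character(tab$group)))
  g <- as.numeric(as.character(tab$group) == lev[2L])
  X <- cbind(1, g, tab$age_years, tab$brain_volume_ml)
  y <- tab[[outcome]]
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  ssrFull <- sum(resid^2)
  Xr <- X[, -2L]
  betaR <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  ssrRed <- sum((y - Xr %*% betaR)^2)
  n <- nrow(X)
  dfDen <- n - 4L
  f <- (ssrRed - ssrFull) / (ssrFull / dfDen)
  sigma2 <- ssrFull / dfDen
  V <- sigma2 * solve(XtX)
  Xm <- rbind(c(1, 0, mean(tab$age_years), mean(tab$brain_volume_ml)),
              c(1, 1, mean(tab$age_years), mean(tab$brain_volume_ml)))
  list(beta = drop(beta), f = f, p = pf(f, 1, dfDen, lower.tail = FALSE),
       dfDen = dfDen, adjMeans = drop(Xm %*% beta),
       adjSe = sqrt(diag(Xm %*% V %*% t(Xm))), levels = lev)
}

# random RSS-like positive series
randomRssSeries <- function(n, trSec = 0.72, smooth = 0) {
  x <- abs(cumsum(rnorm(n)) * 0.1 + rnorm(n)) + 1
  if (smooth > 0) x <- as.numeric(stats::filter(x, rep(1 / smooth, smooth),
                                                sides = 2, circular = TRUE))
  new("RssSeries", values = x, trSeconds = trSec, nEdges = 10L,
      label = "test")
}

tinySpec <- function(...) {
  args <- list(...)
  defaults <- list(nNodes = 12, nTimepoints = 300, nStates = 2,
                   groupSizes = c(A = 8, B = 8), seed = 1L)
  do.call(syntheticSpec, utils::modifyList(defaults, args))
}

randomCohortTable <- function(n = 12, groupEffect = 0) {
  g <- rep(c("A", "B"), length.out = n)
  age <- rnorm(n, 28, 3)
  vol <- rnorm(n, 1100, 60)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = g,
             age_years = age, brain_volume_ml = vol,
             mean_duration_s = 10 + 0.1 * (age - 28) + 0.002 * (vol - 1100) +
               groupEffect * (g == "B") + rnorm(n),
             stringsAsFactors = FALSE)
}
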