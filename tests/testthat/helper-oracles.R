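# Independent brute-force reference implementations used as oracles.
# These deliberately use only elementary arithmetic (no stats::cor) so they
# stay independent of the code paths they check.

oraclePearson <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  den <- sqrt(sum(xm^2) * sum(ym^2))
  if (den == 0) return(NA_real_)
  sum(xm * ym) / den
}

oracleWindowFc <- function(mat, start, len) {
  w <- mat[start:(start + len - 1), , drop = FALSE]
  R <- ncol(w)
  out <- diag(R)
  for (a in seq_len(R)) for (b in seq_len(R)) if (a != b)
    out[a, b] <- oraclePearson(w[, a], w[, b])
  out
}

# mean pairwise correlation over windows of a list of pattern vectors
oracleV <- function(patterns) {
  num <- length(patterns)
  rs <- c()
  for (i in seq_len(num - 1)) for (j in (i + 1):num)
    rs <- c(rs, oraclePearson(patterns[[i]], patterns[[j]]))
  1 - mean(rs, na.rm = TRUE)
}

oracleRegional <- function(fcList, k) {
  oracleV(lapply(fcList, function(fc) fc[k, -k]))
}

oracleIntra <- function(fcList, members) {
  if (length(members) < 3) return(NA_real_)
  oracleV(lapply(fcList, function(fc) {
    b <- fc[members, members]
    b[upper.tri(b)]
  }))
}

oracleInter <- function(fcList, mM, mN) {
  oracleV(lapply(fcList, function(fc) as.vector(fc[mM, mN])))
}

# full naive multi-scale pipeline on a plain matrix
oracleMultiscale <- function(mat, parc, lengths, minWindows = 2) {
  Tn <- nrow(mat); R <- ncol(mat)
  nets <- networkNames(parc)
  mem <- lapply(nets, function(nm) networkMembers(parc, nm))
  prs <- utils::combn(length(nets), 2)
  accR <- matrix(0, R, 2); accI <- matrix(0, length(nets), 2)
  accX <- matrix(0, ncol(prs), 2)
  for (l in lengths) for (s in 1:(l - 1)) {
    num <- (Tn - s + 1) %/% l
    if (num < minWindows) next
    fcs <- lapply(seq_len(num), function(i)
      oracleWindowFc(mat, s + (i - 1) * l, l))
    for (k in seq_len(R)) {
      v <- oracleRegional(fcs, k)
      if (!is.na(v)) { accR[k, 1] <- accR[k, 1] + v; accR[k, 2] <- accR[k, 2] + 1 }
    }
    for (m in seq_along(nets)) {
      v <- oracleIntra(fcs, mem[[m]])
      if (!is.na(v)) { accI[m, 1] <- accI[m, 1] + v; accI[m, 2] <- accI[m, 2] + 1 }
    }
    for (q in seq_len(ncol(prs))) {
      v <- oracleInter(fcs, mem[[prs[1, q]]], mem[[prs[2, q]]])
      if (!is.na(v)) { accX[q, 1] <- accX[q, 1] + v; accX[q, 2] <- accX[q, 2] + 1 }
    }
  }
  list(regional = ifelse(accR[, 2] > 0, accR[, 1] / accR[, 2], NA),
       intra = ifelse(accI[, 2] > 0, accI[, 1] / accI[, 2], NA),
       inter = ifelse(accX[, 2] > 0, accX[, 1] / accX[, 2], NA))
}

# Friston-24 by explicit column-by-column construction
oracleFriston24 <- function(p) {
  Tn <- nrow(p)
  out <- matrix(0, Tn, 24)
  for (j in 1:6) {
    for (t in 1:Tn) {
      out[t, j] <- p[t, j]
      out[t, 6 + j] <- if (t == 1) 0 else p[t - 1, j]
      out[t, 12 + j] <- p[t, j]^2
      out[t, 18 + j] <- if (t == 1) 0 else p[t - 1, j]^2
    }
  }
  out
}

# OLS residuals through the normal equations
oracleOlsResiduals <- function(Y, X) {
  X <- cbind(1, X)
  B <- solve(t(X) %*% X, t(X) %*% Y)
  Y - X %*% B
}

# Spearman by rank-then-Pearson with average ranks
oracleSpearman <- function(x, y) {
  oraclePearson(rank(x), rank(y))
}

# ANCOVA F by explicit residual sums of squares of nested designs
oracleAncovaF <- function(y, group, covs) {
  g <- factor(group)
  X0 <- cbind(1, as.matrix(covs))
  D <- stats::model.matrix(~ g)[, -1, drop = FALSE]
  X1 <- cbind(X0, D)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  r0 <- rss(X0); r1 <- rss(X1)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(y) - ncol(X1)
  ((r0 - r1) / df1) / (r1 / df2)
}

# small random stack of valid FC matrices built from random series
makeRandomStack <- function(R, num, len, seed) {
  set.seed(seed)
  mat <- matrix(rnorm(num * len * R), num * len, R)
  ts <- roiTimeSeries(mat, tr = 2)
  windowFcStack(ts, l = len, s = 1)
}
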