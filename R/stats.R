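#' Covariate-adjusted group comparison (ANCOVA main effect)
#'
#' F-test for a group main effect on one feature, adjusting for covariates:
#' the full linear model [intercept + covariates + group] is compared
#' against the reduced model [intercept + covariates] by the extra
#' sum-of-squares F statistic with (G - 1, N - G - C) degrees of freedom.
#' Rows with a missing feature or covariate are dropped (listwise) and the
#' analysed N is reported.
#'
#' @param y numeric feature vector (one variability feature)
#' @param group factor or character group label per subject
#' @param covariates data.frame of covariates (numeric or factor columns),
#'   e.g. age, sex, education, mean FD; may have zero columns
#' @return list with \code{F}, \code{p}, \code{df} (length 2), \code{n}
#' @export
ancovaMainEffect <- function(y, group, covariates = NULL) {
  group <- factor(group)
  n0 <- length(y)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n0))
  covariates <- as.data.frame(covariates)
  keep <- !is.na(y) & !is.na(group)
  if (ncol(covariates))
    keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; group <- droplevels(group[keep])
  covariates <- covariates[keep, , drop = FALSE]
  G <- nlevels(group)
  if (G < 2) stop("need at least 2 non-empty groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 subjects")
  dat <- cbind(data.frame(.y = y, .group = group), covariates)
  covTerms <- names(covariates)
  f0 <- stats::as.formula(paste(".y ~", if (length(covTerms))
    paste(covTerms, collapse = " + ") else "1"))
  f1 <- stats::update(f0, . ~ . + .group)
  m0 <- stats::lm(f0, data = dat)
  m1 <- stats::lm(f1, data = dat)
  X1 <- stats::model.matrix(m1)
  if (qr(X1)$rank < ncol(X1)) {
    alias <- colnames(X1)[is.na(stats::coef(m1))]
    stop("rank-deficient ANCOVA design; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  a <- stats::anova(m0, m1)
  list(F = a$F[2], p = a$`Pr(>F)`[2],
       df = c(a$Df[2], a$Res.Df[2]), n = length(y))
}

#' Post-hoc pairwise group contrasts with Bonferroni correction
#'
#' For every pair of groups, fits the covariate-adjusted linear model on the
#' two-group subset and tests the group coefficient (two-sided t-test).
#' Raw p-values are Bonferroni-corrected by the number of pairs (capped at
#' 1); pairs are flagged significant at corrected p < alpha. Intended to be
#' run only for features whose ANCOVA main effect passed the gate.
#'
#' @param y numeric feature vector
#' @param group factor or character group labels
#' @param covariates covariate data.frame (as in [ancovaMainEffect()])
#' @param alpha significance level on the corrected p (default 0.05)
#' @return data.frame with columns group1, group2, estimate, p_raw,
#'   p_bonferroni, significant, n
#' @export
posthocPairwise <- function(y, group, covariates = NULL, alpha = 0.05) {
  group <- factor(group)
  lev <- levels(droplevels(group[!is.na(group)]))
  pairs <- utils::combn(lev, 2)
  nPairs <- ncol(pairs)
  rows <- vector("list", nPairs)
  for (q in seq_len(nPairs)) {
    g1 <- pairs[1, q]; g2 <- pairs[2, q]
    sel <- !is.na(group) & group %in% c(g1, g2)
    yy <- y[sel]; gg <- droplevels(factor(group[sel], levels = c(g1, g2)))
    cc <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[sel, , drop = FALSE]
    keep <- !is.na(yy)
    if (!is.null(cc) && ncol(cc)) keep <- keep & stats::complete.cases(cc)
    yy <- yy[keep]; gg <- droplevels(gg[keep])
    if (nlevels(gg) < 2 || any(table(gg) < 2)) {
      rows[[q]] <- data.frame(group1 = g1, group2 = g2, estimate = NA_real_,
                              p_raw = NA_real_, p_bonferroni = NA_real_,
                              significant = NA, n = sum(keep))
      next
    }
    cc <- if (is.null(cc)) data.frame(row.names = seq_along(yy)) else
      cc[keep, , drop = FALSE]
    dat <- cbind(data.frame(.y = yy, .group = gg), cc)
    f <- stats::as.formula(paste(".y ~ .group",
      if (ncol(cc)) paste("+", paste(names(cc), collapse = " + ")) else ""))
    m <- stats::lm(f, data = dat)
    co <- summary(m)$coefficients
    i <- grep("^\\.group", rownames(co))[1]
    rows[[q]] <- data.frame(group1 = g1, group2 = g2,
                            estimate = co[i, "Estimate"],
                            p_raw = co[i, "Pr(>|t|)"],
                            p_bonferroni = NA_real_, significant = NA,
                            n = length(yy))
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nPairs)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out
}

#' Spearman rank correlation between a clinical score and a feature
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' from the t approximation, rho * sqrt((n - 2) / (1 - rho^2)) on n - 2
#' degrees of freedom. Incomplete pairs are dropped.
#'
#' @param x numeric clinical score
#' @param y numeric feature
#' @return list with \code{rho}, \code{p}, \code{n}
#' @export
spearmanAssoc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Group statistics over a cohort feature table
#'
#' Runs the ANCOVA main-effect test on every feature column, and post-hoc
#' pairwise contrasts (Bonferroni-corrected within each feature's family of
#' group pairs) for features whose main-effect p is below the gate. No
#' correction is applied across features by default; set \code{fdr = TRUE}
#' to add a Benjamini-Hochberg q-value over the main-effect p-values.
#'
#' @param features data.frame of feature columns (rows = subjects)
#' @param group group label per subject
#' @param covariates covariate data.frame (rows = subjects)
#' @param gateAlpha main-effect gate for running post-hocs (default 0.05)
#' @param alpha significance level for corrected post-hoc p (default 0.05)
#' @param fdr add an across-feature BH q-value column (default FALSE)
#' @return list with \code{main} (one row per feature: feature, F, p, df1,
#'   df2, n, and q if requested) and \code{pairwise} (rows per feature x
#'   group pair for gated features)
#' @export
groupStats <- function(features, group, covariates = NULL,
                       gateAlpha = 0.05, alpha = 0.05, fdr = FALSE) {
  features <- as.data.frame(features)
  main <- vector("list", ncol(features))
  pw <- list()
  for (j in seq_len(ncol(features))) {
    fn <- names(features)[j]
    y <- features[[j]]
    if (all(is.na(y))) {
      main[[j]] <- data.frame(feature = fn, F = NA_real_, p = NA_real_,
                              df1 = NA_real_, df2 = NA_real_, n = 0L)
      next
    }
    r <- ancovaMainEffect(y, group, covariates)
    main[[j]] <- data.frame(feature = fn, F = r$F, p = r$p,
                            df1 = r$df[1], df2 = r$df[2], n = r$n)
    if (!is.na(r$p) && r$p < gateAlpha) {
      pp <- posthocPairwise(y, group, covariates, alpha = alpha)
      pp <- cbind(feature = fn, pp)
      pw[[length(pw) + 1]] <- pp
    }
  }
  main <- do.call(rbind, main)
  if (fdr) main$q <- stats::p.adjust(main$p, method = "BH")
  pairwise <- if (length(pw)) do.call(rbind, pw) else
    data.frame(feature = character(0), group1 = character(0),
               group2 = character(0), estimate = numeric(0),
               p_raw = numeric(0), p_bonferroni = numeric(0),
               significant = logical(0), n = integer(0))
  list(main = main, pairwise = pairwise)
}

#' Clinical-score correlations per group and pooled
#'
#' Spearman correlations between each clinical score column and each
#' feature column, computed on the pooled sample and within each group;
#' uncorrected p-values.
#'
#' @param scores data.frame of clinical score columns (rows = subjects;
#'   NAs allowed)
#' @param features data.frame of feature columns
#' @param group group label per subject
#' @param minN minimum complete pairs per correlation (default 5)
#' @return data.frame with score, feature, scope, rho, p, n
#' @export
clinicalCorrelations <- function(scores, features, group, minN = 5) {
  scores <- as.data.frame(scores)
  features <- as.data.frame(features)
  group <- factor(group)
  scopes <- c("pooled", levels(group))
  rows <- list()
  for (sc in names(scores)) for (fe in names(features)) {
    for (scope in scopes) {
      sel <- if (scope == "pooled") rep(TRUE, nrow(scores)) else
        !is.na(group) & group == scope
      x <- scores[[sc]][sel]; y <- features[[fe]][sel]
      n <- sum(!is.na(x) & !is.na(y))
      if (n < minN) next
      r <- spearmanAssoc(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        score = sc, feature = fe, scope = scope,
        rho = r$rho, p = r$p, n = r$n)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(score = character(0), feature = character(0),
               scope = character(0), rho = numeric(0), p = numeric(0),
               n = integer(0))
}
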