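makeCohort <- function(n = 60, groups = c("g1", "g2", "g3"), seed = 1) {
  set.seed(seed)
  data.frame(group = rep(groups, length.out = n),
             age = runif(n, 20, 40), sex = rbinom(n, 1, 0.5),
             education = runif(n, 8, 18), mean_fd = runif(n, 0.02, 0.15))
}

test_that("ANCOVA F matches the nested residual-sum-of-squares oracle", {
  d <- makeCohort(36)
  set.seed(2)
  y <- 0.02 * d$age + 0.1 * d$sex + rnorm(36, sd = 0.5) +
    ifelse(d$group == "g2", 0.4, 0)
  covs <- d[c("age", "sex", "education", "mean_fd")]
  r <- ancovaMainEffect(y, d$group, covs)
  expect_equal(r$F, oracleAncovaF(y, d$group, as.matrix(covs)),
               tolerance = 1e-10)
  expect_equal(r$df, c(2, 36 - 3 - 4))
  expect_equal(r$n, 36)
})

test_that("ANCOVA reports ~zero F when the group signal is projected away", {
  d <- makeCohort(45, seed = 3)
  covs <- d[c("age", "mean_fd")]
  # build y orthogonal to the group dummies after covariate projection
  X0 <- cbind(1, as.matrix(covs))
  D <- model.matrix(~ factor(d$group))[, -1]
  set.seed(4)
  raw <- rnorm(45)
  Xall <- cbind(X0, D)
  y <- raw - Xall %*% solve(crossprod(Xall), crossprod(Xall, raw))
  r <- ancovaMainEffect(as.vector(y), d$group, covs)
  expect_lt(r$F, 1e-10)
})

test_that("ANCOVA F is invariant to affine rescaling of covariates", {
  d <- makeCohort(48, seed = 5)
  set.seed(6)
  y <- rnorm(48) + ifelse(d$group == "g1", 0.3, 0)
  covs1 <- d[c("age", "education", "mean_fd")]
  covs2 <- data.frame(age = 12 * covs1$age - 100,
                      education = -covs1$education / 3,
                      mean_fd = 1000 * covs1$mean_fd)
  r1 <- ancovaMainEffect(y, d$group, covs1)
  r2 <- ancovaMainEffect(y, d$group, covs2)
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
})

test_that("ANCOVA errors and missing-data handling behave as declared", {
  d <- makeCohort(30, seed = 7)
  y <- rnorm(30); y[c(3, 10)] <- NA
  r <- ancovaMainEffect(y, d$group, d[c("age", "sex")])
  expect_equal(r$n, 28)   # listwise deletion, N reported
  expect_error(
    ancovaMainEffect(rnorm(30), d$group,
                     data.frame(a = d$age, b = 2 * d$age)),
    "collinear")
  expect_error(ancovaMainEffect(rnorm(4), rep("g", 4), NULL), "2 non-empty")
})

test_that("post-hoc pairwise correction is Bonferroni with cap at 1", {
  d <- makeCohort(60, seed = 8)
  set.seed(9)
  y <- rnorm(60)
  covs <- d[c("age", "sex")]
  pp <- posthocPairwise(y, d$group, covs)
  expect_equal(nrow(pp), 3)
  expect_equal(pp$p_bonferroni, pmin(1, pp$p_raw * 3))
  # identical group means: corrected p near 1, nothing significant
  y0 <- d$age * 0.05 + rep(c(0.3, 0.3, 0.3), 20)
  pp0 <- posthocPairwise(y0 + rnorm(60, sd = 1), d$group, covs)
  expect_true(all(!pp0$significant))
})

test_that("a planted 1-SD difference is detected with high power", {
  hits <- 0L
  for (rep in 1:200) {
    set.seed(3000 + rep)
    n <- 120  # 40 per group
    g <- rep(c("a", "b", "c"), each = 40)
    covs <- data.frame(age = runif(n, 20, 40))
    y <- rnorm(n) + 0.01 * covs$age + ifelse(g == "b", 1, 0)
    pp <- posthocPairwise(y, g, covs)
    sel <- pp$group1 == "a" & pp$group2 == "b"
    if (pp$significant[sel]) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Spearman association is monotone-invariant with t-based p", {
  set.seed(10)
  x <- rnorm(20)
  expect_equal(spearmanAssoc(x, exp(x))$rho, 1)
  expect_equal(spearmanAssoc(x, -x)$rho, -1)
  # ties: rank-then-Pearson oracle
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6, 7, 9)
  r <- spearmanAssoc(xt, yt)
  expect_equal(r$rho, oracleSpearman(xt, yt), tolerance = 1e-12)
  # agrees with the standard implementation (t approximation, two-sided)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                   exact = FALSE))
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  expect_error(spearmanAssoc(1:3, 1:3), "5 complete")
  expect_true(is.na(spearmanAssoc(rep(1, 8), rnorm(8))$rho))
})

test_that("groupStats gates post-hocs and reports per-feature N", {
  d <- makeCohort(90, seed = 11)
  set.seed(12)
  f1 <- rnorm(90) + ifelse(d$group == "g1", 2, 0)   # strong effect
  f2 <- rnorm(90)                                    # null
  f3 <- rep(NA_real_, 90); f3[1:80] <- rnorm(80)     # missing values
  gs <- groupStats(data.frame(f1 = f1, f2 = f2, f3 = f3), d$group,
                   d[c("age", "sex", "education", "mean_fd")])
  expect_equal(gs$main$n[gs$main$feature == "f3"], 80)
  expect_true("f1" %in% gs$pairwise$feature)
  expect_lt(gs$main$p[gs$main$feature == "f1"], 0.001)
  # all-NA feature is reported with n = 0, not silently dropped
  gs2 <- groupStats(data.frame(f = rep(NA_real_, 90)), d$group, NULL)
  expect_equal(gs2$main$n, 0L)
  expect_true(is.na(gs2$main$F))
})

test_that("clinical correlations run pooled and per group", {
  d <- makeCohort(60, seed = 13)
  set.seed(14)
  feat <- data.frame(v = rnorm(60))
  sc <- data.frame(s = feat$v * 2 + rnorm(60, sd = 0.3))
  ct <- clinicalCorrelations(sc, feat, d$group)
  expect_setequal(unique(ct$scope), c("pooled", "g1", "g2", "g3"))
  expect_gt(ct$rho[ct$scope == "pooled"], 0.8)
  expect_equal(ct$n[ct$scope == "pooled"], 60)
})
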