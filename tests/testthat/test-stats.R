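test_that("a noiseless linear relation yields perfect correlation", {
  x <- 1:10
  fit <- univariate_fit(x, 2 * x + 1)
  expect_equal(fit$R, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-9)
  down <- univariate_fit(x, 10 - 3 * x)
  expect_equal(down$r, -1, tolerance = 1e-9)   # correlation keeps its sign
  expect_equal(down$R, 1, tolerance = 1e-9)
})

test_that("the correlation matches a hand-summed Pearson oracle", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  # sum(dx dy) = 8, sum(dx^2) = 10, sum(dy^2) = 10 -> r = 8/10
  fit <- univariate_fit(x, y)
  expect_equal(fit$r, 0.8, tolerance = 1e-12)
  expect_equal(cross_correlation(x, y), 0.8, tolerance = 1e-12)
  expect_equal(fit$n_used, 5L)
})

test_that("missing values are excluded pairwise, never imputed", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 4, 100, 8, NA, 12)
  fit <- univariate_fit(x, y)
  expect_equal(fit$n_used, 4L)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_error(univariate_fit(c(1, 2, NA), c(1, NA, 3)), "at least 3")
  expect_error(univariate_fit(rep(2, 5), 1:5), "constant")
  expect_error(cross_correlation(rep(1, 5), 1:5), "degenerate")
})

test_that("multivariate coefficients solve the normal equations exactly", {
  set.seed(71)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- 1 + 2 * X$a - 3 * X$b + rnorm(20, sd = 0.1)
  fit <- multivariate_fit(X, y)
  Xd <- cbind(1, as.matrix(X))
  beta <- unname(drop(solve(crossprod(Xd), crossprod(Xd, y))))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
  expect_equal(fit$R, cor(fit$fitted, y[complete.cases(X, y)]),
               tolerance = 1e-9)
  expect_error(multivariate_fit(data.frame(a = X$a, b = 2 * X$a), y),
               "collinear")
  expect_error(multivariate_fit(X[1:3, ], y[1:3]), "complete rows")
})

test_that("combining predictors never lowers the in-sample correlation", {
  set.seed(72)
  for (rep in 1:40) {
    n <- 15
    x1 <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n)
    R1 <- univariate_fit(x1, y)$R
    R2 <- univariate_fit(x2, y)$R
    R12 <- multivariate_fit(data.frame(x1, x2), y)$R
    expect_gte(R12, max(R1, R2) - 1e-10)
  }
})

test_that("a second predictor carrying residual signal raises R", {
  set.seed(73)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1 + x2 + rnorm(n, sd = 0.2)
  R1 <- univariate_fit(x1, y)$R
  R12 <- multivariate_fit(data.frame(x1, x2), y)$R
  expect_gt(R12, R1 + 0.1)
})

test_that("AUROC equals the pairwise concordance probability", {
  set.seed(74)
  for (rep in 1:10) {
    n <- 30
    scores <- sample(1:8, n, replace = TRUE)   # forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels),
                 concordance_auc_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(0, 0, 1, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUROC is invariant under monotone score transforms", {
  set.seed(75)
  scores <- rnorm(40)
  labels <- runif(40) < 0.5
  base <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), base)
  expect_equal(roc_auc(scores * 100 - 3, labels), base)
})

test_that("the randomized-split AUROC stream is reproducible from its seed", {
  set.seed(76)
  x <- rnorm(30) + 1.5 * rep(c(0, 1), 15)
  labels <- rep(c(FALSE, TRUE), 15)
  a <- logistic_auroc_ci(x, labels, n_iter = 50, seed = 9)
  b <- logistic_auroc_ci(x, labels, n_iter = 50, seed = 9)
  expect_identical(a$aurocs, b$aurocs)
  c <- logistic_auroc_ci(x, labels, n_iter = 50, seed = 10)
  expect_false(identical(a$aurocs, c$aurocs))
  expect_equal(a$n_skipped, 0L)
  expect_true(a$ci_low <= a$mean && a$mean <= a$ci_high)
})

test_that("a perfectly separating predictor earns a degenerate unit interval", {
  x <- c(rnorm(20, 0, 0.2), rnorm(20, 10, 0.2))
  labels <- rep(c(FALSE, TRUE), each = 20)
  res <- logistic_auroc_ci(x, labels, n_iter = 200, seed = 4)
  expect_identical(res$ci_low, 1)
  expect_identical(res$ci_high, 1)
  expect_identical(res$mean, 1)
})

test_that("an uninformative predictor hovers near chance", {
  set.seed(77)
  x <- rnorm(60)
  labels <- rep(c(FALSE, TRUE), 30)
  res <- logistic_auroc_ci(x, labels, n_iter = 200, seed = 5)
  expect_gt(res$mean, 0.3)
  expect_lt(res$mean, 0.7)
  expect_lt(res$ci_low, 0.6)
  expect_gt(res$ci_high, 0.4)
})

test_that("split-stream inputs are validated", {
  x <- rnorm(10)
  expect_error(logistic_auroc_ci(x, rep(TRUE, 10)), "at least 2")
  expect_error(logistic_auroc_ci(x, rep(c(TRUE, FALSE), 5), n_iter = 0),
               "n_iter")
  expect_error(logistic_auroc_ci(x, rep(c(TRUE, FALSE), 5),
                                 split_fraction = 1), "strictly between")
})

test_that("the report table assembles fits, cross-correlation, and AUROC", {
  set.seed(78)
  n <- 24
  feats <- data.frame(patient_id = sprintf("p%03d", 1:n),
                      scr = NA, vol = NA, isup = rep(0:5, 4))
  feats$scr <- feats$isup + rnorm(n, sd = 0.5)
  feats$vol <- 0.5 * feats$isup + rnorm(n, sd = 0.5)
  feats$cspca <- feats$isup >= 2
  models <- list(list(predictors = "scr", n_iter = 30),
                 list(predictors = c("scr", "vol"), n_iter = 30))
  rep_tab <- analysis_report(feats, models, seed = 2)
  expect_equal(nrow(rep_tab), 2)
  expect_identical(rep_tab$model, c("scr", "scr + vol"))
  expect_equal(rep_tab$R1[1], univariate_fit(feats$scr, feats$isup)$R)
  expect_equal(rep_tab$R2[2], univariate_fit(feats$vol, feats$isup)$R)
  expect_equal(rep_tab$cross_correlation[2],
               cross_correlation(feats$scr, feats$vol))
  expect_equal(rep_tab$R_multi[2],
               multivariate_fit(feats[c("scr", "vol")], feats$isup)$R)
  expect_gte(rep_tab$R_multi[2], max(rep_tab$R1[2], rep_tab$R2[2]) - 1e-10)
  expect_true(all(rep_tab$auroc >= 0 & rep_tab$auroc <= 1))
  expect_true(is.na(rep_tab$R2[1]))
  details <- attr(rep_tab, "details")
  expect_length(details, 2)
  expect_s3_class(details[[2]]$multivariate, "fit_result")
  expect_error(analysis_report(feats, list(list(predictors = "missing"))),
               "absent")
})
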