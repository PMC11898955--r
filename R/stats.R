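#' Univariate linear fit of a feature to an outcome
#'
#' Ordinary least squares of `y` on a single predictor, reporting the
#' signed Pearson correlation `r`, its magnitude `R`, the two-sided
#' F-test p-value (equivalent to the t-test for one predictor), 95%
#' coefficient confidence intervals, and the number of complete pairs
#' used (missing values are excluded pairwise).
#'
#' @param x Predictor vector.
#' @param y Outcome vector (same length).
#' @return A `fit_result` list: `coefficients`, `r`, `R`, `p_value`,
#'   `conf_int`, `n_used`, `fitted`, `residuals`.
#' @export
univariate_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("univariate fit needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("predictor is constant; fit is degenerate", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # noiseless relations are legitimate inputs; silence lm's perfect-fit note
  sm <- suppressWarnings(summary(fit))
  r <- stats::cor(x, y)
  p <- if (is.null(sm$fstatistic)) 1 else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  structure(list(coefficients = stats::coef(fit),
                 r = r, R = abs(r),
                 p_value = unname(p),
                 conf_int = suppressWarnings(stats::confint(fit)),
                 n_used = length(x),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "fit_result")
}

#' Multivariate linear fit of features to an outcome
#'
#' Ordinary least squares of `y` on several predictors over complete
#' rows. `R` is the multiple correlation between fitted and observed
#' values; the p-value comes from the overall F statistic.
#'
#' @param X Predictor matrix or data frame (columns named).
#' @param y Outcome vector.
#' @return A `fit_result` list as in [univariate_fit()] (the `r` field
#'   is `NA`; multiple correlation is unsigned).
#' @export
multivariate_fit <- function(X, y) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(X, y)
  Xc <- X[ok, , drop = FALSE]; yc <- y[ok]
  if (nrow(Xc) < ncol(Xc) + 2L)
    stop("multivariate fit needs more complete rows than predictors + 1",
         call. = FALSE)
  mm <- cbind(1, as.matrix(Xc))
  if (qr(mm)$rank < ncol(mm))
    stop("predictors are collinear on the complete rows", call. = FALSE)
  df <- data.frame(Xc, .y = yc)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) 1 else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  structure(list(coefficients = stats::coef(fit),
                 r = NA_real_,
                 R = sqrt(max(sm$r.squared, 0)),
                 p_value = unname(p),
                 conf_int = stats::confint(fit),
                 n_used = nrow(Xc),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d, R = %.4f%s, p = %.3g\n", x$n_used,
              x$R, if (!is.na(x$r)) sprintf(" (r = %.4f)", x$r) else "",
              x$p_value))
  invisible(x)
}

#' Pearson cross-correlation between two features
#'
#' @param x1,x2 Numeric vectors; missing values excluded pairwise.
#' @return Signed Pearson r.
#' @export
cross_correlation <- function(x1, x2) {
  ok <- stats::complete.cases(x1, x2)
  if (sum(ok) < 3L)
    stop("cross-correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x1[ok]) == 0 || stats::sd(x2[ok]) == 0)
    stop("constant input; correlation is degenerate", call. = FALSE)
  stats::cor(x1[ok], x2[ok])
}

#' Area under the ROC curve
#'
#' Computed as the rank-sum (Mann-Whitney concordance) statistic with
#' ties counted one half, which equals trapezoidal integration of the
#' ROC curve.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (logical or 0/1); both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUROC", call. = FALSE)
  rk <- rank(scores)
  (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Randomized-split logistic AUROC with percentile confidence interval
#'
#' Repeats `n_iter` times: draw a stratified random train/test split,
#' fit a logistic model on the training part by maximum likelihood
#' (falling back to a tiny ridge penalty if the fit degenerates), and
#' score the AUROC on the held-out part. The 2.5th and 97.5th
#' percentiles of the resulting AUROC distribution delineate the 95%
#' confidence interval. Fully reproducible from `seed`.
#'
#' @param x Predictor vector, or matrix/data frame for a multivariate
#'   logistic model.
#' @param labels Binary outcome (both classes present).
#' @param n_iter Number of randomized splits (default 1000).
#' @param split_fraction Fraction of each class assigned to training
#'   (default 0.7, clamped so both splits keep at least one member of
#'   each class).
#' @param seed Integer seed for the split stream.
#' @return An `auroc_result` list: `aurocs`, `mean`, `ci_low`,
#'   `ci_high`, `n_iter`, `split_fraction`, `seed`, `n_skipped`.
#' @export
logistic_auroc_ci <- function(x, labels, n_iter = 1000,
                              split_fraction = 0.7, seed = 1L) {
  X <- as.data.frame(x)
  names(X) <- paste0("x", seq_len(ncol(X)))
  labels <- as.logical(labels)
  ok <- stats::complete.cases(X, labels)
  X <- X[ok, , drop = FALSE]; labels <- labels[ok]
  if (n_iter < 1L) stop("n_iter must be at least 1", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie strictly between 0 and 1", call. = FALSE)
  i1 <- which(labels); i0 <- which(!labels)
  if (length(i1) < 2L || length(i0) < 2L)
    stop("each class needs at least 2 members for train/test splitting",
         call. = FALSE)
  ntr1 <- min(max(round(split_fraction * length(i1)), 1L), length(i1) - 1L)
  ntr0 <- min(max(round(split_fraction * length(i0)), 1L), length(i0) - 1L)
  aurocs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_iter), function(it) {
      tr <- c(sample(i1, ntr1), sample(i0, ntr0))
      te <- setdiff(seq_along(labels), tr)
      fit <- fit_logistic(X[tr, , drop = FALSE], labels[tr])
      pred <- drop(cbind(1, as.matrix(X[te, , drop = FALSE])) %*% fit)
      roc_auc(pred, labels[te])
    }, 0)
  })
  structure(list(aurocs = aurocs,
                 mean = mean(aurocs),
                 ci_low = unname(stats::quantile(aurocs, 0.025, type = 7)),
                 ci_high = unname(stats::quantile(aurocs, 0.975, type = 7)),
                 n_iter = n_iter,
                 split_fraction = split_fraction,
                 seed = as.integer(seed),
                 n_skipped = 0L),
            class = "auroc_result")
}

# logistic coefficients (intercept first); unpenalized ML with a small
# ridge fallback when the ML fit degenerates (perfect separation)
fit_logistic <- function(X, y) {
  df <- data.frame(X, .y = as.numeric(y))
  fit <- tryCatch(
    suppressWarnings(stats::glm(.y ~ ., data = df,
                                family = stats::binomial(),
                                control = list(maxit = 100))),
    error = function(e) NULL)
  cf <- if (!is.null(fit)) stats::coef(fit) else NULL
  if (is.null(cf) || any(!is.finite(cf)))
    cf <- ridge_logistic(cbind(1, as.matrix(X)), as.numeric(y),
                         lambda = 1e-6)
  unname(cf)
}

# Newton iterations for ridge-penalized logistic regression
ridge_logistic <- function(Xd, y, lambda = 1e-6, maxit = 50) {
  beta <- rep(0, ncol(Xd))
  for (i in seq_len(maxit)) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * w, Xd) + diag(lambda, ncol(Xd))
    g <- crossprod(Xd, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("<auroc_result> mean AUROC %.3f [%.3f-%.3f], %d splits\n",
              x$mean, x$ci_low, x$ci_high, x$n_iter))
  invisible(x)
}

#' Run the uni/multivariate regression and AUROC report
#'
#' For each requested model this emits the table-shaped summary row:
#' per-predictor univariate correlations to the graded outcome (R1,
#' R2), the predictor cross-correlation, the multivariate multiple
#' correlation R12 with its F-statistic probability, and the
#' randomized-split logistic AUROC confidence interval against the
#' binary outcome.
#'
#' @param features Data frame of per-patient features including the
#'   outcome columns (`isup`, `cspca`).
#' @param models List of model definitions; each a list with
#'   `predictors` (character, 1 or more feature columns), optional
#'   `outcome` (default `"isup"`), `binary_outcome` (default
#'   `"cspca"`), `n_iter` (default 1000), `split_fraction`
#'   (default 0.7).
#' @param seed Root seed for the AUROC split streams.
#' @return A data frame with one row per model (class
#'   `analysis_report`), with the underlying fits in
#'   `attr(, "details")`.
#' @export
analysis_report <- function(features, models, seed = 1L) {
  stopifnot(is.data.frame(features))
  rows <- list()
  details <- list()
  for (mi in seq_along(models)) {
    mod <- models[[mi]]
    preds <- mod$predictors
    outcome <- if (is.null(mod$outcome)) "isup" else mod$outcome
    bin <- if (is.null(mod$binary_outcome)) "cspca" else mod$binary_outcome
    n_iter <- if (is.null(mod$n_iter)) 1000L else mod$n_iter
    sf <- if (is.null(mod$split_fraction)) 0.7 else mod$split_fraction
    missing_cols <- setdiff(c(preds, outcome), names(features))
    if (length(missing_cols))
      stop("requested feature(s) absent from the table: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    y <- features[[outcome]]
    uni <- lapply(preds, function(p) univariate_fit(features[[p]], y))
    row <- list(model = paste(preds, collapse = " + "),
                outcome = outcome,
                R1 = uni[[1]]$R, p1 = uni[[1]]$p_value,
                R2 = NA_real_, p2 = NA_real_,
                cross_correlation = NA_real_,
                R_multi = NA_real_, p_multi = NA_real_,
                n_used = uni[[1]]$n_used)
    det <- list(univariate = uni)
    if (length(preds) >= 2L) {
      row$R2 <- uni[[2]]$R; row$p2 <- uni[[2]]$p_value
      row$cross_correlation <- cross_correlation(features[[preds[1]]],
                                                 features[[preds[2]]])
      multi <- multivariate_fit(features[preds], y)
      row$R_multi <- multi$R; row$p_multi <- multi$p_value
      row$n_used <- multi$n_used
      det$multivariate <- multi
    }
    if (!is.null(bin) && bin %in% names(features)) {
      # a cohort too small or too one-sided for stratified splitting
      # degrades to a missing AUROC rather than aborting the report
      auc <- tryCatch(
        logistic_auroc_ci(features[preds], features[[bin]],
                          n_iter = n_iter, split_fraction = sf,
                          seed = as.integer(seed) + mi),
        error = function(e) e)
      if (inherits(auc, "error")) {
        row$auroc <- row$auroc_ci_low <- row$auroc_ci_high <- NA_real_
        det$auroc_message <- conditionMessage(auc)
      } else {
        row$auroc <- auc$mean
        row$auroc_ci_low <- auc$ci_low
        row$auroc_ci_high <- auc$ci_high
        det$auroc <- auc
      }
    } else {
      row$auroc <- row$auroc_ci_low <- row$auroc_ci_high <- NA_real_
    }
    rows[[mi]] <- as.data.frame(row, stringsAsFactors = FALSE)
    details[[mi]] <- det
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  class(out) <- c("analysis_report", class(out))
  out
}
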