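#' Estimate normal-prostate background statistics
#'
#' The background tissue class is summarized by its mean spectrum `m`
#' and 3x3 covariance matrix `CM` over the voxels of a prostate mask,
#' together with the eigen-structure of `CM` used by the
#' principal-component and shrinkage variants. The sample covariance
#' uses the unbiased `n - 1` denominator. At least 30 mask voxels are
#' required for a stable estimate.
#'
#' @param cube A [registered_cube()].
#' @param mask Logical 3D array (normal-prostate mask) aligned to the
#'   cube.
#' @param min_voxels Minimum mask size accepted (default 30); worked
#'   examples on tiny hand-checkable masks may relax this explicitly,
#'   but estimates below the default are not trustworthy in analysis.
#' @return An object of class `background_stats` with fields `m`, `CM`,
#'   `sigma` (per-band standard deviations), `eigvals` (descending),
#'   `eigvecs`, `CM_inv` (effective inverse; a pseudo-inverse for the
#'   PC-filtered variant), `n_voxels`, `gamma`, `pcs_removed`,
#'   `variant`, and `singular`.
#' @export
compute_background_stats <- function(cube, mask, min_voxels = 30L) {
  stopifnot(inherits(cube, "registered_cube"))
  X <- cube_spectra(cube, mask)
  if (nrow(X) < max(2L, min_voxels))
    stop("background estimation needs at least ", max(2L, min_voxels),
         " mask voxels, got ", nrow(X), call. = FALSE)
  m <- colMeans(X)
  CM <- stats::cov(X)          # n - 1 denominator
  new_background_stats(m, CM, n_voxels = nrow(X))
}

#' Construct background statistics from a mean and covariance
#'
#' Mostly useful for tests and worked examples; [compute_background_stats()]
#' is the estimating entry point.
#'
#' @param m Length-3 mean spectrum.
#' @param CM 3x3 symmetric covariance.
#' @param n_voxels Sample size behind the estimate.
#' @return A `background_stats` object (variant `"raw"`).
#' @export
background_stats <- function(m, CM, n_voxels = NA_integer_) {
  new_background_stats(as.numeric(m), as.matrix(CM), n_voxels = n_voxels)
}

new_background_stats <- function(m, CM, n_voxels,
                                 gamma = 0, pcs_removed = 0L,
                                 variant = "raw", CM_inv = NULL) {
  if (length(m) != 3L || !all(dim(CM) == c(3L, 3L)))
    stop("background statistics are 3-band: m length 3, CM 3x3",
         call. = FALSE)
  if (max(abs(CM - t(CM))) > 1e-10)
    stop("covariance must be symmetric", call. = FALSE)
  CM <- (CM + t(CM)) / 2
  e <- eigen(CM, symmetric = TRUE)
  eigvals <- pmax(e$values, 0)
  singular <- min(e$values) < 1e-12 * max(abs(e$values), 1e-300)
  if (is.null(CM_inv))
    CM_inv <- if (singular) spd_pseudo_inverse(eigvals, e$vectors)
              else chol2inv(chol(CM))
  structure(list(m = stats::setNames(m, c("ADC", "HBV", "T2")),
                 CM = CM,
                 sigma = sqrt(pmax(diag(CM), 0)),
                 eigvals = eigvals,
                 eigvecs = e$vectors,
                 n_voxels = n_voxels,
                 gamma = gamma,
                 pcs_removed = as.integer(pcs_removed),
                 variant = variant,
                 singular = singular,
                 CM_inv = (CM_inv + t(CM_inv)) / 2),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf("<background_stats %s> n = %s, gamma = %g, PCs removed = %d%s\n",
              x$variant, x$n_voxels, x$gamma, x$pcs_removed,
              if (x$singular) " (singular)" else ""))
  cat("m:", format(x$m, digits = 5), "\n")
  cat("eigenvalues:", format(x$eigvals, digits = 5), "\n")
  invisible(x)
}

spd_pseudo_inverse <- function(eigvals, eigvecs, keep = eigvals > 0) {
  keep <- keep & eigvals > .Machine$double.eps * max(eigvals, 0)
  if (!any(keep)) return(matrix(0, 3, 3))
  V <- eigvecs[, keep, drop = FALSE]
  V %*% diag(1 / eigvals[keep], nrow = sum(keep)) %*% t(V)
}

#' Remove noisy principal components from the background covariance
#'
#' Low-eigenvalue principal components carry mostly noise and corrupt
#' the covariance inversion behind the SCR; they are removed by
#' replacing the inverse with the pseudo-inverse built from the
#' `3 - n_remove` largest-eigenvalue components:
#' `CM^+ = sum_{i <= 3-n_remove} v_i v_i' / lambda_i`.
#'
#' @param stats A raw-variant `background_stats`.
#' @param n_remove Integer 0-2, number of trailing components dropped.
#' @return A `background_stats` with variant `"pc_filtered"` and its
#'   `CM_inv` the subspace pseudo-inverse.
#' @export
pc_filter <- function(stats, n_remove) {
  stopifnot(inherits(stats, "background_stats"))
  if (!identical(stats$variant, "raw"))
    stop("PC filtering applies to the raw covariance", call. = FALSE)
  n_remove <- as.integer(n_remove)
  if (is.na(n_remove) || n_remove < 0L || n_remove > 2L)
    stop("n_remove must be 0, 1, or 2 (removing all 3 components is ",
         "degenerate)", call. = FALSE)
  keep <- seq_len(3L - n_remove)
  inv <- spd_pseudo_inverse(stats$eigvals, stats$eigvecs,
                            keep = seq_len(3L) %in% keep)
  out <- new_background_stats(stats$m, stats$CM, stats$n_voxels,
                              gamma = 0, pcs_removed = n_remove,
                              variant = "pc_filtered", CM_inv = inv)
  out$eigvals <- stats$eigvals
  out$eigvecs <- stats$eigvecs
  out
}

#' Shrink the background covariance toward a diagonal target
#'
#' Shrinkage regularization mixes the sample covariance with a diagonal
#' target: `CM(gamma) = (1 - gamma) CM + gamma T`. The `"regularized"`
#' mode uses the scaled identity `T = (trace(CM)/3) I` (which preserves
#' the trace exactly); the `"modified_regularized"` mode uses
#' `T = diag(CM)` (which preserves per-band variances). For any
#' `gamma > 0` and a non-degenerate `CM`, the result is positive
#' definite.
#'
#' @param stats A raw-variant `background_stats`.
#' @param gamma Mixing weight in `[0, 1]`; 0 leaves `CM` unchanged.
#' @param mode `"regularized"` or `"modified_regularized"`.
#' @return A `background_stats` of the requested variant.
#' @export
shrink_covariance <- function(stats, gamma,
                              mode = c("regularized",
                                       "modified_regularized")) {
  stopifnot(inherits(stats, "background_stats"))
  if (!identical(stats$variant, "raw"))
    stop("shrinkage applies to the raw covariance", call. = FALSE)
  mode <- match.arg(mode)
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]", call. = FALSE)
  CMg <- (1 - gamma) * stats$CM + gamma * shrink_target(stats$CM, mode)
  new_background_stats(stats$m, CMg, stats$n_voxels,
                       gamma = gamma, pcs_removed = 0L, variant = mode)
}

shrink_target <- function(CM, mode) {
  if (mode == "regularized") diag(rep(mean(diag(CM)), 3))
  else diag(diag(CM), nrow = 3)
}

#' Select the shrinkage weight by leave-one-out likelihood
#'
#' The mixing weight is chosen from a candidate grid as the value
#' minimizing the leave-one-out negative Gaussian log-likelihood of the
#' mask voxels under `(m_{-i}, CM_{-i}(gamma))`, the standard selection
#' criterion in the regularized-discriminant literature. The shrinkage
#' target is held at the full-sample target so that tiny samples (whose
#' leave-one-out covariance degenerates) are still driven toward
#' positive shrinkage. Deterministic given its inputs.
#'
#' @param cube A [registered_cube()].
#' @param mask Logical 3D mask of background voxels.
#' @param mode Shrinkage mode, as in [shrink_covariance()].
#' @param grid Candidate gamma values in `[0, 1]`
#'   (default `seq(0, 1, by = 0.05)`).
#' @return The selected gamma (scalar from `grid`).
#' @export
select_gamma <- function(cube, mask, mode = c("regularized",
                                              "modified_regularized"),
                         grid = seq(0, 1, by = 0.05)) {
  mode <- match.arg(mode)
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid < 0 | grid > 1))
    stop("gamma grid must be non-empty and lie in [0, 1]", call. = FALSE)
  X <- cube_spectra(cube, mask)
  n <- nrow(X)
  if (n < 2L) stop("gamma selection needs at least 2 mask voxels",
                   call. = FALSE)
  score <- vapply(grid, function(g) loo_nll(X, g, mode), 0)
  if (all(!is.finite(score)))
    stop("no candidate gamma yields a positive-definite covariance",
         call. = FALSE)
  grid[which.min(score)]
}

# Total leave-one-out Gaussian negative log-likelihood for one gamma.
# Uses rank-one downdates of the mean and scatter, with all 3x3
# determinants and quadratic forms evaluated in closed (adjugate) form,
# vectorized across voxels.
loo_nll <- function(X, gamma, mode) {
  n <- nrow(X)
  m <- colMeans(X)
  S_full <- stats::cov(X)
  Tg <- shrink_target(S_full, mode)
  D <- sweep(X, 2, m)                       # x_i - m
  denom <- max(n - 2L, 1L)
  # S_{-i} = ((n-1) S - (n/(n-1)) d_i d_i') / (n - 2)
  a <- (n - 1) / denom
  b <- (n / (n - 1)) / denom
  # symmetric entries of C_i = (1-gamma) * S_{-i} + gamma * T
  cc <- function(r, s) {
    (1 - gamma) * (a * S_full[r, s] - b * D[, r] * D[, s]) + gamma * Tg[r, s]
  }
  c11 <- cc(1, 1); c22 <- cc(2, 2); c33 <- cc(3, 3)
  c12 <- cc(1, 2); c13 <- cc(1, 3); c23 <- cc(2, 3)
  det3 <- c11 * (c22 * c33 - c23^2) - c12 * (c12 * c33 - c23 * c13) +
    c13 * (c12 * c23 - c22 * c13)
  if (any(det3 <= 0)) return(Inf)
  # held-out deviation from the leave-one-out mean: (n/(n-1)) d_i
  e1 <- D[, 1] * n / (n - 1); e2 <- D[, 2] * n / (n - 1)
  e3 <- D[, 3] * n / (n - 1)
  # adjugate entries
  A11 <- c22 * c33 - c23^2
  A22 <- c11 * c33 - c13^2
  A33 <- c11 * c22 - c12^2
  A12 <- c13 * c23 - c12 * c33
  A13 <- c12 * c23 - c13 * c22
  A23 <- c12 * c13 - c11 * c23
  quad <- (e1 * (A11 * e1 + A12 * e2 + A13 * e3) +
           e2 * (A12 * e1 + A22 * e2 + A23 * e3) +
           e3 * (A13 * e1 + A23 * e2 + A33 * e3)) / det3
  if (any(quad < 0)) return(Inf)
  0.5 * sum(3 * log(2 * pi) + log(det3) + quad)
}

#' Effective inverse covariance of a background model
#'
#' Returns the matrix used in all whitened quadratic forms: the ordinary
#' inverse for invertible variants and the retained-subspace
#' pseudo-inverse for the PC-filtered variant.
#'
#' @param stats A `background_stats`.
#' @return 3x3 symmetric matrix.
#' @export
cov_inverse <- function(stats) {
  stopifnot(inherits(stats, "background_stats"))
  stats$CM_inv
}
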