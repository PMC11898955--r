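#' Derive an in-scene tumor signature
#'
#' The tumor signature `S` is the three-component (ADC, HBV, T2)
#' spectrum that characterizes tumor tissue; here it is the mean
#' spectrum over a seed region of the registered cube.
#'
#' @param cube A [registered_cube()].
#' @param seed_region Integer matrix (n x 3) of 1-based voxel indices,
#'   or a logical 3D array.
#' @return An object of class `tumor_signature` with fields `S` and
#'   `provenance` (`"roi_mean"`).
#' @export
derive_signature <- function(cube, seed_region) {
  stopifnot(inherits(cube, "registered_cube"))
  d <- cube_dim(cube)
  if (is.array(seed_region) && length(dim(seed_region)) == 3L)
    seed_region <- which(as.logical(seed_region)) |> lin_to_coords(d)
  seed_region <- as.matrix(seed_region)
  if (nrow(seed_region) == 0)
    stop("signature seed region is empty", call. = FALSE)
  if (ncol(seed_region) != 3L ||
      any(seed_region < 1L) || any(sweep(seed_region, 2, d, `>`)))
    stop("seed region indices fall outside the cube grid", call. = FALSE)
  lin <- coords_to_lin(seed_region, d)
  X <- cube_spectra(cube)[lin, , drop = FALSE]
  tumor_signature(colMeans(X), provenance = "roi_mean")
}

#' Construct a tumor signature
#' @param S Length-3 (ADC, HBV, T2) spectrum.
#' @param provenance One of `"roi_mean"`, `"automated"`, `"manual"`.
#' @return A `tumor_signature` object.
#' @export
tumor_signature <- function(S, provenance = c("manual", "roi_mean",
                                              "automated")) {
  S <- as.numeric(S)
  if (length(S) != 3L || any(!is.finite(S)))
    stop("signature must be 3 finite intensities", call. = FALSE)
  structure(list(S = stats::setNames(S, c("ADC", "HBV", "T2")),
                 provenance = match.arg(provenance)),
            class = "tumor_signature")
}

as_signature_vector <- function(S) {
  if (inherits(S, "tumor_signature")) S$S else as.numeric(S)
}

#' Per-band and combined z-score of a signature against the background
#'
#' Each band's z-score is the tumor-background contrast scaled by the
#' normal-prostate standard deviation of that sequence:
#' `z_b = (S_b - m_b) / sigma_b`. The combined scalar is the
#' root-mean-square of the three band scores, a sign-insensitive
#' reduction (tumor contrast has opposite signs on ADC/T2 versus HBV).
#'
#' @param S A `tumor_signature` or length-3 vector.
#' @param stats A `background_stats`.
#' @return List with `per_band` (length-3) and `combined` (scalar).
#' @export
zscore <- function(S, stats) {
  stopifnot(inherits(stats, "background_stats"))
  S <- as_signature_vector(S)
  if (any(stats$sigma <= 0))
    stop("degenerate background: a band has zero standard deviation",
         call. = FALSE)
  z <- (S - stats$m) / stats$sigma
  list(per_band = z, combined = sqrt(mean(z^2)))
}

#' Signal-to-clutter ratio of a signature
#'
#' The covariance-whitened squared contrast
#' `SCR = (S - m)' CM^{-1} (S - m)`, a Mahalanobis-style quadratic form
#' using the background model's effective (pseudo-)inverse, so it
#' accounts for correlation between the MRI sequences. Non-negative by
#' construction.
#'
#' @param S A `tumor_signature` or length-3 vector.
#' @param stats A `background_stats` (any variant).
#' @return Scalar SCR.
#' @export
scr <- function(S, stats) {
  stopifnot(inherits(stats, "background_stats"))
  inv <- cov_inverse(stats)
  if (max(abs(inv)) == 0)
    stop("degenerate background model: zero effective inverse covariance",
         call. = FALSE)
  d <- as_signature_vector(S) - stats$m
  drop(t(d) %*% inv %*% d)
}

#' Whiten a cube against its background model
#'
#' Every voxel spectrum `x` is replaced by `CM^{-1/2} (x - m)` with the
#' symmetric inverse square root of the background covariance, giving
#' decorrelated unit-variance bands on background tissue.
#'
#' @param cube A [registered_cube()].
#' @param stats A `background_stats` with positive-definite `CM`.
#' @return A whitened [registered_cube()].
#' @export
whiten <- function(cube, stats) {
  stopifnot(inherits(cube, "registered_cube"),
            inherits(stats, "background_stats"))
  if (min(stats$eigvals) <= 0 || stats$singular)
    stop("whitening needs a positive-definite covariance", call. = FALSE)
  W <- stats$eigvecs %*% diag(1 / sqrt(stats$eigvals)) %*% t(stats$eigvecs)
  X <- sweep(cube_spectra(cube), 2, stats$m) %*% W
  registered_cube(array(X, c(cube_dim(cube), 3L)),
                  spacing = cube$spacing, origin = cube$origin)
}

#' Adaptive cosine estimator detection map
#'
#' ACE scores each voxel by the squared cosine of the angle, in the
#' whitened space of the background model, between the voxel's centered
#' spectrum and the target signature:
#' \deqn{ACE(x) = \frac{[(x-m)' CM^{-1} (S-m)]^2}{[(x-m)' CM^{-1} (x-m)]
#'   \, [(S-m)' CM^{-1} (S-m)]}}
#' The decision surface is a cone around the signature; scores lie in
#' `[0, 1]`, reaching 1 exactly when the whitened voxel is parallel to
#' the whitened signature. Voxels with `x = m` are assigned 0 by
#' convention.
#'
#' @param cube A [registered_cube()].
#' @param stats A `background_stats` (any variant with a non-zero
#'   effective inverse).
#' @param S A `tumor_signature` or length-3 vector, distinct from `m`.
#' @return 3D array of ACE scores (class `score_map`) aligned to the
#'   cube, with the cube's spacing/origin in attributes.
#' @export
ace_map <- function(cube, stats, S) {
  stopifnot(inherits(cube, "registered_cube"),
            inherits(stats, "background_stats"))
  inv <- cov_inverse(stats)
  s <- as_signature_vector(S) - stats$m
  ss <- drop(t(s) %*% inv %*% s)
  if (!is.finite(ss) || ss <= 0)
    stop("degenerate signature: S equals the background mean (or lies in ",
         "the removed subspace)", call. = FALSE)
  D <- sweep(cube_spectra(cube), 2, stats$m)
  Di <- D %*% inv
  num <- drop(Di %*% s)^2
  xx <- rowSums(Di * D)
  score <- ifelse(xx > 0, pmin(pmax(num / (xx * ss), 0), 1), 0)
  structure(array(score, cube_dim(cube)), class = "score_map",
            spacing = cube$spacing, origin = cube$origin)
}

lin_to_coords <- function(lin, d) {
  arrayInd(lin, .dim = d)
}

coords_to_lin <- function(idx, d) {
  (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] + idx[, 1]
}
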