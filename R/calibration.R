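#' Likelihood-to-ISUP calibration constant
#'
#' The hyperbolic-arctangent calibration scales `atanh(p)` so that a
#' likelihood of 0.5 maps to ISUP grade 2: `c = 2 / atanh(0.5)`,
#' approximately 3.6409.
#'
#' @return The scale constant (scalar).
#' @export
calibration_constant <- function() 2 / atanh(0.5)

#' Piecewise-linear likelihood-to-ISUP calibration
#'
#' Maps a detector's clinical-significance likelihood to a continuous
#' inferred ISUP grade by linear interpolation through the anchor
#' points (0, 0), (0.5, 2), (1, 5): slope 4 below 0.5 and slope 6
#' above. The output is kept continuous (not rounded) for regression.
#'
#' @param p Likelihood(s) in `[0, 1]`.
#' @return Inferred ISUP grade(s) in `[0, 5]`.
#' @export
isup_from_likelihood_linear <- function(p) {
  check_probability(p)
  ifelse(p <= 0.5, 4 * p, 2 + 6 * (p - 0.5))
}

#' Hyperbolic-arctangent likelihood-to-ISUP calibration
#'
#' `ISUP = c * atanh(p)` with `c = 2/atanh(0.5)` (about 3.6409), chosen
#' so that a likelihood of 0.5 corresponds to grade 2. Because `atanh`
#' diverges as `p` approaches 1 while the pathology scale is bounded,
#' the output is capped at 5 (reached at `p = tanh(5/c)`, about 0.881).
#'
#' @param p Likelihood(s) in `[0, 1]`.
#' @return Inferred ISUP grade(s) in `[0, 5]`.
#' @export
isup_from_likelihood_atanh <- function(p) {
  check_probability(p)
  pmin(calibration_constant() * atanh(pmin(p, 1 - 1e-15)), 5)
}

check_probability <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("likelihood must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Clinically significant prostate cancer label
#'
#' Clinically significant PCa (CsPCa) is assigned to ISUP grade 2 or
#' higher; grades below 2 are clinically insignificant (CiPCa).
#'
#' @param isup Grade(s), numeric and non-negative (continuous inferred
#'   grades are allowed).
#' @return Logical vector.
#' @export
cspca_label <- function(isup) {
  if (any(!is.finite(isup)) || any(isup < 0))
    stop("isup grades must be non-negative", call. = FALSE)
  isup >= 2
}
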