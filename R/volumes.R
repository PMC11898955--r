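#' Construct a single-sequence MRI volume
#'
#' A `sequence_volume` holds one 3D scalar image together with its voxel
#' spacing and world origin, both in millimetres, and a label naming the
#' MRI sequence it came from. The world coordinate of the centre of voxel
#' `(i, j, k)` (1-based indices) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3 vector of positive voxel sizes (mm).
#' @param origin Numeric length-3 vector of world offsets (mm).
#' @param label Sequence label: one of `"ADC"`, `"HBV"`, `"T2"`, or
#'   `"mask"` for binary masks travelling through the same plumbing.
#' @return An object of class `sequence_volume`.
#' @export
sequence_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            label = "T2") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite lengths (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite offsets (mm)", call. = FALSE)
  label <- match.arg(label, c("ADC", "HBV", "T2", "mask"))
  if (any(!is.finite(data)))
    stop("volume intensities must all be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 label = label),
            class = "sequence_volume")
}

#' @export
print.sequence_volume <- function(x, ...) {
  cat(sprintf("<sequence_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$label, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sequence_volume <- function(x) dim(x$data)

#' Construct a registered three-band image cube
#'
#' A `registered_cube` is the spatially registered vectorial image: a 4D
#' lattice indexed (row, column, slice, band) with the fixed band order
#' (ADC, HBV, T2), one shared spacing and origin. Every voxel carries a
#' three-component spectrum `x` used by the spectral detectors.
#'
#' @param voxels 4D numeric array with third+1 dimension of extent 3.
#' @param spacing,origin Shared grid geometry (mm), as in
#'   [sequence_volume()].
#' @return An object of class `registered_cube`.
#' @export
registered_cube <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L || dim(voxels)[4] != 3L)
    stop("cube voxels must be a 4D array with exactly 3 bands", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("cube intensities must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0) || any(!is.finite(spacing)))
    stop("spacing must be 3 positive finite lengths (mm)", call. = FALSE)
  dimnames(voxels) <- c(rep(list(NULL), 3), list(c("ADC", "HBV", "T2")))
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "registered_cube")
}

#' @export
print.registered_cube <- function(x, ...) {
  cat(sprintf("<registered_cube> %s voxels x 3 bands (ADC, HBV, T2), spacing %s mm\n",
              paste(dim(x$voxels)[1:3], collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Spatial dimensions of a cube
#' @param cube A [registered_cube()].
#' @return Integer length-3 vector.
#' @export
cube_dim <- function(cube) dim(cube$voxels)[1:3]

#' Extract one band of a cube as a sequence volume
#' @param cube A [registered_cube()].
#' @param band Band name (`"ADC"`, `"HBV"`, `"T2"`) or index 1-3.
#' @return A [sequence_volume()].
#' @export
cube_band <- function(cube, band) {
  bands <- c("ADC", "HBV", "T2")
  if (is.character(band)) band <- match(match.arg(band, bands), bands)
  sequence_volume(cube$voxels[, , , band, drop = TRUE],
                  spacing = cube$spacing, origin = cube$origin,
                  label = bands[band])
}

#' Flatten a cube to a spectra matrix
#'
#' @param cube A [registered_cube()].
#' @param mask Optional logical 3D array selecting voxels.
#' @return Numeric matrix, one row per voxel, columns (ADC, HBV, T2).
#' @export
cube_spectra <- function(cube, mask = NULL) {
  d <- cube_dim(cube)
  X <- matrix(cube$voxels, nrow = prod(d), ncol = 3L,
              dimnames = list(NULL, c("ADC", "HBV", "T2")))
  if (!is.null(mask)) {
    check_mask_dims(mask, d)
    X <- X[as.logical(mask), , drop = FALSE]
  }
  X
}

check_mask_dims <- function(mask, d) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L || !all(dim(mask) == d))
    stop("mask dimensions must equal the cube's spatial dimensions",
         call. = FALSE)
  invisible(TRUE)
}

# world coordinates (mm) of voxel centres, one row per voxel in `idx`
# (n x 3 matrix of 1-based indices)
voxel_world <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}
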