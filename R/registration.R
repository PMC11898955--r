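#' Resample a volume to a target spacing
#'
#' The grid is resampled over the same world extent: the new lattice
#' starts at the input origin and keeps one voxel for every full
#' `target_spacing` step that fits inside the old extent. Intensities are
#' interpolated trilinearly; binary masks (label `"mask"`) use
#' nearest-neighbour so they stay binary.
#'
#' @param vol A [sequence_volume()].
#' @param target_spacing Numeric length-3 positive spacing (mm).
#' @param method `"linear"` or `"nearest"`; defaults to nearest for
#'   volumes labelled `"mask"`, linear otherwise.
#' @return A resampled [sequence_volume()].
#' @export
resample_volume <- function(vol, target_spacing,
                            method = if (identical(vol$label, "mask"))
                              "nearest" else "linear") {
  stopifnot(inherits(vol, "sequence_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target spacing must be 3 positive lengths (mm)", call. = FALSE)
  method <- match.arg(method, c("linear", "nearest"))
  d <- dim(vol$data)
  if (all(abs(target_spacing - vol$spacing) < 1e-12)) return(vol)
  # world extent spanned by voxel centres: (d - 1) * spacing
  new_d <- floor((d - 1) * vol$spacing / target_spacing + 1e-9) + 1L
  if (any(new_d < 1L))
    stop("target spacing leaves fewer than 1 voxel along an axis",
         call. = FALSE)
  out <- vol$data
  for (ax in 1:3) {
    # fractional source index of each new voxel centre along this axis
    src <- (seq_len(new_d[ax]) - 1) * target_spacing[ax] / vol$spacing[ax] + 1
    out <- interp_axis(out, src, ax, method)
  }
  sequence_volume(out, spacing = target_spacing, origin = vol$origin,
                  label = vol$label)
}

# 1D interpolation of a 3D array along one axis at fractional indices
interp_axis <- function(arr, src, axis, method) {
  d <- dim(arr)
  if (axis != 1L) {
    perm <- c(axis, setdiff(1:3, axis))
    arr <- aperm(arr, perm)
  }
  da <- dim(arr)
  if (method == "nearest") {
    i <- pmin(pmax(round(src), 1), da[1])
    res <- arr[i, , , drop = FALSE]
  } else {
    i0 <- pmin(pmax(floor(src), 1), da[1])
    i1 <- pmin(i0 + 1, da[1])
    t <- pmin(pmax(src - i0, 0), 1)
    # weights recycle along the first (fastest-varying) dimension
    res <- arr[i0, , , drop = FALSE] * (1 - t) + arr[i1, , , drop = FALSE] * t
  }
  if (axis != 1L) {
    perm <- c(axis, setdiff(1:3, axis))
    res <- aperm(res, order(perm))
  }
  res
}

#' Translate a volume onto a reference grid by whole voxels
#'
#' The header-origin difference between `vol` and `ref` is converted to
#' voxels, rounded to the nearest whole voxel, and added to
#' `extra_shift` (the manual transverse corrections that stand in for
#' visual-inspection adjustments). The output lies on the reference
#' grid; voxels with no source data are `NA` until cropping.
#'
#' @param vol A [sequence_volume()] already at the reference spacing.
#' @param ref The reference [sequence_volume()].
#' @param extra_shift Integer length-3 extra voxel shift (default 0).
#' @return A [sequence_volume()] congruent with `ref` (possibly with
#'   `NA` padding, consumed by [assemble_cube()]'s crop).
#' @export
align_to_reference <- function(vol, ref, extra_shift = c(0L, 0L, 0L)) {
  stopifnot(inherits(vol, "sequence_volume"), inherits(ref, "sequence_volume"))
  if (any(abs(vol$spacing - ref$spacing) > 1e-9))
    stop("volume must already be at the reference spacing", call. = FALSE)
  extra_shift <- as.integer(round(extra_shift))
  # source index in vol for reference index j: j + d
  d_shift <- as.integer(round((ref$origin - vol$origin) / ref$spacing)) +
    extra_shift
  nd <- dim(ref$data)
  nv <- dim(vol$data)
  lo <- pmax(1L, 1L - d_shift)
  hi <- pmin(nd, nv - d_shift)
  if (any(hi < lo))
    stop("no spatial overlap between volume and reference after translation",
         call. = FALSE)
  out <- array(NA_real_, nd)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol$data[(lo[1]:hi[1]) + d_shift[1],
             (lo[2]:hi[2]) + d_shift[2],
             (lo[3]:hi[3]) + d_shift[3]]
  v <- vol
  v$data <- out
  v$origin <- ref$origin
  # NA padding is intentional here; bypass the finite-value constructor
  structure(v, class = "sequence_volume")
}

#' Assemble the registered three-band cube
#'
#' Implements cube assembly: the three sequences are resampled to a
#' common target spacing (the coarsest transverse spacing among them;
#' the ADC slice spacing in the slice direction), translated onto the
#' ADC grid by their header-origin differences rounded to whole voxels
#' plus any manual shifts, then cropped to the common field of view so
#' every remaining voxel has data from all three sequences. Bands are
#' stacked in the fixed order (ADC, HBV, T2).
#'
#' @param adc,hbv,t2 [sequence_volume()]s labelled accordingly.
#' @param manual_shifts Named list of integer length-3 voxel shifts per
#'   sequence (`adc`, `hbv`, `t2`); defaults to zero.
#' @return A [registered_cube()]; the crop keeps track of its own world
#'   origin so masks and ground truth can be mapped by world coordinate.
#' @export
assemble_cube <- function(adc, hbv, t2,
                          manual_shifts = list(adc = c(0, 0, 0),
                                               hbv = c(0, 0, 0),
                                               t2 = c(0, 0, 0))) {
  vols <- list(adc = adc, hbv = hbv, t2 = t2)
  want <- c(adc = "ADC", hbv = "HBV", t2 = "T2")
  for (nm in names(vols)) {
    if (!inherits(vols[[nm]], "sequence_volume"))
      stop("inputs must be sequence_volume objects", call. = FALSE)
    if (!identical(vols[[nm]]$label, want[[nm]]))
      stop(sprintf("argument '%s' must carry label %s, got %s",
                   nm, want[[nm]], vols[[nm]]$label), call. = FALSE)
  }
  for (nm in names(manual_shifts))
    manual_shifts[[nm]] <- as.integer(round(manual_shifts[[nm]]))
  shifts <- utils::modifyList(list(adc = c(0L, 0L, 0L), hbv = c(0L, 0L, 0L),
                                   t2 = c(0L, 0L, 0L)), manual_shifts)
  # common spacing: coarsest in-plane spacing across sequences; the
  # reference (ADC) spacing through-plane
  trans <- vapply(vols, function(v) v$spacing[1:2], numeric(2))
  target <- c(max(trans[1, ]), max(trans[2, ]), adc$spacing[3])
  res <- lapply(vols, resample_volume, target_spacing = target)
  ref <- res$adc
  aligned <- list(
    adc = align_to_reference(res$adc, ref, shifts$adc),
    hbv = align_to_reference(res$hbv, ref, shifts$hbv),
    t2 = align_to_reference(res$t2, ref, shifts$t2))
  valid <- !is.na(aligned$adc$data) & !is.na(aligned$hbv$data) &
    !is.na(aligned$t2$data)
  if (!any(valid))
    stop("empty common field of view after registration", call. = FALSE)
  rng <- apply(which(valid, arr.ind = TRUE), 2, range)
  lo <- unname(rng[1, ]); hi <- unname(rng[2, ])
  dims <- hi - lo + 1L
  voxels <- array(NA_real_, c(dims, 3L))
  for (b in 1:3)
    voxels[, , , b] <- aligned[[b]]$data[lo[1]:hi[1], lo[2]:hi[2],
                                         lo[3]:hi[3]]
  if (any(!is.finite(voxels)))
    stop("common field of view is not a full box; irregular overlap",
         call. = FALSE)
  origin <- ref$origin + (lo - 1) * target
  registered_cube(voxels, spacing = target, origin = origin)
}

#' Resample a mask volume onto a cube's grid
#'
#' Nearest-neighbour lookup by world coordinate, so a prostate mask
#' drawn on any source grid can be carried along with the registered
#' cube. Voxels outside the mask's extent are background.
#'
#' @param mask A [sequence_volume()] holding 0/1 (or logical) values.
#' @param cube The target [registered_cube()].
#' @return Logical 3D array with the cube's spatial dimensions.
#' @export
align_mask <- function(mask, cube) {
  stopifnot(inherits(mask, "sequence_volume"),
            inherits(cube, "registered_cube"))
  d <- cube_dim(cube)
  md <- dim(mask$data)
  out <- array(FALSE, d)
  # per-axis nearest source index for each target index
  src <- lapply(1:3, function(ax) {
    w <- cube$origin[ax] + (seq_len(d[ax]) - 1) * cube$spacing[ax]
    i <- round((w - mask$origin[ax]) / mask$spacing[ax]) + 1
    ifelse(i >= 1 & i <= md[ax], i, NA_integer_)
  })
  ok <- lapply(src, function(s) !is.na(s))
  if (any(vapply(ok, sum, 0) == 0)) return(out)
  sub <- mask$data[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]],
                   drop = FALSE]
  out[ok[[1]], ok[[2]], ok[[3]]] <- sub > 0.5
  out
}

#' Stitch cube slices into a side-by-side mosaic
#'
#' Selected axial slices are concatenated column-wise per band, the
#' mosaicking used for batch visualization of a whole cube; values are
#' unmodified.
#'
#' @param cube A [registered_cube()].
#' @param slice_ids Integer vector of slice indices (1-based).
#' @return 3D array (rows, n_slices x columns, 3 bands).
#' @export
stitch_slices <- function(cube, slice_ids) {
  stopifnot(inherits(cube, "registered_cube"))
  d <- cube_dim(cube)
  slice_ids <- as.integer(slice_ids)
  if (length(slice_ids) == 0 || any(slice_ids < 1L | slice_ids > d[3]))
    stop("slice index out of range 1..", d[3], call. = FALSE)
  out <- array(NA_real_, c(d[1], d[2] * length(slice_ids), 3L))
  for (s in seq_along(slice_ids)) {
    cols <- (s - 1) * d[2] + seq_len(d[2])
    out[, cols, ] <- cube$voxels[, , slice_ids[s], ]
  }
  out
}
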