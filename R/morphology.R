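#' Threshold a detection map
#'
#' @param scores 3D array of scores (e.g. an ACE map); values in `[0, 1]`.
#' @param tau Threshold in `[0, 1]`; the boundary is inclusive (a score
#'   equal to `tau` is tumor). Default 0.9.
#' @return Logical 3D array.
#' @export
threshold_map <- function(scores, tau = 0.9) {
  if (!is.finite(tau) || tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]", call. = FALSE)
  array(as.vector(scores) >= tau, dim(scores))
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 "2d" = g[, 3] == 0,
                 stop("connectivity must be one of 6, 18, 26, or \"2d\"",
                      call. = FALSE))
  g[keep, , drop = FALSE]
}

#' Label connected tumor blobs in a binary mask
#'
#' Connected-component labeling ("blobbing") of the thresholded
#' detection mask. Neighbours are the voxels one step away under the
#' chosen connectivity; the default 26-connectivity is the 3D closure
#' of the in-plane 8-pixel neighbourhood (pass `"2d"` for strictly
#' per-slice 8-connectivity). Components smaller than `min_size`
#' voxels are filtered out (default 5 voxels, roughly 1e-2 mL at
#' typical BP-MRI resolution). Labels follow the raster-scan order of
#' each component's first voxel.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param min_size Minimum surviving component size in voxels
#'   (default 5).
#' @param connectivity 6, 18, 26 (default), or `"2d"`.
#' @param spacing Optional length-3 voxel spacing (mm); when given,
#'   each blob also carries its volume, axes, and eccentricity.
#' @return List of `blob` objects, each with `label`, `voxel_ids`
#'   (n x 3 index matrix), `size`, `centroid`, and (with spacing)
#'   `volume` (mL), `l`, `s`, `ecc`.
#' @export
label_blobs <- function(mask, min_size = 5L, connectivity = 26,
                        spacing = NULL) {
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (min_size < 1L) stop("min_size must be at least 1", call. = FALSE)
  d <- dim(mask)
  off <- neighbour_offsets(connectivity)
  off_lin <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  fg <- which(as.logical(mask))
  lab <- integer(prod(d))
  # pad test: neighbour coords must stay in bounds; precompute coords
  blobs <- list()
  cur <- 0L
  maskv <- as.logical(mask)
  for (v in fg) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    members <- v
    lab[v] <- cur
    frontier <- v
    while (length(frontier)) {
      fc <- arrayInd(frontier, .dim = d)
      cand <- rep(frontier, each = nrow(off)) + rep(off_lin, length(frontier))
      cx <- fc[rep(seq_along(frontier), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), length(frontier)), , drop = FALSE]
      inb <- cx[, 1] >= 1L & cx[, 1] <= d[1] &
        cx[, 2] >= 1L & cx[, 2] <= d[2] &
        cx[, 3] >= 1L & cx[, 3] <= d[3]
      cand <- unique(cand[inb])
      cand <- cand[maskv[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      members <- c(members, cand)
      frontier <- cand
    }
    blobs[[cur]] <- sort(members)
  }
  blobs <- blobs[vapply(blobs, length, 0L) >= min_size]
  out <- vector("list", length(blobs))
  for (k in seq_along(blobs)) {
    idx <- arrayInd(blobs[[k]], .dim = d)
    b <- structure(list(label = k, voxel_ids = idx, size = nrow(idx),
                        centroid = colMeans(idx)),
                   class = "blob")
    if (!is.null(spacing)) {
      b$volume <- blob_volume(b, spacing)
      ax <- blob_axes(b, spacing)
      b$l <- ax$l; b$s <- ax$s; b$ecc <- ax$ecc
    }
    out[[k]] <- b
  }
  out
}

#' @export
print.blob <- function(x, ...) {
  cat(sprintf("<blob %d> %d voxels%s\n", x$label, x$size,
              if (!is.null(x$volume))
                sprintf(", %.4g mL, E = %s", x$volume,
                        format(x$ecc, digits = 3)) else ""))
  invisible(x)
}

#' Volume of a blob in millilitres
#'
#' The voxel count times the voxel volume implied by the MRI spatial
#' resolution, converted from cubic millimetres to millilitres; exact.
#'
#' @param blob A `blob` (or anything with a `size` field).
#' @param spacing Length-3 voxel spacing (mm).
#' @return Volume in mL.
#' @export
blob_volume <- function(blob, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  blob$size * prod(spacing) / 1000
}

blob_axes <- function(blob, spacing) {
  if (blob$size < 2L)
    return(list(l = NA_real_, s = NA_real_, ecc = NA_real_))
  P <- sweep(blob$voxel_ids, 2, spacing, `*`)     # voxel centres, mm
  C <- sweep(P, 2, colMeans(P))
  M <- crossprod(C) / nrow(C)                     # second central moments
  ev <- sort(pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  l <- sqrt(ev[1]); s <- sqrt(ev[2])
  list(l = l, s = s, ecc = if (l > 0) (l - s) / l else NA_real_)
}

#' Eccentricity of a blob
#'
#' The blob's voxel-centre coordinates (in mm) yield a 3x3 second
#' central moment (scatter) matrix whose eigenvalues
#' `lambda1 >= lambda2 >= lambda3` define the axis lengths
#' `l = sqrt(lambda1)` (major) and `s = sqrt(lambda2)` (second,
#' transverse). The eccentricity `E = (l - s) / l` ranges from 0
#' (spherical blob) to 1 (straight line). Undefined (missing) for
#' single-voxel blobs.
#'
#' @param blob A `blob`.
#' @param spacing Length-3 voxel spacing (mm).
#' @return Eccentricity in `[0, 1]`, or `NA` for a 1-voxel blob.
#' @export
blob_eccentricity <- function(blob, spacing) {
  blob_axes(blob, as.numeric(spacing))$ecc
}

#' Aggregate per-patient morphometric features from labeled blobs
#'
#' Computes the per-patient feature set: number of blobs, maximum /
#' average / total blob volume (mL), eccentricity of the largest blob
#' (ties broken by smallest label), unweighted average eccentricity,
#' and mass-weighted eccentricity (weights are voxel counts, i.e. mass
#' at uniform density). With no blobs the volumes are 0 and the
#' eccentricities missing.
#'
#' @param blobs List of `blob`s (already size-filtered), with volumes
#'   and eccentricities attached (see [label_blobs()] with `spacing`).
#' @param scr Named or unnamed numeric vector of SCR values (one per
#'   covariance variant) to carry along, or `NULL`.
#' @param zscore Combined z-score scalar to carry along, or `NULL`.
#' @param outcome One-row data frame or list with `patient_id`, `isup`,
#'   `cspca`, optionally `ai_likelihood`, or `NULL`.
#' @param prefix Optional prefix for the morphometric column names
#'   (used to distinguish AI-detection-map features, e.g. `"ai_"`).
#' @return One-row data frame of features.
#' @export
patient_features <- function(blobs, scr = NULL, zscore = NULL,
                             outcome = NULL, prefix = "") {
  vols <- vapply(blobs, function(b) b$volume, 0)
  eccs <- vapply(blobs, function(b) b$ecc, 0)
  sizes <- vapply(blobs, function(b) b$size, 0L)
  n <- length(blobs)
  morph <- list(
    n_blobs = n,
    max_blob_volume = if (n) max(vols) else 0,
    avg_blob_volume = if (n) mean(vols) else 0,
    total_volume = if (n) sum(vols) else 0,
    ecc_largest = if (n) eccs[[which.max(vols)]] else NA_real_,
    ecc_avg = if (n && any(!is.na(eccs))) mean(eccs, na.rm = TRUE)
              else NA_real_,
    ecc_weighted = if (n && any(!is.na(eccs))) {
      w <- sizes[!is.na(eccs)]
      sum(w * eccs[!is.na(eccs)]) / sum(w)
    } else NA_real_)
  names(morph) <- paste0(prefix, names(morph))
  out <- morph
  if (!is.null(scr)) {
    scr <- as.list(scr)
    if (is.null(names(scr)) || any(names(scr) == ""))
      names(scr) <- if (length(scr) == 1L) "scr"
        else paste0("scr_", seq_along(scr))
    out <- c(out, scr)
  }
  if (!is.null(zscore)) out$zscore <- zscore
  if (!is.null(outcome)) {
    oc <- as.list(outcome)
    out <- c(list(patient_id = oc$patient_id), out,
             oc[intersect(c("ai_likelihood", "isup", "cspca"), names(oc))])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Morphometric features from an external detection map
#'
#' Applies the identical threshold, labeling, volume, and eccentricity
#' chain to an externally supplied detection map (for example the
#' per-voxel output of a trained AI detector), so spectral and AI
#' lesions are measured by one rule set.
#'
#' @param detection 3D array of detection scores in `[0, 1]`.
#' @param tau Threshold (default 0.9).
#' @param min_size Minimum blob size in voxels (default 5).
#' @param spacing Length-3 voxel spacing (mm).
#' @param connectivity Blob connectivity (default 26).
#' @param prefix Column-name prefix (default `"ai_"`).
#' @return One-row data frame of morphometric features.
#' @export
features_from_detection_map <- function(detection, tau = 0.9, min_size = 5L,
                                        spacing = c(1, 1, 1),
                                        connectivity = 26, prefix = "ai_") {
  mask <- threshold_map(detection, tau)
  blobs <- label_blobs(mask, min_size = min_size,
                       connectivity = connectivity, spacing = spacing)
  patient_features(blobs, prefix = prefix)
}
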