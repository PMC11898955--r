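# shared fixtures and independent oracles

# random symmetric positive-definite 3x3 covariance
random_spd <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  crossprod(A) + diag(0.5, 3)
}

# cube whose voxel spectra are the rows of X (n x 3), on a given grid
cube_from_spectra <- function(X, dims, spacing = c(1, 1, 1)) {
  stopifnot(nrow(X) == prod(dims))
  registered_cube(array(X, c(dims, 3L)), spacing = spacing)
}

# brute-force single-voxel stack flood fill; independent of the
# frontier-expansion implementation under test
flood_fill_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off)
  lab <- array(0L, d)
  cur <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k] || lab[i, j, k] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j, k))
    lab[i, j, k] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(off))) {
        u <- v + off[o, ]
        if (any(u < 1L) || any(u > d)) next
        if (mask[u[1], u[2], u[3]] && lab[u[1], u[2], u[3]] == 0L) {
          lab[u[1], u[2], u[3]] <- cur
          stack[[length(stack) + 1L]] <- u
        }
      }
    }
  }
  lab
}

# partition signature invariant under label permutation: sorted list of
# sorted member linear-index sets
partition_signature <- function(lab) {
  grp <- split(which(lab > 0), lab[lab > 0])
  unname(grp[order(vapply(grp, min, 0))])
}

blobs_to_labels <- function(blobs, d) {
  lab <- array(0L, d)
  for (b in blobs) lab[b$voxel_ids] <- b$label
  lab
}

# O(n^2) pairwise concordance AUROC with ties counted one half
concordance_auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# rasterized solid ellipsoid blob, axis-aligned, unit spacing
ellipsoid_blob <- function(semi, centre = semi + 2) {
  dims <- ceiling(centre + semi + 2)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  keep <- rowSums(sweep(sweep(idx, 2, centre), 2, semi, `/`)^2) <= 1
  idx <- idx[keep, , drop = FALSE]
  structure(list(label = 1L, voxel_ids = idx, size = nrow(idx),
                 centroid = colMeans(idx)), class = "blob")
}

# small background-only cube + mask with known Gaussian statistics
gaussian_background_cube <- function(n_side = 20, m = c(5, 2, 7),
                                     Sigma = matrix(c(4, 1, 0,
                                                      1, 3, 1,
                                                      0, 1, 2), 3, 3)) {
  n <- n_side^3
  X <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(Sigma) +
    rep(m, each = n)
  list(cube = cube_from_spectra(X, rep(n_side, 3)),
       mask = array(TRUE, rep(n_side, 3)), m = m, Sigma = Sigma)
}
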