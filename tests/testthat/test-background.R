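test_that("mean and covariance match a hand-computed 4-voxel example", {
  X <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1), c(2, 1, 3))
  cube <- cube_from_spectra(X, c(4, 1, 1))
  st <- compute_background_stats(cube, array(TRUE, c(4, 1, 1)),
                                 min_voxels = 4)
  expect_equal(unname(st$m), c(2, 2, 2))
  # deviations (-1,0,1),(1,0,-1),(0,1,-1),(0,-1,1); n - 1 = 3 denominator
  want <- matrix(c(2 / 3, 0, -2 / 3,
                   0, 2 / 3, -2 / 3,
                   -2 / 3, -2 / 3, 4 / 3), 3, 3)
  expect_equal(unname(st$CM), want)
  expect_equal(st$n_voxels, 4L)
  expect_equal(unname(st$sigma), sqrt(c(2 / 3, 2 / 3, 4 / 3)))
})

test_that("tiny masks are rejected unless the floor is relaxed explicitly", {
  X <- matrix(rnorm(3 * 10), 10, 3)
  cube <- cube_from_spectra(X, c(10, 1, 1))
  mask <- array(TRUE, c(10, 1, 1))
  expect_error(compute_background_stats(cube, mask), "at least 30")
  expect_s3_class(compute_background_stats(cube, mask, min_voxels = 10),
                  "background_stats")
  one <- cube_from_spectra(matrix(rnorm(3), 1, 3), c(1, 1, 1))
  expect_error(compute_background_stats(one, array(TRUE, c(1, 1, 1)),
                                        min_voxels = 1),
               "at least 2")   # a covariance needs two voxels regardless
})

test_that("a zero-variance band is flagged singular with a pseudo-inverse", {
  set.seed(11)
  X <- cbind(rnorm(50), rnorm(50), 7)   # T2 constant
  cube <- cube_from_spectra(X, c(50, 1, 1))
  st <- compute_background_stats(cube, array(TRUE, c(50, 1, 1)))
  expect_true(st$singular)
  inv <- cov_inverse(st)
  # pseudo-inverse axioms on the estimated covariance
  expect_equal(inv %*% st$CM %*% inv, inv, tolerance = 1e-8)
  expect_equal(st$CM %*% inv %*% st$CM, st$CM, tolerance = 1e-8)
})

test_that("the estimator recovers a known covariance from a large sample", {
  set.seed(42)
  g <- gaussian_background_cube(n_side = 22)
  st <- compute_background_stats(g$cube, g$mask)
  expect_equal(unname(st$m), g$m, tolerance = 0.05)
  expect_lt(max(abs(st$CM - g$Sigma)) / max(abs(g$Sigma)), 0.05)
  # eigendecomposition reconstructs the covariance
  expect_equal(st$eigvecs %*% diag(st$eigvals) %*% t(st$eigvecs),
               st$CM, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sort(st$eigvals, decreasing = TRUE), st$eigvals)
})

test_that("PC filtering inverts only the retained leading components", {
  st <- background_stats(c(0, 0, 0), diag(c(4, 1, 0.25)), n_voxels = 100)
  f1 <- pc_filter(st, 1)
  # dropping the smallest component: inverse acts as diag(1/4, 1, 0)
  expect_equal(unname(cov_inverse(f1)), diag(c(0.25, 1, 0)),
               tolerance = 1e-12)
  f2 <- pc_filter(st, 2)
  expect_equal(unname(cov_inverse(f2)), diag(c(0.25, 0, 0)),
               tolerance = 1e-12)
  expect_identical(f2$variant, "pc_filtered")
  expect_identical(f2$pcs_removed, 2L)
  expect_error(pc_filter(st, 3), "degenerate")
  expect_error(pc_filter(st, -1), "n_remove")
  expect_error(pc_filter(f1, 1), "raw")
})

test_that("the PC-filtered inverse satisfies the pseudo-inverse axioms", {
  set.seed(7)
  for (rep in 1:5) {
    st <- background_stats(rnorm(3), random_spd(), n_voxels = 100)
    for (k in 0:2) {
      inv <- cov_inverse(pc_filter(st, k))
      P <- st$CM %*% inv                     # projector onto retained space
      expect_equal(inv %*% st$CM %*% inv, inv, tolerance = 1e-9)
      expect_equal(P %*% P, P, tolerance = 1e-9)
      expect_equal(sum(diag(P)), 3 - k, tolerance = 1e-9)
    }
  }
})

test_that("shrinkage mixes toward the target as computed by hand", {
  CM <- matrix(c(3, 1, 0,
                 1, 4, 0,
                 0, 0, 2), 3, 3)
  st <- background_stats(c(0, 0, 0), CM, n_voxels = 50)
  reg <- shrink_covariance(st, 0.5, "regularized")
  # target (trace/3) I = 3 I; mix: off-diagonals halved, diagonal pulled to 3
  expect_equal(unname(reg$CM), matrix(c(3, 0.5, 0,
                                        0.5, 3.5, 0,
                                        0, 0, 2.5), 3, 3))
  mod <- shrink_covariance(st, 0.5, "modified_regularized")
  # target diag(CM): per-band variances untouched, off-diagonals halved
  expect_equal(unname(mod$CM), matrix(c(3, 0.5, 0,
                                        0.5, 4, 0,
                                        0, 0, 2), 3, 3))
  expect_identical(reg$variant, "regularized")
  expect_identical(mod$gamma, 0.5)
  expect_error(shrink_covariance(st, 1.5, "regularized"), "\\[0, 1\\]")
  expect_error(shrink_covariance(reg, 0.1, "regularized"), "raw")
})

test_that("identity-target shrinkage preserves the trace; the modified
           target preserves per-band variances", {
  set.seed(3)
  for (rep in 1:10) {
    CM <- random_spd()
    st <- background_stats(rnorm(3), CM, n_voxels = 60)
    g <- runif(1)
    expect_equal(sum(diag(shrink_covariance(st, g, "regularized")$CM)),
                 sum(diag(CM)), tolerance = 1e-12)
    expect_equal(diag(shrink_covariance(st, g, "modified_regularized")$CM),
                 diag(CM), tolerance = 1e-12)
  }
})

test_that("positive shrinkage renders a singular covariance invertible", {
  CM <- tcrossprod(c(1, 2, 3)) + 0   # rank 1
  st <- background_stats(c(0, 0, 0), CM, n_voxels = 40)
  expect_true(st$singular)
  for (mode in c("regularized", "modified_regularized")) {
    sh <- shrink_covariance(st, 0.2, mode)
    expect_false(sh$singular)
    expect_gt(min(sh$eigvals), 0)
    expect_equal(sh$CM %*% cov_inverse(sh), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("gamma selection returns the single candidate when forced", {
  set.seed(5)
  g <- gaussian_background_cube(n_side = 6)
  expect_identical(select_gamma(g$cube, g$mask, "regularized", grid = 0.35),
                   0.35)
  expect_error(select_gamma(g$cube, g$mask, "regularized", grid = numeric()),
               "non-empty")
  expect_error(select_gamma(g$cube, g$mask, "regularized", grid = c(0.1, 2)),
               "\\[0, 1\\]")
})

test_that("degenerate two-voxel samples are driven to positive shrinkage", {
  X <- rbind(c(1, 2, 3), c(4, 6, 8))   # rank-1 leave-one-out covariance
  cube <- cube_from_spectra(X, c(2, 1, 1))
  mask <- array(TRUE, c(2, 1, 1))
  for (mode in c("regularized", "modified_regularized"))
    expect_gt(select_gamma(cube, mask, mode), 0)
})

test_that("well-sampled Gaussian backgrounds need little shrinkage", {
  set.seed(8)
  X <- matrix(rnorm(3 * 10000), 10000, 3) %*% chol(random_spd())
  cube <- cube_from_spectra(X, c(100, 100, 1))
  mask <- array(TRUE, c(100, 100, 1))
  expect_lte(select_gamma(cube, mask, "regularized"), 0.05)
  expect_lte(select_gamma(cube, mask, "modified_regularized"), 0.05)
})

test_that("malformed covariance inputs are rejected", {
  expect_error(background_stats(c(0, 0), diag(3)), "3-band")
  M <- diag(3); M[1, 2] <- 0.5
  expect_error(background_stats(c(0, 0, 0), M), "symmetric")
})
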