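test_that("identical spec and seed give a bit-identical cohort", {
  spec <- synthetic_cohort_spec(n_patients = 4, dims = c(24, 24, 10),
                                seed = 33)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$patients$p001$adc$data, b$patients$p001$adc$data)
  expect_identical(a$patients$p003$ai_map, b$patients$p003$ai_map)
  expect_identical(a$patients$p002$ground_truth, b$patients$p002$ground_truth)
  c <- generate_cohort(synthetic_cohort_spec(n_patients = 4,
                                             dims = c(24, 24, 10), seed = 34))
  expect_false(identical(a$patients$p001$adc$data, c$patients$p001$adc$data))
})

test_that("planted tumor volume matches its voxelization on a fine grid", {
  # 2.0 mL near-sphere at 1 mm isotropic resolution: expect about 2000
  # voxels inside the ellipsoid
  spec <- synthetic_cohort_spec(
    n_patients = 4, dims = c(64, 64, 64), seed = 2,
    adc_spacing = c(1, 1, 1), hbv_spacing = c(1, 1, 1),
    t2_spacing = c(1, 1, 1), hbv_origin = c(0, 0, 0),
    t2_origin = c(0, 0, 0),
    prostate_semi_axes = c(26, 24, 22),
    volume_intercept_ml = 2, volume_slope_ml = 0, volume_sd_ml = 0,
    ecc_intercept = 0.05, ecc_slope = 0, ecc_sd = 0)
  p <- generate_patient(spec, isup = 2, seed = 77)
  gt <- p$ground_truth
  expect_equal(gt$volume_ml, 2)
  expect_equal(gt$n_voxels, 2000, tolerance = 0.05)
  # measured blob shape matches the planted axis ratio
  blob <- structure(list(label = 1L, voxel_ids = gt$voxel_ids,
                         size = gt$n_voxels), class = "blob")
  expect_equal(blob_eccentricity(blob, spec$adc_spacing), gt$ecc,
               tolerance = 0.05)
})

test_that("planted shape trends are recorded in the ground truth", {
  spec <- synthetic_cohort_spec(n_patients = 4, dims = c(40, 40, 16),
                                seed = 5, ecc_sd = 0, volume_sd_ml = 0,
                                contrast_sd = 0)
  p2 <- generate_patient(spec, isup = 1, seed = 10)
  p5 <- generate_patient(spec, isup = 5, seed = 10)
  expect_equal(p2$ground_truth$kappa, 4.5)
  expect_equal(p5$ground_truth$kappa, 6.5)
  expect_gt(p5$ground_truth$volume_ml, p2$ground_truth$volume_ml)
  # signature sits kappa background-sigmas from the mean along the
  # planted contrast direction
  expect_equal(unname(p5$ground_truth$signature - spec$background_mean),
               6.5 * spec$background_sd * c(-1, 1, -0.5))
})

test_that("the normal-prostate mask excludes the tumor; the gland keeps it", {
  spec <- synthetic_cohort_spec(n_patients = 4, seed = 6)
  p <- generate_patient(spec, isup = 4, seed = 11)
  tumor <- array(FALSE, spec$dims)
  tumor[p$ground_truth$voxel_ids] <- TRUE
  expect_true(all(p$mask$data[tumor] == 0))
  expect_true(all(p$prostate$data[tumor] == 1))
  expect_equal(sum(p$prostate$data) - sum(p$mask$data),
               p$ground_truth$n_voxels)
})

test_that("cohort grade labels obey the clinical-significance rule", {
  spec <- synthetic_cohort_spec(n_patients = 12, dims = c(24, 24, 10),
                                seed = 13)
  co <- generate_cohort(spec)
  expect_identical(co$metadata$cspca, co$metadata$isup >= 2)
  expect_true(all(co$metadata$isup %in% 0:5))
  expect_true(all(co$metadata$ai_likelihood >= 0 &
                    co$metadata$ai_likelihood <= 1))
})

test_that("the noiseless surrogate AI likelihood is a logistic in the grade", {
  spec <- synthetic_cohort_spec(n_patients = 8, dims = c(24, 24, 10),
                                seed = 21, ai_noise_sd = 0)
  co <- generate_cohort(spec)
  expect_equal(co$metadata$ai_likelihood,
               plogis(1.2 * (co$metadata$isup - 2)), tolerance = 1e-12)
})

test_that("an unperturbed AI detection map reproduces the planted blob", {
  spec <- synthetic_cohort_spec(n_patients = 4, dims = c(30, 30, 12),
                                seed = 22, ai_map_jitter = 0,
                                ai_map_dilate_prob = 0, ai_map_value = 0.95)
  co <- generate_cohort(spec)
  for (p in co$patients) {
    if (!isTRUE(p$ground_truth$has_tumor)) next
    want <- array(FALSE, spec$dims)
    want[p$ground_truth$voxel_ids] <- TRUE
    expect_identical(p$ai_map > 0, want)
    expect_true(all(p$ai_map[want] == 0.95))
  }
})

test_that("tumor-free glands keep low ACE scores and only small clutter", {
  # an exactly Gaussian background still exceeds a 0.9 squared-cosine
  # threshold at a few percent of voxels, so emptiness cannot be
  # promised; the attainable guarantees are a low mean score and the
  # absence of large clutter blobs
  spec <- synthetic_cohort_spec(n_patients = 4, seed = 31,
                                volume_intercept_ml = 0,
                                volume_slope_ml = 0, volume_sd_ml = 0)
  p <- generate_patient(spec, isup = 0, seed = 3)
  expect_false(p$ground_truth$has_tumor)
  cube <- assemble_cube(p$adc, p$hbv, p$t2)
  gland <- align_mask(p$prostate, cube)
  st <- compute_background_stats(cube, gland)
  sig <- spec$background_mean + 4 * spec$background_sd * c(-1, 1, -0.5)
  ace <- ace_map(cube, st, sig)
  expect_lt(mean(ace[gland]), 0.5)
  det <- threshold_map(ace, 0.9)
  det[!gland] <- FALSE
  blobs <- label_blobs(det, min_size = 5, spacing = cube$spacing)
  sizes <- vapply(blobs, function(b) b$size, 0L)
  if (length(sizes)) expect_lt(max(sizes), 100)
  expect_lt(sum(sizes) / sum(gland), 0.05)
})

test_that("a cohort survives a disk round-trip intact", {
  spec <- synthetic_cohort_spec(n_patients = 4, dims = c(24, 24, 10),
                                seed = 41)
  dir <- withr::local_tempdir()
  co <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "p001", "adc.nii.gz")))
  back <- load_cohort(dir)
  expect_identical(back$metadata$patient_id, co$metadata$patient_id)
  expect_identical(back$metadata$isup, co$metadata$isup)
  expect_equal(back$metadata$ai_likelihood, co$metadata$ai_likelihood,
               tolerance = 1e-9)
  expect_equal(back$patients$p001$adc$data, co$patients$p001$adc$data,
               tolerance = 1e-9)
  expect_equal(back$patients$p001$mask$data, co$patients$p001$mask$data)
  gt_a <- co$patients$p002$ground_truth
  gt_b <- back$patients$p002$ground_truth
  expect_equal(gt_b$isup, gt_a$isup)
  if (isTRUE(gt_a$has_tumor)) {
    expect_equal(nrow(gt_b$voxel_ids), nrow(gt_a$voxel_ids))
    expect_equal(gt_b$ecc, gt_a$ecc, tolerance = 1e-9)
  }
})

test_that("spec validation rejects malformed study definitions", {
  expect_error(synthetic_cohort_spec(typo_field = 1), "unknown spec field")
  expect_error(synthetic_cohort_spec(isup_probs = rep(1, 6)), "histogram")
  expect_error(synthetic_cohort_spec(
    background_cor = matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3)),
    "positive definite")
  expect_error(generate_patient(synthetic_cohort_spec(), isup = 7, seed = 1),
               "0..5")
  expect_error(generate_cohort(synthetic_cohort_spec(n_patients = 2)),
               "at least 4")
})
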