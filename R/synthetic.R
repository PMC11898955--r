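#' Specification for a synthetic BP-MRI cohort
#'
#' Defines the phantom study conditions: an ellipsoidal prostate filled
#' with correlated three-band Gaussian tissue, one embedded ellipsoidal
#' tumor per patient whose spectral contrast and volume increase, and
#' whose eccentricity decreases, with the planted ISUP grade; three
#' sequence volumes emitted on deliberately different grids (offset
#' origins, finer in-plane T2) so registration is genuinely exercised;
#' and a surrogate AI detector producing a grade-correlated likelihood
#' plus a perturbed detection map. Identical spec + seed yields an
#' identical cohort.
#'
#' Default grade-conditional models (all linear with Gaussian noise):
#' spectral contrast `kappa(g) = 4 + 0.5 g` background-sigma units
#' along the direction (ADC low, HBV high, T2 low); tumor volume
#' `0.6 + 0.35 g` mL (sd 0.15); eccentricity `0.75 - 0.08 g` (sd 0.06);
#' AI likelihood `plogis(1.2 (g - 2) + noise)` (sd 0.8). The default
#' ISUP histogram is skewed low (cohort mean near 1.2, roughly a
#' quarter clinically significant).
#'
#' @param n_patients Number of patients (default 42).
#' @param dims Reference (ADC) grid dimensions (default 40 x 40 x 16).
#' @param seed Root seed; per-patient seeds are derived as
#'   `(seed * 48271 + index * 1009) mod (2^31 - 1)`.
#' @param ... Overrides for any other spec field (see the function
#'   body for the full list).
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_patients = 42, dims = c(40, 40, 16),
                                  seed = 1L, ...) {
  spec <- list(
    n_patients = as.integer(n_patients),
    dims = as.integer(dims),
    seed = as.integer(seed),
    # per-sequence grids (mm)
    adc_spacing = c(2, 2, 3), adc_origin = c(0, 0, 0),
    hbv_spacing = c(2, 2, 3), hbv_origin = c(2, 0, 0),
    t2_spacing = c(1, 1, 3), t2_origin = c(0.5, 0.5, 0),
    # anatomy
    prostate_semi_axes = c(28, 24, 18),       # mm
    # background tissue model
    background_mean = c(ADC = 1200, HBV = 200, T2 = 500),
    background_sd = c(150, 40, 90),
    background_cor = matrix(c(1, -0.3, 0.4,
                              -0.3, 1, -0.2,
                              0.4, -0.2, 1), 3, 3),
    outside_scale = 0.8,                       # non-prostate mean factor
    # grade-conditional tumor models
    contrast_intercept = 4, contrast_slope = 0.5, contrast_sd = 0.4,
    contrast_direction = c(-1, 1, -0.5),
    volume_intercept_ml = 0.6, volume_slope_ml = 0.35, volume_sd_ml = 0.15,
    volume_min_ml = 0.15,
    ecc_intercept = 0.75, ecc_slope = -0.08, ecc_sd = 0.06,
    ecc_range = c(0.05, 0.92),
    # ISUP histogram (grades 0..5)
    isup_probs = c(0.31, 0.43, 0.12, 0.07, 0.04, 0.03),
    # surrogate AI model
    ai_slope = 1.2, ai_center = 2, ai_noise_sd = 0.8,
    ai_map_jitter = 1L, ai_map_dilate_prob = 0.5, ai_map_value = 0.95)
  over <- list(...)
  bad <- setdiff(names(over), names(spec))
  if (length(bad)) stop("unknown spec field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  spec <- utils::modifyList(spec, over)
  Sigma <- diag(spec$background_sd) %*% spec$background_cor %*%
    diag(spec$background_sd)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("background covariance must be positive definite", call. = FALSE)
  spec$background_cov <- Sigma
  if (abs(sum(spec$isup_probs) - 1) > 1e-8 || any(spec$isup_probs < 0))
    stop("isup_probs must be a probability histogram over grades 0..5",
         call. = FALSE)
  structure(spec, class = "synthetic_cohort_spec")
}

patient_seed <- function(root, i) {
  as.integer((as.double(root) * 48271 + as.double(i) * 1009) %% 2147483647)
}

# correlated Gaussian draws: n x 3 matrix with covariance Sigma
rmvn3 <- function(n, Sigma) {
  matrix(stats::rnorm(n * 3), n, 3) %*% chol(Sigma)
}

#' Generate one synthetic patient
#'
#' Builds the truth scene on the reference (ADC) grid - ellipsoidal
#' prostate, correlated Gaussian tissue, one planted ellipsoidal tumor
#' whose contrast, volume, and axis ratio follow the grade-conditional
#' models - then emits the three sequence volumes by sampling the
#' scene on each sequence's own grid, so the registration stage has
#' real work to do.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param isup Planted ISUP grade 0-5.
#' @param seed Integer seed for this patient.
#' @param patient_id Identifier string.
#' @return List with `adc`, `hbv`, `t2` ([sequence_volume()]s), `mask`
#'   (prostate mask as a [sequence_volume()] on the reference grid),
#'   `ground_truth` (planted signature, tumor voxel set on the
#'   reference grid, volume, eccentricity, centre, semi-axes), and
#'   `record` (patient metadata row).
#' @export
generate_patient <- function(spec, isup, seed, patient_id = "p001") {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (!isup %in% 0:5) stop("isup must be an integer grade 0..5",
                           call. = FALSE)
  withr::with_seed(as.integer(seed), {
    d <- spec$dims
    sp <- spec$adc_spacing
    centre <- (d - 1) / 2 * sp + spec$adc_origin
    # voxel-centre world coordinates of the reference grid
    w1 <- spec$adc_origin[1] + (seq_len(d[1]) - 1) * sp[1]
    w2 <- spec$adc_origin[2] + (seq_len(d[2]) - 1) * sp[2]
    w3 <- spec$adc_origin[3] + (seq_len(d[3]) - 1) * sp[3]
    pr <- ellipsoid_mask(w1, w2, w3, centre, spec$prostate_semi_axes)

    # grade-conditional tumor draw
    vol_ml <- spec$volume_intercept_ml + spec$volume_slope_ml * isup +
      stats::rnorm(1, 0, spec$volume_sd_ml)
    has_tumor <- vol_ml > 0 &&
      (spec$volume_intercept_ml > 0 || spec$volume_slope_ml > 0)
    gt <- list(isup = as.integer(isup), has_tumor = has_tumor)
    shift <- rep(0, 3)
    tu <- array(FALSE, d)
    if (has_tumor) {
      vol_ml <- max(vol_ml, spec$volume_min_ml)
      ecc <- min(max(spec$ecc_intercept + spec$ecc_slope * isup +
                       stats::rnorm(1, 0, spec$ecc_sd),
                     spec$ecc_range[1]), spec$ecc_range[2])
      kappa <- max(spec$contrast_intercept + spec$contrast_slope * isup +
                     stats::rnorm(1, 0, spec$contrast_sd), 0.5)
      # axis-aligned ellipsoid with semi-axes (a, b, b), b = a (1 - E);
      # if the drawn eccentricity would poke the long axis out of the
      # prostate, shorten it at fixed volume and record the realized E
      a <- (3 * vol_ml * 1000 / (4 * pi * (1 - ecc)^2))^(1 / 3)
      b <- a * (1 - ecc)
      long_axis <- sample(1:3, 1)
      a_max <- 0.9 * spec$prostate_semi_axes[long_axis]
      if (a > a_max) {
        a <- a_max
        b <- sqrt(3 * vol_ml * 1000 / (4 * pi * a))
        if (b > a) { b <- a }   # fully spherical fallback
        ecc <- 1 - b / a
      }
      semi <- rep(b, 3); semi[long_axis] <- a
      if (any(semi >= spec$prostate_semi_axes))
        stop("planted tumor does not fit inside the prostate; ",
             "reduce tumor volume or enlarge the prostate", call. = FALSE)
      room <- spec$prostate_semi_axes - semi
      tc <- centre + stats::runif(3, -0.5, 0.5) * room
      tu <- ellipsoid_mask(w1, w2, w3, tc, semi) & pr
      shift <- kappa * spec$background_sd * spec$contrast_direction
      gt <- c(gt, list(volume_ml = vol_ml, ecc = ecc, kappa = kappa,
                       centre = tc, semi_axes = semi,
                       voxel_ids = which(tu, arr.ind = TRUE),
                       n_voxels = sum(tu)))
    }
    gt$signature <- spec$background_mean + shift

    # truth scene: mean field + correlated noise, all three bands
    n <- prod(d)
    mean_field <- matrix(rep(spec$background_mean, each = n), n, 3)
    out_rows <- !as.vector(pr)
    mean_field[out_rows, ] <- mean_field[out_rows, ] * spec$outside_scale
    tu_rows <- as.vector(tu)
    mean_field[tu_rows, ] <- sweep(mean_field[tu_rows, , drop = FALSE],
                                   2, shift, `+`)
    scene <- mean_field + rmvn3(n, spec$background_cov)
    truth <- lapply(1:3, function(b) sequence_volume(
      array(scene[, b], d), spacing = sp, origin = spec$adc_origin,
      label = c("ADC", "HBV", "T2")[b]))

    grids <- list(
      adc = list(spacing = spec$adc_spacing, origin = spec$adc_origin),
      hbv = list(spacing = spec$hbv_spacing, origin = spec$hbv_origin),
      t2 = list(spacing = spec$t2_spacing, origin = spec$t2_origin))
    vols <- lapply(seq_along(grids), function(i) {
      g <- grids[[i]]
      sample_on_grid(truth[[i]], g$spacing, g$origin)
    })
    names(vols) <- names(grids)

    # label-D semantics: the covariance mask is the NORMAL prostate
    # (gland minus tumor); the whole gland is kept as the search region
    mask_vol <- sequence_volume(array(as.numeric(pr & !tu), d),
                                spacing = sp, origin = spec$adc_origin,
                                label = "mask")
    prostate_vol <- sequence_volume(array(as.numeric(pr), d), spacing = sp,
                                    origin = spec$adc_origin, label = "mask")
    list(adc = vols$adc, hbv = vols$hbv, t2 = vols$t2, mask = mask_vol,
         prostate = prostate_vol,
         ground_truth = gt,
         record = list(patient_id = patient_id, isup = as.integer(isup),
                       cspca = unname(cspca_label(isup))))
  })
}

ellipsoid_mask <- function(w1, w2, w3, centre, semi) {
  q1 <- ((w1 - centre[1]) / semi[1])^2
  q2 <- ((w2 - centre[2]) / semi[2])^2
  q3 <- ((w3 - centre[3]) / semi[3])^2
  outer(outer(q1, q2, `+`), q3, `+`) <= 1
}

# sample a volume on a new grid (spacing/origin), trilinear with edge
# clamping; grid extent covers the source volume's world extent
sample_on_grid <- function(vol, spacing, origin, method = "linear") {
  d <- dim(vol$data)
  hi_world <- vol$origin + (d - 1) * vol$spacing
  dims <- pmax(floor((hi_world - origin) / spacing + 1e-9) + 1L, 1L)
  out <- vol$data
  for (ax in 1:3) {
    w <- origin[ax] + (seq_len(dims[ax]) - 1) * spacing[ax]
    src <- (w - vol$origin[ax]) / vol$spacing[ax] + 1
    src <- pmin(pmax(src, 1), d[ax])
    out <- interp_axis(out, src, ax, method)
  }
  sequence_volume(out, spacing = spacing, origin = origin,
                  label = vol$label)
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` ISUP grades from the spec's histogram, generates
#' every patient with [generate_patient()], attaches surrogate AI
#' outputs with [generate_ai_outputs()], and (optionally) serializes
#' the cohort as a directory tree of NIfTI volumes plus `metadata.csv`
#' and `ground_truth.json`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param dir Optional output directory; created if missing.
#' @param ai Attach surrogate AI outputs (default `TRUE`).
#' @return A `synthetic_cohort` list with `patients`, `metadata`
#'   (data frame), and `spec`; written to `dir` when given.
#' @export
generate_cohort <- function(spec, dir = NULL, ai = TRUE) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (spec$n_patients < 4L)
    stop("a cohort needs at least 4 patients for the regression layer",
         call. = FALSE)
  isup <- withr::with_seed(spec$seed,
    sample(0:5, spec$n_patients, replace = TRUE, prob = spec$isup_probs))
  ids <- sprintf("p%03d", seq_len(spec$n_patients))
  patients <- lapply(seq_len(spec$n_patients), function(i)
    generate_patient(spec, isup[i], patient_seed(spec$seed, i), ids[i]))
  names(patients) <- ids
  cohort <- structure(list(patients = patients, spec = spec),
                      class = "synthetic_cohort")
  if (ai) cohort <- generate_ai_outputs(cohort, spec)
  cohort$metadata <- do.call(rbind, lapply(cohort$patients, function(p)
    as.data.frame(c(p$record,
                    list(ai_likelihood =
                           if (is.null(p$ai_likelihood)) NA_real_
                           else p$ai_likelihood)),
                  stringsAsFactors = FALSE)))
  rownames(cohort$metadata) <- NULL
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, seed %d\n",
              nrow(x$metadata), x$spec$seed))
  invisible(x)
}

#' Attach surrogate AI outputs to a cohort
#'
#' Emulates an external detector: a per-patient clinical-significance
#' likelihood `plogis(a (isup - c) + noise)` (monotone in grade up to
#' noise, always in `[0, 1]`) and a per-patient detection-map volume,
#' the ground-truth tumor mask optionally jittered by up to
#' `ai_map_jitter` voxels and dilated, scaled to `ai_map_value`. With
#' jitter 0 and dilate probability 0 the detection map reproduces the
#' ground-truth blob exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param spec The generating spec (defaults to the cohort's).
#' @return The cohort with `ai_likelihood` and `ai_map` set per patient.
#' @export
generate_ai_outputs <- function(cohort, spec = cohort$spec) {
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    p <- withr::with_seed(patient_seed(spec$seed, i) + 7L, {
      eta <- spec$ai_slope * (p$record$isup - spec$ai_center) +
        stats::rnorm(1, 0, spec$ai_noise_sd)
      p$ai_likelihood <- stats::plogis(eta)
      d <- spec$dims
      m <- array(FALSE, d)
      if (isTRUE(p$ground_truth$has_tumor)) {
        idx <- p$ground_truth$voxel_ids
        jit <- if (spec$ai_map_jitter > 0)
          sample(seq(-spec$ai_map_jitter, spec$ai_map_jitter), 3,
                 replace = TRUE) else c(0L, 0L, 0L)
        idx <- sweep(idx, 2, jit, `+`)
        keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
          idx[, 2] >= 1 & idx[, 2] <= d[2] &
          idx[, 3] >= 1 & idx[, 3] <= d[3]
        idx <- idx[keep, , drop = FALSE]
        m[idx] <- TRUE
        if (spec$ai_map_dilate_prob > 0 &&
            stats::runif(1) < spec$ai_map_dilate_prob)
          m <- dilate6(m)
      }
      p$ai_map <- array(ifelse(m, spec$ai_map_value, 0), d)
      p
    })
    cohort$patients[[i]] <- p
  }
  cohort
}

# one step of 6-neighbourhood binary dilation
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Write a cohort to disk
#'
#' One folder per patient (`adc.nii.gz`, `hbv.nii.gz`, `t2.nii.gz`,
#' `mask.nii.gz`, and `ai_map.nii.gz` when present) plus
#' `metadata.csv` and `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$patients)) {
    p <- cohort$patients[[id]]
    pd <- file.path(dir, id)
    dir.create(pd, showWarnings = FALSE)
    write_volume(p$adc, file.path(pd, "adc.nii.gz"))
    write_volume(p$hbv, file.path(pd, "hbv.nii.gz"))
    write_volume(p$t2, file.path(pd, "t2.nii.gz"))
    write_volume(p$mask, file.path(pd, "mask.nii.gz"))
    if (!is.null(p$prostate))
      write_volume(p$prostate, file.path(pd, "prostate.nii.gz"))
    if (!is.null(p$ai_map))
      write_volume(sequence_volume(p$ai_map, spacing = p$mask$spacing,
                                   origin = p$mask$origin, label = "mask"),
                   file.path(pd, "ai_map.nii.gz"))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  gt <- lapply(cohort$patients, function(p) p$ground_truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort`-shaped list usable by [run_pipeline()].
#' @export
load_cohort <- function(dir) {
  meta <- read_cohort_metadata(file.path(dir, "metadata.csv"))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  patients <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$patient_id[i]
    pd <- file.path(dir, id)
    p <- list(adc = read_volume(file.path(pd, "adc.nii.gz"), "ADC"),
              hbv = read_volume(file.path(pd, "hbv.nii.gz"), "HBV"),
              t2 = read_volume(file.path(pd, "t2.nii.gz"), "T2"),
              mask = read_volume(file.path(pd, "mask.nii.gz"), "mask"),
              record = as.list(meta[i, ]))
    pr_path <- file.path(pd, "prostate.nii.gz")
    if (file.exists(pr_path)) p$prostate <- read_volume(pr_path, "mask")
    gt_i <- gt[[id]]
    if (!is.null(gt_i) && !is.null(gt_i$voxel_ids))
      gt_i$voxel_ids <- matrix(as.numeric(as.matrix(gt_i$voxel_ids)),
                               ncol = 3)
    p$ground_truth <- gt_i
    if (!is.na(meta$ai_likelihood[i])) p$ai_likelihood <- meta$ai_likelihood[i]
    ai_path <- file.path(pd, "ai_map.nii.gz")
    if (file.exists(ai_path)) p$ai_map <- read_volume(ai_path, "mask")$data
    p
  })
  names(patients) <- meta$patient_id
  structure(list(patients = patients, metadata = meta, spec = NULL),
            class = "synthetic_cohort")
}
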