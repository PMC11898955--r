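#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one validated
#' list: covariance variant and its gamma grid / PC count, ACE
#' threshold, blob filtering, calibration kind, the regression model
#' specifications, and the root seed that every random stage derives
#' from.
#'
#' @param covariance_variant One of `"raw"`, `"pc_filtered"`,
#'   `"regularized"`, `"modified_regularized"`; the variant used for
#'   whitening/ACE (SCR is always reported for all variants).
#' @param pcs_removed Components removed for the PC-filtered SCR
#'   (default 2, the high-noise components).
#' @param gamma `"auto"` (leave-one-out selection) or a fixed weight in
#'   `[0, 1]`.
#' @param gamma_grid Candidate grid for `"auto"` selection.
#' @param tau ACE detection threshold (default 0.9).
#' @param min_blob_size Minimum blob size in voxels (default 5).
#' @param connectivity Blob connectivity: 6, 18, 26 (default), `"2d"`.
#' @param restrict_to_mask Zero the ACE map outside the prostate mask
#'   before blobbing (default `TRUE`).
#' @param signature_margin Number of tumor seed voxels (nearest the
#'   ground-truth centre) averaged into the in-scene signature
#'   (default 12).
#' @param calibration `"linear"` or `"atanh"` likelihood-to-ISUP map.
#' @param models Model definitions for [analysis_report()]; `NULL`
#'   selects a default set spanning the spectral, morphometric, AI, and
#'   combined predictors.
#' @param n_iter Randomized splits per AUROC (default 1000).
#' @param split_fraction Training fraction per split (default 0.7).
#' @param seed Root seed (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(covariance_variant = "modified_regularized",
                            pcs_removed = 2L,
                            gamma = "auto",
                            gamma_grid = seq(0, 1, by = 0.05),
                            tau = 0.9,
                            min_blob_size = 5L,
                            connectivity = 26,
                            restrict_to_mask = TRUE,
                            signature_margin = 12L,
                            calibration = "linear",
                            models = NULL,
                            n_iter = 1000L,
                            split_fraction = 0.7,
                            seed = 1L) {
  covariance_variant <- match.arg(covariance_variant,
                                  c("raw", "pc_filtered", "regularized",
                                    "modified_regularized"))
  calibration <- match.arg(calibration, c("linear", "atanh"))
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  structure(list(covariance_variant = covariance_variant,
                 pcs_removed = as.integer(pcs_removed),
                 gamma = gamma, gamma_grid = gamma_grid,
                 tau = tau, min_blob_size = as.integer(min_blob_size),
                 connectivity = connectivity,
                 restrict_to_mask = isTRUE(restrict_to_mask),
                 signature_margin = as.integer(signature_margin),
                 calibration = calibration,
                 models = models,
                 n_iter = as.integer(n_iter),
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] args.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

default_models <- function(features) {
  have <- function(v) all(v %in% names(features)) &&
    any(stats::complete.cases(features[v]))
  cand <- list(
    list(predictors = "scr_modreg"),
    list(predictors = "zscore"),
    list(predictors = "total_volume"),
    list(predictors = "avg_blob_volume"),
    list(predictors = "ecc_largest"),
    list(predictors = "ai_likelihood"),
    list(predictors = "ai_avg_blob_volume"),
    list(predictors = c("ai_avg_blob_volume", "scr_modreg")),
    list(predictors = c("ai_avg_blob_volume", "zscore")),
    list(predictors = c("zscore", "scr_modreg")))
  Filter(function(m) have(m$predictors), cand)
}

#' Extract the full spectral and morphometric feature row for one patient
#'
#' Runs the per-patient arm of the pipeline: cube assembly,
#' background-model estimation (all covariance variants), in-scene
#' signature, z-score and SCR, ACE detection, thresholding, blob
#' morphometrics, and (when present) the AI likelihood and
#' detection-map morphometrics.
#'
#' @param patient Patient list (`adc`, `hbv`, `t2`, `mask`,
#'   `ground_truth`, `record`, optional `ai_likelihood`, `ai_map`), as
#'   produced by [generate_patient()] or [load_cohort()].
#' @param config A [pipeline_config()].
#' @return One-row data frame of features.
#' @export
extract_patient_features <- function(patient, config = pipeline_config()) {
  cube <- assemble_cube(patient$adc, patient$hbv, patient$t2)
  mask <- align_mask(patient$mask, cube)          # normal prostate
  search <- if (!is.null(patient$prostate))       # whole gland
    align_mask(patient$prostate, cube) else mask
  stats_raw <- compute_background_stats(cube, mask)

  gamma_for <- function(mode) {
    if (identical(config$gamma, "auto"))
      select_gamma(cube, mask, mode = mode, grid = config$gamma_grid)
    else as.numeric(config$gamma)
  }
  variants <- list(
    raw = stats_raw,
    pc_filtered = pc_filter(stats_raw, config$pcs_removed),
    regularized = shrink_covariance(stats_raw, gamma_for("regularized"),
                                    "regularized"),
    modified_regularized = shrink_covariance(
      stats_raw, gamma_for("modified_regularized"), "modified_regularized"))

  sig <- patient_signature(patient, cube, config)
  z <- zscore(sig, stats_raw)
  scrs <- c(scr_raw = scr(sig, variants$raw),
            scr_pc = scr(sig, variants$pc_filtered),
            scr_reg = scr(sig, variants$regularized),
            scr_modreg = scr(sig, variants$modified_regularized))

  det_stats <- variants[[config$covariance_variant]]
  ace <- ace_map(cube, det_stats, sig)
  if (config$restrict_to_mask) ace[!search] <- 0
  det_mask <- threshold_map(ace, config$tau)
  blobs <- label_blobs(det_mask, min_size = config$min_blob_size,
                       connectivity = config$connectivity,
                       spacing = cube$spacing)
  feats <- patient_features(blobs, scr = scrs, zscore = z$combined,
                            outcome = patient$record)
  feats$gamma_reg <- variants$regularized$gamma
  feats$gamma_modreg <- variants$modified_regularized$gamma

  if (!is.null(patient$ai_likelihood)) {
    feats$ai_likelihood <- patient$ai_likelihood
    feats$ai_isup <- switch(config$calibration,
                            linear = isup_from_likelihood_linear(
                              patient$ai_likelihood),
                            atanh = isup_from_likelihood_atanh(
                              patient$ai_likelihood))
  }
  if (!is.null(patient$ai_map)) {
    ai_feats <- features_from_detection_map(
      patient$ai_map, tau = config$tau, min_size = config$min_blob_size,
      spacing = patient$mask$spacing, connectivity = config$connectivity,
      prefix = "ai_")
    feats <- cbind(feats, ai_feats)
  }
  feats
}

# in-scene signature: mean spectrum over the tumor seed voxels nearest
# the ground-truth centre, mapped onto the cube grid by world coordinate
patient_signature <- function(patient, cube, config) {
  gt <- patient$ground_truth
  if (is.null(gt) || !isTRUE(gt$has_tumor) || is.null(gt$voxel_ids) ||
      nrow(gt$voxel_ids) == 0)
    stop("patient has no tumor seed region for signature derivation",
         call. = FALSE)
  src <- patient$mask   # reference grid carrier
  world <- voxel_world(as.matrix(gt$voxel_ids), src$spacing, src$origin)
  ctr <- colMeans(world)
  ord <- order(rowSums(sweep(world, 2, ctr)^2))
  world <- world[ord[seq_len(min(config$signature_margin, nrow(world)))],
                 , drop = FALSE]
  idx <- round(sweep(sweep(world, 2, cube$origin), 2, cube$spacing, `/`)) + 1
  d <- cube_dim(cube)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  derive_signature(cube, idx[ok, , drop = FALSE])
}

#' Run the full analysis pipeline over a cohort
#'
#' Per patient: assemble the registered cube, estimate the background
#' model, derive the in-scene signature, compute z-score and SCR for
#' every covariance variant, run ACE detection, threshold and label
#' blobs, measure morphometrics, and merge AI columns; then fit the
#' requested univariate/multivariate and logistic-AUROC models. A
#' patient whose stage fails is reported in the failure manifest and
#' the pipeline continues.
#'
#' @param cohort A `synthetic_cohort` (in memory) or a cohort directory
#'   path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for `features.csv`,
#'   `report.csv`, `report.json`, and `log.csv`.
#' @return List with `features` (data frame), `report`
#'   (see [analysis_report()]), `failures` (data frame), `log`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  feats <- list()
  failures <- list()
  log <- list()
  for (id in names(cohort$patients)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(extract_patient_features(cohort$patients[[id]], config),
                    error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[[id]] <- data.frame(patient_id = id,
                                   stage = "features",
                                   message = conditionMessage(res),
                                   stringsAsFactors = FALSE)
      log[[id]] <- data.frame(stage = "features", patient = id,
                              elapsed = elapsed, outcome = "error",
                              stringsAsFactors = FALSE)
    } else {
      feats[[id]] <- res
      log[[id]] <- data.frame(stage = "features", patient = id,
                              elapsed = elapsed, outcome = "ok",
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(feats))
    stop("no patient produced features; see the failure manifest",
         call. = FALSE)
  features <- fill_rbind(feats)
  models <- if (is.null(config$models)) default_models(features)
            else config$models
  models <- lapply(models, function(m) {
    if (is.null(m$n_iter)) m$n_iter <- config$n_iter
    if (is.null(m$split_fraction)) m$split_fraction <- config$split_fraction
    m
  })
  report <- analysis_report(features, models, seed = config$seed)
  failures <- if (length(failures)) do.call(rbind, failures)
    else data.frame(patient_id = character(), stage = character(),
                    message = character())
  out <- list(features = features, report = report, failures = failures,
              log = do.call(rbind, log), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(out$log, file.path(out_dir, "log.csv"),
                     row.names = FALSE)
  }
  out
}

# rbind rows that may miss some columns (failed AI arm etc.)
fill_rbind <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  }))
}
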