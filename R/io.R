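#' Read a 3D volume from NIfTI or MetaImage (MHA)
#'
#' Spacing and origin are taken from the file header; intensities are
#' returned unmodified. Axis order is normalized to (row, column, slice);
#' orientation information beyond spacing and origin is ignored, because
#' downstream registration works by resampling and whole-voxel
#' translation only.
#'
#' @param path Path to a `.nii`, `.nii.gz`, or `.mha` file.
#' @param label Sequence label to attach; see [sequence_volume()].
#' @return A [sequence_volume()].
#' @export
read_volume <- function(path, label = "T2") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", basename(path)))
  vol <- if (ext %in% c(".nii", ".nii.gz")) {
    read_nifti_volume(path)
  } else if (ext == ".mha") {
    read_mha_volume(path)
  } else {
    stop("unsupported volume format (need .nii, .nii.gz or .mha): ", path,
         call. = FALSE)
  }
  sequence_volume(vol$data, spacing = vol$spacing, origin = vol$origin,
                  label = label)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  a <- as.array(img)
  a <- drop(a)
  if (length(dim(a)) != 3L)
    stop("expected a 3D payload, got ", length(dim(a)), "D: ", path,
         call. = FALSE)
  xf <- RNifti::xform(img)
  list(data = array(as.numeric(a), dim(a)),
       spacing = abs(RNifti::pixdim(img)[1:3]),
       origin = as.numeric(xf[1:3, 4]))
}

#' Write a volume to NIfTI or MetaImage (MHA)
#'
#' @param vol A [sequence_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz`, or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "sequence_volume"))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (ext == ".mha") {
    write_mha_volume(vol, path)
  } else {
    stop("unsupported volume format (need .nii, .nii.gz or .mha): ", path,
         call. = FALSE)
  }
  invisible(path)
}

# --- MetaImage (MHA) ----------------------------------------------------
# No installed R package reads MetaImage, so a minimal reader/writer for
# the uncompressed single-file (ElementDataFile = LOCAL) flavour lives
# here. Multi-file (.mhd + .raw) and compressed payloads are out of scope.

mha_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
               MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_mha_volume <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw == as.raw(10L))
  hdr <- character()
  data_off <- NA_integer_
  start <- 1L
  for (p in nl) {
    line <- rawToChar(raw[start:(p - 1L)])
    line <- sub("\r$", "", line)
    hdr <- c(hdr, line)
    start <- p + 1L
    if (grepl("^\\s*ElementDataFile\\s*=", line)) { data_off <- start; break }
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  ok <- vapply(kv, length, 1L) == 2L
  if (is.na(data_off) || !any(ok))
    stop("corrupt or unsupported MHA header: ", path, call. = FALSE)
  keys <- vapply(kv[ok], `[`, "", 1L)
  vals <- vapply(kv[ok], `[`, "", 2L)
  h <- stats::setNames(trimws(vals), trimws(keys))
  if (!identical(h[["ElementDataFile"]], "LOCAL"))
    stop("only single-file MHA (ElementDataFile = LOCAL) is supported: ",
         path, call. = FALSE)
  if (!is.na(h["CompressedData"]) && toupper(h[["CompressedData"]]) == "TRUE")
    stop("compressed MHA payloads are not supported: ", path, call. = FALSE)
  ndims <- as.integer(h[["NDims"]])
  if (is.na(ndims) || ndims != 3L)
    stop("expected a 3D payload, got NDims=", h[["NDims"]], ": ", path,
         call. = FALSE)
  dims <- as.integer(strsplit(h[["DimSize"]], "\\s+")[[1]])
  type <- h[["ElementType"]]
  if (!type %in% names(mha_types))
    stop("unsupported MHA element type: ", type, call. = FALSE)
  spacing <- if (!is.na(h["ElementSpacing"]))
    as.numeric(strsplit(h[["ElementSpacing"]], "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.na(h["Offset"]))
    as.numeric(strsplit(h[["Offset"]], "\\s+")[[1]]) else rep(0, 3)
  msb <- !is.na(h["BinaryDataByteOrderMSB"]) &&
    toupper(h[["BinaryDataByteOrderMSB"]]) == "TRUE"
  n <- prod(dims)
  need <- n * mha_sizes[[type]]
  if (length(raw) - data_off + 1L < need)
    stop("MHA payload truncated: ", path, call. = FALSE)
  vals <- readBin(raw[data_off:length(raw)], mha_types[[type]], n = n,
                  size = mha_sizes[[type]],
                  signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                  endian = if (msb) "big" else "little")
  list(data = array(as.numeric(vals), dims), spacing = spacing,
       origin = origin)
}

write_mha_volume <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(vol$spacing, digits = 15), collapse = " ")),
           paste("Offset =",
                 paste(format(vol$origin, digits = 15), collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
  invisible(path)
}

# --- cohort metadata ----------------------------------------------------

#' Read a cohort metadata table
#'
#' The CSV must contain `patient_id` and `isup` columns; `cspca` and
#' `ai_likelihood` are optional. When `cspca` is absent it is derived
#' from the grade with [cspca_label()] (clinically significant cancer is
#' ISUP grade 2 or higher).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame with columns `patient_id` (character), `isup`
#'   (integer 0-5), `cspca` (logical), and `ai_likelihood` (numeric or
#'   `NA`).
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "isup")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0)
    return(data.frame(patient_id = character(), isup = integer(),
                      cspca = logical(), ai_likelihood = numeric()))
  isup <- as.numeric(df$isup)
  if (any(is.na(isup)) || any(isup != round(isup)) ||
      any(isup < 0 | isup > 5))
    stop("isup grades must be integers in 0..5", call. = FALSE)
  out <- data.frame(patient_id = as.character(df$patient_id),
                    isup = as.integer(isup), stringsAsFactors = FALSE)
  out$cspca <- if ("cspca" %in% names(df)) {
    as.logical(df$cspca)
  } else {
    cspca_label(out$isup)
  }
  out$ai_likelihood <- if ("ai_likelihood" %in% names(df)) {
    p <- as.numeric(df$ai_likelihood)
    if (any(!is.na(p) & (p < 0 | p > 1)))
      stop("ai_likelihood must lie in [0, 1]", call. = FALSE)
    p
  } else {
    NA_real_
  }
  out
}

#' Write a per-patient feature table
#'
#' One row per patient, one column per feature; missing values are
#' written as empty cells (never sentinel numbers) so that downstream
#' regressions can exclude them pairwise. Values survive a read-back to
#' at least 12 significant digits.
#'
#' @param features Data frame of per-patient features (all rows sharing
#'   one column set, as produced by [patient_features()] / the pipeline).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (is.list(features) && !is.data.frame(features)) {
    cols <- lapply(features, names)
    if (length(unique(vapply(cols, paste, "", collapse = "\r"))) > 1L)
      stop("records do not share a common feature set", call. = FALSE)
    features <- do.call(rbind, lapply(features, as.data.frame))
  }
  stopifnot(is.data.frame(features))
  fmt <- features
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- ""
    out
  })
  fmt[!num] <- lapply(fmt[!num], function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  ok <- tryCatch({
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write feature table to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Data frame; empty cells become `NA`.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
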