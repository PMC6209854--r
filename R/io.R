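# NIfTI and table I/O, analysis configuration.

#' Read a 4D BOLD NIfTI file
#'
#' @param path NIfTI-1 file (gzip allowed).
#' @param tr_s Optional repetition-time override; used (with a warning) when
#'   the header TR is missing or non-positive, and always wins when supplied.
#' @return A [bold_run()]; voxel size and TR come from the header unless
#'   overridden.
#' @export
read_bold_nifti <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D BOLD image, got ", length(d), "D: ", path)
  pix <- RNifti::pixdim(img)
  hdr_tr <- if (length(pix) >= 4) pix[4] else 0
  if (!is.null(tr_s)) {
    if (!isTRUE(all.equal(hdr_tr, tr_s)) && hdr_tr > 0)
      warning("header TR ", hdr_tr, " s overridden by configured TR ", tr_s, " s")
    use_tr <- tr_s
  } else if (hdr_tr > 0) {
    use_tr <- hdr_tr
  } else stop("header TR is missing/zero and no override was supplied: ", path)
  sid <- sub("_bold\\.nii(\\.gz)?$", "", basename(path))
  bold_run(array(as.numeric(img), dim = d), voxel_size_mm = pix[1:3],
           tr_s = use_tr, subject_id = sid)
}

#' Write a BOLD run as 4D NIfTI
#'
#' @param run A [bold_run()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size_mm, run$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D ROI mask NIfTI
#'
#' @param path NIfTI file; nonzero voxels are in-mask.
#' @return A [roi_mask()].
#' @export
read_roi_nifti <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- dim(img) }
  if (length(d) != 3L) stop("expected a 3D mask, got ", length(d), "D: ", path)
  roi_mask(array(as.numeric(img), dim = d))
}

#' Write an ROI mask as 3D uint8 NIfTI
#' @param roi A [roi_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_nifti <- function(roi, path) {
  img <- RNifti::asNifti(array(as.integer(roi), dim = dim(roi)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a contrast map as paired NIfTI files with a JSON sidecar
#'
#' @param map A [contrast_map()].
#' @param prefix Output path prefix; writes `<prefix>_effect.nii.gz`,
#'   `<prefix>_variance.nii.gz`, `<prefix>.json`.
#' @return The sidecar path, invisibly.
#' @export
write_contrast_map <- function(map, prefix) {
  stopifnot(inherits(map, "contrast_map"))
  RNifti::writeNifti(RNifti::asNifti(map$effect),
                     paste0(prefix, "_effect.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$variance),
                     paste0(prefix, "_variance.nii.gz"))
  side <- list(subject_id = map$subject_id, dof = map$dof,
               contrast_vector = as.numeric(map$contrast_vector))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Read a contrast map written by [write_contrast_map()]
#' @param prefix Path prefix used when writing.
#' @return A [contrast_map()].
#' @export
read_contrast_map <- function(prefix) {
  eff <- RNifti::readNifti(paste0(prefix, "_effect.nii.gz"))
  va <- RNifti::readNifti(paste0(prefix, "_variance.nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  contrast_map(array(as.numeric(eff), dim(eff)), array(as.numeric(va), dim(va)),
               dof = side$dof, contrast_vector = side$contrast_vector,
               subject_id = side$subject_id)
}

#' Read / write the subjects table
#'
#' Tab-separated with columns `subject_id`, `sex`, `age_years`,
#' `hamd_baseline`, `hamd_week6` plus free covariate columns; a `responder`
#' column is (re)derived from the HAM-D rule on read.
#'
#' @param path TSV path.
#' @return Data frame of subject records.
#' @export
read_subjects_tsv <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "hamd_baseline", "hamd_week6")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subjects file missing column(s): ", paste(miss, collapse = ", "))
  df$responder <- classify_response(df$hamd_baseline, df$hamd_week6)
  df
}

#' @rdname read_subjects_tsv
#' @param records Data frame of subject records.
#' @export
write_subjects_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every analysis constant in one serialisable object.
#'
#' @param tr_s Repetition time (2 s).
#' @param n_volumes Volumes per run (256).
#' @param fwhm_mm Spatial smoothing FWHM (5 mm).
#' @param highpass_cutoff_s High-pass cutoff (120 s).
#' @param hrf_delay_s,hrf_sd_s Gamma HRF mean and SD (6 s, 3 s).
#' @param cluster_forming_z Cluster-forming Z (2.3).
#' @param alpha_fwe Familywise alpha (0.05).
#' @param n_permutations Permutations (5000).
#' @param n_nuisance Nuisance regressors (33).
#' @param response_threshold HAM-D reduction defining response (0.5).
#' @param connectivity Cluster connectivity (26).
#' @param roi_path Optional ROI file path.
#' @param seed Master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(tr_s = 2, n_volumes = 256, fwhm_mm = 5,
                            highpass_cutoff_s = 120, hrf_delay_s = 6,
                            hrf_sd_s = 3, cluster_forming_z = 2.3,
                            alpha_fwe = 0.05, n_permutations = 5000,
                            n_nuisance = 33, response_threshold = 0.5,
                            connectivity = 26, roi_path = NULL, seed = 1) {
  num <- list(tr_s = tr_s, n_volumes = n_volumes, fwhm_mm = fwhm_mm,
              highpass_cutoff_s = highpass_cutoff_s, hrf_delay_s = hrf_delay_s,
              hrf_sd_s = hrf_sd_s, cluster_forming_z = cluster_forming_z,
              alpha_fwe = alpha_fwe, n_permutations = n_permutations,
              n_nuisance = n_nuisance, response_threshold = response_threshold,
              connectivity = connectivity, seed = seed)
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("configuration field(s) must be positive numbers: ",
         paste(bad, collapse = ", "))
  if (alpha_fwe >= 1) stop("alpha_fwe must be in (0, 1)")
  structure(c(num, list(roi_path = roi_path)), class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_config_yaml
#' @param config An [analysis_config()].
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
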