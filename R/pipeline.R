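# End-to-end orchestration: cohort serialisation and the full analysis.

#' Write a simulated cohort to a data directory
#'
#' Lays out the directory that [run_full_pipeline()] consumes: one
#' `<id>_bold.nii.gz` and `<id>_nuisance.tsv` per subject, shared
#' `events.tsv`, `subjects.tsv` and `roi.nii.gz`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param design The [task_design()] used for the runs.
#' @param noise The [noise_spec()] used (nuisance tables are regenerated from
#'   its per-subject seeds).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, design = make_task_schedule(),
                         noise = noise_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events_tsv(design, file.path(dir, "events.tsv"))
  write_subjects_tsv(cohort$records, file.path(dir, "subjects.tsv"))
  write_roi_nifti(cohort$roi, file.path(dir, "roi.nii.gz"))
  for (i in seq_along(cohort$runs)) {
    run <- cohort$runs[[i]]
    write_bold_nifti(run, file.path(dir, paste0(run$subject_id, "_bold.nii.gz")))
    nv <- dim(run$data)[4]
    nu <- simulate_nuisance_regressors(nv, run$tr_s,
                                       noise$physio_frequencies_hz,
                                       noise$n_nuisance,
                                       seed = derive_seed(noise$seed %||% 1, i))
    write.table(round(nu, 6), file.path(dir, paste0(run$subject_id, "_nuisance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Run the complete analysis pipeline
#'
#' Executes, from a data directory: per-subject first-level GLM (smoothing,
#' high-pass, gamma-HRF design with temporal derivatives and nuisance
#' regressors, AR(1) prewhitening, sad - happy contrast); group inference
#' (ROI small-volume permutation correction, whole-brain permutation cluster
#' correction, and TFCE within the ROI), all with baseline HAM-D as
#' covariate; leave-one-out response prediction; and the demographic table.
#'
#' @param config An [analysis_config()].
#' @param data_dir Directory laid out as by [write_cohort()].
#' @param out_dir Optional output directory; when given, Z maps, cluster
#'   tables, the LOO report (JSON) and the demographics table are written
#'   there, each stamped with the configuration hash and seed.
#' @return List with `contrast_maps`, `svc` (ROI permutation result),
#'   `whole_brain`, `tfce`, `loo` ([run_loo()] report), `demographics`, and
#'   `config_hash`.
#' @export
run_full_pipeline <- function(config = analysis_config(), data_dir,
                              out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  subjects <- read_subjects_tsv(file.path(data_dir, "subjects.tsv"))
  design <- read_events_tsv(file.path(data_dir, "events.tsv"))
  roi_file <- config$roi_path %||% file.path(data_dir, "roi.nii.gz")
  roi <- read_roi_nifti(roi_file)
  hrf <- hrf_spec(config$hrf_delay_s, config$hrf_sd_s)
  maps <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    bold_file <- file.path(data_dir, paste0(sid, "_bold.nii.gz"))
    if (!file.exists(bold_file))
      stop("first-level stage: missing BOLD run for subject ", sid)
    run <- tryCatch(read_bold_nifti(bold_file, tr_s = config$tr_s),
                    error = function(e)
                      stop("first-level stage (", sid, "): ",
                           conditionMessage(e), call. = FALSE))
    nuis_file <- file.path(data_dir, paste0(sid, "_nuisance.tsv"))
    nuisance <- if (file.exists(nuis_file))
      as.matrix(read.delim(nuis_file, sep = "\t")) else NULL
    maps[[i]] <- fit_first_level(run, design, nuisance = nuisance,
                                 fwhm_mm = config$fwhm_mm,
                                 cutoff_s = config$highpass_cutoff_s,
                                 hrf = hrf)
  }
  cfg <- inference_config(cluster_forming_z = config$cluster_forming_z,
                          alpha_fwe = config$alpha_fwe,
                          n_permutations = config$n_permutations,
                          connectivity = config$connectivity,
                          seed = config$seed)
  model <- group_model(maps, subjects$responder,
                       covariates = subjects$hamd_baseline)
  svc <- small_volume_correct(model, roi, cfg, method = "perm")
  whole <- permutation_cluster_correct(model, mask = NULL, cfg = cfg)
  tfce <- tfce_permutation_correct(model, mask = roi, cfg = cfg)
  loo <- run_loo(maps, subjects$responder,
                 covariates = subjects$hamd_baseline, roi = roi, cfg = cfg)
  demo <- demographics_table(subjects)
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    RNifti::writeNifti(RNifti::asNifti(unclass(svc$zmap)),
                       file.path(out_dir, "svc_zmap.nii.gz"))
    for (nm in c("svc", "whole_brain")) {
      res <- if (nm == "svc") svc else whole
      tab <- as.data.frame(res$clusters)
      tab$config_hash <- hash
      write.table(tab, file.path(out_dir, paste0(nm, "_clusters.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           accuracy = loo$accuracy, binomial_p = loo$binomial_p,
           confusion = as.list(loo$confusion), folds = loo$folds),
      file.path(out_dir, "loo_report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    write.table(cbind(as.data.frame(demo), config_hash = hash),
                file.path(out_dir, "demographics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_config_yaml(config, file.path(out_dir, "config.yaml"))
  }
  list(contrast_maps = maps, svc = svc, whole_brain = whole, tfce = tfce,
       loo = loo, demographics = demo, config_hash = hash)
}
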