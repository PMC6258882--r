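#' Write a synthetic two-site study to disk
#'
#' Materializes a [generate_two_site_study()] result as NIfTI volumes
#' (decay data, white-matter mask, ground-truth MWF) plus a manifest CSV
#' consumable by [run_pipeline()].
#'
#' @param study A `two_site_study`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "two_site_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(study$records, function(rec) {
    stem <- sprintf("p%02d_%s", rec$participant, rec$site)
    decay <- paste0(stem, "_decay.nii.gz")
    mask <- paste0(stem, "_wm_mask.nii.gz")
    truth <- paste0(stem, "_true_mwf.nii.gz")
    write_nifti(rec$volume, file.path(dir, decay))
    write_nifti(array((rec$truth$regions == 1L) * 1, dim(rec$truth$regions)),
                file.path(dir, mask))
    write_nifti(rec$truth$mwf, file.path(dir, truth))
    data.frame(participant = rec$participant, site = rec$site,
               decay = decay, mask = mask, truth = truth,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline over a study manifest
#'
#' For every manifest row: read the decay volume and mask, fit the
#' stimulated-echo-corrected T2 spectrum in every mask voxel, write the
#' MWF/flip-angle/chi-square maps, and summarize the mask ROI. The
#' per-participant per-site ROI means then feed the intersite
#' reproducibility statistics. Outputs are written atomically (temp file
#' then rename), so reruns overwrite cleanly.
#'
#' @param manifest Path to a manifest CSV ([read_manifest()]) or an
#'   equivalent data frame.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param verbose Log per-stage progress.
#' @return List: `roi_table` (data frame), `report` (a `repro_report` or
#'   `NULL` when fewer than two sites), `paths` of the written outputs.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = "mwfpipe_out", verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  config <- validate_config(config)
  obj <- config_objects(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    t0 <- Sys.time()
    res <- tryCatch({
      vol <- read_decay_volume(row$decay)
      mask <- read_nifti(row$mask)$data
      maps <- fit_volume(vol$data, mask, obj$grid, obj$train, obj$fit,
                         verbose = verbose)
      prefix <- file.path(out_dir,
                          sprintf("p%s_%s", row$participant, row$site))
      write_mwf_maps(maps, prefix, vol$affine)
      s <- roi_mean(maps$mwf, mask, roi = "global_wm")
      data.frame(participant = row$participant, site = row$site,
                 roi = s$roi, n_voxels = s$n_voxels, mean_mwf = s$mean,
                 sd_mwf = s$sd, stringsAsFactors = FALSE)
    }, error = function(e) {
      stop(sprintf("pipeline stage 'fit' failed for participant %s site %s: %s",
                   row$participant, row$site, conditionMessage(e)),
           call. = FALSE)
    })
    say("fit participant %s site %s: %d voxels in %.1f s", row$participant,
        row$site, res$n_voxels, as.numeric(Sys.time() - t0, units = "secs"))
    res
  })
  roi_table <- do.call(rbind, rows)
  write_atomic_csv(roi_table, file.path(out_dir, "roi_summary.csv"))

  report <- NULL
  paths <- c(roi_summary = file.path(out_dir, "roi_summary.csv"))
  if (length(unique(roi_table$site)) == 2) {
    report <- cohort_report(roi_table, delta = config$delta,
                            alpha = config$alpha)
    paths <- c(paths, write_report(report, out_dir))
  }
  list(roi_table = roi_table, report = report, paths = paths)
}

write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, na = "")
  file.rename(tmp, path)
  invisible(path)
}

#' Write a reproducibility report to disk
#'
#' Emits `covs.csv` (per-participant per-ROI corrected COVs),
#' `agreement.csv` (per-ROI Pearson / paired-t / TOST / Bland-Altman
#' summaries) and a human-readable `report.txt`.
#'
#' @param report A `repro_report` from [cohort_report()].
#' @param out_dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "repro_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  covs_path <- file.path(out_dir, "covs.csv")
  write_atomic_csv(report$cov, covs_path)
  agr <- do.call(rbind, lapply(names(report$agreement), function(roi) {
    a <- report$agreement[[roi]]
    grab <- function(x, field) if (is.null(x)) NA_real_ else x[[field]]
    data.frame(
      roi = roi,
      mean_cov = report$cov_summary$mean_cov[report$cov_summary$roi == roi],
      pearson_r = grab(a$pearson, "r"),
      pearson_p = grab(a$pearson, "p"),
      t = grab(a$paired_t, "t"), t_p = grab(a$paired_t, "p"),
      mean_diff = grab(a$paired_t, "mean_diff"),
      tost_p = grab(a$tost, "p"),
      bias = a$bland_altman$bias,
      loa_lower = a$bland_altman$loa[1], loa_upper = a$bland_altman$loa[2],
      ba_slope = a$bland_altman$slope, ba_slope_p = a$bland_altman$slope_p,
      stringsAsFactors = FALSE)
  }))
  agr_path <- file.path(out_dir, "agreement.csv")
  write_atomic_csv(agr, agr_path)
  txt_path <- file.path(out_dir, "report.txt")
  tmp <- paste0(txt_path, ".tmp")
  con <- file(tmp, "w")
  sink(con); print(report); sink()
  close(con)
  file.rename(tmp, txt_path)
  invisible(c(covs = covs_path, agreement = agr_path, report = txt_path))
}
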