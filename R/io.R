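#' Read a 4D multi-echo decay volume
#'
#' Thin wrapper over [read_nifti()] that enforces 4D data with the echo
#' axis last. Echo times are defined by the [echo_train()] configuration,
#' not by header fields (NIfTI headers are unreliable for echo spacing).
#'
#' @param path NIfTI file.
#' @return List: `data` (4D array), `affine`, `n_echoes`.
#' @export
read_decay_volume <- function(path) {
  v <- read_nifti(path)
  if (length(dim(v$data)) != 4L)
    stop(path, ": expected a 4D multi-echo volume, got ",
         length(dim(v$data)), "D", call. = FALSE)
  list(data = v$data, affine = v$affine, n_echoes = dim(v$data)[4])
}

#' Write the fitted maps of a volume
#'
#' Writes `<prefix>_mwf.nii.gz`, `<prefix>_alpha.nii.gz` (flip angle) and
#' `<prefix>_chi2.nii.gz`, preserving the input affine. Undefined voxels
#' are stored as NaN.
#'
#' @param maps An `mwf_maps` object from [fit_volume()].
#' @param prefix Output path prefix.
#' @param affine 4x4 affine to carry over.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_mwf_maps <- function(maps, prefix, affine = diag(4)) {
  stopifnot(inherits(maps, "mwf_maps"))
  paths <- c(mwf = paste0(prefix, "_mwf.nii.gz"),
             alpha = paste0(prefix, "_alpha.nii.gz"),
             chi2 = paste0(prefix, "_chi2.nii.gz"))
  write_nifti(maps$mwf, paths["mwf"], affine)
  write_nifti(maps$angle, paths["alpha"], affine)
  write_nifti(maps$chi2, paths["chi2"], affine)
  invisible(paths)
}

#' Read a study manifest
#'
#' The manifest is a CSV with columns `participant`, `site`, `decay`
#' (path to the 4D volume), `mask` (path to the analysis mask) and
#' optionally `truth` (path to a ground-truth MWF map). Relative paths
#' are resolved against the manifest's directory. (participant, site)
#' pairs must be unique and every referenced file must exist.
#'
#' @param path Manifest CSV.
#' @return Data frame with absolute paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "site", "decay", "mask")
  if (!all(need %in% names(m)))
    stop("manifest needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m[, c("participant", "site")]))
    stop("duplicate (participant, site) rows in manifest", call. = FALSE)
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "", NA_character_,
    ifelse(grepl("^/", p), p, file.path(base, p)))
  for (col in intersect(c("decay", "mask", "truth"), names(m))) {
    m[[col]] <- fix(m[[col]])
    missing <- m[[col]][!is.na(m[[col]]) & !file.exists(m[[col]])]
    if (length(missing))
      stop("manifest references missing files: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  m
}

#' Pipeline configuration
#'
#' Collects every tunable of the fit, phantom and statistics stages with
#' the conventional defaults: T2 grid 0.015-2 s with 40 points, myelin
#' window 15-40 ms, 8 candidate angles on 50-180 degrees, echo spacing
#' 10 ms with 32 echoes, TOST bounds +/-0.005, alpha 0.05.
#'
#' @param ... Overrides of the default fields (unknown names are an
#'   error).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    t2_min = 0.015, t2_max = 2.0, n_t2 = 40L,
    echo_spacing = 0.010, n_echoes = 32L, repetition_time = 1.0,
    angle_min = 50, angle_max = 180, n_angles = 8L,
    window = c(0.015, 0.040), reg = c(1.02, 1.025), t1 = 1.0,
    mask_threshold = 0.9, erode_iterations = 1L,
    delta = 0.005, alpha = 0.05, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$t2_min > 0, cfg$t2_max > cfg$t2_min, cfg$n_t2 >= 2,
            cfg$echo_spacing > 0, cfg$n_echoes >= 1,
            cfg$angle_min > 0, cfg$angle_max <= 180,
            cfg$angle_max > cfg$angle_min, cfg$n_angles >= 2,
            length(cfg$window) == 2, length(cfg$reg) == 2,
            cfg$reg[1] > 1, cfg$reg[2] > cfg$reg[1],
            cfg$delta > 0, cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML document holds a flat mapping of [pipeline_config()] fields;
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  do.call(pipeline_config, y)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k,
                                  paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

# Internal: expand a pipeline_config into the stage-level objects.
config_objects <- function(cfg) {
  list(
    train = echo_train(cfg$echo_spacing, cfg$n_echoes, cfg$repetition_time),
    grid = make_t2_grid(cfg$t2_min, cfg$t2_max, cfg$n_t2),
    fit = fit_config(
      candidate_angles = seq(cfg$angle_min, cfg$angle_max,
                             length.out = cfg$n_angles),
      reg_lo = cfg$reg[1], reg_hi = cfg$reg[2],
      myelin_window = cfg$window, t1 = cfg$t1))
}

#' Bundled two-site reference COV tables
#'
#' Per-participant corrected intersite COVs of global white-matter MWF,
#' and per-ROI mean COVs, from a published two-site (two-vendor) myelin
#' water imaging reproducibility study of 10 healthy participants. Used
#' by the acceptance checks to verify the table-summary arithmetic.
#'
#' @return List of two data frames: `global_wm` (participant,
#'   cov_percent) and `roi` (roi, mean_cov_percent).
#' @export
reference_cov_tables <- function() {
  dir <- system.file("extdata", "reference_study", package = "mwfpipe",
                     mustWork = TRUE)
  list(
    global_wm = utils::read.csv(file.path(dir, "global_wm_cov.csv"),
                                stringsAsFactors = FALSE),
    roi = utils::read.csv(file.path(dir, "roi_cov.csv"),
                          stringsAsFactors = FALSE))
}
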