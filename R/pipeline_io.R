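# Formats, configuration, manifests and the end-to-end pipeline driver.
#
# Conventions (project-wide): NIfTI-1 volumes written uncompressed (.nii);
# motion traces as 6-column whitespace-delimited text (translations mm then
# rotations rad, one row per volume); all tables TSV with a header row and
# floats at 6 significant digits; manifests JSON. Voxel indices are 0-based
# when passed through an affine; world coordinates are RAS+ mm.

#' Read a 4D BOLD NIfTI file
#'
#' @param path Path to a 4D NIfTI-1 file.
#' @param tr_s Optional repetition-time override in seconds; required when
#'   the header carries no usable TR.
#' @param subject_id Optional subject id (defaults to the file stem).
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr_s = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("cannot read NIfTI file ", path, ": ",
                         conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 4L)
    stop(path, " is ", length(d), "D; a 4D BOLD series is required")
  hdr <- RNifti::niftiHeader(img)
  if (is.null(tr_s)) {
    tr_s <- hdr$pixdim[5]
    if (!is.finite(tr_s) || tr_s <= 0)
      stop(path, " has no TR in its header; pass an explicit `tr_s`")
  }
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  bold_run(array(as.numeric(img), dim = d), tr_s = tr_s,
           affine = matrix(aff, 4, 4), subject_id = subject_id)
}

#' Write a BOLD run as NIfTI-1
#'
#' Volumes are stored as 32-bit float, uncompressed by default so repeated
#' writes of identical data are bit-identical.
#'
#' @param run A [bold_run()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::sform(img) <- structure(run$affine, code = 2L)
  RNifti::qform(img) <- structure(run$affine, code = 2L)
  RNifti::pixdim(img) <- c(abs(diag(run$affine)[1:3]), run$tr_s)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write / read a binary network mask as NIfTI-1
#' @param mask A [network_mask()].
#' @param path File path.
#' @return `path` (write) or a [network_mask()] (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "network_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$indicator),
                               dim = dim(mask$indicator)))
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::pixdim(img) <- abs(diag(mask$affine)[1:3])
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop(path, " is not a 3D mask volume")
  aff <- matrix(structure(RNifti::xform(img), imagedim = NULL, code = NULL),
                4, 4)
  network_mask(array(img, dim = dim(img)) > 0, aff)
}

#' Write / read a motion trace as whitespace-delimited text
#'
#' Six columns, one row per volume: translations (mm) then rotations
#' (radians), no header.
#'
#' @param motion A [motion_trace()].
#' @param path File path.
#' @return `path` (write) or a [motion_trace()] (read).
#' @export
write_motion <- function(motion, path) {
  stopifnot(inherits(motion, "motion_trace"))
  utils::write.table(format(motion$params, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_trace(m)
}

#' Write / read a phenotype table as TSV
#' @param pheno Phenotype data.frame.
#' @param path File path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_phenotypes <- function(pheno, path) {
  write_tsv(pheno, path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# TSV with 6-significant-digit floats, stable column order
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Layout: `sub-XXX_bold.nii`, `sub-XXX_motion.txt`, `phenotypes.tsv`,
#' `mask_truth.nii`, and `truth.json` (planted effects, correlations, true
#' regional NH and mean FD).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$runs)) {
    id <- cohort$runs[[i]]$subject_id
    write_bold(cohort$runs[[i]], file.path(dir, paste0(id, "_bold.nii")))
    write_motion(cohort$motions[[i]],
                 file.path(dir, paste0(id, "_motion.txt")))
  }
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_mask(cohort$mask_truth, file.path(dir, "mask_truth.nii"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(region_names = truth$region_names,
         effect_regions = lapply(cohort$spec$effect_regions, function(e)
           list(label = e$label, sign = e$sign, delta = e$delta)),
         planted_correlations = truth$planted_correlations,
         true_mean_fd = as.list(truth$true_mean_fd),
         true_region_nh = as.data.frame(truth$true_region_nh)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param tr_s Optional TR override for the runs.
#' @return A list with `runs`, `motions`, `phenotypes`, `mask_truth`.
#' @export
read_cohort <- function(dir, tr_s = NULL) {
  bolds <- sort(list.files(dir, pattern = "_bold\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(bolds)) stop("no *_bold.nii files under ", dir)
  runs <- lapply(bolds, read_bold, tr_s = tr_s)
  runs <- lapply(runs, function(r) {
    r$subject_id <- sub("_bold$", "", r$subject_id); r
  })
  motions <- lapply(runs, function(r) {
    p <- file.path(dir, paste0(r$subject_id, "_motion.txt"))
    if (!file.exists(p)) stop("missing motion trace ", p)
    read_motion(p)
  })
  ph_path <- file.path(dir, "phenotypes.tsv")
  pheno <- if (file.exists(ph_path)) read_phenotypes(ph_path) else NULL
  mask_path <- file.path(dir, "mask_truth.nii")
  mask <- if (file.exists(mask_path)) read_mask(mask_path) else NULL
  list(runs = runs, motions = motions, phenotypes = pheno,
       mask_truth = mask)
}

#' Default pipeline configuration
#'
#' Every stage parameter with its default; [run_pipeline()] rejects
#' configs containing keys not present here.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    simulate = list(enabled = TRUE, n_patients = 20L, n_controls = 20L,
                    n_volumes = 100L, tr_s = 2, fd_confound = 0,
                    n_high_motion = 0L),
    input = list(dir = NULL, tr_s = NULL),
    preprocess = list(drop_volumes = 10L, low_hz = 0.01, high_hz = 0.08,
                      use_friston24 = FALSE, head_radius_mm = 50,
                      max_translation_mm = 2, max_rotation_deg = 2,
                      max_mean_fd_mm = 0.5),
    mask = list(method = "truth", template = NULL, n_components = 20L,
                pca_k = 25L, z_thresh = 2.3, min_cluster_voxels = 10L),
    nh = list(standardize = FALSE),
    compare = list(voxel_p = 0.001, n_perm = 500L, alpha = 0.05,
                   use_covariates = TRUE, bonferroni_signs = TRUE),
    correlate = list(variables = c("TG", "CHOL", "HDL_C", "LDL_C",
                                   "RBANS_verbal_fluency",
                                   "RBANS_verbal_total"),
                     group = "patient", adjust = "none"),
    classify = list(nested = FALSE))
}

check_config_keys <- function(config, template = default_config(),
                              path = "") {
  extra <- setdiff(names(config), names(template))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(config))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(config[[k]]))
      check_config_keys(config[[k]], template[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

merge_config <- function(config, template = default_config()) {
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(config[[k]]))
      template[[k]] <- merge_config(config[[k]], template[[k]])
    else template[[k]] <- config[[k]]
  }
  template
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file path.
#' @return The merged config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg)
  merge_config(cfg)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  canonical <- rapply(config, function(x) x, how = "replace")
  jsonlite::write_json(sort_named_lists(canonical), f, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(f))
}

sort_named_lists <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sort_named_lists)
  } else x
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

stage_log <- function(log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  cat(sprintf("%s\t%s\t%s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage, msg), file = log, append = TRUE)
}

#' Run the full NH analysis pipeline
#'
#' Executes simulate (optional), preprocess + motion QC, mask derivation,
#' NH computation, group comparison, clinical correlation and SVM
#' classification in order, writing each stage's outputs under `out_dir`
#' and returning a JSON-serializable manifest. The manifest records the
#' config hash, per-stage outputs with md5 checksums and key counts, and
#' contains no timestamps: re-running with the same config yields a
#' bit-identical manifest. Wall-clock times go to `pipeline.log`.
#'
#' @param config A config list (see [default_config()]) or a YAML path.
#' @param out_dir Output directory.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  check_config_keys(config)
  config <- merge_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "pipeline.log")
  cat("", file = log)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("nethom")),
                   config = config, config_hash = config_hash(config),
                   stages = list())

  # -- simulate / load ------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sp <- config$simulate
    spec <- sim_spec(n_patients = sp$n_patients,
                     n_controls = sp$n_controls,
                     n_volumes = sp$n_volumes, tr_s = sp$tr_s,
                     fd_confound = sp$fd_confound,
                     motion_plan = utils::modifyList(
                       default_motion_plan(),
                       list(n_high_motion = sp$n_high_motion)),
                     seed = config$seed)
    cohort <- generate_cohort(spec)
    stage_log(log, "simulate", "generated %d subjects (%d patients)",
              length(cohort$runs), spec$n_patients)
    runs <- cohort$runs; motions <- cohort$motions
    pheno <- cohort$phenotypes; template <- cohort$mask_truth
    manifest$stages$simulate <- list(n_subjects = length(runs),
                                     seed = config$seed)
  } else {
    if (is.null(config$input$dir))
      stop("simulate is disabled and no input.dir is configured")
    co <- read_cohort(config$input$dir, tr_s = config$input$tr_s)
    runs <- co$runs; motions <- co$motions; pheno <- co$phenotypes
    template <- co$mask_truth
    stage_log(log, "load", "read %d subjects from %s", length(runs),
              config$input$dir)
    manifest$stages$load <- list(n_subjects = length(runs),
                                 dir = config$input$dir)
  }
  if (is.null(pheno)) stop("no phenotype table available")

  # -- preprocess + QC ------------------------------------------------
  pp <- config$preprocess
  qc_rows <- list()
  kept_runs <- list(); kept_fd <- numeric(0); kept_ids <- character(0)
  for (i in seq_along(runs)) {
    fd <- compute_framewise_displacement(motions[[i]], pp$head_radius_mm)
    qc <- apply_exclusion_rule(motions[[i]], fd, runs[[i]]$subject_id,
                               pp$max_translation_mm, pp$max_rotation_deg,
                               pp$max_mean_fd_mm)
    qc_rows[[i]] <- data.frame(
      subject_id = qc$subject_id, included = qc$included,
      mean_fd = qc$mean_fd,
      max_abs_translation_mm = qc$max_abs_translation_mm,
      max_abs_rotation_deg = qc$max_abs_rotation_deg,
      reasons = paste(qc$reasons, collapse = "; "),
      stringsAsFactors = FALSE)
    if (!qc$included) next
    prep <- preprocess_run(runs[[i]], motions[[i]], pp$drop_volumes,
                           pp$low_hz, pp$high_hz, pp$use_friston24)
    if (length(prep$flat_voxels))
      stop("run ", runs[[i]]$subject_id, " has ",
           length(prep$flat_voxels), " zero-variance voxels after ",
           "preprocessing")
    kept_runs[[length(kept_runs) + 1L]] <- prep$run
    kept_fd <- c(kept_fd, fd$mean_fd)
    kept_ids <- c(kept_ids, runs[[i]]$subject_id)
  }
  qc_tbl <- do.call(rbind, qc_rows)
  write_tsv(qc_tbl, file.path(out_dir, "qc_report.tsv"))
  stage_log(log, "preprocess", "%d/%d subjects pass motion QC",
            length(kept_runs), length(runs))
  pheno <- pheno[match(kept_ids, pheno$subject_id), , drop = FALSE]
  if (anyNA(pheno$subject_id)) stop("phenotype rows missing for some runs")
  groups <- pheno$group
  if (!any(groups == "patient") || !any(groups == "control"))
    stop("empty group after motion QC exclusions")
  manifest$stages$preprocess <- list(
    n_in = length(runs), n_out = length(kept_runs),
    excluded = qc_tbl$subject_id[!qc_tbl$included])

  # -- mask ------------------------------------------------------------
  mk <- config$mask
  if (!is.null(mk$template) && is.character(mk$template))
    template <- read_mask(mk$template)
  if (mk$method == "truth") {
    if (is.null(template))
      stop("mask.method 'truth' requires a template/ground-truth mask")
    mask <- template
    stage_log(log, "mask", "using ground-truth mask (%d voxels)",
              mask$n_voxels)
  } else if (mk$method == "ica") {
    ctrl <- kept_runs[groups == "control"]
    der <- derive_network_mask(ctrl, template,
                               n_components = mk$n_components,
                               pca_k = mk$pca_k, seed = config$seed,
                               z_thresh = mk$z_thresh,
                               min_cluster_voxels = mk$min_cluster_voxels)
    mask <- der$mask
    stage_log(log, "mask",
              "ICA component %d (score %.3f) -> %d-voxel mask",
              der$selection$index, der$selection$score, mask$n_voxels)
  } else stop("unknown mask.method: ", mk$method)
  write_mask(mask, file.path(out_dir, "network_mask.nii"))
  manifest$stages$mask <- list(method = mk$method,
                               n_voxels = mask$n_voxels)

  # -- nh --------------------------------------------------------------
  nh_maps <- lapply(kept_runs, compute_nh_map, mask = mask)
  if (isTRUE(config$nh$standardize))
    nh_maps <- lapply(nh_maps, standardize_nh_map)
  stage_log(log, "nh", "computed %d NH maps (%s)", length(nh_maps),
            if (isTRUE(config$nh$standardize)) "standardized" else "raw")
  manifest$stages$nh <- list(n_maps = length(nh_maps),
                             standardized = isTRUE(config$nh$standardize))

  # -- compare ---------------------------------------------------------
  cmp <- config$compare
  design <- group_design(kept_ids, groups, pheno$age, kept_fd)
  clusters <- cluster_extent_inference(
    nh_maps, design, voxel_p = cmp$voxel_p, n_perm = cmp$n_perm,
    alpha = cmp$alpha, seed = config$seed,
    use_covariates = cmp$use_covariates,
    bonferroni_signs = cmp$bonferroni_signs)
  write_tsv(as.data.frame(clusters), file.path(out_dir, "clusters.tsv"))
  stage_log(log, "compare", "%d significant cluster(s)", nrow(clusters))
  manifest$stages$compare <- list(
    n_clusters = nrow(clusters),
    directions = clusters$direction, extents = clusters$extent)

  # -- correlate + classify -------------------------------------------
  if (nrow(clusters) > 0L) {
    features <- extract_region_means(nh_maps, clusters)
    write_tsv(features, file.path(out_dir, "region_features.tsv"))
    vars <- intersect(config$correlate$variables, names(pheno))
    corr <- correlate_regions_with_clinical(
      features, pheno, vars, group_filter = config$correlate$group,
      adjust = config$correlate$adjust)
    write_tsv(as.data.frame(corr), file.path(out_dir, "correlations.tsv"))
    stage_log(log, "correlate", "%d (region, variable) tests", nrow(corr))
    manifest$stages$correlate <- list(n_tests = nrow(corr))

    cls <- classify_all_regions(features, groups,
                                nested = isTRUE(config$classify$nested))
    write_tsv(cls, file.path(out_dir, "classification.tsv"))
    stage_log(log, "classify", "best region %s (accuracy %.2f%%)",
              cls$region[which.max(cls$accuracy)], max(cls$accuracy))
    manifest$stages$classify <- list(
      regions = cls$region, accuracy = cls$accuracy)
  } else {
    stage_log(log, "correlate", "skipped: no significant clusters")
    stage_log(log, "classify", "skipped: no significant clusters")
    manifest$stages$correlate <- list(n_tests = 0L)
    manifest$stages$classify <- list(regions = character(0))
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in%
                       c("manifest.json", "pipeline.log")]
  manifest$outputs <- as.list(md5_of(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
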