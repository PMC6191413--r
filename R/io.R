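#' Read and write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the grid's voxel size into
#' the NIfTI header.
#'
#' @param vol 3D numeric array.
#' @param grid a [volume_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a plain 3D array.
#' @export
write_volume <- function(vol, grid, path) {
  img <- RNifti::asNifti(array(vol, dim = grid$shape))
  RNifti::pixdim(img) <- rep(grid$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write a beta set as NIfTI volumes plus a JSON manifest
#'
#' One volume per (run, condition, stimulus) cell, named
#' `beta_run-<r>_<condition>_<stimulus>.nii.gz`, and a `manifest.json`
#' recording subject, grid and the cell-to-file map.
#'
#' @param betas a `beta_set`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_beta_set <- function(betas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dn <- dimnames(betas$beta)
  files <- list()
  for (r in dn[[2]]) for (cond in dn[[3]]) for (s in dn[[4]]) {
    fn <- sprintf("beta_run-%s_%s_%s.nii.gz", r, gsub(":", "+", cond), s)
    write_volume(array(betas$beta[, r, cond, s], betas$grid$shape),
                 betas$grid, file.path(dir, fn))
    files[[length(files) + 1]] <- list(run = r, condition = cond,
                                       stimulus = s, file = fn)
  }
  manifest <- list(subject_id = betas$subject_id,
                   shape = betas$grid$shape,
                   voxel_size_mm = betas$grid$voxel_size_mm,
                   volumes = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a beta set written by [write_beta_set()]
#'
#' @param dir directory containing `manifest.json` and the beta volumes.
#' @return a `beta_set` (with an all-true mask except where volumes are NA).
#' @export
read_beta_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  shape <- as.integer(manifest$shape)
  vols <- manifest$volumes
  runs <- unique(vols$run)
  conds <- unique(vols$condition)
  beta <- array(NA_real_, c(prod(shape), length(runs), length(conds), 2),
                dimnames = list(NULL, runs, conds, STIMULI))
  for (i in seq_len(nrow(vols)))
    beta[, vols$run[i], vols$condition[i], vols$stimulus[i]] <-
      as.vector(read_volume(file.path(dir, vols$file[i])))
  mask <- array(!apply(is.na(beta), 1, any), dim = shape)
  grid <- volume_grid(shape, manifest$voxel_size_mm, mask)
  new_beta_set(beta, grid, manifest$subject_id)
}

#' Serialise and restore a pipeline configuration as JSON
#'
#' The round trip is lossless for every analysis-relevant field (grids and
#' population specs are reconstructed exactly; the all-true default mask is
#' encoded compactly).
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- config
  x$grid <- list(shape = config$grid$shape,
                 voxel_size_mm = config$grid$voxel_size_mm,
                 mask_true = which(as.vector(config$grid$mask)))
  x$spec <- list(informative_region =
                   as.vector(t(config$spec$informative_region)),
                 preference = config$spec$preference,
                 baseline = config$spec$baseline,
                 amp_preferred = config$spec$amp_preferred,
                 amp_nonpreferred = config$spec$amp_nonpreferred,
                 gain = config$spec$gain,
                 hypothesis = config$spec$hypothesis,
                 noise_sd = config$spec$noise_sd)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- array(FALSE, dim = as.integer(x$grid$shape))
  mask[x$grid$mask_true] <- TRUE
  grid <- volume_grid(x$grid$shape, x$grid$voxel_size_mm, mask)
  ir <- if (length(x$spec$informative_region) > 0)
    matrix(x$spec$informative_region, ncol = 3, byrow = TRUE) else NULL
  spec <- population_spec(informative_region = ir,
                          preference = x$spec$preference,
                          baseline = x$spec$baseline,
                          amp_preferred = x$spec$amp_preferred,
                          amp_nonpreferred = x$spec$amp_nonpreferred,
                          gain = x$spec$gain,
                          hypothesis = x$spec$hypothesis,
                          noise_sd = x$spec$noise_sd)
  pipeline_config(n_subjects = x$n_subjects, n_runs = x$n_runs,
                  trials_per_session = x$trials_per_session, grid = grid,
                  spec = spec, mode = x$mode,
                  radius_voxels = x$radius_voxels, cost = x$cost,
                  smooth_fwhm_mm = x$smooth_fwhm_mm, height_p = x$height_p,
                  extent_fwe_p = x$extent_fwe_p, n_perm = x$n_perm,
                  connectivity = x$connectivity, task_split = x$task_split,
                  TR_s = x$TR_s, seed = x$seed,
                  output_dir = x$output_dir)
}

# Write the main artifacts of a pipeline run: events TSV, config JSON,
# accuracy maps and t map as NIfTI, cluster and cell tables as TSV.
write_pipeline_result <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events(do.call(rbind, result$design), file.path(dir, "events.tsv"))
  write_pipeline_config(result$config, file.path(dir, "config.json"))
  grid <- result$config$grid
  for (subj in names(result$maps))
    for (cond in names(result$maps[[subj]]))
      write_volume(result$maps[[subj]][[cond]]$data, grid,
                   file.path(dir, sprintf("accuracy_%s_%s.nii.gz",
                                          subj, cond)))
  write_volume(attr(result$rois, "t_map"), grid,
               file.path(dir, "group_t_no_move.nii.gz"))
  lab <- array(0, dim = grid$shape)
  for (i in seq_along(result$rois))
    lab[coords_to_index(result$rois[[i]]$voxels, grid$shape)] <- i
  write_volume(lab, grid, file.path(dir, "roi_labels.nii.gz"))
  write.table(cluster_table(result$rois), file.path(dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$accuracy_cells))
    write.table(result$accuracy_cells, file.path(dir, "accuracy_cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$anova))
    jsonlite::write_json(result$anova, file.path(dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(result$tuning_cells))
    write.table(result$tuning_cells, file.path(dir, "tuning_cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
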