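#' Write a cohort to disk
#'
#' Writes the sample metadata as TSV (`subject_id`, `run_id`, `site_id`,
#' `group`, `scale_1`, ...) and each run's series as a 4-D NIfTI volume
#' (`grid_dims` x time), one file per run, named
#' `<subject_id>_run<run_id>.nii.gz`. Voxels outside the mask are zero.
#'
#' @param cohort list with `samples` and `runs` ([generate_cohort()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the metadata file path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  readr::write_tsv(cohort$samples, meta_path)
  for (i in seq_along(cohort$runs)) {
    run <- cohort$runs[[i]]
    arr <- array(0, dim = c(run$grid_dims, ncol(run$series)))
    idx <- run$node_coords + 1L
    for (t in seq_len(ncol(run$series)))
      arr[cbind(idx, t)] <- run$series[, t]
    fn <- sprintf("%s_run%d.nii.gz", cohort$samples$subject_id[i],
                  cohort$samples$run_id[i])
    RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, fn))
  }
  mask_arr <- array(as.integer(cohort$runs[[1]]$mask),
                    dim = cohort$runs[[1]]$grid_dims)
  RNifti::writeNifti(RNifti::asNifti(mask_arr), file.path(dir, "mask.nii.gz"))
  invisible(meta_path)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]: reads the metadata TSV and one 4-D
#' NIfTI per run (plus `mask.nii.gz` when present; otherwise all voxels
#' are in-mask). This is also the entry point for real per-run 4-D NIfTI
#' data accompanied by a matching metadata table.
#'
#' @param dir directory holding `metadata.tsv` and the run volumes.
#' @return List with `samples` (tibble) and `runs` (list of `run_ts`).
#' @export
read_cohort <- function(dir) {
  samples <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                             show_col_types = FALSE)
  mask_file <- file.path(dir, "mask.nii.gz")
  mask <- NULL
  runs <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    fn <- sprintf("%s_run%d.nii.gz", samples$subject_id[i], samples$run_id[i])
    arr <- as.array(RNifti::readNifti(file.path(dir, fn)))
    grid_dims <- dim(arr)[1:3]
    if (is.null(mask)) {
      mask <- if (file.exists(mask_file)) {
        array(as.array(RNifti::readNifti(mask_file)) != 0, dim = grid_dims)
      } else array(TRUE, dim = grid_dims)
    }
    coords <- which(mask, arr.ind = TRUE) - 1L
    colnames(coords) <- c("x", "y", "z")
    # order voxels exactly as voxel_grid(): x fastest (column-major)
    ord <- order(coords[, 3], coords[, 2], coords[, 1])
    coords <- coords[ord, , drop = FALSE]
    tt <- dim(arr)[4]
    series <- matrix(0, nrow(coords), tt)
    idx <- coords + 1L
    for (t in seq_len(tt)) series[, t] <- arr[cbind(idx, t)]
    runs[[i]] <- new_run_ts(series, coords, mask, grid_dims)
  }
  list(samples = samples, runs = runs)
}

#' Write a voxel statistic map as 3-D NIfTI
#'
#' Places per-voxel statistics (e.g. t or `-log10(p)` for degree
#' features) back on the grid; out-of-mask voxels are zero.
#'
#' @param values numeric vector, one per voxel feature.
#' @param descriptors descriptor tibble with `x`, `y`, `z` (0-based).
#' @param grid_dims integer triple.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_stat_map <- function(values, descriptors, grid_dims, path) {
  arr <- array(0, dim = grid_dims)
  arr[cbind(descriptors$x, descriptors$y, descriptors$z) + 1L] <- values
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
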