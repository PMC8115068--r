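#' Write a simulated scan to disk
#'
#' Emits the 4D dynamic volume as float32 NIfTI-1, the mask as int16
#' NIfTI-1 with a sidecar label-map text file, the frame schedule as CSV,
#' and (when ground truth is attached) a per-subject truth CSV.
#'
#' @param scan A [subject_scan()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths (invisible).
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "subject_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, paste0(scan$subject_id, "_", scan$session))
  paths <- c(image = paste0(stem, "_pet.nii"),
             mask = file.path(dir, "mask.nii"),
             labels = file.path(dir, "mask_labels.txt"),
             frames = paste0(stem, "_frames.csv"))
  write_nifti(scan$data, paths[["image"]],
              voxel_size_mm = scan$mask$voxel_size_mm)
  if (!file.exists(paths[["mask"]]))
    write_nifti(scan$mask$data, paths[["mask"]],
                voxel_size_mm = scan$mask$voxel_size_mm, datatype = "int16")
  labs <- scan$mask$labels
  writeLines(sprintf("%d %s", labs, names(labs)), paths[["labels"]])
  write_frame_schedule(scan$schedule, paths[["frames"]])
  if (!is.null(scan$truth_ki)) {
    paths[["truth"]] <- paste0(stem, "_truth.csv")
    idx <- mask_region_idx(scan$mask, "striatum")
    utils::write.csv(
      data.frame(voxel_index = idx, label = scan$mask$data[idx],
                 ki_true_per_min = scan$truth_ki),
      paths[["truth"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Assemble a scan from files on disk
#'
#' @param path_image 4D NIfTI-1 dynamic volume.
#' @param path_frames Frame-schedule CSV (`start_s,duration_s`).
#' @param path_mask Integer NIfTI-1 labelled mask.
#' @param subject_id,group,session Metadata to stamp on the scan.
#' @return A [subject_scan()] (without ground truth).
#' @export
read_dynamic_scan <- function(path_image, path_frames, path_mask,
                              subject_id = "unknown", group = "unknown",
                              session = "test") {
  img <- read_nifti(path_image)
  sched <- read_frame_schedule(path_frames)
  mvol <- read_nifti(path_mask)
  if (length(dim(img)) != 4L)
    stop("expected a 4D image, found ", length(dim(img)), "D")
  if (dim(img)[4L] != nframes(sched))
    stop(sprintf("frame-count mismatch: image has %d frames, schedule %d",
                 dim(img)[4L], nframes(sched)))
  if (!all(dim(img)[1:3] == dim(mvol)))
    stop(sprintf("image grid [%s] does not match mask [%s]",
                 paste(dim(img)[1:3], collapse = "x"),
                 paste(dim(mvol), collapse = "x")))
  labs <- region_labels()
  present <- sort(unique(as.integer(mvol)))
  if (!labs[["cerebellum"]] %in% present)
    stop("mask is missing the cerebellum label (4); present labels: ",
         paste(present, collapse = ", "))
  mask <- structure(list(data = array(as.integer(mvol), dim(mvol)),
                         labels = labs,
                         voxel_size_mm = attr(mvol, "voxel_size_mm")),
                    class = "mask_volume")
  subject_scan(subject_id, group, session, img, sched, mask)
}

#' Write a cohort manifest CSV
#'
#' @param scans List of [subject_scan()]s already written with
#'   [write_scan()].
#' @param dir Directory that holds the scan files.
#' @return Path of the manifest (invisible).
#' @export
write_cohort_manifest <- function(scans, dir) {
  rows <- do.call(rbind, lapply(scans, function(s) {
    stem <- paste0(s$subject_id, "_", s$session)
    data.frame(subject_id = s$subject_id, group = s$group,
               session = s$session,
               scan_path = paste0(stem, "_pet.nii"),
               truth_path = if (is.null(s$truth_ki)) ""
                            else paste0(stem, "_truth.csv"))
  }))
  path <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
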