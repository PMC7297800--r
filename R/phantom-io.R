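write_nifti_vol <- function(x, spacing, file) {
  img <- RNifti::asNifti(x * 1)  # logical -> numeric
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write a phantom subject to disk as NIfTI volumes plus a JSON sidecar
#'
#' One NIfTI file per modality (`<prefix>_<modality>.nii.gz`), the CE,
#' progression and brain masks, and a `<prefix>_truth.json` sidecar holding
#' the ground-truth geometry and generation seeds.
#'
#' @param subject A [generate_subject()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `sub<index>`.
#' @return Invisibly, the named character vector of files written.
#' @export
write_subject <- function(subject, dir,
                          prefix = sprintf("sub%03d", subject$subject_index)) {
  stopifnot(inherits(subject, "phantom_subject"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  for (m in names(subject$volumes)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, m))
    write_nifti_vol(subject$volumes[[m]], subject$spacing, f)
    files[m] <- f
  }
  for (m in c("ce_mask", "progression_mask", "brain_mask")) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, m))
    write_nifti_vol(subject[[m]], subject$spacing, f)
    files[m] <- f
  }
  side <- file.path(dir, sprintf("%s_truth.json", prefix))
  jsonlite::write_json(list(subject_index = subject$subject_index,
                            seed = subject$seed,
                            spacing_mm = subject$spacing,
                            geometry = subject$geometry),
                       side, auto_unbox = TRUE, digits = NA)
  files["truth"] <- side
  invisible(files)
}

#' Read a phantom subject back from [write_subject()] output
#'
#' @param dir Directory holding the files.
#' @param prefix The file-name prefix used when writing.
#' @return A `phantom_subject` object (volumes, masks, spacing, geometry).
#' @export
read_subject <- function(dir, prefix) {
  vols <- lapply(modalities(), function(m) {
    arr <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", prefix, m)))
    array(as.numeric(arr), dim = dim(arr))
  })
  names(vols) <- modalities()
  msk <- lapply(c("ce_mask", "progression_mask", "brain_mask"), function(m) {
    arr <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", prefix, m)))
    array(as.numeric(arr) != 0, dim = dim(arr))
  })
  truth <- jsonlite::read_json(file.path(dir, sprintf("%s_truth.json", prefix)),
                               simplifyVector = TRUE)
  structure(list(volumes = vols, spacing = as.numeric(truth$spacing_mm),
                 ce_mask = msk[[1]], progression_mask = msk[[2]],
                 brain_mask = msk[[3]], truth_labels = msk[[2]],
                 geometry = truth$geometry,
                 subject_index = as.integer(truth$subject_index),
                 seed = as.integer(truth$seed)),
            class = "phantom_subject")
}

#' Write a phantom cohort: per-subject files plus a manifest CSV
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame (one row per subject).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    prefix <- sprintf("sub%03d", s$subject_index)
    write_subject(s, dir, prefix)
    data.frame(subject = s$subject_index, prefix = prefix,
               ce_voxels = sum(s$ce_mask),
               progression_voxels = sum(s$progression_mask),
               core_radius_mm = s$geometry$core_radius_mm)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
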