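#' Spacing-aware Euclidean distance transform of a binary mask
#'
#' Distance (in mm) from every voxel to the nearest voxel of `mask`,
#' honouring anisotropic voxel spacing. Voxels inside the mask have
#' distance 0. Uses an exact separable lower-envelope algorithm.
#'
#' @param mask Binary 3D array.
#' @param spacing Numeric vector of 3 voxel spacings in mm.
#' @return Numeric 3D array of distances in mm.
#' @export
mask_edt <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_mask(mask)
  stopifnot(length(dim(mask)) == 3, length(spacing) == 3, all(spacing > 0))
  if (!any(mask)) stop("mask is empty: distances are undefined")
  cpp_edt(mask, dim(mask), as.numeric(spacing))
}

#' Progression ROI by subtraction of the contrast-enhancing lesion
#'
#' The peritumoral progression region is the progression lesion (already
#' co-registered to the preoperative grid) minus the preoperative
#' contrast-enhancing lesion: the part of the later recurrence that lay in
#' non-enhancing tissue at surgery.
#'
#' @param progression_mask,ce_mask Binary arrays on the same grid.
#' @return Logical array: `progression_mask & !ce_mask`.
#' @export
progression_roi <- function(progression_mask, ce_mask) {
  progression_mask <- as_mask(progression_mask)
  ce_mask <- as_mask(ce_mask)
  check_same_dim(progression_mask, ce_mask)
  progression_mask & !ce_mask
}

#' Peritumoral non-progression shells at increasing distance from the CE lesion
#'
#' Band *k* contains the brain voxels whose Euclidean distance (mm) to the
#' CE lesion lies in the half-open interval (d\[k-1\], d\[k\]\] (with d\[0\] = 0),
#' excluding the CE lesion itself and the progression ROI. With the default
#' distances this yields the 5, 10, 15 and 20 mm non-progression bands.
#'
#' @param ce_mask Binary CE lesion mask (must be non-empty).
#' @param progression_roi Binary progression ROI to exclude, or `NULL`.
#' @param brain_mask Binary brain mask.
#' @param distances_mm Strictly increasing positive outer band edges (mm).
#' @param spacing Voxel spacing in mm (length 3).
#' @return Named list of logical masks, one per band, named by the outer
#'   edge (`"5"`, `"10"`, ...); attribute `distances_mm` records the edges.
#' @export
shell_masks <- function(ce_mask, progression_roi = NULL, brain_mask,
                        distances_mm = c(5, 10, 15, 20), spacing = c(1, 1, 1)) {
  ce_mask <- as_mask(ce_mask)
  brain_mask <- as_mask(brain_mask)
  check_same_dim(ce_mask, brain_mask)
  if (!any(ce_mask)) stop("CE mask is empty")
  stopifnot(length(distances_mm) >= 1, all(distances_mm > 0),
            all(diff(distances_mm) > 0))
  excl <- ce_mask
  if (!is.null(progression_roi)) {
    progression_roi <- as_mask(progression_roi)
    check_same_dim(ce_mask, progression_roi)
    excl <- excl | progression_roi
  }
  d <- mask_edt(ce_mask, spacing)
  edges <- c(0, distances_mm)
  shells <- lapply(seq_along(distances_mm), function(k) {
    d > edges[k] & d <= edges[k + 1] & brain_mask & !excl
  })
  names(shells) <- as.character(distances_mm)
  attr(shells, "distances_mm") <- distances_mm
  shells
}

#' Contralateral normal-appearing white matter (NAWM) control mask
#'
#' Mirrors the abnormal region (CE lesion, progression ROI and the
#' peritumoral envelope out to `envelope_mm`) across the midsagittal plane
#' of the grid, intersects with the brain mask, and removes any voxel of
#' the ipsilateral abnormal masks. Intended for grids whose brain mask is
#' roughly symmetric about that plane.
#'
#' @param ce_mask,progression_mask,brain_mask Binary arrays, same grid.
#' @param spacing Voxel spacing in mm.
#' @param midline_axis Axis (1, 2 or 3) perpendicular to the midsagittal
#'   plane; the grid is flipped along it.
#' @param envelope_mm Peritumoral envelope distance mirrored along with the
#'   lesion, default 20 mm.
#' @return Logical NAWM mask. Warns if part of the mirrored region falls
#'   outside the brain (the intersection is returned).
#' @export
nawm_mask <- function(ce_mask, progression_mask, brain_mask,
                      spacing = c(1, 1, 1), midline_axis = 1,
                      envelope_mm = 20) {
  ce_mask <- as_mask(ce_mask)
  progression_mask <- as_mask(progression_mask)
  brain_mask <- as_mask(brain_mask)
  check_same_dim(ce_mask, progression_mask, brain_mask)
  if (!any(ce_mask)) stop("CE mask is empty")
  stopifnot(midline_axis %in% 1:3)
  envelope <- mask_edt(ce_mask, spacing) <= envelope_mm
  abnormal <- ce_mask | progression_mask
  region <- abnormal | (envelope & brain_mask)
  idx <- rep(list(quote(expr = )), 3)
  idx[[midline_axis]] <- rev(seq_len(dim(region)[midline_axis]))
  mirrored <- do.call(`[`, c(list(region), idx))
  if (any(mirrored & !brain_mask))
    warning("mirrored region extends outside the brain mask; returning the intersection")
  mirrored & brain_mask & !abnormal
}

#' Build the full ROI set of a subject
#'
#' Convenience constructor assembling the study's regions on one grid:
#' CE lesion, progression ROI (progression minus CE), the non-progression
#' shells, the contralateral NAWM control, and the brain mask.
#'
#' @param subject A `phantom_subject`, or a list with elements `ce_mask`,
#'   `progression_mask`, `brain_mask` and `spacing`.
#' @param distances_mm Outer edges of the non-progression bands (mm).
#' @param midline_axis Axis perpendicular to the midsagittal plane.
#' @return An object of class `roi_set`: list with `ce`, `progression`,
#'   `shells`, `nawm`, `brain`, `spacing`.
#' @export
roi_set <- function(subject, distances_mm = c(5, 10, 15, 20), midline_axis = 1) {
  prog <- progression_roi(subject$progression_mask, subject$ce_mask)
  shells <- shell_masks(subject$ce_mask, prog, subject$brain_mask,
                        distances_mm, subject$spacing)
  nawm <- nawm_mask(subject$ce_mask, subject$progression_mask,
                    subject$brain_mask, subject$spacing, midline_axis,
                    envelope_mm = max(distances_mm))
  structure(list(ce = subject$ce_mask, progression = prog, shells = shells,
                 nawm = nawm, brain = subject$brain_mask,
                 spacing = subject$spacing),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:\n")
  cat(sprintf("  CE %d, progression %d, NAWM %d, brain %d voxels\n",
              sum(x$ce), sum(x$progression), sum(x$nawm), sum(x$brain)))
  for (nm in names(x$shells))
    cat(sprintf("  NP-%s band: %d voxels\n", nm, sum(x$shells[[nm]])))
  invisible(x)
}

#' Write an ROI set as NIfTI masks plus a labelled band volume
#'
#' The four bands are serialized as one integer volume (0 = none, 1..K =
#' bands in increasing distance) with a JSON legend.
#'
#' @param rs An [roi_set()] object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the files written.
#' @export
write_roi_set <- function(rs, dir, prefix = "roi") {
  stopifnot(inherits(rs, "roi_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  for (nm in c("ce", "progression", "nawm", "brain")) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    write_nifti_vol(rs[[nm]], rs$spacing, f)
    files[nm] <- f
  }
  bands <- array(0L, dim = dim(rs$ce))
  for (k in seq_along(rs$shells)) bands[rs$shells[[k]]] <- k
  f <- file.path(dir, sprintf("%s_bands.nii.gz", prefix))
  write_nifti_vol(bands, rs$spacing, f)
  files["bands"] <- f
  legend <- file.path(dir, sprintf("%s_bands.json", prefix))
  jsonlite::write_json(list(labels = seq_along(rs$shells),
                            outer_edge_mm = as.numeric(names(rs$shells))),
                       legend, auto_unbox = FALSE, digits = NA)
  files["legend"] <- legend
  invisible(files)
}
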