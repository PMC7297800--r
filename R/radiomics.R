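first_order_names <- function() c(
  "mean", "sd", "median", "min", "max", "variance", "skewness", "kurtosis",
  "energy", "entropy", "uniformity", "rms", "mean_gray_level")

glcm_names <- function() c(
  "autocorrelation", "contrast", "correlation_m", "correlation_p",
  "cluster_prominence", "cluster_shade", "dissimilarity", "energy",
  "entropy", "homogeneity_m", "homogeneity_p", "sum_of_squares",
  "sum_average", "sum_variance", "sum_entropy", "difference_variance",
  "difference_entropy", "imc1", "imc2", "idn", "maximum_probability")

glrlm_names <- function() c(
  "sre", "lre", "gln", "run_percentage", "rln", "lgle", "hgle", "rlnn")

#' The 294-entry voxel-wise radiomics feature registry
#'
#' Thirteen first-order statistics plus 29 second-order texture features
#' (21 co-occurrence, 8 run-length) per modality, over the seven modalities:
#' 91 first-order and 203 second-order entries, 294 in total. Three of the
#' per-modality second-order entries (GLCM `sum_average` and
#' `maximum_probability`, GLRLM `rlnn`) reconcile the per-modality count to
#' 29 and are flagged `reconciliation = TRUE`.
#'
#' @param mods Modalities to include, default [modalities()].
#' @return Data frame with columns `name`, `modality`, `family`
#'   (`first_order` / `glcm` / `glrlm`), `base` and `reconciliation`, in
#'   the exact column order of [voxelwise_feature_table()].
#' @examples
#' table(feature_registry()$family)
#' @export
feature_registry <- function(mods = modalities()) {
  rec_glcm <- glcm_names() %in% c("sum_average", "maximum_probability")
  rec_glrlm <- glrlm_names() %in% "rlnn"
  one <- function(m) data.frame(
    name = paste(m, c(paste0("fo_", first_order_names()),
                      paste0("glcm_", glcm_names()),
                      paste0("glrlm_", glrlm_names())), sep = "_"),
    modality = m,
    family = rep(c("first_order", "glcm", "glrlm"),
                 c(length(first_order_names()), length(glcm_names()),
                   length(glrlm_names()))),
    base = c(first_order_names(), glcm_names(), glrlm_names()),
    reconciliation = c(rep(FALSE, length(first_order_names())), rec_glcm,
                       rec_glrlm),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(mods, one))
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Export the feature registry as JSON
#' @param file Output path.
#' @param mods Modalities to include.
#' @return Invisibly, `file`.
#' @export
write_feature_registry <- function(file, mods = modalities()) {
  jsonlite::write_json(feature_registry(mods), file, auto_unbox = FALSE,
                       digits = NA)
  invisible(file)
}

#' The 13 unique 3D offsets at Chebyshev distance 1
#'
#' Standard direction set for 3D texture matrices: one representative per
#' axis-symmetric pair of the 26-neighbourhood.
#'
#' @return Integer matrix, 13 rows x 3 columns.
#' @export
glcm_offsets_3d <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,  0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

coerce_patch <- function(patch) {
  if (is.null(dim(patch))) dim(patch) <- c(length(patch), 1L, 1L)
  d <- dim(patch)
  if (length(d) == 2) dim(patch) <- c(d, 1L)
  if (length(dim(patch)) != 3) stop("patch must be a 1D, 2D or 3D array")
  patch
}

#' Quantize a patch to gray levels by linear min-max binning
#'
#' Bin edges divide the patch's \[min, max\] range into `n_levels` equal
#' bins; the maximum falls in the top bin and a constant patch maps
#' entirely to level 1. Adding a constant to the patch leaves the result
#' unchanged.
#'
#' @param patch Numeric array of raw intensities.
#' @param n_levels Number of gray levels (>= 1), default 32.
#' @return Integer array of levels in `1..n_levels`, same shape.
#' @export
quantize <- function(patch, n_levels = 32) {
  stopifnot(n_levels >= 1)
  patch <- coerce_patch(patch)
  cpp_quantize(patch, as.integer(n_levels))
}

#' First-order (histogram) features of a patch
#'
#' The 13 statistics: mean, standard deviation, median, minimum, maximum,
#' variance, skewness, kurtosis, energy (sum of squares), entropy (bits,
#' over the quantized histogram), uniformity, root mean square, and mean
#' gray level (mean of the quantized levels). Moments use the population
#' (divide-by-n) convention; skewness and kurtosis of a zero-variance patch
#' are defined as 0.
#'
#' @param patch Numeric array of raw intensities.
#' @param n_levels Gray levels for the entropy/uniformity histogram.
#' @return Named numeric vector of length 13.
#' @export
first_order_features <- function(patch, n_levels = 32) {
  patch <- coerce_patch(patch)
  if (length(patch) == 0) stop("patch is empty")
  out <- cpp_first_order(patch, as.integer(n_levels))
  names(out) <- first_order_names()
  out
}

#' Gray level co-occurrence matrix of a quantized patch
#'
#' Counts pairs of levels at each integer voxel offset, symmetrizes, sums
#' over the offsets and normalizes to total 1. If no offset fits inside the
#' patch the all-zero matrix is returned with attribute `empty = TRUE`.
#'
#' @param qpatch Integer array of levels in `1..n_levels` (see [quantize()]).
#' @param n_levels Number of gray levels.
#' @param offsets Integer matrix of offsets (rows), default the 13-direction
#'   3D set of [glcm_offsets_3d()].
#' @return `n_levels` x `n_levels` numeric matrix summing to 1 (or 0).
#' @export
glcm_matrix <- function(qpatch, n_levels = max(qpatch), offsets = glcm_offsets_3d()) {
  qpatch <- coerce_patch(qpatch)
  stopifnot(is.numeric(offsets) || is.integer(offsets), ncol(offsets) == 3,
            all(rowSums(offsets != 0) > 0))
  P <- cpp_glcm(as.integer(qpatch), dim(qpatch), as.integer(n_levels),
                matrix(as.integer(offsets), ncol = 3))
  if (sum(P) == 0) attr(P, "empty") <- TRUE
  P
}

#' Haralick-family features of a co-occurrence matrix
#'
#' The 21 statistics of the registry's GLCM block: autocorrelation,
#' contrast, the two correlation conventions, cluster prominence/shade,
#' dissimilarity, energy, entropy, the two homogeneity conventions
#' (weights `1/(1+|i-j|)` and `1/(1+(i-j)^2)`), sum of squares (variance),
#' sum average, sum variance, sum entropy, difference variance, difference
#' entropy, the two information measures of correlation, inverse difference
#' normalized, and maximum probability. Entropies are in bits with
#' `0 log 0 = 0`; correlations of a zero-variance marginal are defined as 0.
#'
#' @param P Normalized symmetric co-occurrence matrix from [glcm_matrix()].
#' @return Named numeric vector of length 21.
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (sum(P) > 0 && abs(sum(P) - 1) > 1e-8)
    stop("co-occurrence matrix must be normalized to sum 1")
  out <- cpp_glcm_features(P)
  names(out) <- glcm_names()
  out
}

#' Gray level run length matrix of a quantized patch
#'
#' Counts maximal runs of identical levels along each direction, summed
#' over the configured directions. Entry (g, l) is the number of runs of
#' level g and length l; per direction the lengths weighted by counts sum
#' to the patch voxel count.
#'
#' @param qpatch Integer array of levels in `1..n_levels`.
#' @param n_levels Number of gray levels.
#' @param directions Integer matrix of directions, default
#'   [glcm_offsets_3d()].
#' @return `n_levels` x `L` numeric count matrix, `L` the longest possible
#'   run; attributes `n_voxels` and `n_directions` carry the normalizers.
#' @export
glrlm_matrix <- function(qpatch, n_levels = max(qpatch),
                         directions = glcm_offsets_3d()) {
  qpatch <- coerce_patch(qpatch)
  R <- cpp_glrlm(as.integer(qpatch), dim(qpatch), as.integer(n_levels),
                 matrix(as.integer(directions), ncol = 3))
  attr(R, "n_voxels") <- length(qpatch)
  attr(R, "n_directions") <- nrow(directions)
  R
}

#' Run-length features of a run length matrix
#'
#' The 8 statistics of the registry's GLRLM block: short/long run emphasis,
#' gray level non-uniformity, run percentage, run length non-uniformity,
#' low/high gray level run emphasis, and run length non-uniformity
#' normalized.
#'
#' @param R Run length matrix from [glrlm_matrix()].
#' @param n_voxels Patch voxel count (defaults to the attribute set by
#'   [glrlm_matrix()]).
#' @param n_directions Number of directions summed (attribute default).
#' @return Named numeric vector of length 8.
#' @export
glrlm_features <- function(R, n_voxels = attr(R, "n_voxels"),
                           n_directions = attr(R, "n_directions")) {
  stopifnot(is.matrix(R))
  if (sum(R) == 0) stop("run length matrix has no runs")
  if (is.null(n_voxels) || is.null(n_directions))
    stop("n_voxels and n_directions are required")
  out <- cpp_glrlm_features(R, as.numeric(n_voxels), as.integer(n_directions))
  names(out) <- glrlm_names()
  out
}

#' Voxel-wise 294-feature radiomics table
#'
#' For every voxel of `mask`, extracts the cubic neighbourhood of side
#' `window` (clipped at the volume edge) from each of the seven modalities
#' and computes the full registry: 13 first-order + 21 GLCM + 8 GLRLM
#' features per modality (294 columns, ordered as [feature_registry()]).
#' Texture features use per-patch min-max quantization to `n_levels` gray
#' levels and the 13-direction 3D offset set.
#'
#' @param volumes Named list of the seven modality arrays (names must cover
#'   [modalities()]), all on one grid.
#' @param mask Binary array of target voxels (non-empty).
#' @param window Odd cubic window side in voxels, default 5.
#' @param n_levels Gray levels for quantization, default 32.
#' @param labels Optional binary array or per-voxel vector: 1 = progression,
#'   0 = non-progression; stored in column `label`.
#' @param subject_id Optional scalar stored in column `subject`.
#' @return Data frame: `subject` (if given), voxel coordinates `x`, `y`,
#'   `z` (1-based), `label` (if given), then the 294 feature columns.
#' @export
voxelwise_feature_table <- function(volumes, mask, window = 5, n_levels = 32,
                                    labels = NULL, subject_id = NULL) {
  stopifnot(window %% 2 == 1, window >= 1, n_levels >= 1)
  miss <- setdiff(modalities(), names(volumes))
  if (length(miss) > 0)
    stop("missing modalities: ", paste(miss, collapse = ", "))
  volumes <- volumes[modalities()]
  mask <- as_mask(mask)
  do.call(check_same_dim, c(volumes, list(mask)))
  idx <- which(mask)
  if (length(idx) == 0) stop("mask selects no voxels")
  dm <- dim(mask)
  feats <- cpp_voxelwise_features(volumes, dm, as.numeric(idx),
                                  as.integer(window), as.integer(n_levels))
  colnames(feats) <- feature_registry()$name
  coords <- arrayInd(idx, dm)
  out <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  if (!is.null(subject_id)) out <- cbind(subject = subject_id, out)
  if (!is.null(labels)) {
    lab <- if (length(labels) == prod(dm)) as.integer(labels[idx] != 0)
           else as.integer(labels != 0)
    if (length(lab) != length(idx))
      stop("labels must cover the grid or the mask voxels")
    out$label <- lab
  }
  cbind(out, as.data.frame(feats))
}

#' Feature columns of a voxel-wise table
#'
#' @param table A [voxelwise_feature_table()] result.
#' @return Numeric matrix of the 294 feature columns, in registry order.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_registry()$name, drop = FALSE])
}

#' Labelled peritumoral feature table of one subject
#'
#' Builds the subject's ROI set, pools the progression ROI (label 1) with
#' the non-progression shells (label 0) into the peritumoral mask, and
#' extracts the 294-feature table there. `max_voxels` optionally subsamples
#' the mask voxels (uniformly, seeded) to bound cost.
#'
#' @param subject A `phantom_subject` (or compatible list).
#' @param window,n_levels Passed to [voxelwise_feature_table()].
#' @param distances_mm Non-progression band edges, default 5/10/15/20 mm.
#' @param max_voxels Optional cap on the number of rows.
#' @param seed Seed for the subsample draw.
#' @return A [voxelwise_feature_table()] data frame with `subject` and
#'   `label` columns.
#' @export
subject_feature_table <- function(subject, window = 5, n_levels = 32,
                                  distances_mm = c(5, 10, 15, 20),
                                  max_voxels = NULL, seed = 1) {
  rs <- roi_set(subject, distances_mm)
  nonprog <- Reduce(`|`, rs$shells)
  mask <- rs$progression | nonprog
  if (!is.null(max_voxels) && sum(mask) > max_voxels) {
    idx <- which(mask)
    keep <- with_seed(derive_seed(seed, subject$subject_index),
                      sample(idx, max_voxels))
    mask <- array(FALSE, dim = dim(mask))
    mask[keep] <- TRUE
  }
  labels <- array(0L, dim = dim(mask))
  labels[rs$progression] <- 1L
  voxelwise_feature_table(subject$volumes, mask, window, n_levels,
                          labels = labels, subject_id = subject$subject_index)
}

#' Peritumoral feature tables for a whole cohort
#'
#' @param cohort A `phantom_cohort`.
#' @inheritParams subject_feature_table
#' @return One stacked data frame (rows from all subjects).
#' @export
cohort_feature_table <- function(cohort, window = 5, n_levels = 32,
                                 distances_mm = c(5, 10, 15, 20),
                                 max_voxels = NULL, seed = 1) {
  do.call(rbind, lapply(cohort, subject_feature_table, window = window,
                        n_levels = n_levels, distances_mm = distances_mm,
                        max_voxels = max_voxels, seed = seed))
}

#' Write a feature table as CSV (header row = registry names)
#' @param table A [voxelwise_feature_table()] result.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_feature_table <- function(table, file) {
  write.csv(table, file, row.names = FALSE)
  invisible(file)
}
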