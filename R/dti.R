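#' Isotropic/anisotropic (p/q) decomposition of diffusion-tensor eigenvalues
#'
#' Decomposes an eigenvalue triple \eqn{(\lambda_1,\lambda_2,\lambda_3)} of
#' the diffusion tensor into the norm of its isotropic component
#' \eqn{p = \sqrt{3}\,MD} and the norm of its anisotropic (deviatoric)
#' component \eqn{q = \sqrt{\sum_i (\lambda_i - MD)^2}}, where
#' \eqn{MD = (\lambda_1+\lambda_2+\lambda_3)/3} is the mean diffusivity.
#' Fractional anisotropy is \eqn{FA = \sqrt{3/2}\, q / \sqrt{\sum_i \lambda_i^2}}.
#' The two components are orthogonal: \eqn{p^2 + q^2 = \sum_i \lambda_i^2}.
#'
#' @param l1,l2,l3 Numeric vectors (or arrays of common shape) of
#'   eigenvalues, typically in mm^2/s. Must be finite and non-negative;
#'   eigenvalue ordering is irrelevant.
#' @return A list with components `p`, `q`, `fa`, `md`, each shaped like the
#'   input. `fa` lies in \[0, 1\]; an all-zero triple has no defined FA and
#'   is an error.
#' @examples
#' decompose_pq(1.7e-3, 0.4e-3, 0.4e-3)
#' @export
decompose_pq <- function(l1, l2, l3) {
  if (length(l1) != length(l2) || length(l1) != length(l3))
    stop("eigenvalue inputs must have equal length")
  if (!all(is.finite(l1), is.finite(l2), is.finite(l3)))
    stop("eigenvalues must be finite")
  if (any(l1 < 0) || any(l2 < 0) || any(l3 < 0))
    stop("negative eigenvalues are not admissible diffusivities")
  norm2 <- l1^2 + l2^2 + l3^2
  if (any(norm2 == 0))
    stop("all-zero eigenvalue triple: FA is undefined")
  md <- (l1 + l2 + l3) / 3
  p <- sqrt(3) * md
  q <- sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2)
  fa <- sqrt(3 / 2) * q / sqrt(norm2)
  fa <- pmin(pmax(fa, 0), 1)  # guard rounding at the anisotropic limit
  shape <- dim(l1)
  out <- list(p = p, q = q, fa = fa, md = md)
  if (!is.null(shape)) out <- lapply(out, function(x) { dim(x) <- shape; x })
  out
}

#' Voxel-wise p/q decomposition of eigenvalue volumes, NIfTI in/out
#'
#' Reads three co-registered eigenvalue NIfTI volumes, applies
#' [decompose_pq()] inside `mask` (outside voxels are written as 0), and
#' writes four NIfTI maps: p, q, FA and MD.
#'
#' @param files Character vector of 3 NIfTI paths (one per eigenvalue).
#' @param outdir Output directory.
#' @param mask Optional binary array; defaults to voxels where not all three
#'   eigenvalues are zero.
#' @param prefix Output file prefix, default `"dti"`.
#' @return Invisibly, named vector of the four files written.
#' @export
dti_decompose_nifti <- function(files, outdir, mask = NULL, prefix = "dti") {
  stopifnot(length(files) == 3)
  imgs <- lapply(files, RNifti::readNifti)
  spacing <- RNifti::pixdim(imgs[[1]])
  arrs <- lapply(imgs, function(x) array(as.numeric(x), dim = dim(x)))
  check_same_dim(arrs[[1]], arrs[[2]], arrs[[3]])
  if (is.null(mask))
    mask <- (arrs[[1]]^2 + arrs[[2]]^2 + arrs[[3]]^2) > 0
  mask <- as_mask(mask)
  idx <- which(mask)
  if (length(idx) == 0) stop("mask selects no voxels")
  dec <- decompose_pq(arrs[[1]][idx], arrs[[2]][idx], arrs[[3]][idx])
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files_out <- c()
  for (nm in c("p", "q", "fa", "md")) {
    vol <- array(0, dim = dim(mask))
    vol[idx] <- dec[[nm]]
    f <- file.path(outdir, sprintf("%s_%s.nii.gz", prefix, nm))
    write_nifti_vol(vol, spacing, f)
    files_out[nm] <- f
  }
  invisible(files_out)
}
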