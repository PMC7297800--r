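#' Modalities of the multimodal MR stack
#'
#' The seven co-registered scalar maps the pipeline operates on:
#' post-contrast T1 (T1C), FLAIR, apparent diffusion coefficient (ADC),
#' fractional anisotropy (FA), the isotropic (DTIp) and anisotropic (DTIq)
#' components of the diffusion tensor, and relative cerebral blood volume
#' (rCBV).
#'
#' @return Character vector of the seven modality names, in canonical order.
#' @export
modalities <- function() c("T1C", "FLAIR", "ADC", "FA", "DTIp", "DTIq", "rCBV")

#' Default per-modality effect table for the synthetic phantom
#'
#' Encodes the direction of the progression-vs-non-progression intensity
#' contrast for each modality: FLAIR, T1C and rCBV are elevated in tissue
#' that later progresses, ADC, DTI-p and FA are depressed, and DTI-q shows
#' no group difference. Baselines are arbitrary units on deliberately
#' different scales per modality; the progression shift defaults to 0.8
#' noise standard deviations in the appropriate direction.
#'
#' @param effect_size Magnitude of the progression shift, in units of the
#'   per-modality noise standard deviation. Default 0.8.
#' @return A data frame with columns `modality`, `baseline`, `shift`,
#'   `noise_sd` (one row per modality).
#' @examples
#' default_effect_table()
#' @export
default_effect_table <- function(effect_size = 0.8) {
  stopifnot(is.numeric(effect_size), length(effect_size) == 1, effect_size >= 0)
  baseline <- c(T1C = 120, FLAIR = 110, ADC = 1.1, FA = 0.35,
                DTIp = 1.9, DTIq = 1.1, rCBV = 1.5)
  noise_sd <- c(T1C = 10, FLAIR = 10, ADC = 0.10, FA = 0.05,
                DTIp = 0.15, DTIq = 0.12, rCBV = 0.30)
  sign <- c(T1C = 1, FLAIR = 1, ADC = -1, FA = -1, DTIp = -1, DTIq = 0, rCBV = 1)
  data.frame(modality = modalities(),
             baseline = unname(baseline[modalities()]),
             shift = unname(sign[modalities()] * effect_size * noise_sd[modalities()]),
             noise_sd = unname(noise_sd[modalities()]),
             stringsAsFactors = FALSE)
}

#' Parameters of the synthetic multimodal phantom
#'
#' Bundles and validates the geometry, intensity-effect and noise settings
#' used to generate co-registered multimodal phantom subjects: a spherical
#' contrast-enhancing (CE) core placed off the midline, a directional
#' progression cap abutting the core, and spatially smoothed Gaussian noise
#' per modality.
#'
#' @param grid_shape Integer vector of 3 voxel counts per axis.
#' @param voxel_spacing_mm Numeric vector of 3 positive spacings (mm).
#' @param core_radius_mm Radius of the CE core (mm); varied by +/-15\% per
#'   subject.
#' @param progression_extent_mm Thickness of the progression cap beyond the
#'   core surface (mm).
#' @param effect_table Per-modality baseline / shift / noise table, as from
#'   [default_effect_table()].
#' @param smoothing_fwhm_mm Full width at half maximum of the Gaussian
#'   spatial smoothing applied to the noise field (mm); 0 disables smoothing.
#' @param n_subjects Number of subjects a cohort will contain.
#' @param seed Base RNG seed; each subject derives its own stream from it.
#' @return An object of class `phantom_params`.
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
phantom_params <- function(grid_shape = c(26L, 26L, 26L),
                           voxel_spacing_mm = c(2.5, 2.5, 2.5),
                           core_radius_mm = 7,
                           progression_extent_mm = 6,
                           effect_table = default_effect_table(),
                           smoothing_fwhm_mm = 2,
                           n_subjects = 1L,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            core_radius_mm > 0, progression_extent_mm > 0,
            smoothing_fwhm_mm >= 0, n_subjects >= 1)
  req <- c("modality", "baseline", "shift", "noise_sd")
  if (!is.data.frame(effect_table) || !all(req %in% names(effect_table)))
    stop("effect_table must have columns modality, baseline, shift, noise_sd")
  if (!setequal(effect_table$modality, modalities()))
    stop("effect_table must contain exactly the 7 modalities: ",
         paste(modalities(), collapse = ", "))
  if (any(effect_table$noise_sd < 0)) stop("noise sd must be >= 0")
  effect_table <- effect_table[match(modalities(), effect_table$modality), ]
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 core_radius_mm = core_radius_mm,
                 progression_extent_mm = progression_extent_mm,
                 effect_table = effect_table,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("Synthetic multimodal phantom parameters\n")
  cat(sprintf("  grid %s voxels, spacing %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_spacing_mm, collapse = "x")))
  cat(sprintf("  CE core radius %.1f mm, progression cap %.1f mm, noise FWHM %.1f mm\n",
              x$core_radius_mm, x$progression_extent_mm, x$smoothing_fwhm_mm))
  cat(sprintf("  %d subject(s), seed %d\n", x$n_subjects, x$seed))
  invisible(x)
}

# Spatially correlated unit-variance Gaussian field via circular convolution
# of white noise with a Gaussian kernel normalized to unit L2 norm (so the
# marginal variance is exactly preserved).
smooth_noise_field <- function(dim, spacing, fwhm) {
  z <- array(rnorm(prod(dim)), dim = dim)
  if (fwhm <= 0) return(z)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k1 <- lapply(1:3, function(a) {
    n <- dim[a]
    d <- pmin(0:(n - 1), n - (0:(n - 1))) * spacing[a]  # circular distance, mm
    exp(-d^2 / (2 * sigma^2))
  })
  K <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(K) <- dim
  K <- K / sqrt(sum(K^2))
  Re(fft(fft(z) * fft(K), inverse = TRUE)) / prod(dim)
}

#' Generate one synthetic multimodal phantom subject
#'
#' Builds a co-registered seven-modality volume stack on a shared grid: a
#' spherical brain, an off-midline spherical CE core, and a directional
#' spherical-cap progression region of the configured thickness abutting
#' (and disjoint from) the core. Each modality is
#' `baseline + shift * 1[progression] + noise`, with spatially smoothed
#' Gaussian noise. Generation is deterministic given `(seed, subject_index)`.
#'
#' @param params A [phantom_params()] object.
#' @param subject_index Positive integer selecting the subject's RNG stream.
#' @return An object of class `phantom_subject` with elements `volumes`
#'   (named list of 3D arrays), `spacing`, `ce_mask`, `progression_mask`,
#'   `brain_mask`, `truth_labels` and `geometry`.
#' @examples
#' s <- generate_subject(phantom_params(seed = 7))
#' sapply(s$volumes, mean)
#' @export
generate_subject <- function(params, subject_index = 1L) {
  stopifnot(inherits(params, "phantom_params"), subject_index >= 1)
  dm <- params$grid_shape
  sp <- params$voxel_spacing_mm
  extent <- dm * sp
  centre <- extent / 2
  brain_r <- 0.45 * min(extent)

  with_seed(derive_seed(params$seed, subject_index), {
    radius <- params$core_radius_mm * runif(1, 0.85, 1.15)
    off <- c(0.35 * brain_r, 0, 0) + runif(3, -1, 1) * 0.05 * brain_r
    core <- centre + off
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))  # cap orientation

    # voxel-centre coordinates (mm)
    cx <- ((seq_len(dm[1]) - 1) + 0.5) * sp[1]
    cy <- ((seq_len(dm[2]) - 1) + 0.5) * sp[2]
    cz <- ((seq_len(dm[3]) - 1) + 0.5) * sp[3]
    X <- array(cx, dim = dm)
    Y <- array(rep(cy, each = dm[1]), dim = dm)
    Z <- array(rep(cz, each = dm[1] * dm[2]), dim = dm)

    D2b <- (X - centre[1])^2 + (Y - centre[2])^2 + (Z - centre[3])^2
    brain <- D2b <= brain_r^2
    dxc <- X - core[1]; dyc <- Y - core[2]; dzc <- Z - core[3]
    Dc <- sqrt(dxc^2 + dyc^2 + dzc^2)
    ce <- Dc <= radius
    proj <- dxc * ax[1] + dyc * ax[2] + dzc * ax[3]
    cap <- Dc > radius & Dc <= radius + params$progression_extent_mm &
      proj >= Dc * cos(pi / 3)

    if (any((ce | cap) & !brain))
      stop("phantom geometry error: CE core plus progression cap does not fit inside the brain mask")

    et <- params$effect_table
    vols <- vector("list", nrow(et))
    names(vols) <- et$modality
    for (m in seq_len(nrow(et))) {
      noise <- if (et$noise_sd[m] > 0)
        et$noise_sd[m] * smooth_noise_field(dm, sp, params$smoothing_fwhm_mm)
      else array(0, dim = dm)
      vols[[m]] <- et$baseline[m] + et$shift[m] * cap + noise
    }

    structure(list(volumes = vols,
                   spacing = sp,
                   ce_mask = ce,
                   progression_mask = cap,
                   brain_mask = brain,
                   truth_labels = cap,
                   geometry = list(core_centre_mm = core, core_radius_mm = radius,
                                   cap_axis = ax, brain_radius_mm = brain_r,
                                   brain_centre_mm = centre),
                   subject_index = as.integer(subject_index),
                   seed = params$seed),
              class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("Phantom subject %d: grid %s, CE %d vox, progression %d vox, brain %d vox\n",
              x$subject_index, paste(dim(x$ce_mask), collapse = "x"),
              sum(x$ce_mask), sum(x$progression_mask), sum(x$brain_mask)))
  invisible(x)
}

#' Generate a cohort of phantom subjects
#'
#' Subjects vary in CE core radius, progression-cap orientation and noise
#' realization; the cohort is reproducible given the seed in `params`.
#'
#' @param params A [phantom_params()] object; `params$n_subjects` subjects
#'   are generated.
#' @return A list of [generate_subject()] results, class `phantom_cohort`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  subjects <- lapply(seq_len(params$n_subjects),
                     function(i) generate_subject(params, i))
  structure(subjects, class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort of %d subject(s)\n", length(x)))
  invisible(x)
}
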