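# Seeded synthetic 3D volumes ("phantoms") standing in for preprocessed
# T1-weighted MRI. Each volume is an ellipsoidal tissue mask (baseline
# intensity 1 on background 0) with:
#   * a designated interior "atrophy" region whose intensity is reduced by
#     class_effect_size for disease-positive participants (the learnable
#     class signal), further modulated by age;
#   * a per-center multiplicative gain and a smooth low-order multiplicative
#     bias field (scanner/center nuisance; real pipelines remove bias fields,
#     here one is injected deliberately as a heterogeneity stressor);
#   * additive Gaussian noise with a vendor-specific standard deviation.
# Everything is generated on the fly from seeds derived from
# (master_seed, participant_id) / (master_seed, center_id): no image files
# are needed, and re-rendering any participant is bit-identical.

#' Phantom generation parameters
#'
#' @param grid_size voxels per axis (volumes are `grid_size^3`), minimum 8.
#' @param class_effect_size fractional intensity reduction of the designated
#'   region for disease-positive volumes (0.06 = 6% darker). The default is
#'   deliberately weak relative to the voxel noise and center nuisance so the
#'   task is noise-limited (ideal-observer AUROC well below 1), the regime of
#'   real multi-center disease classification.
#' @param age_effect_slope additional fractional regional intensity change per
#'   decade of age relative to age 65 (negative = darker with age).
#' @param center_gain_sd standard deviation of the per-center multiplicative
#'   gain (drawn around 1).
#' @param bias_field_amplitude scale of the smooth multiplicative bias field
#'   (exponentiated low-order polynomial in normalized coordinates); 0
#'   disables it.
#' @param noise_sd_by_vendor named vector of additive Gaussian noise standard
#'   deviations per scanner vendor.
#' @param master_seed master seed; per-participant and per-center streams are
#'   derived from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 24L,
                         class_effect_size = 0.06,
                         age_effect_slope = -0.02,
                         center_gain_sd = 0.08,
                         bias_field_amplitude = 0.4,
                         noise_sd_by_vendor = c(Siemens = 0.15, GE = 0.19,
                                                Philips = 0.22),
                         master_seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 8L) stop_config("grid_size must be >= 8")
  if (class_effect_size < 0 || center_gain_sd < 0 || bias_field_amplitude < 0 ||
      any(noise_sd_by_vendor < 0)) {
    stop_config("effect sizes, spreads and noise must be >= 0")
  }
  structure(list(grid_size = grid_size, class_effect_size = class_effect_size,
                 age_effect_slope = age_effect_slope,
                 center_gain_sd = center_gain_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sd_by_vendor = noise_sd_by_vendor,
                 master_seed = as.integer(master_seed)),
            class = "phantom_spec")
}

# Normalized voxel-center coordinates in [-1, 1] on one axis.
norm_coords <- function(g) 2 * (seq_len(g) - 0.5) / g - 1

.ELLIPSOID_AXES <- c(0.82, 0.90, 0.75)   # semi-axes in normalized units
.REGION_CENTER <- c(0.15, -0.20, 0.10)   # "atrophy" region (normalized)
.REGION_RADIUS <- 0.25

#' Deterministic ellipsoidal brain template
#'
#' Tissue (intensity 1) inside an ellipsoid with semi-axes 0.82/0.90/0.75 in
#' normalized coordinates, background 0, plus a fixed spherical interior
#' subregion designated as the class-effect ("atrophy") region. Purely
#' geometric: no randomness.
#'
#' @param grid_size voxels per axis, minimum 8.
#' @return 3D array of class `phantom_template` with attributes
#'   `region_idx` (voxel indices of the class region), `tissue_idx`, and
#'   `grid_size`.
#' @export
make_template <- function(grid_size = 24L) {
  g <- as.integer(grid_size)
  if (g < 8L) stop("grid_size must be >= 8")
  u <- norm_coords(g)
  U <- array(rep(u, times = g * g), dim = c(g, g, g))
  V <- array(rep(rep(u, each = g), times = g), dim = c(g, g, g))
  W <- array(rep(u, each = g * g), dim = c(g, g, g))
  a <- .ELLIPSOID_AXES
  inside <- (U / a[1])^2 + (V / a[2])^2 + (W / a[3])^2 <= 1
  ctr <- .REGION_CENTER
  region <- ((U - ctr[1])^2 + (V - ctr[2])^2 + (W - ctr[3])^2) <= .REGION_RADIUS^2
  tpl <- array(0, dim = c(g, g, g))
  tpl[inside] <- 1
  structure(tpl,
            region_idx = which(region), tissue_idx = which(inside),
            grid_size = g, class = c("phantom_template", "array"))
}

#' Per-center scanner effect parameters
#'
#' Draws the center's multiplicative gain (`Normal(1, center_gain_sd)`) and
#' the 9 coefficients of its low-order bias-field polynomial from a stream
#' derived from `(master_seed, center_id)` — deterministic per center, and
#' independent across centers.
#'
#' @param center_id center identifier.
#' @param spec a `phantom_spec`.
#' @return list with `gain` and `bias_coef` (length 9).
#' @export
center_effect_params <- function(center_id, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(derive_seed(spec$master_seed, "center-fx", center_id), {
    list(gain = rnorm(1, mean = 1, sd = spec$center_gain_sd),
         bias_coef = rnorm(9))
  })
}

# exp(amplitude * P(u,v,w)/3) with P a quadratic polynomial without intercept.
bias_field <- function(g, coef, amplitude) {
  if (amplitude == 0) return(1)
  u <- norm_coords(g)
  U <- array(rep(u, times = g * g), dim = c(g, g, g))
  V <- array(rep(rep(u, each = g), times = g), dim = c(g, g, g))
  W <- array(rep(u, each = g * g), dim = c(g, g, g))
  P <- coef[1] * U + coef[2] * V + coef[3] * W +
    coef[4] * U * V + coef[5] * U * W + coef[6] * V * W +
    coef[7] * U^2 + coef[8] * V^2 + coef[9] * W^2
  exp(amplitude * P / 3)
}

#' Render one participant's phantom volume
#'
#' Applies, in order: the class-region intensity reduction
#' `(1 - class_effect_size)` for label-1 participants; the age modulation
#' `(1 + age_effect_slope * (age - 65)/10)` of the same region (clamped at 0);
#' the center's multiplicative gain and bias field; additive vendor noise
#' drawn from a stream derived from `(master_seed, participant_id)`.
#' Rendering the same record twice is bit-identical.
#'
#' @param record one-row data.frame (a participant record).
#' @param template a `phantom_template` matching `spec$grid_size`.
#' @param spec a `phantom_spec`.
#' @return list of class `volume_sample`: `intensities` (3D array), `record`.
#' @export
render_participant <- function(record, template, spec) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(template, "phantom_template"))
  g <- attr(template, "grid_size")
  if (g != spec$grid_size) stop("template grid does not match spec grid_size")
  sdv <- unname(spec$noise_sd_by_vendor[record$vendor])
  if (is.na(sdv)) stop("unknown vendor: ", record$vendor)
  vol <- array(as.numeric(template), dim = dim(template))
  region <- attr(template, "region_idx")
  factor <- 1
  if (record$label == 1L) factor <- factor * (1 - spec$class_effect_size)
  factor <- factor * max(1 + spec$age_effect_slope * (record$age_years - 65) / 10, 0)
  vol[region] <- vol[region] * factor
  ce <- center_effect_params(record$center_id, spec)
  vol <- vol * ce$gain * bias_field(g, ce$bias_coef, spec$bias_field_amplitude)
  if (sdv > 0) {
    noise <- with_seed(derive_seed(spec$master_seed, "phantom", record$participant_id),
                       rnorm(length(vol), 0, sdv))
    vol <- vol + noise
  }
  structure(list(intensities = vol, record = record), class = "volume_sample")
}

#' Render all volumes of a cohort
#'
#' @param cohort a `cohort` (or the `train`/`test` part of a `split_cohort`).
#' @param spec a `phantom_spec`.
#' @param template optional pre-built template (defaults to
#'   `make_template(spec$grid_size)`).
#' @return object of class `volume_set`: list with `x` (matrix, one flattened
#'   volume per column, named by participant id), `grid`, `labels` (named),
#'   and `records`.
#' @export
render_cohort <- function(cohort, spec, template = make_template(spec$grid_size)) {
  stopifnot(inherits(cohort, "cohort"))
  g <- spec$grid_size
  x <- matrix(0, nrow = g^3, ncol = nrow(cohort))
  colnames(x) <- cohort$participant_id
  for (i in seq_len(nrow(cohort))) {
    x[, i] <- as.numeric(render_participant(cohort[i, ], template, spec)$intensities)
  }
  structure(list(x = x, grid = g,
                 labels = setNames(cohort$label, cohort$participant_id),
                 records = cohort),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("<volume_set> %d volumes of %d^3 voxels (%d disease / %d healthy)\n",
              ncol(x$x), x$grid, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' @rdname render_cohort
#' @param volumes a `volume_set`.
#' @export
volume_ids <- function(volumes) colnames(volumes$x)

#' @rdname render_cohort
#' @export
volume_labels <- function(volumes) volumes$labels

#' Write / read phantom volumes as NIfTI
#'
#' Optional interoperability with imaging tools and the real-data path:
#' each volume is written as `<participant_id>.nii.gz`. Requires the
#' suggested package `RNifti`.
#'
#' @param volumes a `volume_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_volumes_nifti <- function(volumes, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI export requires the 'RNifti' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- volumes$grid
  paths <- vapply(volume_ids(volumes), function(id) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    RNifti::writeNifti(array(volumes$x[, id], dim = c(g, g, g)), p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_volumes_nifti
#' @param cohort the cohort whose participant volumes should be loaded; files
#'   are looked up as `<participant_id>.nii.gz` under `dir`.
#' @export
read_volumes_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI import requires the 'RNifti' package")
  }
  stopifnot(inherits(cohort, "cohort"))
  vols <- lapply(cohort$participant_id, function(id) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(p)) stop("missing volume file: ", p)
    as.numeric(RNifti::readNifti(p))
  })
  g <- round(length(vols[[1]])^(1 / 3))
  x <- do.call(cbind, vols)
  colnames(x) <- cohort$participant_id
  structure(list(x = x, grid = as.integer(g),
                 labels = setNames(cohort$label, cohort$participant_id),
                 records = cohort),
            class = "volume_set")
}
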