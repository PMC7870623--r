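# Synthetic knee phantoms.
#
# Each phantom volume holds three bright bone analogues (femur, tibia and —
# on coronal phantoms — fibula), each split into shaft and epiphysis by a
# dark growth-plate gap whose physical width shrinks linearly with age and
# closes at a configurable closure age.  A smooth multiplicative bias field,
# additive Gaussian noise and in-plane pose jitter emulate acquisition
# nuisances.  Ground-truth masks, per-bone gap widths and subject records
# (age, anthropometrics, ossification stages) accompany every volume, so the
# entire downstream pipeline is testable without clinical data.

INTENS <- list(background = 0.05, soft = 0.35, bone = 1.0, gap = 0.12,
               pcl = 0.55)

#' Phantom cohort configuration
#'
#' Defaults emulate the acquisition conditions of the male-adolescent knee
#' cohorts this pipeline targets: ages uniform over 13.00-21.83 years,
#' in-plane voxel spacing 0.29-0.49 mm on a 512 x 512 grid (148-250 mm field
#' of view), slice spacing 2.2-5.2 mm over 32 slices, and a growth-plate gap
#' that closes at 19 years.
#'
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param n_subjects number of subjects.
#' @param age_range ages are drawn uniformly from this interval (years).
#' @param closure_age age (years) at which the synthetic growth plate closes;
#'   must lie inside `age_range`.
#' @param in_plane_spacing_mm range the per-subject in-plane spacing is drawn
#'   from (mm).
#' @param slice_spacing_mm range for the slice spacing (mm).
#' @param grid_shape voxels per axis (rows, cols, slices).
#' @param noise_sd additive Gaussian noise, relative intensity units.
#' @param bias_amplitude peak relative amplitude of the smooth multiplicative
#'   bias field (0 disables).
#' @param pose_jitter_px maximal in-plane pose offset, in pixels.
#' @param gap_max_mm gap width (mm) at the lower end of the age range.
#' @param gap_sdlog sdlog of the per-subject lognormal multiplicative gap
#'   variation (0 makes gap width an exact function of age).
#' @param orientation phantom anatomy style; sagittal cohorts carry no
#'   fibula, no ossification stages and no anthropometrics.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(seed = 1L, n_subjects = 60L,
                           age_range = c(13, 21.83), closure_age = 19,
                           in_plane_spacing_mm = c(0.29, 0.49),
                           slice_spacing_mm = c(2.2, 5.2),
                           grid_shape = c(512L, 512L, 32L),
                           noise_sd = 0.05, bias_amplitude = 0.3,
                           pose_jitter_px = 10, gap_max_mm = 8,
                           gap_sdlog = 0.1,
                           orientation = c("coronal", "sagittal")) {
  orientation <- match.arg(orientation)
  stopifnot(n_subjects >= 1,
            length(age_range) == 2, diff(age_range) > 0,
            age_range[1] >= 13 - 1e-9, age_range[2] <= 21.83 + 1e-9,
            closure_age > age_range[1], closure_age <= age_range[2],
            diff(in_plane_spacing_mm) >= 0, all(in_plane_spacing_mm > 0),
            diff(slice_spacing_mm) >= 0, all(slice_spacing_mm > 0),
            length(grid_shape) == 3, all(grid_shape >= 8),
            noise_sd >= 0, bias_amplitude >= 0, pose_jitter_px >= 0,
            gap_max_mm > 0, gap_sdlog >= 0)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 age_range = age_range, closure_age = closure_age,
                 in_plane_spacing_mm = in_plane_spacing_mm,
                 slice_spacing_mm = slice_spacing_mm,
                 grid_shape = as.integer(grid_shape),
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 pose_jitter_px = pose_jitter_px, gap_max_mm = gap_max_mm,
                 gap_sdlog = gap_sdlog, orientation = orientation),
            class = "phantom_config")
}

#' Expected growth-plate gap width as a function of age
#'
#' Linear decrease from `gap_max_mm` at the lower end of the age range to 0
#' at the closure age; 0 for any age at or beyond closure.
#'
#' @param age age(s) in years.
#' @param config a [phantom_config()].
#' @return gap width(s) in mm.
#' @export
gap_width_mm <- function(age, config) {
  frac <- (config$closure_age - age) /
    (config$closure_age - config$age_range[1])
  config$gap_max_mm * pmax(0, pmin(1, frac))
}

# membership array of an axis-aligned ellipsoid; rr/cc/zz are the mm
# coordinates of the grid axes (row downward, col rightward, slice).
ellipsoid <- function(rr, cc, zz, c0, semi) {
  tr <- ((rr - c0[1]) / semi[1])^2
  tc <- ((cc - c0[2]) / semi[2])^2
  tz <- ((zz - c0[3]) / semi[3])^2
  outer(outer(tr, tc, `+`), tz, `+`) <= 1
}

# Render the noise- and bias-free scene.  Returns intensity + truth mask
# (bone voxels only; the dark gap is *not* part of the mask).
render_scene <- function(shape, spacing, orientation, gaps_mm,
                         offset_mm = c(0, 0)) {
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  rr <- (seq_len(H) - (H + 1) / 2) * spacing[1] - offset_mm[1]
  cc <- (seq_len(W) - (W + 1) / 2) * spacing[2] - offset_mm[2]
  zz <- (seq_len(D) - (D + 1) / 2) * spacing[3]
  depth <- D * spacing[3]
  bz <- 0.40 * depth
  img <- array(INTENS$background, shape)

  soft <- ellipsoid(rr, cc, zz, c(0, 0, 0), c(85, 55, 0.48 * depth))
  img[soft] <- INTENS$soft

  in_band <- function(center, halfw) {
    if (halfw <= 0) return(array(FALSE, shape))
    array(rep(rr >= center - halfw & rr < center + halfw, times = W * D),
          shape)
  }

  femur <- ellipsoid(rr, cc, zz, c(-48, 0, 0), c(30, 17, bz)) |
    ellipsoid(rr, cc, zz, c(-15, 0, 0), c(11, 37, bz))
  fgap <- femur & in_band(-23, gaps_mm[["femur"]] / 2)

  tibia <- ellipsoid(rr, cc, zz, c(45, 0, 0), c(28, 16, bz)) |
    ellipsoid(rr, cc, zz, c(14, 0, 0), c(10, 35, bz))
  tgap <- tibia & in_band(21, gaps_mm[["tibia"]] / 2)

  bone <- femur | tibia
  gap <- fgap | tgap

  if (orientation == "coronal") {
    fib <- ellipsoid(rr, cc, zz, c(20, 45, 0), c(6, 6, 0.3 * depth)) |
      ellipsoid(rr, cc, zz, c(50, 47, 0), c(26, 5, 0.3 * depth))
    bone <- bone | fib
    gap <- gap | (fib & in_band(26, gaps_mm[["fibula"]] / 2))
  }

  img[bone] <- INTENS$bone
  img[gap] <- INTENS$gap
  mask <- (bone & !gap) * 1L

  if (orientation == "sagittal") {
    # posterior-cruciate-ligament analogue: oblique band in the joint space
    rg <- array(rep(rr, times = W * D), shape)
    cg <- aperm(array(rep(cc, times = H * D), c(W, H, D)), c(2, 1, 3))
    pcl <- abs(rg - 0.8 * cg) <= 2.5 & (rg^2 + cg^2) <= 16^2 & !bone & !gap
    img[pcl & soft] <- INTENS$pcl
  }

  list(intensity = img, mask = array(mask, shape))
}

smooth_bias_field <- function(shape, amplitude) {
  if (amplitude <= 0) return(array(1, shape))
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  u <- seq(-1, 1, length.out = H)
  v <- seq(-1, 1, length.out = W)
  w <- seq(-1, 1, length.out = D)
  a <- stats::runif(6, -1, 1)
  f <- outer(outer(a[1] * u + a[4] * u^2, a[2] * v + a[5] * v^2, `+`),
             a[3] * w + a[6] * w^2, `+`)
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f <- f / m
  1 + amplitude * f
}

stage_from_fraction <- function(frac) {
  ifelse(frac == 0, 3L, ifelse(frac > 0.5, 1L, 2L))
}

#' Generate a synthetic knee cohort
#'
#' Produces `n_subjects` phantom samples: each a volume (bias and noise
#' applied), its ground-truth bone mask (rendered before bias/noise), a
#' subject record (age, anthropometrics and — for coronal cohorts —
#' ossification stages derived by thresholding the relative gap width at
#' 50% and closure), the true per-bone gap widths, and the in-plane pose
#' offset used.  Identical configurations yield bit-identical cohorts.
#'
#' @param config a [phantom_config()].
#' @return list of `phantom_sample` objects, each with elements `volume`
#'   (`knee_volume`), `truth_mask` (0/1 array), `record` (one-row data
#'   frame), `true_gap_mm` (named length-3 vector) and `pose_offset_mm`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_subjects < 1) stop("n_subjects must be positive")
  set.seed(config$seed)
  n <- config$n_subjects
  ages <- sort(stats::runif(n, config$age_range[1], config$age_range[2]))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    age <- ages[i]
    sp_in <- stats::runif(1, config$in_plane_spacing_mm[1],
                          config$in_plane_spacing_mm[2])
    sp_sl <- stats::runif(1, config$slice_spacing_mm[1],
                          config$slice_spacing_mm[2])
    spacing <- c(sp_in, sp_in, sp_sl)
    jit <- round(stats::runif(2, -config$pose_jitter_px, config$pose_jitter_px))
    offset <- jit * sp_in
    gfac <- exp(stats::rnorm(3, 0, config$gap_sdlog))
    base <- gap_width_mm(age, config)
    gaps <- c(femur = base * gfac[1], tibia = base * gfac[2],
              fibula = base * gfac[3])
    sc <- render_scene(config$grid_shape, spacing, config$orientation,
                       gaps, offset)
    img <- sc$intensity * smooth_bias_field(config$grid_shape,
                                            config$bias_amplitude)
    if (config$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, config$noise_sd),
                         dim(img))
    }
    img[img < 0] <- 0
    frac <- base / config$gap_max_mm
    coronal <- config$orientation == "coronal"
    a_eff <- min(age, config$closure_age)
    standing <- 140 + 2.2 * a_eff + stats::rnorm(1, 0, 4)
    rec <- data.frame(
      subject_id = sprintf("S%03d", i),
      age_years = age,
      weight_kg = if (coronal) 0.42 * standing - 5 + stats::rnorm(1, 0, 3) else NA_real_,
      standing_height_cm = if (coronal) standing else NA_real_,
      sitting_height_cm = if (coronal) 0.52 * standing + stats::rnorm(1, 0, 2) else NA_real_,
      lll_cm = if (coronal) 0.245 * standing + stats::rnorm(1, 0, 1.5) else NA_real_,
      os_df = if (coronal) stage_from_fraction(frac) else NA_integer_,
      os_pt = if (coronal) stage_from_fraction(frac) else NA_integer_,
      os_pf = if (coronal) stage_from_fraction(frac) else NA_integer_,
      stringsAsFactors = FALSE)
    rec$skj <- if (coronal) rec$os_df + rec$os_pt + rec$os_pf else NA_integer_
    samples[[i]] <- structure(
      list(volume = knee_volume(img, spacing, config$orientation),
           truth_mask = sc$mask,
           record = rec,
           true_gap_mm = gaps,
           pose_offset_mm = offset),
      class = "phantom_sample")
  }
  samples
}

#' Template patch of the phantom's characteristic region
#'
#' Renders the noise-free reference scene (mid-range age, no pose jitter) at
#' a declared reference spacing and cuts the patch used for template
#' matching: the inter-bone notch between the femoral and tibial epiphyses
#' for coronal phantoms, the oblique central ligament band for sagittal
#' phantoms.
#'
#' @param orientation `"coronal"` or `"sagittal"`.
#' @param config a [phantom_config()].
#' @param patch_mm physical side length of the square patch.
#' @return list with `patch` (matrix), `spacing_mm` (scalar in-plane
#'   reference spacing) and `center_mm` (scene coordinates the patch is
#'   centred on).
#' @export
make_template_patch <- function(orientation = c("coronal", "sagittal"),
                                config = phantom_config(), patch_mm = 40) {
  orientation <- match.arg(orientation)
  sp <- mean(config$in_plane_spacing_mm)
  age <- mean(config$age_range)
  g <- gap_width_mm(age, config)
  gaps <- c(femur = g, tibia = g, fibula = g)
  # a compact single-slice scene around the joint is enough for the patch
  n_px <- 2L * floor(100 / sp / 2) # ~200 mm field, even
  sc <- render_scene(c(n_px, n_px, 1L), c(sp, sp, 3), orientation, gaps)
  img <- sc$intensity[, , 1]
  center_mm <- if (orientation == "coronal") c(0, 0) else c(0, 2)
  half <- floor(patch_mm / sp / 2)
  ctr <- (n_px + 1) / 2 + center_mm / sp
  rs <- round(ctr[1] - half):round(ctr[1] + half)
  cs <- round(ctr[2] - half):round(ctr[2] + half)
  stopifnot(min(rs) >= 1, max(rs) <= n_px, min(cs) >= 1, max(cs) <= n_px)
  list(patch = img[rs, cs], spacing_mm = sp, center_mm = center_mm)
}

#' Write a phantom cohort to disk
#'
#' Volumes and truth masks are written as NIfTI (`.nii.gz`) with correct
#' voxel spacing, subject records as a single CSV, and the configuration as
#' JSON.
#'
#' @param samples output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the generating [phantom_config()], stored alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(samples, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- do.call(rbind, lapply(samples, function(s) s$record))
  utils::write.csv(recs, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (s in samples) {
    id <- s$record$subject_id
    write_volume(s$volume, file.path(dir, paste0(id, ".nii.gz")))
    write_volume(array(as.integer(s$truth_mask), dim(s$truth_mask)),
                 file.path(dir, paste0(id, "_mask.nii.gz")),
                 spacing_mm = s$volume$spacing_mm)
  }
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Cohort ages as a vector
#' @param samples list of `phantom_sample`s.
#' @return numeric ages in years.
#' @export
cohort_ages <- function(samples) {
  vapply(samples, function(s) s$record$age_years, numeric(1))
}
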