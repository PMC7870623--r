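#' Preprocessing configuration
#'
#' @param bfc_enabled apply bias-field correction.
#' @param bfc_order polynomial order of the fitted log-bias field.
#' @param standard_inplane_px common in-plane resolution all volumes are
#'   resampled to before correction and matching (default 448).
#' @param voi_extent_mm side length of the square volume of interest
#'   extracted around the template match (default 130 mm, read as a full
#'   width centred on the match point).
#' @param net_input_px side length of the network input slices (default 224).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(bfc_enabled = TRUE, bfc_order = 2L,
                              standard_inplane_px = 448L,
                              voi_extent_mm = 130, net_input_px = 224L) {
  stopifnot(standard_inplane_px > 0, net_input_px > 0, voi_extent_mm > 0,
            bfc_order >= 1)
  structure(list(bfc_enabled = isTRUE(bfc_enabled),
                 bfc_order = as.integer(bfc_order),
                 standard_inplane_px = as.integer(standard_inplane_px),
                 voi_extent_mm = voi_extent_mm,
                 net_input_px = as.integer(net_input_px)),
            class = "preprocess_config")
}

#' Correct smooth multiplicative intensity non-uniformity
#'
#' Estimates a low-order polynomial log-bias field from foreground voxels
#' (least squares on log intensities over normalized coordinates), divides
#' it out, and rescales so the foreground mean is preserved.  A no-op when
#' `bfc_enabled` is `FALSE`.
#'
#' @param volume a `knee_volume` with non-negative intensities.
#' @param config a [preprocess_config()].
#' @param max_fit_voxels foreground voxels are subsampled to at most this
#'   many for the least-squares fit.
#' @return list with `volume` (corrected `knee_volume`) and `field` (the
#'   estimated multiplicative field, same shape).
#' @export
correct_bias <- function(volume, config = preprocess_config(),
                         max_fit_voxels = 50000L) {
  stopifnot(inherits(volume, "knee_volume"))
  x <- volume$data
  if (all(x == 0)) stop("degenerate input: all-zero volume")
  if (!config$bfc_enabled) {
    return(list(volume = volume, field = array(1, dim(x))))
  }
  dm <- dim(x)
  fg <- which(x > mean(x))
  if (length(fg) < 100) {
    return(list(volume = volume, field = array(1, dim(x))))
  }
  # deterministic even subsample of foreground voxels for the fit
  sub <- fg[unique(round(seq(1, length(fg),
                             length.out = min(max_fit_voxels, length(fg)))))]
  coord <- arrayInd(sub, dm)
  ax <- lapply(1:3, function(a) 2 * (seq_len(dm[a]) - 1) / max(1, dm[a] - 1) - 1)
  u <- ax[[1]][coord[, 1]]
  v <- ax[[2]][coord[, 2]]
  w <- ax[[3]][coord[, 3]]
  order <- config$bfc_order
  basis <- function(u, v, w) {
    cols <- list(rep(1, length(u)))
    for (p in seq_len(order)) cols <- c(cols, list(u^p, v^p, w^p))
    if (order >= 2) cols <- c(cols, list(u * v, u * w, v * w))
    do.call(cbind, cols)
  }
  B <- basis(u, v, w)
  beta <- stats::lm.fit(B, log(pmax(x[sub], 1e-6)))$coefficients
  beta[is.na(beta)] <- 0
  # evaluate the smooth log-field slice by slice (separable terms)
  poly_sum <- function(t, which_axis) {
    # sum_p beta[1 + 3*(p-1) + which_axis] * t^p
    s <- 0
    for (p in seq_len(order)) s <- s + beta[1 + 3 * (p - 1) + which_axis] * t^p
    s
  }
  Ar <- poly_sum(ax[[1]], 1)
  Ac <- poly_sum(ax[[2]], 2)
  Az <- poly_sum(ax[[3]], 3)
  field <- array(0, dm)
  cross <- if (order >= 2) beta[(1 + 3 * order) + 1:3] else c(0, 0, 0)
  uv <- cross[1] * outer(ax[[1]], ax[[2]])
  for (k in seq_len(dm[3])) {
    wk <- ax[[3]][k]
    rowpart <- Ar + cross[2] * ax[[1]] * wk + beta[1] + Az[k]
    colpart <- Ac + cross[3] * ax[[2]] * wk
    field[, , k] <- outer(rowpart, colpart, `+`) + uv
  }
  field <- exp(field - mean(field[sub]))
  corr <- x / field
  # preserve foreground mean
  corr <- corr * (mean(x[fg]) / mean(corr[fg]))
  out <- volume
  out$data <- corr
  list(volume = out, field = field)
}

#' Resample a volume to a common in-plane resolution
#'
#' Area-averaging (anti-aliased) resampling of every slice to
#' `target_px` x `target_px`; the slice count is unchanged and the in-plane
#' spacing is rescaled so the physical extent is preserved.
#'
#' @param volume a `knee_volume`.
#' @param target_px target in-plane side length (default 448).
#' @return the resampled `knee_volume`.
#' @export
standardize_inplane <- function(volume, target_px = 448L) {
  stopifnot(inherits(volume, "knee_volume"), target_px > 0)
  dm <- dim(volume$data)
  if (dm[1] == target_px && dm[2] == target_px) return(volume)
  out <- array(0, c(target_px, target_px, dm[3]))
  for (k in seq_len(dm[3])) {
    out[, , k] <- resample_area(volume$data[, , k], target_px, target_px)
  }
  knee_volume(out,
              c(volume$spacing_mm[1] * dm[1] / target_px,
                volume$spacing_mm[2] * dm[2] / target_px,
                volume$spacing_mm[3]),
              volume$orientation)
}

#' Locate a characteristic region by template matching
#'
#' The patch, defined at its own reference spacing, is first resampled to
#' the image spacing, then slid over all full-overlap placements; the
#' zero-normalized cross-correlation is computed for each and the argmax
#' returned (ties broken toward the first placement in row-major order:
#' smaller row, then smaller column).
#'
#' @param image 2D numeric matrix (one slice).
#' @param patch 2D template patch.
#' @param patch_spacing_mm in-plane spacing the patch is defined at
#'   (scalar or length-2).
#' @param image_spacing_mm in-plane spacing of `image`.
#' @return a `match_result`: list with `center_px` (row, col of the central
#'   pixel of the best placement), `top_left` and `score` between -1 and 1.
#' @export
match_template <- function(image, patch, patch_spacing_mm = 1,
                           image_spacing_mm = 1) {
  stopifnot(is.matrix(image), is.matrix(patch))
  psp <- rep(patch_spacing_mm, length.out = 2)
  isp <- rep(image_spacing_mm, length.out = 2)
  out_r <- max(2L, round(nrow(patch) * psp[1] / isp[1]))
  out_c <- max(2L, round(ncol(patch) * psp[2] / isp[2]))
  rp <- if (out_r == nrow(patch) && out_c == ncol(patch)) patch else
    resample_area(patch, out_r, out_c)
  if (nrow(rp) > nrow(image) || ncol(rp) > ncol(image)) {
    stop("patch larger than image after spacing-aware resampling")
  }
  if (stats::sd(rp) == 0) stop("patch has zero variance")
  sc <- .cpp_zncc_map(image, rp)
  best <- which(t(sc) == max(sc))[1]     # row-major first
  i <- (best - 1) %/% ncol(sc) + 1
  j <- (best - 1) %% ncol(sc) + 1
  structure(list(center_px = c(row = i + floor((nrow(rp) - 1) / 2),
                               col = j + floor((ncol(rp) - 1) / 2)),
                 top_left = c(row = i, col = j),
                 score = max(sc)),
            class = "match_result")
}

#' Extract a fixed-extent volume of interest
#'
#' Crops a square in-plane region of physical side `extent_mm` centred on
#' `center_px`, keeping all slices.  Regions falling outside the volume are
#' zero-padded so the output shape is always exact; intensities inside
#' bounds are copied without interpolation.
#'
#' @param volume a `knee_volume`.
#' @param center_px (row, col) centre in pixels.
#' @param extent_mm physical side length of the crop (default 130 mm).
#' @return the cropped `knee_volume`.
#' @export
extract_voi <- function(volume, center_px, extent_mm = 130) {
  stopifnot(inherits(volume, "knee_volume"), extent_mm > 0,
            length(center_px) == 2)
  dm <- dim(volume$data)
  stopifnot(center_px[1] >= 1, center_px[1] <= dm[1],
            center_px[2] >= 1, center_px[2] <= dm[2])
  n_r <- round(extent_mm / volume$spacing_mm[1])
  n_c <- round(extent_mm / volume$spacing_mm[2])
  out <- array(0, c(n_r, n_c, dm[3]))
  r0 <- round(center_px[1]) - floor(n_r / 2)
  c0 <- round(center_px[2]) - floor(n_c / 2)
  rs <- r0:(r0 + n_r - 1)
  cs <- c0:(c0 + n_c - 1)
  ok_r <- rs >= 1 & rs <= dm[1]
  ok_c <- cs >= 1 & cs <= dm[2]
  out[which(ok_r), which(ok_c), ] <- volume$data[rs[ok_r], cs[ok_c], , drop = FALSE]
  knee_volume(out, volume$spacing_mm, volume$orientation)
}

#' Standard-score normalization of a slice
#'
#' @param slice numeric matrix.
#' @return the slice transformed to zero mean and unit standard deviation;
#'   a constant slice returns all zeros with a warning.
#' @export
normalize_slice <- function(slice) {
  stopifnot(all(is.finite(slice)))
  s <- stats::sd(slice)
  if (s == 0) {
    warning("constant slice: returning all zeros")
    return(slice * 0)
  }
  (slice - mean(slice)) / s
}

#' Downsample a VOI to network input resolution and normalize each slice
#'
#' @param voi a `knee_volume` (the 130 mm crop).
#' @param net_input_px target side length (default 224).
#' @param normalize standard-score each slice.
#' @return array `(net_input_px, net_input_px, n_slices)`.
#' @export
voi_to_net_slices <- function(voi, net_input_px = 224L, normalize = TRUE) {
  dm <- dim(voi$data)
  out <- array(0, c(net_input_px, net_input_px, dm[3]))
  for (k in seq_len(dm[3])) {
    sl <- resample_area(voi$data[, , k], net_input_px, net_input_px)
    if (normalize) {
      s <- stats::sd(sl)
      sl <- if (s == 0) sl * 0 else (sl - mean(sl)) / s
    }
    out[, , k] <- sl
  }
  out
}

#' Full pre-processing chain for one volume
#'
#' Standardizes the in-plane resolution, corrects the bias field, locates
#' the characteristic region on the central slice by template matching, and
#' extracts the fixed 130 mm volume of interest (applied with the same
#' in-plane centre on every slice).
#'
#' @param volume a raw `knee_volume`.
#' @param template output of [make_template_patch()] (or any list with
#'   `patch` and `spacing_mm`).
#' @param config a [preprocess_config()].
#' @return list with `voi` (`knee_volume`), `match` (`match_result`) and
#'   `field` (estimated bias field at standardized resolution).
#' @export
preprocess_volume <- function(volume, template,
                              config = preprocess_config()) {
  std <- standardize_inplane(volume, config$standard_inplane_px)
  bc <- correct_bias(std, config)
  std <- bc$volume
  mid <- ceiling(dim(std$data)[3] / 2)
  mr <- match_template(std$data[, , mid], template$patch,
                       template$spacing_mm, std$spacing_mm[1:2])
  voi <- extract_voi(std, mr$center_px, config$voi_extent_mm)
  list(voi = voi, match = mr, field = bc$field)
}
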