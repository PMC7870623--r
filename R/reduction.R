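#' Slice-reduction configuration
#'
#' @param min_bone_fraction slices must carry strictly more than this
#'   fraction of nonzero (bone) pixels to survive the first reduction
#'   (default 0.02, i.e. the strict ">2%" rule).
#' @param target_slices number of slices kept by the second reduction
#'   (default 12).
#' @return a `reduction_config` list.
#' @export
reduction_config <- function(min_bone_fraction = 0.02, target_slices = 12L) {
  stopifnot(min_bone_fraction > 0, min_bone_fraction < 1, target_slices >= 1)
  structure(list(min_bone_fraction = min_bone_fraction,
                 target_slices = as.integer(target_slices)),
            class = "reduction_config")
}

#' Reduction 1: drop slices with no or sparse bone content
#'
#' The bone fraction of a slice is its count of nonzero pixels divided by
#' the pixels per slice.  Only slices whose fraction strictly exceeds
#' `min_bone_fraction` survive; order is preserved.
#'
#' @param masked a masked `knee_volume` or 3D array (zeros outside bone).
#' @param config a [reduction_config()].
#' @return list with `indices` (surviving slice indices), `fractions`
#'   (their bone fractions) and `all_fractions` (per input slice).
#' @export
reduction1 <- function(masked, config = reduction_config()) {
  dat <- if (inherits(masked, "knee_volume")) masked$data else masked
  stopifnot(length(dim(dat)) == 3)
  per_slice <- dim(dat)[1] * dim(dat)[2]
  frac <- apply(dat != 0, 3, sum) / per_slice
  keep <- which(frac > config$min_bone_fraction)
  if (length(keep) == 0) stop("insufficient bone content: no slice exceeds the bone-fraction threshold")
  list(indices = keep, fractions = frac[keep], all_fractions = frac)
}

# Deterministic even-selection rule used by reduction 2.
#
# Survivor list positions 1..m; the position nearest the fraction-weighted
# centre of gravity (tie: lower) anchors an equally spaced grid of
# `target` sample points with spacing (m-1)/(target-1); points are rounded
# to the nearest position (half up), clamped, and collisions move to the
# nearest unused position (lower first).
select_even_indices <- function(indices, fractions, target) {
  m <- length(indices)
  if (m < target) stop("volume too thin: fewer surviving slices than required")
  if (m == target) return(seq_len(m))
  g <- sum(fractions * indices) / sum(fractions)
  c_pos <- which.min(abs(indices - g))           # ties: lower index
  if (target == 1) return(c_pos)
  h <- (m - 1) / (target - 1)
  q <- 1 + (seq_len(target) - 1) * h
  j_c <- which.min(abs(q - c_pos))
  p <- c_pos + (seq_len(target) - j_c) * h
  pos <- pmin(m, pmax(1, floor(p + 0.5)))
  taken <- logical(m)
  out <- integer(target)
  for (j in seq_len(target)) {
    k <- pos[j]
    if (taken[k]) {
      free <- which(!taken)
      k <- free[which.min(abs(free - pos[j]))]   # nearest unused, lower first
    }
    taken[k] <- TRUE
    out[j] <- k
  }
  sort(out)
}

#' Reduction 2: evenly select the target number of slices
#'
#' Selects exactly `target_slices` of the surviving slices: the slice
#' nearest the centre of gravity of the bone-amount-per-slice distribution
#' is always included, and the remaining picks are spread at the most even
#' spacing achievable over the survivor list (see the documented selection
#' rule), with deterministic tie-breaks toward lower indices.
#'
#' @param indices surviving slice indices from [reduction1()].
#' @param fractions matching bone fractions.
#' @param config a [reduction_config()].
#' @return integer vector of `target_slices` selected slice indices,
#'   strictly increasing, a subset of `indices`.
#' @export
reduction2 <- function(indices, fractions, config = reduction_config()) {
  stopifnot(length(indices) == length(fractions))
  sel <- select_even_indices(indices, fractions, config$target_slices)
  indices[sel]
}

#' Reduce a masked volume to a fixed-size slice stack
#'
#' Applies both reductions and packages the selected slices.
#'
#' @param masked masked `knee_volume` or array (slices already at network
#'   resolution).
#' @param config a [reduction_config()].
#' @return a `slice_stack`: list with `slices` (array H x W x target),
#'   `source_indices` and `bone_fractions`.
#' @export
reduce_volume <- function(masked, config = reduction_config()) {
  dat <- if (inherits(masked, "knee_volume")) masked$data else masked
  r1 <- reduction1(dat, config)
  sel <- reduction2(r1$indices, r1$fractions, config)
  structure(list(slices = dat[, , sel, drop = FALSE],
                 source_indices = sel,
                 bone_fractions = r1$all_fractions[sel]),
            class = "slice_stack")
}

#' Write a slice stack as NIfTI plus JSON sidecar
#'
#' @param stack a `slice_stack`.
#' @param path output NIfTI path; the sidecar gets extension `.json`.
#' @param spacing_mm voxel spacing recorded in the NIfTI header.
#' @return `path`, invisibly.
#' @export
write_slice_stack <- function(stack, path, spacing_mm = c(1, 1, 1)) {
  write_volume(stack$slices, path, spacing_mm = spacing_mm)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(source_indices = stack$source_indices,
                            bone_fractions = stack$bone_fractions),
                       side, digits = NA)
  invisible(path)
}
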