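# Area-overlap (box) resampling.  Downsampling averages input cells in
# proportion to their geometric overlap with each output cell, which
# anti-aliases; upsampling degenerates to piecewise-constant replication.

area_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * r
    hi <- j * r
    i0 <- max(1L, floor(lo) + 1L)
    i1 <- min(n_in, ceiling(hi))
    for (i in i0:i1) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[j, i] <- ov
    }
    W[j, ] <- W[j, ] / sum(W[j, ])
  }
  W
}

#' Resample a 2D image to a new pixel grid by area averaging
#'
#' @param img numeric matrix.
#' @param out_r,out_c output numbers of rows / columns.
#' @return numeric matrix of size `out_r` x `out_c` covering the same
#'   physical extent as the input.
#' @keywords internal
resample_area <- function(img, out_r, out_c) {
  stopifnot(is.matrix(img), out_r >= 1, out_c >= 1)
  Wr <- area_weights(nrow(img), out_r)
  Wc <- area_weights(ncol(img), out_c)
  Wr %*% img %*% t(Wc)
}

# ---- geometric augmentation primitives (shared by both networks) ----------

shift_image <- function(img, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

flip_h <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# Nearest-neighbour rotation about the image centre (keeps masks binary).
rotate_image <- function(img, angle_deg, fill = 0) {
  if (angle_deg == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - cr; dc <- g$c - cc
  sr <- round(cos(th) * dr + sin(th) * dc + cr)
  sc <- round(-sin(th) * dr + cos(th) * dc + cc)
  out <- rep(fill, nr * nc)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  matrix(out, nr, nc)
}

# Re-crop to a different physical field of view, then resample back to the
# original pixel grid.  fov_scale > 1 zooms out (zero-padded), < 1 zooms in.
crop_fov <- function(img, fov_scale, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- max(2L, round(nr * fov_scale))
  pc <- max(2L, round(nc * fov_scale))
  big <- matrix(fill, pr, pc)
  r0 <- floor((pr - nr) / 2); c0 <- floor((pc - nc) / 2)
  rs <- (1 + max(0, r0)):(min(pr, r0 + nr))
  cs <- (1 + max(0, c0)):(min(pc, c0 + nc))
  big[rs, cs] <- img[rs - r0, cs - c0, drop = FALSE]
  resample_area(big, nr, nc)
}
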