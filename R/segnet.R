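#' Specification of the bone-segmentation network
#'
#' An encoder-decoder ("U"-shaped) network.  The encoder is identical in
#' layout to the age network's Down Blocks (two `3x3 conv -> elu -> bn`
#' units per block, 2x2 max-pooling, channel doubling) so that its learned
#' weights can initialize the age network.  The decoder mirrors the encoder
#' with 2x2 stride-2 transposed-convolution upsampling and skip
#' connections; a final 1x1 convolution produces per-pixel bone
#' probabilities (sigmoid).
#'
#' @inheritParams agenet_spec
#' @return an object of class `segnet_spec`.
#' @export
segnet_spec <- function(input_px = 224, n_blocks = 5, base_channels = 16,
                        block_dropout = 0.1) {
  stopifnot(input_px %% (2^n_blocks) == 0)
  channels <- base_channels * 2^(seq_len(n_blocks) - 1)
  structure(list(input_px = input_px, n_blocks = n_blocks,
                 channels = channels, block_dropout = block_dropout),
            class = "segnet_spec")
}

#' Build the segmentation network
#'
#' @param spec a [segnet_spec()].
#' @param seed seed for parameter initialization.
#' @return a `segnet` model with `par`, `stats` as for [build_agenet2d()];
#'   encoder parameters share the age network's naming so transfer is a
#'   name-for-name copy.
#' @export
build_segnet <- function(spec = segnet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "segnet_spec"))
  set.seed(seed)
  par <- list(); stats <- list()
  cin <- 1L
  for (d in seq_len(spec$n_blocks)) {
    ch <- spec$channels[d]
    for (u in 1:2) {
      ps <- init_unit(par, stats, sprintf("b%d.u%d", d, u), cin, ch)
      par <- ps$par; stats <- ps$stats
      cin <- ch
    }
  }
  # decoder: step at level d upsamples to the resolution of skip d
  below <- spec$channels[spec$n_blocks]
  for (d in rev(seq_len(spec$n_blocks))) {
    ch <- spec$channels[d]
    par[[sprintf("d%d.t.w", d)]] <-
      array(stats::rnorm(4 * below * ch, sd = sqrt(2 / (4 * below))),
            c(2, 2, below, ch))
    par[[sprintf("d%d.t.b", d)]] <- numeric(ch)
    cin2 <- 2L * ch
    for (u in 1:2) {
      ps <- init_unit(par, stats, sprintf("d%d.u%d", d, u), cin2, ch)
      par <- ps$par; stats <- ps$stats
      cin2 <- ch
    }
    below <- ch
  }
  par[["out.w"]] <- array(stats::rnorm(spec$channels[1],
                                       sd = sqrt(2 / spec$channels[1])),
                          c(1, 1, spec$channels[1], 1))
  par[["out.b"]] <- 0
  structure(list(spec = spec, par = par, stats = stats), class = "segnet")
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Forward pass producing per-pixel logits (H, W, N, 1).
segnet_forward <- function(model, x, train = FALSE, want_cache = train) {
  spec <- model$spec; par <- model$par; stats <- model$stats
  caches <- list(); newstats <- list(); skips <- list()
  note_stats <- function(pre, ns) {
    if (!is.null(ns)) {
      newstats[[paste0(pre, ".rm")]] <<- ns$rm
      newstats[[paste0(pre, ".rv")]] <<- ns$rv
    }
  }
  h <- x
  for (d in seq_len(spec$n_blocks)) {
    p <- spec$block_dropout * d
    for (u in 1:2) {
      pre <- sprintf("b%d.u%d", d, u)
      uf <- unit_fwd(par, stats, pre, h, p, train)
      h <- uf$y
      if (want_cache) caches[[pre]] <- uf$cache
      note_stats(pre, uf$newstats)
    }
    skips[[d]] <- h
    pf <- pool_fwd(h)
    if (want_cache) caches[[sprintf("pool%d", d)]] <-
      list(argmax = pf$argmax, in_dim = dim(h))
    h <- pf$y
  }
  for (d in rev(seq_len(spec$n_blocks))) {
    tw <- par[[sprintf("d%d.t.w", d)]]
    tb <- par[[sprintf("d%d.t.b", d)]]
    if (want_cache) caches[[sprintf("d%d.t", d)]] <- list(x = h)
    up <- .cpp_convt2_fwd(h, tw, tb)
    h <- cat_channels(up, skips[[d]])
    for (u in 1:2) {
      pre <- sprintf("d%d.u%d", d, u)
      uf <- unit_fwd(par, stats, pre, h, 0, train)
      h <- uf$y
      if (want_cache) caches[[pre]] <- uf$cache
      note_stats(pre, uf$newstats)
    }
  }
  if (want_cache) caches[["out"]] <- list(x = h)
  logits <- conv_fwd(h, par[["out.w"]], par[["out.b"]])
  list(logits = logits,
       cache = if (want_cache) caches else NULL,
       newstats = newstats)
}

segnet_backward <- function(model, cache, dlogits) {
  spec <- model$spec; par <- model$par
  grads <- list()
  cb <- conv_bwd(cache[["out"]]$x, par[["out.w"]], dlogits)
  grads[["out.w"]] <- cb$dw; grads[["out.b"]] <- cb$db
  dh <- cb$dx
  dskips <- vector("list", spec$n_blocks)
  for (d in seq_len(spec$n_blocks)) {        # reverse of decoder order
    for (u in 2:1) {
      pre <- sprintf("d%d.u%d", d, u)
      ub <- unit_bwd(par, pre, cache[[pre]], dh)
      dh <- ub$dx
      grads <- c(grads, ub$grads)
    }
    ch <- spec$channels[d]
    dup <- dh[, , , seq_len(ch), drop = FALSE]
    dskips[[d]] <- dh[, , , ch + seq_len(ch), drop = FALSE]
    tc <- cache[[sprintf("d%d.t", d)]]
    tb <- .cpp_convt2_bwd(tc$x, par[[sprintf("d%d.t.w", d)]], dup)
    grads[[sprintf("d%d.t.w", d)]] <- tb$dw
    grads[[sprintf("d%d.t.b", d)]] <- tb$db
    dh <- tb$dx
  }
  for (d in rev(seq_len(spec$n_blocks))) {
    pc <- cache[[sprintf("pool%d", d)]]
    dh <- pool_bwd(pc$argmax, dh, pc$in_dim) + dskips[[d]]
    for (u in 2:1) {
      pre <- sprintf("b%d.u%d", d, u)
      ub <- unit_bwd(par, pre, cache[[pre]], dh)
      dh <- ub$dx
      grads <- c(grads, ub$grads)
    }
  }
  grads
}

#' Predict a segmentation probability map or binary mask
#'
#' @param model trained `segnet`.
#' @param x array `(H, W, N)` of normalized slices or `(H, W, N, 1)`.
#' @param threshold probability cut for the binary mask; `NULL` returns
#'   probabilities.
#' @return array `(H, W, N)` of probabilities in `[0, 1]`, or 0/1 labels.
#' @export
predict_mask <- function(model, x, threshold = 0.5) {
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(dim(x), 1))
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  pr <- sigmoid(segnet_forward(model, x, train = FALSE,
                               want_cache = FALSE)$logits)
  pr <- if (was_matrix) pr[, , 1, 1] else array(pr, dim(pr)[c(1, 2, 3)])
  if (is.null(threshold)) pr else (pr > threshold) * 1
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b arrays of 0/1 labels with identical shape.
#' @return `2|A∩B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @export
dice_coef <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Segmentation training configuration
#'
#' Defaults: random 70/15/15 subject split, Adam with learning rate 1e-3,
#' combined binary cross-entropy + soft Dice loss, batch size 16, early
#' stopping on validation loss with patience 10.
#'
#' @param split_fractions train/val/test fractions (sum to 1).
#' @param learning_rate,batch_size,epochs,patience optimizer settings;
#'   `patience` is the early-stopping patience in epochs (Inf disables).
#' @param seed RNG seed.
#' @return a `seg_train_config` list.
#' @export
seg_train_config <- function(split_fractions = c(0.70, 0.15, 0.15),
                             learning_rate = 1e-3, batch_size = 16L,
                             epochs = 50L, patience = 10L, seed = 1L) {
  stopifnot(length(split_fractions) == 3,
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(split_fractions = split_fractions,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed)), class = "seg_train_config")
}

#' Random subject split for segmentation training
#'
#' Splits `n` samples into train/validation/test sets of sizes
#' `round(n * f_train)`, `round(n * f_val)` and the remainder.
#'
#' @param n number of samples (or a vector of sample ids).
#' @param config a [seg_train_config()] carrying the fractions and seed.
#' @return list of disjoint index vectors `train`, `val`, `test`.
#' @export
split_segmentation_data <- function(n, config = seg_train_config()) {
  ids <- if (length(n) == 1 && is.numeric(n)) seq_len(n) else n
  stopifnot(length(ids) >= 3)
  set.seed(config$seed)
  ord <- sample(ids)
  n_tr <- round(length(ids) * config$split_fractions[1])
  n_va <- round(length(ids) * config$split_fractions[2])
  stopifnot(n_tr >= 1, n_va >= 1, length(ids) - n_tr - n_va >= 1)
  list(train = sort(ord[seq_len(n_tr)]),
       val = sort(ord[n_tr + seq_len(n_va)]),
       test = sort(ord[(n_tr + n_va + 1):length(ids)]))
}

#' Paired geometric augmentation of a slice and its mask
#'
#' Applies the identical transform to image and mask: random in-plane
#' translations, random rotations, a horizontal flip, and re-crops at three
#' fields of view (110/130/150 mm relative to the standard 130 mm crop).
#' The untransformed pair is always first in the output.
#'
#' @param image,mask aligned matrices (mask in 0/1).
#' @param n_translate,n_rotate numbers of random draws per family.
#' @param flip include the horizontally flipped pair.
#' @param fov_scales numeric zoom factors for the crop family.
#' @param max_shift_px,max_rot_deg magnitudes of the random draws.
#' @param seed RNG seed.
#' @return list of `list(image, mask)` pairs; length
#'   `1 + n_translate + n_rotate + flip + length(fov_scales)`.
#' @export
augment_segmentation <- function(image, mask, n_translate = 1, n_rotate = 1,
                                 flip = TRUE,
                                 fov_scales = c(110, 130, 150) / 130,
                                 max_shift_px = 10, max_rot_deg = 10,
                                 seed = 1L) {
  stopifnot(all(dim(image) == dim(mask)))
  set.seed(seed)
  out <- list(list(image = image, mask = mask))
  for (i in seq_len(n_translate)) {
    dr <- sample(-max_shift_px:max_shift_px, 1)
    dc <- sample(-max_shift_px:max_shift_px, 1)
    out <- c(out, list(list(image = shift_image(image, dr, dc),
                            mask = shift_image(mask, dr, dc))))
  }
  for (i in seq_len(n_rotate)) {
    a <- stats::runif(1, -max_rot_deg, max_rot_deg)
    out <- c(out, list(list(image = rotate_image(image, a),
                            mask = rotate_image(mask, a))))
  }
  if (flip) out <- c(out, list(list(image = flip_h(image), mask = flip_h(mask))))
  for (s in fov_scales) {
    out <- c(out, list(list(image = crop_fov(image, s),
                            mask = (crop_fov(mask, s) > 0.5) * 1)))
  }
  out
}

#' Train the segmentation network
#'
#' Minimizes binary cross-entropy plus soft Dice loss with Adam; logs
#' per-epoch losses and returns the checkpoint with the lowest validation
#' loss, stopping early when validation loss has not improved for
#' `patience` epochs.
#'
#' @param model a `segnet`.
#' @param x array `(H, W, N, 1)` (or `(H, W, N)`) of normalized slices.
#' @param y matching binary masks.
#' @param x_val,y_val validation pairs.
#' @param config a [seg_train_config()].
#' @return trained model with `log` and `best_epoch` fields.
#' @export
train_segnet <- function(model, x, y, x_val, y_val,
                         config = seg_train_config()) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  if (length(dim(y)) == 3) y <- array(y, c(dim(y), 1))
  if (length(dim(x_val)) == 3) x_val <- array(x_val, c(dim(x_val), 1))
  if (length(dim(y_val)) == 3) y_val <- array(y_val, c(dim(y_val), 1))
  stopifnot(dim(x)[3] >= 1, dim(x_val)[3] >= 1,
            all(dim(x) == dim(y)[seq_along(dim(x))]))
  set.seed(config$seed)
  par <- model$par; stats <- model$stats
  opt <- adam_init(par)
  n <- dim(x)[3]
  best <- list(loss = Inf, par = par, stats = stats, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  stale <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (s in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      m <- list(spec = model$spec, par = par, stats = stats)
      fw <- segnet_forward(m, x[, , s, , drop = FALSE], train = TRUE)
      for (k in names(fw$newstats)) stats[[k]] <- fw$newstats[[k]]
      lg <- seg_loss_grad(fw$logits, y[, , s, , drop = FALSE])
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite segmentation loss at epoch %d", ep))
      }
      grads <- segnet_backward(m, fw$cache, lg$grad)
      st <- adam_step(par, grads, opt, config$learning_rate)
      par <- st$par; opt <- st$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    m <- structure(list(spec = model$spec, par = par, stats = stats),
                   class = "segnet")
    vl <- 0
    for (s in split(seq_len(dim(x_val)[3]),
                    ceiling(seq_len(dim(x_val)[3]) / config$batch_size))) {
      fv <- segnet_forward(m, x_val[, , s, , drop = FALSE], train = FALSE,
                           want_cache = FALSE)
      vl <- vl + seg_loss_grad(fv$logits, y_val[, , s, , drop = FALSE])$loss *
        length(s)
    }
    vl <- vl / dim(x_val)[3]
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, par = par, stats = stats, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  out <- model
  out$par <- best$par; out$stats <- best$stats
  out$log <- log; out$best_epoch <- best$epoch
  out
}

#' Fine-tune a coronal segmentation model on sagittal data
#'
#' Starts from the coronal checkpoint's weights (copied exactly, verified
#' shape-by-shape) and retrains for a small number of epochs (default 5).
#'
#' @param coronal_model trained `segnet`.
#' @param x,y,x_val,y_val sagittal training/validation pairs as in
#'   [train_segnet()].
#' @param epochs fine-tuning epochs.
#' @param config base [seg_train_config()]; its `epochs` is overridden.
#' @return fine-tuned `segnet`.
#' @export
finetune_sagittal <- function(coronal_model, x, y, x_val, y_val, epochs = 5L,
                              config = seg_train_config()) {
  config$epochs <- as.integer(epochs)
  config$patience <- Inf
  train_segnet(coronal_model, x, y, x_val, y_val, config)
}

#' Mask a volume to its age-relevant structures
#'
#' @param voi a `knee_volume` or numeric array.
#' @param mask binary array of identical shape.
#' @return the input with every voxel outside the mask set to zero and
#'   voxels inside unchanged.
#' @export
mask_volume <- function(voi, mask) {
  dat <- if (inherits(voi, "knee_volume")) voi$data else voi
  m <- if (inherits(mask, "knee_volume")) mask$data else mask
  if (!all(dim(dat) == dim(m))) stop("volume and mask shapes differ")
  out <- dat * (m != 0)
  if (inherits(voi, "knee_volume")) { voi$data <- out; voi } else out
}
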