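#' Architecture specification for the 2D age-regression network
#'
#' The network is a stack of "Down Blocks", each holding two
#' `3x3 conv -> elu -> batch-norm -> dropout` units followed by 2x2
#' max-pooling, with per-block channel doubling, followed by a head of
#' global average pooling, dropout (p = 0.5) and a single linear output
#' unit regressing age in years.  The block dropout rate grows with depth
#' d as `block_dropout * d`.  With the defaults (224 px input, five blocks,
#' base width 16 so the deepest convolutions carry 256 channels) the model
#' compresses 224^2 to 7^2 before pooling and holds 1.18 million trainable
#' parameters.
#'
#' @param input_px input image side length in pixels; must be divisible by
#'   `2^n_blocks`.
#' @param n_blocks number of Down Blocks (pooling stages).
#' @param base_channels channels of the first block; doubled per block.
#' @param block_dropout base dropout rate, multiplied by block depth.
#' @param head_dropout dropout rate before the fully-connected output.
#' @return an object of class `agenet_spec`.
#' @export
agenet_spec <- function(input_px = 224, n_blocks = 5, base_channels = 16,
                        block_dropout = 0.1, head_dropout = 0.5) {
  stopifnot(input_px %% (2^n_blocks) == 0, n_blocks >= 1, base_channels >= 1)
  channels <- base_channels * 2^(seq_len(n_blocks) - 1)
  structure(list(input_px = input_px, n_blocks = n_blocks,
                 channels = channels, block_dropout = block_dropout,
                 head_dropout = head_dropout,
                 final_px = input_px / 2^n_blocks),
            class = "agenet_spec")
}

#' Build the age-regression network
#'
#' Initializes all trainable parameters (He-normal convolution weights,
#' unit batch-norm scales, zero biases/shifts).
#'
#' @param spec an [agenet_spec()].
#' @param seed integer seed for the parameter initialization.
#' @param head_bias initial value of the output unit's bias.  Setting it to
#'   the training-set mean age starts the network at the best constant
#'   predictor, so short training budgets are spent on learning deviations
#'   rather than the output scale.
#' @return a model object (class `agenet`) with elements `spec`, `par`
#'   (flat named list of trainable arrays) and `stats` (batch-norm running
#'   moments, not trainable).
#' @export
build_agenet2d <- function(spec = agenet_spec(), seed = 1L, head_bias = 0) {
  stopifnot(inherits(spec, "agenet_spec"))
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
  cl <- spec$channels[spec$n_blocks]
  par[["head.w"]] <- matrix(stats::rnorm(cl, sd = sqrt(1 / cl)), cl, 1)
  par[["head.b"]] <- head_bias
  structure(list(spec = spec, par = par, stats = stats), class = "agenet")
}

#' Count trainable parameters of a network
#'
#' Convolution weights and biases, batch-norm scale/shift and the dense head
#' are trainable; batch-norm running statistics are not and are excluded.
#'
#' @param model an `agenet` or `segnet` model.
#' @return integer total count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$par, length, integer(1)))
}

# Forward pass.  x: array (H, W, N, 1).  Returns yhat (length N) and, when
# `want_cache`, everything needed for backprop plus the pre-GAP feature map.
agenet_forward <- function(model, x, train = FALSE, want_cache = train) {
  spec <- model$spec
  par <- model$par; stats <- model$stats
  caches <- list(); newstats <- list()
  h <- x
  for (d in seq_len(spec$n_blocks)) {
    p <- spec$block_dropout * d
    for (u in 1:2) {
      pre <- sprintf("b%d.u%d", d, u)
      uf <- unit_fwd(par, stats, pre, h, p, train)
      h <- uf$y
      if (want_cache) caches[[pre]] <- uf$cache
      if (!is.null(uf$newstats)) {
        newstats[[paste0(pre, ".rm")]] <- uf$newstats$rm
        newstats[[paste0(pre, ".rv")]] <- uf$newstats$rv
      }
    }
    pf <- pool_fwd(h)
    if (want_cache) caches[[sprintf("pool%d", d)]] <-
      list(argmax = pf$argmax, in_dim = dim(h))
    h <- pf$y
  }
  pre_gap_dim <- dim(h)
  feat <- gap_fwd(h)
  dof <- dropout_dense_fwd(feat, spec$head_dropout, train)
  yhat <- as.numeric(dense_fwd(dof$y, par[["head.w"]], par[["head.b"]]))
  list(yhat = yhat,
       pre_gap_dim = pre_gap_dim,
       cache = if (want_cache) list(caches = caches, feat = dof$y,
                                    head_mask = dof$mask,
                                    pre_gap_dim = pre_gap_dim) else NULL,
       newstats = newstats)
}

agenet_backward <- function(model, cache, dyhat) {
  spec <- model$spec; par <- model$par
  grads <- list()
  dyhat <- matrix(dyhat, ncol = 1)
  grads[["head.w"]] <- t(cache$feat) %*% dyhat
  grads[["head.b"]] <- sum(dyhat)
  dfeat <- dyhat %*% t(par[["head.w"]])
  if (!is.null(cache$head_mask)) dfeat <- dfeat * cache$head_mask
  dh <- gap_bwd(dfeat, cache$pre_gap_dim)
  for (d in rev(seq_len(spec$n_blocks))) {
    pc <- cache$caches[[sprintf("pool%d", d)]]
    dh <- pool_bwd(pc$argmax, dh, pc$in_dim)
    for (u in 2:1) {
      pre <- sprintf("b%d.u%d", d, u)
      ub <- unit_bwd(par, pre, cache$caches[[pre]], dh)
      dh <- ub$dx
      grads <- c(grads, ub$grads)
    }
  }
  grads
}

#' Predict per-slice ages
#'
#' Runs the network in inference mode (dropout off, batch-norm running
#' statistics) over the slices of one subject's slice stack.
#'
#' @param model trained `agenet` model.
#' @param stack a `slice_stack` (see [reduce_volume()]) or an array
#'   `(H, W, n_slices)`.
#' @param expected_slices required stack length (default 12); a stack of a
#'   different length is an error.
#' @return numeric vector of one predicted age (years) per slice, in order.
#' @export
predict_slice_ages <- function(model, stack, expected_slices = 12L) {
  sl <- if (inherits(stack, "slice_stack")) stack$slices else stack
  stopifnot(length(dim(sl)) == 3)
  if (dim(sl)[3] != expected_slices) {
    stop("expected a stack of ", expected_slices, " slices, got ",
         dim(sl)[3])
  }
  x <- array(sl, c(dim(sl)[1], dim(sl)[2], dim(sl)[3], 1))
  agenet_forward(model, x, train = FALSE, want_cache = FALSE)$yhat
}

# Batched inference for arbitrary (H, W, N, 1) arrays.
agenet_predict <- function(model, x, batch = 32L) {
  n <- dim(x)[3]
  out <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    out[s] <- agenet_forward(model, x[, , s, , drop = FALSE],
                             train = FALSE, want_cache = FALSE)$yhat
  }
  out
}

#' Training configuration for the age-regression network
#'
#' Defaults follow the pipeline's training recipe: Adam with learning rate
#' 1e-4 (reduced from Adam's 1e-3 default because training usually starts
#' from transfer-initialized weights), mean-squared-error loss, batch size
#' 16 and 1000 epochs.  No early stopping is applied; the checkpoint with
#' the lowest validation loss is returned.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param seed seed controlling shuffling, dropout and any augmentation.
#' @return an `age_train_config` list.
#' @export
age_train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                             epochs = 1000L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "age_train_config")
}

#' Train the age-regression network
#'
#' Minimizes the mean squared error between predicted and chronological age
#' over all training slices (each slice of a subject carries the subject's
#' age).  Logs per-epoch training and validation loss and returns the
#' parameters of the epoch with the lowest validation loss.
#'
#' @param model an `agenet` model (typically transfer-initialized).
#' @param x training slices, array `(H, W, N, 1)`.
#' @param y length-N chronological ages (years).
#' @param x_val,y_val validation set in the same layout.
#' @param config an [age_train_config()].
#' @return the model with trained parameters plus a `log` data frame
#'   (epoch, train_loss, val_loss) and `best_epoch`.
#' @export
train_agenet <- function(model, x, y, x_val, y_val,
                         config = age_train_config()) {
  stopifnot(dim(x)[3] == length(y), dim(x_val)[3] == length(y_val))
  set.seed(config$seed)
  par <- model$par; stats <- model$stats
  opt <- adam_init(par)
  n <- length(y)
  best <- list(loss = Inf, par = par, stats = stats, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (s in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      m <- list(spec = model$spec, par = par, stats = stats)
      fw <- agenet_forward(m, x[, , s, , drop = FALSE], train = TRUE)
      for (k in names(fw$newstats)) stats[[k]] <- fw$newstats[[k]]
      lg <- mse_loss_grad(y[s], fw$yhat)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", ep))
      }
      grads <- agenet_backward(m, fw$cache, lg$grad)
      st <- adam_step(par, grads, opt, config$learning_rate)
      par <- st$par; opt <- st$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    m <- list(spec = model$spec, par = par, stats = stats)
    vp <- agenet_predict(structure(m, class = "agenet"), x_val)
    vl <- mean((vp - y_val)^2)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, par = par, stats = stats,
                                     epoch = ep)
  }
  out <- model
  out$par <- best$par; out$stats <- best$stats
  out$log <- log; out$best_epoch <- best$epoch
  out
}

#' Initialize the age network from a trained segmentation encoder
#'
#' Copies every encoder parameter (convolution weights/biases, batch-norm
#' scale/shift and running moments) from the segmentation checkpoint into
#' the age network; the dense head keeps its fresh initialization.
#'
#' @param model an `agenet` model.
#' @param seg_model a trained `segnet` whose encoder blocks match the
#'   age network's blocks (same depth and channel plan).
#' @return the transfer-initialized `agenet` model.
#' @export
transfer_init <- function(model, seg_model) {
  enc <- grep("^b\\d+\\.u\\d+\\.", names(model$par), value = TRUE)
  missing <- setdiff(enc, names(seg_model$par))
  if (length(missing) > 0) {
    stop("segmentation checkpoint lacks encoder parameters: ",
         paste(missing, collapse = ", "))
  }
  for (k in enc) {
    if (!identical(dim(model$par[[k]]), dim(seg_model$par[[k]])) &&
        length(model$par[[k]]) != length(seg_model$par[[k]])) {
      stop("incompatible shape for ", k)
    }
    model$par[[k]] <- seg_model$par[[k]]
  }
  for (k in grep("^b\\d+\\.u\\d+\\.", names(model$stats), value = TRUE)) {
    model$stats[[k]] <- seg_model$stats[[k]]
  }
  model
}

#' Age-stratified subject split
#'
#' Partitions subjects into train/validation/test sets so that each set's
#' age distribution mirrors the cohort's (stratified by age bins), and the
#' training set spans the full age range (the youngest and oldest subjects
#' are always assigned to training).
#'
#' @param ages numeric vector of chronological ages (years).
#' @param fractions length-3 target fractions (train, val, test);
#'   defaults c(0.63, 0.18, 0.19).
#' @param bin_width stratification bin width in years.
#' @param seed RNG seed.
#' @return a `split_plan`: list with integer index vectors `train`, `val`,
#'   `test` and the bin assignment `bins`.
#' @export
age_stratified_split <- function(ages, fractions = c(0.63, 0.18, 0.19),
                                 bin_width = 1, seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0), length(ages) >= 3)
  set.seed(seed)
  bins <- floor(ages / bin_width)
  idx <- list(train = integer(), val = integer(), test = integer())
  for (b in sort(unique(bins))) {
    ib <- which(bins == b)
    ib <- ib[sample.int(length(ib))]
    nb <- length(ib)
    n_tr <- round(nb * fractions[1])
    n_va <- round(nb * fractions[2])
    n_tr <- min(n_tr, nb); n_va <- min(n_va, nb - n_tr)
    idx$train <- c(idx$train, ib[seq_len(n_tr)])
    idx$val <- c(idx$val, ib[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, ib[n_tr + n_va + seq_len(nb - n_tr - n_va)])
  }
  # training must cover the full age range
  for (i in c(which.min(ages), which.max(ages))) {
    if (!(i %in% idx$train)) {
      from <- if (i %in% idx$val) "val" else "test"
      # swap with a same-bin training subject when possible, else just move
      mates <- idx$train[bins[idx$train] == bins[i]]
      idx[[from]] <- setdiff(idx[[from]], i)
      if (length(mates) > 0) idx[[from]] <- c(idx[[from]], mates[1])
      idx$train <- c(setdiff(idx$train, mates[1]), i)
    }
  }
  structure(list(train = sort(idx$train), val = sort(idx$val),
                 test = sort(idx$test), bins = bins,
                 fractions = fractions), class = "split_plan")
}

#' Age-stratified training augmentation
#'
#' Balances the training set by augmenting only images from under-represented
#' age bins: each such image gains two additional fields of view (zoomed
#' re-crops), one horizontal translation and one rotation, with the age label
#' copied unchanged.  Bins at or above the count threshold are untouched.
#'
#' @param images array `(H, W, N)` of training slices.
#' @param ages length-N ages (years); slices of one subject share its age.
#' @param count_threshold bins with fewer images than this are augmented;
#'   default is the median bin count.
#' @param bin_width stratification bin width (years).
#' @param fov_scales two zoom factors for the extra fields of view.
#' @param max_shift_px,max_rot_deg augmentation magnitudes.
#' @param seed RNG seed.
#' @return list with augmented `images` array and `ages` vector (originals
#'   first, in input order).
#' @export
augment_age_stratified <- function(images, ages, count_threshold = NULL,
                                   bin_width = 1,
                                   fov_scales = c(110 / 130, 150 / 130),
                                   max_shift_px = 10, max_rot_deg = 10,
                                   seed = 1L) {
  stopifnot(length(dim(images)) == 3, dim(images)[3] == length(ages),
            length(ages) >= 1)
  set.seed(seed)
  bins <- floor(ages / bin_width)
  cnt <- table(bins)
  if (is.null(count_threshold)) count_threshold <- stats::median(cnt)
  low_bins <- as.numeric(names(cnt)[cnt < count_threshold])
  extra_imgs <- list(); extra_ages <- numeric()
  for (i in seq_along(ages)) {
    if (!(bins[i] %in% low_bins)) next
    img <- images[, , i]
    aug <- c(lapply(fov_scales, function(s) crop_fov(img, s)),
             list(shift_image(img, 0,
                              sample(-max_shift_px:max_shift_px, 1)),
                  rotate_image(img, stats::runif(1, -max_rot_deg, max_rot_deg))))
    extra_imgs <- c(extra_imgs, aug)
    extra_ages <- c(extra_ages, rep(ages[i], length(aug)))
  }
  n_extra <- length(extra_imgs)
  out <- array(0, c(dim(images)[1], dim(images)[2], dim(images)[3] + n_extra))
  out[, , seq_len(dim(images)[3])] <- images
  for (j in seq_len(n_extra)) out[, , dim(images)[3] + j] <- extra_imgs[[j]]
  list(images = out, ages = c(ages, extra_ages))
}
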