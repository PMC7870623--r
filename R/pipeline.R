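# End-to-end orchestration: phantom cohort -> preprocessing -> segmentation
# -> masking -> slice reduction -> age network -> aggregation -> repeated
# stratified cross-validation.  Stage outputs are persisted under the run
# directory with a manifest keyed by (stage, config hash, seed) so a run can
# resume from any completed stage.

#' Pipeline configuration
#'
#' `desk_scale = TRUE` switches every stage to a small geometry suited to a
#' laptop CPU: 96-voxel phantom grids at ~1.5 mm spacing, 64 px network
#' inputs with three Down Blocks of base width 8, and short training
#' budgets.  The default (`desk_scale = FALSE`) keeps the full geometry
#' (448 px standardization, 224 px inputs, five blocks to 256 channels,
#' 1000 training epochs).
#'
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @param out_dir run directory for artifacts and the manifest.
#' @param desk_scale use the reduced geometry.
#' @param n_subjects phantom cohort size.
#' @param phantom,preprocess,reduction stage configurations; sensible
#'   defaults are derived from `desk_scale` when `NULL`.
#' @param seg_epochs,age_epochs training budgets.
#' @param cv_k,cv_repeats cross-validation folds and repeats.
#' @param use_masking mask slices with the segmentation output (set FALSE
#'   to run the ablation on raw slices).
#' @param use_truth_masks use the phantom ground-truth masks instead of the
#'   trained segmentation network (isolates the age network from
#'   segmentation error).
#' @param augment_training apply age-stratified training augmentation.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("kneeage_run_"),
                            desk_scale = FALSE, n_subjects = 60L,
                            phantom = NULL, preprocess = NULL,
                            reduction = reduction_config(),
                            seg_epochs = if (desk_scale) 6L else 50L,
                            age_epochs = if (desk_scale) 10L else 1000L,
                            cv_k = 5L, cv_repeats = if (desk_scale) 1L else 10L,
                            use_masking = TRUE, use_truth_masks = FALSE,
                            augment_training = TRUE) {
  if (is.null(phantom)) {
    phantom <- if (desk_scale) {
      phantom_config(seed = seed, n_subjects = n_subjects,
                     grid_shape = c(96L, 96L, 20L),
                     in_plane_spacing_mm = c(1.4, 1.7),
                     slice_spacing_mm = c(3.0, 5.0),
                     pose_jitter_px = 4)
    } else {
      phantom_config(seed = seed, n_subjects = n_subjects)
    }
  }
  if (is.null(preprocess)) {
    preprocess <- if (desk_scale) {
      preprocess_config(standard_inplane_px = 96L, net_input_px = 64L)
    } else {
      preprocess_config()
    }
  }
  net <- if (desk_scale) list(n_blocks = 3L, base_channels = 8L)
         else list(n_blocks = 5L, base_channels = 16L)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 desk_scale = desk_scale, phantom = phantom,
                 preprocess = preprocess, reduction = reduction,
                 net = net, seg_epochs = as.integer(seg_epochs),
                 age_epochs = as.integer(age_epochs),
                 cv_k = as.integer(cv_k),
                 cv_repeats = as.integer(cv_repeats),
                 use_masking = use_masking,
                 use_truth_masks = use_truth_masks,
                 augment_training = augment_training),
            class = "pipeline_config")
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, manifest_path(out_dir), auto_unbox = TRUE)
}

# run `fun` unless the manifest already records this (stage, key) and the
# artifact exists; artifacts are stored as RDS under the run directory.
stage_cached <- function(config, stage, key, fun) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- read_manifest(config$out_dir)
  art <- file.path(config$out_dir, paste0(stage, ".rds"))
  entry <- man[[stage]]
  if (!is.null(entry) && identical(entry$key, key) && file.exists(art)) {
    return(readRDS(art))
  }
  t0 <- Sys.time()
  out <- fun()
  saveRDS(out, art)
  man[[stage]] <- list(key = key, seed = config$seed,
                       seconds = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                       written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_manifest(config$out_dir, man)
  out
}

cfg_key <- function(...) rlang::hash(list(...))

# preprocess + (optionally) segment + mask + reduce one cohort into per-
# subject slice stacks at network resolution.
prepare_stacks <- function(samples, config, seg_model = NULL,
                           masked = TRUE) {
  pp <- config$preprocess
  template <- make_template_patch(config$phantom$orientation, config$phantom)
  stacks <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pre <- preprocess_volume(s$volume, template, pp)
    slices <- voi_to_net_slices(pre$voi, pp$net_input_px)
    if (masked) {
      if (config$use_truth_masks || is.null(seg_model)) {
        mvol <- knee_volume(s$truth_mask * 1, s$volume$spacing_mm,
                            s$volume$orientation)
        mstd <- standardize_inplane(mvol, pp$standard_inplane_px)
        mvoi <- extract_voi(mstd, pre$match$center_px, pp$voi_extent_mm)
        msk <- voi_to_net_slices(mvoi, pp$net_input_px, normalize = FALSE)
        msk <- (msk > 0.5) * 1
      } else {
        msk <- predict_mask(seg_model, array(slices, c(dim(slices), 1)))
      }
      slices <- slices * msk
    }
    stacks[[i]] <- reduce_volume(slices, config$reduction)
  }
  stacks
}

# train the segmentation network on a 70/15/15 subject split using central
# slices and ground-truth masks at network resolution.
train_pipeline_segnet <- function(samples, config) {
  pp <- config$preprocess
  template <- make_template_patch(config$phantom$orientation, config$phantom)
  imgs <- list(); msks <- list()
  for (s in samples) {
    pre <- preprocess_volume(s$volume, template, pp)
    sl <- voi_to_net_slices(pre$voi, pp$net_input_px)
    mvol <- knee_volume(s$truth_mask * 1, s$volume$spacing_mm,
                        s$volume$orientation)
    mstd <- standardize_inplane(mvol, pp$standard_inplane_px)
    mvoi <- extract_voi(mstd, pre$match$center_px, pp$voi_extent_mm)
    mm <- voi_to_net_slices(mvoi, pp$net_input_px, normalize = FALSE)
    mid <- ceiling(dim(sl)[3] / 2)
    for (k in mid + c(-1L, 0L, 1L)) {
      if (k < 1 || k > dim(sl)[3]) next
      imgs[[length(imgs) + 1]] <- sl[, , k]
      msks[[length(msks) + 1]] <- (mm[, , k] > 0.5) * 1
    }
  }
  n <- length(imgs)
  scfg <- seg_train_config(epochs = config$seg_epochs,
                           seed = config$seed + 11L)
  sp <- split_segmentation_data(n, scfg)
  to_arr <- function(ix) {
    a <- array(0, c(dim(imgs[[1]]), length(ix)))
    for (j in seq_along(ix)) a[, , j] <- imgs[[ix[j]]]
    a
  }
  to_arr_m <- function(ix) {
    a <- array(0, c(dim(msks[[1]]), length(ix)))
    for (j in seq_along(ix)) a[, , j] <- msks[[ix[j]]]
    a
  }
  model <- build_segnet(segnet_spec(input_px = config$preprocess$net_input_px,
                                    n_blocks = config$net$n_blocks,
                                    base_channels = config$net$base_channels),
                        seed = config$seed + 12L)
  train_segnet(model, to_arr(sp$train), to_arr_m(sp$train),
               to_arr(sp$val), to_arr_m(sp$val), scfg)
}

# slices + per-slice age labels for a set of subjects
stack_training_set <- function(stacks, ages, idx) {
  hw <- dim(stacks[[1]]$slices)[1:2]
  ns <- dim(stacks[[1]]$slices)[3]
  x <- array(0, c(hw[1], hw[2], length(idx) * ns))
  y <- numeric(length(idx) * ns)
  for (j in seq_along(idx)) {
    x[, , (j - 1) * ns + seq_len(ns)] <- stacks[[idx[j]]]$slices
    y[(j - 1) * ns + seq_len(ns)] <- ages[idx[j]]
  }
  list(x = x, y = y)
}

# the subject-level predictor handed to run_cv: trains the age network and
# the aggregators on the training subjects, predicts the test subjects.
pipeline_predictor <- function(stacks, ages, config, seg_model = NULL) {
  force(stacks); force(ages); force(config)
  function(train_idx, test_idx, seed) {
    ss <- age_stratified_split(ages[train_idx], seed = seed)
    fit_sub <- train_idx[c(ss$train, ss$test)]
    val_sub <- train_idx[ss$val]
    if (length(val_sub) == 0) {       # tiny folds: hold out one subject
      val_sub <- fit_sub[length(fit_sub)]
      fit_sub <- fit_sub[-length(fit_sub)]
    }
    tr <- stack_training_set(stacks, ages, fit_sub)
    va <- stack_training_set(stacks, ages, val_sub)
    if (config$augment_training) {
      aug <- augment_age_stratified(tr$x, tr$y, seed = seed + 1L)
      tr <- list(x = aug$images, y = aug$ages)
    }
    spec <- agenet_spec(input_px = dim(tr$x)[1],
                        n_blocks = config$net$n_blocks,
                        base_channels = config$net$base_channels)
    model <- build_agenet2d(spec, seed = seed, head_bias = mean(tr$y))
    if (!is.null(seg_model)) model <- transfer_init(model, seg_model)
    # short budgets keep Adam's default step size; the reduced fine-tuning
    # rate only pays off over the full 1000-epoch schedule
    lr <- if (config$age_epochs < 100) 1e-3 else 1e-4
    model <- train_agenet(model,
                          array(tr$x, c(dim(tr$x), 1)), tr$y,
                          array(va$x, c(dim(va$x), 1)), va$y,
                          age_train_config(learning_rate = lr,
                                           epochs = config$age_epochs,
                                           seed = seed))
    feat <- function(idx) {
      t(vapply(idx, function(i) {
        predict_slice_ages(model, stacks[[i]],
                           config$reduction$target_slices)
      }, numeric(config$reduction$target_slices)))
    }
    f_train <- feat(train_idx)
    f_test <- feat(test_idx)
    reg <- fit_age_regressor(f_train, ages[train_idx],
                             aggregator_spec("regression", seed = seed))
    minor_train <- ages[train_idx] < MINOR_AGE_LIMIT
    out <- list(age = predict_age(reg, f_test))
    if (length(unique(minor_train)) == 2) {
      clf <- fit_minor_classifier(f_train, minor_train,
                                  aggregator_spec("classification",
                                                  seed = seed))
      pm <- predict_minor(clf, f_test)
      out$score <- pm$score
      out$minor <- pm$minor
    }
    out
  }
}

#' Run the full pipeline end to end
#'
#' Generates (or resumes) a phantom cohort, preprocesses every volume,
#' trains the segmentation network, masks and reduces the volumes to slice
#' stacks, and evaluates the age network plus aggregators under repeated
#' stratified k-fold cross-validation.  All stage outputs land in
#' `config$out_dir` with a manifest recording config hashes, seeds and
#' timings; rerunning with the same configuration reuses completed stages.
#'
#' @param config a [pipeline_config()].
#' @return list with `report` (a `metrics_report`), `fold_plan`, `ages`,
#'   and the run directory `out_dir`.
#' @export
run_end_to_end <- function(config = pipeline_config(desk_scale = TRUE)) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- stage_cached(config, "cohort", cfg_key(config$phantom),
                          function() generate_cohort(config$phantom))
  ages <- cohort_ages(samples)
  seg_model <- NULL
  if (config$use_masking && !config$use_truth_masks) {
    seg_model <- stage_cached(
      config, "segnet",
      cfg_key(config$phantom, config$preprocess, config$net,
              config$seg_epochs, config$seed),
      function() train_pipeline_segnet(samples, config))
  }
  stacks <- stage_cached(
    config, "stacks",
    cfg_key(config$phantom, config$preprocess, config$reduction,
            config$net, config$use_masking, config$use_truth_masks,
            config$seg_epochs, config$seed),
    function() prepare_stacks(samples, config, seg_model,
                              masked = config$use_masking))
  plan <- make_repeated_stratified_folds(ages, k = config$cv_k,
                                         repeats = config$cv_repeats,
                                         seed = config$seed)
  report <- stage_cached(
    config, "cv_report", cfg_key(config, "cv"),
    function() run_cv(ages, plan,
                      pipeline_predictor(stacks, ages, config, seg_model)))
  list(report = report, fold_plan = plan, ages = ages,
       out_dir = config$out_dir)
}
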