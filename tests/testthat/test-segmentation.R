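# small helper: slice/mask training pairs from the shared phantom cohort
seg_pairs <- function(n_subjects = 6) {
  co <- fixture_cohort()[seq_len(n_subjects)]
  cfg <- desk_preprocess_config()
  tpl <- make_template_patch("coronal", desk_phantom_config())
  imgs <- list(); msks <- list()
  for (s in co) {
    pre <- preprocess_volume(s$volume, tpl, cfg)
    sl <- voi_to_net_slices(pre$voi, 64L)
    mvol <- knee_volume(s$truth_mask * 1, s$volume$spacing_mm, "coronal")
    mstd <- standardize_inplane(mvol, 96L)
    mvoi <- extract_voi(mstd, pre$match$center_px, 130)
    mm <- voi_to_net_slices(mvoi, 64L, normalize = FALSE)
    mid <- ceiling(dim(sl)[3] / 2)
    imgs[[length(imgs) + 1]] <- sl[, , mid]
    msks[[length(msks) + 1]] <- (mm[, , mid] > 0.5) * 1
  }
  x <- array(unlist(imgs), c(64, 64, length(imgs)))
  y <- array(unlist(msks), c(64, 64, length(msks)))
  list(x = x, y = y)
}

test_that("masking conserves intensities inside and zeroes outside", {
  set.seed(1)
  voi <- array(runif(8 * 8 * 3, 0.1, 1), c(8, 8, 3))
  mask <- array(rbinom(8 * 8 * 3, 1, 0.4), c(8, 8, 3))
  out <- mask_volume(voi, mask)
  expect_identical(out == 0, mask == 0)
  expect_identical(out[mask == 1], voi[mask == 1])
  expect_identical(mask_volume(voi, array(1, dim(voi))), voi)
  expect_true(all(mask_volume(voi, array(0, dim(voi))) == 0))
  expect_error(mask_volume(voi, mask[, , 1:2]), "shapes differ")
})

test_that("segmentation split sizes follow the rounding rule", {
  sp100 <- split_segmentation_data(100, seg_train_config(seed = 1))
  expect_equal(lengths(sp100[c("train", "val", "test")]),
               c(train = 70L, val = 15L, test = 15L))
  sp20 <- split_segmentation_data(20, seg_train_config(seed = 2))
  expect_equal(lengths(sp20[c("train", "val", "test")]),
               c(train = 14L, val = 3L, test = 3L))
  # partition: union is the input set, pairwise disjoint
  all_idx <- sort(c(sp20$train, sp20$val, sp20$test))
  expect_equal(all_idx, 1:20)
  expect_identical(split_segmentation_data(20, seg_train_config(seed = 2)),
                   sp20)
})

test_that("augmentation applies identical transforms to image and mask", {
  set.seed(5)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[8:20, 10:24] <- 1
  pairs <- augment_segmentation(img, msk, seed = 3)
  # 1 original + 1 translate + 1 rotate + 1 flip + 3 crops
  expect_length(pairs, 7)
  expect_identical(pairs[[1]]$image, img)
  # horizontal flip applied twice is the identity
  fl <- kneeage:::flip_h(img)
  expect_identical(kneeage:::flip_h(fl), img)
  # rotation by zero degrees is the identity
  expect_identical(kneeage:::rotate_image(img, 0), img)
  # image/mask stay synchronized: for every augmented pair, the mask is the
  # transform of the original mask under the same parameters.  The translated
  # pair is checked explicitly by replaying the seeded draw.
  set.seed(3)
  dr <- sample(-10:10, 1); dc <- sample(-10:10, 1)
  expect_identical(pairs[[2]]$image, kneeage:::shift_image(img, dr, dc))
  expect_identical(pairs[[2]]$mask, kneeage:::shift_image(msk, dr, dc))
  # flipped pair
  expect_identical(pairs[[4]]$image, kneeage:::flip_h(img))
  expect_identical(pairs[[4]]$mask, kneeage:::flip_h(msk))
})

test_that("augmented pair counts follow the configured families", {
  img <- matrix(runif(16 * 16), 16, 16)
  msk <- (img > 0.5) * 1
  p <- augment_segmentation(img, msk, n_translate = 2, n_rotate = 3,
                            flip = FALSE, fov_scales = c(0.8, 1.2), seed = 1)
  expect_length(p, 1 + 2 + 3 + 0 + 2)
  # fixed seed reproduces the same augmented set
  p2 <- augment_segmentation(img, msk, n_translate = 2, n_rotate = 3,
                             flip = FALSE, fov_scales = c(0.8, 1.2), seed = 1)
  expect_identical(p, p2)
})

test_that("an untrained network outputs per-pixel probabilities of input shape", {
  sm <- build_segnet(segnet_spec(32, 2, 4), seed = 1)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  pr <- predict_mask(sm, x, threshold = NULL)
  expect_equal(dim(pr), c(32, 32, 2))
  expect_true(all(pr > 0 & pr < 1))
  hard <- predict_mask(sm, x)
  expect_true(all(hard %in% c(0, 1)))
})

test_that("the network can overfit a single slice", {
  pr <- seg_pairs(2)
  x <- pr$x[, , 1, drop = FALSE]; y <- pr$y[, , 1, drop = FALSE]
  sm <- build_segnet(segnet_spec(64, 3, 8), seed = 2)
  sm <- train_segnet(sm, x, y, x, y,
                     seg_train_config(epochs = 100, patience = Inf, seed = 2))
  d <- dice_coef(predict_mask(sm, x[, , 1]), y[, , 1])
  expect_gt(d, 0.95)
})

test_that("training on a few phantom slices generalizes (held-out Dice)", {
  pr <- seg_pairs(8)
  tr <- 1:5; va <- 6; te <- 7:8
  sm <- build_segnet(segnet_spec(64, 3, 8), seed = 3)
  sm <- train_segnet(sm, pr$x[, , tr], pr$y[, , tr],
                     pr$x[, , va, drop = FALSE], pr$y[, , va, drop = FALSE],
                     seg_train_config(epochs = 25, patience = 10, seed = 3))
  dice <- mean(vapply(te, function(i) {
    dice_coef(predict_mask(sm, pr$x[, , i]), pr$y[, , i])
  }, numeric(1)))
  expect_gt(dice, 0.8)
  # beats the trivial all-background predictor
  expect_gt(dice, mean(vapply(te, function(i) {
    dice_coef(array(0, c(64, 64)), pr$y[, , i])
  }, numeric(1))))
  # training log supports loss-curve diagnostics
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(sm$log)))
  assign("trained_segnet", sm, envir = .fixture_env)
})

test_that("sagittal fine-tuning starts from the coronal weights exactly", {
  sm <- get0("trained_segnet", envir = .fixture_env)
  skip_if(is.null(sm), "coronal model not available")
  pr <- seg_pairs(4)
  # zero learning rate isolates the initialization contract
  frozen <- finetune_sagittal(sm, pr$x[, , 1:2], pr$y[, , 1:2],
                              pr$x[, , 3, drop = FALSE],
                              pr$y[, , 3, drop = FALSE],
                              epochs = 1,
                              config = seg_train_config(learning_rate = 0,
                                                        seed = 4))
  for (k in names(sm$par)) expect_identical(frozen$par[[k]], sm$par[[k]])
  # default fine-tuning budget is 5 epochs
  expect_equal(formals(finetune_sagittal)$epochs, 5L)
})

test_that("fine-tuning on sagittal phantoms does not hurt sagittal Dice", {
  sm <- get0("trained_segnet", envir = .fixture_env)
  skip_if(is.null(sm), "coronal model not available")
  cfg <- desk_phantom_config(seed = 31, n_subjects = 6,
                             orientation = "sagittal")
  co <- generate_cohort(cfg)
  tpl <- make_template_patch("sagittal", cfg)
  pcfg <- desk_preprocess_config()
  imgs <- array(0, c(64, 64, 6)); msks <- array(0, c(64, 64, 6))
  for (i in seq_along(co)) {
    pre <- preprocess_volume(co[[i]]$volume, tpl, pcfg)
    sl <- voi_to_net_slices(pre$voi, 64L)
    mvol <- knee_volume(co[[i]]$truth_mask * 1, co[[i]]$volume$spacing_mm,
                        "sagittal")
    mvoi <- extract_voi(standardize_inplane(mvol, 96L), pre$match$center_px,
                        130)
    mm <- voi_to_net_slices(mvoi, 64L, normalize = FALSE)
    mid <- ceiling(dim(sl)[3] / 2)
    imgs[, , i] <- sl[, , mid]
    msks[, , i] <- (mm[, , mid] > 0.5) * 1
  }
  dice_with <- function(model) {
    mean(vapply(5:6, function(i) {
      dice_coef(predict_mask(model, imgs[, , i]), msks[, , i])
    }, numeric(1)))
  }
  before <- dice_with(sm)
  ft <- finetune_sagittal(sm, imgs[, , 1:3], msks[, , 1:3],
                          imgs[, , 4, drop = FALSE],
                          msks[, , 4, drop = FALSE],
                          config = seg_train_config(seed = 5))
  expect_equal(nrow(ft$log), 5)   # exactly the requested epochs
  expect_gte(dice_with(ft) + 0.02, before)
})
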