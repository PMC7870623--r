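flat_phantom <- function(dim3 = c(40, 40, 6), fg = 1) {
  x <- array(0.05, dim3)
  x[10:30, 10:30, ] <- fg
  knee_volume(x, c(1, 1, 3), "coronal")
}

poly_bias <- function(dim3, strength = 0.4) {
  u <- seq(-1, 1, length.out = dim3[1])
  v <- seq(-1, 1, length.out = dim3[2])
  w <- seq(-1, 1, length.out = dim3[3])
  f <- outer(outer(0.8 * u + 0.5 * u^2, -0.6 * v + 0.3 * v^2, `+`),
             0.4 * w, `+`)
  1 + strength * (f - mean(f)) / max(abs(f - mean(f)))
}

test_that("bias correction leaves unbiased volumes essentially unchanged", {
  v <- flat_phantom()
  out <- correct_bias(v)
  fg <- v$data > mean(v$data)
  expect_lt(max(abs(out$volume$data[fg] - v$data[fg]) / v$data[fg]), 0.01)
  # disabled correction is an exact no-op
  off <- correct_bias(v, preprocess_config(bfc_enabled = FALSE))
  expect_identical(off$volume$data, v$data)
  expect_error(correct_bias(knee_volume(array(0, c(8, 8, 2)), c(1, 1, 1))),
               "degenerate")
})

test_that("bias correction reduces foreground variation and recovers the field", {
  v <- flat_phantom(c(48, 48, 8))
  field <- poly_bias(dim(v$data))
  biased <- knee_volume(v$data * field, v$spacing_mm, v$orientation)
  out <- correct_bias(biased)
  fg <- v$data > mean(v$data)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(out$volume$data[fg]), cv(biased$data[fg]))
  expect_gt(stats::cor(as.numeric(out$field[fg]), as.numeric(field[fg])),
            0.9)
})

test_that("in-plane standardization hits the target grid and keeps extent", {
  v512 <- knee_volume(array(stats::runif(512 * 512 * 4), c(512, 512, 4)),
                      c(0.3, 0.3, 4), "coronal")
  s <- standardize_inplane(v512, 448)
  expect_equal(dim(s$data), c(448, 448, 4))
  expect_equal(s$spacing_mm[1] * 448, 0.3 * 512)   # physical extent kept
  expect_equal(s$spacing_mm[3], 4)

  v800 <- knee_volume(array(stats::runif(800 * 800 * 3), c(800, 800, 3)),
                      c(0.2, 0.2, 5), "coronal")
  s800 <- standardize_inplane(v800, 448)
  expect_equal(dim(s800$data), c(448, 448, 3))
  expect_equal(s800$spacing_mm[2] * 448, 0.2 * 800)

  v448 <- knee_volume(array(stats::runif(448 * 448 * 2), c(448, 448, 2)),
                      c(0.33, 0.33, 3), "coronal")
  expect_identical(standardize_inplane(v448, 448), v448)

  # area averaging preserves the volume-wide mean
  expect_equal(mean(s$data), mean(v512$data), tolerance = 1e-12)
})

test_that("template matching equals the brute-force correlation oracle", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(runif(48 * 40), 48, 40)
    patch <- matrix(runif(7 * 9), 7, 9)
    mr <- match_template(img, patch)
    oracle <- zncc_oracle(img, patch)
    expect_equal(mr$score, max(oracle), tolerance = 1e-10)
    best <- which(t(oracle) == max(oracle))[1]
    i <- (best - 1) %/% ncol(oracle) + 1
    j <- (best - 1) %% ncol(oracle) + 1
    expect_equal(unname(mr$top_left), c(i, j))
  }
})

test_that("an embedded copy of the patch is found exactly, score 1", {
  set.seed(4)
  img <- matrix(runif(64 * 64, 0, 0.2), 64, 64)
  patch <- matrix(runif(9 * 9), 9, 9)
  img[21:29, 32:40] <- patch   # top-left at (21, 32)
  mr <- match_template(img, patch)
  expect_equal(unname(mr$top_left), c(21, 32))
  expect_equal(unname(mr$center_px), c(21 + 4, 32 + 4))
  expect_equal(mr$score, 1.0, tolerance = 1e-12)

  # self-match of a full-size region at the origin
  mr2 <- match_template(patch, patch)
  expect_equal(unname(mr2$top_left), c(1, 1))
  expect_equal(mr2$score, 1.0, tolerance = 1e-12)

  expect_error(match_template(matrix(0.5, 4, 4), matrix(1, 8, 8)), "larger")
  expect_error(match_template(img, matrix(1, 5, 5)), "zero variance")
})

test_that("spacing-aware matching recovers the same physical location", {
  # scene at 1 mm: bright square with top-left corner at (17, 25)
  scene <- function(px_per_mm) {
    n <- 60 * px_per_mm
    img <- matrix(0, n, n)
    img[(17 * px_per_mm):(28 * px_per_mm),
        (25 * px_per_mm):(36 * px_per_mm)] <- 1
    img
  }
  img1 <- scene(1)                      # spacing 1 mm
  img2 <- scene(2)                      # spacing 0.5 mm, same physical scene
  patch <- img1[15:31, 23:39]           # patch defined at 1 mm spacing
  m1 <- match_template(img1, patch, 1, 1)
  m2 <- match_template(img2, patch, 1, 0.5)
  mm1 <- m1$center_px * 1               # physical centre, mm
  mm2 <- m2$center_px * 0.5
  expect_lt(max(abs(mm1 - mm2)), 1.5)
})

test_that("VOI extraction yields exact shapes with zero padding", {
  v <- knee_volume(array(stats::runif(100 * 100 * 24), c(100, 100, 24)),
                   c(0.5, 0.5, 3), "coronal")
  voi <- extract_voi(v, c(50, 50), 130)
  expect_equal(dim(voi$data), c(260, 260, 24))   # 130 / 0.5 per axis
  # depth always preserved
  expect_equal(dim(voi$data)[3], 24)
  # interior intensities are copied exactly (no interpolation)
  inner <- extract_voi(v, c(50, 50), 20)         # 40 px crop, fully inside
  expect_identical(inner$data,
                   v$data[30:69, 30:69, , drop = FALSE])
  # corner centre: correct shape, zero padding outside
  corner <- extract_voi(v, c(1, 1), 30)
  expect_equal(dim(corner$data), c(60, 60, 24))
  expect_true(all(corner$data[1:20, , ] == 0))
  expect_true(all(corner$data[, 1:20, ] == 0))
  expect_error(extract_voi(v, c(50, 50), -1))
})

test_that("standard-score normalization is exact and idempotent", {
  set.seed(2)
  sl <- matrix(runif(50 * 50, 3, 9), 50, 50)
  z <- normalize_slice(sl)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(stats::sd(z) - 1), 1e-6)
  expect_equal(normalize_slice(z), z, tolerance = 1e-12)
  expect_warning(z0 <- normalize_slice(matrix(5, 4, 4)), "constant")
  expect_true(all(z0 == 0))
})

test_that("the full preprocessing chain is deterministic", {
  s <- fixture_cohort()[[2]]
  tpl <- make_template_patch("coronal", desk_phantom_config())
  cfg <- desk_preprocess_config()
  a <- preprocess_volume(s$volume, tpl, cfg)
  b <- preprocess_volume(s$volume, tpl, cfg)
  expect_identical(a$voi$data, b$voi$data)
  expect_identical(a$match, b$match)
})
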