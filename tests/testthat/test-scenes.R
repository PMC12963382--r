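test_that("compose_affine matches the stated matrix forms", {
  expect_equal(compose_affine(0, 0, 0, 1),
               matrix(c(1, 0, 0, 1, 0, 0), 2, 3), tolerance = 1e-12)
  expect_equal(compose_affine(180, 0, 0, 1),
               matrix(c(-1, 0, 0, -1, 0, 0), 2, 3), tolerance = 1e-12)
  expect_error(compose_affine(10, 0, 0, 0), class = "occlnet_invalid_argument")
  expect_error(compose_affine(10, 0, 0, -2), class = "occlnet_invalid_argument")
})

test_that("warp agrees with a brute-force per-pixel resampling oracle", {
  set.seed(8)
  img <- matrix(runif(25), 5, 5)
  A <- compose_affine(90, 0.2, -0.1, 2.2)
  out <- warp(img, A, 5, 5)
  # independent oracle: explicit normalized-coordinate mapping + bilinear
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xt <- -1 + 2 * (j - 1) / 4
    yt <- -1 + 2 * (i - 1) / 4
    xs <- A[1, 1] * xt + A[1, 2] * yt + A[1, 3]
    ys <- A[2, 1] * xt + A[2, 2] * yt + A[2, 3]
    js <- (xs + 1) * 2 + 1   # 1-based source pixel coords
    is <- (ys + 1) * 2 + 1
    j0 <- floor(js); i0 <- floor(is)
    acc <- 0
    for (dj in 0:1) for (di in 0:1) {
      jj <- j0 + dj; ii <- i0 + di
      if (jj >= 1 && jj <= 5 && ii >= 1 && ii <= 5) {
        w <- (if (dj == 1) js - j0 else 1 - (js - j0)) *
             (if (di == 1) is - i0 else 1 - (is - i0))
        acc <- acc + w * img[ii, jj]
      }
    }
    oracle[i, j] <- acc
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("warp handles identity, mass relocation, and degenerate input", {
  set.seed(1)
  img <- matrix(runif(36), 6, 6)
  expect_equal(warp(img, compose_affine(0, 0, 0, 1), 6, 6), img,
               tolerance = 1e-12)
  # one bright pixel translated by exactly one grid step: normalized offset
  # 2/(n-1) moves the sampling grid one pixel in the source
  pt <- matrix(0, 5, 5); pt[3, 3] <- 1
  shifted <- warp(pt, compose_affine(0, 2 / 4, 0, 1), 5, 5)
  expect_equal(shifted[3, 2], 1)
  expect_equal(sum(shifted), 1)
  expect_equal(warp(matrix(0, 4, 4), compose_affine(33, .1, .2, 1.5), 4, 4),
               matrix(0, 4, 4))
  expect_error(warp(matrix(1, 2, 2), compose_affine(0, 0, 0, 1), 0, 3),
               class = "occlnet_invalid_argument")
})

test_that("transform sampling obeys each regime's laws", {
  set.seed(2)
  tr <- replicate(400, sample_scene_transforms("comparison"),
                  simplify = FALSE)
  for (t in tr) expect_equal(t$fg_t + t$bg_t, c(0, 0))
  r <- vapply(tr, `[[`, 0, "radial_dist")
  expect_true(all(r >= 0.1 & r <= 0.15))
  ks <- ks_two_sample(r, qunif(ppoints(400), 0.1, 0.15))
  expect_gt(ks$p, 0.01)
  rec <- replicate(50, sample_scene_transforms("reconnet"), simplify = FALSE)
  expect_true(all(vapply(rec, `[[`, 0, "scale") == 2.2))
  tx <- vapply(rec, function(t) t$fg_t[1], 0)
  expect_true(all(abs(tx) <= 0.55))
  to <- sample_scene_transforms("translation_only")
  expect_equal(to$fg_rotation_deg, 0)
  ro <- sample_scene_transforms("rotation_only")
  expect_equal(ro$fg_t, c(0, 0))
})

test_that("two-threshold segmentation follows the stated rule exactly", {
  # 0.009 falls below the rough threshold and, with a bright pixel setting
  # the mask mean, below the 10-percent cut as well; 0.011 clears both
  img <- matrix(0, 50, 50)
  img[1, 1] <- 0.009
  img[2, 2] <- 0.5
  m <- segment(img)
  expect_false(m[1, 1])
  expect_true(m[2, 2])
  imgb <- matrix(0, 50, 50)
  imgb[1, 1] <- 0.011
  expect_true(segment(imgb)[1, 1])
  # two nonzero pixels 0.02 and 0.5: rough mean 0.26, cut 0.026
  img2 <- matrix(0, 50, 50)
  img2[5, 5] <- 0.02
  img2[6, 6] <- 0.5
  m2 <- segment(img2)
  expect_false(m2[5, 5])
  expect_true(m2[6, 6])
  expect_equal(sum(m2), 1)
  expect_error(segment(matrix(0, 50, 50)), class = "occlnet_empty_object")
})

test_that("occlusion level is the exact mask ratio", {
  a <- matrix(FALSE, 4, 4); b <- matrix(FALSE, 4, 4)
  b[1:2, 1:4] <- TRUE            # |bg| = 8
  a[1, 1:2] <- TRUE              # overlap 2
  expect_equal(occlusion_level(a, b), 0.25)
  expect_equal(occlusion_level(b, b), 1.0)
  expect_equal(occlusion_level(matrix(FALSE, 4, 4), b), 0.0)
  expect_error(occlusion_level(a, matrix(FALSE, 4, 4)),
               class = "occlnet_division_by_zero")
})

test_that("composed scenes satisfy the overlay identity", {
  bank <- fx_bank()
  set.seed(5)
  for (k in 1:5) {
    tr <- sample_scene_transforms("comparison")
    sc <- try(compose_scene(bank$objects[[k]], bank$objects[[k + 30]], tr),
              silent = TRUE)
    if (inherits(sc, "try-error")) next
    expect_equal(sc$image[sc$fg_mask], sc$fg_only[sc$fg_mask])
    expect_equal(sc$image[!sc$fg_mask], sc$bg_only[!sc$fg_mask])
    expect_equal(sc$occlusion_level,
                 sum(sc$fg_mask & sc$bg_mask) / sum(sc$bg_mask))
  }
  # a foreground warped fully out of frame fails segmentation
  tr <- sample_scene_transforms("comparison")
  tr$fg_t <- c(5, 5)
  expect_error(compose_scene(bank$objects[[1]], bank$objects[[2]], tr),
               class = "occlnet_empty_object")
})

test_that("zero-overlap scenes equal the brute-force overlay oracle", {
  bank <- fx_bank()
  set.seed(9)
  # constructed placement: the in-regime radial range keeps objects close,
  # so a separated pair is built with explicit transform values
  tr <- sample_scene_transforms("comparison")
  tr$fg_t <- c(0.45, 0.45)
  tr$bg_t <- c(-0.45, -0.45)
  sc <- compose_scene(bank$objects[[1]], bank$objects[[31]], tr)
  expect_equal(sc$occlusion_level, 0)
  # with no mask overlap the composite equals the pixelwise overlay oracle,
  # which here is also the pixelwise maximum outside the (empty) overlap
  oracle <- sc$bg_only
  oracle[sc$fg_mask] <- sc$fg_only[sc$fg_mask]
  expect_equal(sc$image, oracle)
  expect_equal(sc$image[sc$fg_mask | sc$bg_mask],
               pmax(sc$fg_only, sc$bg_only)[sc$fg_mask | sc$bg_mask],
               tolerance = 1e-12)
})

test_that("balanced datasets have exact cell counts and occlusion bounds", {
  ds <- fx_scenes()
  occ <- vapply(ds$scenes, function(s) s$occlusion_level, 0)
  expect_true(all(occ >= 0.50 & occ <= 0.75))
  expect_equal(occlusion_histogram(ds), rep(32L, 5))
  # exact per-(bin x pair) audit
  cell <- table(
    bin = vapply(occ, function(o) ag("occ_bin_of")(o, ds$spec), 0L),
    pair = vapply(ds$scenes, function(s)
      paste0(s$fg_label, "-", s$bg_label), ""))
  expect_equal(dim(cell), c(5L, 16L))
  expect_true(all(cell == 2L))
  # determinism: same seed, same manifest
  ds2 <- build_dataset(fx_bank(), ds$spec, seed = 3)
  expect_identical(scene_manifest(ds), scene_manifest(ds2))
})

test_that("dataset spec validation and empty datasets behave", {
  expect_error(dataset_spec(occ_min = 0.6, occ_max = 0.5),
               class = "occlnet_invalid_argument")
  expect_error(dataset_spec(bin_width = 0.07),
               class = "occlnet_invalid_argument")
  expect_error(dataset_spec(n_images = 100),
               class = "occlnet_invalid_argument")  # not divisible by 80
  empty <- build_dataset(fx_bank(), dataset_spec(n_images = 0), seed = 1)
  expect_length(empty$scenes, 0)
  expect_error(build_dataset(list(objects = list()), dataset_spec(n_images = 80)),
               class = "occlnet_invalid_argument")
})

test_that("unoccluded inputs carry the stored channel images in fixed order", {
  ds <- fx_scenes()
  for (s in ds$scenes[1:5]) {
    u <- make_unoccluded_input(s)
    expect_equal(u[, , 1], s$fg_only)
    expect_equal(u[, , 2], s$bg_only)
  }
  te <- dataset_tensors(ds, "unoccluded")
  expect_equal(dim(te$x), c(2, 50, 50, length(ds$scenes)))
  expect_equal(te$x[1, , , 3], ds$scenes[[3]]$fg_only)
})

test_that("original-pose recovery inverts the background transform", {
  bank <- fx_bank()
  set.seed(12)
  tr <- sample_scene_transforms("reconnet")
  sc <- NULL
  for (k in 1:20) {
    sc <- tryCatch(compose_scene(bank$objects[[k]], bank$objects[[k + 60]], tr),
                   occlnet_empty_object = function(e) NULL)
    if (!is.null(sc)) break
  }
  op <- to_original_pose(sc)
  expect_equal(dim(op$x), c(28, 28))
  expect_equal(dim(op$x_f), c(28, 28))
  # round trip on the single-object channel: warp then inverse-warp stays
  # close to the original away from the object boundary
  src <- bank$objects[[k + 60]]$pixels
  A <- ag("scene_affine")(tr$bg_rotation_deg, tr$bg_t, tr$scale)
  fwd <- warp(src, A, 50, 50)
  back <- warp(fwd, invert_affine(A), 28, 28)
  inside <- src > 0.05
  eroded <- inside & rbind(inside[-1, ], FALSE) & rbind(FALSE, inside[-28, ]) &
    cbind(inside[, -1], FALSE) & cbind(FALSE, inside[, -28])
  expect_lt(max(abs(back[eroded] - src[eroded])), 0.25)
  expect_lt(mean(abs(back[eroded] - src[eroded])), 0.05)
  # comparison-regime scenes cannot be pose-normalized
  expect_error(to_original_pose(fx_scenes()$scenes[[1]]),
               class = "occlnet_invalid_argument")
})

test_that("dataset IO round-trips bit-identically and rejects bad archives", {
  ds <- build_dataset(fx_bank(), dataset_spec(n_images = 80), seed = 6)
  dir <- withr::local_tempdir()
  write_scene_dataset(ds, file.path(dir, "d1"))
  back <- read_scene_dataset(file.path(dir, "d1"))
  expect_identical(back$scenes, ds$scenes)
  expect_equal(nrow(utils::read.csv(file.path(dir, "d1", "manifest.csv"))),
               length(ds$scenes))
  expect_error(read_scene_dataset(file.path(dir, "missing")),
               class = "occlnet_format_error")
  # version mismatch
  meta <- readRDS(file.path(dir, "d1", "meta.rds"))
  meta$version <- 99L
  saveRDS(meta, file.path(dir, "d1", "meta.rds"))
  expect_error(read_scene_dataset(file.path(dir, "d1")),
               class = "occlnet_format_error")
})
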