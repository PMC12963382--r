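test_that("reconnet tensors carry matched poses and targets", {
  rd <- fx_reconnet_scenes()
  expect_equal(dim(rd$x), c(1, 28, 28, 160))
  expect_equal(dim(rd$x_f), dim(rd$x))
  expect_equal(dim(rd$target), dim(rd$x))
  expect_true(all(rd$labels %in% 1:4))
  occ <- vapply(rd$scenes$scenes, function(s) s$occlusion_level, 0)
  expect_true(all(occ >= 0.10 & occ <= 0.60))
  expect_true(all(vapply(rd$scenes$scenes, function(s)
    s$transforms$scale == 2.2, TRUE)))
})

test_that("generator architecture arithmetic gives 28x28 images in (0,1)", {
  gan <- make_gan(seed = 2, width_scale = 0.0625)
  z <- sample_latent(5)
  expect_equal(dim(z), c(62, 5))
  expect_true(all(z >= 0 & z <= 1))
  img <- generate_images(gan, z)
  expect_equal(dim(img), c(1, 28, 28, 5))
  expect_true(all(img > 0 & img < 1))
})

test_that("latent states stay clamped and the initial latent is exactly 0.5", {
  gan <- make_gan(seed = 2, width_scale = 0.0625)
  recon <- make_inference(seed = 3, width_scale = 0.0625)
  expect_equal(unique(as.vector(1 / (1 + exp(-recon$z0$val)))), 0.5)
  rd <- fx_reconnet_scenes()
  tr <- reconstitute(rd$x[, , , 1:6, drop = FALSE],
                     rd$x_f[, , , 1:6, drop = FALSE], recon, gan)
  expect_equal(dim(tr$z)[3], 6)  # t = 0..5
  expect_true(all(tr$z >= 0 & tr$z <= 1))
  expect_true(all(tr$z[, , 1] == 0.5))
  tr2 <- reconstitute(rd$x[, , , 1:6, drop = FALSE],
                      rd$x_f[, , , 1:6, drop = FALSE], recon, gan)
  expect_identical(tr$z, tr2$z)  # deterministic
})

test_that("a zeroed correction head leaves the latent unchanged; clamping caps it", {
  gan <- make_gan(seed = 2, width_scale = 0.0625)
  recon <- make_inference(seed = 3, width_scale = 0.0625)
  # force delta = 0 by zeroing the head's output layer
  nlay <- length(recon$head$layers)
  wkey <- paste0("L", nlay - 1L, "_W")  # final fc before tanh
  recon$head$params[[wkey]]$val[] <- 0
  recon$head$params[[paste0("L", nlay - 1L, "_b")]]$val[] <- 0
  rd <- fx_reconnet_scenes()
  z <- matrix(0.37, 62, 3)
  st <- infer_step(z, rd$x[, , , 1:3, drop = FALSE],
                   rd$x_f[, , , 1:3, drop = FALSE], recon, gan)
  expect_equal(st$z$val, z, tolerance = 1e-12)
  # clamp: a coordinate at 0.9 plus a correction of +0.7 saturates at 1
  agc <- ag("ag_clamp01")
  nd <- agc(ag("ag_const")(matrix(0.9 + 0.7, 1, 1)), NULL)
  expect_equal(nd$val[1, 1], 1)
})

test_that("GAN training runs, improves nothing catastrophically, and warns on collapse guard only", {
  bank <- fx_bank()
  gan <- make_gan(seed = 4, width_scale = 0.0625)
  gan <- train_generator(gan, bank, epochs = 2, batch_size = 32, seed = 4)
  expect_true(gan$trained)
  expect_length(gan$disc_acc, 2)
  img <- generate_images(gan, sample_latent(8))
  expect_true(all(is.finite(img)))
})

test_that("inference training reduces reconstruction error over timesteps", {
  bank <- fx_bank()
  rd <- fx_reconnet_scenes()
  gan <- train_generator(make_gan(seed = 5, width_scale = 0.0625), bank,
                         epochs = 3, batch_size = 32, seed = 5)
  recon <- make_inference(seed = 6, width_scale = 0.0625)
  # zero-epoch call returns the module unchanged
  expect_false(train_inference(recon, gan, rd, epochs = 0)$trained)
  recon <- train_inference(recon, gan, rd, epochs = 4, batch_size = 32,
                           seed = 6)
  err <- reconstruction_errors(recon, gan, rd)
  expect_length(err, 6)
  expect_lte(err[6], err[2])  # final step no worse than first refinement
  # the no-x_f variant trains and evaluates
  r2 <- make_inference(seed = 7, width_scale = 0.0625, use_xf = FALSE)
  r2 <- train_inference(r2, gan, rd, epochs = 1, batch_size = 32, seed = 7)
  expect_true(r2$trained)
})

test_that("decoders train, evaluate, and chance-level holds for random ones", {
  rd <- fx_reconnet_scenes()
  arch <- decoder_arch(0.0625)
  frozen <- occlnet:::mark_trained(
    initialize_network(arch, 91, task = "background_only", in_h = 28))
  acc <- decoder_accuracy(frozen, rd$x, rd$labels)
  expect_lt(abs(acc - 0.25), 0.22)  # random decoder stays near chance
  dec <- train_decoder(rd$target, rd$labels, arch, seed = 9,
                       hp = list(lr = 1e-3, l2 = 0, batch_size = 32L,
                                 dropout_p = 0.5), epochs = 6)
  acc_tr <- decoder_accuracy(dec, rd$target, rd$labels)
  expect_gt(acc_tr, 0.4)  # learns its own training set well above chance
  res <- decoder_transfer_eval(dec, dec,
                               train_inference(make_inference(seed = 8,
                                                              width_scale = 0.0625),
                                               train_generator(make_gan(seed = 8,
                                                                        width_scale = 0.0625),
                                                               fx_bank(), epochs = 1,
                                                               batch_size = 32, seed = 8),
                                               rd, epochs = 0),
                               train_generator(make_gan(seed = 8, width_scale = 0.0625),
                                               fx_bank(), epochs = 1,
                                               batch_size = 32, seed = 8), rd)
  expect_named(res, c("unocc_on_occluded", "occ_on_occluded",
                      "unocc_on_reconstituted"))
  expect_true(all(res >= 0 & res <= 1))
})

test_that("generalization asymmetry produces the labelled 2x2 table", {
  rd <- fx_reconnet_scenes()
  arch <- decoder_arch(0.0625)
  d1 <- train_decoder(rd$target, rd$labels, arch, seed = 13, epochs = 2)
  d2 <- train_decoder(rd$x, rd$labels, arch, seed = 14, epochs = 2)
  out <- generalization_asymmetry(d2, d1,
                                  test_unocc = list(x = rd$target,
                                                    labels = rd$labels),
                                  test_occ = list(x = rd$x,
                                                  labels = rd$labels))
  expect_equal(dim(out$table), c(2, 2))
  expect_true(is.finite(out$asymmetry))
})

test_that("disentangler splits the latent in half and reports classes", {
  dis <- make_disentangler(seed = 15, width_scale = 0.0625)
  expect_equal(dis$half * 2L,
               dim(dis$enc$params[[length(dis$enc$params) - 1]]$val)[2])
  rd <- fx_reconnet_scenes()
  dis <- train_disentangler(dis, rd$scenes, epochs = 1, batch_size = 32,
                            seed = 15)
  x50 <- array(0, c(1, 50, 50, 3))
  for (i in 1:3) x50[1, , , i] <- rd$scenes$scenes[[i]]$image
  out <- infer_disentangled(dis, x50)
  expect_equal(dim(out$fg_only), c(1, 50, 50, 3))  # decoder reaches 50x50
  expect_true(all(out$fg_only > 0 & out$fg_only < 1))
  expect_true(all(out$fg_class %in% 1:4))
})

test_that("posenet trains and the inverse-then-apply round trip is consistent", {
  pn <- make_posenet(seed = 16, width_scale = 0.0625)
  rd <- fx_reconnet_scenes()
  pn <- train_posenet(pn, rd$scenes, epochs = 1, batch_size = 32, seed = 16)
  x50 <- array(0, c(1, 50, 50, 2))
  for (i in 1:2) x50[1, , , i] <- rd$scenes$scenes[[i]]$bg_only
  pe <- infer_pose(pn, x50)
  expect_length(pe$scale, 2)
  expect_true(all(is.finite(pe$rotation_deg)))
  # algebraic round trip of the de-transform helper at known parameters
  img <- rd$scenes$scenes[[1]]$bg_only
  M <- compose_affine(0, 0.2, -0.1, 1.3)
  fwdw <- warp(img, M, 50, 50)
  back <- warp(fwdw, invert_affine(M), 50, 50)
  inner <- img > 0.05
  expect_lt(mean(abs(back[inner] - img[inner])), 0.1)
})
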