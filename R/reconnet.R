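# The reconstitution model: a GAN generative module over unoccluded object
# images, an iterative latent-inference module that "morphs" an occluded
# background object toward its unoccluded appearance, pose/disentangling
# networks for the predicted-pose condition, and the decoder-transfer
# evaluations.

.z_dim <- 62L

# ---- data -------------------------------------------------------------------

#' Assemble reconnet-regime training tensors
#'
#' Builds reconnet-regime scenes, transforms each back to the background
#' object's original pose via [to_original_pose()], and pairs them with the
#' unoccluded background source image as reconstruction target.
#'
#' @param bank object bank the scenes were composed from
#' @param n_images number of scenes
#' @param seed integer seed
#' @param occ_min,occ_max,bin_width occlusion filter (the core comparison
#'   dataset uses 10-60 percent in 10-percent bins)
#' @return list(x, x_f, target: \code{[1,28,28,N]} arrays; labels: 1..4;
#'   scenes: the underlying dataset)
#' @export
reconnet_data <- function(bank, n_images, seed = 1, occ_min = 0.10,
                          occ_max = 0.60, bin_width = 0.10) {
  spec <- dataset_spec(occ_min = occ_min, occ_max = occ_max,
                       bin_width = bin_width, n_images = n_images,
                       regime = "reconnet", balance = TRUE)
  ds <- build_dataset(bank, spec, seed = seed)
  lookup <- new.env(parent = emptyenv())
  for (o in bank$objects)
    assign(paste0(o$class_id, "/", o$instance_id), o$pixels, envir = lookup)
  n <- length(ds$scenes)
  x <- array(0, c(1, 28, 28, n))
  xf <- array(0, c(1, 28, 28, n))
  tg <- array(0, c(1, 28, 28, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    s <- ds$scenes[[i]]
    op <- to_original_pose(s)
    x[1, , , i] <- op$x
    xf[1, , , i] <- op$x_f
    tg[1, , , i] <- get(paste0(s$bg_label, "/", s$bg_instance), envir = lookup)
    labels[i] <- s$bg_label + 1L
  }
  list(x = x, x_f = xf, target = tg, labels = labels, scenes = ds)
}

# ---- GAN --------------------------------------------------------------------

#' Create an untrained GAN (generator + discriminator)
#'
#' Generator: FC(1024)-BN-ReLU, FC(128*7*7)-BN-ReLU,
#' TransConv(64,k4,s2)-BN-ReLU, TransConv(1,k4,s2)-Sigmoid, fed by a latent
#' uniform on \code{[0,1]^62}.  Discriminator: Conv(64,k4,s2)-LReLU(0.2),
#' Conv(128,k4,s2)-BN-LReLU(0.2), FC(1024)-BN-LReLU(0.2), FC(1)-Sigmoid.
#' Weights are initialized N(0, 0.02), biases 0.  \code{width_scale}
#' shrinks all channel counts for desk-scale runs.
#'
#' @param seed integer seed
#' @param width_scale positive factor on unit counts
#' @return an \code{occl_gan} list
#' @export
make_gan <- function(seed = 1, width_scale = 1) {
  su <- function(n) scale_units(n, width_scale)
  gen_layers <- list(ly_fc(su(1024)), ly_bn(), ly_relu(),
                     ly_fc(su(128) * 49L), ly_bn(), ly_relu(),
                     ly_reshape(su(128), 7L, 7L),
                     ly_tconv(su(64), 4L, 2L, 1L), ly_bn(), ly_relu(),
                     ly_tconv(1L, 4L, 2L, 1L))  # sigmoid applied by caller
  disc_layers <- list(ly_conv(su(64), 4L, 2L, 1L), ly_lrelu(),
                      ly_conv(su(128), 4L, 2L, 1L), ly_bn(), ly_lrelu(),
                      ly_flatten(), ly_fc(su(1024)), ly_bn(), ly_lrelu(),
                      ly_fc(1L))
  structure(list(
    gen = stack_init(gen_layers, .z_dim, derive_seed(seed, "gan/gen"), "dcgan"),
    disc = stack_init(disc_layers, c(1L, 28L, 28L),
                      derive_seed(seed, "gan/disc"), "dcgan"),
    width_scale = width_scale, seed = seed, trained = FALSE),
    class = "occl_gan")
}

#' Draw latent vectors uniform on the 62-dimensional unit interval
#' @param n number of draws
#' @return a 62 x n matrix
#' @export
sample_latent <- function(n) matrix(stats::runif(.z_dim * n), .z_dim, n)

# generator forward; returns the pre-sigmoid logits node ([1,28,28,N])
generator_logits <- function(gan, z, tape = NULL, training = FALSE) {
  zn <- if (is.environment(z)) z else ag_const(z)
  stack_forward(gan$gen, zn, tape, training)
}

#' Generate images from latent vectors
#' @param gan an \code{occl_gan}
#' @param z a 62 x n matrix (or tensor node)
#' @return a \code{[1,28,28,n]} array of images in (0,1)
#' @export
generate_images <- function(gan, z) {
  lg <- generator_logits(gan, z)
  1 / (1 + exp(-lg$val))
}

#' Adversarially train the GAN on unoccluded object images
#'
#' Standard alternating updates with the stated regimen: Adam learning rate
#' 2e-4 for both networks, first-moment coefficient 0.5, batch 64.  A
#' mode-collapse guard warns (without failing) when discriminator accuracy
#' is pinned at 1 for 3 consecutive epochs.
#'
#' @param gan an \code{occl_gan}
#' @param bank object bank supplying the real images
#' @param epochs training epochs (25 at paper scale)
#' @param batch_size minibatch size
#' @param seed integer seed
#' @param lr Adam learning rate for both networks (2e-4 at paper scale;
#'   small desk banks provide far fewer updates per epoch and may use more)
#' @return the trained \code{occl_gan}, with a \code{disc_acc} trace
#' @export
train_generator <- function(gan, bank, epochs = 25L, batch_size = 64L,
                            seed = 1, lr = 2e-4) {
  n <- length(bank$objects)
  x <- array(0, c(1, 28, 28, n))
  for (i in seq_len(n)) x[1, , , i] <- bank$objects[[i]]$pixels
  stg <- adam_state(); std <- adam_state()
  disc_acc <- numeric(0)
  pinned <- 0L
  with_seed(derive_seed(seed, "gan/train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      accs <- c()
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        nb <- length(idx)
        # discriminator step; fakes are detached (no generator gradients),
        # generated in training mode so batch-norm statistics advance
        # exactly as in a joint pass
        tape <- new_tape()
        real <- ag_const(x[, , , idx, drop = FALSE])
        fake_val <- generator_logits(gan, sample_latent(nb), NULL,
                                     training = TRUE)$val
        fake_img <- ag_const(1 / (1 + exp(-fake_val)))
        dr <- stack_forward(gan$disc, real, tape, training = TRUE)
        df <- stack_forward(gan$disc, fake_img, tape, training = TRUE)
        dloss <- ag_scalar_sum(list(ag_bce_logits(dr, rep(1, nb), tape),
                                    ag_bce_logits(df, rep(0, nb), tape)),
                               tape = tape)
        ag_zero_grads(c(gan$disc$params, gan$gen$params))
        ag_backward(dloss, tape)
        adam_step(gan$disc$params, std, lr = lr, beta1 = 0.5)
        accs <- c(accs, mean(c(dr$val > 0, df$val < 0)))
        # generator step
        tape <- new_tape()
        fake_img <- ag_sigmoid(generator_logits(gan, sample_latent(nb), tape,
                                                training = TRUE), tape)
        df <- stack_forward(gan$disc, fake_img, tape, training = TRUE)
        gloss <- ag_bce_logits(df, rep(1, nb), tape)
        ag_zero_grads(c(gan$disc$params, gan$gen$params))
        params_set_trainable(gan$disc$params, FALSE)
        ag_backward(gloss, tape)
        params_set_trainable(gan$disc$params, TRUE)
        adam_step(gan$gen$params, stg, lr = lr, beta1 = 0.5)
      }
      disc_acc <- c(disc_acc, mean(accs))
      pinned <- if (mean(accs) >= 0.999) pinned + 1L else 0L
      if (pinned >= 3L) {
        warning("discriminator accuracy pinned at 1 for 3 epochs; possible mode collapse")
        pinned <- 0L
      }
    }
  })
  gan$trained <- TRUE
  gan$disc_acc <- disc_acc
  gan
}

# ---- iterative latent inference --------------------------------------------

#' Create an untrained latent-inference module
#'
#' The module channel-concatenates the current generated image G(z) with the
#' occluded background image x (and optionally the foreground image x_f),
#' encodes the stack through three convolutions and a fully connected layer,
#' concatenates with the current latent, and emits a Tanh-bounded correction
#' that is added to the latent and clamped to \code{[0,1]}.  The initial
#' latent is the sigmoid of a learned parameter initialized to 0 (so exactly
#' 0.5 before training).
#'
#' @param seed integer seed
#' @param width_scale factor on channel counts
#' @param use_xf include the foreground-object channel (default TRUE)
#' @return an \code{occl_reconnet}
#' @export
make_inference <- function(seed = 1, width_scale = 1, use_xf = TRUE) {
  su <- function(n) scale_units(n, width_scale)
  in_ch <- if (use_xf) 3L else 2L
  enc_layers <- list(ly_conv(su(256), 4L, 2L, 1L), ly_bn(), ly_lrelu(),
                     ly_conv(su(256), 4L, 2L, 1L), ly_bn(), ly_lrelu(),
                     ly_conv(su(128), 3L, 1L, 1L), ly_bn(), ly_lrelu(),
                     ly_flatten(), ly_fc(su(512)), ly_bn(), ly_lrelu())
  head_layers <- list(ly_fc(su(512)), ly_bn(), ly_relu(),
                      ly_fc(.z_dim), ly_tanh())
  enc <- stack_init(enc_layers, c(in_ch, 28L, 28L),
                    derive_seed(seed, "recon/enc"))
  head <- stack_init(head_layers, su(512) + .z_dim,
                     derive_seed(seed, "recon/head"))
  structure(list(enc = enc, head = head,
                 z0 = ag_param(matrix(0, .z_dim, 1L)),
                 use_xf = use_xf, width_scale = width_scale, seed = seed,
                 trained = FALSE),
            class = "occl_reconnet")
}

#' One latent-inference step
#'
#' @param z a 62 x n matrix (or node) with entries in \[0,1\]
#' @param x,x_f \code{[1,28,28,n]} input arrays (x_f ignored when the module
#'   was built without it)
#' @param recon an \code{occl_reconnet}
#' @param gan the (frozen) generative module
#' @param tape autodiff tape (NULL for inference)
#' @param training batch-norm / dropout mode
#' @return list(z = updated latent node, gen_logits = generator output for
#'   the *input* latent)
#' @export
infer_step <- function(z, x, x_f, recon, gan, tape = NULL, training = FALSE) {
  zn <- if (is.environment(z)) z else ag_const(z)
  gl <- generator_logits(gan, zn, tape, training = FALSE)
  gimg <- ag_sigmoid(gl, tape)
  xs <- list(gimg, if (is.environment(x)) x else ag_const(x))
  if (recon$use_xf)
    xs <- c(xs, list(if (is.environment(x_f)) x_f else ag_const(x_f)))
  inp <- ag_concat_c(xs, tape)
  feat <- stack_forward(recon$enc, inp, tape, training)
  hin <- ag_concat_c(list(feat, zn), tape)
  delta <- stack_forward(recon$head, hin, tape, training)
  z_new <- ag_clamp01(ag_add(zn, delta, tape), tape)
  list(z = z_new, gen_logits = gl)
}

#' Run the full 5-step reconstitution trajectory
#'
#' @inheritParams infer_step
#' @param n_steps number of refinement steps (5)
#' @return an \code{occl_recon_trajectory}: z (62 x n x (n_steps+1)) and
#'   generated images \code{[1,28,28,n,(n_steps+1)]} for t = 0..n_steps
#' @export
reconstitute <- function(x, x_f, recon, gan, n_steps = 5L) {
  n <- dim(x)[4]
  z0 <- matrix(1 / (1 + exp(-recon$z0$val)), .z_dim, n)
  zs <- array(0, c(.z_dim, n, n_steps + 1L))
  gen <- array(0, c(1, 28, 28, n, n_steps + 1L))
  zs[, , 1] <- z0
  gen[, , , , 1] <- generate_images(gan, z0)
  z <- z0
  for (t in seq_len(n_steps)) {
    st <- infer_step(z, x, x_f, recon, gan)
    z <- st$z$val
    zs[, , t + 1L] <- z
    gen[, , , , t + 1L] <- generate_images(gan, z)
  }
  structure(list(z = zs, generated = gen, n_steps = n_steps),
            class = "occl_recon_trajectory")
}

#' Train the inference module (generator frozen)
#'
#' Objective: pixel-wise binary cross-entropy between G(z_t) and the
#' unoccluded background target image, summed over t = 1..5 with equal
#' weights.  Regimen: Adam, learning rate 1e-4, batch 64, no weight decay.
#'
#' @param recon an \code{occl_reconnet}
#' @param gan a trained \code{occl_gan} (its weights are not updated)
#' @param data tensors from [reconnet_data()]
#' @param epochs training epochs (100 at paper scale)
#' @param batch_size minibatch size
#' @param seed integer seed
#' @param n_steps refinement steps per trajectory
#' @param lr Adam learning rate (the paper-scale regimen uses 1e-4 over
#'   100 epochs; brief desk runs use a proportionally larger rate)
#' @return the trained \code{occl_reconnet}
#' @export
train_inference <- function(recon, gan, data, epochs = 100L, batch_size = 64L,
                            seed = 1, n_steps = 5L, lr = 1e-4) {
  if (epochs == 0L) return(recon)
  params <- c(recon$enc$params, recon$head$params, list(z0 = recon$z0))
  st <- adam_state()
  n <- dim(data$x)[4]
  params_set_trainable(gan$gen$params, FALSE)
  on.exit(params_set_trainable(gan$gen$params, TRUE), add = TRUE)
  with_seed(derive_seed(seed, "recon/train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        nb <- length(idx)
        tape <- new_tape()
        xb <- ag_const(data$x[, , , idx, drop = FALSE])
        xfb <- ag_const(data$x_f[, , , idx, drop = FALSE])
        tgt <- data$target[, , , idx, drop = FALSE]
        z0b <- ag_bcast_n(recon$z0, nb, tape)
        z <- ag_sigmoid(z0b, tape)
        losses <- list()
        for (t in seq_len(n_steps)) {
          step <- infer_step(z, xb, xfb, recon, gan, tape, training = TRUE)
          z <- step$z
          gl <- generator_logits(gan, z, tape, training = FALSE)
          losses[[t]] <- ag_bce_logits(gl, tgt, tape)
        }
        loss <- ag_scalar_sum(losses, tape = tape)
        if (!is.finite(loss$val))
          occl_error("non-finite reconstruction loss",
                     "occlnet_training_diverged")
        ag_zero_grads(c(params, gan$gen$params))
        ag_backward(loss, tape)
        adam_step(params, st, lr = lr)
      }
    }
  })
  recon$trained <- TRUE
  recon
}

#' Per-timestep reconstruction error of a trajectory
#'
#' @param recon,gan trained modules
#' @param data held-out tensors from [reconnet_data()]
#' @return numeric vector of mean squared reconstruction errors for
#'   t = 0..5
#' @export
reconstruction_errors <- function(recon, gan, data) {
  tr <- reconstitute(data$x, data$x_f, recon, gan)
  vapply(seq_len(dim(tr$generated)[5]), function(t)
    mean((tr$generated[, , , , t] - data$target[1, , , ])^2), 0)
}

# ---- decoders and transfer evaluation --------------------------------------

#' Decoder architecture for 28x28 object images
#'
#' The feedforward decoder used by the reconstitution analyses: three 5x5
#' convolutions (64/128/128 maps), each max-pooled, then FC(512) and a
#' 4-way readout.
#'
#' @param width_scale factor on unit counts
#' @return an \code{occl_arch}
#' @export
decoder_arch <- function(width_scale = 1) {
  su <- function(n) scale_units(n, width_scale)
  structure(list(type = "ff", name = "FF decoder",
                 conv_maps = c(su(64), su(128), su(128)),
                 pool_after = c(TRUE, TRUE, TRUE),
                 fc_units = su(512), kernel = 5L, n_timesteps = 1L,
                 schedule = list(list(object = "background", timestep = 1L)),
                 feedback_edges = list(), width_scale = width_scale),
            class = "occl_arch")
}

#' Train a 4-way image classifier (decoder)
#'
#' @param x \code{[1,28,28,N]} images
#' @param labels integer labels 1..4
#' @param arch an \code{occl_arch} (see [decoder_arch()])
#' @param seed integer seed
#' @param hp hyperparameters (default: the fixed reconstitution regimen)
#' @param epochs training epochs
#' @return a trained \code{occl_network}
#' @export
train_decoder <- function(x, labels, arch = decoder_arch(0.125), seed = 1,
                          hp = NULL, epochs = 20L) {
  hp <- hp %||% reconnet_regimen()
  inst <- initialize_network(arch, seed, task = "background_only",
                             in_h = dim(x)[2])
  st <- adam_state()
  n <- dim(x)[4]
  with_seed(derive_seed(seed, "decoder/train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[b0:min(b0 + hp$batch_size - 1L, n)]
        tape <- new_tape()
        out <- network_forward(inst, x[, , , idx, drop = FALSE],
                               training = TRUE, dropout_p = hp$dropout_p,
                               tape = tape)
        loss <- ag_softmax_ce(out$logits$background, labels[idx], tape)
        ag_zero_grads(inst$params)
        ag_backward(loss, tape)
        adam_step(inst$params, st, lr = hp$lr, l2 = hp$l2)
      }
    }
  })
  inst$trained <- TRUE
  inst
}

#' Accuracy of a decoder on labelled images
#' @param inst a trained decoder (see [train_decoder()])
#' @param x \code{[1,H,H,N]} images
#' @param labels integer labels 1..4
#' @param batch_size evaluation batch size
#' @return the classification accuracy
#' @export
decoder_accuracy <- function(inst, x, labels, batch_size = 256L) {
  n <- dim(x)[4]
  pred <- integer(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    out <- network_forward(inst, x[, , , idx, drop = FALSE])
    pred[idx] <- apply(out$logits$background$val, 2, which.max)
  }
  mean(pred == labels)
}

#' Decoder-transfer evaluation
#'
#' Reports (i) the unoccluded-trained decoder on raw occluded images,
#' (ii) the occluded-trained decoder on the same images, and (iii) the
#' unoccluded-trained decoder on the reconstituted images G(z_5).
#'
#' @param decoder_unocc decoder trained only on unoccluded background images
#' @param decoder_occ decoder trained on occluded images
#' @param recon,gan trained reconstitution modules
#' @param data held-out tensors from [reconnet_data()]
#' @return named numeric vector with entries \code{unocc_on_occluded},
#'   \code{occ_on_occluded}, \code{unocc_on_reconstituted}
#' @export
decoder_transfer_eval <- function(decoder_unocc, decoder_occ, recon, gan,
                                  data) {
  tr <- reconstitute(data$x, data$x_f, recon, gan)
  g5 <- array(tr$generated[, , , , tr$n_steps + 1L],
              dim = c(1, 28, 28, dim(data$x)[4]))
  c(unocc_on_occluded = decoder_accuracy(decoder_unocc, data$x, data$labels),
    occ_on_occluded = decoder_accuracy(decoder_occ, data$x, data$labels),
    unocc_on_reconstituted = decoder_accuracy(decoder_unocc, g5, data$labels))
}

#' Occluded-to-unoccluded generalization asymmetry
#'
#' Cross-evaluation of decoders trained on heavily occluded versus
#' unoccluded images.  The asymmetry statistic is (occluded-trained decoder
#' on unoccluded images) minus (unoccluded-trained decoder on occluded
#' images); positive values reproduce the finding that classifiers trained
#' under heavy occlusion generalize the better way around.
#'
#' @param decoder_occ,decoder_unocc trained decoders
#' @param test_unocc,test_occ lists with \code{x} and \code{labels}
#' @return list(table = 2x2 accuracy matrix, asymmetry = statistic)
#' @export
generalization_asymmetry <- function(decoder_occ, decoder_unocc,
                                     test_unocc, test_occ) {
  tab <- matrix(c(
    decoder_accuracy(decoder_occ, test_occ$x, test_occ$labels),
    decoder_accuracy(decoder_occ, test_unocc$x, test_unocc$labels),
    decoder_accuracy(decoder_unocc, test_occ$x, test_occ$labels),
    decoder_accuracy(decoder_unocc, test_unocc$x, test_unocc$labels)),
    2, 2, byrow = TRUE,
    dimnames = list(trained = c("occluded", "unoccluded"),
                    tested = c("occluded", "unoccluded")))
  list(table = tab,
       asymmetry = tab["occluded", "unoccluded"] - tab["unoccluded", "occluded"])
}

# ---- Disentangler and PoseNet ----------------------------------------------

#' Create an untrained Disentangler
#'
#' Encoder maps a 50x50 two-object image to a 512-unit latent split in half
#' (foreground half first); a shared decoder reconstructs a single-object
#' image from either half; a shared classifier predicts the 4-way class
#' from either half.
#'
#' @param seed integer seed
#' @param width_scale factor on unit counts
#' @return an \code{occl_disentangler}
#' @export
make_disentangler <- function(seed = 1, width_scale = 1) {
  su <- function(n) scale_units(n, width_scale)
  half <- su(256)
  enc <- stack_init(list(ly_conv(su(128), 4L, 2L, 1L), ly_lrelu(),
                         ly_conv(su(128), 4L, 2L, 1L), ly_bn(), ly_lrelu(),
                         ly_conv(su(128), 4L, 2L, 1L), ly_bn(), ly_lrelu(),
                         ly_flatten(), ly_fc(2L * half)),
                    c(1L, 50L, 50L), derive_seed(seed, "dis/enc"))
  dec <- stack_init(list(ly_fc(su(64) * 36L), ly_bn(), ly_relu(),
                         ly_reshape(su(64), 6L, 6L),
                         ly_tconv(su(64), 4L, 2L, 1L), ly_bn(), ly_relu(),
                         ly_tconv(su(64), 4L, 2L, 1L), ly_bn(), ly_relu(),
                         ly_tconv(1L, 4L, 2L, 1L, op = 2L)),
                    half, derive_seed(seed, "dis/dec"))
  cls <- stack_init(list(ly_fc(su(128)), ly_bn(), ly_relu(), ly_dropout(0.5),
                         ly_fc(su(64)), ly_bn(), ly_relu(), ly_dropout(0.5),
                         ly_fc(4L)),
                    half, derive_seed(seed, "dis/cls"))
  structure(list(enc = enc, dec = dec, cls = cls, half = half,
                 width_scale = width_scale, seed = seed, trained = FALSE),
            class = "occl_disentangler")
}

disentangler_forward <- function(dis, x, tape = NULL, training = FALSE) {
  lat <- stack_forward(dis$enc, x, tape, training)
  fg_lat <- ag_slice_c(lat, 1L, dis$half, tape)
  bg_lat <- ag_slice_c(lat, dis$half + 1L, 2L * dis$half, tape)
  list(fg_lat = fg_lat, bg_lat = bg_lat,
       fg_img = stack_forward(dis$dec, fg_lat, tape, training),
       bg_img = stack_forward(dis$dec, bg_lat, tape, training),
       fg_cls = stack_forward(dis$cls, fg_lat, tape, training),
       bg_cls = stack_forward(dis$cls, bg_lat, tape, training))
}

#' Train the Disentangler on reconnet-regime scenes
#'
#' Loss: pixel-wise binary cross-entropy of both reconstructed single-object
#' images (weight 1 each) plus both classification cross-entropies (weight
#' 0.5 each), under the fixed reconstitution regimen.
#'
#' @param dis an \code{occl_disentangler}
#' @param ds a reconnet-regime scene dataset
#' @param epochs,batch_size,seed training configuration
#' @return the trained \code{occl_disentangler}
#' @export
train_disentangler <- function(dis, ds, epochs = 10L, batch_size = 64L,
                               seed = 1) {
  n <- length(ds$scenes)
  x <- array(0, c(1, 50, 50, n))
  fgt <- array(0, c(1, 50, 50, n))
  bgt <- array(0, c(1, 50, 50, n))
  fgl <- integer(n); bgl <- integer(n)
  for (i in seq_len(n)) {
    s <- ds$scenes[[i]]
    x[1, , , i] <- s$image
    fgt[1, , , i] <- s$fg_only
    bgt[1, , , i] <- s$bg_only
    fgl[i] <- s$fg_label + 1L
    bgl[i] <- s$bg_label + 1L
  }
  params <- c(dis$enc$params, dis$dec$params, dis$cls$params)
  st <- adam_state()
  hp <- reconnet_regimen()
  with_seed(derive_seed(seed, "dis/train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        tape <- new_tape()
        fw <- disentangler_forward(dis, ag_const(x[, , , idx, drop = FALSE]),
                                   tape, training = TRUE)
        loss <- ag_scalar_sum(list(
          ag_bce_logits(fw$fg_img, fgt[, , , idx, drop = FALSE], tape),
          ag_bce_logits(fw$bg_img, bgt[, , , idx, drop = FALSE], tape),
          ag_softmax_ce(fw$fg_cls, fgl[idx], tape),
          ag_softmax_ce(fw$bg_cls, bgl[idx], tape)),
          weights = c(1, 1, 0.5, 0.5), tape = tape)
        if (!is.finite(loss$val))
          occl_error("non-finite disentangler loss",
                     "occlnet_training_diverged")
        ag_zero_grads(params)
        ag_backward(loss, tape)
        adam_step(params, st, lr = hp$lr)
      }
    }
  })
  dis$trained <- TRUE
  dis
}

#' Disentangle a batch of two-object images
#' @param dis a trained \code{occl_disentangler}
#' @param x \code{[1,50,50,N]} images
#' @return list(fg_only, bg_only images in (0,1); fg_class, bg_class 1..4)
#' @export
infer_disentangled <- function(dis, x) {
  fw <- disentangler_forward(dis, ag_const(x))
  list(fg_only = 1 / (1 + exp(-fw$fg_img$val)),
       bg_only = 1 / (1 + exp(-fw$bg_img$val)),
       fg_class = apply(fw$fg_cls$val, 2, which.max),
       bg_class = apply(fw$bg_cls$val, 2, which.max))
}

#' Create an untrained PoseNet
#'
#' Two stacked regressors: the first estimates scale and x/y translation
#' from a single-object image; the image is then transformed by the inverse
#' of that estimate, and the second regressor estimates the rotation angle
#' (radians) from the result.
#'
#' @param seed integer seed
#' @param width_scale factor on unit counts
#' @return an \code{occl_posenet}
#' @export
make_posenet <- function(seed = 1, width_scale = 1) {
  su <- function(n) scale_units(n, width_scale)
  mk <- function(nout, nm) stack_init(
    list(ly_conv(su(128), 4L, 2L, 1L), ly_bn(), ly_relu(),
         ly_conv(su(128), 4L, 2L, 1L), ly_bn(), ly_relu(),
         ly_conv(su(128), 4L, 2L, 1L), ly_bn(), ly_relu(),
         ly_flatten(), ly_fc(su(256)), ly_bn(), ly_relu(),
         ly_fc(su(128)), ly_bn(), ly_relu(), ly_fc(nout)),
    c(1L, 50L, 50L), derive_seed(seed, nm))
  structure(list(st_net = mk(3L, "pose/st"), rot_net = mk(1L, "pose/rot"),
                 width_scale = width_scale, seed = seed, trained = FALSE),
            class = "occl_posenet")
}

# remove the estimated scale/translation from a batch of images
pose_destransform <- function(x, est) {
  n <- dim(x)[4]
  out <- array(0, dim(x))
  for (i in seq_len(n)) {
    M <- invert_affine(compose_affine(0, est[2, i], est[3, i],
                                      max(est[1, i], 1e-3)))
    out[1, , , i] <- warp(matrix(x[1, , , i], 50, 50), M, 50, 50)
  }
  out
}

#' Train PoseNet on single-object images with known transforms
#'
#' @param pn an \code{occl_posenet}
#' @param ds a reconnet-regime scene dataset (ground-truth background
#'   transforms are the regression targets)
#' @param epochs,batch_size,seed training configuration
#' @return the trained \code{occl_posenet}
#' @export
train_posenet <- function(pn, ds, epochs = 10L, batch_size = 64L, seed = 1) {
  n <- length(ds$scenes)
  x <- array(0, c(1, 50, 50, n))
  tgt_st <- matrix(0, 3, n)
  tgt_rot <- matrix(0, 1, n)
  for (i in seq_len(n)) {
    s <- ds$scenes[[i]]
    x[1, , , i] <- s$bg_only
    tr <- s$transforms
    tgt_st[, i] <- c(tr$scale, tr$bg_t[1], tr$bg_t[2])
    tgt_rot[1, i] <- tr$bg_rotation_deg * pi / 180
  }
  params1 <- pn$st_net$params
  params2 <- pn$rot_net$params
  st1 <- adam_state(); st2 <- adam_state()
  hp <- reconnet_regimen()
  with_seed(derive_seed(seed, "pose/train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        tape <- new_tape()
        est <- stack_forward(pn$st_net, ag_const(xb), tape, training = TRUE)
        loss1 <- ag_mse(est, tgt_st[, idx, drop = FALSE], tape)
        ag_zero_grads(params1)
        ag_backward(loss1, tape)
        adam_step(params1, st1, lr = hp$lr)
        # rotation is regressed only after the scale/translation estimate
        # has been inverted out of the image
        x2 <- pose_destransform(xb, est$val)
        tape <- new_tape()
        rot <- stack_forward(pn$rot_net, ag_const(x2), tape, training = TRUE)
        loss2 <- ag_mse(rot, tgt_rot[, idx, drop = FALSE], tape)
        ag_zero_grads(params2)
        ag_backward(loss2, tape)
        adam_step(params2, st2, lr = hp$lr)
      }
    }
  })
  pn$trained <- TRUE
  pn
}

#' Estimate the pose of single-object images
#' @param pn a trained \code{occl_posenet}
#' @param x \code{[1,50,50,N]} single-object images
#' @return list(scale, tx, ty, rotation_deg), each length N
#' @export
infer_pose <- function(pn, x) {
  est <- stack_forward(pn$st_net, ag_const(x), NULL)$val
  x2 <- pose_destransform(x, est)
  rot <- stack_forward(pn$rot_net, ag_const(x2), NULL)$val
  list(scale = est[1, ], tx = est[2, ], ty = est[3, ],
       rotation_deg = rot[1, ] * 180 / pi)
}
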