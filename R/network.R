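# Seeded initialization and forward semantics for the architecture zoo.
#
# Feedforward weights use Kaiming initialization, with the sqrt(2) factor
# dropped for layers not followed by a ReLU (the readouts).  Recurrent-model
# weights are normal with sd = 1/sqrt(fan_in); biases are zero except
# (Conv)LSTM forget biases, which start at 1.  Initial hidden states are
# trainable parameters initialized to zero.  Gate order inside the fused
# (Conv)LSTM weight blocks is (input, forget, cell, output).

pool_floor <- function(x) x %/% 2L

# spatial size of each conv layer's activations given the input size
layer_sizes <- function(arch, in_h = 50L) {
  sz <- integer(length(arch$conv_maps))
  cur <- in_h
  pools <- arch$pool_after %||% rep(TRUE, length(arch$conv_maps))
  for (l in seq_along(arch$conv_maps)) {
    sz[l] <- cur
    if (pools[l]) cur <- pool_floor(cur)
  }
  attr(sz, "final") <- cur
  sz
}

rnorm_arr <- function(dim, sd) array(stats::rnorm(prod(dim), 0, sd), dim = dim)

# feedforward input channels of conv layer l
ff_in_channels <- function(arch, l, in_channels) {
  if (l == 1) in_channels else arch$conv_maps[l - 1]
}

#' Initialize a network instance from an architecture spec
#'
#' @param arch an architecture spec from [make_architecture()]
#' @param seed integer seed; identical seeds reproduce identical weights
#' @param task one of "full", "background_only", "foreground_only",
#'   "unoccluded" (fixes the readout heads and the input channel count)
#' @param in_h input image side length (50 for the scene datasets)
#' @return an \code{occl_network} instance
#' @export
initialize_network <- function(arch, seed, task = "full", in_h = 50L) {
  in_ch <- task_channels(task)
  sched <- task_schedule(arch, task)
  objects <- unique(vapply(sched, function(s) s$object, ""))
  sizes <- layer_sizes(arch, in_h)
  params <- list()
  rec <- arch$type == "rec"
  add <- function(name, dim, fan, relu_next = TRUE) {
    sd <- if (rec) 1 / sqrt(fan) else if (relu_next) sqrt(2 / fan) else sqrt(1 / fan)
    params[[name]] <<- ag_param(rnorm_arr(dim, sd))
  }
  add_bias <- function(name, n) params[[name]] <<- ag_param(numeric(n))
  with_seed(derive_seed(seed, paste0("init/", arch$name, "/", task)), {
    if (!rec) {
      groups <- arch$ws_groups %||% seq_along(arch$conv_maps)
      made <- character(0)
      for (l in seq_along(arch$conv_maps)) {
        cin <- ff_in_channels(arch, l, in_ch)
        cout <- arch$conv_maps[l]
        key <- sprintf("convW_g%d_%dx%d", groups[l], cin, cout)
        if (!key %in% made) {
          add(key, c(cin, arch$kernel, arch$kernel, cout),
              cin * arch$kernel^2)
          add_bias(sub("convW", "convB", key), cout)
          made <- c(made, key)
        }
      }
      final <- attr(sizes, "final")
      # sequential variants branch their own fully connected layer per
      # object; the plain feedforward nets share one hidden fc feeding two
      # parallel readouts
      for (obj in objects) {
        bl <- if (!is.null(arch$seq)) arch$seq[[obj]]$after_conv
              else length(arch$conv_maps)
        pools <- arch$pool_after %||% rep(TRUE, length(arch$conv_maps))
        cur <- in_h
        for (l in seq_len(bl)) if (pools[l]) cur <- pool_floor(cur)
        flat <- cur * cur * (if (bl == 0) in_ch else arch$conv_maps[bl])
        fckey <- if (is.null(arch$seq)) "shared" else obj
        if (is.null(params[[paste0("fcW_", fckey)]])) {
          add(paste0("fcW_", fckey), c(flat, arch$fc_units), flat)
          add_bias(paste0("fcB_", fckey), arch$fc_units)
        }
        add(paste0("roW_", obj), c(arch$fc_units, 4L), arch$fc_units,
            relu_next = FALSE)
        add_bias(paste0("roB_", obj), 4L)
      }
    } else {
      for (l in seq_along(arch$conv_maps)) {
        cmaps <- arch$conv_maps[l]
        ffch <- ff_in_channels(arch, l, in_ch)
        fbch <- 0L
        for (e in arch$feedback_edges) if (e[2] == l) {
          # feedback 1x1 conv: out maps = feedforward maps entering layer l
          add(sprintf("fbW_%dto%d", e[1], e[2]),
              c(arch$conv_maps[e[1]], 1L, 1L, ffch), arch$conv_maps[e[1]])
          add_bias(sprintf("fbB_%dto%d", e[1], e[2]), ffch)
          fbch <- fbch + ffch
        }
        cin <- ffch + fbch + cmaps
        add(paste0("clstmW_", l), c(cin, arch$kernel, arch$kernel, 4L * cmaps),
            cin * arch$kernel^2)
        b <- numeric(4L * cmaps)
        b[(cmaps + 1L):(2L * cmaps)] <- 1  # forget gate
        params[[paste0("clstmB_", l)]] <- ag_param(b)
        params[[paste0("h0_", l)]] <- ag_param(array(0, c(cmaps, sizes[l], sizes[l], 1L)))
        params[[paste0("c0_", l)]] <- ag_param(array(0, c(cmaps, sizes[l], sizes[l], 1L)))
      }
      final <- attr(sizes, "final")
      flat <- final * final * arch$conv_maps[length(arch$conv_maps)]
      u <- arch$lstm_units
      add("lstmW", c(flat + u, 4L * u), flat + u)
      b <- numeric(4L * u)
      b[(u + 1L):(2L * u)] <- 1
      params[["lstmB"]] <- ag_param(b)
      params[["lstm_h0"]] <- ag_param(array(0, c(u, 1L)))
      params[["lstm_c0"]] <- ag_param(array(0, c(u, 1L)))
      for (obj in objects) {
        add(paste0("roW_", obj), c(u, 4L), u, relu_next = FALSE)
        add_bias(paste0("roB_", obj), 4L)
      }
    }
  })
  structure(list(arch = arch, task = task, seed = seed, in_channels = in_ch,
                 in_h = in_h, params = params, trained = FALSE),
            class = "occl_network")
}

#' Number of free parameters of an instance
#' @param instance an \code{occl_network}
#' @return integer count (shared weights counted once)
#' @export
n_params <- function(instance) {
  sum(vapply(instance$params, function(p) length(p$val), 0))
}

param_values <- function(instance) lapply(instance$params, function(p) p$val)

# ---- ConvLSTM / LSTM cells --------------------------------------------------

convlstm_step <- function(inp, h_prev, c_prev, W, b, tape) {
  z <- ag_conv2d(ag_concat_c(list(inp, h_prev), tape), W, b,
                 stride = 1L, pad = 2L, tape = tape)
  ag_lstm_cell(z, c_prev, tape)
}

lstm_step <- function(flat, h_prev, c_prev, W, b, tape) {
  z <- ag_fc(ag_concat_c(list(flat, h_prev), tape), W, b, tape)
  ag_lstm_cell(z, c_prev, tape)
}

# ---- forward ----------------------------------------------------------------

#' Run a network forward
#'
#' The static input is re-presented at every timestep.  Feedback edges
#' deliver the previous timestep's source-layer hidden state, upsampled to
#' the target resolution, passed through a 1x1 convolution and concatenated
#' with the target layer's feedforward input.  At timestep 1 the feedback
#' contribution comes from the learned initial hidden states.
#'
#' @param instance an \code{occl_network}
#' @param x input array \code{[C, H, W, N]} with C matching the task
#' @param training enables dropout
#' @param dropout_p dropout probability on the penultimate-to-readout path
#' @param tape an autodiff tape (NULL for inference)
#' @param inject optional hidden-state transplant:
#'   \code{list(after_t =, layers =, states =)} replaces the named layers'
#'   (h, c) with donor values at the end of timestep \code{after_t}
#' @param collect_states return all hidden states per layer and timestep
#' @return list(logits = per-object list of \code{[4, N]} value nodes,
#'   states = optional per-timestep states)
#' @export
network_forward <- function(instance, x, training = FALSE, dropout_p = 0,
                            tape = NULL, inject = NULL,
                            collect_states = FALSE) {
  arch <- instance$arch
  p <- instance$params
  d <- dim(x)
  if (length(d) != 4 || d[1] != instance$in_channels ||
      d[2] != instance$in_h || d[3] != instance$in_h)
    occl_error(sprintf("input shape [%s] does not match task '%s' (expect C=%d, H=%d)",
                       paste(d, collapse = ","), instance$task,
                       instance$in_channels, instance$in_h),
               "occlnet_invalid_argument")
  n <- d[4]
  xin <- ag_const(x)
  sched <- task_schedule(arch, instance$task)
  logits <- list()
  states_out <- list()
  if (arch$type == "ff") {
    groups <- arch$ws_groups %||% seq_along(arch$conv_maps)
    pools <- arch$pool_after %||% rep(TRUE, length(arch$conv_maps))
    cur <- xin
    taps <- list()
    for (l in seq_along(arch$conv_maps)) {
      cin <- ff_in_channels(arch, l, instance$in_channels)
      key <- sprintf("convW_g%d_%dx%d", groups[l], cin, arch$conv_maps[l])
      cur <- ag_relu(ag_conv2d(cur, p[[key]], p[[sub("convW", "convB", key)]],
                               stride = 1L, pad = 2L, tape = tape), tape)
      if (pools[l]) cur <- ag_maxpool2(cur, tape)
      taps[[l]] <- cur
    }
    for (entry in sched) {
      obj <- entry$object
      bl <- if (!is.null(arch$seq)) arch$seq[[obj]]$after_conv
            else length(arch$conv_maps)
      src <- if (bl == 0) xin else taps[[bl]]
      sd <- dim(src$val)
      flat <- ag_reshape(src, c(prod(sd[1:3]), n), tape)
      fckey <- if (is.null(arch$seq)) "shared" else obj
      hid <- ag_relu(ag_fc(flat, p[[paste0("fcW_", fckey)]],
                           p[[paste0("fcB_", fckey)]], tape), tape)
      hid <- ag_dropout(hid, dropout_p, training, tape)
      logits[[obj]] <- ag_fc(hid, p[[paste0("roW_", obj)]],
                             p[[paste0("roB_", obj)]], tape)
    }
    if (collect_states)
      states_out[[1]] <- list(conv = lapply(taps, function(t) list(h = t$val)))
  } else {
    L <- length(arch$conv_maps)
    h <- lapply(seq_len(L), function(l) ag_bcast_n(p[[paste0("h0_", l)]], n, tape))
    cst <- lapply(seq_len(L), function(l) ag_bcast_n(p[[paste0("c0_", l)]], n, tape))
    lh <- ag_bcast_n(p[["lstm_h0"]], n, tape)
    lc <- ag_bcast_n(p[["lstm_c0"]], n, tape)
    for (t in seq_len(arch$n_timesteps)) {
      h_prev <- h; c_prev <- cst
      below <- xin
      for (l in seq_len(L)) {
        inp <- below
        for (e in arch$feedback_edges) {
          if (e[2] != l) next
          src <- h_prev[[e[1]]]
          tgt_hw <- dim(inp$val)[2:3]
          fb <- ag_upsample_nn(src, tgt_hw[1], tgt_hw[2], tape)
          fb <- ag_conv2d(fb, p[[sprintf("fbW_%dto%d", e[1], e[2])]],
                          p[[sprintf("fbB_%dto%d", e[1], e[2])]],
                          stride = 1L, pad = 0L, tape = tape)
          inp <- ag_concat_c(list(inp, fb), tape)
        }
        st <- convlstm_step(inp, h_prev[[l]], c_prev[[l]],
                            p[[paste0("clstmW_", l)]], p[[paste0("clstmB_", l)]],
                            tape)
        h[[l]] <- st$h; cst[[l]] <- st$c
        below <- ag_maxpool2(st$h, tape)
      }
      bd <- dim(below$val)
      flat <- ag_reshape(below, c(prod(bd[1:3]), n), tape)
      lst <- lstm_step(flat, lh, lc, p[["lstmW"]], p[["lstmB"]], tape)
      lh <- lst$h; lc <- lst$c
      # readouts fire before any state transplant at this timestep, so a
      # swap "after timestep t" cannot touch the prediction made at t
      for (entry in sched) {
        if (entry$timestep != t) next
        obj <- entry$object
        hid <- ag_dropout(lh, dropout_p, training, tape)
        logits[[obj]] <- ag_fc(hid, p[[paste0("roW_", obj)]],
                               p[[paste0("roB_", obj)]], tape)
      }
      if (!is.null(inject) && inject$after_t == t) {
        for (lyr in inject$layers) {
          if (lyr == "lstm") {
            lh <- ag_const(inject$states$lstm$h)
            lc <- ag_const(inject$states$lstm$c)
          } else {
            li <- as.integer(lyr)
            h[[li]] <- ag_const(inject$states$conv[[li]]$h)
            cst[[li]] <- ag_const(inject$states$conv[[li]]$c)
          }
        }
      }
      if (collect_states) {
        states_out[[t]] <- list(
          conv = lapply(seq_len(L), function(l)
            list(h = h[[l]]$val, c = cst[[l]]$val)),
          lstm = list(h = lh$val, c = lc$val))
      }
    }
  }
  list(logits = logits, states = if (collect_states) states_out else NULL)
}
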