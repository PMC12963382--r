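# Representational similarity by linear mapping: ordinary least squares from
# one network's layer activations to another's, per-unit held-out Pearson
# correlation, median over units, averaged over instance pairs; the noise
# ceiling is the same statistic across distinct instances of the target
# regime.

#' Construct an activation set
#'
#' @param mat images x units matrix of activations
#' @param unit_ids indices of the sampled units
#' @param layer,timestep,probe bookkeeping tags
#' @return an \code{occl_activations}
#' @export
activation_set <- function(mat, unit_ids = seq_len(ncol(mat)), layer = NA,
                           timestep = NA_integer_, probe = NA_character_) {
  structure(list(matrix = mat, unit_ids = unit_ids, layer = layer,
                 timestep = timestep, probe = probe),
            class = "occl_activations")
}

#' Extract layer activations from a network instance
#'
#' Convolutional/ConvLSTM layers are subsampled to \code{n_sample} random
#' unit positions (constant-zero units are resampled away); fully connected
#' and LSTM layers contribute all units.
#'
#' @param instance an \code{occl_network}
#' @param x input tensor \code{[C,H,W,N]}
#' @param layer conv layer index, or "lstm" / "fc"
#' @param timestep timestep to read (recurrent instances)
#' @param n_sample units to sample from convolutional layers
#' @param seed integer seed for the unit sample
#' @param probe probe tag recorded on the result
#' @return an \code{occl_activations} (images x units)
#' @export
extract_activations <- function(instance, x, layer, timestep = 1L,
                                n_sample = 256L, seed = 1,
                                probe = NA_character_) {
  arch <- instance$arch
  out <- network_forward(instance, x, collect_states = TRUE)
  if (arch$type == "rec") {
    if (timestep < 1 || timestep > arch$n_timesteps)
      occl_error("invalid timestep", "occlnet_invalid_argument")
    st <- out$states[[timestep]]
    if (identical(layer, "lstm")) {
      mat <- t(st$lstm$h)
      return(activation_set(mat, seq_len(ncol(mat)), layer, timestep, probe))
    }
    li <- as.integer(layer)
    if (is.na(li) || li < 1 || li > length(arch$conv_maps))
      occl_error("invalid layer", "occlnet_invalid_argument")
    h <- st$conv[[li]]$h
  } else {
    if (identical(layer, "fc"))
      occl_error("use extract_activations on conv layers or 'lstm' for recurrent instances; feedforward fc taps are not collected",
                 "occlnet_invalid_argument")
    li <- as.integer(layer)
    if (is.na(li) || li < 1 || li > length(arch$conv_maps))
      occl_error("invalid layer", "occlnet_invalid_argument")
    h <- out$states[[1]]$conv[[li]]$h
  }
  d <- dim(h)
  m <- t(matrix(h, nrow = prod(d[1:3])))  # images x all units
  n_units <- ncol(m)
  ids <- with_seed(derive_seed(seed, paste0("units/", layer, "/", timestep)), {
    pool <- seq_len(n_units)
    picked <- integer(0)
    while (length(picked) < min(n_sample, n_units) && length(pool) > 0) {
      take <- sample(pool, min(length(pool), n_sample - length(picked)))
      ok <- take[apply(m[, take, drop = FALSE], 2, function(col) any(col != 0))]
      picked <- c(picked, ok)
      pool <- setdiff(pool, take)
    }
    sort(picked)
  })
  activation_set(m[, ids, drop = FALSE], ids, layer, timestep, probe)
}

#' Linear-mapping representational similarity
#'
#' Ordinary least squares (with intercept, no penalty) from the source
#' units to each target unit on a fit partition; Pearson correlation
#' between predicted and actual activations per target unit on the held-out
#' partition; the median over target units is the similarity.
#'
#' @param source,target \code{occl_activations} over the same images
#' @param train_frac fraction of images used to fit the map
#' @param seed seed for the fit/held-out split
#' @return the similarity value in \[-1, 1\]
#' @export
linear_map_similarity <- function(source, target, train_frac = 0.8, seed = 1) {
  xs <- source$matrix
  yt <- target$matrix
  if (nrow(xs) != nrow(yt))
    occl_error("source and target must cover the same images",
               "occlnet_invalid_argument")
  n <- nrow(xs)
  idx <- with_seed(derive_seed(seed, "simsplit"), sample.int(n))
  n_fit <- floor(train_frac * n)
  fit_i <- idx[seq_len(n_fit)]
  held_i <- idx[(n_fit + 1L):n]
  if (length(held_i) < 10)
    occl_error("fewer than 10 held-out images", "occlnet_invalid_argument")
  X <- cbind(1, xs[fit_i, , drop = FALSE])
  Y <- yt[fit_i, , drop = FALSE]
  qrX <- qr(X)
  B <- if (qrX$rank < ncol(X)) {
    warning("rank-deficient linear map; using least-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  } else {
    qr.coef(qrX, Y)
  }
  pred <- cbind(1, xs[held_i, , drop = FALSE]) %*% B
  obs <- yt[held_i, , drop = FALSE]
  rs <- vapply(seq_len(ncol(obs)), function(j) {
    if (stats::sd(obs[, j]) == 0 || stats::sd(pred[, j]) == 0) return(0)
    stats::cor(pred[, j], obs[, j])
  }, 0)
  stats::median(rs)
}

#' Instance-variability noise ceiling
#'
#' The mean linear-mapping similarity over all ordered pairs of *distinct*
#' instances of one regime: with 5 instances, 20 pairs.
#'
#' @param acts list (length >= 2) of \code{occl_activations}, one per
#'   instance, over the same images
#' @inheritParams linear_map_similarity
#' @return list(ceiling = mean similarity, n_pairs)
#' @export
noise_ceiling <- function(acts, train_frac = 0.8, seed = 1) {
  k <- length(acts)
  if (k < 2)
    occl_error("noise ceiling needs at least 2 instances",
               "occlnet_invalid_argument")
  vals <- c()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    vals <- c(vals, linear_map_similarity(acts[[i]], acts[[j]],
                                          train_frac, seed))
  }
  list(ceiling = mean(vals), n_pairs = length(vals))
}

#' Compare internal representations across training regimes
#'
#' For each (layer, timestep, probe) cell: the mean similarity over all
#' source x target instance pairs (source = the non-occlusion-trained
#' group by default) and the target group's noise ceiling.
#'
#' @param source_instances,target_instances lists of trained
#'   \code{occl_network} instances with matching architectures
#' @param probes named list of input tensors (e.g. occluded / unoccluded)
#' @param layers conv layer indices and/or "lstm"
#' @param timesteps timesteps to probe
#' @param n_sample,seed unit sampling controls
#' @return a long-format data.frame with columns layer, timestep, probe,
#'   similarity, ceiling, n_pairs, n_ceiling_pairs
#' @export
compare_training_regimes <- function(source_instances, target_instances,
                                     probes, layers, timesteps = 1L,
                                     n_sample = 256L, seed = 1) {
  a1 <- source_instances[[1]]$arch
  a2 <- target_instances[[1]]$arch
  if (!identical(a1$conv_maps, a2$conv_maps))
    occl_error("architectures differ across regimes",
               "occlnet_invalid_argument")
  rows <- list()
  for (pn in names(probes)) {
    for (ly in layers) {
      for (ts in timesteps) {
        src_a <- lapply(source_instances, extract_activations, x = probes[[pn]],
                        layer = ly, timestep = ts, n_sample = n_sample,
                        seed = seed, probe = pn)
        tgt_a <- lapply(target_instances, extract_activations, x = probes[[pn]],
                        layer = ly, timestep = ts, n_sample = n_sample,
                        seed = seed, probe = pn)
        vals <- c()
        for (s in src_a) for (t in tgt_a)
          vals <- c(vals, linear_map_similarity(s, t, seed = seed))
        ceil <- noise_ceiling(tgt_a, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          layer = as.character(ly), timestep = ts, probe = pn,
          similarity = mean(vals), ceiling = ceil$ceiling,
          n_pairs = length(vals), n_ceiling_pairs = ceil$n_pairs)
      }
    }
  }
  do.call(rbind, rows)
}
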