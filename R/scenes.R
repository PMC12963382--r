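# Scene composition: affine warps in normalized coordinates, two-threshold
# segmentation, overlay with exact occlusion-level bookkeeping, and balanced
# dataset assembly by rejection sampling.

.scene_size <- 50L

#' Build a 2x3 affine map in normalized coordinates
#'
#' The map sends output (target) coordinates to input (source) coordinates,
#' in the spatial-transformer convention where corner pixels sit at
#' normalized +/-1: \code{matrix = [scale * R(rotation) | t]}.  A scale
#' factor above 1 shrinks the object in the target frame.
#'
#' @param rotation_deg rotation angle in degrees
#' @param tx,ty translation components in normalized units
#' @param scale positive scale factor
#' @return a 2x3 numeric matrix
#' @export
compose_affine <- function(rotation_deg, tx = 0, ty = 0, scale = 1) {
  if (!is.finite(scale) || scale <= 0)
    occl_error("scale must be positive", "occlnet_invalid_argument")
  th <- rotation_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cbind(scale * r, c(tx, ty))
}

#' Invert a 2x3 affine map
#' @param A a 2x3 affine map
#' @return the 2x3 map of the inverse transformation
#' @export
invert_affine <- function(A) {
  L <- A[, 1:2]
  dt <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  if (!is.finite(dt) || abs(dt) < 1e-12)
    occl_error("non-invertible affine map", "occlnet_numeric_error")
  Li <- matrix(c(L[2, 2], -L[2, 1], -L[1, 2], L[1, 1]), 2, 2) / dt
  cbind(Li, -Li %*% A[, 3])
}

#' Warp an image under an affine map
#'
#' Bilinear interpolation in normalized coordinates; samples falling outside
#' the source frame contribute 0 (black background semantics).
#'
#' @param image numeric matrix
#' @param map 2x3 affine map (target to source)
#' @param out_h,out_w output size
#' @return an out_h x out_w matrix
#' @export
warp <- function(image, map, out_h, out_w) {
  if (length(image) == 0)
    occl_error("empty input image", "occlnet_invalid_argument")
  if (out_h < 1 || out_w < 1)
    occl_error("degenerate output size", "occlnet_invalid_argument")
  cpp_warp_bilinear(image, map, as.integer(out_h), as.integer(out_w))
}

#' Sample the random transforms for one scene
#'
#' Comparison regime: rotations independently uniform on (-180, 180); one
#' translation drawn in polar form (radial distance uniform on
#' \[0.1, 0.15\], angle uniform on (-180, 180)) and applied with opposite
#' signs to the two objects.  Reconnet regime: fixed scale 2.2, independent
#' rotations, independent x/y translations uniform on \[-0.55, 0.55\].
#' Transform-only regimes carry a single object with one transform family
#' suppressed.
#'
#' @param regime one of "comparison", "reconnet", "translation_only",
#'   "rotation_only"
#' @return a list of transform parameters (see fields in the source)
#' @export
sample_scene_transforms <- function(regime = c("comparison", "reconnet",
                                               "translation_only",
                                               "rotation_only")) {
  regime <- match.arg(regime)
  rot <- function() stats::runif(1, -180, 180)
  out <- list(regime = regime)
  if (regime == "comparison") {
    out$fg_rotation_deg <- rot()
    out$bg_rotation_deg <- rot()
    out$radial_dist <- stats::runif(1, 0.1, 0.15)
    out$trans_angle_deg <- rot()
    phi <- out$trans_angle_deg * pi / 180
    out$fg_t <- out$radial_dist * c(cos(phi), sin(phi))
    out$bg_t <- -out$fg_t
    out$scale <- 1
  } else if (regime == "reconnet") {
    out$fg_rotation_deg <- rot()
    out$bg_rotation_deg <- rot()
    out$fg_t <- stats::runif(2, -0.55, 0.55)
    out$bg_t <- stats::runif(2, -0.55, 0.55)
    out$radial_dist <- NA_real_
    out$trans_angle_deg <- NA_real_
    out$scale <- 2.2
  } else if (regime == "translation_only") {
    out$fg_rotation_deg <- 0
    out$bg_rotation_deg <- NA_real_
    out$radial_dist <- stats::runif(1, 0.1, 0.15)
    out$trans_angle_deg <- rot()
    phi <- out$trans_angle_deg * pi / 180
    out$fg_t <- out$radial_dist * c(cos(phi), sin(phi))
    out$bg_t <- c(NA_real_, NA_real_)
    out$scale <- 1
  } else {
    out$fg_rotation_deg <- rot()
    out$bg_rotation_deg <- NA_real_
    out$fg_t <- c(0, 0)
    out$bg_t <- c(NA_real_, NA_real_)
    out$radial_dist <- 0
    out$trans_angle_deg <- NA_real_
    out$scale <- 1
  }
  out
}

#' Two-threshold segmentation mask
#'
#' A rough mask keeps pixels above 0.01; the final mask keeps pixels above
#' 10 percent of the mean pixel value inside the rough mask.
#'
#' @param image numeric matrix in \[0,1\]
#' @return a logical matrix of the same shape
#' @export
segment <- function(image) {
  rough <- image > 0.01
  if (!any(rough))
    occl_error("segmentation found no object pixels", "occlnet_empty_object")
  m <- mean(image[rough])
  image > 0.1 * m
}

#' Occlusion level of a mask pair
#'
#' The fraction of the background-object mask covered by the foreground
#' mask: \code{|fg & bg| / |bg|}.
#'
#' @param fg_mask,bg_mask logical matrices of equal shape
#' @return a fraction in \[0,1\]
#' @export
occlusion_level <- function(fg_mask, bg_mask) {
  nb <- sum(bg_mask)
  if (nb == 0)
    occl_error("empty background mask", "occlnet_division_by_zero")
  sum(fg_mask & bg_mask) / nb
}

pad_to_50 <- function(px) {
  out <- matrix(0, .scene_size, .scene_size)
  out[12:39, 12:39] <- px
  out
}

scene_affine <- function(rotation_deg, t, scale) {
  compose_affine(rotation_deg, t[1], t[2], scale)
}

warp_object <- function(obj, rotation_deg, t, transforms) {
  if (transforms$regime %in% c("comparison", "translation_only",
                               "rotation_only")) {
    src <- pad_to_50(obj$pixels)
    warp(src, scene_affine(rotation_deg, t, 1), .scene_size, .scene_size)
  } else {
    warp(obj$pixels, scene_affine(rotation_deg, t, transforms$scale),
         .scene_size, .scene_size)
  }
}

#' Compose an occlusion scene from two objects
#'
#' Warps both objects to 50x50 (zero-pad-then-warp in the comparison regime;
#' direct warp at fixed scale 2.2 in the reconnet regime), segments each with
#' [segment()], overlays the foreground over the background via the
#' foreground mask, and records the occlusion level and the two
#' single-object channel images.
#'
#' @param fg,bg objects (see [generate_object()])
#' @param transforms a transform pair from [sample_scene_transforms()]
#' @return an \code{occl_scene}
#' @export
compose_scene <- function(fg, bg, transforms) {
  fg_only <- warp_object(fg, transforms$fg_rotation_deg, transforms$fg_t,
                         transforms)
  bg_only <- warp_object(bg, transforms$bg_rotation_deg, transforms$bg_t,
                         transforms)
  fg_mask <- segment(fg_only)
  bg_mask <- segment(bg_only)
  image <- bg_only
  image[fg_mask] <- fg_only[fg_mask]
  structure(list(image = image,
                 fg_label = fg$class_id, bg_label = bg$class_id,
                 fg_instance = fg$instance_id, bg_instance = bg$instance_id,
                 occlusion_level = occlusion_level(fg_mask, bg_mask),
                 fg_mask = fg_mask, bg_mask = bg_mask,
                 fg_only = fg_only, bg_only = bg_only,
                 transforms = transforms),
            class = "occl_scene")
}

# single-object scene for the transform-only datasets
compose_single <- function(obj, transforms) {
  img <- warp_object(obj, transforms$fg_rotation_deg, transforms$fg_t,
                     transforms)
  structure(list(image = img, fg_label = obj$class_id, bg_label = NA_integer_,
                 occlusion_level = 0, fg_mask = segment(img), bg_mask = NULL,
                 fg_only = img, bg_only = NULL, transforms = transforms),
            class = "occl_scene")
}

#' Specification of a scene dataset
#'
#' @param occ_min,occ_max occlusion-level range (fractions)
#' @param bin_width width of the balancing bins; the range must be an
#'   integer number of bins
#' @param n_images total number of scenes
#' @param regime sampling regime (see [sample_scene_transforms()])
#' @param balance if TRUE, every (bin x (fg,bg) label pair) cell receives
#'   exactly the same number of scenes
#' @return a \code{occl_dataset_spec} list
#' @export
dataset_spec <- function(occ_min = 0.50, occ_max = 0.75, bin_width = 0.05,
                         n_images = 800, regime = "comparison",
                         balance = TRUE) {
  if (occ_min >= occ_max)
    occl_error("occ_min must be below occ_max", "occlnet_invalid_argument")
  nbins <- (occ_max - occ_min) / bin_width
  if (abs(nbins - round(nbins)) > 1e-9)
    occl_error("occlusion range must be divisible by bin_width",
               "occlnet_invalid_argument")
  nbins <- as.integer(round(nbins))
  if (balance && n_images > 0 && n_images %% (nbins * 16L) != 0)
    occl_error("n_images must be divisible by (#bins x 16 label pairs)",
               "occlnet_invalid_argument")
  structure(list(occ_min = occ_min, occ_max = occ_max, bin_width = bin_width,
                 n_bins = nbins, n_images = as.integer(n_images),
                 regime = regime, balance = balance),
            class = "occl_dataset_spec")
}

occ_bin_of <- function(occ, spec) {
  b <- as.integer(floor((occ - spec$occ_min) / spec$bin_width)) + 1L
  # the top edge belongs to the last bin
  min(max(b, 1L), spec$n_bins)
}

#' Build a (balanced) scene dataset by rejection sampling
#'
#' Draws object pairs and transforms until every
#' (occlusion-bin x (fg,bg) label pair) cell holds exactly
#' \code{n_images / (n_bins * 16)} scenes (balanced mode), or until
#' \code{n_images} scenes inside the occlusion range have been accepted.
#' Deterministic under \code{seed}.
#'
#' @param bank an object bank
#' @param spec a [dataset_spec()]
#' @param seed integer seed
#' @param attempt_factor rejection budget: at most
#'   \code{attempt_factor * n_images} draws before failing with a per-cell
#'   progress report
#' @return an \code{occl_scene_dataset}
#' @export
build_dataset <- function(bank, spec, seed = 1, attempt_factor = 500) {
  if (length(bank$objects) == 0)
    occl_error("empty object bank", "occlnet_invalid_argument")
  if (spec$n_images == 0)
    return(structure(list(scenes = list(), spec = spec, seed = seed),
                     class = "occl_scene_dataset"))
  by_class <- split(bank$objects,
                    vapply(bank$objects, function(o) o$class_id, 0L))
  quota <- if (spec$balance) spec$n_images %/% (spec$n_bins * 16L) else NA
  cells <- if (spec$balance) {
    array(0L, dim = c(spec$n_bins, 4, 4))
  } else NULL
  scenes <- vector("list", spec$n_images)
  kept <- 0L
  with_seed(derive_seed(seed, "build_dataset"), {
    budget <- attempt_factor * spec$n_images
    for (att in seq_len(budget)) {
      if (spec$balance) {
        # draw objects for a label pair that still has an unfilled cell;
        # the occlusion bin itself cannot be targeted and stays rejection-based
        open_pair <- which(apply(cells, c(2, 3), sum) < spec$n_bins * quota,
                           arr.ind = TRUE)
        pick <- open_pair[sample.int(nrow(open_pair), 1L), ]
        fg_cls <- pick[1] - 1L
        bg_cls <- pick[2] - 1L
      } else {
        fg_cls <- sample.int(4, 1) - 1L
        bg_cls <- sample.int(4, 1) - 1L
      }
      fg <- by_class[[as.character(fg_cls)]][[
        sample.int(length(by_class[[as.character(fg_cls)]]), 1)]]
      bg <- by_class[[as.character(bg_cls)]][[
        sample.int(length(by_class[[as.character(bg_cls)]]), 1)]]
      tr <- sample_scene_transforms(spec$regime)
      sc <- tryCatch(compose_scene(fg, bg, tr),
                     occlnet_empty_object = function(e) NULL)
      if (is.null(sc)) next
      if (sc$occlusion_level < spec$occ_min ||
          sc$occlusion_level > spec$occ_max) next
      if (spec$balance) {
        b <- occ_bin_of(sc$occlusion_level, spec)
        if (cells[b, fg_cls + 1L, bg_cls + 1L] >= quota) next
        cells[b, fg_cls + 1L, bg_cls + 1L] <-
          cells[b, fg_cls + 1L, bg_cls + 1L] + 1L
      }
      kept <- kept + 1L
      scenes[[kept]] <- sc
      if (kept == spec$n_images) break
    }
  })
  if (kept < spec$n_images) {
    prog <- if (spec$balance) {
      paste(sprintf("bin %d: %d/%d", seq_len(spec$n_bins),
                    apply(cells, 1, sum), 16L * quota), collapse = "; ")
    } else sprintf("%d/%d scenes", kept, spec$n_images)
    occl_error(paste("rejection sampling budget exhausted:", prog),
               "occlnet_sampling_exhausted")
  }
  structure(list(scenes = scenes, spec = spec, seed = seed),
            class = "occl_scene_dataset")
}

#' Two-channel unoccluded input for a scene
#'
#' Channel 1 holds the foreground-only image and channel 2 the
#' background-only image, under the same transforms as the occluded scene.
#'
#' @param scene an \code{occl_scene}
#' @return a 50 x 50 x 2 array
#' @export
make_unoccluded_input <- function(scene) {
  if (is.null(scene$fg_only) || is.null(scene$bg_only))
    occl_error("scene lacks channel images", "occlnet_invalid_argument")
  array(c(scene$fg_only, scene$bg_only), dim = c(.scene_size, .scene_size, 2))
}

#' Transform a reconnet-regime scene back to the background object's pose
#'
#' Applies the inverse of the background object's affine map to the composed
#' image and to the foreground-only image, downsampling both to 28x28.
#'
#' @param scene an \code{occl_scene} from the reconnet regime
#' @return list(x = occluded background image, x_f = foreground image), both
#'   28x28
#' @export
to_original_pose <- function(scene) {
  tr <- scene$transforms
  if (tr$regime != "reconnet")
    occl_error("to_original_pose expects a reconnet-regime scene",
               "occlnet_invalid_argument")
  A <- scene_affine(tr$bg_rotation_deg, tr$bg_t, tr$scale)
  Ai <- invert_affine(A)
  list(x = warp(scene$image, Ai, 28, 28),
       x_f = warp(scene$fg_only, Ai, 28, 28))
}

#' Occlusion-bin histogram of a dataset
#' @param ds a scene dataset
#' @return integer vector of per-bin counts
#' @export
occlusion_histogram <- function(ds) {
  occ <- vapply(ds$scenes, function(s) s$occlusion_level, 0)
  tabulate(vapply(occ, occ_bin_of, 0L, spec = ds$spec), nbins = ds$spec$n_bins)
}
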