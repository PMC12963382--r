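# Hidden-state replacement experiments: does foreground information carried
# in the recurrent state causally support background recognition?

#' Edit the foreground object of a scene
#'
#' Builds a paired scene in which only the foreground object differs -
#' its category ("category": different-class object, same transform), its
#' orientation ("orientation": resampled rotation, same object), or both -
#' while the background channel, transform and label stay bit-identical to
#' the original.
#'
#' @param scene a comparison-regime \code{occl_scene}
#' @param mode one of "category", "orientation", "both"
#' @param bank object bank to draw replacement foregrounds from
#' @param seed integer seed
#' @param budget resampling attempts (used both when an edit yields an
#'   empty segmentation and to keep the occlusion level close to the
#'   original; orientation-only edits need a generous budget because
#'   re-rotating the same object explores a narrow occlusion range)
#' @param occ_tol resample until the edited occlusion level is within this
#'   distance of the original's, so that edits change the foreground
#'   object without shifting the occlusion distribution; after the budget
#'   the closest attempt is kept
#' @param occ_range optional c(min, max): additionally keep the edited
#'   occlusion level inside the dataset's retained range, so both the
#'   original and edited samples see the same truncation
#' @return an \code{occl_scene}
#' @export
make_edited_scene <- function(scene, mode = c("category", "orientation", "both"),
                              bank, seed = 1, budget = 250L, occ_tol = 0.025,
                              occ_range = NULL) {
  mode <- match.arg(mode)
  if (scene$transforms$regime != "comparison")
    occl_error("foreground edits are defined for comparison-regime scenes",
               "occlnet_invalid_argument")
  best <- NULL
  best_gap <- Inf
  with_seed(derive_seed(seed, paste0("edit/", mode)), {
    for (att in seq_len(budget)) {
      tr <- scene$transforms
      fg_obj <- NULL
      if (mode %in% c("category", "both")) {
        other <- Filter(function(o) o$class_id != scene$fg_label, bank$objects)
        fg_obj <- other[[sample.int(length(other), 1)]]
      }
      if (mode %in% c("orientation", "both")) {
        tr$fg_rotation_deg <- stats::runif(1, -180, 180)
      }
      if (is.null(fg_obj)) {
        # same object re-warped under the new rotation
        fg_obj <- structure(list(pixels = NULL, class_id = scene$fg_label),
                            class = "occl_object")
        fg_only <- warp(pad_to_50(scene_fg_source(scene)),
                        scene_affine(tr$fg_rotation_deg, tr$fg_t, 1), 50, 50)
      } else {
        fg_only <- warp_object(fg_obj, tr$fg_rotation_deg, tr$fg_t, tr)
      }
      fg_mask <- tryCatch(segment(fg_only),
                          occlnet_empty_object = function(e) NULL)
      if (is.null(fg_mask)) next
      image <- scene$bg_only
      image[fg_mask] <- fg_only[fg_mask]
      occ <- occlusion_level(fg_mask, scene$bg_mask)
      cand <- structure(list(
        image = image, fg_label = fg_obj$class_id, bg_label = scene$bg_label,
        occlusion_level = occ,
        fg_mask = fg_mask, bg_mask = scene$bg_mask,
        fg_only = fg_only, bg_only = scene$bg_only, transforms = tr),
        class = "occl_scene")
      gap <- abs(occ - scene$occlusion_level)
      in_range <- is.null(occ_range) ||
        (occ >= occ_range[1] && occ <= occ_range[2])
      if (!in_range) gap <- gap + 1  # keep only as a last resort
      if (gap <= occ_tol) return(cand)
      if (gap < best_gap) {
        best <- cand
        best_gap <- gap
      }
    }
    if (is.null(best))
      occl_error("could not produce a segmentable edited foreground",
                 "occlnet_empty_object")
    best
  })
}

# recover the un-warped foreground source for orientation edits: scenes keep
# only warped channels, so the original 28x28 pixels are re-derived by
# inverse-warping the stored foreground channel
scene_fg_source <- function(scene) {
  tr <- scene$transforms
  A <- scene_affine(tr$fg_rotation_deg, tr$fg_t, 1)
  src50 <- warp(scene$fg_only, invert_affine(A), 50, 50)
  src50[12:39, 12:39]
}

#' Edit every scene of a dataset
#' @inheritParams make_edited_scene
#' @param ds a scene dataset
#' @return a scene dataset of edited scenes, paired 1:1 with the input
#' @export
edit_dataset <- function(ds, mode, bank, seed = 1) {
  rng <- c(ds$spec$occ_min, ds$spec$occ_max)
  scenes <- lapply(seq_along(ds$scenes), function(i)
    make_edited_scene(ds$scenes[[i]], mode, bank,
                      seed = derive_seed(seed, paste0("scene", i)),
                      occ_range = rng))
  structure(list(scenes = scenes, spec = ds$spec, seed = seed),
            class = "occl_scene_dataset")
}

perturb_layer_sets <- function(arch) {
  c(as.list(as.character(seq_along(arch$conv_maps))), list("lstm"),
    list("all"))
}

expand_layer_set <- function(layer_set, arch) {
  if (identical(layer_set, "all"))
    c(as.character(seq_along(arch$conv_maps)), "lstm")
  else as.character(layer_set)
}

#' Hidden-state swap evaluation
#'
#' Runs the model on each edited (donor) scene to the end of timestep 1,
#' transplants the selected layers' hidden and cell states into the run on
#' the original scene, and continues to timestep 2.  Reports background
#' accuracy (timestep 2, perturbed run) and foreground accuracy (timestep 1;
#' the swap happens after that readout, so it reflects the unperturbed
#' pass), alongside unperturbed baselines.
#'
#' @param instance a trained 2-timestep foreground-first recurrent instance
#' @param ds original scenes; \code{edited_ds} must be paired 1:1
#' @param edited_ds dataset of foreground-edited twins
#' @param layer_set layers to transplant: a subset of layer indices and
#'   "lstm", or "all"
#' @param batch_size evaluation batch size
#' @return list(bg_accuracy, fg_accuracy, baseline_bg, baseline_fg, n)
#' @export
hidden_state_swap_eval <- function(instance, ds, edited_ds, layer_set = "all",
                                   batch_size = 128L) {
  arch <- instance$arch
  if (arch$type != "rec" || arch$n_timesteps != 2L ||
      arch$schedule[[1]]$object != "foreground")
    occl_error("swap evaluation expects a 2-timestep foreground-first recurrent model",
               "occlnet_invalid_argument")
  if (length(ds$scenes) != length(edited_ds$scenes))
    occl_error("original and edited datasets must be paired 1:1",
               "occlnet_invalid_argument")
  layers <- expand_layer_set(layer_set, arch)
  te <- dataset_tensors(ds, instance$task)
  td <- dataset_tensors(edited_ds, instance$task)
  n <- dim(te$x)[4]
  pred_fg <- integer(n); pred_bg <- integer(n)
  base_fg <- integer(n); base_bg <- integer(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    donor <- network_forward(instance, td$x[, , , idx, drop = FALSE],
                             collect_states = TRUE)
    out <- network_forward(instance, te$x[, , , idx, drop = FALSE],
                           inject = list(after_t = 1L, layers = layers,
                                         states = donor$states[[1]]))
    base <- network_forward(instance, te$x[, , , idx, drop = FALSE])
    pred_fg[idx] <- apply(out$logits$foreground$val, 2, which.max)
    pred_bg[idx] <- apply(out$logits$background$val, 2, which.max)
    base_fg[idx] <- apply(base$logits$foreground$val, 2, which.max)
    base_bg[idx] <- apply(base$logits$background$val, 2, which.max)
  }
  list(bg_accuracy = mean(pred_bg == te$bg),
       fg_accuracy = mean(pred_fg == te$fg),
       baseline_bg = mean(base_bg == te$bg),
       baseline_fg = mean(base_fg == te$fg),
       layer_set = layer_set, n = n)
}
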