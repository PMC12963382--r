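# Evaluation harness and the explaining-away comparisons: background and
# foreground accuracy deltas across tasks, prediction orders, and the
# sequential feedforward variants.

#' Evaluate a trained instance on a held-out dataset
#'
#' Predictions are the argmax over the 4 class logits at each scheduled
#' readout (ties broken toward the lowest class index).
#'
#' @param instance a trained \code{occl_network}
#' @param ds a scene dataset
#' @param task task tag the instance was trained on
#' @param batch_size evaluation minibatch size
#' @return an \code{occl_eval}: per-object accuracies, predictions, n_test
#' @export
evaluate <- function(instance, ds, task = instance$task, batch_size = 128L) {
  if (!identical(task, instance$task))
    occl_error("instance was trained on a different task",
               "occlnet_invalid_argument")
  te <- dataset_tensors(ds, task)
  n <- dim(te$x)[4]
  sched <- task_schedule(instance$arch, task)
  objects <- vapply(sched, function(s) s$object, "")
  preds <- lapply(objects, function(o) integer(n))
  names(preds) <- objects
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    out <- network_forward(instance, te$x[, , , idx, drop = FALSE])
    for (o in objects)
      preds[[o]][idx] <- apply(out$logits[[o]]$val, 2, which.max)
  }
  truth <- lapply(objects, function(o) labels_for(te, o))
  names(truth) <- objects
  acc <- vapply(objects, function(o) mean(preds[[o]] == truth[[o]]), 0)
  structure(list(accuracy = acc,
                 a_fg = unname(acc["foreground"]),
                 a_bg = unname(acc["background"]),
                 predictions = preds, truth = truth, n_test = n, task = task,
                 schedule = sched),
            class = "occl_eval")
}

#' Scalar accuracy of an evaluation
#' @param ev an \code{occl_eval}
#' @param joint if TRUE and both objects are scheduled, the fraction of
#'   scenes with both predictions correct; otherwise the mean of the
#'   per-object accuracies
#' @export
mean_accuracy <- function(ev, joint = FALSE) {
  if (joint && length(ev$accuracy) == 2) {
    ok <- ev$predictions$foreground == ev$truth$foreground &
      ev$predictions$background == ev$truth$background
    return(mean(ok))
  }
  mean(ev$accuracy)
}

delta_result <- function(deltas, paired = TRUE, x = NULL, y = NULL) {
  tt <- tryCatch(
    if (paired) paired_t(x, y) else unpaired_t(x, y),
    occlnet_degenerate_variance = function(e)
      list(statistic = NA_real_, p = NA_real_, df = NA_integer_,
           test = "degenerate"))
  structure(list(deltas = deltas, mean_delta = mean(deltas),
                 statistic = tt$statistic, p = tt$p, n = length(deltas),
                 paired = paired),
            class = "occl_delta")
}

#' Explaining-away delta on background accuracy
#'
#' For paired model instances, the difference between background-object
#' accuracy in the context of the full task and in the background-only
#' task.  Positive values mean the background object is recognized better
#' when the foreground object must also be predicted.
#'
#' @param full_evals,bgonly_evals equal-length lists of \code{occl_eval}
#'   results on the same test dataset (paired by seed)
#' @return an \code{occl_delta} with per-pair deltas and a two-sided paired t
#' @export
background_delta <- function(full_evals, bgonly_evals) {
  if (length(full_evals) != length(bgonly_evals))
    occl_error("instance counts differ", "occlnet_invalid_argument")
  a_full <- vapply(full_evals, function(e) e$a_bg, 0)
  a_only <- vapply(bgonly_evals, function(e) e$a_bg, 0)
  delta_result(a_full - a_only, paired = TRUE, x = a_full, y = a_only)
}

#' Control delta on foreground accuracy
#'
#' Same construction as [background_delta()] but for the foreground object,
#' comparing the full task against the foreground-only task.  Only variants
#' that predict the foreground at the same (last) timestep in both tasks
#' are eligible; e.g. Rec is excluded because its full-task foreground
#' prediction happens at the next-to-last step.
#'
#' @param full_evals,fgonly_evals paired evaluation lists
#' @param arch the architecture (used to enforce the schedule gate)
#' @return an \code{occl_delta}
#' @export
foreground_delta <- function(full_evals, fgonly_evals, arch) {
  fg_t <- NULL
  for (s in arch$schedule) if (s$object == "foreground") fg_t <- s$timestep
  if (!identical(fg_t, arch$n_timesteps))
    occl_error("architecture predicts the foreground before the last timestep in the full task; comparison would confound prediction depth",
               "occlnet_invalid_argument")
  if (length(full_evals) != length(fgonly_evals))
    occl_error("instance counts differ", "occlnet_invalid_argument")
  a_full <- vapply(full_evals, function(e) e$a_fg, 0)
  a_only <- vapply(fgonly_evals, function(e) e$a_fg, 0)
  delta_result(a_full - a_only, paired = TRUE, x = a_full, y = a_only)
}

#' Prediction-order comparison at matched computational depth
#'
#' Compares background accuracy between foreground-first and
#' background-first model groups trained on the full task (unpaired,
#' two-sided).  With \code{match_depth = TRUE}, the computational depth at
#' the background readout must be equal across the two architectures.
#'
#' @param fg_first_evals,bg_first_evals evaluation lists for the two groups
#' @param fg_arch,bg_arch the two architecture specs
#' @param match_depth enforce equal background-readout depth
#' @return an \code{occl_delta} (foreground-first minus background-first)
#' @export
order_comparison <- function(fg_first_evals, bg_first_evals,
                             fg_arch = NULL, bg_arch = NULL,
                             match_depth = TRUE) {
  if (match_depth) {
    if (is.null(fg_arch) || is.null(bg_arch))
      occl_error("match_depth requires both architecture specs",
                 "occlnet_invalid_argument")
    d1 <- computational_depth(fg_arch, at = "background")
    d2 <- computational_depth(bg_arch, at = "background")
    if (d1 != d2)
      occl_error(sprintf("background-readout depth differs: %d vs %d", d1, d2),
                 "occlnet_invalid_argument")
  }
  a1 <- vapply(fg_first_evals, function(e) e$a_bg, 0)
  a2 <- vapply(bg_first_evals, function(e) e$a_bg, 0)
  delta_result(rep(mean(a1) - mean(a2), 1L), paired = FALSE, x = a1, y = a2)
}

#' Sequential feedforward comparison
#'
#' Background-accuracy delta between the sequential (foreground first) and
#' reverse-sequential variants of one feedforward base architecture,
#' unpaired and two-sided; the background-readout depth must match.
#'
#' @param seq_evals,seq_reverse_evals evaluation lists
#' @param seq_arch,seq_reverse_arch the two variant specs
#' @return an \code{occl_delta}
#' @export
ffseq_comparison <- function(seq_evals, seq_reverse_evals,
                             seq_arch, seq_reverse_arch) {
  if (seq_arch$type != "ff" || seq_reverse_arch$type != "ff" ||
      is.null(seq_arch$seq) || is.null(seq_reverse_arch$seq))
    occl_error("both specs must be sequential feedforward variants",
               "occlnet_invalid_argument")
  d1 <- computational_depth(seq_arch, at = "background")
  d2 <- computational_depth(seq_reverse_arch, at = "background")
  if (d1 != d2)
    occl_error("background-readout depth differs across variants",
               "occlnet_invalid_argument")
  a1 <- vapply(seq_evals, function(e) e$a_bg, 0)
  a2 <- vapply(seq_reverse_evals, function(e) e$a_bg, 0)
  delta_result(rep(mean(a1) - mean(a2), 1L), paired = FALSE, x = a1, y = a2)
}
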