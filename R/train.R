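# Training: hyperparameter sampling, the plateau learning-rate schedule with
# its abort rules, the Adam training loop, and multi-instance training.

#' Convert a scene dataset to network input tensors
#'
#' @param ds a scene dataset
#' @param task task tag; "unoccluded" produces the two-channel single-object
#'   input, every other task the one-channel occluded image
#' @return list(x = \code{[C,50,50,N]} array, fg = integer labels 1..4,
#'   bg = integer labels 1..4)
#' @export
dataset_tensors <- function(ds, task = "full") {
  n <- length(ds$scenes)
  hh <- nrow(ds$scenes[[1]]$image)
  if (task == "unoccluded") {
    x <- array(0, c(2L, hh, hh, n))
    for (i in seq_len(n)) {
      x[1, , , i] <- ds$scenes[[i]]$fg_only
      x[2, , , i] <- ds$scenes[[i]]$bg_only
    }
  } else {
    x <- array(0, c(1L, hh, hh, n))
    for (i in seq_len(n)) x[1, , , i] <- ds$scenes[[i]]$image
  }
  list(x = x,
       fg = vapply(ds$scenes, function(s) s$fg_label, 0L) + 1L,
       bg = vapply(ds$scenes, function(s) s$bg_label, 0L) + 1L)
}

#' Sample one hyperparameter set
#'
#' Learning rate: log-uniform on \[1e-4, 5e-3\].  Weight decay: 0 with
#' probability 0.15, otherwise log-uniform on \[1e-12, 1e-3\].  Batch size:
#' uniform over \{32, 64, 128\}.  Dropout probability: uniform on
#' \[0.2, 0.7\].
#'
#' @return a list with lr, l2, batch_size, dropout_p
#' @export
sample_hyperparams <- function() {
  list(lr = exp(stats::runif(1, log(1e-4), log(5e-3))),
       l2 = if (stats::runif(1) < 0.15) 0
            else exp(stats::runif(1, log(1e-12), log(1e-3))),
       batch_size = c(32L, 64L, 128L)[sample.int(3L, 1L)],
       dropout_p = stats::runif(1, 0.2, 0.7))
}

#' Create a fresh learning-rate schedule state
#' @param lr initial learning rate
#' @return a schedule-state list
#' @export
schedule_state <- function(lr) {
  list(lr_current = lr, bad_epochs = 0L, cooldown_remaining = 0L,
       best_val_acc = -Inf, epoch = 0L)
}

#' Advance the learning-rate schedule by one validation epoch
#'
#' An epoch is "bad" if validation accuracy improved over the best so far by
#' at most 0.5 percentage points; a larger improvement resets the bad-epoch
#' counter.  After more than 4 consecutive bad epochs the learning rate is
#' halved, followed by a 4-epoch cooldown during which it cannot be halved
#' again.
#'
#' @param state a [schedule_state()]
#' @param new_val_acc validation accuracy in \[0,1\]
#' @return the updated state
#' @export
schedule_step <- function(state, new_val_acc) {
  state$epoch <- state$epoch + 1L
  improvement <- new_val_acc - state$best_val_acc
  if (improvement > 0.005) {
    state$bad_epochs <- 0L
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
  }
  if (new_val_acc > state$best_val_acc) state$best_val_acc <- new_val_acc
  if (state$cooldown_remaining > 0L) {
    state$cooldown_remaining <- state$cooldown_remaining - 1L
  } else if (state$bad_epochs > 4L) {
    state$lr_current <- state$lr_current / 2
    state$cooldown_remaining <- 4L
  }
  state
}

#' Abort decision for a training run
#'
#' Aborts if validation accuracy has not reached 60 percent by epoch 10
#' (strict: exactly 0.60 continues) or if 10 bad epochs have accumulated.
#'
#' @param state a schedule state
#' @return list(abort = flag, reason = "low-start", "bad-epochs" or NA)
#' @export
should_abort <- function(state) {
  if (state$epoch == 10L && state$best_val_acc < 0.60)
    return(list(abort = TRUE, reason = "low-start"))
  if (state$bad_epochs >= 10L)
    return(list(abort = TRUE, reason = "bad-epochs"))
  list(abort = FALSE, reason = NA_character_)
}

labels_for <- function(tensors, object) {
  if (object == "foreground") tensors$fg else tensors$bg
}

#' Train one network instance
#'
#' Adam with default moment coefficients, cross-entropy summed over the
#' scheduled readouts, the plateau learning-rate schedule of
#' [schedule_step()] and the abort rules of [should_abort()].  Validation
#' accuracy (the mean of the per-object accuracies for two-label tasks) is
#' recorded after every epoch.  Deterministic under a fixed seed.
#'
#' @param arch an architecture spec
#' @param train_ds,val_ds scene datasets
#' @param task task tag
#' @param hp hyperparameters (see [sample_hyperparams()])
#' @param seed integer seed (initialization, shuffling and dropout)
#' @param max_epochs epoch budget (0 returns the untrained instance)
#' @param use_schedule apply learning-rate decay and abort rules (disable
#'   for fixed-regimen presets)
#' @param joint_accuracy use joint-correct instead of mean accuracy for the
#'   validation metric
#' @return list(instance, val_curve, aborted, abort_reason, best_val_acc)
#' @export
train_network <- function(arch, train_ds, val_ds, task = "full", hp = NULL,
                          seed = 1, max_epochs = 100L, use_schedule = TRUE,
                          joint_accuracy = FALSE) {
  hp <- hp %||% list(lr = 1e-3, l2 = 0, batch_size = 64L, dropout_p = 0.5)
  instance <- initialize_network(arch, seed, task)
  tr <- dataset_tensors(train_ds, task)
  sched <- task_schedule(arch, task)
  st <- adam_state()
  state <- schedule_state(hp$lr)
  val_curve <- numeric(0)
  aborted <- FALSE
  reason <- NA_character_
  n <- dim(tr$x)[4]
  with_seed(derive_seed(seed, paste0("train/", arch$name, "/", task)), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[b0:min(b0 + hp$batch_size - 1L, n)]
        tape <- new_tape()
        out <- network_forward(instance, tr$x[, , , idx, drop = FALSE],
                               training = TRUE, dropout_p = hp$dropout_p,
                               tape = tape)
        losses <- lapply(sched, function(entry)
          ag_softmax_ce(out$logits[[entry$object]],
                        labels_for(tr, entry$object)[idx], tape))
        loss <- ag_scalar_sum(losses, tape = tape)
        if (!is.finite(loss$val))
          occl_error("non-finite training loss", "occlnet_training_diverged")
        ag_zero_grads(instance$params)
        ag_backward(loss, tape)
        adam_step(instance$params, st, lr = state$lr_current, l2 = hp$l2)
      }
      ev <- evaluate(mark_trained(instance), val_ds, task)
      acc <- mean_accuracy(ev, joint = joint_accuracy)
      val_curve <- c(val_curve, acc)
      if (use_schedule) {
        state <- schedule_step(state, acc)
        ab <- should_abort(state)
        if (ab$abort) {
          aborted <- TRUE
          reason <- ab$reason
          break
        }
      } else {
        state$epoch <- state$epoch + 1L
        state$best_val_acc <- max(state$best_val_acc, acc)
      }
    }
  })
  instance$trained <- length(val_curve) > 0
  list(instance = instance, val_curve = val_curve, aborted = aborted,
       abort_reason = reason,
       best_val_acc = if (length(val_curve)) max(val_curve) else NA_real_,
       hp = hp)
}

mark_trained <- function(instance) {
  instance$trained <- TRUE
  instance
}

#' Random hyperparameter search
#'
#' Runs \code{n_searches} sample-train-record rounds and returns the
#' hyperparameters with the highest validation accuracy.  The paper-scale
#' configuration default is 90 searches; desk-scale runs use far fewer.
#'
#' @inheritParams train_network
#' @param n_searches number of random draws (>= 1)
#' @return list(best_hp, leaderboard (data.frame sorted by accuracy,
#'   ties broken by earlier search index), results)
#' @export
random_search <- function(arch, train_ds, val_ds, task = "full",
                          n_searches = 90L, seed = 1, max_epochs = 100L) {
  if (n_searches < 1)
    occl_error("n_searches must be >= 1", "occlnet_invalid_argument")
  draws <- with_seed(derive_seed(seed, "hp_search"),
                     lapply(seq_len(n_searches), function(i) sample_hyperparams()))
  results <- vector("list", n_searches)
  for (i in seq_len(n_searches)) {
    results[[i]] <- train_network(arch, train_ds, val_ds, task, draws[[i]],
                                  seed = derive_seed(seed, paste0("search", i)),
                                  max_epochs = max_epochs)
  }
  lb <- data.frame(search = seq_len(n_searches),
                   best_val_acc = vapply(results, function(r)
                     r$best_val_acc %||% NA_real_, 0),
                   aborted = vapply(results, function(r) r$aborted, TRUE))
  lb <- lb[order(-lb$best_val_acc, lb$search), ]
  if (all(lb$aborted)) {
    cond <- errorCondition("all hyperparameter searches aborted",
                           class = c("occlnet_search_failed", "occlnet_error"))
    cond$leaderboard <- lb
    stop(cond)
  }
  best <- lb$search[1]
  list(best_hp = draws[[best]], leaderboard = lb, results = results)
}

#' Train several independent instances of one model
#'
#' @inheritParams train_network
#' @param n_instances number of instances
#' @param base_seed instance i uses seed \code{base_seed + i}
#' @return list of train results, in instance order
#' @export
train_instances <- function(arch, train_ds, val_ds, task = "full", hp = NULL,
                            n_instances = 5L, base_seed = 1,
                            max_epochs = 100L, use_schedule = TRUE) {
  if (n_instances < 1)
    occl_error("n_instances must be >= 1", "occlnet_invalid_argument")
  lapply(seq_len(n_instances), function(i)
    train_network(arch, train_ds, val_ds, task, hp, seed = base_seed + i,
                  max_epochs = max_epochs, use_schedule = use_schedule))
}

#' Fixed training regimen preset used by the reconstitution-model analyses
#' @return a hyperparameter list (lr 1e-4, batch 64, no decay, dropout 0.5)
#' @export
reconnet_regimen <- function() {
  list(lr = 1e-4, l2 = 0, batch_size = 64L, dropout_p = 0.5)
}
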