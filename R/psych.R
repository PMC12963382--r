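# Behavioral-experiment analysis: quality control, condition comparisons,
# occlusion binning, and a synthetic generator emulating the task design
# (occluder vs. random prime trials, attention checks, 70-90% occlusion).

#' Simulate a behavioral cohort
#'
#' Emulates the task design: conditions interleaved 50/50, a random 10% of
#' trials are attention checks, the inter-stimulus fixation is 25 or 50 ms
#' with equal probability, and occlusion is drawn from \[0.70, 0.90\] (with
#' lower levels overrepresented when \code{low_occ_overrep}).  Each
#' participant has their own accuracy and response-time baseline, plus the
#' planted condition effects.  A fraction of participants violates the
#' quality-control rules by construction (fast responding, failed attention
#' checks, or near-chance accuracy).
#'
#' @param n_participants,trials_per_participant cohort size
#' @param effect_size_acc accuracy advantage of occluder-prime trials
#' @param effect_size_rt response-time difference (seconds; negative =
#'   occluder trials faster)
#' @param baseline_acc,baseline_rt population means
#' @param sd_participant_acc,sd_participant_rt between-participant sds
#' @param fraction_low_quality fraction of participants built to fail QC
#' @param low_occ_overrep overrepresent lower occlusion levels
#' @param seed integer seed
#' @return a data.frame of trial records
#' @export
simulate_behavior <- function(n_participants = 41L,
                              trials_per_participant = 400L,
                              effect_size_acc = 0.04,
                              effect_size_rt = -0.039,
                              baseline_acc = 0.745, baseline_rt = 0.955,
                              sd_participant_acc = 0.05,
                              sd_participant_rt = 0.12,
                              fraction_low_quality = 0,
                              low_occ_overrep = TRUE, seed = 1) {
  with_seed(derive_seed(seed, "behavior"), {
    n_bad <- round(fraction_low_quality * n_participants)
    bad_kind <- if (n_bad > 0)
      sample(c("fast", "attention", "accuracy"), n_bad, replace = TRUE)
    else character(0)
    rows <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      kind <- if (p <= n_bad) bad_kind[p] else "good"
      pacc <- min(0.98, max(0.58, stats::rnorm(1, baseline_acc,
                                               sd_participant_acc)))
      prt <- max(0.35, stats::rnorm(1, baseline_rt, sd_participant_rt))
      if (kind == "accuracy") pacc <- stats::runif(1, 0.35, 0.50)
      nt <- trials_per_participant
      is_check <- stats::runif(nt) < 0.10
      condition <- ifelse(stats::runif(nt) < 0.5, "occluder", "random")
      occ <- if (low_occ_overrep) {
        0.70 + 0.20 * stats::rbeta(nt, 1.3, 2.0)
      } else stats::runif(nt, 0.70, 0.90)
      eff <- ifelse(condition == "occluder", effect_size_acc / 2,
                    -effect_size_acc / 2)
      correct <- stats::runif(nt) < pmin(0.999, pmax(0.001, pacc + eff))
      rt_mean <- prt + ifelse(condition == "occluder", effect_size_rt / 2,
                              -effect_size_rt / 2)
      rt <- pmax(0.12, stats::rnorm(nt, rt_mean, 0.25))
      if (kind == "fast") rt <- stats::runif(nt, 0.01, 0.08)
      att_pass <- rep(NA, nt)
      fail_rate <- if (kind == "attention") 0.45 else 0.02
      att_pass[is_check] <- stats::runif(sum(is_check)) > fail_rate
      rows[[p]] <- data.frame(
        participant_id = sprintf("P%03d", p),
        condition = condition, rt_s = rt, correct = correct,
        occlusion = occ, is_attention_check = is_check,
        attention_passed = att_pass,
        fixation_ms = sample(c(25L, 50L), nt, replace = TRUE))
    }
    do.call(rbind, rows)
  })
}

#' Quality-control filter for behavioral data
#'
#' Drops trials with response times below 100 ms, then excludes
#' participants whose mean response time (over their submitted trials) is
#' below 100 ms, who failed more than 20% of presented attention checks
#' (an unanswered check counts as a miss), or whose task accuracy
#' (non-attention trials, after the trial-level exclusion) is below 0.55.
#' The filter is idempotent.
#'
#' @param trials a data.frame of trial records (see [simulate_behavior()])
#' @return list(trials = included trials, report = QC report)
#' @export
qc_filter <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0)
    occl_error("empty trial table", "occlnet_invalid_argument")
  ids <- unique(trials$participant_id)
  reasons <- list()
  keep_ids <- character(0)
  kept_trials <- list()
  n_dropped <- 0L
  for (pid in ids) {
    tt <- trials[trials$participant_id == pid, ]
    why <- character(0)
    if (mean(tt$rt_s) < 0.100) why <- c(why, "mean-RT")
    checks <- tt[tt$is_attention_check, ]
    if (nrow(checks) > 0) {
      fail_rate <- mean(!(checks$attention_passed %in% TRUE))
      if (fail_rate > 0.20) why <- c(why, "attention")
    }
    ok <- tt[tt$rt_s >= 0.100, ]
    n_dropped <- n_dropped + (nrow(tt) - nrow(ok))
    task <- ok[!ok$is_attention_check, ]
    if (nrow(task) == 0 || mean(task$correct) < 0.55)
      why <- c(why, "accuracy")
    if (length(why) == 0) {
      keep_ids <- c(keep_ids, pid)
      kept_trials[[pid]] <- ok
    } else {
      reasons[[pid]] <- why
    }
  }
  out <- if (length(kept_trials)) do.call(rbind, kept_trials) else trials[0, ]
  rownames(out) <- NULL
  list(trials = out,
       report = list(n_initiated = length(ids), n_passed = length(keep_ids),
                     reasons = reasons, n_trials_dropped = n_dropped))
}

participant_condition_means <- function(trials) {
  task <- trials[!trials$is_attention_check, ]
  ids <- unique(task$participant_id)
  out <- lapply(ids, function(pid) {
    tt <- task[task$participant_id == pid, ]
    conds <- unique(tt$condition)
    if (!all(c("occluder", "random") %in% conds))
      occl_error(paste("participant", pid, "is missing a condition"),
                 "occlnet_invalid_argument")
    data.frame(participant_id = pid,
               acc_occluder = mean(tt$correct[tt$condition == "occluder"]),
               acc_random = mean(tt$correct[tt$condition == "random"]),
               rt_occluder = mean(tt$rt_s[tt$condition == "occluder"]),
               rt_random = mean(tt$rt_s[tt$condition == "random"]))
  })
  do.call(rbind, out)
}

#' Compare the occluder and random prime conditions
#'
#' Participant-level means first, then a two-sided paired t test across
#' participants, separately for accuracy and response time.
#'
#' @param trials QC-passed trial records
#' @return list(means = per-participant means, accuracy = list(mean_occluder,
#'   mean_random, difference, t, p), rt = same for response time)
#' @export
condition_compare <- function(trials) {
  m <- participant_condition_means(trials)
  ta <- paired_t(m$acc_occluder, m$acc_random)
  tr <- paired_t(m$rt_occluder, m$rt_random)
  list(means = m,
       accuracy = list(mean_occluder = mean(m$acc_occluder),
                       mean_random = mean(m$acc_random),
                       difference = mean(m$acc_occluder - m$acc_random),
                       t = ta$statistic, p = ta$p, n = nrow(m)),
       rt = list(mean_occluder = mean(m$rt_occluder),
                 mean_random = mean(m$rt_random),
                 difference = mean(m$rt_occluder - m$rt_random),
                 t = tr$statistic, p = tr$p, n = nrow(m)))
}

#' Split trials into three equal-count occlusion bins
#'
#' Task trials are stably sorted by (occlusion, original order) and split
#' into three near-equal groups (counts differ by at most one); each bin is
#' then analysed with [condition_compare()].
#'
#' @param trials QC-passed trial records
#' @return list(bins = per-trial bin assignment (1 = low), counts,
#'   cut_points, comparisons = per-bin condition comparisons)
#' @export
occlusion_bins <- function(trials) {
  task_idx <- which(!trials$is_attention_check)
  if (length(task_idx) < 3)
    occl_error("need at least 3 task trials", "occlnet_invalid_argument")
  occ <- trials$occlusion[task_idx]
  ord <- order(occ, task_idx)  # stable: ties broken by original trial order
  n <- length(ord)
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- base + (seq_len(3L) <= extra)
  bin_of_sorted <- rep(1:3, times = sizes)
  bins <- integer(n)
  bins[ord] <- bin_of_sorted
  cuts <- c(max(occ[ord[seq_len(sizes[1])]]),
            max(occ[ord[seq_len(sizes[1] + sizes[2])]]))
  comparisons <- lapply(1:3, function(b) {
    sub <- trials[task_idx[bins == b], ]
    tryCatch(condition_compare(sub),
             occlnet_invalid_argument = function(e) NULL,
             occlnet_degenerate_variance = function(e) NULL)
  })
  full_bins <- rep(NA_integer_, nrow(trials))
  full_bins[task_idx] <- bins
  list(bins = full_bins, counts = as.vector(table(bins)), cut_points = cuts,
       comparisons = comparisons)
}

#' Read a behavioral CSV
#'
#' Expects the package schema (participant_id, condition, rt_s, correct,
#' occlusion, is_attention_check, attention_passed, fixation_ms); an
#' optional rename map adapts deposited datasets with different column
#' names.
#'
#' @param path CSV file
#' @param rename named character vector mapping schema names to the file's
#'   column names
#' @return a trial data.frame
#' @export
read_behavior_csv <- function(path, rename = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(rename)) {
    for (nm in names(rename)) {
      if (!rename[[nm]] %in% names(df))
        occl_error(paste("missing column:", rename[[nm]]),
                   "occlnet_format_error")
      names(df)[names(df) == rename[[nm]]] <- nm
    }
  }
  need <- c("participant_id", "condition", "rt_s", "correct", "occlusion",
            "is_attention_check")
  miss <- setdiff(need, names(df))
  if (length(miss))
    occl_error(paste("missing columns:", paste(miss, collapse = ", ")),
               "occlnet_format_error")
  df
}
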