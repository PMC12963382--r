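# Declarative architecture zoo.  Every variant studied in the comparison
# experiments is emitted from its name; width_scale shrinks all unit counts
# for desk-scale runs while preserving the layer graph, timestep counts and
# readout schedules.

.arch_names <- c("FF", "FF Wide", "FF Wider Taller", "FF WS Wider Taller",
                 "Rec", "Rec 5", "Rec 10", "Rec Thin", "Rec Reverse",
                 "Rec Reverse 3", "Rec Reverse 5", "Rec Last", "Rec Last 5",
                 "Rec Control", "TD v1", "TD v2", "TD v3", "TD v4",
                 "FF Seq", "FF Seq Reverse")

scale_units <- function(n, w) max(4L, as.integer(round(n * w)))

#' Construct a named architecture specification
#'
#' Feedforward variants: \code{FF} is three 5x5 convolutions of 64 maps
#' (each followed by a 2x2 max-pool) and a 1024-unit fully connected layer;
#' \code{FF Wide} doubles all unit counts; \code{FF Wider Taller} has twelve
#' convolutions at four times the width; \code{FF WS Wider Taller}
#' additionally ties groups of consecutive convolution layers.  Recurrent
#' variants: \code{Rec} is three ConvLSTM layers of 64 maps (each followed
#' by a max-pool) and a 512-unit LSTM, run for two timesteps, predicting the
#' foreground class at the next-to-last step and the background class at the
#' last; \code{Rec 5} / \code{Rec 10} run 5 / 10 steps; \code{Rec Thin}
#' halves all unit counts; the \code{Reverse} variants swap the prediction
#' order; \code{Rec Last} predicts both at the final step; \code{Rec
#' Control} runs a single step.  \code{TD v1..v4} add top-down feedback
#' edges (2->1, 3->1, \{3->2, 2->1\}, 3->2) to \code{Rec}.  \code{FF Seq}
#' branches the foreground readout after the second convolution (via its own
#' fully connected layer) and reads the background after the full stack;
#' \code{FF Seq Reverse} reads the background after the full stack and the
#' foreground after one extra convolution, so the background readout depth
#' matches.
#'
#' @param name one of the architecture tags listed above
#' @param width_scale positive factor applied to all unit counts
#' @return an \code{occl_arch} specification
#' @export
make_architecture <- function(name, width_scale = 1) {
  if (!name %in% .arch_names)
    occl_error(paste("unknown architecture:", name),
               "occlnet_invalid_argument")
  w <- width_scale
  sched <- function(...) list(...)
  ro <- function(object, timestep) list(object = object, timestep = timestep)
  a <- switch(
    name,
    "FF" = list(type = "ff", conv_maps = rep(scale_units(64, w), 3),
                pool_after = c(TRUE, TRUE, TRUE),
                fc_units = scale_units(1024, w)),
    "FF Wide" = list(type = "ff", conv_maps = rep(scale_units(128, w), 3),
                     pool_after = c(TRUE, TRUE, TRUE),
                     fc_units = scale_units(2048, w)),
    "FF Wider Taller" = list(type = "ff",
                             conv_maps = rep(scale_units(256, w), 12),
                             pool_after = rep(c(FALSE, FALSE, FALSE, TRUE), 3),
                             fc_units = scale_units(4096, w)),
    "FF WS Wider Taller" = list(type = "ff",
                                conv_maps = rep(scale_units(256, w), 12),
                                pool_after = rep(c(FALSE, FALSE, FALSE, TRUE), 3),
                                fc_units = scale_units(4096, w),
                                ws_groups = rep(1:4, each = 3)),
    "Rec" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                 lstm_units = scale_units(512, w), n_timesteps = 2L,
                 schedule = sched(ro("foreground", 1L), ro("background", 2L))),
    "Rec 5" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                   lstm_units = scale_units(512, w), n_timesteps = 5L,
                   schedule = sched(ro("foreground", 4L), ro("background", 5L))),
    "Rec 10" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                    lstm_units = scale_units(512, w), n_timesteps = 10L,
                    schedule = sched(ro("foreground", 9L), ro("background", 10L))),
    "Rec Thin" = list(type = "rec", conv_maps = rep(scale_units(32, w), 3),
                      lstm_units = scale_units(256, w), n_timesteps = 2L,
                      schedule = sched(ro("foreground", 1L), ro("background", 2L))),
    "Rec Reverse" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                         lstm_units = scale_units(512, w), n_timesteps = 2L,
                         schedule = sched(ro("background", 1L), ro("foreground", 2L))),
    "Rec Reverse 3" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                           lstm_units = scale_units(512, w), n_timesteps = 3L,
                           schedule = sched(ro("background", 2L), ro("foreground", 3L))),
    "Rec Reverse 5" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                           lstm_units = scale_units(512, w), n_timesteps = 5L,
                           schedule = sched(ro("background", 4L), ro("foreground", 5L))),
    "Rec Last" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                      lstm_units = scale_units(512, w), n_timesteps = 2L,
                      schedule = sched(ro("foreground", 2L), ro("background", 2L))),
    "Rec Last 5" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                        lstm_units = scale_units(512, w), n_timesteps = 5L,
                        schedule = sched(ro("foreground", 5L), ro("background", 5L))),
    "Rec Control" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                         lstm_units = scale_units(512, w), n_timesteps = 1L,
                         schedule = sched(ro("foreground", 1L), ro("background", 1L))),
    "TD v1" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                   lstm_units = scale_units(512, w), n_timesteps = 2L,
                   feedback_edges = list(c(2L, 1L)),
                   schedule = sched(ro("foreground", 1L), ro("background", 2L))),
    "TD v2" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                   lstm_units = scale_units(512, w), n_timesteps = 2L,
                   feedback_edges = list(c(3L, 1L)),
                   schedule = sched(ro("foreground", 1L), ro("background", 2L))),
    "TD v3" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                   lstm_units = scale_units(512, w), n_timesteps = 2L,
                   feedback_edges = list(c(3L, 2L), c(2L, 1L)),
                   schedule = sched(ro("foreground", 1L), ro("background", 2L))),
    "TD v4" = list(type = "rec", conv_maps = rep(scale_units(64, w), 3),
                   lstm_units = scale_units(512, w), n_timesteps = 2L,
                   feedback_edges = list(c(3L, 2L)),
                   schedule = sched(ro("foreground", 1L), ro("background", 2L))),
    "FF Seq" = list(type = "ff", conv_maps = rep(scale_units(64, w), 3),
                    pool_after = c(TRUE, TRUE, TRUE),
                    fc_units = scale_units(1024, w),
                    seq = list(foreground = list(after_conv = 2L),
                               background = list(after_conv = 3L))),
    "FF Seq Reverse" = list(type = "ff",
                            conv_maps = rep(scale_units(64, w), 4),
                            pool_after = c(TRUE, TRUE, TRUE, FALSE),
                            fc_units = scale_units(1024, w),
                            seq = list(background = list(after_conv = 3L),
                                       foreground = list(after_conv = 4L)))
  )
  a$name <- name
  a$width_scale <- w
  a$kernel <- 5L
  if (a$type == "ff") {
    a$n_timesteps <- 1L
    if (is.null(a$schedule))
      a$schedule <- sched(ro("foreground", 1L), ro("background", 1L))
  }
  if (is.null(a$feedback_edges)) a$feedback_edges <- list()
  for (e in a$feedback_edges) {
    if (e[1] <= e[2])
      occl_error("feedback edges must go from higher to lower layers",
                 "occlnet_invalid_argument")
  }
  structure(a, class = "occl_arch")
}

# Readout schedule for a given task.  Single-object tasks read their object
# at the final timestep; the full and unoccluded tasks use the variant's
# native schedule.
task_schedule <- function(arch, task) {
  switch(task,
         full = ,
         unoccluded = arch$schedule,
         background_only = list(list(object = "background",
                                     timestep = arch$n_timesteps)),
         foreground_only = list(list(object = "foreground",
                                     timestep = arch$n_timesteps)),
         occl_error(paste("unknown task:", task), "occlnet_invalid_argument"))
}

task_channels <- function(task) if (task == "unoccluded") 2L else 1L

# ---- computational depth ----------------------------------------------------

#' Time-unrolled computation graph of an architecture
#'
#' Nodes carry a weight of 1 if traversing them applies an affine transform
#' followed by a nonlinearity (convolutions, ConvLSTM/LSTM steps, fully
#' connected and readout layers) and 0 otherwise (max-pooling, channel
#' concatenation).  Edges follow feedforward structure within a timestep,
#' recurrence and feedback across consecutive timesteps.
#'
#' @param arch an architecture spec
#' @param include_readout should readout layers count one unit of depth?
#' @return list(weights = named integer vector, edges = list of
#'   c(from, to) node names, readout_nodes = named list per object)
#' @export
unrolled_graph <- function(arch, include_readout = TRUE) {
  weights <- integer()
  edges <- list()
  add_node <- function(id, w) weights[[id]] <<- w
  add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  readouts <- list()
  sched <- arch$schedule
  if (arch$type == "ff") {
    add_node("input", 0L)
    prev <- "input"
    L <- length(arch$conv_maps)
    for (l in seq_len(L)) {
      id <- paste0("conv", l)
      add_node(id, 1L)
      add_edge(prev, id)
      prev <- id
    }
    branch_of <- function(obj) {
      if (!is.null(arch$seq)) arch$seq[[obj]]$after_conv else L
    }
    for (entry in sched) {
      obj <- entry$object
      bl <- branch_of(obj)
      src <- if (bl == 0) "input" else paste0("conv", bl)
      fcid <- paste0("fc_", obj)
      add_node(fcid, 1L)
      add_edge(src, fcid)
      roid <- paste0("readout_", obj)
      add_node(roid, if (include_readout) 1L else 0L)
      add_edge(fcid, roid)
      readouts[[obj]] <- roid
    }
  } else {
    add_node("input", 0L)
    L <- length(arch$conv_maps)
    for (t in seq_len(arch$n_timesteps)) {
      for (l in seq_len(L)) {
        id <- sprintf("conv%d_t%d", l, t)
        # feedback nodes are created before their consumer so that node
        # creation order stays topological
        fb_ids <- character(0)
        for (e in arch$feedback_edges) {
          if (e[2] == l && t > 1) {
            fb <- sprintf("fb%dto%d_t%d", e[1], e[2], t)
            add_node(fb, 1L)  # the 1x1 feedback convolution
            add_edge(sprintf("conv%d_t%d", e[1], t - 1), fb)
            fb_ids <- c(fb_ids, fb)
          }
        }
        add_node(id, 1L)
        add_edge(if (l == 1) "input" else sprintf("conv%d_t%d", l - 1, t), id)
        if (t > 1) add_edge(sprintf("conv%d_t%d", l, t - 1), id)
        for (fb in fb_ids) add_edge(fb, id)
      }
      id <- sprintf("lstm_t%d", t)
      add_node(id, 1L)
      add_edge(sprintf("conv%d_t%d", L, t), id)
      if (t > 1) add_edge(sprintf("lstm_t%d", t - 1), id)
    }
    for (entry in sched) {
      roid <- paste0("readout_", entry$object)
      add_node(roid, if (include_readout) 1L else 0L)
      add_edge(sprintf("lstm_t%d", entry$timestep), roid)
      readouts[[entry$object]] <- roid
    }
  }
  list(weights = weights, edges = edges, readout_nodes = readouts)
}

#' Computational depth of an architecture
#'
#' The maximum number of affine-transform-plus-nonlinearity applications
#' along any input-to-readout path of the time-unrolled computation graph
#' (max-pooling and concatenation count zero).  For an ordinary feedforward
#' network this equals the number of layers; for an ordinary recurrent
#' network, the number of layers plus the number of recurrent iterations.
#'
#' @param arch an architecture spec
#' @param at "foreground", "background", or "output" (the deepest readout)
#' @param include_readout count the readout layer as one application
#'   (default TRUE); FALSE reports depth up to the last hidden layer
#' @return integer depth
#' @export
computational_depth <- function(arch, at = "output", include_readout = TRUE) {
  g <- unrolled_graph(arch, include_readout)
  preds <- split(vapply(g$edges, `[`, "", 1), vapply(g$edges, `[`, "", 2))
  depth <- numeric(0)
  # nodes were created in topological order
  for (id in names(g$weights)) {
    p <- preds[[id]]
    base <- if (is.null(p)) 0 else max(unlist(depth[p]))
    depth[[id]] <- base + g$weights[[id]]
  }
  targets <- if (at == "output") unlist(g$readout_nodes) else {
    if (is.null(g$readout_nodes[[at]]))
      occl_error(paste("no readout for object", at),
                 "occlnet_invalid_argument")
    g$readout_nodes[[at]]
  }
  as.integer(max(depth[targets]))
}
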