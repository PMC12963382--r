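# Shared fixtures, memoised across test files (test_dir runs everything in
# one session).  All fixtures are generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_bank <- function() fx("bank", generate_bank(60, "train", seed = 11))
fx_bank_test <- function() fx("bank_test", generate_bank(40, "test", seed = 11))

fx_scenes <- function() fx("scenes", {
  build_dataset(fx_bank(), dataset_spec(n_images = 160), seed = 3)
})

fx_scenes_test <- function() fx("scenes_test", {
  build_dataset(fx_bank_test(), dataset_spec(n_images = 80), seed = 4)
})

fx_reconnet_scenes <- function() fx("reconnet_scenes", {
  reconnet_data(fx_bank(), 160, seed = 7)
})

# numerical gradient of f at p (central differences)
num_grad <- function(f, p, eps = 1e-5) {
  g <- array(0, dim = dim(p) %||% length(p))
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag <- function(name) getFromNamespace(name, "occlnet")

# brute-force longest-path oracle over the explicitly unrolled graph:
# exhaustive depth-first enumeration of all input-to-target paths
brute_force_depth <- function(arch, at = "output", include_readout = TRUE) {
  g <- unrolled_graph(arch, include_readout)
  succ <- split(vapply(g$edges, `[`, "", 2), vapply(g$edges, `[`, "", 1))
  targets <- if (at == "output") unlist(g$readout_nodes) else g$readout_nodes[[at]]
  best <- -Inf
  dfs <- function(node, w) {
    w <- w + g$weights[[node]]
    if (node %in% targets && w > best) best <<- w
    for (s in succ[[node]] %||% character(0)) dfs(s, w)
  }
  dfs("input", 0L)
  as.integer(best)
}
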