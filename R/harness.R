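# Shared utilities: classed errors, seed management, statistics used by the
# analyses, and round-trip dataset IO.

occl_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "occlnet_error")))
}

#' Derive a named sub-seed from a global seed
#'
#' Every source of randomness in the package draws from a seed obtained by
#' hashing a global integer seed together with a short stream name, so that
#' independent stages (object generation, scene sampling, training instances,
#' behavioral simulation) have stable, auditable streams.
#'
#' @param seed integer global seed
#' @param name character stream name
#' @return an integer seed in \code{[0, 2^31 - 2]}
#' @export
derive_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- statistics -------------------------------------------------------------

#' Two-sided paired Student's t test
#'
#' Classical paired t on the differences, with the p value from the t
#' distribution on \code{n - 1} degrees of freedom.  Used for all paired
#' comparisons in the package (per-participant condition means, per-seed
#' accuracy deltas).
#'
#' @param x,y equal-length numeric samples, paired elementwise
#' @return a list with \code{statistic}, \code{p}, \code{df}, \code{test}
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    occl_error("paired_t needs two samples of equal length >= 2",
               "occlnet_invalid_argument")
  d <- x - y
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0)
    occl_error("zero-variance differences", "occlnet_degenerate_variance")
  n <- length(d)
  tval <- mean(d) / (s / sqrt(n))
  list(statistic = tval, p = 2 * stats::pt(-abs(tval), df = n - 1),
       df = n - 1, test = "paired t")
}

#' Two-sided unpaired Student's t test (pooled variance)
#'
#' @param x,y numeric samples, each of length >= 2
#' @return a list with \code{statistic}, \code{p}, \code{df}, \code{test}
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    occl_error("unpaired_t needs two samples of length >= 2",
               "occlnet_invalid_argument")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 == 0)
    occl_error("zero pooled variance", "occlnet_degenerate_variance")
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = tval, p = 2 * stats::pt(-abs(tval), df = df),
       df = df, test = "unpaired t (pooled)")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum gap between the two empirical CDFs.  For small samples
#' (\code{n * m <= 100}) the two-sided p value is computed exactly by
#' counting lattice paths under the null; otherwise the asymptotic series
#' is used.
#'
#' @param x,y numeric samples
#' @return a list with \code{statistic} (D), \code{p}, \code{n}, \code{m}
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    occl_error("ks_two_sample needs non-empty samples",
               "occlnet_invalid_argument")
  n <- length(x); m <- length(y)
  all_v <- sort(unique(c(x, y)))
  cx <- stats::ecdf(x)(all_v)
  cy <- stats::ecdf(y)(all_v)
  D <- max(abs(cx - cy))
  p <- if (as.double(n) * m <= 100) {
    ks_exact_p(n, m, D)
  } else {
    en <- sqrt(n * m / (n + m))
    lam <- (en + 0.12 + 0.11 / en) * D
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))))
  }
  list(statistic = D, p = p, n = n, m = m, test = "two-sample KS")
}

# Exact null probability P(D >= d) for the two-sample KS statistic by dynamic
# programming over monotone lattice paths from (0,0) to (n,m); assumes no ties
# across samples (the package's occlusion levels are continuous).
ks_exact_p <- function(n, m, d) {
  eps <- 1e-9
  cnt <- matrix(0, n + 1, m + 1)
  cnt[1, 1] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      if (abs(i / n - j / m) >= d - eps) { cnt[i + 1, j + 1] <- 0; next }
      acc <- 0
      if (i > 0) acc <- acc + cnt[i, j + 1]
      if (j > 0) acc <- acc + cnt[i + 1, j]
      cnt[i + 1, j + 1] <- acc
    }
  }
  total <- choose(n + m, n)
  # paths whose maximum deviation stays strictly below d
  below <- if (abs(1 - 1) >= d - eps) 0 else cnt[n + 1, m + 1]
  max(0, min(1, 1 - below / total))
}

# ---- dataset IO -------------------------------------------------------------

.occlnet_io_version <- 1L

#' Write / read a scene dataset directory
#'
#' A dataset is stored as an RDS array container plus a plain-text CSV
#' manifest (one row per scene) that mirrors the labels, occlusion levels and
#' transform parameters; write-then-read is bit-identical.
#'
#' @param ds a SceneDataset (see [build_dataset()])
#' @param dir directory to create
#' @export
write_scene_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(version = .occlnet_io_version, seed = ds$seed, spec = ds$spec)
  saveRDS(meta, file.path(dir, "meta.rds"))
  saveRDS(ds$scenes, file.path(dir, "scenes.rds"))
  utils::write.csv(scene_manifest(ds), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene_dataset
#' @export
read_scene_dataset <- function(dir) {
  mf <- file.path(dir, "meta.rds")
  if (!file.exists(mf))
    occl_error("not a scene dataset directory", "occlnet_format_error")
  meta <- tryCatch(readRDS(mf), error = function(e)
    occl_error("corrupt dataset archive", "occlnet_format_error"))
  if (!identical(meta$version, .occlnet_io_version))
    occl_error(sprintf("archive schema version %s; this build reads %s - regenerate the dataset",
                       meta$version, .occlnet_io_version),
               "occlnet_format_error")
  scenes <- readRDS(file.path(dir, "scenes.rds"))
  structure(list(scenes = scenes, spec = meta$spec, seed = meta$seed),
            class = "occl_scene_dataset")
}

#' Manifest of a scene dataset
#'
#' @param ds a SceneDataset
#' @return a data.frame with one row per scene
#' @export
scene_manifest <- function(ds) {
  do.call(rbind, lapply(seq_along(ds$scenes), function(i) {
    s <- ds$scenes[[i]]
    tr <- s$transforms
    data.frame(index = i, fg_label = s$fg_label, bg_label = s$bg_label,
               occlusion_level = s$occlusion_level,
               fg_rotation_deg = tr$fg_rotation_deg,
               bg_rotation_deg = tr$bg_rotation_deg,
               regime = tr$regime)
  }))
}
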