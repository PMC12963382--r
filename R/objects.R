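# Synthetic single-object images standing in for the four FashionMNIST
# classes used in the occlusion analyses.  Classes are parametric silhouette
# families (boxy, tapered, handled, heeled) with per-instance random
# deformation, fill texture and brightness, so that downstream recognition
# is non-trivial but linearly separable.

.obj_size <- 28L

#' Generate one synthetic object image
#'
#' Produces a 28x28 grayscale image in \[0,1\] on an exactly-black
#' background.  The four classes have visually distinct base silhouettes
#' with randomized deformation: 0 = boxy torso with sleeve bar (shirt-like),
#' 1 = tapered trapezoid (pullover-like), 2 = box with a handle hole
#' (bag-like), 3 = L-shape with a heel (boot-like).  Interior intensities
#' are a smooth random texture in \[0.2, 1\].
#'
#' @param class_id integer in 0..3
#' @param seed integer seed; the same (class_id, seed) pair is bit-reproducible
#' @param style optional list of overrides for the shape-family parameters
#' @return an object of class \code{occl_object}: list(pixels, class_id,
#'   instance_id)
#' @export
generate_object <- function(class_id, seed, style = list()) {
  if (!is.numeric(class_id) || length(class_id) != 1 || !(class_id %in% 0:3))
    occl_error("class_id must be one of 0,1,2,3", "occlnet_invalid_argument")
  with_seed(seed, {
    for (attempt in 1:50) {
      mask <- switch(as.character(class_id),
                     "0" = silhouette_boxy(style),
                     "1" = silhouette_tapered(style),
                     "2" = silhouette_handled(style),
                     "3" = silhouette_heeled(style))
      area <- sum(mask)
      if (area >= 0.16 * 784 && area <= 0.55 * 784) break
    }
    px <- mask * object_texture(class_id)
    structure(list(pixels = px, class_id = as.integer(class_id),
                   instance_id = NA_integer_),
              class = "occl_object")
  })
}

# smooth fill texture: coarse uniform field bilinearly upsampled, then a
# brightness factor drawn from a class-dependent (overlapping) range,
# emulating the distinct but non-separating intensity statistics of the
# four real clothing classes; values stay in [0.2, 1]
.class_brightness <- list(c(0.45, 0.67), c(0.62, 0.84),
                          c(0.80, 1.02), c(0.26, 0.48))
object_texture <- function(class_id) {
  coarse <- matrix(stats::runif(25, 0.35, 1), 5, 5)
  ident <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  tex <- cpp_warp_bilinear(coarse, ident, .obj_size, .obj_size)
  br <- .class_brightness[[class_id + 1L]]
  bright <- stats::runif(1, br[1], br[2])
  pmin(pmax(tex * bright, 0.2), 1)
}

# pixel-centre coordinate grids (columns = x, rows = y), 1..28
.obj_xy <- local({
  x <- matrix(rep(1:28, each = 28), 28, 28)
  y <- matrix(rep(1:28, 28), 28, 28)
  list(x = x, y = y)
})

jit <- function(lo, hi) stats::runif(1, lo, hi)

# class 0: body rectangle plus a wider, shorter bar near the top (sleeves)
silhouette_boxy <- function(style = list()) {
  x <- .obj_xy$x; y <- .obj_xy$y
  cx <- jit(13, 16); cy <- jit(13, 16)
  bw <- style$body_w %||% jit(4.2, 5.8)   # half-widths
  bh <- style$body_h %||% jit(6.5, 8.5)
  sw <- jit(8.5, 10.5); sh <- jit(2.0, 3.0)
  stop_y <- cy - bh + jit(1.5, 3.0)
  wob <- jit(0.2, 0.9); ph <- jit(0, 2 * pi)
  edge <- wob * sin(y / 4 + ph)
  body <- abs(x - cx - edge) <= bw & abs(y - cy) <= bh
  sleeves <- abs(x - cx) <= sw & abs(y - stop_y) <= sh
  (body | sleeves) * 1
}

# class 1: trapezoid widening toward the bottom
silhouette_tapered <- function(style = list()) {
  x <- .obj_xy$x; y <- .obj_xy$y
  cx <- jit(13, 16); top <- jit(5, 7); bot <- jit(22, 24)
  wt <- style$top_w %||% jit(2.0, 3.2)
  wb <- style$bot_w %||% jit(7.5, 9.5)
  frac <- pmin(pmax((y - top) / (bot - top), 0), 1)
  hw <- wt + (wb - wt) * frac
  wob <- jit(0.2, 0.8); ph <- jit(0, 2 * pi)
  (abs(x - cx - wob * sin(y / 3.5 + ph)) <= hw & y >= top & y <= bot) * 1
}

# class 2: rectangle with an elliptic handle (with hole) on top
silhouette_handled <- function(style = list()) {
  x <- .obj_xy$x; y <- .obj_xy$y
  cx <- jit(13, 16); cy <- jit(16, 18)
  bw <- style$body_w %||% jit(6.5, 8.0)
  bh <- style$body_h %||% jit(4.5, 5.8)
  body <- abs(x - cx) <= bw & abs(y - cy) <= bh
  hy <- cy - bh; hr <- jit(4.0, 5.2); hth <- jit(1.4, 2.0)
  r <- sqrt((x - cx)^2 + ((y - hy) * jit(1.1, 1.4))^2)
  handle <- r <= hr & r >= hr - hth & y <= hy
  (body | handle) * 1
}

# class 3: vertical shaft joined to a horizontal foot with a heel step
silhouette_heeled <- function(style = list()) {
  x <- .obj_xy$x; y <- .obj_xy$y
  sx <- jit(9, 12)
  sw <- style$shaft_w %||% jit(3.2, 4.2)
  top <- jit(4, 7); base <- jit(20, 22)
  fh <- jit(2.8, 3.8); flen <- jit(9, 11)
  shaft <- abs(x - sx) <= sw & y >= top & y <= base + fh
  foot <- x >= sx - sw & x <= sx + flen & y >= base - fh & y <= base + fh
  heel <- x >= sx - sw - jit(1, 2) & x <= sx - sw & y >= base & y <= base + fh
  (shaft | foot | heel) * 1
}

#' Generate a bank of synthetic objects
#'
#' @param n_per_class number of instances per class (>= 1)
#' @param split "train" or "test"; the two splits draw from disjoint
#'   instance-id ranges so banks never share an object
#' @param seed integer seed
#' @return an \code{occl_object_bank}: list(objects, split, source, seed)
#' @export
generate_bank <- function(n_per_class, split = c("train", "test"), seed = 1) {
  split <- match.arg(split)
  if (!is.numeric(n_per_class) || n_per_class < 1)
    occl_error("n_per_class must be >= 1", "occlnet_invalid_argument")
  n_per_class <- as.integer(n_per_class)
  offset <- if (split == "train") 0L else 1000000L
  objects <- vector("list", 4L * n_per_class)
  k <- 0L
  for (cls in 0:3) {
    for (i in seq_len(n_per_class)) {
      inst <- offset + i
      obj <- generate_object(cls, derive_seed(seed, sprintf("obj/%d/%d", cls, inst)))
      obj$instance_id <- inst
      k <- k + 1L
      objects[[k]] <- obj
    }
  }
  structure(list(objects = objects, split = split, source = "synthetic",
                 seed = seed),
            class = "occl_object_bank")
}

object_area <- function(obj) sum(obj$pixels > 0.01)

#' Per-class mean object areas of a bank
#' @param bank an object bank
#' @return named numeric vector of mean areas (pixels > 0.01) per class
#' @export
bank_class_areas <- function(bank) {
  cls <- vapply(bank$objects, function(o) o$class_id, 0L)
  ar <- vapply(bank$objects, object_area, 0)
  tapply(ar, cls, mean)
}

# ---- FashionMNIST (IDX) adapter --------------------------------------------

read_idx <- function(path) {
  if (!file.exists(path))
    occl_error(paste("missing IDX file:", path), "occlnet_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(magic) == 0)
    occl_error("empty IDX file", "occlnet_io_error")
  ndim <- magic %% 256
  if (!(ndim %in% c(1, 3)) || magic %/% 256 != 8)
    occl_error("malformed IDX header", "occlnet_io_error")
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  n_items <- prod(as.double(dims))
  raw <- readBin(con, "integer", n = n_items, size = 1, signed = FALSE)
  if (length(raw) < n_items)
    occl_error("truncated IDX file", "occlnet_io_error")
  list(dims = dims, data = raw)
}

write_idx <- function(path, data, dims) {
  con <- file(path, "wb")
  on.exit(close(con))
  magic <- 8L * 256L + length(dims)
  writeBin(as.integer(magic), con, size = 4, endian = "big")
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  writeBin(as.raw(data), con)
  invisible(path)
}

# FashionMNIST label order: 0 T-Shirt/Top, 2 Pullover, 8 Bag, 9 Ankle boot
.fmnist_keep <- c(0L, 2L, 8L, 9L)

#' Load the 4-class FashionMNIST subset from IDX files
#'
#' Keeps only T-Shirt/Top, Pullover, Bag and Ankle boot (mapped to class ids
#' 0..3 in that order) and rescales pixels to \[0,1\].  The standard train
#' split yields 24,000 objects and the test split 4,000.
#'
#' @param path directory containing \code{train-images-idx3-ubyte},
#'   \code{train-labels-idx1-ubyte} (and the \code{t10k-} test pair)
#' @param split "train" or "test"
#' @return an \code{occl_object_bank} with source "fashionmnist"
#' @export
load_fashionmnist_subset <- function(path, split = c("train", "test")) {
  split <- match.arg(split)
  prefix <- if (split == "train") "train" else "t10k"
  imgs <- read_idx(file.path(path, paste0(prefix, "-images-idx3-ubyte")))
  labs <- read_idx(file.path(path, paste0(prefix, "-labels-idx1-ubyte")))
  if (length(imgs$dims) != 3 || imgs$dims[2] != 28 || imgs$dims[3] != 28)
    occl_error("image IDX file is not n x 28 x 28", "occlnet_io_error")
  if (any(labs$data < 0 | labs$data > 9))
    occl_error("label outside 0-9", "occlnet_format_error")
  keep <- which(labs$data %in% .fmnist_keep)
  offset <- if (split == "train") 0L else 1000000L
  objects <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    # IDX stores each image row-major (rows of the image contiguous)
    px <- matrix(imgs$data[((k - 1) * 784 + 1):(k * 784)] / 255,
                 28, 28, byrow = TRUE)
    objects[[i]] <- structure(
      list(pixels = px,
           class_id = match(labs$data[k], .fmnist_keep) - 1L,
           instance_id = offset + i),
      class = "occl_object")
  }
  structure(list(objects = objects, split = split, source = "fashionmnist",
                 seed = NA_integer_),
            class = "occl_object_bank")
}
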