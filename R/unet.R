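#' U-Net configuration
#'
#' A compact U-Net pixel classifier: a contracting path of `depth` levels
#' (two 3x3 convolutions + ReLU per level, 2x2 max-pooling between levels)
#' and a symmetric expanding path (2x nearest-neighbour upsampling followed
#' by a 2x2 convolution, skip concatenation, then two 3x3 convolutions),
#' closed by a 1x1 convolution to two classes (background, cell-center) with
#' a per-pixel softmax. All convolutions use same-padding, so the probability
#' map aligns pixel-for-pixel with the input.
#'
#' @param depth Number of encoder levels (>= 2).
#' @param base_channels Channels at the first level (>= 4); doubled per level.
#' @param in_channels Input channels (grayscale: 1).
#' @param n_classes Output classes (2).
#' @return `cec_unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 16L, in_channels = 1L,
                        n_classes = 2L) {
  stopifnot(depth >= 2, base_channels >= 4, in_channels == 1, n_classes == 2)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = 1L, n_classes = 2L),
            class = "cec_unet_config")
}

# Layer table; must mirror arch_layers() in src/ops.cpp.
unet_layer_table <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  rows <- list()
  for (l in seq_len(cfg$depth)) {
    cin <- if (l == 1) cfg$in_channels else ch[l - 1]
    rows[[length(rows) + 1]] <- list(name = paste0("enc", l, "_conv1"), k = 3L,
                                     cin = cin, cout = ch[l])
    rows[[length(rows) + 1]] <- list(name = paste0("enc", l, "_conv2"), k = 3L,
                                     cin = ch[l], cout = ch[l])
  }
  for (l in rev(seq_len(cfg$depth - 1))) {
    rows[[length(rows) + 1]] <- list(name = paste0("up", l), k = 2L,
                                     cin = ch[l + 1], cout = ch[l])
    rows[[length(rows) + 1]] <- list(name = paste0("dec", l, "_conv1"), k = 3L,
                                     cin = 2L * ch[l], cout = ch[l])
    rows[[length(rows) + 1]] <- list(name = paste0("dec", l, "_conv2"), k = 3L,
                                     cin = ch[l], cout = ch[l])
  }
  rows[[length(rows) + 1]] <- list(name = "final", k = 1L, cin = ch[1],
                                   cout = cfg$n_classes)
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Build a U-Net model
#'
#' Initializes weights with He (Kaiming) normal draws scaled by fan-in and
#' zero biases, under a fixed seed.
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for the weight initialization.
#' @return `cec_unet`: list with `config` and a flat named `weights` list
#'   (`<layer>.W` is a `(k^2 cin) x cout` matrix, `<layer>.b` a length-`cout`
#'   vector).
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cec_unet_config"))
  layers <- unet_layer_table(cfg)
  weights <- with_seed(seed, {
    w <- list()
    for (i in seq_len(nrow(layers))) {
      l <- layers[i, ]
      fan_in <- l$k^2 * l$cin
      w[[paste0(l$name, ".W")]] <-
        matrix(rnorm(fan_in * l$cout, 0, sqrt(2 / fan_in)), fan_in, l$cout)
      w[[paste0(l$name, ".b")]] <- numeric(l$cout)
    }
    w
  })
  structure(list(config = cfg, weights = weights), class = "cec_unet")
}

#' @rdname build_unet
#' @param model A `cec_unet`.
#' @return `count_params`: total number of trainable parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

pad_to_multiple <- function(img, m) {
  h <- nrow(img); w <- ncol(img)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph > 0) img <- rbind(img, img[rep(h, ph), , drop = FALSE])
  if (pw > 0) img <- cbind(img, img[, rep(w, pw), drop = FALSE])
  img
}

#' Predict a two-class probability map
#'
#' Runs the network on one grayscale image (values 0-255; scaled to [0, 1]
#' internally). Inputs whose sides are not divisible by `2^depth` are edge-
#' padded for the forward pass and the map is cropped back, so the output
#' always matches the input shape.
#'
#' @param model A trained or freshly built `cec_unet`.
#' @param img H x W matrix of gray values in 0-255.
#' @param image_id Identifier carried into the result.
#' @return `cec_probability_map`: list with `probs` (H x W x 2 array, slice 1
#'   = background, slice 2 = cell-center; per-pixel sums are 1) and
#'   `image_id`.
#' @export
predict_probs <- function(model, img, image_id = "") {
  stopifnot(inherits(model, "cec_unet"), is.matrix(img))
  m <- 2^model$config$depth
  x <- pad_to_multiple(img / 255, m)
  p <- cpp_unet_probs(model$weights, model$config$depth,
                      model$config$base_channels, x)
  p <- p[seq_len(nrow(img)), seq_len(ncol(img)), , drop = FALSE]
  structure(list(probs = p, image_id = image_id), class = "cec_probability_map")
}

#' Rasterize center points into a binary training target
#'
#' Point annotations become a segmentation target by stamping a filled disk
#' of the given radius at each center (rounded to the nearest pixel);
#' overlapping disks merge into their union.
#'
#' @param centers Data frame of `x`, `y` (0-based pixel coordinates).
#' @param shape `c(height, width)` of the target mask.
#' @param disk_radius_px Disk radius in pixels (>= 1).
#' @return Integer H x W matrix of 0/1.
#' @export
rasterize_labels <- function(centers, shape, disk_radius_px = 3L) {
  stopifnot(disk_radius_px >= 1)
  centers <- as_centers_df(centers)
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0L, h, w)
  r <- disk_radius_px
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  for (i in seq_len(nrow(centers))) {
    cx <- round(centers$x[i]); cy <- round(centers$y[i])
    xs <- cx + off$dx; ys <- cy + off$dy
    ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
    mask[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- 1L
  }
  mask
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the architecture config and all
#' weights (written at run time; none ship with the package).
#'
#' @param model A `cec_unet`.
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cec_unet"))
  saveRDS(list(config = unclass(model$config), weights = model$weights), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(unet_config, x$config[c("depth", "base_channels",
                                         "in_channels", "n_classes")])
  structure(list(config = cfg, weights = x$weights), class = "cec_unet")
}
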