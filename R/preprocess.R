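#' Preprocessing configuration
#'
#' The preprocessing chain applied to every micrograph before training or
#' inference, in fixed order: (1) downscale by `resize_factor` with area
#' (block-mean) interpolation, scaling center coordinates by the same factor;
#' (2) gamma correction `I' = 255 (I/255)^gamma`; (3) linear contrast stretch
#' between two intensity percentiles; (4) boundary highlighting by unsharp
#' masking (subtracting a weighted smoothed copy accentuates the dark cell
#' borders); (5) histogram equalization. The study names these operations
#' without parameters; the defaults here are the package's own calibration.
#'
#' Percentiles `(0, 100)` disable the stretch entirely (identity), so the
#' all-defaults-off configuration reproduces the resized input exactly.
#'
#' @param resize_factor Scale factor in (0, 1]; 0.25 mirrors the study's
#'   quarter-resolution working images (1392 x 1040 -> 348 x 260).
#' @param gamma Gamma exponent (> 0).
#' @param contrast_stretch Length-2 percentiles `(low_pct, high_pct)`.
#' @param boundary_highlight_weight Unsharp-mask weight in [0, 1).
#' @param equalize Apply histogram equalization last?
#' @param blur_sigma Gaussian sigma (px) of the smoothed copy used by the
#'   unsharp mask.
#' @return `cec_preprocess_config`.
#' @export
preprocess_config <- function(resize_factor = 0.25, gamma = 0.8,
                              contrast_stretch = c(1, 99),
                              boundary_highlight_weight = 0.5,
                              equalize = TRUE, blur_sigma = 2) {
  stopifnot(resize_factor > 0, resize_factor <= 1, gamma > 0,
            length(contrast_stretch) == 2,
            contrast_stretch[1] >= 0, contrast_stretch[1] < contrast_stretch[2],
            contrast_stretch[2] <= 100,
            boundary_highlight_weight >= 0, boundary_highlight_weight < 1,
            blur_sigma > 0)
  structure(list(resize_factor = resize_factor, gamma = gamma,
                 contrast_stretch = contrast_stretch,
                 boundary_highlight_weight = boundary_highlight_weight,
                 equalize = equalize, blur_sigma = blur_sigma),
            class = "cec_preprocess_config")
}

resize_area <- function(img, factor) {
  if (factor == 1) return(img)
  hin <- nrow(img); win <- ncol(img)
  hout <- max(1L, floor(hin * factor))
  wout <- max(1L, floor(win * factor))
  k <- 1 / factor
  if (abs(k - round(k)) < 1e-9 && hin %% round(k) == 0 && win %% round(k) == 0) {
    k <- as.integer(round(k))
    # exact block mean via pooling matrices
    A <- matrix(0, hout, hin)
    A[cbind(rep(seq_len(hout), each = k), seq_len(hin))] <- 1 / k
    B <- matrix(0, wout, win)
    B[cbind(rep(seq_len(wout), each = k), seq_len(win))] <- 1 / k
    return(A %*% img %*% t(B))
  }
  # general case: bilinear sampling at destination pixel centers
  sx <- (seq_len(wout) - 0.5) / factor - 0.5
  sy <- (seq_len(hout) - 0.5) / factor - 0.5
  x0 <- clamp(floor(sx), 0, win - 1); x1 <- clamp(x0 + 1, 0, win - 1)
  y0 <- clamp(floor(sy), 0, hin - 1); y1 <- clamp(y0 + 1, 0, hin - 1)
  fx <- sx - x0; fy <- sy - y0
  i00 <- img[y0 + 1, x0 + 1, drop = FALSE]; i01 <- img[y0 + 1, x1 + 1, drop = FALSE]
  i10 <- img[y1 + 1, x0 + 1, drop = FALSE]; i11 <- img[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, hout, wout); wx <- matrix(fx, hout, wout, byrow = TRUE)
  i00 * (1 - wy) * (1 - wx) + i01 * (1 - wy) * wx +
    i10 * wy * (1 - wx) + i11 * wy * wx
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

equalize_hist <- function(img) {
  v <- as.integer(round(clamp(img, 0, 255)))
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  n <- length(v)
  if (n == cdf_min) return(img)  # constant image: nothing to equalize
  map <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  matrix(map[v + 1L], nrow(img), ncol(img))
}

#' Preprocess an annotated image
#'
#' Applies the fixed pipeline of [preprocess_config()] to the pixels and maps
#' the center annotations through the geometry change. Deterministic: same
#' input and config give the same output.
#'
#' @param img An [annotated_image()] with pixels.
#' @param cfg A [preprocess_config()].
#' @return An [annotated_image()] at working resolution; its `um_per_px` is
#'   the acquisition pitch divided by `resize_factor`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "cec_annotated_image"), !is.null(img$pixels))
  px <- resize_area(img$pixels, cfg$resize_factor)
  if (nrow(px) < 16 || ncol(px) < 16) {
    stop("resize_factor ", cfg$resize_factor, " yields ", nrow(px), "x",
         ncol(px), " (< 16 px)")
  }
  px <- 255 * (clamp(px, 0, 255) / 255)^cfg$gamma
  cs <- cfg$contrast_stretch
  if (!(cs[1] <= 0 && cs[2] >= 100)) {
    q <- quantile(px, cs / 100, names = FALSE)
    if (q[2] > q[1]) px <- clamp((px - q[1]) / (q[2] - q[1]) * 255, 0, 255)
  }
  w <- cfg$boundary_highlight_weight
  if (w > 0) {
    sm <- cpp_sep_blur(px, gaussian_kernel(cfg$blur_sigma))
    px <- clamp((px - w * sm) / (1 - w), 0, 255)
  }
  if (cfg$equalize) px <- equalize_hist(px)
  # scaled edge centers can land a fraction beyond the last working pixel
  annotated_image(img$image_id, pixels = px,
                  centers = data.frame(
                    x = clamp(img$centers$x * cfg$resize_factor, 0, ncol(px) - 1),
                    y = clamp(img$centers$y * cfg$resize_factor, 0, nrow(px) - 1)),
                  source = img$source,
                  um_per_px = img$um_per_px / cfg$resize_factor)
}

flip_record <- function(r, flip_x, flip_y, suffix) {
  px <- r$pixels
  cx <- r$centers$x; cy <- r$centers$y
  if (flip_x) {
    px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    cx <- ncol(px) - 1 - cx
  }
  if (flip_y) {
    px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
    cy <- nrow(px) - 1 - cy
  }
  annotated_image(paste0(r$image_id, suffix), pixels = px,
                  centers = data.frame(x = cx, y = cy),
                  source = r$source, um_per_px = r$um_per_px)
}

#' Flip-based data augmentation
#'
#' `x2_flip` emits each record plus its horizontal mirror; `x4_flip` emits
#' the record, horizontal mirror, vertical mirror, and 180-degree rotation
#' (both mirrors composed). Center coordinates are remapped exactly
#' (horizontal mirror sends `x` to `width - 1 - x`), so flipping twice
#' restores the original annotations bit for bit. 2341 inputs under `x4_flip`
#' give the study's 9364 stage-2 training images.
#'
#' @param records Nonempty list of [annotated_image()] with pixels.
#' @param mode `"x2_flip"` or `"x4_flip"`.
#' @return List of length `2 * length(records)` or `4 * length(records)`.
#' @export
augment <- function(records, mode = c("x2_flip", "x4_flip")) {
  mode <- match.arg(mode)
  if (length(records) == 0) stop("augment needs at least one record")
  out <- lapply(records, function(r) {
    res <- list(r, flip_record(r, TRUE, FALSE, "__hf"))
    if (mode == "x4_flip") {
      res <- c(res, list(flip_record(r, FALSE, TRUE, "__vf"),
                         flip_record(r, TRUE, TRUE, "__r180")))
    }
    res
  })
  do.call(c, out)
}
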