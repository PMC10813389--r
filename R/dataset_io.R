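#' Annotated images, annotation CSVs, and dataset splits
#'
#' An annotated image couples a grayscale micrograph with its list of cell
#' center points and the provenance of those points: `manual` (drawn by a
#' human), `model` (pseudo-labels predicted by a trained network), or
#' `model_corrected` (pseudo-labels after human revision). Coordinates are
#' 0-based sub-pixel floats with `x` = column and `y` = row of the stored
#' image.
#'
#' @param image_id Identifier string.
#' @param pixels Optional H x W matrix of gray values (0-255); annotation
#'   records loaded from CSV alone carry `NULL` pixels.
#' @param centers Data frame (or 2-column matrix) of `x`, `y` coordinates.
#' @param source Annotation provenance.
#' @param um_per_px Pixel pitch of `pixels` in micrometres per pixel.
#' @return An object of class `cec_annotated_image`.
#' @export
annotated_image <- function(image_id, pixels = NULL,
                            centers = data.frame(x = numeric(0), y = numeric(0)),
                            source = c("manual", "model", "model_corrected"),
                            um_per_px = 0.645) {
  source <- match.arg(source)
  centers <- as_centers_df(centers)
  if (!is.null(pixels)) {
    stopifnot(is.matrix(pixels))
    bad <- centers$x < 0 | centers$x > ncol(pixels) - 1 |
      centers$y < 0 | centers$y > nrow(pixels) - 1
    if (any(bad)) {
      stop("image ", image_id, ": ", sum(bad),
           " center(s) outside image bounds")
    }
  }
  structure(list(image_id = image_id, pixels = pixels, centers = centers,
                 source = source, um_per_px = um_per_px),
            class = "cec_annotated_image")
}

#' Read / write 8-bit grayscale PNG images
#'
#' Images are stored as 8-bit grayscale PNG; in memory they are H x W
#' matrices of doubles in 0-255. RGB(A) input collapses to its first channel.
#'
#' @param path File path.
#' @return `read_image`: H x W matrix in 0-255.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  round(a * 255)
}

#' @rdname read_image
#' @param img H x W matrix of gray values in 0-255.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Load center annotations from CSV
#'
#' The annotation schema is a CSV with header `image_id,x,y`, one row per
#' center, possibly covering several images. Malformed rows are reported with
#' their line numbers; coordinates outside the supplied bounds raise an error
#' naming the offending image.
#'
#' @param path CSV path.
#' @param image_ids Optional character vector: ids that must appear in the
#'   result even with zero annotated centers (e.g. empty images).
#' @param bounds Optional bounds check: either a single `c(width, height)`
#'   applied to all images, or a named list of such vectors per image id.
#' @param source Provenance to record on the loaded records.
#' @param um_per_px Pixel pitch recorded on the loaded records.
#' @return List of [annotated_image()] records (pixels `NULL`), one per id.
#' @export
load_annotations <- function(path, image_ids = NULL, bounds = NULL,
                             source = "manual", um_per_px = 0.645) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("image_id", "x", "y")
  if (!all(required %in% names(df))) {
    stop("annotation file ", path, " lacks required columns image_id,x,y")
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y) | df$image_id == "")
  if (length(bad)) {
    stop("malformed annotation rows in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  ids <- unique(c(df$image_id, image_ids))
  lapply(ids, function(id) {
    sel <- df$image_id == id
    cx <- x[sel]; cy <- y[sel]
    if (!is.null(bounds)) {
      b <- if (is.list(bounds)) bounds[[id]] else bounds
      if (!is.null(b)) {
        out <- cx < 0 | cx > b[1] - 1 | cy < 0 | cy > b[2] - 1
        if (any(out)) {
          stop("annotations for image ", id, " fall outside bounds ",
               b[1], "x", b[2])
        }
      }
    }
    annotated_image(id, centers = data.frame(x = cx, y = cy),
                    source = source, um_per_px = um_per_px)
  })
}

#' @rdname load_annotations
#' @param records List of [annotated_image()] records to write.
#' @export
save_annotations <- function(records, path) {
  if (inherits(records, "cec_annotated_image")) records <- list(records)
  rows <- lapply(records, function(r) {
    if (nrow(r$centers) == 0L) return(NULL)
    data.frame(image_id = r$image_id, x = r$centers$x, y = r$centers$y,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(image_id = character(0), x = numeric(0), y = numeric(0))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic dataset splits
#'
#' Shuffles `ids` with the given seed and partitions them in order into
#' train/validation/test sets of the requested sizes (random-by-image; the
#' upstream study's 606 images went 402/121/83 and its 3098 pseudo-labeled
#' pool 2341/757).
#'
#' @param ids Character or integer vector of image ids.
#' @param sizes Length-3 vector `c(n_train, n_val, n_test)`; must sum to
#'   `length(ids)`.
#' @param seed Integer seed.
#' @return `cec_split_spec`: list with `train`, `val`, `test`, `seed`.
#' @export
make_split <- function(ids, sizes, seed = 1L) {
  stopifnot(length(sizes) == 3)
  if (sum(sizes) != length(ids)) {
    stop("sizes sum to ", sum(sizes), " but there are ", length(ids), " ids")
  }
  if (anyDuplicated(ids)) stop("ids must be unique")
  shuffled <- with_seed(seed, sample(ids))
  structure(list(
    train = shuffled[seq_len(sizes[1])],
    val = shuffled[seq_len(sizes[2]) + sizes[1]],
    test = if (sizes[3] > 0) shuffled[seq_len(sizes[3]) + sizes[1] + sizes[2]]
           else character(0),
    seed = as.integer(seed)
  ), class = "cec_split_spec")
}

#' @rdname make_split
#' @param split A `cec_split_spec`.
#' @param path JSON file path.
#' @export
save_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname make_split
#' @export
load_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(s$train), val = as.character(s$val),
                 test = as.character(s$test %||% character(0)),
                 seed = as.integer(s$seed %||% NA)),
            class = "cec_split_spec")
}
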