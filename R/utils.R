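# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deep copy of a flat list of numeric vectors/matrices. Needed because the
# C++ optimizer updates weight memory in place, bypassing R's copy-on-write.
deep_copy <- function(x) unserialize(serialize(x, NULL))

`%||%` <- function(a, b) if (is.null(a)) b else a

as_centers_df <- function(centers) {
  if (is.null(centers)) return(data.frame(x = numeric(0), y = numeric(0)))
  if (is.matrix(centers)) centers <- data.frame(x = centers[, 1], y = centers[, 2])
  if (!all(c("x", "y") %in% names(centers))) {
    stop("centers must have columns 'x' and 'y'")
  }
  data.frame(x = as.numeric(centers$x), y = as.numeric(centers$y))
}

centers_matrix <- function(centers) {
  df <- as_centers_df(centers)
  cbind(df$x, df$y)
}
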