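#' One-to-one point matching between predictions and references
#'
#' Greedy globally-nearest-first assignment: enumerate all prediction-
#' reference pairs within `match_radius_px`, sort them by distance (ties
#' broken by prediction index, then reference index), and accept a pair iff
#' neither endpoint is already matched. Matched pairs are true positives;
#' unmatched predictions are false positives and unmatched references false
#' negatives.
#'
#' @param pred,ref Data frames (or 2-column matrices) of `x`, `y`.
#' @param match_radius_px Maximum accepted center distance in pixels (> 0).
#' @return `cec_match_result`: `pairs` (data frame `pred_idx`, `ref_idx`,
#'   `distance`), counts `n_tp`, `n_fp`, `n_fn`, and `match_radius_px`.
#' @export
match_points <- function(pred, ref, match_radius_px = 10) {
  stopifnot(match_radius_px > 0)
  p <- centers_matrix(pred)
  r <- centers_matrix(ref)
  np <- nrow(p); nr <- nrow(r)
  pairs <- data.frame(pred_idx = integer(0), ref_idx = integer(0),
                      distance = numeric(0))
  if (np > 0 && nr > 0) {
    d <- sqrt(outer(p[, 1], r[, 1], "-")^2 + outer(p[, 2], r[, 2], "-")^2)
    cand <- which(d <= match_radius_px, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dist <- d[cand]
      ord <- order(dist, cand[, 1], cand[, 2])
      used_p <- logical(np); used_r <- logical(nr)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_r[j]) {
          used_p[i] <- TRUE; used_r[j] <- TRUE
          pairs <- rbind(pairs, data.frame(pred_idx = i, ref_idx = j,
                                           distance = dist[k]))
        }
      }
    }
  }
  structure(list(pairs = pairs, n_tp = nrow(pairs),
                 n_fp = np - nrow(pairs), n_fn = nr - nrow(pairs),
                 match_radius_px = match_radius_px),
            class = "cec_match_result")
}

per_image_prf <- function(m) {
  tp <- m$n_tp; fp <- m$n_fp; fn <- m$n_fn
  if (tp + fp == 0 && tp + fn == 0) {
    return(c(precision = 1, recall = 1, f_value = 1, flag = 1))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_value = f, flag = 0)
}

#' Detection metrics with bootstrap confidence intervals
#'
#' Per image, precision = TP/(TP+FP), recall = TP/(TP+FN) and F is their
#' harmonic mean; an image with neither predictions nor references scores
#' P = R = F = 1 and is flagged in the per-image table; an image with
#' references but no predictions (or vice versa) scores 0 on the undefined
#' ratio. The report gives macro averages (means over images) with
#' nonparametric percentile bootstrap CIs over images.
#'
#' @param matches List of `cec_match_result`, one per image (optionally
#'   named by image id).
#' @param bootstrap_reps Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return `cec_metrics_report`: `precision`, `recall`, `f_value` (macro
#'   means), `ci95` (named list of `c(lo, hi)` per metric), `per_image` table.
#' @export
compute_metrics <- function(matches, bootstrap_reps = 2000L, seed = 1L,
                            conf_level = 0.95) {
  stopifnot(length(matches) >= 1)
  tab <- t(vapply(matches, per_image_prf, numeric(4)))
  per_image <- data.frame(
    image_id = names(matches) %||% as.character(seq_along(matches)),
    n_tp = vapply(matches, `[[`, numeric(1), "n_tp"),
    n_fp = vapply(matches, `[[`, numeric(1), "n_fp"),
    n_fn = vapply(matches, `[[`, numeric(1), "n_fn"),
    precision = tab[, "precision"], recall = tab[, "recall"],
    f_value = tab[, "f_value"], both_empty = tab[, "flag"] == 1,
    row.names = NULL
  )
  pt <- colMeans(tab[, 1:3, drop = FALSE])
  alpha <- (1 - conf_level) / 2
  n <- nrow(tab)
  ci <- with_seed(seed, {
    reps <- vapply(seq_len(bootstrap_reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      colMeans(tab[idx, 1:3, drop = FALSE])
    }, numeric(3))
    apply(reps, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  })
  structure(list(
    precision = pt[["precision"]], recall = pt[["recall"]],
    f_value = pt[["f_value"]],
    ci95 = list(precision = ci[, 1], recall = ci[, 2], f_value = ci[, 3]),
    conf_level = conf_level, per_image = per_image
  ), class = "cec_metrics_report")
}

#' Pearson correlation between predicted and reference densities
#'
#' Sample Pearson r with a two-sided p-value from the t transform on n - 2
#' degrees of freedom.
#'
#' @param pred_densities,ref_densities Equal-length numeric vectors (n >= 3).
#' @return `cec_density_correlation`: `pearson_r`, `p_value`, `n`.
#' @export
density_correlation <- function(pred_densities, ref_densities) {
  stopifnot(length(pred_densities) == length(ref_densities),
            length(pred_densities) >= 3)
  if (stats::sd(pred_densities) == 0 || stats::sd(ref_densities) == 0) {
    stop("density_correlation undefined: zero variance input")
  }
  ct <- cor.test(pred_densities, ref_densities, method = "pearson")
  structure(list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(pred_densities)),
            class = "cec_density_correlation")
}
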