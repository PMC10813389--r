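# Independent oracles used by the property tests. These deliberately avoid
# the package's own C++ routines: flood fill is plain recursive R, and the
# matching oracle enumerates assignments exhaustively.

# Connected components by BFS flood fill over an 0/1 matrix.
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (cc in seq_len(w)) for (rr in seq_len(h)) {
    if (mask[rr, cc] == 0 || lab[rr, cc] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(rr, cc))
    lab[rr, cc] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        r2 <- p[1] + nbr[k, 1]; c2 <- p[2] + nbr[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            mask[r2, c2] == 1 && lab[r2, c2] == 0) {
          lab[r2, c2] <- nxt
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# Canonical partition signature so label numbering cannot matter.
component_signature <- function(lab) {
  groups <- split(which(lab > 0), lab[lab > 0])
  sig <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1)))
  unname(sig)
}

# Exhaustive maximum-cardinality, minimum-total-distance one-to-one matching
# within `radius`; feasible only for small instances (<= ~6 per side).
exhaustive_match_oracle <- function(pred, ref, radius) {
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) return(list(n_tp = 0L, cost = 0))
  d <- sqrt(outer(pred[, 1], ref[, 1], "-")^2 +
            outer(pred[, 2], ref[, 2], "-")^2)
  best <- list(n_tp = 0L, cost = 0)
  # recurse over predictions; each matches an unused ref within radius or none
  rec <- function(i, used, ntp, cost) {
    if (i > np) {
      if (ntp > best$n_tp || (ntp == best$n_tp && cost < best$cost)) {
        best <<- list(n_tp = ntp, cost = cost)
      }
      return(invisible())
    }
    rec(i + 1, used, ntp, cost)
    for (j in seq_len(nr)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        rec(i + 1, used, ntp + 1L, cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nr), 0L, 0)
  best
}

# Small preprocessed synthetic pool for smoke-training tests (working
# resolution 16x16 via 64px scenes, quarter resize).
tiny_pool <- function(n, seed_base, regime = "middle", px = 64L) {
  lapply(seq_len(n), function(i) {
    spec <- scene_spec(width_px = px, height_px = px, density_regime = regime,
                       seed = seed_base + i)
    smp <- generate_scene(spec)
    preprocess_image(
      annotated_image(sprintf("t%d_%03d", seed_base, i), pixels = smp$image,
                      centers = smp$centers, um_per_px = spec$um_per_px),
      preprocess_config())
  })
}
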