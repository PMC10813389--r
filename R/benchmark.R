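#' Scaled-down synthetic benchmark of the full pipeline
#'
#' Runs the complete two-stage semi-supervised workflow at desk scale on
#' synthetic data and reports the headline statistics: macro precision,
#' recall and F of the final cell-count model on held-out test images, the
#' F of the stage-1 initial model, and the Pearson correlation between
#' predicted and true per-image density.
#'
#' The profile is fixed: 200 labeled + 400 unlabeled + 80 test images of
#' 256 x 256 px at 0.645 um/px (64 x 64 after quarter-resolution
#' preprocessing), density regimes low/middle/high in equal thirds, a depth-2
#' / 8-channel U-Net, up to 8 epochs per stage — both stages train by the
#' same method with the same budget, as in the source workflow (which used up
#' to 30 and selected epochs 14 and 6) — label disks of
#' radius 2 px at working resolution (at the high-density regime centers sit
#' ~6.4 px apart, so radius-3 disks would fuse adjacent targets by
#' construction), perfect correction policy, 10 px match radius.
#'
#' @param seed Master seed; governs scene generation, splits, weight
#'   initialization, shuffling, correction and bootstrap.
#' @param n_labeled,n_unlabeled,n_test Pool sizes (scale down for smoke
#'   tests; results below the default scale are not comparable).
#' @param image_px Scene side length in pixels.
#' @param max_epochs1,max_epochs2 Epoch budgets of the two stages.
#' @param verbose Print stage progress to stderr.
#' @return `cec_benchmark_result`: the `cec_semisup_result` plus a `summary`
#'   list with `precision_pct`, `recall_pct`, `f_pct` (cell-count model),
#'   `f_initial_pct`, and `pearson_r`.
#' @export
run_benchmark <- function(seed = 1L, n_labeled = 200L, n_unlabeled = 400L,
                          n_test = 80L, image_px = 256L,
                          max_epochs1 = 8L, max_epochs2 = 8L,
                          verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  seed <- as.integer(seed)
  pp_cfg <- preprocess_config()  # 1/4 resize, gamma 0.8, stretch (1,99), ...
  regimes <- c("low", "middle", "high")

  make_pool <- function(n, seed_base) {
    lapply(seq_len(n), function(i) {
      regime <- regimes[(i - 1L) %% 3L + 1L]
      spec <- scene_spec(width_px = image_px, height_px = image_px,
                        density_regime = regime, seed = seed_base + i)
      smp <- generate_scene(spec)
      acq <- annotated_image(sprintf("s%d_img%04d", seed_base, i),
                             pixels = smp$image, centers = smp$centers,
                             um_per_px = spec$um_per_px)
      preprocess_image(acq, pp_cfg)  # keep only working resolution
    })
  }

  say("generating synthetic pools (", n_labeled, " labeled / ", n_unlabeled,
      " unlabeled / ", n_test, " test) ...")
  labeled <- make_pool(n_labeled, seed * 10000L)
  unlabeled <- make_pool(n_unlabeled, seed * 10000L + 1000L)
  test <- make_pool(n_test, seed * 10000L + 2000L)

  say("running two-stage semi-supervised training ...")
  res <- run_semi_supervised(
    labeled, unlabeled, test,
    model_cfg = unet_config(depth = 2L, base_channels = 8L),
    train_cfg1 = train_config(max_epochs = max_epochs1, seed = seed),
    train_cfg2 = train_config(max_epochs = max_epochs2, seed = seed + 1L),
    detect_cfg = detection_config(),
    policy = correction_policy(1, 1, 0),
    disk_radius_px = 2L, match_radius_px = 10,
    bootstrap_reps = 2000L, seed = seed
  )
  res$summary <- list(
    precision_pct = 100 * res$cellcount$metrics$precision,
    recall_pct = 100 * res$cellcount$metrics$recall,
    f_pct = 100 * res$cellcount$metrics$f_value,
    f_initial_pct = 100 * res$initial$metrics$f_value,
    pearson_r = res$cellcount$density$correlation$pearson_r,
    initial_epoch = res$initial$selected_epoch,
    cellcount_epoch = res$cellcount$selected_epoch
  )
  class(res) <- c("cec_benchmark_result", class(res))
  say(sprintf(
    "cell count model: P %.1f%% R %.1f%% F %.1f%% | initial F %.1f%% | r %.3f",
    res$summary$precision_pct, res$summary$recall_pct, res$summary$f_pct,
    res$summary$f_initial_pct, res$summary$pearson_r))
  res
}
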