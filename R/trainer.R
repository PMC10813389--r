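#' Training configuration
#'
#' Adam-optimized pixelwise cross-entropy training, one image per step. Both
#' the training and validation losses are recorded per epoch; the train loss
#' is re-evaluated on the full training set after the epoch's updates, so a
#' validation set identical to the training set yields identical curves.
#'
#' @param max_epochs Maximum epochs (>= 1); the study trained up to 30 and
#'   picked the epoch by validation loss.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param crop_size Optional square random-crop side (multiple of
#'   `2^depth`); `NULL` trains on full images.
#' @param seed Seed for shuffling and cropping.
#' @param fg_weight Relative loss weight of foreground (cell-center) pixels.
#' @param init_bias_prior Initialize the final-layer bias to the log prior of
#'   the two classes computed from the training masks; spares early epochs
#'   the work of learning the foreground/background imbalance.
#' @return `cec_train_config`.
#' @export
train_config <- function(max_epochs = 30L, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, crop_size = NULL,
                         seed = 1L, fg_weight = 1, init_bias_prior = TRUE) {
  stopifnot(max_epochs >= 1, lr > 0, beta1 >= 0, beta1 < 1, beta2 >= 0,
            beta2 < 1, fg_weight > 0)
  structure(list(max_epochs = as.integer(max_epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, crop_size = crop_size,
                 seed = as.integer(seed), fg_weight = fg_weight,
                 init_bias_prior = isTRUE(init_bias_prior)),
            class = "cec_train_config")
}

# Build (image/255, mask) training samples from annotated images.
make_samples <- function(records, disk_radius_px = 3L) {
  lapply(records, function(r) {
    list(x = r$pixels / 255,
         mask = rasterize_labels(r$centers, dim(r$pixels), disk_radius_px),
         image_id = r$image_id)
  })
}

mean_loss <- function(weights, cfg_model, samples, fg_weight) {
  mean(vapply(samples, function(s) {
    cpp_unet_loss(weights, cfg_model$depth, cfg_model$base_channels,
                  s$x, s$mask, fg_weight)
  }, numeric(1)))
}

#' Train a U-Net
#'
#' Runs up to `max_epochs` Adam epochs over the training samples (shuffled
#' each epoch under the config seed), snapshots the weights after every
#' epoch, and records the loss curve. Deterministic given the seed. A
#' non-finite loss aborts with a diagnostic.
#'
#' @param model A `cec_unet` (will not be modified).
#' @param train_set,val_set Nonempty lists of samples as built by
#'   `make_samples()`: each a list with `x` (H x W matrix in [0, 1]) and
#'   `mask` (integer 0/1 matrix).
#' @param cfg A [train_config()].
#' @return `cec_training`: `curve` (data frame `epoch, train_loss, val_loss`),
#'   `epoch_weights` (list of weight snapshots), `model_config`, `config`.
#' @export
train_unet <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(model, "cec_unet"), length(train_set) > 0,
            length(val_set) > 0)
  mc <- model$config
  if (!is.null(cfg$crop_size) && cfg$crop_size %% 2^mc$depth != 0) {
    stop("crop_size must be a multiple of 2^depth")
  }
  weights <- deep_copy(model$weights)
  if (isTRUE(cfg$init_bias_prior)) {
    fg <- mean(vapply(train_set, function(s) mean(s$mask), numeric(1)))
    fg <- min(max(fg, 1e-4), 1 - 1e-4)
    weights[["final.b"]] <- c(log(1 - fg), log(fg))
  }
  m <- deep_copy(weights); v <- deep_copy(weights)
  for (nm in names(m)) { m[[nm]][] <- 0; v[[nm]][] <- 0 }
  t_step <- 0L
  curve <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  epoch_weights <- list()
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$max_epochs)) {
      for (i in sample(length(train_set))) {
        s <- train_set[[i]]
        x <- s$x; msk <- s$mask
        if (!is.null(cfg$crop_size) &&
            (nrow(x) > cfg$crop_size || ncol(x) > cfg$crop_size)) {
          r0 <- sample.int(nrow(x) - cfg$crop_size + 1L, 1L)
          c0 <- sample.int(ncol(x) - cfg$crop_size + 1L, 1L)
          x <- x[r0:(r0 + cfg$crop_size - 1L), c0:(c0 + cfg$crop_size - 1L)]
          msk <- msk[r0:(r0 + cfg$crop_size - 1L), c0:(c0 + cfg$crop_size - 1L)]
        }
        t_step <- t_step + 1L
        loss <- cpp_unet_train_step(weights, m, v, mc$depth, mc$base_channels,
                                    x, msk, cfg$fg_weight, cfg$lr, cfg$beta1,
                                    cfg$beta2, cfg$eps, t_step)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", ep, ", step ", t_step)
        }
      }
      tl <- mean_loss(weights, mc, train_set, cfg$fg_weight)
      vl <- mean_loss(weights, mc, val_set, cfg$fg_weight)
      if (!is.finite(tl) || !is.finite(vl)) {
        stop("non-finite evaluation loss at epoch ", ep)
      }
      curve <- rbind(curve, data.frame(epoch = ep, train_loss = tl,
                                       val_loss = vl))
      epoch_weights[[ep]] <- deep_copy(weights)
    }
  })
  structure(list(curve = curve, epoch_weights = epoch_weights,
                 model_config = mc, config = cfg),
            class = "cec_training")
}

#' Select the epoch with minimal validation loss
#'
#' Mechanizes the study's visual loss-curve inspection as the argmin of the
#' validation loss, ties broken toward the earlier epoch.
#'
#' @param curve A `cec_training`, its `curve` data frame, or a numeric vector
#'   of per-epoch validation losses.
#' @return 1-based epoch index.
#' @export
select_epoch <- function(curve) {
  if (inherits(curve, "cec_training")) curve <- curve$curve
  v <- if (is.data.frame(curve)) curve$val_loss else as.numeric(curve)
  if (length(v) == 0) stop("empty loss curve")
  which.min(v)  # which.min returns the first (earliest) minimum
}

#' @rdname select_epoch
#' @param training A `cec_training`.
#' @param epoch Epoch whose snapshot to extract (default: [select_epoch()]).
#' @return `model_at_epoch`: a `cec_unet` with that epoch's weights.
#' @export
model_at_epoch <- function(training, epoch = select_epoch(training)) {
  stopifnot(inherits(training, "cec_training"),
            epoch >= 1, epoch <= length(training$epoch_weights))
  structure(list(config = training$model_config,
                 weights = training$epoch_weights[[epoch]]),
            class = "cec_unet")
}

#' Pseudo-label unlabeled images
#'
#' Runs prediction + center extraction on each image and returns annotation
#' records with `source = "model"`. Per-image failures propagate as errors
#' only after the whole batch is attempted.
#'
#' @param model A trained `cec_unet`.
#' @param records List of [annotated_image()] with pixels (any centers they
#'   carry are ignored).
#' @param detect_cfg A [detection_config()].
#' @return List of [annotated_image()] with predicted centers,
#'   `source = "model"`.
#' @export
pseudo_label <- function(model, records, detect_cfg = detection_config()) {
  out <- lapply(records, function(r) {
    tryCatch({
      pm <- predict_probs(model, r$pixels, r$image_id)
      det <- extract_centers(pm, detect_cfg)
      annotated_image(r$image_id, pixels = r$pixels, centers = det$centers,
                      source = "model", um_per_px = r$um_per_px)
    }, error = function(e) e)
  })
  errs <- vapply(out, inherits, logical(1), "error")
  if (any(errs)) {
    stop("pseudo_label failed on ", sum(errs), " image(s); first error: ",
         conditionMessage(out[[which(errs)[1]]]))
  }
  out
}

#' Policy for simulated manual correction of pseudo-labels
#'
#' The study's human annotators revised plot omissions and over-detections on
#' every pseudo-labeled image. This package replaces that manual step with a
#' stochastic policy so imperfect correction can be studied: each missed true
#' center is added with probability `p_fix_miss` (jittered by a Gaussian of
#' sd `jitter_px`), each spurious prediction removed with probability
#' `p_fix_spurious`. The default (1, 1, 0) reproduces perfect correction,
#' under which corrected pseudo-labels carry exactly one point per true cell.
#'
#' @param p_fix_miss,p_fix_spurious Probabilities in [0, 1].
#' @param jitter_px Gaussian sd (px) applied to re-added centers.
#' @return `cec_correction_policy`.
#' @export
correction_policy <- function(p_fix_miss = 1, p_fix_spurious = 1,
                              jitter_px = 0) {
  stopifnot(p_fix_miss >= 0, p_fix_miss <= 1, p_fix_spurious >= 0,
            p_fix_spurious <= 1, jitter_px >= 0)
  structure(list(p_fix_miss = p_fix_miss, p_fix_spurious = p_fix_spurious,
                 jitter_px = jitter_px), class = "cec_correction_policy")
}

#' Simulate manual correction of one pseudo-labeled image
#'
#' Matches the pseudo-labels one-to-one to the true centers within
#' `match_radius_px`; matched predictions are kept at their predicted
#' positions, misses and spurious detections are fixed according to the
#' policy. Uses the caller's RNG state (seed around it for reproducibility).
#'
#' @param pseudo,truth [annotated_image()] records for the same image id.
#' @param policy A [correction_policy()].
#' @param match_radius_px Matching radius in pixels.
#' @return An [annotated_image()] with `source = "model_corrected"`.
#' @export
simulate_correction <- function(pseudo, truth, policy = correction_policy(),
                                match_radius_px = 10) {
  if (pseudo$image_id != truth$image_id) {
    stop("image id mismatch: ", pseudo$image_id, " vs ", truth$image_id)
  }
  mr <- match_points(pseudo$centers, truth$centers, match_radius_px)
  keep_pred <- pseudo$centers[mr$pairs$pred_idx, , drop = FALSE]
  fp_idx <- setdiff(seq_len(nrow(pseudo$centers)), mr$pairs$pred_idx)
  fn_idx <- setdiff(seq_len(nrow(truth$centers)), mr$pairs$ref_idx)
  kept_fp <- pseudo$centers[fp_idx[runif(length(fp_idx)) >= policy$p_fix_spurious],
                            , drop = FALSE]
  added_fn <- truth$centers[fn_idx[runif(length(fn_idx)) < policy$p_fix_miss],
                            , drop = FALSE]
  if (nrow(added_fn) > 0 && policy$jitter_px > 0) {
    added_fn$x <- added_fn$x + rnorm(nrow(added_fn), 0, policy$jitter_px)
    added_fn$y <- added_fn$y + rnorm(nrow(added_fn), 0, policy$jitter_px)
    if (!is.null(truth$pixels)) {
      added_fn$x <- clamp(added_fn$x, 0, ncol(truth$pixels) - 1)
      added_fn$y <- clamp(added_fn$y, 0, nrow(truth$pixels) - 1)
    }
  }
  centers <- rbind(keep_pred, kept_fp, added_fn)
  annotated_image(pseudo$image_id, pixels = pseudo$pixels, centers = centers,
                  source = "model_corrected", um_per_px = pseudo$um_per_px)
}

#' Two-stage semi-supervised training workflow
#'
#' Stage 1 ("initial model"): split the labeled pool into train/validation
#' (proportions 402:121 as in the source workflow), rasterize the center
#' annotations into disk targets, augment the training half with `x2_flip`,
#' train, and keep the epoch with minimal validation loss. Stage 2 ("cell
#' count model"): pseudo-label the unlabeled pool with the initial model,
#' apply the (simulated) manual correction, merge with the labeled pool,
#' re-split at proportions 2341:757, augment with `x4_flip`, train, select
#' the epoch again. Both models are evaluated on the held-out test pool
#' (one-to-one matching, macro precision/recall/F, per-image density
#' correlation).
#'
#' @param labeled,unlabeled,test Disjoint lists of [annotated_image()] at
#'   working resolution with ground-truth centers (the unlabeled pool's truth
#'   is used only by the simulated correction; the test pool's only for
#'   evaluation).
#' @param model_cfg A [unet_config()].
#' @param train_cfg1,train_cfg2 [train_config()] for the two stages.
#' @param detect_cfg A [detection_config()].
#' @param policy A [correction_policy()].
#' @param disk_radius_px Label disk radius at working resolution.
#' @param match_radius_px Matching radius for correction and evaluation.
#' @param bootstrap_reps Bootstrap resamples for the metric CIs.
#' @param seed Master seed for splits, initialization, and correction.
#' @return `cec_semisup_result`: per-stage `model`, `training`,
#'   `selected_epoch`, `metrics`, `density` (correlation + per-image
#'   densities), plus the stage-2 label sets and the configuration.
#' @export
run_semi_supervised <- function(labeled, unlabeled, test,
                                model_cfg = unet_config(depth = 2L, base_channels = 8L),
                                train_cfg1 = train_config(),
                                train_cfg2 = train_cfg1,
                                detect_cfg = detection_config(),
                                policy = correction_policy(),
                                disk_radius_px = 3L,
                                match_radius_px = 10,
                                bootstrap_reps = 2000L,
                                seed = 1L) {
  stopifnot(length(labeled) > 0, length(test) > 0)
  ids <- function(z) vapply(z, `[[`, character(1), "image_id")
  if (anyDuplicated(c(ids(labeled), ids(unlabeled), ids(test)))) {
    stop("labeled, unlabeled, and test pools must be disjoint")
  }

  # --- stage 1: supervised on the labeled pool --------------------------
  n_tr1 <- round(length(labeled) * 402 / (402 + 121))
  sp1 <- make_split(seq_along(labeled),
                    c(n_tr1, length(labeled) - n_tr1, 0), seed = seed)
  train1 <- augment(labeled[as.integer(sp1$train)], "x2_flip")
  val1 <- labeled[as.integer(sp1$val)]
  net <- build_unet(model_cfg, seed = seed)
  tr1 <- train_unet(net, make_samples(train1, disk_radius_px),
                    make_samples(val1, disk_radius_px), train_cfg1)
  ep1 <- select_epoch(tr1)
  initial <- model_at_epoch(tr1, ep1)

  # --- stage 2: pseudo-label, correct, merge, retrain -------------------
  if (length(unlabeled) == 0) {
    warning("empty unlabeled pool: stage 2 degenerates to supervised training")
    merged <- labeled
  } else {
    pseudo <- pseudo_label(initial, unlabeled, detect_cfg)
    corrected <- with_seed(seed + 1L, {
      lapply(seq_along(unlabeled), function(i) {
        simulate_correction(pseudo[[i]], unlabeled[[i]], policy,
                            match_radius_px)
      })
    })
    merged <- c(labeled, corrected)
  }
  n_tr2 <- round(length(merged) * 2341 / (2341 + 757))
  sp2 <- make_split(seq_along(merged),
                    c(n_tr2, length(merged) - n_tr2, 0), seed = seed + 2L)
  train2 <- augment(merged[as.integer(sp2$train)], "x4_flip")
  val2 <- merged[as.integer(sp2$val)]
  net2 <- build_unet(model_cfg, seed = seed)
  tr2 <- train_unet(net2, make_samples(train2, disk_radius_px),
                    make_samples(val2, disk_radius_px), train_cfg2)
  ep2 <- select_epoch(tr2)
  cellcount <- model_at_epoch(tr2, ep2)

  # --- evaluation on the held-out test pool -----------------------------
  eval_model <- function(model) {
    dets <- lapply(test, function(r) {
      extract_centers(predict_probs(model, r$pixels, r$image_id), detect_cfg)
    })
    matches <- lapply(seq_along(test), function(i) {
      match_points(dets[[i]]$centers, test[[i]]$centers, match_radius_px)
    })
    names(matches) <- ids(test)
    geoms <- lapply(test, function(r) {
      field_geometry(ncol(r$pixels), nrow(r$pixels), r$um_per_px)
    })
    pred_d <- vapply(seq_along(test), function(i) {
      density_from_centers(dets[[i]], geoms[[i]])$density_cells_per_mm2
    }, numeric(1))
    true_d <- vapply(seq_along(test), function(i) {
      nrow(test[[i]]$centers) / geoms[[i]]$field_area_mm2
    }, numeric(1))
    # tiny smoke runs can yield degenerate (constant) predicted densities;
    # report an NA correlation rather than aborting the whole pipeline
    corr <- tryCatch(density_correlation(pred_d, true_d), error = function(e) {
      structure(list(pearson_r = NA_real_, p_value = NA_real_,
                     n = length(pred_d)), class = "cec_density_correlation")
    })
    list(metrics = compute_metrics(matches, bootstrap_reps, seed = seed),
         density = list(correlation = corr, predicted = pred_d, true = true_d),
         detections = dets)
  }
  ev1 <- eval_model(initial)
  ev2 <- eval_model(cellcount)

  structure(list(
    initial = list(model = initial, training = tr1, selected_epoch = ep1,
                   metrics = ev1$metrics, density = ev1$density),
    cellcount = list(model = cellcount, training = tr2, selected_epoch = ep2,
                     metrics = ev2$metrics, density = ev2$density),
    stage2_labels = if (length(unlabeled) > 0) merged[-seq_along(labeled)]
                    else list(),
    config = list(model_cfg = model_cfg, train_cfg1 = train_cfg1,
                  train_cfg2 = train_cfg2, detect_cfg = detect_cfg,
                  policy = policy, disk_radius_px = disk_radius_px,
                  match_radius_px = match_radius_px, seed = seed)
  ), class = "cec_semisup_result")
}
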