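# A small shared fixture: 10 sparse (subconfluent) scenes plus a
# depth-2/base-4 net trained to memorize them (20 epochs x 10 steps = 200).
overfit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pool <- lapply(1:10, function(i) {
        smp <- generate_scene(scene_spec(256, 256, target_density = 150,
                                         seed = 400 + i))
        preprocess_image(
          annotated_image(sprintf("ov%03d", i), pixels = smp$image,
                          centers = smp$centers),
          preprocess_config())
      })
      samples <- cecounter:::make_samples(pool, disk_radius_px = 2L)
      net <- build_unet(unet_config(2, 4), seed = 5)
      tr <- train_unet(net, samples, samples,
                       train_config(max_epochs = 20, lr = 3e-3, seed = 5))
      cache <<- list(pool = pool, samples = samples, training = tr,
                     model = model_at_epoch(tr, 20))
    }
    cache
  }
})

test_that("a depth-2/base-4 net memorizes a 10-image fixture within 200 steps", {
  fx <- overfit_fixture()
  expect_lt(fx$training$curve$train_loss[20], 0.05)
})

test_that("identical train and validation sets give identical loss curves", {
  pool <- tiny_pool(4, seed_base = 500)
  samples <- cecounter:::make_samples(pool, 2L)
  net <- build_unet(unet_config(2, 4), seed = 1)
  tr <- train_unet(net, samples, samples, train_config(max_epochs = 3, seed = 2))
  expect_equal(tr$curve$train_loss, tr$curve$val_loss, tolerance = 1e-9)
})

test_that("training is reproducible under a fixed seed", {
  pool <- tiny_pool(4, seed_base = 510)
  samples <- cecounter:::make_samples(pool, 2L)
  net <- build_unet(unet_config(2, 4), seed = 1)
  tr1 <- train_unet(net, samples[1:3], samples[4], train_config(max_epochs = 2, seed = 9))
  tr2 <- train_unet(net, samples[1:3], samples[4], train_config(max_epochs = 2, seed = 9))
  expect_identical(tr1$curve, tr2$curve)
  expect_identical(tr1$epoch_weights[[2]], tr2$epoch_weights[[2]])
})

test_that("select_epoch is argmin with the earlier-epoch tie rule", {
  expect_equal(select_epoch(c(0.50, 0.30, 0.35)), 2)
  expect_equal(select_epoch(c(0.4, 0.3, 0.3)), 2)
  expect_equal(select_epoch(rev(seq_len(30)) / 30), 30)
  expect_error(select_epoch(numeric(0)), "empty")
  curve <- data.frame(epoch = 1:3, train_loss = c(1, 2, 3),
                      val_loss = c(0.5, 0.3, 0.35))
  expect_equal(select_epoch(curve), 2)
})

test_that("pseudo-labeling is deterministic and silent on blank images", {
  fx <- overfit_fixture()
  blank <- annotated_image("blank", matrix(127, 16, 16))
  out <- pseudo_label(fx$model, list(blank, fx$pool[[1]]))
  expect_equal(nrow(out[[1]]$centers), 0)
  expect_equal(out[[2]]$source, "model")
  expect_gt(nrow(out[[2]]$centers), 0)
  again <- pseudo_label(fx$model, list(blank, fx$pool[[1]]))
  expect_identical(out[[2]]$centers, again[[2]]$centers)
})

test_that("simulated correction obeys its limiting policies", {
  truth <- annotated_image("i", centers = data.frame(x = c(10, 40), y = c(10, 40)))
  # 1 TP (near first truth), 1 FP (far from both): second truth is a miss
  pseudo <- annotated_image("i", centers = data.frame(x = c(11, 80), y = c(10, 80)),
                            source = "model")
  perfect <- simulate_correction(pseudo, truth, correction_policy(1, 1, 0),
                                 match_radius_px = 5)
  expect_equal(nrow(perfect$centers), 2)
  expect_equal(perfect$source, "model_corrected")
  # kept at the matched predicted position, missed truth added exactly
  expect_true(any(perfect$centers$x == 11 & perfect$centers$y == 10))
  expect_true(any(perfect$centers$x == 40 & perfect$centers$y == 40))
  expect_false(any(perfect$centers$x == 80))

  none <- simulate_correction(pseudo, truth, correction_policy(0, 0, 0),
                              match_radius_px = 5)
  expect_equal(none$centers[order(none$centers$x), ],
               pseudo$centers[order(pseudo$centers$x), ],
               ignore_attr = TRUE)

  other <- annotated_image("j", centers = truth$centers)
  expect_error(simulate_correction(pseudo, other, correction_policy()),
               "mismatch")
})

test_that("the two-stage workflow reduces to supervised truth under perfect correction", {
  labeled <- tiny_pool(8, seed_base = 600)
  unlabeled <- tiny_pool(6, seed_base = 700)
  test <- tiny_pool(4, seed_base = 800)
  res <- run_semi_supervised(
    labeled, unlabeled, test,
    model_cfg = unet_config(2, 4),
    train_cfg1 = train_config(max_epochs = 4, seed = 1),
    train_cfg2 = train_config(max_epochs = 2, seed = 2),
    policy = correction_policy(1, 1, 0),
    disk_radius_px = 2L, match_radius_px = 6, bootstrap_reps = 100,
    seed = 3
  )
  # perfect correction: every stage-2 label set has exactly one point per
  # true center, each within the match radius of the truth
  expect_length(res$stage2_labels, 6)
  for (i in seq_along(unlabeled)) {
    lab <- res$stage2_labels[[i]]
    expect_equal(lab$image_id, unlabeled[[i]]$image_id)
    expect_equal(nrow(lab$centers), nrow(unlabeled[[i]]$centers))
    m <- match_points(lab$centers, unlabeled[[i]]$centers, 6)
    expect_equal(m$n_fp + m$n_fn, 0)
  }
  expect_equal(res$initial$selected_epoch,
               which.min(res$initial$training$curve$val_loss))
  expect_s3_class(res$cellcount$metrics, "cec_metrics_report")
  expect_error(run_semi_supervised(labeled, unlabeled, labeled), "disjoint")
})

test_that("non-finite losses abort with a diagnostic", {
  # softmax max-subtraction and probability clamping keep any finite input
  # finite, so inject the failure at the data level
  pool <- tiny_pool(2, seed_base = 900)
  samples <- cecounter:::make_samples(pool, 2L)
  samples[[1]]$x[3, 3] <- NaN
  net <- build_unet(unet_config(2, 4), seed = 1)
  expect_error(train_unet(net, samples, samples,
                          train_config(max_epochs = 2, seed = 1)),
               "non-finite")
})
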