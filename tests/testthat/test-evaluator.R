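test_that("matching basics: identity, mixed instance, nearest-wins", {
  pts <- data.frame(x = c(1, 5, 9.5), y = c(2, 2, 8))
  m <- match_points(pts, pts, 4)
  expect_equal(m$n_tp, 3); expect_equal(m$n_fp, 0); expect_equal(m$n_fn, 0)
  expect_true(all(m$pairs$distance == 0))

  m2 <- match_points(data.frame(x = c(12, 90), y = c(11, 90)),
                     data.frame(x = c(10, 50), y = c(10, 50)), 8)
  expect_equal(c(m2$n_tp, m2$n_fp, m2$n_fn), c(1, 1, 1))
  # exhaustive enumeration on the 2x2 instance finds the same cardinality
  oracle <- exhaustive_match_oracle(cbind(c(12, 90), c(11, 90)),
                                    cbind(c(10, 50), c(10, 50)), 8)
  expect_equal(m2$n_tp, oracle$n_tp)

  m3 <- match_points(data.frame(x = 0, y = 0),
                     data.frame(x = c(0, 0), y = c(3, 4)), 5)
  expect_equal(m3$n_tp, 1)
  expect_equal(m3$pairs$ref_idx, 1)  # the nearer reference at (0,3)
  expect_equal(m3$n_fn, 1)
})

test_that("swapping prediction and reference swaps FP and FN", {
  set.seed(31)
  a <- data.frame(x = runif(7, 0, 50), y = runif(7, 0, 50))
  b <- data.frame(x = runif(5, 0, 50), y = runif(5, 0, 50))
  m1 <- match_points(a, b, 10)
  m2 <- match_points(b, a, 10)
  expect_equal(m1$n_tp, m2$n_tp)
  expect_equal(m1$n_fp, m2$n_fn)
  expect_equal(m1$n_fn, m2$n_fp)
})

test_that("greedy matching equals exhaustive optimal matching on unambiguous instances", {
  # references spaced > 2 x radius apart, predictions jittered well inside
  # the radius: the optimal assignment is then unique and greedy must find it
  set.seed(123)
  radius <- 5
  for (rep in 1:40) {
    nr <- sample(2:6, 1)
    repeat {
      ref <- data.frame(x = runif(nr, 0, 100), y = runif(nr, 0, 100))
      d <- as.matrix(dist(ref)); diag(d) <- Inf
      if (min(d) > 2.5 * radius) break
    }
    keep <- runif(nr) < 0.8
    pred <- ref[keep, , drop = FALSE]
    if (nrow(pred) > 0) {
      pred$x <- pred$x + runif(nrow(pred), -1.5, 1.5)
      pred$y <- pred$y + runif(nrow(pred), -1.5, 1.5)
    }
    n_extra <- sample(0:2, 1)  # spurious detections far from any reference
    if (n_extra > 0) {
      pred <- rbind(pred, data.frame(x = runif(n_extra, 150, 200),
                                     y = runif(n_extra, 150, 200)))
    }
    m <- match_points(pred, ref, radius)
    o <- exhaustive_match_oracle(cbind(pred$x, pred$y), cbind(ref$x, ref$y),
                                 radius)
    expect_equal(m$n_tp, o$n_tp)
    expect_equal(sum(m$pairs$distance), o$cost, tolerance = 1e-9)
  }
})

test_that("per-image metrics follow the stated conventions", {
  mk <- function(tp, fp, fn) {
    structure(list(pairs = data.frame(), n_tp = tp, n_fp = fp, n_fn = fn,
                   match_radius_px = 10), class = "cec_match_result")
  }
  r1 <- compute_metrics(list(mk(1, 1, 1)), bootstrap_reps = 50)
  expect_equal(r1$precision, 0.5)
  expect_equal(r1$recall, 0.5)
  expect_equal(r1$f_value, 0.5)

  # macro mean of per-image F values 1.0 and 0.5
  r2 <- compute_metrics(list(mk(5, 0, 0), mk(1, 1, 1)), bootstrap_reps = 50)
  expect_equal(r2$f_value, 0.75)

  r3 <- compute_metrics(list(mk(0, 0, 10)), bootstrap_reps = 50)
  expect_equal(c(r3$precision, r3$recall, r3$f_value), c(0, 0, 0))

  r4 <- compute_metrics(list(mk(0, 0, 0)), bootstrap_reps = 50)
  expect_equal(r4$f_value, 1)
  expect_true(r4$per_image$both_empty[1])

  # macro F is generally not the harmonic mean of macro P and macro R
  r5 <- compute_metrics(list(mk(9, 1, 0), mk(1, 0, 9)), bootstrap_reps = 50)
  hm <- 2 * r5$precision * r5$recall / (r5$precision + r5$recall)
  expect_gt(abs(r5$f_value - hm), 0.01)
})

test_that("bootstrap CIs bracket the point estimate and tighten with n", {
  mk_img <- function(seed) {
    set.seed(seed)
    tp <- rbinom(1, 40, 0.9)
    structure(list(pairs = data.frame(), n_tp = tp,
                   n_fp = rbinom(1, 8, 0.5), n_fn = 40 - tp,
                   match_radius_px = 10), class = "cec_match_result")
  }
  small <- compute_metrics(lapply(1:20, mk_img), bootstrap_reps = 500, seed = 2)
  large <- compute_metrics(lapply(1:80, mk_img), bootstrap_reps = 500, seed = 2)
  for (m in c("precision", "recall", "f_value")) {
    expect_lte(small$ci95[[m]][1], small[[m]])
    expect_gte(small$ci95[[m]][2], small[[m]])
    expect_lt(diff(large$ci95[[m]]), diff(small$ci95[[m]]))
  }
  # seeded bootstrap is reproducible
  again <- compute_metrics(lapply(1:20, mk_img), bootstrap_reps = 500, seed = 2)
  expect_identical(small$ci95, again$ci95)
})

test_that("density correlation handles exact and degenerate cases", {
  v <- c(1200, 1500, 2100, 900, 1800)
  expect_equal(density_correlation(v, v)$pearson_r, 1)
  expect_equal(density_correlation(v, -v + 2 * mean(v))$pearson_r, -1)
  r <- density_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(r$pearson_r, 1)
  expect_equal(r$n, 4)
  # p-value matches the t transform computed by hand
  set.seed(8)
  a <- rnorm(12); b <- a + rnorm(12)
  dc <- density_correlation(a, b)
  tstat <- dc$pearson_r * sqrt((dc$n - 2) / (1 - dc$pearson_r^2))
  expect_equal(dc$p_value, 2 * stats::pt(-abs(tstat), dc$n - 2),
               tolerance = 1e-12)
  expect_error(density_correlation(rep(1, 5), v), "variance")
  expect_error(density_correlation(1:2, 1:2))
})
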