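test_that("scenes are bit-identical under a fixed seed and grow with density", {
  spec <- scene_spec(96, 96, "middle", seed = 11)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$centers, b$centers)

  lo <- generate_scene(scene_spec(128, 128, "low", seed = 3))
  hi <- generate_scene(scene_spec(128, 128, "high", seed = 3))
  expect_lt(nrow(lo$centers), nrow(hi$centers))
  # centers inside bounds, spacing contract honored
  for (s in list(lo, hi)) {
    expect_true(all(s$centers$x >= 0 & s$centers$x <= 127))
    expect_true(all(s$centers$y >= 0 & s$centers$y <= 127))
    d <- as.matrix(dist(s$centers)); diag(d) <- Inf
    n <- nrow(s$centers)
    d_min <- min(0.8 * 2 * s$spec$cell_radius_mean_um / s$spec$um_per_px,
                 0.8 * 2 * sqrt(128 * 128 / (n * pi)))
    expect_gte(min(d), d_min - 1e-9)
  }
})

test_that("center counts follow the Poisson law of the target density", {
  # field engineered to ~0.5 mm^2 -> Poisson mean ~1000 at 2000 cells/mm^2
  px <- round(sqrt(0.5) / (0.645 / 1000))  # 1097 px sides
  area <- px^2 * (0.645 / 1000)^2
  mu <- 2000 * area
  counts <- vapply(1:100, function(s) {
    nrow(cecounter:::place_centers(
      scene_spec(px, px, target_density = 2000, seed = 1000 + s)))
  }, numeric(1))
  se <- sqrt(mu / 100)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # realized density within 5% of target when averaged over many seeds
  dens <- counts / area
  expect_lt(abs(mean(dens) - 2000) / 2000, 0.05)
})

test_that("rendered boundaries are darker than their two adjacent interiors", {
  smp <- generate_scene(scene_spec(128, 128, "low", seed = 21))
  ctr <- smp$centers
  h <- nrow(smp$image); w <- ncol(smp$image)
  # independent nearest-two computation in plain R
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  n <- nrow(ctr)
  d <- array(0, c(h, w, n))
  for (i in seq_len(n)) {
    d[, , i] <- sqrt((xs - ctr$x[i])^2 + (ys - ctr$y[i])^2)
  }
  idx1 <- apply(d, c(1, 2), which.min)
  d_sorted <- apply(d, c(1, 2), function(v) sort(v)[1:2])
  gap <- d_sorted[2, , ] - d_sorted[1, , ]
  idx2 <- apply(d, c(1, 2), function(v) order(v)[2])
  interior <- gap >= 4
  boundary <- gap < 2
  int_mean <- vapply(seq_len(n), function(i) {
    mean(smp$image[interior & idx1 == i])
  }, numeric(1))
  bpix <- which(boundary, arr.ind = TRUE)
  for (k in seq_len(nrow(bpix))) {
    r <- bpix[k, 1]; c <- bpix[k, 2]
    ref <- mean(int_mean[c(idx1[r, c], idx2[r, c])], na.rm = TRUE)
    expect_lt(smp$image[r, c], ref)
  }
})

test_that("placement rejects unsatisfiable densities", {
  # packing fraction > 0.9: tiny field, huge density, fat exclusion radius
  spec <- scene_spec(64, 64, target_density = 4000, cell_radius_mean_um = 20,
                     seed = 1)
  expect_error(generate_scene(spec), "infeasible")
})

test_that("generate_dataset writes a reproducible manifest with regime mix", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(10, c(low = 0.5, high = 0.5), base_seed = 5,
                         out_dir = d1, width_px = 64, height_px = 64)
  expect_equal(nrow(m1), 10)
  expect_equal(as.integer(table(m1$regime)[c("low", "high")]), c(5L, 5L))
  expect_true(all(file.exists(m1$path)))
  expect_true(all(file.exists(m1$annotation_path)))
  m2 <- generate_dataset(10, c(low = 0.5, high = 0.5), base_seed = 5,
                         out_dir = d2, width_px = 64, height_px = 64)
  expect_identical(m1[, c("image_id", "regime", "true_density_cells_per_mm2",
                          "seed")],
                   m2[, c("image_id", "regime", "true_density_cells_per_mm2",
                          "seed")])
  # identical bytes for the first image of both runs
  expect_identical(readBin(m1$path[1], "raw", 1e6),
                   readBin(m2$path[1], "raw", 1e6))
  expect_error(generate_dataset(10, c(low = 0.5, high = 0.5), base_seed = 5,
                                out_dir = d1, width_px = 64, height_px = 64),
               "overwrite")
})

test_that("the labeled-pool-sized dataset materializes completely", {
  d <- withr::local_tempdir()
  m <- generate_dataset(606, c(low = 1/3, middle = 1/3, high = 1/3),
                        base_seed = 9, out_dir = d,
                        width_px = 48, height_px = 48)
  expect_equal(nrow(m), 606)
  expect_equal(sum(file.exists(m$path)), 606)
  expect_equal(as.integer(table(m$regime)[c("low", "middle", "high")]),
               c(202L, 202L, 202L))
})
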