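test_that("density follows directly from counts and field geometry", {
  # 500 x 1000 px at 1 um/px -> exactly 0.5 mm^2
  geom <- field_geometry(500, 1000, 1)
  expect_equal(geom$field_area_mm2, 0.5)
  det0 <- list(image_id = "e", centers = data.frame(x = numeric(0),
                                                    y = numeric(0)))
  expect_equal(density_from_centers(det0, geom)$density_cells_per_mm2, 0)
  det <- list(image_id = "f",
              centers = data.frame(x = runif(500, 0, 499),
                                   y = runif(500, 0, 999)))
  expect_equal(density_from_centers(det, geom)$density_cells_per_mm2, 1000)
  # halving the pixel pitch quarters the area, quadrupling the density
  geom2 <- field_geometry(500, 1000, 0.5)
  expect_equal(density_from_centers(det, geom2)$density_cells_per_mm2, 4000)
})

test_that("total cells scale linearly in density and growth area", {
  est <- function(d) structure(list(image_id = "x", n_centers = NA,
                                    density_cells_per_mm2 = d),
                               class = "cec_density_estimate")
  tot <- total_cells(list(est(1000)), vessel_spec("well_6"))
  expect_equal(tot$total_cells, 9.6e5)  # 9.6 cm^2 = 960 mm^2
  tot2 <- total_cells(list(est(800), est(1200)), vessel_spec("well_6"))
  expect_equal(tot2$mean_density, 1000)
  expect_equal(tot2$n_fields, 2)
  # linear in area
  expect_equal(total_cells(list(est(1000)), vessel_spec("T75"))$total_cells,
               total_cells(list(est(1000)), vessel_spec("T25"))$total_cells * 3)
  # linear in density
  expect_equal(total_cells(list(est(2000)), vessel_spec("T25"))$total_cells,
               2 * total_cells(list(est(1000)), vessel_spec("T25"))$total_cells)
  expect_error(total_cells(list(), vessel_spec("well_6")), "at least one")
  expect_equal(vessel_spec("custom", growth_area_cm2 = 12.5)$growth_area_cm2,
               12.5)
  expect_error(vessel_spec("custom"), "growth_area_cm2")
})

test_that("five sampled fields estimate a vessel total within ~10% on average", {
  # Monte-Carlo with perfect detection: the only error is Poisson field
  # sampling, exactly what the generator's drawn counts emulate.
  spec0 <- scene_spec(256, 256, "middle", seed = 1)
  area <- 256^2 * (0.645 / 1000)^2
  vessel <- vessel_spec("well_6")
  true_total <- 1500 * vessel$growth_area_cm2 * 100
  rel_err <- vapply(1:100, function(rep) {
    dens <- vapply(1:5, function(k) {
      s <- scene_spec(256, 256, "middle", seed = 5000 + rep * 10 + k)
      nrow(cecounter:::place_centers(s)) / area
    }, numeric(1))
    est <- mean(dens) * vessel$growth_area_cm2 * 100
    abs(est - true_total) / true_total
  }, numeric(1))
  expect_lt(mean(rel_err), 0.10)
})

test_that("a synthetic passage series tracks hemocytometer-style totals", {
  # passages grow into larger vessels at a 1:3 split; totals must track the
  # truth within the field-sampling error band at every passage
  areas <- c(9.6, 9.6 * 3, 9.6 * 9, 9.6 * 27)
  dens_true <- c(1200, 1500, 1800, 2200)
  area_field <- 256^2 * (0.645 / 1000)^2
  for (p in 1:4) {
    vessel <- vessel_spec("custom", growth_area_cm2 = areas[p])
    ests <- lapply(1:5, function(k) {
      s <- scene_spec(256, 256, target_density = dens_true[p],
                      seed = 900 + p * 20 + k)
      n <- nrow(cecounter:::place_centers(s))
      structure(list(image_id = paste0("p", p, "f", k), n_centers = n,
                     density_cells_per_mm2 = n / area_field),
                class = "cec_density_estimate")
    })
    tot <- total_cells(ests, vessel, passage = p)
    hemo <- dens_true[p] * areas[p] * 100
    n_cells_sampled <- sum(vapply(ests, `[[`, numeric(1), "n_centers"))
    band <- 4 / sqrt(n_cells_sampled)  # ~4 sigma Poisson band
    expect_lt(abs(tot$total_cells - hemo) / hemo, band)
    expect_equal(tot$passage, p)
  }
})
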