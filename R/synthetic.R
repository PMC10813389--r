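#' Synthetic phase-contrast monolayer scenes
#'
#' Cultured corneal endothelial monolayers in phase contrast look like a
#' mosaic of polygonal cells: dark borders, brighter interiors, a faint halo
#' along the borders. The generator emulates that appearance as a Voronoi
#' tessellation seeded at known cell centers, so every downstream stage
#' (training, detection, evaluation, density quantification) can be exercised
#' against exact ground truth without microscope data.
#'
#' `scene_spec()` describes one field of view. The number of cells is drawn
#' from a Poisson law with mean `target_density` times the field area, so
#' repeated fields show realistic sampling error; centers are placed with a
#' guaranteed minimum spacing of 0.8 x the mean cell diameter.
#'
#' @param width_px,height_px Field size in pixels.
#' @param density_regime One of `"low"`, `"middle"`, `"high"`; supplies the
#'   default `target_density` (500, 1500, 3000 cells/mm^2).
#' @param target_density Mean cell density in cells/mm^2; overrides the
#'   regime default when given.
#' @param um_per_px Pixel pitch in micrometres per pixel.
#' @param cell_radius_mean_um Mean cell radius in micrometres. Default is the
#'   radius of a disk occupying the mean area per cell at `target_density`.
#' @param cell_radius_cv Coefficient of variation of per-cell appearance
#'   (drives per-cell brightness variability in the rendering).
#' @param halo_strength Phase-halo intensity in `[0, 1]`.
#' @param noise_sigma Additive Gaussian noise, in 8-bit gray levels.
#' @param seed Integer seed; fixes all randomness of the scene.
#' @return An object of class `cec_scene_spec`.
#' @export
scene_spec <- function(width_px = 256L, height_px = 256L,
                       density_regime = c("middle", "low", "high"),
                       target_density = NULL,
                       um_per_px = 0.645,
                       cell_radius_mean_um = NULL,
                       cell_radius_cv = 0.15,
                       halo_strength = 0.3,
                       noise_sigma = 6,
                       seed = 1L) {
  density_regime <- match.arg(density_regime)
  if (is.null(target_density)) {
    target_density <- c(low = 500, middle = 1500, high = 3000)[[density_regime]]
  }
  if (is.null(cell_radius_mean_um)) {
    # radius of a disk with the mean per-cell area (1e6 um^2/mm^2 / density)
    cell_radius_mean_um <- sqrt(1e6 / (pi * target_density))
  }
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    target_density = target_density, density_regime = density_regime,
    um_per_px = um_per_px, cell_radius_mean_um = cell_radius_mean_um,
    cell_radius_cv = cell_radius_cv, halo_strength = halo_strength,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  )
  class(spec) <- "cec_scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(
    spec$width_px > 0, spec$height_px > 0,
    spec$target_density > 0, spec$um_per_px > 0,
    spec$cell_radius_mean_um > 0, spec$cell_radius_cv >= 0,
    spec$halo_strength >= 0, spec$halo_strength <= 1,
    spec$noise_sigma >= 0
  )
  invisible(spec)
}

field_area_mm2_of <- function(spec) {
  spec$width_px * spec$height_px * (spec$um_per_px / 1000)^2
}

# Seeded center placement. A pure rejection (dart-throwing) scheme jams near
# packing fraction 0.55, below what a confluent monolayer needs, so centers
# are placed on a jittered hexagonal lattice instead: pick a random subset of
# lattice sites, then jitter each uniformly within a disk whose radius keeps
# the pairwise minimum distance at d_min by construction. Placement fails
# exactly when the requested spacing exceeds hexagonal close packing.
place_centers <- function(spec) {
  with_seed(spec$seed, {
    area_mm2 <- field_area_mm2_of(spec)
    mu <- spec$target_density * area_mm2
    n <- rpois(1L, mu)
    if (n == 0L && mu >= 1) n <- 1L
    if (n == 0L) {
      return(data.frame(x = numeric(0), y = numeric(0)))
    }
    # Infeasibility is judged on the nominal configuration (mean count x
    # spec'd radius), so a spec either always works or always errors.
    d_spec <- 0.8 * 2 * spec$cell_radius_mean_um / spec$um_per_px  # px
    packing <- mu * pi * (d_spec / 2)^2 / (spec$width_px * spec$height_px)
    if (packing > 0.9) {
      stop("infeasible placement: packing fraction ", round(packing, 3),
           " > 0.9 for target_density ", spec$target_density)
    }
    # A crowded Poisson draw makes the realized mean cell smaller than the
    # nominal one; the spacing floor follows the realized mean diameter.
    d_real <- 0.8 * 2 *
      sqrt(spec$width_px * spec$height_px / (n * pi))
    d_min <- min(d_spec, d_real)
    # Shrink the lattice spacing (never below d_min) until edge truncation
    # still leaves at least n sites.
    s_max <- sqrt(2 * spec$width_px * spec$height_px / (sqrt(3) * n))
    s <- max(d_min, 0.94 * s_max)
    repeat {
      row_h <- s * sqrt(3) / 2
      # every row/column whose center lies inside [0, dim-1] counts
      nrow_l <- floor((spec$height_px - 1) / row_h + 0.5)
      xs <- ys <- numeric(0)
      for (i in seq_len(nrow_l)) {
        off <- if (i %% 2 == 0) s / 2 else 0
        cx <- seq(off + s / 2, spec$width_px - 1, by = s)
        xs <- c(xs, cx)
        ys <- c(ys, rep((i - 0.5) * row_h, length(cx)))
      }
      if (length(xs) >= n) break
      if (s <= d_min) {
        stop("infeasible placement: lattice provides ", length(xs),
             " sites for ", n, " cells at the minimum spacing")
      }
      s <- max(d_min, 0.96 * s)
    }
    keep <- sample.int(length(xs), n)
    xs <- xs[keep]; ys <- ys[keep]
    jr <- (s - d_min) / 2
    if (jr > 0) {
      ang <- runif(n, 0, 2 * pi)
      rad <- jr * sqrt(runif(n))
      xs <- xs + rad * cos(ang)
      ys <- ys + rad * sin(ang)
    }
    data.frame(x = clamp(xs, 0, spec$width_px - 1),
               y = clamp(ys, 0, spec$height_px - 1))
  })
}

#' Render one synthetic scene
#'
#' Renders the Voronoi mosaic implied by the placed centers: interiors shade
#' from bright at the seed to dimmer at the ridge, borders (ridge pixels)
#' drop to 30% of the local interior intensity over a ~2 px band, an optional
#' halo brightens the band just inside the border, and i.i.d. Gaussian noise
#' is added before quantizing to 8-bit gray.
#'
#' @param spec A [scene_spec()].
#' @return `cec_synthetic_sample`: list with `image` (H x W matrix, values
#'   0-255), `centers` (data frame `x`, `y`, 0-based pixel coordinates), and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  centers <- place_centers(spec)
  H <- spec$height_px; W <- spec$width_px
  img <- with_seed(spec$seed + 1L, {
    if (nrow(centers) == 0L) {
      matrix(140, H, W) + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    } else {
      nn <- cpp_nearest2(centers_matrix(centers), H, W)
      shade <- nn$d1 / (nn$d1 + pmax(nn$d2, 1e-9))        # 0 at seed, 0.5 at ridge
      base <- 200 - 240 * shade                           # 200 -> 80
      fac <- clamp(rnorm(nrow(centers), 1, spec$cell_radius_cv), 0.7, 1.3)
      base <- base * matrix(fac[nn$index], H, W)
      gap <- nn$d2 - nn$d1
      boundary <- gap < 2
      halo <- !boundary & gap < 4
      base[boundary] <- 0.3 * base[boundary]
      base[halo] <- base[halo] * (1 + 0.5 * spec$halo_strength)
      base + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    }
  })
  img <- round(clamp(img, 0, 255))
  structure(list(image = img, centers = centers, spec = spec),
            class = "cec_synthetic_sample")
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` scenes as 8-bit grayscale PNGs with per-image center
#' annotation CSVs and a manifest. Regimes are allotted by largest-remainder
#' rounding of `regime_mix`; image `i` uses seed `base_seed + i - 1`.
#'
#' @param n_images Number of images to generate.
#' @param regime_mix Named fractions over `low`/`middle`/`high`; must sum to 1.
#' @param base_seed Integer; per-image seeds are derived from it.
#' @param out_dir Output directory (created if needed).
#' @param width_px,height_px,um_per_px,... Passed to [scene_spec()].
#' @param overwrite Refuse to overwrite an existing manifest unless `TRUE`.
#' @return The manifest data frame (invisibly written to
#'   `out_dir/manifest.csv`) with columns `image_id, path, annotation_path,
#'   regime, true_density_cells_per_mm2, seed`. The recorded density is the
#'   realized one (placed centers / field area) - the ground truth that
#'   downstream evaluation compares against.
#' @export
generate_dataset <- function(n_images, regime_mix = c(low = 1/3, middle = 1/3, high = 1/3),
                             base_seed = 1L, out_dir,
                             width_px = 256L, height_px = 256L,
                             um_per_px = 0.645, overwrite = FALSE, ...) {
  stopifnot(n_images > 0, abs(sum(regime_mix) - 1) < 1e-8)
  if (is.null(names(regime_mix)) ||
      !all(names(regime_mix) %in% c("low", "middle", "high"))) {
    stop("regime_mix must be named with low/middle/high")
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         "; pass overwrite = TRUE to replace it")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- largest_remainder(regime_mix * n_images)
  regimes <- rep(names(regime_mix), counts)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    seed_i <- as.integer(base_seed + i - 1L)
    spec <- scene_spec(width_px = width_px, height_px = height_px,
                       density_regime = regimes[i], um_per_px = um_per_px,
                       seed = seed_i, ...)
    smp <- generate_scene(spec)
    id <- sprintf("img%04d", i)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    ann_path <- file.path(out_dir, paste0(id, ".csv"))
    write_image(smp$image, img_path)
    save_annotations(list(annotated_image(id, centers = smp$centers,
                                          um_per_px = um_per_px)), ann_path)
    rows[[i]] <- data.frame(
      image_id = id, path = img_path, annotation_path = ann_path,
      regime = regimes[i],
      true_density_cells_per_mm2 = nrow(smp$centers) / field_area_mm2_of(spec),
      seed = seed_i, stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, manifest_path, row.names = FALSE)
  manifest
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}
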