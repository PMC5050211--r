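## Independent brute-force oracles. These deliberately use naive direct
## computation (loops, explicit padding, exhaustive enumeration) so that
## they share no code path with the package implementations they check.

## Exhaustive 3-class Otsu: direct between-class variance from class
## masses and means, scanning all split pairs in lexicographic order.
otsu3_brute <- function(counts, mids) {
  n <- length(counts)
  tot <- sum(counts)
  mu <- sum(counts * mids) / tot
  best <- -1; bi <- NA; bj <- NA
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      cls <- list(1:i, (i + 1):j, (j + 1):n)
      v <- 0
      for (c in cls) {
        w <- sum(counts[c]) / tot
        if (w > 0) {
          m <- sum(counts[c] * mids[c]) / sum(counts[c])
          v <- v + w * (m - mu)^2
        }
      }
      if (v > best + 1e-12 * (1 + abs(best))) { best <- v; bi <- i; bj <- j }
    }
  }
  list(i = bi, j = bj,
       t1 = (mids[bi] + mids[bi + 1]) / 2,
       t2 = (mids[bj] + mids[bj + 1]) / 2,
       bcv = best)
}

## Brute-force ball density: loop over every voxel of the mask, count
## centres within the radius of the point (and in bounds by construction).
density_brute <- function(mask_arr, spacing, p, r) {
  d <- dim(mask_arr)
  n_in <- 0L; n_fg <- 0L
  for (iz in 1:d[1]) for (iy in 1:d[2]) for (ix in 1:d[3]) {
    dz <- (iz - 0.5) * spacing - p[1]
    dy <- (iy - 0.5) * spacing - p[2]
    dx <- (ix - 0.5) * spacing - p[3]
    if (dz * dz + dy * dy + dx * dx <= r * r) {
      n_in <- n_in + 1L
      if (mask_arr[iz, iy, ix]) n_fg <- n_fg + 1L
    }
  }
  if (n_in == 0L) NA_real_ else n_fg / n_in
}

## Direct-summation box mean filter with mirror padding.
box_brute <- function(a, radius) {
  d <- dim(a)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- array(0, d)
  w <- (2 * radius + 1)^3
  for (iz in 1:d[1]) for (iy in 1:d[2]) for (ix in 1:d[3]) {
    s <- 0
    for (oz in -radius:radius) for (oy in -radius:radius) for (ox in -radius:radius) {
      s <- s + a[refl(iz + oz, d[1]), refl(iy + oy, d[2]), refl(ix + ox, d[3])]
    }
    out[iz, iy, ix] <- s / w
  }
  out
}

## Small isotropic stack wrapping a 3-D array as a single channel.
stack1 <- function(a, spacing = 0.5, channel = "constitutive") {
  image_stack(array(a, c(1, dim(a))), rep(spacing, 3), channel)
}

## A tiny scene rendered without blur or noise, for geometry tests.
clean_optics <- function(spacing = 0.5, amp = 100, seed = 1) {
  optics_params(voxel_spacing_um = rep(spacing, 3),
                psf_sigma_um = c(0, 0, 0),
                default_amplitude = c(on = amp, off = 0),
                read_noise_sd = 0, poisson_noise = FALSE,
                background_level = 0, seed = seed)
}

## One-cell scene with a known centre, built from the generator then pinned
## to exact coordinates so geometry is controlled.
one_cell_scene <- function(center = c(6, 6, 6), domain = c(12, 12, 12),
                           radii = c(0.5, 0.5, 1.0)) {
  sc <- generate_scene(scene_params(n_single = 1L, n_aggregates = 0L,
                                    cell_radii_um = radii),
                       domain_size_um = domain, seed = 1)
  sc$cells$center_z_um <- center[1]
  sc$cells$center_y_um <- center[2]
  sc$cells$center_x_um <- center[3]
  sc
}

## Default dual-reporter pipeline used by the end-to-end recovery tests.
run_dual_reporter <- function(seed, channels = c("curli", "flagella"),
                              params = scene_params()) {
  sc <- generate_scene(params, seed = seed)
  st <- render_scene(sc, optics_params(seed = seed + 1000), channels)
  iso <- upsample_to_isotropic(st)
  sm <- smooth_stack(iso)
  masks <- lapply(channels, function(ch) segment(sm, ch))
  names(masks) <- channels
  merged <- merge_masks(masks)
  cubes <- dissect(merged, iso)
  cubes <- annotate_density(cubes, merged)
  cubes <- classify_cubes(cubes, masks)
  list(scene = sc, masks = masks, merged = merged, cubes = cubes)
}
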