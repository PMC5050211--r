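## Scene rendering: each cell is rasterized as a solid spheroid at a
## state-dependent amplitude per channel (overlaps resolved by maximum),
## blurred by a separable Gaussian PSF, offset by a constant background and
## optionally degraded with Poisson shot noise plus Gaussian read noise —
## the standard photon-limited confocal model.

#' Optics / rendering parameters
#'
#' @param voxel_spacing_um (z, y, x) voxel spacing in um; the default
#'   (1.0, 0.5, 0.5) is anisotropic in z, as confocal stacks typically are.
#' @param psf_sigma_um Gaussian PSF standard deviation (z, y, x) in um; the
#'   axial width exceeds the lateral one as in a real confocal point-spread
#'   function.
#' @param amplitude_per_state named list channel -> c(on, off) intensity
#'   levels; channels absent from the list use \code{default_amplitude}.
#' @param default_amplitude fallback c(on, off) levels.
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param poisson_noise apply Poisson shot noise to the signal.
#' @param background_level constant background (counts).
#' @param seed integer seed for the noise draws.
#' @return A list of class \code{optics_params}.
#' @export
optics_params <- function(voxel_spacing_um = c(1.0, 0.5, 0.5),
                          psf_sigma_um = c(0.6, 0.25, 0.25),
                          amplitude_per_state = list(),
                          default_amplitude = c(on = 150, off = 0),
                          read_noise_sd = 1,
                          poisson_noise = TRUE,
                          background_level = 2,
                          seed = 1L) {
  voxel_spacing_um <- as.numeric(voxel_spacing_um)
  if (any(voxel_spacing_um <= 0)) stop("voxel spacings must be > 0")
  for (a in amplitude_per_state)
    if (a[1] < a[2] || a[2] < 0) stop("amplitudes must satisfy on >= off >= 0")
  if (default_amplitude[1] < default_amplitude[2] || default_amplitude[2] < 0)
    stop("amplitudes must satisfy on >= off >= 0")
  structure(list(voxel_spacing_um = voxel_spacing_um,
                 psf_sigma_um = as.numeric(psf_sigma_um),
                 amplitude_per_state = amplitude_per_state,
                 default_amplitude = as.numeric(default_amplitude),
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "optics_params")
}

render_channels <- c("constitutive", "curli", "flagella", "sigmaS",
                     "timer_green", "timer_orange")

## state weight in [0, inf): scales the channel amplitude between off and on
channel_weight <- function(cells, channel) {
  switch(channel,
         constitutive = rep(1, nrow(cells)),
         curli        = as.numeric(cells$curli_on),
         flagella     = as.numeric(cells$flagella_on),
         sigmaS       = pmin(cells$sigmaS_level, 1),
         timer_green  = cells$timer_green,
         timer_orange = cells$timer_orange,
         stop("unknown channel '", channel, "'; valid channels: ",
              paste(render_channels, collapse = ", ")))
}

## linear voxel indices (z, y, x array) covered by each cell's spheroid:
## a voxel belongs to a cell when its centre lies inside the spheroid.
rasterize_cells <- function(cells, dims, spacing, radii) {
  lapply(seq_len(nrow(cells)), function(i) {
    ctr <- c(cells$center_z_um[i], cells$center_y_um[i], cells$center_x_um[i])
    lo <- pmax(1L, ceiling((ctr - radii) / spacing + 0.5))
    hi <- pmin(dims, floor((ctr + radii) / spacing + 0.5))
    if (any(hi < lo)) return(integer())
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- ((iz - 0.5) * spacing[1] - ctr[1])^2 / radii[1]^2
    dy2 <- ((iy - 0.5) * spacing[2] - ctr[2])^2 / radii[2]^2
    dx2 <- ((ix - 0.5) * spacing[3] - ctr[3])^2 / radii[3]^2
    g <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    inside <- which(g <= 1)
    if (!length(inside)) return(integer())
    ai <- arrayInd(inside, dim(g))
    (iz[ai[, 1]] - 1L) + dims[1] * ((iy[ai[, 2]] - 1L) + dims[2] * (ix[ai[, 3]] - 1L)) + 1L
  })
}

#' Render a scene to a noisy multi-channel image stack
#'
#' @param scene a \code{scene}.
#' @param optics an \code{optics_params}.
#' @param channels channel names to render, among constitutive, curli,
#'   flagella, sigmaS, timer_green, timer_orange.
#' @return An \code{image_stack} on the optics voxel grid.
#' @export
render_scene <- function(scene, optics = optics_params(),
                         channels = c("constitutive", "curli")) {
  stopifnot(inherits(scene, "scene"), inherits(optics, "optics_params"))
  for (ch in channels)
    if (!ch %in% render_channels)
      stop("unknown channel '", ch, "'; valid channels: ",
           paste(render_channels, collapse = ", "))
  sp <- optics$voxel_spacing_um
  dims <- as.integer(round(scene$domain_size_um / sp))
  cells <- scene$cells
  radii <- scene$params$cell_radii_um
  vox_idx <- rasterize_cells(cells, dims, sp, radii)
  set.seed(optics$seed)
  out <- array(0, c(length(channels), dims))
  sigma_vox <- optics$psf_sigma_um / sp
  for (k in seq_along(channels)) {
    ch <- channels[k]
    amp_lv <- optics$amplitude_per_state[[ch]] %||% optics$default_amplitude
    w <- channel_weight(cells, ch)
    amp <- amp_lv[2] + (amp_lv[1] - amp_lv[2]) * w
    img <- array(0, dims)
    for (i in seq_len(nrow(cells))) {
      idx <- vox_idx[[i]]
      if (length(idx)) img[idx] <- pmax(img[idx], amp[i])
    }
    if (any(sigma_vox > 0)) img <- gaussian_filter3(img, sigma_vox)
    img <- img + optics$background_level
    if (optics$poisson_noise) {
      img[] <- stats::rpois(length(img), pmax(img, 0))
    }
    if (optics$read_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, optics$read_noise_sd)
    }
    out[k, , , ] <- img
  }
  image_stack(out, sp, channels)
}
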