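## Cube-based quantification. The segmented biomass map is dissected into a
## non-overlapping grid of cubes (side 5 voxels ~ 1 um on the isotropic
## grid); each occupied cube is the unit of measurement: raw per-channel
## mean intensity over its foreground voxels, its foreground centre of
## mass, and the local density — the occupied volume fraction inside a
## 3 um ball around that centre of mass.

cube_key <- function(ci, K) ci[, 1] + K[1] * (ci[, 2] + K[2] * ci[, 3])

#' Dissect a biomass mask into a cube table
#'
#' The cube grid is anchored at the index origin; partial cubes at the far
#' borders are retained with their true voxel counts. Mean intensities are
#' averaged over the cube's foreground voxels only (raw, unprocessed
#' values), and the centre of mass is the unweighted mean of foreground
#' voxel centres.
#'
#' @param mask a \code{binary_mask}.
#' @param raw an isotropic \code{image_stack} sharing the mask's shape and
#'   spacing (typically the upsampled, un-smoothed stack).
#' @param cube_side_vox cube side in voxels (default 5, ~1 um at 0.2 um
#'   spacing — with the default optics, 5 px of the 0.5 um isotropic grid).
#' @param min_occupancy cubes with fewer foreground voxels are dropped.
#' @return A data frame of class \code{cube_table}: 0-based grid index
#'   (\code{cube_z/y/x}), \code{occupancy_vox}, centre of mass
#'   (\code{com_z/y/x_um}) and one \code{mean_<channel>} column per channel.
#' @export
dissect <- function(mask, raw, cube_side_vox = 5L, min_occupancy = 1L) {
  stopifnot(inherits(mask, "binary_mask"), inherits(raw, "image_stack"))
  d <- dim(mask$voxels)
  if (!identical(as.integer(d), as.integer(dim(raw$voxels)[2:4])))
    stop("mask and raw stack shapes differ")
  if (!is_isotropic(raw$spacing_um) ||
      abs(raw$spacing_um[1] - mask$spacing_um) > 1e-9)
    stop("mask and raw stack spacings differ")
  side <- as.integer(cube_side_vox)
  if (side < 1L) stop("cube_side_vox must be >= 1")
  if (side > min(d)) stop("cube side ", side, " exceeds an image axis (",
                          paste(d, collapse = "x"), ")")
  s <- mask$spacing_um
  K <- as.integer(ceiling(d / side))
  idx <- which(mask$voxels)
  empty <- data.frame(cube_z = integer(), cube_y = integer(), cube_x = integer(),
                      occupancy_vox = integer(),
                      com_z_um = numeric(), com_y_um = numeric(), com_x_um = numeric())
  chans <- raw$channel_names
  for (ch in chans) empty[[paste0("mean_", ch)]] <- numeric()
  if (!length(idx)) {
    class(empty) <- c("cube_table", "data.frame")
    attr(empty, "cube_side_vox") <- side
    attr(empty, "spacing_um") <- s
    return(empty)
  }
  ai <- arrayInd(idx, d)                      # 1-based (z, y, x)
  ci <- (ai - 1L) %/% side                    # 0-based cube grid index
  key <- cube_key(ci, K)
  g <- match(key, sort(unique(key)))
  occ <- as.vector(rowsum(rep(1L, length(idx)), g))
  com <- rowsum((ai - 0.5) * s, g) / occ
  ukey <- sort(unique(key))
  cz <- ukey %% K[1]
  cy <- (ukey %/% K[1]) %% K[2]
  cx <- ukey %/% (K[1] * K[2])
  out <- data.frame(cube_z = cz, cube_y = cy, cube_x = cx,
                    occupancy_vox = occ,
                    com_z_um = com[, 1], com_y_um = com[, 2], com_x_um = com[, 3])
  for (k in seq_along(chans)) {
    a <- raw$voxels[k, , , , drop = FALSE]; dim(a) <- d
    out[[paste0("mean_", chans[k])]] <- as.vector(rowsum(a[idx], g)) / occ
  }
  out <- out[out$occupancy_vox >= min_occupancy, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cube_table", "data.frame")
  attr(out, "cube_side_vox") <- side
  attr(out, "spacing_um") <- s
  attr(out, "grid_dim") <- K
  attr(out, "image_dim") <- as.integer(d)
  out
}

#' Local biomass density around a point
#'
#' Fraction of foreground among all voxels whose centres lie within
#' \code{radius_um} (Euclidean) of the point \emph{and} inside the image
#' bounds — boundary normalisation divides by the in-bounds ball count, so
#' densities at the substratum are not systematically underestimated. The
#' ball is solid: the occupied volume fraction within the radius.
#'
#' @param mask a \code{binary_mask}.
#' @param points_um numeric matrix (n x 3) or length-3 vector of physical
#'   (z, y, x) coordinates in um; points must lie inside the volume.
#' @param radius_um ball radius in um (default 3).
#' @return Numeric vector of densities in [0, 1].
#' @export
local_density <- function(mask, points_um, radius_um = 3.0) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius_um <= 0) stop("radius_um must be > 0")
  if (is.null(dim(points_um))) points_um <- matrix(points_um, ncol = 3)
  d <- dim(mask$voxels)
  s <- mask$spacing_um
  hi_phys <- d * s
  if (any(points_um < 0) || any(points_um > matrix(hi_phys, nrow(points_um), 3, byrow = TRUE)))
    stop("point outside the volume bounds")
  r2 <- radius_um^2
  vapply(seq_len(nrow(points_um)), function(i) {
    p <- points_um[i, ]
    lo <- pmax(1L, ceiling((p - radius_um) / s + 0.5))
    hi <- pmin(d, floor((p + radius_um) / s + 0.5))
    if (any(hi < lo)) return(NA_real_)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- ((iz - 0.5) * s - p[1])^2
    dy2 <- ((iy - 0.5) * s - p[2])^2
    dx2 <- ((ix - 0.5) * s - p[3])^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r2
    if (!any(inside)) return(NA_real_)
    sub <- mask$voxels[iz, iy, ix, drop = FALSE]
    sum(sub[inside]) / sum(inside)
  }, numeric(1))
}

#' Annotate a cube table with local density
#'
#' @param cubes a \code{cube_table}.
#' @param mask the \code{binary_mask} the cubes were dissected from.
#' @param radius_um ball radius in um (default 3).
#' @return The cube table with a \code{local_density} column.
#' @export
annotate_density <- function(cubes, mask, radius_um = 3.0) {
  if (!nrow(cubes)) {
    cubes$local_density <- numeric(0)
    return(cubes)
  }
  pts <- as.matrix(cubes[, c("com_z_um", "com_y_um", "com_x_um")])
  cubes$local_density <- local_density(mask, pts, radius_um)
  cubes
}

#' Classify cubes by per-channel reporter positivity
#'
#' Dual-reporter mode: a cube is positive for a channel when at least
#' \code{min_overlap_vox} of its voxels are foreground in that channel's
#' individual (pre-merge) mask. Cubes may be positive for zero, one or
#' several channels.
#'
#' @param cubes a \code{cube_table} from \code{\link{dissect}}.
#' @param per_channel_masks named list of \code{binary_mask} objects on the
#'   same grid as the dissected mask.
#' @param min_overlap_vox minimum foreground voxels for positivity.
#' @return The cube table with one logical \code{pos_<channel>} column per
#'   mask.
#' @export
classify_cubes <- function(cubes, per_channel_masks, min_overlap_vox = 1L) {
  side <- attr(cubes, "cube_side_vox")
  K <- attr(cubes, "grid_dim")
  d <- attr(cubes, "image_dim")
  if (is.null(side) || is.null(K))
    stop("cube table lacks dissection attributes; classify straight after dissect()")
  key_tab <- cube_key(as.matrix(cubes[, c("cube_z", "cube_y", "cube_x")]), K)
  for (nm in names(per_channel_masks)) {
    m <- per_channel_masks[[nm]]
    if (!identical(as.integer(dim(m$voxels)), d))
      stop("mask shape mismatch for channel '", nm, "'")
    idx <- which(m$voxels)
    col <- paste0("pos_", nm)
    if (!length(idx)) { cubes[[col]] <- FALSE; next }
    ci <- (arrayInd(idx, d) - 1L) %/% side
    cnt <- table(cube_key(ci, K))
    hits <- cnt[as.character(key_tab)]
    hits[is.na(hits)] <- 0
    cubes[[col]] <- as.vector(hits) >= min_overlap_vox
  }
  cubes
}
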