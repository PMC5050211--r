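#' Multi-channel 3D image stack
#'
#' Container for a multi-channel volumetric fluorescence image. Voxels are
#' stored as a 4-D array in the fixed axis order (channel, z, y, x) with
#' per-axis physical spacing in micrometres. The physical coordinate of a
#' voxel centre is \code{(index - 1 + 0.5) * spacing} per axis (voxel-centre
#' convention, 0-based geometry), with z = 0 at the substratum.
#'
#' @param voxels 4-D numeric array, dimensions (channel, z, y, x).
#' @param spacing_um numeric length-3 vector, (z, y, x) voxel spacing in um.
#' @param channel_names character vector naming the channel axis.
#' @return An object of class \code{image_stack}.
#' @examples
#' v <- array(0, c(1, 4, 8, 8))
#' s <- image_stack(v, spacing_um = c(1, 0.5, 0.5), channel_names = "constitutive")
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing_um, channel_names) {
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4-D array (channel, z, y, x)")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("spacing_um must be 3 positive numbers (z, y, x)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(voxels)[1])
    stop("channel_names length (", length(channel_names),
         ") does not match channel axis length (", dim(voxels)[1], ")")
  structure(list(voxels = voxels, spacing_um = spacing_um,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack> ", d[1], " channel(s) [",
      paste(x$channel_names, collapse = ", "), "]\n", sep = "")
  cat("  volume (z,y,x): ", paste(d[2:4], collapse = " x "),
      " voxels at (", paste(format(x$spacing_um), collapse = ", "),
      ") um\n", sep = "")
  cat("  intensity range: [", format(min(x$voxels)), ", ",
      format(max(x$voxels)), "]\n", sep = "")
  invisible(x)
}

## Extract one channel as a plain 3-D (z, y, x) array.
channel_array <- function(stack, channel) {
  i <- match(channel, stack$channel_names)
  if (is.na(i)) stop("unknown channel '", channel, "'; stack has: ",
                     paste(stack$channel_names, collapse = ", "))
  a <- stack$voxels[i, , , , drop = FALSE]
  dim(a) <- dim(stack$voxels)[2:4]
  a
}

is_isotropic <- function(spacing_um, tol = 1e-9) {
  diff(range(spacing_um)) <= tol * max(spacing_um)
}

#' Binary biomass mask
#'
#' Foreground/background volume produced by segmentation; the biomass map all
#' downstream quantification consumes. By construction masks are isotropic
#' (segmentation runs after upsampling), so spacing is a single scalar.
#'
#' @param voxels 3-D logical array (z, y, x).
#' @param spacing_um scalar isotropic voxel spacing in um.
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(voxels, spacing_um) {
  if (length(dim(voxels)) != 3L) stop("mask voxels must be a 3-D array (z, y, x)")
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 1L || spacing_um <= 0)
    stop("binary_mask spacing_um must be one positive scalar (isotropic)")
  structure(list(voxels = voxels, spacing_um = spacing_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<binary_mask> ", paste(d, collapse = " x "), " voxels at ",
      format(x$spacing_um), " um; foreground fraction ",
      format(mean(x$voxels), digits = 4), "\n", sep = "")
  invisible(x)
}
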