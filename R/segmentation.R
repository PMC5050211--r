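## Segmentation chain: confocal z-stacks are acquired with coarser axial than
## lateral sampling, so the stack is first resampled to an isotropic grid,
## denoised with a small averaging filter, and then thresholded with a
## three-class Otsu criterion in which class 1 is background and classes 2-3
## (dim and bright biomass) are foreground. In dual-reporter mode each
## channel is segmented individually and the masks merged by union.

#' Upsample a stack along z to an isotropic voxel grid
#'
#' Linear interpolation between z slice centres; the output spacing is the
#' (equal) y/x spacing on all three axes. The output z grid is aligned to
#' the first input slice centre with step equal to the target spacing, so
#' original slices are retained and intermediate slices interpolated.
#' Values beyond the last slice centre are clamped; linear interpolation is
#' convex, so the value range is never exceeded. An already isotropic stack
#' is returned unchanged.
#'
#' @param stack an \code{image_stack} with equal y and x spacing.
#' @return An isotropic \code{image_stack}.
#' @export
upsample_to_isotropic <- function(stack) {
  sp <- stack$spacing_um
  if (abs(sp[2] - sp[3]) > 1e-9 * max(sp))
    stop("unsupported geometry: y and x spacings differ (",
         sp[2], " vs ", sp[3], ")")
  if (is_isotropic(sp)) return(stack)
  s <- sp[2]; sz <- sp[1]
  d <- dim(stack$voxels)
  nz <- d[2]
  n_out <- floor((nz - 1) * sz / s + 1e-9) + 1L
  ## position of output slice j (0-based) in input slice-index units
  t <- (seq_len(n_out) - 1L) * s / sz
  i0 <- pmin(floor(t), nz - 1L)
  f <- t - i0
  i0 <- i0 + 1L                      # 1-based lower slice
  i1 <- pmin(i0 + 1L, nz)
  out <- array(0, c(d[1], n_out, d[3], d[4]))
  for (j in seq_len(n_out)) {
    out[, j, , ] <- (1 - f[j]) * stack$voxels[, i0[j], , , drop = FALSE] +
      f[j] * stack$voxels[, i1[j], , , drop = FALSE]
  }
  image_stack(out, c(s, s, s), stack$channel_names)
}

#' Denoise a stack with a small uniform averaging filter
#'
#' Box mean filter of side \code{2 * kernel_radius_vox + 1} per axis with
#' mirror (reflect) padding at the borders, applied to every channel.
#' Reflect padding avoids artificial darkening at the substratum plane,
#' where the biofilm touches the image border.
#'
#' @param stack an isotropic \code{image_stack}.
#' @param kernel_radius_vox nonnegative integer radius (default 1: 3x3x3).
#' @return The smoothed (real-valued) \code{image_stack}.
#' @export
smooth_stack <- function(stack, kernel_radius_vox = 1L) {
  if (kernel_radius_vox < 0) stop("kernel_radius_vox must be >= 0")
  if (!is_isotropic(stack$spacing_um))
    warning("smoothing an anisotropic stack; upsample_to_isotropic() first")
  d <- dim(stack$voxels)
  out <- stack$voxels
  for (ch in seq_len(d[1])) {
    a <- stack$voxels[ch, , , , drop = FALSE]; dim(a) <- d[2:4]
    out[ch, , , ] <- box_filter3(a, as.integer(kernel_radius_vox))
  }
  image_stack(out, stack$spacing_um, stack$channel_names)
}

#' Three-class Otsu thresholds of an intensity histogram
#'
#' Finds the threshold pair (t1, t2) that maximises the between-class
#' variance of a three-class split of the histogram (background, dim
#' foreground, bright foreground). The search is exhaustive over all
#' admissible split pairs; ties are broken deterministically toward the
#' lexicographically smallest (t1, t2).
#'
#' @param counts numeric vector of histogram bin counts (>= 3 nonempty bins).
#' @param mids bin centres (default \code{seq_along(counts) - 1}, i.e.
#'   integer intensities starting at 0).
#' @param edges optional bin edges (length \code{length(counts) + 1}); when
#'   given, thresholds are reported as the edge between the split bins,
#'   otherwise as the midpoint between adjacent bin centres.
#' @return A list of class \code{otsu_result} with elements \code{t1},
#'   \code{t2}, \code{class_counts} (triple) and
#'   \code{between_class_variance}.
#' @examples
#' h <- numeric(256); h[c(1, 129, 256)] <- 100   # values 0, 128, 255
#' otsu3_thresholds(h)[c("t1", "t2")]
#' @export
otsu3_thresholds <- function(counts, mids = seq_along(counts) - 1, edges = NULL) {
  counts <- as.numeric(counts)
  n <- length(counts)
  if (sum(counts > 0) < 3L)
    stop("degenerate histogram: fewer than 3 nonempty bins; ",
         "3-class thresholding is undefined")
  tot <- sum(counts)
  p <- counts / tot
  W <- cumsum(p)
  S <- cumsum(p * mids)
  mu <- S[n]
  ## split after bin i (class 1 = 1..i) and after bin j (class 2 = i+1..j)
  ii <- rep(seq_len(n - 2L), times = (n - 2L):1L)
  jj <- sequence((n - 2L):1L) + ii
  w1 <- W[ii]; w2 <- W[jj] - W[ii]; w3 <- 1 - W[jj]
  s1 <- S[ii]; s2 <- S[jj] - S[ii]; s3 <- mu - S[jj]
  term <- function(s, w) ifelse(w > 0, s * s / w, 0)
  crit <- term(s1, w1) + term(s2, w2) + term(s3, w3)
  best <- which(crit == max(crit))
  ## (ii, jj) pairs are generated in lexicographic order already
  b <- best[1L]
  i <- ii[b]; j <- jj[b]
  thr <- function(k) {
    if (!is.null(edges)) edges[k + 1L] else (mids[k] + mids[k + 1L]) / 2
  }
  cc <- c(sum(counts[seq_len(i)]),
          sum(counts[seq(i + 1L, j)]),
          sum(counts[seq(j + 1L, n)]))
  bcv <- max(crit) - mu^2
  structure(list(t1 = thr(i), t2 = thr(j), class_counts = cc,
                 between_class_variance = bcv),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat("<otsu_result> t1 =", format(x$t1), " t2 =", format(x$t2),
      " class counts:", paste(x$class_counts, collapse = "/"),
      " BCV =", format(x$between_class_variance), "\n")
  invisible(x)
}

## 2-class Otsu threshold (used for cytometry auto-gating); same exhaustive
## criterion with a single split, smallest maximiser.
otsu2_threshold <- function(counts, mids = seq_along(counts) - 1, edges = NULL) {
  counts <- as.numeric(counts)
  n <- length(counts)
  if (sum(counts > 0) < 2L) stop("degenerate histogram: fewer than 2 nonempty bins")
  p <- counts / sum(counts)
  W <- cumsum(p); S <- cumsum(p * mids); mu <- S[n]
  i <- seq_len(n - 1L)
  w1 <- W[i]; w2 <- 1 - w1
  s1 <- S[i]; s2 <- mu - s1
  crit <- ifelse(w1 > 0, s1^2 / w1, 0) + ifelse(w2 > 0, s2^2 / w2, 0)
  b <- which(crit == max(crit))[1L]
  if (!is.null(edges)) edges[b + 1L] else (mids[b] + mids[b + 1L]) / 2
}

## 256 equal-width bins over the observed range; returns counts/mids/edges.
intensity_histogram <- function(x, bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) stop("degenerate histogram: constant volume")
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  w <- (r[2] - r[1]) / bins
  idx <- pmin(floor((x - r[1]) / w), bins - 1L) + 1L
  counts <- tabulate(idx, nbins = bins)
  list(counts = counts, mids = edges[-1] - w / 2, edges = edges)
}

#' Segment one channel into a binary biomass mask
#'
#' Computes three-class Otsu thresholds on the full-volume intensity
#' histogram (256 equal-width bins over the observed range) and returns the
#' mask of classes 2 and 3, i.e. all voxels with intensity above the lower
#' threshold t1. The stack should already be isotropic and smoothed; a
#' warning is issued for anisotropic input. Degenerate volumes (fewer than
#' three distinct values) are an error, never a silent empty mask.
#'
#' @param stack an \code{image_stack}.
#' @param channel channel name to segment.
#' @param bins histogram bin count (default 256).
#' @return A \code{binary_mask} with attributes \code{thresholds} (the
#'   \code{otsu_result}) and \code{foreground_fraction}.
#' @export
segment <- function(stack, channel, bins = 256L) {
  if (!is_isotropic(stack$spacing_um))
    warning("segmenting an anisotropic stack; upsample_to_isotropic() first")
  a <- channel_array(stack, channel)
  if (length(unique(as.vector(a))) < 3L)
    stop("degenerate histogram in channel '", channel,
         "': fewer than 3 distinct values")
  h <- intensity_histogram(as.vector(a), bins)
  ot <- otsu3_thresholds(h$counts, h$mids, h$edges)
  m <- binary_mask(a > ot$t1, stack$spacing_um[1])
  attr(m, "thresholds") <- ot
  attr(m, "foreground_fraction") <- mean(m$voxels)
  m
}

#' Merge per-channel masks by voxelwise union
#'
#' @param masks list of \code{binary_mask} objects with equal shapes and
#'   spacings.
#' @return The union \code{binary_mask}.
#' @export
merge_masks <- function(masks) {
  if (!length(masks)) stop("no masks to merge")
  d <- dim(masks[[1]]$voxels); sp <- masks[[1]]$spacing_um
  out <- masks[[1]]$voxels
  for (m in masks[-1]) {
    if (!identical(dim(m$voxels), d)) stop("mask shape mismatch in merge_masks")
    if (abs(m$spacing_um - sp) > 1e-9) stop("mask spacing mismatch in merge_masks")
    out <- out | m$voxels
  }
  binary_mask(out, sp)
}
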