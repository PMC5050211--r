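## Profiles and expression ratios over the cube table: mean local density
## versus depth, constitutive-normalised reporter expression as 2-D
## density/expression and depth/expression histograms, and the TIMER
## orange/green growth-rate ratio.

profile_obj <- function(bin_edges, values, n_per_bin, axis) {
  structure(list(bin_edges = bin_edges, values = values,
                 n_per_bin = n_per_bin, axis = axis),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("<profile> over ", x$axis, ": ", length(x$values), " bins, ",
      sum(x$n_per_bin), " cubes\n", sep = "")
  invisible(x)
}

#' @export
plot.profile <- function(x, ...) {
  mids <- (utils::head(x$bin_edges, -1) + utils::tail(x$bin_edges, -1)) / 2
  graphics::plot(mids, x$values, type = "b", xlab = x$axis,
                 ylab = "mean local density", ...)
  invisible(x)
}

#' Mean local density along the biofilm height
#'
#' @param cubes a \code{cube_table} annotated with \code{local_density}.
#' @param z_bin_um bin width along z in um (default 2).
#' @return A \code{profile}: per-bin mean local density (NA for empty bins).
#' @export
density_z_profile <- function(cubes, z_bin_um = 2.0) {
  if (z_bin_um <= 0) stop("z_bin_um must be > 0")
  if (is.null(cubes$local_density))
    stop("cube table lacks local_density; run annotate_density() first")
  if (!nrow(cubes))
    return(profile_obj(c(0, z_bin_um), NA_real_, 0L, "z_um"))
  zmax <- max(cubes$com_z_um)
  edges <- seq(0, (floor(zmax / z_bin_um) + 1) * z_bin_um, by = z_bin_um)
  bin <- findInterval(cubes$com_z_um, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n <- tabulate(bin, nb)
  vals <- rep(NA_real_, nb)
  means <- tapply(cubes$local_density, factor(bin, levels = seq_len(nb)), mean)
  vals[!is.na(means)] <- means[!is.na(means)]
  profile_obj(edges, vals, n, "z_um")
}

#' Normalised per-cube expression ratio
#'
#' Ratio of raw mean intensities, reporter over reference (the constitutive
#' marker labelling all cells). Cubes whose reference intensity is at or
#' below \code{floor} are excluded (returned NA) and the exclusion count is
#' reported.
#'
#' @param cubes a \code{cube_table}.
#' @param channel reporter channel name.
#' @param reference reference channel name.
#' @param floor reference intensities <= floor are excluded (default 0).
#' @return Numeric vector aligned with \code{cubes} rows (NA = excluded),
#'   with attribute \code{n_excluded}.
#' @export
normalize_channel <- function(cubes, channel, reference, floor = 0) {
  chc <- paste0("mean_", channel); rfc <- paste0("mean_", reference)
  for (col in c(chc, rfc))
    if (is.null(cubes[[col]])) stop("unknown channel column '", col, "'")
  ref <- cubes[[rfc]]
  bad <- ref <= floor
  ratio <- ifelse(bad, NA_real_, cubes[[chc]] / ref)
  n_bad <- sum(bad)
  if (n_bad) message(n_bad, " cube(s) excluded: reference '", reference,
                     "' <= ", floor)
  attr(ratio, "n_excluded") <- n_bad
  ratio
}

#' TIMER orange/green ratio per cube
#'
#' The slowly maturing orange TIMER intensity normalised to the internal
#' green control; the ratio rises as growth slows.
#'
#' @param cubes a \code{cube_table}.
#' @param orange,green channel names.
#' @param floor green intensities <= floor are excluded.
#' @return As \code{\link{normalize_channel}}.
#' @export
timer_ratio <- function(cubes, orange = "timer_orange",
                        green = "timer_green", floor = 0) {
  normalize_channel(cubes, orange, green, floor)
}

hist2d <- function(xv, yv, x_edges, y_edges) {
  ## clamp into the outer bins so every included cube is counted
  bx <- pmin(pmax(findInterval(xv, x_edges, rightmost.closed = TRUE), 1L),
             length(x_edges) - 1L)
  by <- pmin(pmax(findInterval(yv, y_edges, rightmost.closed = TRUE), 1L),
             length(y_edges) - 1L)
  counts <- matrix(0L, length(x_edges) - 1L, length(y_edges) - 1L)
  t <- table(factor(bx, seq_len(nrow(counts))), factor(by, seq_len(ncol(counts))))
  counts[] <- as.integer(t)
  counts
}

profile2d_obj <- function(x_edges, y_edges, counts, axis) {
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 n_included = sum(counts), axis = axis),
            class = "profile2d")
}

#' @export
print.profile2d <- function(x, ...) {
  cat("<profile2d> ", x$axis, " x expression: ",
      nrow(x$counts), " x ", ncol(x$counts), " bins, ",
      x$n_included, " cubes\n", sep = "")
  invisible(x)
}

#' @export
plot.profile2d <- function(x, ...) {
  graphics::image(x$x_edges, x$y_edges, log1p(x$counts), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = x$axis, ylab = "normalized expression", ...)
  invisible(x)
}

default_value_edges <- function(v, nbins = 40L) {
  r <- range(v, finite = TRUE)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = nbins + 1L)
}

#' Expression profile as a function of local density
#'
#' 2-D histogram of (local density, normalised reporter expression) over
#' all included cubes; counts sum to the included-cube count.
#'
#' @param cubes annotated \code{cube_table}.
#' @param channel,reference reporter and reference channel names.
#' @param density_bins density bin edges (default \code{seq(0, 1, 0.05)}).
#' @param value_bins expression bin edges (default: 40 bins over the
#'   observed range).
#' @param floor passed to \code{\link{normalize_channel}}.
#' @return A \code{profile2d}.
#' @export
expression_vs_density <- function(cubes, channel, reference,
                                  density_bins = seq(0, 1, 0.05),
                                  value_bins = NULL, floor = 0) {
  if (!nrow(cubes)) stop("empty cube table")
  if (is.null(cubes$local_density))
    stop("cube table lacks local_density; run annotate_density() first")
  ratio <- normalize_channel(cubes, channel, reference, floor)
  keep <- !is.na(ratio) & !is.na(cubes$local_density)
  if (is.null(value_bins)) value_bins <- default_value_edges(ratio[keep])
  counts <- hist2d(cubes$local_density[keep], ratio[keep],
                   density_bins, value_bins)
  profile2d_obj(density_bins, value_bins, counts, "local_density")
}

#' Expression profile along the biofilm height
#'
#' @param cubes a \code{cube_table}.
#' @param channel,reference reporter and reference channel names.
#' @param z_bins z bin edges in um (default 2 um bins over the cube range).
#' @param value_bins expression bin edges (default as
#'   \code{\link{expression_vs_density}}).
#' @param floor passed to \code{\link{normalize_channel}}.
#' @return A \code{profile2d} over z.
#' @export
expression_z_profile <- function(cubes, channel, reference, z_bins = NULL,
                                 value_bins = NULL, floor = 0) {
  if (!nrow(cubes)) stop("empty cube table")
  ratio <- normalize_channel(cubes, channel, reference, floor)
  keep <- !is.na(ratio)
  if (is.null(z_bins)) {
    zmax <- max(cubes$com_z_um)
    z_bins <- seq(0, (base::floor(zmax / 2) + 1) * 2, by = 2)
  }
  if (is.null(value_bins)) value_bins <- default_value_edges(ratio[keep])
  counts <- hist2d(cubes$com_z_um[keep], ratio[keep], z_bins, value_bins)
  profile2d_obj(z_bins, value_bins, counts, "z_um")
}
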