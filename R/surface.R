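## Biofilm surface topography. The height map records, per (y, x) column,
## the physical z of the topmost foreground voxel centre (substratum at
## z = 0); roughness is the windowed standard deviation of that height
## field — the estimator behind the roughness maps of structured vs flat
## biofilms.

#' Biofilm height map
#'
#' @param mask an isotropic \code{binary_mask}; z = 0 is the substratum.
#' @return An object of class \code{surface_map}: \code{height_um} is a
#'   (y, x) matrix, \code{NA} where the column holds no biomass;
#'   \code{roughness_um} is filled by \code{\link{roughness_map}}.
#' @export
height_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$voxels)
  s <- mask$spacing_um
  ## topmost foreground z index per column via a weighted max over z
  zi <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  zi[!mask$voxels] <- 0L
  top <- apply(zi, c(2, 3), max)
  h <- ifelse(top > 0, (top - 0.5) * s, NA_real_)
  structure(list(height_um = h, roughness_um = NULL, spacing_um = s),
            class = "surface_map")
}

#' Windowed roughness of a height map
#'
#' Roughness at (y, x) is the sample standard deviation of the defined
#' height values inside the centred \code{window_px} x \code{window_px}
#' window; undefined where fewer than 2 heights are defined. A constant
#' height field has roughness 0, and the statistic is invariant to adding a
#' constant to all heights.
#'
#' @param surface a \code{surface_map} from \code{\link{height_map}}.
#' @param window_px odd window side in pixels (default 11).
#' @return The \code{surface_map} with \code{roughness_um} filled.
#' @export
roughness_map <- function(surface, window_px = 11L) {
  stopifnot(inherits(surface, "surface_map"))
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("window_px must be an odd integer >= 3")
  h <- surface$height_um
  def <- !is.na(h)
  h0 <- ifelse(def, h, 0)
  k <- rep(1, window_px)
  boxsum2 <- function(m) {
    m <- conv_matrix(nrow(m), k, "zero") %*% m
    m %*% t(conv_matrix(ncol(m), k, "zero"))
  }
  S0 <- boxsum2(def * 1)
  S1 <- boxsum2(h0)
  S2 <- boxsum2(h0^2)
  rough <- matrix(NA_real_, nrow(h), ncol(h))
  ok <- S0 >= 2
  v <- (S2[ok] - S1[ok]^2 / S0[ok]) / (S0[ok] - 1)
  rough[ok] <- sqrt(pmax(v, 0))
  surface$roughness_um <- rough
  surface$window_px <- window_px
  surface
}

#' @export
print.surface_map <- function(x, ...) {
  h <- x$height_um
  cat("<surface_map> ", nrow(h), " x ", ncol(h), " columns; ",
      sum(!is.na(h)), " defined; height range [",
      format(suppressWarnings(min(h, na.rm = TRUE))), ", ",
      format(suppressWarnings(max(h, na.rm = TRUE))), "] um\n", sep = "")
  if (!is.null(x$roughness_um))
    cat("  mean roughness ", format(mean(x$roughness_um, na.rm = TRUE),
                                    digits = 4), " um (window ",
        x$window_px, " px)\n", sep = "")
  invisible(x)
}

#' @export
plot.surface_map <- function(x, what = c("height", "roughness"), ...) {
  what <- match.arg(what)
  m <- if (what == "height") x$height_um else x$roughness_um
  if (is.null(m)) stop("roughness not computed; run roughness_map() first")
  graphics::image(t(m), useRaster = TRUE, asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = paste0(what, " (um)"), ...)
  invisible(x)
}
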