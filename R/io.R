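## Image and table I/O. TIFF is the single image dialect; spacing, channel
## names, dtype and shape travel in a JSON sidecar next to the TIFF because
## intensities must survive round-trips untouched ("unprocessed fluorescence
## intensities") and no rescaling may ever happen implicitly.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack or binary mask as multi-page TIFF
#'
#' Pages are written z-major within channel (all z of channel 1, then all z
#' of channel 2, ...). Integer data (uint8/uint16) round-trip bit-exactly;
#' float data are stored as 32-bit float with a recorded scale/offset.
#' Boolean masks are written as 8-bit \{0, 255\}. Voxel spacing and channel
#' names are recorded in a JSON sidecar (\code{<path>.json}).
#'
#' @param stack an \code{image_stack} or \code{binary_mask}.
#' @param path output TIFF path.
#' @param dtype one of "uint8", "uint16", "float32" or "auto" (integer data
#'   in range are stored as the narrowest lossless integer type).
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, dtype = "auto") {
  if (inherits(stack, "binary_mask")) {
    v <- array(as.numeric(stack$voxels) * 255, c(1, dim(stack$voxels)))
    stack <- image_stack(v, rep(stack$spacing_um, 3), "mask")
    dtype <- "uint8"
  }
  if (!inherits(stack, "image_stack")) stop("write_stack expects an image_stack or binary_mask")
  v <- stack$voxels
  if (identical(dtype, "auto")) {
    integral <- all(v == round(v)) && min(v) >= 0
    dtype <- if (integral && max(v) <= 255) "uint8"
             else if (integral && max(v) <= 65535) "uint16"
             else "float32"
  }
  d <- dim(v)
  scale <- 1; offset <- 0
  pages <- vector("list", d[1] * d[2])
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L,
                 stop("unknown dtype '", dtype, "'"))
  if (dtype == "float32") {
    offset <- min(v)
    scale <- max(v) - offset
    if (scale == 0) scale <- 1
  } else {
    if (any(v != round(v)) || min(v) < 0 || max(v) > (2^bits - 1))
      stop("data do not fit dtype ", dtype, " losslessly")
    scale <- 2^bits - 1
  }
  p <- 0L
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    p <- p + 1L
    pg <- matrix(v[ch, z, , ], d[3], d[4])
    pages[[p]] <- (pg - offset) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- list(spacing_um = stack$spacing_um, channel_names = stack$channel_names,
               dtype = dtype, shape = d, scale = scale, offset = offset)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tiff_pages <- function(path, dtype) {
  pg <- tiff::readTIFF(path, all = TRUE, as.is = (dtype != "float32"))
  if (!is.list(pg)) pg <- list(pg)
  pg
}

#' Read an image stack from one or more TIFF files
#'
#' Accepts either one multi-channel TIFF written by \code{\link{write_stack}}
#' or one single-channel multi-page TIFF per channel (equal shapes). Spacing
#' is taken from the JSON sidecar when present; an explicit \code{spacing_um}
#' overrides it, and the absence of both is an error — never a silent
#' default. Integer pixel types are returned without rescaling.
#'
#' @param paths character vector of TIFF paths (one per channel, or a single
#'   multi-channel file).
#' @param spacing_um optional (z, y, x) spacing override in um.
#' @param channel_names optional channel names; required when no sidecar
#'   names them.
#' @return An \code{image_stack}.
#' @export
read_stack <- function(paths, spacing_um = NULL, channel_names = NULL) {
  metas <- lapply(paths, function(p) {
    sp <- sidecar_path(p)
    if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
  })
  if (is.null(spacing_um)) {
    spaced <- Filter(Negate(is.null), lapply(metas, `[[`, "spacing_um"))
    if (length(spaced) == 0)
      stop("voxel spacing unknown: pass spacing_um or provide the JSON sidecar")
    spacing_um <- spaced[[1]]
  }
  arrays <- list(); names_acc <- character()
  for (i in seq_along(paths)) {
    meta <- metas[[i]]
    dtype <- meta$dtype %||% "uint16"
    pg <- read_tiff_pages(paths[[i]], dtype)
    sh <- meta$shape %||% c(1L, length(pg), nrow(pg[[1]]), ncol(pg[[1]]))
    if (length(pg) != sh[1] * sh[2]) stop("page count does not match sidecar shape in ", paths[[i]])
    a <- array(0, sh)
    p <- 0L
    for (ch in seq_len(sh[1])) for (z in seq_len(sh[2])) {
      p <- p + 1L
      a[ch, z, , ] <- pg[[p]]
    }
    if (dtype == "float32") a <- a * (meta$scale %||% 1) + (meta$offset %||% 0)
    arrays[[i]] <- a
    names_acc <- c(names_acc, meta$channel_names %||% rep(NA_character_, sh[1]))
  }
  shapes <- vapply(arrays, function(a) paste(dim(a)[2:4], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("channel files have mismatched shapes: ", paste(shapes, collapse = " vs "))
  v <- do.call(abind_channel, arrays)
  if (!is.null(channel_names)) names_acc <- channel_names
  if (anyNA(names_acc))
    stop("channel names unknown: pass channel_names or provide the JSON sidecar")
  if (length(names_acc) != dim(v)[1])
    stop("channel_names length does not match total channel count")
  image_stack(v, spacing_um, names_acc)
}

## rbind-like concatenation along the channel axis of 4-D arrays.
abind_channel <- function(...) {
  as <- list(...)
  if (length(as) == 1L) return(as[[1]])
  d <- dim(as[[1]])[2:4]
  ncs <- vapply(as, function(a) dim(a)[1], 0L)
  out <- array(0, c(sum(ncs), d))
  at <- 0L
  for (a in as) {
    for (ch in seq_len(dim(a)[1])) out[at + ch, , , ] <- a[ch, , , ]
    at <- at + dim(a)[1]
  }
  out
}

#' Read a TIFF mask written by \code{write_stack}
#'
#' @param path TIFF path (8-bit \{0, 255\} encoding).
#' @param spacing_um optional isotropic spacing override.
#' @return A \code{binary_mask}.
#' @export
read_mask <- function(path, spacing_um = NULL) {
  st <- read_stack(path, spacing_um = spacing_um, channel_names = "mask")
  sp <- st$spacing_um
  if (!is_isotropic(sp)) stop("mask file is not isotropic")
  binary_mask(channel_array(st, "mask") > 0, sp[1])
}

cube_table_columns <- c("cube_z", "cube_y", "cube_x", "occupancy_vox",
                        "com_z_um", "com_y_um", "com_x_um")

#' Write / read a cube table as CSV
#'
#' Delimited text with a header row; one row per occupied cube. Numeric
#' values round-trip to full double precision (written with 15 significant
#' digits).
#'
#' @param cubes a \code{cube_table} data frame.
#' @param path CSV path.
#' @return \code{write_cube_table}: the path, invisibly;
#'   \code{read_cube_table}: the \code{cube_table}.
#' @export
write_cube_table <- function(cubes, path) {
  utils::write.csv(as.data.frame(cubes), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cube_table
#' @export
read_cube_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(cube_table_columns, names(df))
  if (length(missing))
    stop("cube table at ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  class(df) <- c("cube_table", "data.frame")
  df
}
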