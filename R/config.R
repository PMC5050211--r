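## YAML run configuration. Every parameter has a typed default; unknown
## keys and type violations are collected and reported together (never
## first-failure), and an empty file yields the all-defaults config.

default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    paths = list(outdir = "biofilmcubes-out"),
    input = list(stacks = list(), spacing_um = NULL, channel_names = NULL,
                 events = NULL, control = NULL),
    segmentation = list(smooth_radius = 1L, bins = 256L,
                        segment_channels = list("constitutive")),
    quantification = list(cube_side_vox = 5L, density_radius_um = 3.0,
                          roughness_window_px = 11L, z_bin_um = 2.0,
                          density_bin = 0.05, min_occupancy = 1L,
                          reference_channel = "constitutive"),
    cytometry = list(cofactor = 150, threshold = "auto", channel = "reporter"),
    synthetic = list(
      enabled = TRUE,
      domain_size_um = c(64, 64, 64),
      channels = list("constitutive", "curli", "flagella"),
      scene = unclass(scene_params()),
      optics = unclass(optics_params())[
        setdiff(names(unclass(optics_params())), "seed")],
      mixture = unclass(mixture_params())[
        setdiff(names(unclass(mixture_params())), "seed")]
    )
  )
}

## recursive merge of user values over defaults; unknown keys and type
## mismatches are appended to `errs` (by reference through an environment)
merge_config <- function(def, usr, path, errs) {
  if (is.null(usr)) return(def)
  if (!is.list(usr)) {
    errs$msgs <- c(errs$msgs, paste0(path, ": expected a mapping, got a scalar"))
    return(def)
  }
  unknown <- setdiff(names(usr), names(def))
  if (length(unknown))
    errs$msgs <- c(errs$msgs, paste0(path, ": unknown key(s): ",
                                     paste(unknown, collapse = ", ")))
  for (k in intersect(names(usr), names(def))) {
    dv <- def[[k]]; uv <- usr[[k]]
    kp <- paste0(path, "/", k)
    if (is.list(dv) && !is.null(names(dv)) && length(dv)) {
      def[[k]] <- merge_config(dv, uv, kp, errs)
    } else {
      def[k] <- list(uv)   # preserves NULL assignments
    }
  }
  def
}

check_types <- function(cfg, errs) {
  num_pos <- function(x, nm, strict = TRUE) {
    x <- unlist(x)
    if (!is.numeric(x) || any(!is.finite(x)) ||
        (strict && any(x <= 0)) || (!strict && any(x < 0)))
      errs$msgs <- c(errs$msgs, paste0(nm, " must be ",
                                       if (strict) "positive" else "nonnegative",
                                       " numeric"))
  }
  num_pos(cfg$quantification$cube_side_vox, "quantification/cube_side_vox")
  num_pos(cfg$quantification$density_radius_um, "quantification/density_radius_um")
  num_pos(cfg$quantification$roughness_window_px, "quantification/roughness_window_px")
  num_pos(cfg$quantification$z_bin_um, "quantification/z_bin_um")
  num_pos(cfg$segmentation$smooth_radius, "segmentation/smooth_radius", strict = FALSE)
  num_pos(cfg$segmentation$bins, "segmentation/bins")
  num_pos(cfg$cytometry$cofactor, "cytometry/cofactor")
  num_pos(cfg$synthetic$domain_size_um, "synthetic/domain_size_um")
  probs <- c("p_curli_given_aggregate", "p_curli_given_single",
             "epsilon_double", "p_sigmaS_high_given_curli_off")
  for (p in probs) {
    v <- cfg$synthetic$scene[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      errs$msgs <- c(errs$msgs, paste0("synthetic/scene/", p,
                                       " must be a probability in [0, 1]"))
  }
  fo <- cfg$synthetic$mixture$f_on
  if (!is.numeric(fo) || fo < 0 || fo > 1)
    errs$msgs <- c(errs$msgs, "synthetic/mixture/f_on must be a probability in [0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errs$msgs <- c(errs$msgs, "seed must be a single integer")
  invisible(NULL)
}

#' Validate a YAML run configuration
#'
#' Parses the file, fills documented defaults, rejects unknown keys and
#' reports all type violations together. An empty (or absent-key) file is
#' the all-defaults configuration.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A validated configuration list of class \code{run_config}.
#' @export
validate_config <- function(path = NULL) {
  usr <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    usr <- yaml::read_yaml(path)
  }
  errs <- new.env(); errs$msgs <- character()
  cfg <- merge_config(default_config(), usr, "config", errs)
  check_types(cfg, errs)
  if (length(errs$msgs))
    stop("invalid configuration:\n  - ",
         paste(errs$msgs, collapse = "\n  - "))
  class(cfg) <- c("run_config", "list")
  cfg
}
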