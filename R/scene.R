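## Ground-truthed synthetic biofilm scenes. A scene emulates the structure
## of a static submerged E. coli biofilm: dense cell aggregates/microcolonies
## concentrated in the lower tens of micrometres (curli-ON dominated), motile
## flagella-ON single cells dispersed through the volume, an optional
## pellicle slab at the liquid-air interface, a sigma-S activity level only
## partially correlated with the curli state, and per-class TIMER
## orange/green ratios encoding slow aggregate growth. Every stochastic
## choice is driven by one seed so identical (params, seed) reproduce an
## identical scene.

#' Scene generator parameters
#'
#' Defaults describe the default study condition: three subpopulations —
#' flagella-ON motile singles, curli-ON aggregated cells, and stationary
#' cells expressing neither — with mutually exclusive curli/flagella
#' expression (\code{epsilon_double = 0}), aggregates confined below
#' \code{aggregate_zmax_um}, and slow-growing aggregates
#' (TIMER orange/green ratio 2.0 vs 0.5 for singles). No quantitative
#' aggregate size or count distribution is available to match, so
#' \code{n_aggregates}, \code{cells_per_aggregate} and
#' \code{aggregate_radius_um} are explicitly configurable placeholders.
#'
#' @param n_single number of dispersed single cells.
#' @param n_aggregates number of aggregates/microcolonies.
#' @param cells_per_aggregate cells packed into each aggregate.
#' @param aggregate_radius_um aggregate packing radius (um).
#' @param p_curli_given_aggregate P(curli ON | aggregate or pellicle cell).
#' @param p_curli_given_single P(curli ON | single cell).
#' @param epsilon_double probability a cell is forced double-positive
#'   (curli AND flagella); 0 gives strictly exclusive expression.
#' @param rho_sigmaS coupling in [-1, 1] between curli state and sigma-S
#'   activity; 1 makes every curli-ON cell sigma-S-high.
#' @param p_sigmaS_high_given_curli_off P(sigma-S high | curli OFF) — the
#'   sigma-S-positive/curli-negative subpopulation.
#' @param timer_ratio_aggregate,timer_ratio_single TIMER orange/green ratio
#'   per class (slow growers accumulate orange).
#' @param pellicle add a pellicle slab at the top of the domain.
#' @param n_pellicle pellicle cell count (used when \code{pellicle}).
#' @param pellicle_thickness_um pellicle slab thickness (um).
#' @param aggregate_zmax_um aggregate centres are placed below this height.
#' @param cell_radii_um spheroid semi-axes (z, y, x) in um; the default
#'   0.5 x 0.5 x 1.0 approximates a rod-shaped bacterium lying flat.
#' @return A list of class \code{scene_params}.
#' @export
scene_params <- function(n_single = 300L,
                         n_aggregates = 12L,
                         cells_per_aggregate = 80L,
                         aggregate_radius_um = 3.5,
                         p_curli_given_aggregate = 0.9,
                         p_curli_given_single = 0.05,
                         epsilon_double = 0,
                         rho_sigmaS = 0.9,
                         p_sigmaS_high_given_curli_off = 0.3,
                         timer_ratio_aggregate = 2.0,
                         timer_ratio_single = 0.5,
                         pellicle = FALSE,
                         n_pellicle = 200L,
                         pellicle_thickness_um = 3,
                         aggregate_zmax_um = 40,
                         cell_radii_um = c(0.5, 0.5, 1.0)) {
  p <- list(n_single = as.integer(n_single),
            n_aggregates = as.integer(n_aggregates),
            cells_per_aggregate = as.integer(cells_per_aggregate),
            aggregate_radius_um = aggregate_radius_um,
            p_curli_given_aggregate = p_curli_given_aggregate,
            p_curli_given_single = p_curli_given_single,
            epsilon_double = epsilon_double,
            rho_sigmaS = rho_sigmaS,
            p_sigmaS_high_given_curli_off = p_sigmaS_high_given_curli_off,
            timer_ratio_aggregate = timer_ratio_aggregate,
            timer_ratio_single = timer_ratio_single,
            pellicle = isTRUE(pellicle),
            n_pellicle = as.integer(n_pellicle),
            pellicle_thickness_um = pellicle_thickness_um,
            aggregate_zmax_um = aggregate_zmax_um,
            cell_radii_um = as.numeric(cell_radii_um))
  probs <- c("p_curli_given_aggregate", "p_curli_given_single",
             "epsilon_double", "p_sigmaS_high_given_curli_off")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be a probability in [0, 1]")
  if (p$rho_sigmaS < -1 || p$rho_sigmaS > 1) stop("rho_sigmaS must lie in [-1, 1]")
  if (p$n_single < 0 || p$n_aggregates < 0 || p$cells_per_aggregate < 0)
    stop("counts must be nonnegative")
  structure(p, class = "scene_params")
}

#' Generate a ground-truthed biofilm scene
#'
#' Cell positions: singles uniform in the domain interior, aggregate members
#' uniform within \code{aggregate_radius_um} of cluster centres placed
#' uniformly below \code{aggregate_zmax_um}, pellicle cells uniform in a
#' slab just below the top of the domain. Expression states are drawn per
#' \code{\link{scene_params}}; the full ground truth is retained.
#'
#' @param params a \code{scene_params} object.
#' @param domain_size_um (z, y, x) physical extent of the domain in um.
#' @param seed integer seed; identical (params, seed) give identical scenes.
#' @return A list of class \code{scene} with elements \code{cells} (one row
#'   per cell), \code{domain_size_um}, \code{pellicle_z_um}, \code{params}
#'   and \code{seed}.
#' @export
generate_scene <- function(params = scene_params(),
                           domain_size_um = c(64, 64, 64),
                           seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  D <- as.numeric(domain_size_um)
  r_agg <- params$aggregate_radius_um
  if (params$n_aggregates > 0L) {
    zmax <- min(params$aggregate_zmax_um, D[1])
    if (2 * r_agg > min(zmax, D[2], D[3]))
      stop("impossible packing: aggregate diameter ", 2 * r_agg,
           " um exceeds the placement region")
    v_agg <- params$n_aggregates * 4 / 3 * pi * r_agg^3
    if (v_agg > 0.5 * prod(D))
      stop("impossible packing: requested aggregate volume (", round(v_agg),
           " um^3) exceeds half the domain volume")
  }
  set.seed(as.integer(seed))
  margin <- max(params$cell_radii_um)

  runif3 <- function(n, lo, hi) {
    cbind(z = stats::runif(n, lo[1], hi[1]),
          y = stats::runif(n, lo[2], hi[2]),
          x = stats::runif(n, lo[3], hi[3]))
  }
  pos <- NULL; cls <- character()

  centers <- NULL
  if (params$n_aggregates > 0L) {
    zmax <- min(params$aggregate_zmax_um, D[1])
    centers <- runif3(params$n_aggregates, rep(r_agg, 3),
                      c(zmax - r_agg, D[2] - r_agg, D[3] - r_agg))
  }
  if (params$n_single > 0L) {
    ## singles occupy the free volume: a dispersed cell cannot sit inside a
    ## packed aggregate, so resample draws landing within one cell length
    ## of an aggregate ball
    clearance <- r_agg + margin
    p <- runif3(params$n_single, rep(margin, 3), D - margin)
    if (!is.null(centers)) {
      for (iter in 1:100) {
        d2 <- sapply(seq_len(nrow(centers)), function(k)
          rowSums(sweep(p, 2, centers[k, ], `-`)^2))
        bad <- apply(matrix(d2, nrow(p)) < clearance^2, 1, any)
        if (!any(bad)) break
        p[bad, ] <- runif3(sum(bad), rep(margin, 3), D - margin)
      }
    }
    pos <- rbind(pos, p)
    cls <- c(cls, rep("single", params$n_single))
  }
  if (params$n_aggregates > 0L) {
    for (k in seq_len(params$n_aggregates)) {
      n <- params$cells_per_aggregate
      ## uniform in the ball of radius r_agg
      u <- matrix(stats::rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- r_agg * stats::runif(n)^(1 / 3)
      p <- sweep(u * rad, 2, centers[k, ], `+`)
      p <- pmin(pmax(p, margin), matrix(D - margin, n, 3, byrow = TRUE))
      colnames(p) <- c("z", "y", "x")
      pos <- rbind(pos, p)
      cls <- c(cls, rep("aggregate", n))
    }
  }
  pellicle_z <- NULL
  if (params$pellicle && params$n_pellicle > 0L) {
    th <- params$pellicle_thickness_um
    pos <- rbind(pos, runif3(params$n_pellicle,
                             c(D[1] - th, margin, margin),
                             c(D[1] - margin, D[2] - margin, D[3] - margin)))
    cls <- c(cls, rep("pellicle", params$n_pellicle))
    pellicle_z <- D[1] - th / 2
  }
  n <- length(cls)
  if (n == 0L) {
    cells <- data.frame(center_z_um = numeric(), center_y_um = numeric(),
                        center_x_um = numeric(), class = character(),
                        curli_on = logical(), flagella_on = logical(),
                        sigmaS_level = numeric(), timer_green = numeric(),
                        timer_orange = numeric())
  } else {
    p_curli <- ifelse(cls == "single", params$p_curli_given_single,
                      params$p_curli_given_aggregate)
    curli <- stats::runif(n) < p_curli
    ## flagella mark motile non-curli singles; aggregated / pellicle
    ## curli-OFF cells are the stationary OFF/OFF subpopulation
    flagella <- !curli & cls == "single"
    if (params$epsilon_double > 0) {
      dp <- stats::runif(n) < params$epsilon_double
      curli[dp] <- TRUE
      flagella[dp] <- TRUE
    }
    p_off <- params$p_sigmaS_high_given_curli_off
    rho <- params$rho_sigmaS
    p_on <- if (rho >= 0) p_off + rho * (1 - p_off) else p_off * (1 + rho)
    sig_high <- stats::runif(n) < ifelse(curli, p_on, p_off)
    sigmaS <- ifelse(sig_high, 1, 0)
    ratio <- ifelse(cls == "single", params$timer_ratio_single,
                    params$timer_ratio_aggregate)
    cells <- data.frame(center_z_um = pos[, "z"], center_y_um = pos[, "y"],
                        center_x_um = pos[, "x"], class = cls,
                        curli_on = curli, flagella_on = flagella,
                        sigmaS_level = sigmaS,
                        timer_green = 1, timer_orange = ratio)
  }
  structure(list(cells = cells, domain_size_um = D,
                 pellicle_z_um = pellicle_z, params = params,
                 seed = as.integer(seed)),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ", nrow(x$cells), " cells in ",
      paste(format(x$domain_size_um), collapse = " x "), " um (seed ",
      x$seed, ")\n", sep = "")
  if (nrow(x$cells)) print(table(x$cells$class))
  invisible(x)
}

#' Ground-truth summary of a scene
#'
#' The recovery targets for end-to-end tests: per-class cell counts,
#' per-reporter ON fractions, the double-positive fraction, and per-class
#' mean TIMER orange/green ratios.
#'
#' @param scene a \code{scene}.
#' @return A list of class \code{scene_truth}.
#' @export
scene_truth_summary <- function(scene) {
  cl <- scene$cells
  cls <- table(cl$class)
  ratio_by_class <- if (nrow(cl))
    tapply(cl$timer_orange / cl$timer_green, cl$class, mean) else numeric()
  structure(list(
    n_cells = nrow(cl),
    class_counts = cls,
    frac_curli_on = if (nrow(cl)) mean(cl$curli_on) else NA_real_,
    frac_flagella_on = if (nrow(cl)) mean(cl$flagella_on) else NA_real_,
    frac_sigmaS_high = if (nrow(cl)) mean(cl$sigmaS_level > 0.5) else NA_real_,
    frac_double_positive = if (nrow(cl)) mean(cl$curli_on & cl$flagella_on) else NA_real_,
    frac_sigmaS_only = if (nrow(cl)) mean(cl$sigmaS_level > 0.5 & !cl$curli_on) else NA_real_,
    mean_timer_ratio_by_class = ratio_by_class
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", x$n_cells, " cells\n", sep = "")
  print(x$class_counts)
  cat("ON fractions: curli ", format(x$frac_curli_on, digits = 3),
      ", flagella ", format(x$frac_flagella_on, digits = 3),
      ", sigmaS-high ", format(x$frac_sigmaS_high, digits = 3),
      ", double+ ", format(x$frac_double_positive, digits = 3), "\n", sep = "")
  if (length(x$mean_timer_ratio_by_class)) {
    cat("mean TIMER orange/green by class:\n")
    print(x$mean_timer_ratio_by_class)
  }
  invisible(x)
}

#' Write scene ground truth as CSV
#'
#' @param scene a \code{scene}.
#' @param path CSV path; one row per cell.
#' @return The path, invisibly.
#' @export
write_scene_truth <- function(scene, path) {
  utils::write.csv(scene$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
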