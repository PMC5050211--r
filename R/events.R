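## Flow-cytometry-like event tables drawn from a two-component ON/OFF
## mixture. OFF events come from a signed Gaussian centred near zero (the
## scale left after background subtraction, where negative values are
## legitimate); ON events come from a log-normal component, mimicking the
## bimodal reporter distributions seen in biofilm fractions.

#' ON/OFF mixture parameters
#'
#' @param f_on probability an event is ON.
#' @param mu_off,sd_off location/scale of the OFF component on the signed,
#'   background-subtracted intensity scale.
#' @param mu_on,sd_on log-domain location/scale of the ON component (values
#'   are exponentiated).
#' @param n_events number of events.
#' @param channel channel name for the value column.
#' @param seed integer seed.
#' @return A list of class \code{mixture_params}.
#' @export
mixture_params <- function(f_on = 0.30, mu_off = 0, sd_off = 30,
                           mu_on = log(1000), sd_on = 0.4,
                           n_events = 50000L, channel = "reporter",
                           seed = 1L) {
  if (f_on < 0 || f_on > 1) stop("f_on must lie in [0, 1]")
  if (sd_off <= 0 || sd_on <= 0) stop("component scales must be > 0")
  if (n_events < 1) stop("n_events must be >= 1")
  structure(list(f_on = f_on, mu_off = mu_off, sd_off = sd_off,
                 mu_on = mu_on, sd_on = sd_on,
                 n_events = as.integer(n_events),
                 channel = channel, seed = as.integer(seed)),
            class = "mixture_params")
}

#' Generate a flow-cytometry-like event table
#'
#' @param mix a \code{mixture_params}.
#' @param fraction fraction label attached to every event (pellicle,
#'   supernatant or surface).
#' @param time_h time point in hours attached to every event.
#' @return A data frame of class \code{event_table} with the channel value
#'   column, \code{fraction}, \code{time_h} and the ground-truth
#'   \code{truth} label ("ON"/"OFF").
#' @export
generate_events <- function(mix = mixture_params(), fraction = "surface",
                            time_h = 24) {
  stopifnot(inherits(mix, "mixture_params"))
  set.seed(mix$seed)
  n <- mix$n_events
  on <- stats::runif(n) < mix$f_on
  v <- numeric(n)
  v[on] <- exp(stats::rnorm(sum(on), mix$mu_on, mix$sd_on))
  v[!on] <- stats::rnorm(sum(!on), mix$mu_off, mix$sd_off)
  df <- data.frame(v = v, fraction = fraction, time_h = time_h,
                   truth = ifelse(on, "ON", "OFF"))
  names(df)[1] <- mix$channel
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write / read event tables as CSV
#'
#' @param events an \code{event_table}.
#' @param path CSV path.
#' @return the path / the \code{event_table}.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  class(df) <- c("event_table", "data.frame")
  df
}
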