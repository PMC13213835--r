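#' Potential-energy time series
#'
#' Container for a uniformly sampled per-frame potential-energy trace, the
#' input of the proxy energy-landscape (MDDG) construction. Frames are
#' 0-based, times in ns, energies in kcal/mol.
#'
#' @param energy numeric vector of potential energies (kcal/mol), length >= 2,
#'   all finite.
#' @param time numeric vector of frame times (ns), uniformly spaced; defaults
#'   to `0, dt, 2 dt, ...`.
#' @param dt sampling interval (ns) used when `time` is not given.
#' @param frame integer frame indices; defaults to `0:(n-1)`.
#' @return An object of class `energy_series`: a data frame with columns
#'   `frame`, `time`, `energy` and attribute `dt`.
#' @examples
#' es <- energy_series(c(5, 1, 4, 0, 3, 2, 6))
#' es
#' @export
energy_series <- function(energy, time = NULL, dt = 1, frame = NULL) {
  energy <- as.numeric(energy)
  n <- length(energy)
  if (n < 2L) .stopf("an energy series needs at least 2 frames, got %d", n)
  if (!all(is.finite(energy))) .stopf("all energies must be finite")
  if (is.null(time)) {
    if (!is.finite(dt) || dt <= 0) .stopf("sampling interval dt must be > 0")
    time <- seq(0, by = dt, length.out = n)
  } else {
    time <- as.numeric(time)
    if (length(time) != n) .stopf("time and energy lengths differ")
    d <- diff(time)
    if (any(d <= 0)) .stopf("times must be strictly increasing")
    if (diff(range(d)) > 1e-9 * max(abs(d)))
      .stopf("times must be uniformly spaced (relative tolerance 1e-9)")
    dt <- mean(d)
  }
  if (is.null(frame)) frame <- 0:(n - 1L)
  out <- data.frame(frame = as.integer(frame), time = time, energy = energy)
  attr(out, "dt") <- dt
  class(out) <- c("energy_series", "data.frame")
  out
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %d frames, dt = %g ns, energy range [%.4g, %.4g] kcal/mol\n",
              nrow(x), attr(x, "dt"), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Read / write an energy series as CSV
#'
#' CSV dialect: comma separated, header `frame,time_ns,energy_kcal_mol`,
#' '.' decimal, UTF-8.
#'
#' @param path file path.
#' @return `read_energy_csv` returns an [energy_series()];
#'   `write_energy_csv` returns `path` invisibly.
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "time_ns", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    .stopf("energy CSV must have columns %s", paste(need, collapse = ","))
  energy_series(df$energy_kcal_mol, time = df$time_ns, frame = df$frame)
}

#' @param series an [energy_series()].
#' @rdname read_energy_csv
#' @export
write_energy_csv <- function(series, path) {
  stopifnot(inherits(series, "energy_series"))
  utils::write.csv(
    data.frame(frame = series$frame, time_ns = series$time,
               energy_kcal_mol = series$energy),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Order-parameter series for coloring disconnectivity graphs
#'
#' A non-negative per-frame scalar (e.g. the GAG RMSD to the first frame, in
#' Angstrom) defined on the same frame grid as the energy series it
#' annotates.
#'
#' @param value numeric vector, values >= 0.
#' @param frame integer frame indices, default `0:(n-1)`.
#' @return data frame of class `order_parameter_series` with columns
#'   `frame`, `value`.
#' @export
order_parameter_series <- function(value, frame = NULL) {
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value < 0))
    .stopf("order-parameter values must be finite and >= 0")
  if (is.null(frame)) frame <- 0:(length(value) - 1L)
  out <- data.frame(frame = as.integer(frame), value = value)
  class(out) <- c("order_parameter_series", "data.frame")
  out
}

#' @rdname order_parameter_series
#' @param path CSV path with header `frame,value_angstrom`.
#' @export
read_order_parameter_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "value_angstrom") %in% names(df)))
    .stopf("order-parameter CSV must have columns frame,value_angstrom")
  order_parameter_series(df$value_angstrom, frame = df$frame)
}

#' @rdname order_parameter_series
#' @param series an `order_parameter_series`.
#' @export
write_order_parameter_csv <- function(series, path) {
  utils::write.csv(
    data.frame(frame = series$frame, value_angstrom = series$value),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
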