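#' Umbrella-sampling window
#'
#' One biased simulation window along the COM-COM reaction coordinate:
#' restraint centre, harmonic force constant and the sampled coordinate
#' values.
#'
#' @param center restraint target (Angstrom).
#' @param force_constant harmonic force constant `k`
#'   (kcal mol^-1 Angstrom^-2), > 0. The production-scale setup uses windows
#'   spaced 1.0 Angstrom with k = 4.
#' @param samples numeric vector of reaction-coordinate samples (Angstrom),
#'   non-empty.
#' @return list of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples) {
  if (!is.finite(force_constant) || force_constant <= 0)
    .stopf("force_constant must be > 0")
  samples <- as.numeric(samples)
  if (!length(samples)) .stopf("window at %g has no samples", center)
  structure(list(center = center, force_constant = force_constant,
                 samples = samples),
            class = "umbrella_window")
}

#' WHAM analysis specification
#'
#' Binning, temperature and convergence settings of the weighted histogram
#' analysis. The defaults mirror a 20 Angstrom distance range divided into
#' 21 bins with a convergence tolerance of 0.01 kcal/mol.
#'
#' `bias_convention` states the restraint energy form: `"full-k"` means
#' `U_i(x) = k (x - x_i)^2` (AMBER-style restraints, the default),
#' `"half-k"` means `U_i(x) = k/2 (x - x_i)^2`; `half-k` with `k' = 2k`
#' is equivalent to `full-k` with `k`.
#'
#' @param n_bins number of bins (>= 2).
#' @param range length-2 numeric, reaction-coordinate range (Angstrom).
#' @param tolerance convergence tolerance on the window free-energy shifts
#'   (kcal/mol).
#' @param temperature K (WHAM beta).
#' @param bias_convention `"full-k"` or `"half-k"`.
#' @return list of class `wham_spec`.
#' @export
wham_spec <- function(n_bins = 21L, range = c(0, 20), tolerance = 0.01,
                      temperature = 298.15,
                      bias_convention = c("full-k", "half-k")) {
  bias_convention <- match.arg(bias_convention)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) .stopf("n_bins must be >= 2")
  if (length(range) != 2L || range[2] <= range[1]) .stopf("invalid range")
  if (tolerance <= 0) .stopf("tolerance must be > 0")
  if (temperature <= 0) .stopf("temperature must be > 0")
  structure(list(n_bins = n_bins, range = range, tolerance = tolerance,
                 temperature = temperature, bias_convention = bias_convention),
            class = "wham_spec")
}

#' Weighted histogram analysis of umbrella-sampling windows
#'
#' Self-consistent WHAM iteration over binned window histograms: the
#' unbiased bin probability is
#' `P(x_b) = sum_i n_i(x_b) / sum_i N_i exp(-beta (U_i(x_b) - f_i))` and
#' the window shifts are
#' `f_i = -kT log sum_b P(x_b) exp(-beta U_i(x_b))`, iterated until the
#' largest change in any `f_i` falls below the tolerance. The free energy
#' `-kT log P` is reported on populated bins, shifted so its minimum is 0.
#'
#' @param windows list of [umbrella_window()]s whose histograms jointly
#'   cover the range without an interior gap.
#' @param spec a [wham_spec()].
#' @param max_iter iteration cap.
#' @return object of class `pmf`: data frame `bin_center`, `free_energy`
#'   (kcal/mol, min 0), `count`, with attributes `f` (window shifts),
#'   `iterations`, `temperature`.
#' @export
wham_solve <- function(windows, spec = wham_spec(), max_iter = 1e5L) {
  stopifnot(inherits(spec, "wham_spec"))
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  kT <- .R_KCAL * spec$temperature
  beta <- 1 / kT
  kfac <- if (spec$bias_convention == "full-k") 1 else 0.5
  edges <- seq(spec$range[1], spec$range[2], length.out = spec$n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nw <- length(windows)
  nb <- spec$n_bins
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    inside <- s >= edges[1] & s <= edges[length(edges)]
    h <- findInterval(s[inside], edges, rightmost.closed = TRUE)
    counts[i, ] <- tabulate(h, nbins = nb)
  }
  pop <- colSums(counts) > 0
  if (!any(pop)) .stopf("no samples fall inside the WHAM range")
  ## an unsampled interior bin separating populated regions breaks WHAM
  ip <- which(pop)
  gap <- setdiff(seq(min(ip), max(ip)), ip)
  if (length(gap))
    .stopf("window histograms do not overlap: unsampled interior bin(s) at x = %s",
           paste(sprintf("%.3g", centers[gap]), collapse = ", "))
  Ni <- rowSums(counts)
  U <- matrix(0, nw, nb)
  for (i in seq_len(nw))
    U[i, ] <- kfac * windows[[i]]$force_constant * (centers - windows[[i]]$center)^2
  expU <- exp(-beta * U)
  f <- numeric(nw)
  nib <- colSums(counts)
  for (it in seq_len(max_iter)) {
    ef <- exp(beta * f)
    denom <- colSums((Ni * ef) * expU)          # sum_i N_i exp(-beta(U - f))
    P <- nib / denom
    P[!pop] <- 0
    P <- P / sum(P)
    fnew <- -kT * log(as.numeric(expU %*% P))
    fnew <- fnew - mean(fnew)          # gauge: permutation-invariant
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < spec$tolerance) break
  }
  if (delta >= spec$tolerance)
    .stopf("WHAM failed to converge after %d iterations (residual %.3g kcal/mol)",
           max_iter, delta)
  Fb <- -kT * log(P[pop])
  Fb <- Fb - min(Fb)
  out <- data.frame(bin_center = centers[pop], free_energy = Fb,
                    count = nib[pop])
  attr(out, "f") <- f
  attr(out, "iterations") <- it
  attr(out, "temperature") <- spec$temperature
  class(out) <- c("pmf", "data.frame")
  out
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("<pmf> %d populated bins over [%.3g, %.3g] A, max %.3g kcal/mol (%d WHAM iterations)\n",
              nrow(x), min(x$bin_center), max(x$bin_center),
              max(x$free_energy), attr(x, "iterations")))
  invisible(x)
}

#' @export
plot.pmf <- function(x, ...) {
  graphics::plot(x$bin_center, x$free_energy, type = "b", pch = 16,
                 xlab = "COM-COM distance (A)",
                 ylab = "free energy (kcal/mol)", ...)
  invisible(x)
}

#' Dissociation free energy from a PMF
#'
#' Free energy of the dissociated plateau, read as the mean of the last
#' `n_plateau` populated bins of the (min-shifted) profile.
#'
#' @param pmf a [wham_solve()] result.
#' @param n_plateau number of tail bins averaged (default 3).
#' @return kcal/mol.
#' @export
dissociation_free_energy <- function(pmf, n_plateau = 3L) {
  stopifnot(inherits(pmf, "pmf"))
  nb <- nrow(pmf)
  if (nb < 2L) .stopf("PMF must have >= 2 populated bins")
  if (n_plateau < 1L || n_plateau > nb)
    .stopf("plateau of %d bins not available (%d populated)", n_plateau, nb)
  mean(pmf$free_energy[(nb - n_plateau + 1L):nb])
}

#' Standard binding free energy from a dissociation constant
#'
#' `dG = R T log(K_D / c0)` with the standard concentration `c0 = 1 M` and
#' `R = 1.98720425e-3 kcal mol^-1 K^-1`; negative for sub-molar `K_D`.
#'
#' @param K_D dissociation constant (molar), > 0.
#' @param temperature K, > 0 (default 298.15).
#' @return kcal/mol.
#' @examples
#' delta_g_from_kd(1100e-9)  # about -8.1
#' delta_g_from_kd(10e-9)    # about -10.9
#' @export
delta_g_from_kd <- function(K_D, temperature = 298.15) {
  if (any(!is.finite(K_D)) || any(K_D <= 0)) .stopf("K_D must be > 0")
  if (!is.finite(temperature) || temperature <= 0) .stopf("temperature must be > 0")
  .R_KCAL * temperature * log(K_D / 1)
}

#' Read / write umbrella windows as per-window CSVs with a manifest
#'
#' The manifest is a CSV with columns `center`, `force_constant`, `file`;
#' each window file is a one-column CSV `x_angstrom`. Paths in the
#' manifest are taken relative to its directory.
#'
#' @param manifest_path manifest CSV path.
#' @return list of [umbrella_window()]s.
#' @export
read_umbrella_windows <- function(manifest_path) {
  man <- utils::read.csv(manifest_path)
  need <- c("center", "force_constant", "file")
  if (!all(need %in% names(man)))
    .stopf("window manifest needs columns %s", paste(need, collapse = ","))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.csv(file.path(base, man$file[i]))
    umbrella_window(man$center[i], man$force_constant[i], df$x_angstrom)
  })
}

#' @rdname read_umbrella_windows
#' @param windows list of [umbrella_window()]s.
#' @param dir output directory (created if needed).
#' @return `write_umbrella_windows` returns the manifest path invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.csv", seq_along(windows))
  for (i in seq_along(windows))
    utils::write.csv(data.frame(x_angstrom = windows[[i]]$samples),
                     file.path(dir, files[i]), row.names = FALSE, quote = FALSE)
  man <- data.frame(center = vapply(windows, `[[`, numeric(1), "center"),
                    force_constant = vapply(windows, `[[`, numeric(1), "force_constant"),
                    file = files)
  path <- file.path(dir, "windows_manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PMF as CSV
#'
#' Columns `bin_center`, `free_energy`, `count`.
#'
#' @param pmf a `pmf` object.
#' @param path output path.
#' @export
write_pmf_csv <- function(pmf, path) {
  utils::write.csv(as.data.frame(pmf), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
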