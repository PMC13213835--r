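#' Basin-hopping model for synthetic energy traces
#'
#' Markov-chain model of an MD potential-energy time series that hops
#' between Gaussian basins, emulating the production-scale regime of 1000
#' frames at 1 ns spacing: each basin has a mean energy and within-basin
#' standard deviation, dwell times are geometric with the given means, and
#' a positive barrier spike is added at switch frames.
#'
#' @param means basin mean energies (kcal/mol).
#' @param sds within-basin standard deviations (>= 0), recycled.
#' @param transition optional row-stochastic per-frame transition matrix
#'   (diagonal = stay probability); when given it overrides the dwell
#'   parameterization.
#' @param dwell mean dwell times in frames (>= 1), recycled. Dwells are
#'   `min_dwell - 1` plus a geometric variable with matching mean; with
#'   `min_dwell = 1` this is the plain Markov-chain geometric dwell.
#' @param min_dwell guaranteed minimum dwell in frames (`1 <= min_dwell <=
#'   dwell`); use >= 5 to keep every visit resolvable after the default
#'   5-frame smoothing.
#' @param spike barrier offset (kcal/mol, >= 0) added at the frame where a
#'   basin switch occurs.
#' @return list of class `basin_model`.
#' @export
basin_model <- function(means, sds = 0.2, transition = NULL, dwell = 20,
                        min_dwell = 1L, spike = 8) {
  nb <- length(means)
  sds <- rep_len(sds, nb)
  if (any(sds < 0)) .stopf("sds must be >= 0")
  dwell <- rep_len(dwell, nb)
  if (any(dwell < 1)) .stopf("dwell must be >= 1 frame")
  min_dwell <- as.integer(min_dwell)
  if (min_dwell < 1L || any(min_dwell > dwell))
    .stopf("min_dwell must satisfy 1 <= min_dwell <= dwell")
  mode <- if (is.null(transition)) "dwell" else "markov"
  if (mode == "markov") {
    if (min_dwell > 1L)
      .stopf("min_dwell > 1 requires the dwell parameterization, not a transition matrix")
    if (!all(abs(rowSums(transition) - 1) < 1e-9))
      .stopf("transition matrix rows must sum to 1")
  }
  if (spike < 0) .stopf("spike must be >= 0")
  structure(list(means = means, sds = sds, transition = transition,
                 dwell = dwell, min_dwell = min_dwell, spike = spike,
                 mode = mode),
            class = "basin_model")
}

#' Generate a basin-hopping energy series with known labels
#'
#' Samples a Markov basin sequence from the model, adds Gaussian
#' within-basin noise, and places the positive barrier spike on each
#' switch frame. Fully reproducible from the seed; the caller's RNG state
#' is left untouched.
#'
#' @param model a [basin_model()].
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param dt sampling interval in ns.
#' @return list with `series` (an [energy_series()]), `labels` (basin
#'   index per frame) and `n_visits` (number of dwell segments, i.e.
#'   1 + number of switches).
#' @export
gen_basin_energy_series <- function(model, n_frames, seed = 1L, dt = 1) {
  stopifnot(inherits(model, "basin_model"), n_frames >= 2L)
  nb <- length(model$means)
  .with_seed(seed, {
    lab <- integer(n_frames)
    if (model$mode == "markov") {
      lab[1] <- 1L
      for (f in 2L:n_frames)
        lab[f] <- sample.int(nb, 1L, prob = model$transition[lab[f - 1L], ])
    } else {
      ## dwell-block construction: dwell = min_dwell - 1 + geometric with
      ## matching mean; uniform jumps between distinct basins
      state <- 1L; pos <- 0L
      while (pos < n_frames) {
        p <- 1 / (model$dwell[state] - model$min_dwell + 1)
        len <- model$min_dwell + stats::rgeom(1L, p)
        len <- min(len, n_frames - pos)
        lab[(pos + 1L):(pos + len)] <- state
        pos <- pos + len
        state <- if (nb > 1L) sample(setdiff(seq_len(nb), state), 1L) else state
      }
    }
    e <- model$means[lab] + stats::rnorm(n_frames, 0, model$sds[lab])
    switch_frame <- c(FALSE, diff(lab) != 0)
    e[switch_frame] <- e[switch_frame] + model$spike
    list(series = energy_series(e, dt = dt),
         labels = lab,
         n_visits = 1L + sum(switch_frame))
  })
}

#' Generate six-membered-ring coordinates of a canonical conformer
#'
#' Inverts the Cremer-Pople construction: the conformer's canonical
#' `(theta, phi)` position (from [conformer_table()]) is converted to
#' out-of-plane displacements
#' `z_j = sqrt(1/3) q2 cos(phi + 120 j) + sqrt(1/6) q3 (-1)^j` on a
#' regular ring of 1.52 Angstrom bonds. With `angular_noise > 0` the
#' sphere position of each frame is jittered by Gaussian noise on
#' `(theta, phi)`. At zero noise [cremer_pople()] recovers the requested
#' `(Q, theta, phi)` to below 1e-6.
#'
#' @param conformer canonical label (e.g. `"4C1"`, `"1C4"`, `"2SO"`).
#' @param Q puckering amplitude (Angstrom), > 0.
#' @param angular_noise sd of the per-frame `(theta, phi)` jitter (deg).
#' @param n_frames number of frames.
#' @param seed integer seed (only consumed when `angular_noise > 0`).
#' @param bond_length planar ring bond length (Angstrom).
#' @return numeric array `6 x 3 x n_frames`, atom order O5, C1, ..., C5.
#' @export
gen_ring_coords <- function(conformer, Q = 0.55, angular_noise = 0,
                            n_frames = 1L, seed = 1L, bond_length = 1.52) {
  tab <- conformer_table()
  row <- tab[tab$label == conformer, ]
  if (nrow(row) != 1L) .stopf("unknown conformer label '%s'", conformer)
  if (Q <= 0) .stopf("Q must be > 0")
  .with_seed(if (angular_noise > 0) seed else NULL, {
    theta <- rep(row$theta, n_frames)
    phi <- rep(row$phi, n_frames)
    if (angular_noise > 0) {
      theta <- pmin(180, pmax(0, theta + stats::rnorm(n_frames, 0, angular_noise)))
      phi <- (phi + stats::rnorm(n_frames, 0, angular_noise)) %% 360
    }
    j <- 0:5
    ## clockwise regular hexagon so the CP normal is +z
    hex <- cbind(bond_length * cos(-2 * pi * j / 6),
                 bond_length * sin(-2 * pi * j / 6), 0)
    out <- array(NA_real_, c(6L, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      q2 <- Q * sin(theta[f] * pi / 180)
      q3 <- Q * cos(theta[f] * pi / 180)
      z <- sqrt(1 / 3) * q2 * cos((phi[f] + 120 * j) * pi / 180) +
        sqrt(1 / 6) * q3 * (-1)^j
      out[, , f] <- hex + cbind(0, 0, z)
    }
    out
  })
}

#' Generate a single-ring trajectory with a conformer mixture
#'
#' Builds an [md_trajectory()] of one annotated monosaccharide ring whose
#' frames are drawn from a mixture of canonical conformers, for testing
#' pucker-population recovery against known ground truth.
#'
#' @param conformers character vector of canonical labels.
#' @param weights mixture weights (recycled, normalized).
#' @param n_frames number of frames.
#' @param Q puckering amplitude (Angstrom).
#' @param angular_noise per-frame `(theta, phi)` jitter sd (deg).
#' @param seed integer seed.
#' @return list with `traj` (ring annotated as residue `"G:1"`) and
#'   `labels` (true conformer per frame).
#' @export
gen_ring_trajectory <- function(conformers, weights = 1, n_frames = 1000L,
                                Q = 0.55, angular_noise = 0, seed = 1L) {
  weights <- rep_len(weights, length(conformers))
  weights <- weights / sum(weights)
  .with_seed(seed, {
    pick <- sample.int(length(conformers), n_frames, replace = TRUE,
                       prob = weights)
    coords <- array(NA_real_, c(6L, 3L, n_frames))
    for (k in seq_along(conformers)) {
      idx <- which(pick == k)
      if (!length(idx)) next
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      coords[, , idx] <- gen_ring_coords(conformers[k], Q = Q,
                                         angular_noise = angular_noise,
                                         n_frames = length(idx),
                                         seed = sub_seed)
    }
    atoms <- data.frame(name = c("O5", "C1", "C2", "C3", "C4", "C5"),
                        element = c("O", "C", "C", "C", "C", "C"),
                        resno = 1L, resname = "SUG", chain = "G")
    traj <- annotate_rings(md_trajectory(coords, atoms))
    list(traj = traj, labels = conformers[pick])
  })
}

#' Stated double-well potential of mean force
#'
#' The package's reference ground-truth profile for WHAM validation on the
#' production-scale window layout (range 0-20 Angstrom): a bound well of depth
#' 5 kcal/mol at 5 Angstrom, a secondary well of depth 2 at 11 Angstrom,
#' and a flat dissociated plateau at 0.
#'
#' @param x reaction-coordinate values (Angstrom).
#' @return F(x) in kcal/mol.
#' @export
demo_double_well <- function(x) {
  -5 * exp(-(x - 5)^2 / 6) - 2 * exp(-(x - 11)^2 / 6)
}

#' Generate umbrella-window samples from a known free-energy profile
#'
#' Draws each window's samples from the exact biased density
#' `p_i(x) ~ exp(-beta (F(x) + kfac k (x - x_i)^2))` by inverse-CDF
#' sampling on a fine grid, so [wham_solve()] on the output should
#' recover `F` up to statistical and binning error.
#'
#' @param truth function F(x) in kcal/mol.
#' @param centers window centres (Angstrom); production-scale default is 21
#'   windows spaced 1.0 Angstrom.
#' @param k harmonic force constant (kcal mol^-1 Angstrom^-2).
#' @param n_per_window samples per window.
#' @param temperature K.
#' @param seed integer seed.
#' @param range sampling support; defaults to the window span extended by
#'   3 thermal widths.
#' @param bias_convention `"full-k"` (`U = k (x-x_i)^2`) or `"half-k"`.
#' @param grid_n grid resolution for the inverse CDF.
#' @return list of [umbrella_window()]s.
#' @export
gen_umbrella_samples <- function(truth, centers = 0:20, k = 4,
                                 n_per_window = 1e4, temperature = 298.15,
                                 seed = 1L, range = NULL,
                                 bias_convention = c("full-k", "half-k"),
                                 grid_n = 4001L) {
  bias_convention <- match.arg(bias_convention)
  stopifnot(is.function(truth), k > 0, n_per_window >= 1)
  kfac <- if (bias_convention == "full-k") 1 else 0.5
  beta <- 1 / (.R_KCAL * temperature)
  if (is.null(range)) {
    hw <- 3 / sqrt(2 * beta * kfac * k)
    range <- c(min(centers) - hw, max(centers) + hw)
  }
  xg <- seq(range[1], range[2], length.out = grid_n)
  Fg <- truth(xg)
  .with_seed(seed, {
    lapply(centers, function(ci) {
      u <- Fg + kfac * k * (xg - ci)^2
      w <- exp(-beta * (u - min(u)))
      if (!any(w > 0)) .stopf("biased density numerically zero everywhere at center %g", ci)
      cdf <- cumsum((w[-1] + w[-length(w)]) / 2 * diff(xg))
      cdf <- c(0, cdf) / cdf[length(cdf)]
      ## strictly increasing portion for inversion
      keep <- c(TRUE, diff(cdf) > 0)
      s <- stats::approx(cdf[keep], xg[keep], xout = stats::runif(n_per_window),
                         rule = 2)$y
      umbrella_window(ci, k, s)
    })
  })
}

#' Generate a pair of positive profiles with a target correlation
#'
#' Bivariate Gaussian construction emulating computed-vs-experimental
#' RMSF profile pairs: latent standard normals with population correlation
#' `target_pearson`, mapped to `mu + sigma z` and floored at a small
#' positive value (the floor triggers with probability ~1e-11 at the
#' defaults).
#'
#' @param n_res number of residues (>= 10).
#' @param target_pearson population Pearson correlation in (-1, 1).
#' @param seed integer seed.
#' @param mu,sigma location and scale of the profiles (Angstrom).
#' @return list of two [flex_profile()]s `x`, `y`.
#' @export
gen_correlated_profiles <- function(n_res, target_pearson, seed = 1L,
                                    mu = 1, sigma = 0.15) {
  if (n_res < 10L) .stopf("n_res must be >= 10")
  if (abs(target_pearson) >= 1) .stopf("target_pearson must be in (-1, 1)")
  .with_seed(seed, {
    z1 <- stats::rnorm(n_res)
    z2 <- target_pearson * z1 +
      sqrt(1 - target_pearson^2) * stats::rnorm(n_res)
    mk <- function(z) flex_profile(seq_len(n_res), pmax(mu + sigma * z, 1e-6))
    list(x = mk(z1), y = mk(z2))
  })
}
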