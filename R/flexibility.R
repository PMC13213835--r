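#' Per-residue flexibility profile
#'
#' A per-residue fluctuation vector (Angstrom), either computed from a
#' trajectory ([rmsf_profile()]) or derived from crystallographic
#' B-factors ([bfactor_to_rmsf()]). The unit of force-field-vs-experiment
#' comparison.
#'
#' @param resid residue identifiers (integer or character).
#' @param rmsf numeric vector of fluctuations (Angstrom), >= 0.
#' @param provenance `"computed"` or `"bfactor-derived"`.
#' @param normalized logical, `TRUE` after [normalize_profile()].
#' @return data frame of class `flex_profile` with columns `resid`, `rmsf`.
#' @export
flex_profile <- function(resid, rmsf, provenance = "computed",
                         normalized = FALSE) {
  rmsf <- as.numeric(rmsf)
  if (length(resid) != length(rmsf)) .stopf("resid and rmsf lengths differ")
  if (any(!is.finite(rmsf)) || any(rmsf < 0))
    .stopf("rmsf values must be finite and >= 0")
  out <- data.frame(resid = resid, rmsf = rmsf)
  attr(out, "provenance") <- provenance
  attr(out, "normalized") <- normalized
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' @export
print.flex_profile <- function(x, ...) {
  cat(sprintf("<flex_profile> %d residues, %s%s, mean %.4g A\n", nrow(x),
              attr(x, "provenance"),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else "",
              mean(x$rmsf)))
  invisible(x)
}

#' Root-mean-square fluctuations per residue
#'
#' Frames are superposed onto the first frame (Kabsch fit on
#' `fit_selection`), the time-average structure is computed, per-atom
#' fluctuations `sqrt(<|r - <r>|^2>)` are taken about that average, and
#' residues are summarized by the mass-weighted average
#' `sqrt(sum(m_a <dr_a^2>) / sum(m_a))` over their atoms in `selection`.
#'
#' @param traj an [md_trajectory()].
#' @param selection atoms contributing to the per-residue average
#'   (default all atoms).
#' @param fit_selection atoms used for the superposition fit; default
#'   C-alpha atoms, falling back to heavy atoms when absent.
#' @param superpose logical; set `FALSE` if frames are already aligned.
#' @return a [flex_profile()] in residue order of appearance; resid keys
#'   are `"chain:resno"`.
#' @export
rmsf_profile <- function(traj, selection = NULL, fit_selection = NULL,
                         superpose = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) {
    .warnf("single-frame trajectory: RMSF is identically zero")
    keys <- unique(.residue_key(traj$atoms))
    return(flex_profile(keys, rep(0, length(keys))))
  }
  if (superpose) {
    if (is.null(fit_selection)) {
      fit_selection <- "calpha"
      if (length(select_atoms(traj, fit_selection)) < 3L) fit_selection <- "heavy"
    }
    traj <- superpose(traj, 1L, fit_selection)
  }
  sel <- select_atoms(traj, selection)
  avg <- apply(traj$coords[sel, , , drop = FALSE], c(1, 2), mean)
  dev2 <- matrix(0, length(sel), nf)
  for (f in seq_len(nf))
    dev2[, f] <- rowSums((traj$coords[sel, , f, drop = TRUE] - avg)^2)
  msf <- rowMeans(dev2)                       # per-atom <dr^2>
  keys <- .residue_key(traj$atoms)[sel]
  m <- traj$atoms$mass[sel]
  ukeys <- unique(keys)
  rmsf <- vapply(ukeys, function(k) {
    i <- keys == k
    sqrt(sum(m[i] * msf[i]) / sum(m[i]))
  }, numeric(1))
  flex_profile(ukeys, rmsf)
}

#' Per-residue B-factor profile from a structure
#'
#' Mean of the atomic B column over each residue's atoms.
#'
#' @param traj an [md_trajectory()] read from a PDB with B-factors.
#' @param selection optional atom selection (default all atoms).
#' @return data frame of class `bfactor_profile` with columns `resid`, `B`
#'   (Angstrom^2).
#' @export
bfactor_profile <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(traj$atoms$b)) .stopf("trajectory carries no B-factors")
  sel <- select_atoms(traj, selection)
  keys <- .residue_key(traj$atoms)[sel]
  b <- traj$atoms$b[sel]
  ukeys <- unique(keys)
  B <- vapply(ukeys, function(k) mean(b[keys == k]), numeric(1))
  out <- data.frame(resid = ukeys, B = B)
  class(out) <- c("bfactor_profile", "data.frame")
  out
}

#' Convert B-factors to equivalent fluctuations
#'
#' Debye-Waller relation `RMSF = sqrt(3 B / (8 pi^2))`, giving the
#' isotropic fluctuation equivalent to a crystallographic B-factor.
#'
#' @param profile a [bfactor_profile()] or data frame with columns
#'   `resid`, `B` (Angstrom^2, >= 0).
#' @return a [flex_profile()] with provenance `"bfactor-derived"`.
#' @examples
#' bfactor_to_rmsf(data.frame(resid = 1, B = 8 * pi^2 / 3))  # 1 A
#' @export
bfactor_to_rmsf <- function(profile) {
  if (any(!is.finite(profile$B)) || any(profile$B < 0))
    .stopf("B-factors must be finite and >= 0")
  flex_profile(profile$resid, sqrt(3 * profile$B / (8 * pi^2)),
               provenance = "bfactor-derived")
}

#' Per-residue fluctuation of an NMR-style multi-model ensemble
#'
#' Experimental fluctuation profile for structures without B-factors:
#' the per-residue RMSF across ensemble models, computed by
#' [rmsf_profile()] with models treated as frames.
#'
#' @inheritParams rmsf_profile
#' @return a [flex_profile()] with provenance `"ensemble"`.
#' @export
ensemble_rmsf <- function(traj, selection = NULL, fit_selection = NULL) {
  p <- rmsf_profile(traj, selection = selection, fit_selection = fit_selection)
  attr(p, "provenance") <- "ensemble"
  p
}

#' Normalize a flexibility profile to unit Euclidean norm
#'
#' Divides each value by `sqrt(sum(rmsf^2))` so that the squared values
#' sum to 1. Pearson and Spearman correlations are invariant to this
#' rescaling.
#'
#' @param profile a [flex_profile()].
#' @return the normalized [flex_profile()].
#' @examples
#' normalize_profile(flex_profile(1:2, c(3, 4)))$rmsf  # 0.6 0.8
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "flex_profile"))
  nrm <- sqrt(sum(profile$rmsf^2))
  if (nrm == 0) .stopf("cannot normalize an all-zero profile")
  out <- flex_profile(profile$resid, profile$rmsf / nrm,
                      provenance = attr(profile, "provenance"),
                      normalized = TRUE)
  out
}

## align two profiles on their residue-id intersection; errors on mismatch
.align_profiles <- function(a, b, strict = TRUE) {
  ia <- match(a$resid, b$resid)
  unmatched_a <- a$resid[is.na(ia)]
  unmatched_b <- setdiff(b$resid, a$resid)
  if (strict && (length(unmatched_a) || length(unmatched_b)))
    .stopf("residue ids do not match; only in first: [%s]; only in second: [%s]",
           paste(unmatched_a, collapse = ","), paste(unmatched_b, collapse = ","))
  keep <- !is.na(ia)
  list(resid = a$resid[keep], x = a$rmsf[keep], y = b$rmsf[ia[keep]],
       unmatched = c(unmatched_a, unmatched_b))
}

#' Per-residue RMSF difference (bound minus unbound)
#'
#' @param bound,unbound [flex_profile()]s over the same residue ids.
#' @param strict error on residue-id mismatch (`TRUE`, listing the
#'   unmatched residues) or drop to the intersection with a warning.
#' @return data frame `resid`, `delta` (bound minus unbound, Angstrom).
#' @export
delta_rmsf <- function(bound, unbound, strict = TRUE) {
  al <- .align_profiles(bound, unbound, strict = strict)
  if (!strict && length(al$unmatched))
    .warnf("dropped unmatched residues: %s", paste(al$unmatched, collapse = ","))
  data.frame(resid = al$resid, delta = al$x - al$y)
}

#' Correlation coefficients between profiles
#'
#' `pearson` is the sample Pearson correlation; `spearman` is the Pearson
#' correlation of average-ranked values (ties receive mean ranks).
#'
#' @param x,y equal-length numeric vectors (or [flex_profile()]s, matched
#'   by residue id).
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  v <- .comparison_vectors(x, y)
  if (length(v$x) < 2L) .stopf("need at least 2 paired values")
  if (stats::sd(v$x) == 0 || stats::sd(v$y) == 0)
    .stopf("undefined correlation: zero variance")
  stats::cor(v$x, v$y, method = "pearson")
}

#' @rdname pearson
#' @export
spearman <- function(x, y) {
  v <- .comparison_vectors(x, y)
  if (length(v$x) < 2L) .stopf("need at least 2 paired values")
  if (stats::sd(v$x) == 0 || stats::sd(v$y) == 0)
    .stopf("undefined correlation: constant vector")
  stats::cor(v$x, v$y, method = "spearman")
}

.comparison_vectors <- function(x, y) {
  if (inherits(x, "flex_profile") && inherits(y, "flex_profile")) {
    al <- .align_profiles(x, y)
    list(x = al$x, y = al$y)
  } else list(x = as.numeric(x), y = as.numeric(y))
}

#' Paired Student's t test
#'
#' Two-sided paired t test on differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Thin wrapper over [stats::t.test()] returning the package's comparison
#' record.
#'
#' @param x,y paired numeric vectors.
#' @return object of class `paired_comparison`: list with `statistic`,
#'   `p.value`, `n`, `method`.
#' @export
paired_t_test <- function(x, y) {
  v <- .comparison_vectors(x, y)
  if (length(v$x) < 2L) .stopf("paired t test needs n >= 2")
  d <- v$x - v$y
  if (stats::sd(d) == 0) .stopf("degenerate paired t test: zero-variance differences")
  ht <- stats::t.test(v$x, v$y, paired = TRUE)
  structure(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                 n = length(v$x), method = "paired-t"),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: statistic = %.4f, p = %.4f, n = %d\n",
              x$method, x$statistic, x$p.value, x$n))
  invisible(x)
}

## exact null distribution of W+ for signed ranks r (possibly tied mean
## ranks): generating-function convolution over all 2^n sign assignments.
## Ranks are doubled so tied half-ranks become integers.
.signed_rank_null <- function(r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  p <- numeric(total + 1L)          # index k+1 <-> W2 = k
  p[1] <- 1
  for (rk in r2) {
    shifted <- c(rep(0, rk), p[seq_len(total + 1L - rk)])
    p <- (p + shifted) / 2
  }
  p                                  # P(2*W+ = k), k = 0..total
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `d = x - y` are ranked by `|d|` after dropping zeros
#' (mean ranks for ties); the statistic is `W = min(W+, W-)`. For
#' `n <= 25` (or `mode = "exact"`) the two-sided p-value is exact over all
#' `2^n` sign assignments, `p = min(1, 2 P(W+ <= W))`; larger samples use
#' the normal approximation with continuity and tie correction.
#'
#' @param x,y paired numeric vectors.
#' @param mode `"auto"` (exact up to n = 25), `"exact"`, or `"normal"`.
#' @return object of class `paired_comparison` with `statistic` (W),
#'   `p.value`, `n` (pairs after dropping zeros), `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 5), c(0, 0, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  v <- .comparison_vectors(x, y)
  d <- v$x - v$y
  nzero <- sum(d == 0)
  if (nzero) .warnf("dropping %d zero difference(s) before ranking", nzero)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) .stopf("degenerate Wilcoxon test: all differences zero")
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  wminus <- sum(r[d < 0])
  W <- min(wplus, wminus)
  exact <- mode == "exact" || (mode == "auto" && n <= 25L)
  if (exact) {
    null <- .signed_rank_null(r)
    pv <- min(1, 2 * sum(null[seq_len(as.integer(round(2 * W)) + 1L)]))
    method <- "wilcoxon-exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu + 0.5) / sqrt(sig2)     # continuity-corrected lower tail
    pv <- min(1, 2 * stats::pnorm(z))
    method <- "wilcoxon-normal"
  }
  structure(list(statistic = W, p.value = pv, n = n, method = method,
                 w_plus = wplus, w_minus = wminus),
            class = "paired_comparison")
}
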