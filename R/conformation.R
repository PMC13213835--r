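#' Signed torsion angle of four points
#'
#' IUPAC sign convention: the angle between the plane (p1, p2, p3) and the
#' plane (p2, p3, p4), zero for the cis (eclipsed) arrangement, positive
#' clockwise when viewed from p2 toward p3, reported on (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return torsion in degrees.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1))
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) == 0 || sum(n2^2) == 0)
    .stopf("undefined torsion: collinear or coincident points")
  x <- sum(n1 * n2)
  y <- sum(cx(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  .wrap180(ang)
}

## Kabsch: optimal rotation (+translation) of mobile onto ref (n x 3 each).
## Returns the transformed mobile coordinates.
.kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  Rm <- sv$v %*% D %*% t(sv$u)
  sweep(A %*% t(Rm), 2, cr, `+`)
}

#' Superpose trajectory frames onto a reference frame
#'
#' Kabsch least-squares superposition of every frame onto
#' `reference_frame`, fitting on `fit_selection` and applying the rigid
#' transform to all atoms.
#'
#' @param traj an [md_trajectory()].
#' @param reference_frame frame index (1-based).
#' @param fit_selection atoms used for the fit (see [select_atoms()]);
#'   default all heavy atoms.
#' @return the superposed trajectory.
#' @export
superpose <- function(traj, reference_frame = 1L, fit_selection = "heavy") {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj, fit_selection)
  if (length(sel) < 3L) .stopf("superposition needs >= 3 fit atoms, got %d", length(sel))
  ref <- traj$coords[sel, , reference_frame]
  for (f in seq_len(n_frames(traj))) {
    mob <- traj$coords[sel, , f]
    cm <- colMeans(mob); cr <- colMeans(ref)
    A <- sweep(mob, 2, cm); B <- sweep(ref, 2, cr)
    sv <- svd(crossprod(A, B))
    d <- sign(det(sv$v %*% t(sv$u)))
    Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    all_shift <- sweep(traj$coords[, , f], 2, cm)
    traj$coords[, , f] <- sweep(all_shift %*% t(Rm), 2, cr, `+`)
  }
  traj
}

#' RMSD time series against a reference frame
#'
#' Root-mean-square deviation of a selection per frame, optionally after
#' Kabsch superposition of the selection onto the reference frame (the
#' default, matching alignment to the first frame before GAG heavy-atom
#' RMSD).
#'
#' @param traj an [md_trajectory()].
#' @param reference_frame frame index (1-based), default the first frame.
#' @param selection atom selection (see [select_atoms()]); default heavy
#'   atoms.
#' @param superpose logical, fit each frame onto the reference first.
#' @return data frame of class `rmsd_series` with columns `frame` (0-based)
#'   and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = "heavy",
                        superpose = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj, selection)
  if (length(sel) == 0L) .stopf("empty atom selection")
  if (superpose && length(sel) < 3L)
    .stopf("superposed RMSD needs >= 3 atoms, got %d", length(sel))
  ref <- traj$coords[sel, , reference_frame, drop = TRUE]
  nf <- n_frames(traj)
  r <- numeric(nf)
  for (f in seq_len(nf)) {
    mob <- traj$coords[sel, , f, drop = TRUE]
    if (superpose) mob <- .kabsch(mob, ref)
    r[f] <- sqrt(mean(rowSums((mob - ref)^2)))
  }
  out <- data.frame(frame = 0:(nf - 1L), rmsd = r)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Glycosidic torsion series and heatmap histograms
#'
#' Computes the phi/psi torsions of every annotated glycosidic linkage per
#' frame and bins them on a fixed 2-D grid over (-180, 180]^2 (5 degree
#' bins by default). A linkage whose atoms cannot be resolved is reported
#' in `$errors`; the remaining linkages are still processed.
#'
#' @param traj an [md_trajectory()] with linkages (see [define_linkage()],
#'   [gag_linkages()]).
#' @param linkages optional subset of linkage ids.
#' @param bin_width histogram bin width in degrees (must divide 360).
#' @return object of class `glyco_series`: list with `series` (per linkage,
#'   data frame `frame`, `phi`, `psi`), `histogram` (per linkage, matrix of
#'   counts with bin-centre dimnames; counts sum to `n_frames`), `breaks`,
#'   and `errors`.
#' @export
glycosidic_series <- function(traj, linkages = NULL, bin_width = 5) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (360 %% bin_width != 0) .stopf("bin_width must divide 360")
  lks <- traj$linkages
  if (!length(lks)) .stopf("trajectory has no annotated linkages")
  if (!is.null(linkages))
    lks <- Filter(function(l) l$linkage_id %in% linkages, lks)
  breaks <- seq(-180, 180, by = bin_width)
  centers <- breaks[-1] - bin_width / 2
  nf <- n_frames(traj)
  series <- list(); hists <- list(); errors <- list()
  for (lk in lks) {
    res <- tryCatch({
      phi <- psi <- numeric(nf)
      for (f in seq_len(nf)) {
        X <- traj$coords[, , f]
        phi[f] <- dihedral_angle(X[lk$phi[1], ], X[lk$phi[2], ], X[lk$phi[3], ], X[lk$phi[4], ])
        psi[f] <- dihedral_angle(X[lk$psi[1], ], X[lk$psi[2], ], X[lk$psi[3], ], X[lk$psi[4], ])
      }
      list(df = data.frame(frame = 0:(nf - 1L), phi = phi, psi = psi))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[lk$linkage_id]] <- conditionMessage(res)
      next
    }
    df <- res$df
    ## bins are (lo, hi]: values at exactly -180 wrap to +180 by .wrap180
    bin <- function(a) pmin(length(centers), pmax(1L, ceiling((a + 180) / bin_width)))
    H <- matrix(0L, length(centers), length(centers),
                dimnames = list(phi = centers, psi = centers))
    for (f in seq_len(nf)) H[bin(df$phi[f]), bin(df$psi[f])] <- H[bin(df$phi[f]), bin(df$psi[f])] + 1L
    series[[lk$linkage_id]] <- df
    hists[[lk$linkage_id]] <- H
  }
  structure(list(series = series, histogram = hists, breaks = breaks,
                 errors = errors),
            class = "glyco_series")
}

#' @export
print.glyco_series <- function(x, ...) {
  cat(sprintf("<glyco_series> %d linkages (%d failed)\n",
              length(x$series), length(x$errors)))
  invisible(x)
}

#' Plot a glycosidic torsion heatmap
#'
#' @param x a `glyco_series`.
#' @param linkage linkage id (default the first).
#' @param ... passed to [graphics::image()].
#' @export
plot.glyco_series <- function(x, linkage = names(x$histogram)[1], ...) {
  H <- x$histogram[[linkage]]
  centers <- as.numeric(rownames(H))
  graphics::image(centers, centers, H, xlab = expression(phi~"(deg)"),
                  ylab = expression(psi~"(deg)"),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = paste("linkage", linkage), ...)
  invisible(x)
}

## mass-weighted centre of mass of atom indices in one frame
.residue_com <- function(X, mass, idx) {
  m <- mass[idx]
  colSums(X[idx, , drop = FALSE] * m) / sum(m)
}

#' Protein-GAG residue contact map
#'
#' Mean over frames of the distance between the mass-weighted centres of
#' mass of each protein residue (rows) and each GAG residue (columns).
#' Hydrogens are included in the COM.
#'
#' @param traj an [md_trajectory()].
#' @param protein_chain,gag_chain chain ids.
#' @return matrix of mean COM-COM distances (Angstrom) with residue-key
#'   dimnames, class `contact_map`.
#' @export
contact_map <- function(traj, protein_chain, gag_chain) {
  stopifnot(inherits(traj, "md_trajectory"))
  keys <- .residue_key(traj$atoms)
  pres <- unique(keys[traj$atoms$chain == protein_chain])
  gres <- unique(keys[traj$atoms$chain == gag_chain])
  if (!length(pres)) .stopf("no residues in protein chain '%s'", protein_chain)
  if (!length(gres)) .stopf("no residues in GAG chain '%s'", gag_chain)
  pidx <- lapply(pres, function(k) which(keys == k))
  gidx <- lapply(gres, function(k) which(keys == k))
  nf <- n_frames(traj)
  M <- matrix(0, length(pres), length(gres), dimnames = list(pres, gres))
  for (f in seq_len(nf)) {
    X <- traj$coords[, , f]
    pc <- t(vapply(pidx, function(ix) .residue_com(X, traj$atoms$mass, ix), numeric(3)))
    gc <- t(vapply(gidx, function(ix) .residue_com(X, traj$atoms$mass, ix), numeric(3)))
    for (i in seq_along(pres))
      M[i, ] <- M[i, ] + sqrt(colSums((t(gc) - pc[i, ])^2))
  }
  M <- M / nf
  class(M) <- c("contact_map", "matrix")
  M
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d protein x %d GAG residues, mean distance %.2f A\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)), t(unclass(x)),
                  xlab = "GAG residue", ylab = "protein residue",
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE), ...)
  invisible(x)
}
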