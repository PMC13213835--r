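#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Standard Cremer-Pople construction for a pyranose ring: origin at the
#' geometric centre, mean plane from the two weighted lattice vectors,
#' out-of-plane displacements `z_j`, then the m = 2 Fourier pair
#' (`q2`, `phi2`) and the alternating component `q3`, with total amplitude
#' `Q = sqrt(q2^2 + q3^2) = sqrt(sum(z_j^2))`, `theta = atan2(q2, q3)` in
#' `[0, 180]` and phase `phi` in `[0, 360)`. Atom order is
#' O5, C1, C2, C3, C4, C5; `theta = 0` is the 4C1 chair.
#'
#' @param ring_coords 6 x 3 matrix of coordinates (Angstrom) in ring order
#'   O5, C1, C2, C3, C4, C5.
#' @return list with `Q` (Angstrom), `theta`, `phi` (degrees), `q2`, `q3`,
#'   `z` (displacements), and `planar` (`TRUE` when `Q` is numerically 0,
#'   in which case `theta`/`phi` are `NA`).
#' @examples
#' ring <- gen_ring_coords("4C1", Q = 0.55, n_frames = 1)[, , 1]
#' cremer_pople(ring)
#' @export
cremer_pople <- function(ring_coords) {
  X <- as.matrix(ring_coords)
  if (!all(dim(X) == c(6L, 3L))) .stopf("ring_coords must be a 6 x 3 matrix")
  if (nrow(unique(X)) < 6L) .stopf("ring atoms must be distinct points")
  X <- sweep(X, 2, colMeans(X))
  j <- 0:5
  s <- sin(2 * pi * j / 6); cth <- cos(2 * pi * j / 6)
  Rp <- colSums(X * s)          # R'
  Rpp <- colSums(X * cth)       # R''
  nrm <- c(Rp[2] * Rpp[3] - Rp[3] * Rpp[2],
           Rp[3] * Rpp[1] - Rp[1] * Rpp[3],
           Rp[1] * Rpp[2] - Rp[2] * Rpp[1])
  nl <- sqrt(sum(nrm^2))
  if (nl == 0) .stopf("degenerate ring geometry (undefined mean plane)")
  nrm <- nrm / nl
  z <- as.numeric(X %*% nrm)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(sum(z^2))
  planar <- Q < 1e-8
  theta <- if (planar) NA_real_ else atan2(q2, q3) * 180 / pi
  phi <- if (planar || q2 < 1e-10) NA_real_ else (atan2(q2s, q2c) * 180 / pi) %% 360
  list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3, z = z, planar = planar)
}

## canonical z-pattern of a conformer (unnormalized), atom order O5..C5
.canonical_patterns <- function() {
  j <- 0:5
  out <- list()
  add <- function(label, z, class) out[[label]] <<- list(z = z, class = class)
  add("4C1", (-1)^j, "chair")
  add("1C4", -(-1)^j, "chair")
  pos <- c("O", "1", "2", "3", "4", "5")
  ## boats: para pair (p, p+3) displaced to the same side
  for (p in 0:2) {
    z <- rep(-0.5, 6); z[c(p, p + 3) + 1L] <- 1
    up <- paste0(pos[p + 1L], ",", pos[p + 4L], "B")
    dn <- paste0("B", pos[p + 1L], ",", pos[p + 4L])
    add(up, z, "boat")
    add(dn, -z, "boat")
  }
  ## skew-boats: the six canonical pSq twist forms (pure q2 at odd 30-degree
  ## phases); pattern cos(phi + 120 j) has p above / q below the best plane
  skews <- c("3S1" = 30, "5S1" = 90, "2SO" = 150, "1S3" = 210,
             "1S5" = 270, "OS2" = 330)
  for (lab in names(skews))
    add(lab, cos((skews[[lab]] + 120 * j) * pi / 180), "skew")
  ## envelopes: one atom out of plane
  for (p in 0:5) {
    z <- -rep(1 / 6, 6); z[p + 1L] <- z[p + 1L] + 1
    add(paste0(pos[p + 1L], "E"), z, "envelope")
    add(paste0("E", pos[p + 1L]), -z, "envelope")
  }
  ## half-chairs: adjacent pair on opposite sides, jHk = j above, k below
  for (p in 0:5) {
    k <- (p + 1L) %% 6L
    z <- rep(0, 6); z[p + 1L] <- 1; z[k + 1L] <- -1
    add(paste0(pos[p + 1L], "H", pos[k + 1L]), z, "half-chair")
    add(paste0(pos[k + 1L], "H", pos[p + 1L]), -z, "half-chair")
  }
  out
}

## package cache for the canonical table
.gagmd_cache <- new.env(parent = emptyenv())

#' Canonical pyranose conformer table
#'
#' The 38 canonical IUPAC ring forms (2 chairs, 6 boats, 6 skew-boats,
#' 12 envelopes, 12 half-chairs) with their Cremer-Pople sphere positions
#' `(theta, phi)`, generated from idealized out-of-plane displacement
#' patterns through the same Cremer-Pople formulas used for measurement.
#' Atom order convention O5, C1, C2, C3, C4, C5 puts 4C1 at the north pole
#' (`theta = 0`) and 1C4 at the south pole.
#'
#' @return data frame with columns `label`, `class`, `theta`, `phi`.
#' @export
conformer_table <- function() {
  if (!is.null(.gagmd_cache$conformer_table)) return(.gagmd_cache$conformer_table)
  pats <- .canonical_patterns()
  j <- 0:5
  rows <- lapply(names(pats), function(lab) {
    z <- pats[[lab]]$z
    z <- z - mean(z)
    q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
    q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
    q2 <- sqrt(q2c^2 + q2s^2)
    q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
    theta <- atan2(q2, q3) * 180 / pi
    phi <- if (q2 < 1e-12) 0 else (atan2(q2s, q2c) * 180 / pi) %% 360
    data.frame(label = lab, class = pats[[lab]]$class, theta = theta, phi = phi)
  })
  tab <- do.call(rbind, rows)
  .gagmd_cache$conformer_table <- tab
  tab
}

## great-circle distance (deg) between points on the (theta, phi) sphere
.sphere_dist <- function(t1, p1, t2, p2) {
  t1 <- t1 * pi / 180; p1 <- p1 * pi / 180
  t2 <- t2 * pi / 180; p2 <- p2 * pi / 180
  cd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(p1 - p2)
  acos(pmin(1, pmax(-1, cd))) * 180 / pi
}

#' Classify a pucker state by nearest canonical conformer
#'
#' Nearest vertex on the Cremer-Pople `(theta, phi)` sphere among the 38
#' canonical forms of [conformer_table()]. Amplitudes below the planarity
#' threshold are labelled `"planar"`.
#'
#' @param state list with `Q`, `theta`, `phi` (as from [cremer_pople()]).
#' @param planarity_threshold amplitude (Angstrom) below which the ring is
#'   called planar; default 0.1, well under pyranose amplitudes (~0.5-0.6).
#' @return conformer label (character).
#' @export
assign_conformer_cp <- function(state, planarity_threshold = 0.1) {
  if (!is.finite(state$Q) || state$Q < planarity_threshold) return("planar")
  tab <- conformer_table()
  phi <- if (is.finite(state$phi)) state$phi else 0
  d <- .sphere_dist(state$theta, phi, tab$theta, tab$phi)
  tab$label[which.min(d)]
}

#' Collapse conformer labels to population classes
#'
#' Maps canonical labels to the coarse classes used in population tables:
#' `chair`, `boat`, `skew`, or `other` (envelopes, half-chairs, planar and
#' unassigned states).
#'
#' @param label character vector of conformer labels.
#' @return character vector of classes.
#' @export
conformer_class <- function(label) {
  tab <- conformer_table()
  cls <- tab$class[match(label, tab$label)]
  out <- ifelse(cls %in% c("chair", "boat", "skew"), cls, "other")
  out[is.na(cls)] <- "other"
  out
}

#' Reference two-dihedral table for ring conformer assignment
#'
#' Reference values of the two classifier dihedrals C1-C2-C3-C4 and
#' C1-O5-C5-C4 for canonical conformers, measured on ideal geometries
#' built by [gen_ring_coords()] (canonical Cremer-Pople displacements on a
#' regular ring of 1.52 Angstrom bonds).
#'
#' Two ring torsions cannot separate every canonical form: symmetry pairs
#' such as 3S1/1S5 or O,3B/B2,5 share identical `(d1, d2)` signatures.
#' The default reference therefore covers the two chairs and the two
#' skew-boats relevant to iduronate/GAG ring analysis (4C1, 1C4, 2SO,
#' 1S3), which are mutually well separated; pass `labels` to extend it.
#'
#' @param Q puckering amplitude (Angstrom) of the reference geometries.
#' @param labels conformers to include.
#' @return data frame with columns `label`, `d1`, `d2` (degrees).
#' @export
dihedral_reference_table <- function(Q = 0.55,
                                     labels = c("4C1", "1C4", "2SO", "1S3")) {
  key <- paste0("dihref", Q, paste(labels, collapse = ","))
  if (!is.null(.gagmd_cache[[key]])) return(.gagmd_cache[[key]])
  tab <- conformer_table()
  if (is.null(labels)) labels <- tab$label[tab$class %in% c("chair", "boat", "skew")]
  labels <- unique(labels)
  rows <- lapply(labels, function(lab) {
    xyz <- gen_ring_coords(lab, Q = Q, n_frames = 1)[, , 1]
    ## atom order O5,C1,C2,C3,C4,C5 -> rows 1..6
    d1 <- dihedral_angle(xyz[2, ], xyz[3, ], xyz[4, ], xyz[5, ])  # C1-C2-C3-C4
    d2 <- dihedral_angle(xyz[2, ], xyz[1, ], xyz[6, ], xyz[5, ])  # C1-O5-C5-C4
    data.frame(label = lab, d1 = d1, d2 = d2)
  })
  out <- do.call(rbind, rows)
  .gagmd_cache[[key]] <- out
  out
}

#' Classify ring conformation by two dihedrals
#'
#' Assigns the label of the reference pair nearest in wrapped angular
#' distance, provided both dihedrals are within `tol`; otherwise
#' `"other"`.
#'
#' @param d1,d2 classifier dihedrals C1-C2-C3-C4 and C1-O5-C5-C4 (deg).
#' @param reference data frame `label`, `d1`, `d2`
#'   (default [dihedral_reference_table()]).
#' @param tol angular tolerance in degrees on each dihedral.
#' @return conformer label (character).
#' @export
assign_conformer_dihedral <- function(d1, d2, reference = dihedral_reference_table(),
                                      tol = 30) {
  stopifnot(nrow(reference) > 0, tol > 0)
  dd1 <- abs(.wrap180(reference$d1 - d1))
  dd2 <- abs(.wrap180(reference$d2 - d2))
  ok <- dd1 <= tol & dd2 <= tol
  if (!any(ok)) return("other")
  cand <- which(ok)
  reference$label[cand[which.min(dd1[cand]^2 + dd2[cand]^2)]]
}

#' Ring conformer populations over a trajectory
#'
#' Fraction of frames each conformer label occupies for one annotated
#' monosaccharide residue, using either the Cremer-Pople nearest-vertex
#' classifier or the two-dihedral rule. Fractions (including
#' `"other"`/`"planar"`) sum to 1.
#'
#' @param traj an [md_trajectory()] with ring annotations
#'   (see [annotate_rings()]).
#' @param residue residue key `"chain:resno"` (or ring-map name).
#' @param classifier `"cp"` or `"dihedral"`.
#' @param ... passed to the classifier
#'   ([assign_conformer_cp()] / [assign_conformer_dihedral()]).
#' @return named numeric vector of fractions.
#' @export
pucker_populations <- function(traj, residue, classifier = c("cp", "dihedral"), ...) {
  stopifnot(inherits(traj, "md_trajectory"))
  classifier <- match.arg(classifier)
  ring <- traj$rings[[residue]]
  if (is.null(ring)) .stopf("residue '%s' has no ring annotation", residue)
  nf <- n_frames(traj)
  labels <- character(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[ring, , f]
    if (classifier == "cp") {
      labels[f] <- assign_conformer_cp(cremer_pople(xyz), ...)
    } else {
      d1 <- dihedral_angle(xyz[2, ], xyz[3, ], xyz[4, ], xyz[5, ])
      d2 <- dihedral_angle(xyz[2, ], xyz[1, ], xyz[6, ], xyz[5, ])
      labels[f] <- assign_conformer_dihedral(d1, d2, ...)
    }
  }
  tb <- table(labels)
  fr <- as.numeric(tb) / nf
  names(fr) <- names(tb)
  fr
}
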