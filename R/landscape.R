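#' Savitzky-Golay smoothing specification
#'
#' Parameters of the gentle smoothing applied to an energy time series
#' before proxy extrema are extracted. The defaults (5-frame window, cubic
#' polynomial) attenuate barrier inflation from skipped intermediate minima
#' while leaving basin assignments essentially unchanged; at 1 ns sampling
#' they correspond to an effective cutoff time scale of 3 ns
#' (see [cutoff_timescale()]).
#'
#' @param window_length odd integer >= 1, window size in frames.
#' @param poly_order integer >= 0, degree of the fitted polynomial,
#'   `< window_length`.
#' @param sampling_interval sampling interval in ns.
#' @return list of class `smoothing_spec`.
#' @export
smoothing_spec <- function(window_length = 5L, poly_order = 3L,
                           sampling_interval = 1) {
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  if (window_length < 1L || window_length %% 2L == 0L)
    .stopf("window_length must be an odd integer >= 1, got %d", window_length)
  if (poly_order < 0L || poly_order >= window_length)
    .stopf("poly_order must satisfy 0 <= order < window (got order %d, window %d)",
           poly_order, window_length)
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    .stopf("sampling_interval must be > 0")
  structure(list(window_length = window_length, poly_order = poly_order,
                 sampling_interval = sampling_interval),
            class = "smoothing_spec")
}

## central SG convolution weights for odd window w, degree p:
## row of the least-squares polynomial projector evaluated at the centre
.sg_weights <- function(w, p, at = (w + 1L) / 2L) {
  x <- seq_len(w) - (w + 1L) / 2L
  A <- outer(x, 0:p, `^`)
  ## projector row: e_at' A (A'A)^-1 A'
  H <- A %*% solve(crossprod(A), t(A))
  H[at, ]
}

## least-squares polynomial fit over points y at abscissae x, value at x0;
## degree reduced when the window is too short to determine it
.ls_poly_at <- function(x, y, p, x0) {
  p <- min(p, length(x) - 1L)
  A <- outer(x - x0, 0:p, `^`)
  cf <- qr.coef(qr(A), y)
  unname(cf[1L])
}

#' Savitzky-Golay smoothing of an energy series
#'
#' Least-squares local polynomial smoothing on the frame grid. Interior
#' frames use the centred window; the first and last `(window-1)/2` frames
#' are fitted over the truncated asymmetric window with the same degree
#' (reduced to `n_points - 1` where the truncated window cannot determine
#' it, which leaves those frames interpolated). No padding is invented.
#'
#' @param series an [energy_series()].
#' @param spec a [smoothing_spec()].
#' @return an `energy_series` on the same frame grid.
#' @examples
#' es <- energy_series(c(5, 1, 4, 0, 3, 2, 6))
#' smooth_energy(es, smoothing_spec(5, 3))
#' @export
smooth_energy <- function(series, spec = smoothing_spec()) {
  stopifnot(inherits(series, "energy_series"), inherits(spec, "smoothing_spec"))
  w <- spec$window_length
  p <- spec$poly_order
  n <- nrow(series)
  if (n < w) .stopf("series length %d shorter than window %d", n, w)
  y <- series$energy
  if (w == 1L) return(series)          # identity filter
  h <- (w - 1L) %/% 2L
  wt <- .sg_weights(w, p)
  sm <- as.numeric(stats::filter(y, rev(wt), sides = 2))
  for (i in seq_len(h)) {
    idx <- 1L:(i + h)                  # truncated head window
    sm[i] <- .ls_poly_at(idx, y[idx], p, i)
    jdx <- (n - i - h + 1L):n          # truncated tail window
    sm[n - i + 1L] <- .ls_poly_at(jdx, y[jdx], p, n - i + 1L)
  }
  energy_series(sm, time = series$time, frame = series$frame)
}

#' Effective cutoff time scale of the smoothing filter
#'
#' Reciprocal of the approximate -3 dB cutoff frequency of a
#' Savitzky-Golay smoothing filter, from the least-squares-derived closed
#' form `f3dB = (p + 1) / (3.2 W - 4.6)` (per sampling interval), with `W`
#' the full window length and `p` the polynomial order. The default
#' 5-frame cubic window at 1 ns sampling gives 2.85 ns, i.e. an effective
#' cutoff time scale of 3 ns at nearest-ns rounding.
#'
#' The identity filter (window 1) has no -3 dB point; the Nyquist period
#' `2 * sampling_interval` is returned with a warning.
#'
#' @param spec a [smoothing_spec()].
#' @return cutoff time scale in ns.
#' @examples
#' cutoff_timescale(smoothing_spec(5, 3, 1))  # 2.85 -> "3 ns"
#' @export
cutoff_timescale <- function(spec = smoothing_spec()) {
  stopifnot(inherits(spec, "smoothing_spec"))
  if (spec$window_length == 1L) {
    .warnf("window 1 is the identity filter; returning the Nyquist period")
    return(2 * spec$sampling_interval)
  }
  f3db <- (spec$poly_order + 1) / (3.2 * spec$window_length - 4.6)
  spec$sampling_interval / f3db
}

#' Proxy minima and transition states of a smoothed energy series
#'
#' Alternating local minima / maxima of the (smoothed) trace. Runs of equal
#' values collapse to a single extremum located at their first frame.
#' Boundary frames may be minima (when lower than their single interior
#' neighbour) but never transition states: a trajectory is assumed to start
#' and end inside a basin.
#'
#' @param smoothed an [energy_series()] (typically the output of
#'   [smooth_energy()]), length >= 2.
#' @return data frame of class `proxy_extrema` with columns `frame`,
#'   `energy`, `kind` (`"minimum"`/`"maximum"`); kinds strictly alternate
#'   and the first and last rows are minima.
#' @examples
#' detect_proxy_extrema(energy_series(c(5, 1, 4, 0, 3, 2, 6)))
#' @export
detect_proxy_extrema <- function(smoothed) {
  stopifnot(inherits(smoothed, "energy_series"))
  y <- smoothed$energy
  fr <- smoothed$frame
  ## collapse plateau runs to their first frame
  keep <- c(TRUE, diff(y) != 0)
  v <- y[keep]
  f <- fr[keep]
  m <- length(v)
  kind <- character(0); ef <- integer(0); ee <- numeric(0)
  add <- function(i, k) { ef <<- c(ef, f[i]); ee <<- c(ee, v[i]); kind <<- c(kind, k) }
  if (m == 1L) {
    add(1L, "minimum")                 # constant series
  } else {
    if (v[1] < v[2]) add(1L, "minimum")
    if (m > 2L) for (i in 2L:(m - 1L)) {
      if (v[i] < v[i - 1] && v[i] < v[i + 1]) add(i, "minimum")
      else if (v[i] > v[i - 1] && v[i] > v[i + 1]) add(i, "maximum")
    }
    if (v[m] < v[m - 1]) add(m, "minimum")
    ## boundary maxima are dropped above; drop any leading/trailing maximum
    ## that alternation would otherwise demand (cannot occur by construction)
  }
  out <- data.frame(frame = ef, energy = ee, kind = kind)
  class(out) <- c("proxy_extrema", "data.frame")
  out
}

#' @export
print.proxy_extrema <- function(x, ...) {
  cat(sprintf("<proxy_extrema> %d minima, %d maxima\n",
              sum(x$kind == "minimum"), sum(x$kind == "maximum")))
  print.data.frame(x, ...)
  invisible(x)
}

.extrema_minima <- function(extrema) which(extrema$kind == "minimum")

#' Barrier between two proxy minima
#'
#' The highest proxy transition-state energy strictly between minima `i`
#' and `j` along the time axis. This is the reference ("oracle") quantity
#' the disconnectivity-graph merge heights must reproduce.
#'
#' @param extrema a `proxy_extrema` object.
#' @param i,j leaf (minimum) indices, 1-based in time order, `i != j`.
#' @return barrier energy in kcal/mol.
#' @export
pairwise_barrier <- function(extrema, i, j) {
  stopifnot(inherits(extrema, "proxy_extrema"))
  mins <- .extrema_minima(extrema)
  nmin <- length(mins)
  if (i == j) .stopf("i and j must be distinct minima")
  if (i < 1 || j < 1 || i > nmin || j > nmin)
    .stopf("leaf index out of range (1..%d)", nmin)
  lo <- min(i, j); hi <- max(i, j)
  between <- (mins[lo] + 1L):(mins[hi] - 1L)
  maxs <- between[extrema$kind[between] == "maximum"]
  max(extrema$energy[maxs])
}

#' Disconnectivity graph (barrier tree) of proxy minima
#'
#' Single-linkage agglomeration of the proxy minima in ascending order of
#' the intervening proxy transition-state energies: the lowest separating
#' maximum merges its two flanking basins first, and so on toward the root.
#' With `n` minima the tree has exactly `n - 1` internal nodes whose
#' heights are the sorted maxima energies, hence monotone non-decreasing
#' toward the root and ultrametric.
#'
#' @param extrema a `proxy_extrema` object.
#' @param order_values optional [order_parameter_series()] covering every
#'   minimum frame (used to color leaves, e.g. by GAG RMSD to frame 0).
#' @return object of class `barrier_tree`: list with `leaves` (data frame
#'   `frame`, `energy`, `order_value`, in time order), `merge` (hclust-style
#'   merge matrix, negative entries = leaves) and `height` (barrier energy
#'   of each merge, kcal/mol).
#' @examples
#' ex <- detect_proxy_extrema(energy_series(c(5, 1, 4, 0, 3, 2, 6)))
#' build_disconnectivity(ex)
#' @export
build_disconnectivity <- function(extrema, order_values = NULL) {
  stopifnot(inherits(extrema, "proxy_extrema"))
  mins <- .extrema_minima(extrema)
  n <- length(mins)
  ov <- rep(NA_real_, n)
  if (!is.null(order_values)) {
    idx <- match(extrema$frame[mins], order_values$frame)
    if (anyNA(idx))
      .stopf("order_values must cover all minima frames (missing: %s)",
             paste(extrema$frame[mins][is.na(idx)], collapse = ","))
    ov <- order_values$value[idx]
  }
  leaves <- data.frame(frame = extrema$frame[mins],
                       energy = extrema$energy[mins],
                       order_value = ov)
  merge <- matrix(integer(0), 0, 2)
  height <- numeric(0)
  if (n > 1L) {
    ## separating maxima between consecutive minima, in time order
    sep <- vapply(seq_len(n - 1L), function(k) {
      between <- (mins[k] + 1L):(mins[k + 1L] - 1L)
      mx <- between[extrema$kind[between] == "maximum"]
      max(extrema$energy[mx])
    }, numeric(1))
    ## merge adjacent clusters in ascending barrier order
    cl <- -(seq_len(n))                # current node id per time slot
    alive <- rep(TRUE, n - 1L)         # separating barriers still present
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    ord <- order(sep)
    node <- 0L
    for (b in ord) {
      node <- node + 1L
      left <- cl[b]; right <- cl[b + 1L]
      merge[node, ] <- c(left, right)
      height[node] <- sep[b]
      cl[cl == left | cl == right] <- node
    }
  }
  structure(list(leaves = leaves, merge = merge, height = height),
            class = "barrier_tree")
}

#' @export
print.barrier_tree <- function(x, ...) {
  n <- nrow(x$leaves)
  cat(sprintf("<barrier_tree> %d leaves, %d merges", n, length(x$height)))
  if (length(x$height))
    cat(sprintf(", merge heights [%.4g, %.4g] kcal/mol", min(x$height), max(x$height)))
  cat("\n")
  invisible(x)
}

## leaves (1-based) under node id (internal > 0, leaf < 0)
.tree_members <- function(tree, id) {
  if (id < 0) return(-id)
  c(.tree_members(tree, tree$merge[id, 1]), .tree_members(tree, tree$merge[id, 2]))
}

#' Pairwise merge heights of a barrier tree
#'
#' Height at which leaves `i` and `j` first belong to one subtree
#' (cophenetic barrier). `barrier_matrix` returns the full symmetric
#' matrix with `NA` on the diagonal.
#'
#' @param tree a `barrier_tree`.
#' @return numeric matrix `n x n`.
#' @export
barrier_matrix <- function(tree) {
  stopifnot(inherits(tree, "barrier_tree"))
  n <- nrow(tree$leaves)
  M <- matrix(NA_real_, n, n)
  for (k in seq_along(tree$height)) {
    a <- .tree_members(tree, tree$merge[k, 1])
    b <- .tree_members(tree, tree$merge[k, 2])
    M[a, b] <- tree$height[k]
    M[b, a] <- tree$height[k]
  }
  M
}

#' Coarse-grain proxy minima by barrier threshold
#'
#' Merges proxy minima whose separating barriers lie below `threshold`
#' above the lower of the two flanking minima, keeping one representative
#' (the lowest-energy minimum) per merged group. Raw proxy-minima counts
#' of gently smoothed traces are dominated by within-basin noise wiggles
#' (roughly one shallow minimum every 4-5 frames); thresholding on barrier
#' prominence recovers genuine basin visits.
#'
#' @param extrema a `proxy_extrema` object.
#' @param threshold barrier prominence (kcal/mol) below which adjacent
#'   minima are merged.
#' @return a `proxy_extrema` object containing the surviving alternating
#'   minima/maxima.
#' @export
coarse_grain_minima <- function(extrema, threshold) {
  stopifnot(inherits(extrema, "proxy_extrema"), threshold >= 0)
  df <- extrema
  repeat {
    mins <- which(df$kind == "minimum")
    if (length(mins) < 2L) break
    maxs <- which(df$kind == "maximum")
    ## prominence of each separating maximum over its shallower neighbour
    prom <- vapply(maxs, function(m) {
      lo <- max(mins[mins < m]); hi <- min(mins[mins > m])
      df$energy[m] - max(df$energy[lo], df$energy[hi])
    }, numeric(1))
    k <- which.min(prom)
    if (prom[k] >= threshold) break
    m <- maxs[k]
    lo <- max(mins[mins < m]); hi <- min(mins[mins > m])
    drop <- if (df$energy[lo] <= df$energy[hi]) c(m, hi) else c(lo, m)
    df <- df[-drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("proxy_extrema", "data.frame")
  df
}

#' Rendering primitives for a disconnectivity graph
#'
#' Computes the line segments of the classic disconnectivity-graph
#' rendering: vertical axis = energy, each leaf descends from its first
#' merge height to its minimum energy, internal nodes are horizontal
#' connectors at their barrier energies with vertical risers toward the
#' parent. Within each internal node the subtree containing the
#' lower-energy minimum is placed on the left.
#'
#' @param tree a `barrier_tree`.
#' @return list with `segments` (data frame `type`
#'   (`leaf`/`connector`/`stem`), `x0`, `y0`, `x1`, `y1`, `order_value`
#'   (leaf segments only)) and `leaf_x` (display x position per leaf, in
#'   leaf order of `tree$leaves`).
#' @export
layout_tree <- function(tree) {
  stopifnot(inherits(tree, "barrier_tree"))
  n <- nrow(tree$leaves)
  nI <- length(tree$height)
  root_h <- if (nI) max(tree$height) else tree$leaves$energy[1]
  ## display order: recursive, lower-energy-subtree first
  min_e <- function(id) min(tree$leaves$energy[.tree_members(tree, id)])
  ord <- integer(0)
  walk <- function(id) {
    if (id < 0) { ord <<- c(ord, -id); return(invisible()) }
    ch <- tree$merge[id, ]
    ch <- ch[order(vapply(ch, min_e, numeric(1)))]
    walk(ch[1]); walk(ch[2])
  }
  walk(if (nI) nI else -1L)
  leaf_x <- integer(n); leaf_x[ord] <- seq_len(n)

  segs <- list()
  ## x and top height of each node (leaf nodes: merge height of parent)
  node_x <- numeric(nI); node_h <- tree$height
  top_of <- function(id) {          # height at which node id hangs from parent
    if (nI == 0L) return(root_h)
    for (k in seq_len(nI)) if (any(tree$merge[k, ] == id)) return(tree$height[k])
    root_h                          # root itself
  }
  if (nI) {
    for (k in seq_len(nI)) {
      xs <- vapply(tree$merge[k, ], function(id)
        if (id < 0) leaf_x[-id] else node_x[id], numeric(1))
      node_x[k] <- mean(xs)
      segs[[length(segs) + 1L]] <- data.frame(
        type = "connector", x0 = min(xs), y0 = tree$height[k],
        x1 = max(xs), y1 = tree$height[k], order_value = NA_real_)
      top <- top_of(k)
      if (top > tree$height[k])
        segs[[length(segs) + 1L]] <- data.frame(
          type = "stem", x0 = node_x[k], y0 = tree$height[k],
          x1 = node_x[k], y1 = top, order_value = NA_real_)
    }
  }
  for (l in seq_len(n)) {
    top <- top_of(-l)
    segs[[length(segs) + 1L]] <- data.frame(
      type = "leaf", x0 = leaf_x[l], y0 = tree$leaves$energy[l],
      x1 = leaf_x[l], y1 = top, order_value = tree$leaves$order_value[l])
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  list(segments = segments, leaf_x = leaf_x)
}

#' Plot a disconnectivity graph
#'
#' @param x a `barrier_tree`.
#' @param palette colormap for leaf order-parameter values, as in
#'   [grDevices::hcl.colors()].
#' @param lwd line width.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the [layout_tree()] result, invisibly.
#' @export
plot.barrier_tree <- function(x, palette = "Viridis", lwd = 2, ...) {
  lay <- layout_tree(x)
  s <- lay$segments
  ylim <- range(c(s$y0, s$y1))
  graphics::plot(NA, xlim = range(c(s$x0, s$x1)) + c(-0.5, 0.5), ylim = ylim,
                 xlab = "", ylab = "energy (kcal/mol)", xaxt = "n", ...)
  other <- s$type != "leaf"
  graphics::segments(s$x0[other], s$y0[other], s$x1[other], s$y1[other],
                     col = "grey40", lwd = lwd)
  leaf <- s[s$type == "leaf", ]
  col <- rep("black", nrow(leaf))
  if (any(is.finite(leaf$order_value))) {
    v <- leaf$order_value
    rng <- range(v, na.rm = TRUE)
    u <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
    ramp <- grDevices::hcl.colors(256, palette)
    col <- ramp[pmax(1L, ceiling(u * 255 + 1e-9))]
    col[!is.finite(v)] <- "black"
  }
  graphics::segments(leaf$x0, leaf$y0, leaf$x1, leaf$y1, col = col, lwd = lwd)
  invisible(lay)
}

#' Serialize a barrier tree to JSON
#'
#' Nodes carry `id` (internal nodes 1..n-1, leaves -1..-n), `children`,
#' `height`, and leaf payloads (`frame`, `energy`, `order_value`). Keys are
#' emitted in a stable order for diffability.
#'
#' @param tree a `barrier_tree`.
#' @param path optional output path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "barrier_tree"))
  leaves <- lapply(seq_len(nrow(tree$leaves)), function(l) list(
    id = -l, frame = tree$leaves$frame[l], energy = tree$leaves$energy[l],
    order_value = tree$leaves$order_value[l]))
  internal <- lapply(seq_along(tree$height), function(k) list(
    id = k, children = as.integer(tree$merge[k, ]), height = tree$height[k]))
  js <- jsonlite::toJSON(list(leaves = leaves, internal = internal),
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
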