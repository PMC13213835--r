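# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force neighbour-comparison scan for alternating extrema (plateaus
# collapsed to their first frame; boundaries only ever minima)
oracle_extrema <- function(y, frames = seq_along(y) - 1L) {
  keep <- c(TRUE, diff(y) != 0)
  v <- y[keep]; f <- frames[keep]
  m <- length(v)
  out <- data.frame(frame = integer(0), energy = numeric(0), kind = character(0))
  push <- function(i, k) out <<- rbind(out, data.frame(frame = f[i], energy = v[i], kind = k))
  if (m == 1L) push(1L, "minimum")
  else {
    if (v[1] < v[2]) push(1L, "minimum")
    if (m > 2) for (i in 2:(m - 1)) {
      if (v[i] < v[i - 1] && v[i] < v[i + 1]) push(i, "minimum")
      if (v[i] > v[i - 1] && v[i] > v[i + 1]) push(i, "maximum")
    }
    if (v[m] < v[m - 1]) push(m, "minimum")
  }
  out
}

# brute-force barrier between minima i < j: enumerate intervening maxima
oracle_barrier <- function(extrema, i, j) {
  mins <- which(extrema$kind == "minimum")
  lo <- min(i, j); hi <- max(i, j)
  rows <- (mins[lo] + 1):(mins[hi] - 1)
  max(extrema$energy[rows[extrema$kind[rows] == "maximum"]])
}

# exact Wilcoxon two-sided p by literal enumeration of all 2^n sign patterns
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wobs <- min(sum(r[d > 0]), sum(r[d < 0]))
  wplus <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * mean(wplus <= wobs))
}

# independent torsion construction: project the outer bonds onto the plane
# normal to the central bond and take the signed angle between them
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2n <- b2 / sqrt(sum(b2^2))
  proj <- function(v) v - sum(v * b2n) * b2n
  u <- proj(p1 - p2)
  w <- proj(p4 - p3)
  x <- sum(u * w)
  y <- sum(b2n * c(u[2] * w[3] - u[3] * w[2],
                   u[3] * w[1] - u[1] * w[3],
                   u[1] * w[2] - u[2] * w[1]))
  atan2(y, x) * 180 / pi
}

# small multi-model PDB text for IO tests: two residues (one "protein"
# glycine-like, one sugar ring), two models
make_test_pdb <- function(path, n_models = 2L, jitter = 0) {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O", "O5", "C1", "C2", "C3", "C4", "C5"),
    resno = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L),
    resname = c(rep("GLY", 4), rep("SUG", 6)),
    chain = c(rep("A", 4), rep("G", 6)))
  base <- cbind(seq_len(10), seq_len(10) %% 3, seq_len(10) %% 2)
  con <- file(path, "w")
  set.seed(42)
  for (m in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- base + if (jitter > 0) matrix(rnorm(30, 0, jitter), 10, 3) else 0
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(10), ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
      atoms$resname, atoms$chain, atoms$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.0, seq_len(10) + 10,
      substr(atoms$name, 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  path
}

# rigid rotation helper
rotate_z <- function(X, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  X %*% R
}
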