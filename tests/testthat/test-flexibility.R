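table1 <- list(
  rp_ff = c(0.7308, 0.6109, 0.6243, 0.7247, 0.5346, 0.5547),
  rp_ch = c(0.4840, 0.5716, 0.5748, 0.2559, 0.5945, 0.6655),
  rs_ff = c(0.7457, 0.5325, 0.6901, 0.7385, 0.5269, 0.6461),
  rs_ch = c(0.5105, 0.5172, 0.6296, 0.3231, 0.6219, 0.7017))

test_that("RMSF: identical frames, free oscillator, mass weighting", {
  atoms <- data.frame(name = paste0("C", 1:4), element = "C",
                      resno = rep(1:2, each = 2), resname = "GLY", chain = "A")
  X <- matrix(rnorm(12), 4, 3)
  same <- md_trajectory(array(rep(X, 3), c(4, 3, 3)), atoms)
  expect_equal(rmsf_profile(same, superpose = FALSE)$rmsf, c(0, 0))

  # one atom oscillating +/- d along x across two frames: RMSF = d
  d <- 0.8
  f1 <- rbind(c(-d, 0, 0)); f2 <- rbind(c(d, 0, 0))
  one <- md_trajectory(array(c(f1, f2), c(1, 3, 2)),
                       data.frame(name = "CA", element = "C", resno = 1L,
                                  resname = "GLY", chain = "A"))
  expect_equal(rmsf_profile(one, superpose = FALSE)$rmsf, d)

  # two-atom residue, masses 12 and 1, fluctuations a and b
  a <- 0.5; b <- 1.2
  f1 <- rbind(c(-a, 0, 0), c(10 - b, 0, 0))
  f2 <- rbind(c(a, 0, 0), c(10 + b, 0, 0))
  two <- md_trajectory(array(c(f1, f2), c(2, 3, 2)),
                       data.frame(name = c("C1", "H1"), element = c("C", "H"),
                                  resno = 1L, resname = "SUG", chain = "G"))
  got <- rmsf_profile(two, superpose = FALSE)$rmsf
  expect_equal(got, sqrt((12.011 * a^2 + 1.008 * b^2) / (12.011 + 1.008)))
})

test_that("RMSF of a rigidly moving structure vanishes after superposition", {
  set.seed(21)
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  frames <- lapply(seq(0, 120, by = 30), function(ang)
    rotate_z(X, ang) + matrix(rep(c(ang / 10, -1, 2), each = 10), 10, 3))
  coords <- array(unlist(frames), c(10, 3, length(frames)))
  atoms <- data.frame(name = paste0("C", 1:10), element = "C",
                      resno = rep(1:5, each = 2), resname = "GLY", chain = "A")
  prof <- rmsf_profile(md_trajectory(coords, atoms), fit_selection = "heavy")
  expect_lt(max(prof$rmsf), 1e-6)
})

test_that("single-frame trajectory yields a zero profile with a warning", {
  atoms <- data.frame(name = "CA", element = "C", resno = 1L,
                      resname = "GLY", chain = "A")
  tr <- md_trajectory(array(rnorm(3), c(1, 3, 1)), atoms)
  expect_warning(p <- rmsf_profile(tr), "single-frame")
  expect_equal(p$rmsf, 0)
})

test_that("B-factor conversion inverts the Debye-Waller relation", {
  expect_equal(bfactor_to_rmsf(data.frame(resid = 1, B = 0))$rmsf, 0)
  expect_equal(bfactor_to_rmsf(data.frame(resid = 1, B = 8 * pi^2 / 3))$rmsf, 1)
  expect_equal(bfactor_to_rmsf(data.frame(resid = 1, B = 8 * pi^2))$rmsf,
               sqrt(3), tolerance = 1e-12)
  expect_error(bfactor_to_rmsf(data.frame(resid = 1, B = -2)), ">= 0")
})

test_that("profile normalization: unit norm, 3-4-5 case, correlation invariance", {
  p <- normalize_profile(flex_profile(1:2, c(3, 4)))
  expect_equal(p$rmsf, c(0.6, 0.8))
  expect_true(attr(p, "normalized"))

  pn <- normalize_profile(flex_profile(1:5, rep(2, 5)))
  expect_equal(pn$rmsf, rep(1 / sqrt(5), 5))

  set.seed(2)
  for (r in 1:10) {
    x <- flex_profile(1:30, runif(30, 0.2, 2))
    y <- flex_profile(1:30, runif(30, 0.2, 2))
    expect_equal(sum(normalize_profile(x)$rmsf^2), 1, tolerance = 1e-9)
    expect_equal(pearson(normalize_profile(x), y), pearson(x, y), tolerance = 1e-12)
    expect_equal(spearman(x, normalize_profile(y)), spearman(x, y), tolerance = 1e-12)
  }
  expect_error(normalize_profile(flex_profile(1:3, rep(0, 3))), "all-zero")
})

test_that("delta RMSF subtracts by residue id and reports mismatches", {
  b <- flex_profile(1:5, c(1, 2, 3, 4, 5) / 10)
  u <- flex_profile(1:5, c(1, 2, 3, 4, 5) / 10)
  expect_equal(delta_rmsf(b, u)$delta, rep(0, 5))
  b2 <- flex_profile(1:5, u$rmsf + 0.1)
  expect_equal(delta_rmsf(b2, u)$delta, rep(0.1, 5))
  mism <- flex_profile(2:6, rep(1, 5))
  expect_error(delta_rmsf(b, mism), "only in")
})

test_that("delta RMSF recovers an injected perturbation sign pattern", {
  set.seed(19)
  base <- runif(40, 0.5, 1.5)
  sign_pattern <- rep(c(1, -1), 20)
  bound <- flex_profile(1:40, base + 0.2 * sign_pattern)
  unbound <- flex_profile(1:40, base + rnorm(40, 0, 0.01))
  d <- delta_rmsf(bound, unbound)$delta
  expect_true(all(sign(d) == sign_pattern))
})

test_that("correlations: closed-form cases and rank handling", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman(x, exp(x)), 1)        # any strictly monotone map
  expect_equal(spearman(x, -x^3), -1)
  # tied data: Pearson on mean ranks
  expect_equal(spearman(c(1, 1, 2), c(3, 5, 4)),
               pearson(c(1.5, 1.5, 3), c(1, 3, 2)))
  expect_error(pearson(c(1, 1, 1), x[1:3]), "zero variance")
  # affine invariance
  set.seed(6)
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(pearson(3 * a + 2, b), pearson(a, b), tolerance = 1e-12)
  expect_equal(spearman(exp(a), b), spearman(a, b), tolerance = 1e-12)
})

test_that("paired t test reproduces the printed force-field comparison", {
  # Pearson columns: p = 0.2850; Spearman columns: p = 0.2803
  tt_p <- paired_t_test(table1$rp_ff, table1$rp_ch)
  expect_equal(round(tt_p$p.value, 4), 0.2850)
  tt_s <- paired_t_test(table1$rs_ff, table1$rs_ch)
  expect_equal(round(tt_s$p.value, 4), 0.2803)
  # matches the base-R implementation exactly
  expect_equal(tt_p$p.value,
               t.test(table1$rp_ff, table1$rp_ch, paired = TRUE)$p.value)
  # symmetry and degenerate input
  expect_equal(paired_t_test(table1$rp_ch, table1$rp_ff)$p.value, tt_p$p.value)
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("paired t p-value tends to zero for a constant shift as noise vanishes", {
  set.seed(14)
  x <- runif(10)
  ps <- vapply(c(0.1, 0.01, 0.001), function(s)
    paired_t_test(x + 0.5 + rnorm(10, 0, s), x)$p.value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[3], 1e-10)
})

test_that("exact Wilcoxon reproduces the printed force-field comparison", {
  w_p <- wilcoxon_signed_rank(table1$rp_ff, table1$rp_ch)
  expect_equal(w_p$method, "wilcoxon-exact")
  expect_equal(w_p$p.value, 0.5625)
  expect_equal(min(w_p$w_plus, w_p$w_minus), 7)
  w_s <- wilcoxon_signed_rank(table1$rs_ff, table1$rs_ch)
  expect_equal(w_s$p.value, 0.4375)
  expect_equal(min(w_s$w_plus, w_s$w_minus), 6)
  # n = 6 all-positive differences: W- = 0, p = 2/64
  w0 <- wilcoxon_signed_rank(2:7, (2:7) - rep(1, 6))
  expect_equal(w0$p.value, 2 / 64)
})

test_that("exact Wilcoxon equals the brute-force sign enumeration", {
  set.seed(33)
  for (r in 1:30) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(0:2, 1))   # rounding produces ties and zeros
    if (all(d == 0)) d[1] <- 1
    got <- suppressWarnings(wilcoxon_signed_rank(d, rep(0, n)))
    expect_equal(got$p.value, oracle_wilcoxon_p(d))
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test when tie-free", {
  set.seed(44)
  for (r in 1:20) {
    n <- sample(4:15, 1)
    d <- rnorm(n)
    got <- wilcoxon_signed_rank(d, rep(0, n))
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(got$p.value, ref)
  }
})

test_that("signed-rank null distribution sums to one for all n up to 25", {
  for (n in c(1, 2, 5, 10, 25)) {
    null <- gagmd:::.signed_rank_null(seq_len(n))
    expect_equal(sum(null), 1, tolerance = 1e-12)
  }
})

test_that("Wilcoxon two-sided symmetry and normal branch sanity", {
  set.seed(55)
  x <- rnorm(30); y <- rnorm(30)
  a <- wilcoxon_signed_rank(x, y, mode = "normal")
  b <- wilcoxon_signed_rank(y, x, mode = "normal")
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$method, "wilcoxon-normal")
  # normal approximation tracks base R's continuity-corrected version
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)$p.value
  expect_equal(a$p.value, ref, tolerance = 1e-6)
  # exact branch symmetry
  expect_equal(wilcoxon_signed_rank(x[1:8], y[1:8])$p.value,
               wilcoxon_signed_rank(y[1:8], x[1:8])$p.value)
})

test_that("ensemble RMSF provides an experimental profile for NMR-style input", {
  set.seed(66)
  X <- matrix(rnorm(30, sd = 3), 10, 3)
  frames <- lapply(1:6, function(i) X + matrix(rnorm(30, 0, 0.2), 10, 3))
  coords <- array(unlist(frames), c(10, 3, 6))
  atoms <- data.frame(name = paste0("C", 1:10), element = "C",
                      resno = rep(1:5, each = 2), resname = "GLY", chain = "A")
  p <- ensemble_rmsf(md_trajectory(coords, atoms))
  expect_equal(attr(p, "provenance"), "ensemble")
  expect_true(all(p$rmsf > 0) && all(p$rmsf < 1))
})
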