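# Normalization, thresholding, the windowed binomial test, smoothing,
# SER calling and the permutation FDR.

test_that("lowess normalization removes the dye trend and centres the median", {
  set.seed(1)
  n <- 2000
  wce <- 2^runif(n, 6, 14)
  chip <- wce  # identical channels
  out <- lowess_normalize(chip, wce)
  expect_true(all(abs(out) < 1e-8))

  # synthetic intensity-dependent bias
  a <- runif(n, 6, 14)
  bias <- 0.5 * log10(2^a)
  chip <- 2^(a + (bias + rnorm(n, 0, 0.1)) / 2)
  wce <- 2^(a - (bias + rnorm(n, 0, 0.1)) / 2)
  out <- lowess_normalize(chip, wce)
  slope <- coef(lm(out ~ a))[2]
  expect_lt(abs(slope), 0.01)
  expect_equal(median(out), 0)
  expect_error(lowess_normalize(c(1, -1), c(1, 1)), "positive")
})

test_that("quantile normalization equalizes distributions, preserves ranks", {
  mk <- function(v) probe_track(rep("c", 3), c(1, 20, 40), rep("+", 3), v)
  out <- quantile_normalize(list(mk(c(1, 2, 3)), mk(c(2, 4, 6))))
  expect_equal(out[[1]]$ratio, c(1.5, 3, 4.5))
  expect_equal(out[[2]]$ratio, c(1.5, 3, 4.5))

  set.seed(2)
  t1 <- probe_track(rep("c", 100), seq(1, by = 17, length.out = 100),
                    rep("+", 100), rnorm(100))
  t2 <- probe_track(rep("c", 100), seq(1, by = 17, length.out = 100),
                    rep("+", 100), rnorm(100, 2, 3))
  qn <- quantile_normalize(list(t1, t2))
  expect_equal(sort(qn[[1]]$ratio), sort(qn[[2]]$ratio))
  expect_equal(order(qn[[2]]$ratio), order(t2$ratio))
  # identical tracks unchanged
  same <- quantile_normalize(list(t1, t1))
  expect_equal(same[[1]]$ratio, t1$ratio)
  t3 <- probe_track(rep("c", 50), seq(1, by = 17, length.out = 50),
                    rep("+", 50), rnorm(50))
  expect_error(quantile_normalize(list(t1, t3)), "identical probe set")
})

test_that("MAD threshold matches the hand computation and Gaussian tail", {
  expect_equal(mad_threshold(rep(2.2, 10)), 2.2)
  expect_equal(mad_threshold(c(1, 2, 3, 4, 100), n = 2.5), 5.5)
  expect_error(mad_threshold(numeric(0)), "empty")
  # Gaussian: median + 2.5 * MAD ~ 1.69 sigma, upper tail ~ 4.6%
  set.seed(4)
  x <- rnorm(2e5)
  frac <- mean(x > mad_threshold(x, 2.5))
  expect_equal(frac, pnorm(2.5 * qnorm(0.75), lower.tail = FALSE),
               tolerance = 0.1)
})

test_that("windowed binomial p equals the exhaustive pattern enumeration", {
  expect_equal(window_binom_p(0, 9, 0.3), 1)
  expect_equal(window_binom_p(9, 9, 0.5), 0.5^9)
  expect_equal(window_binom_p(4, 9, 0.03), 9.0e-5, tolerance = 0.01)
  expect_error(window_binom_p(1, 9, 0), "Pr")

  # brute force over all 2^L exceedance patterns
  brute <- function(m, L, Pr) {
    pat <- as.matrix(expand.grid(rep(list(0:1), L)))
    w <- Pr^rowSums(pat) * (1 - Pr)^(L - rowSums(pat))
    sum(w[rowSums(pat) >= m])
  }
  for (L in c(5, 9, 12)) {
    for (m in c(1, floor(L / 2), L)) {
      for (Pr in c(0.03, 0.3)) {
        expect_equal(window_binom_p(m, L, Pr), brute(m, L, Pr),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("triple boxcar smoothing: constants, impulse response, max bound", {
  const <- probe_track(rep("c", 30), seq(1, by = 17, length.out = 30),
                       rep("+", 30), rep(1.7, 30))
  expect_equal(smooth_track(const, 5, 3)$ratio, rep(1.7, 30))

  imp <- probe_track(rep("c", 31), seq(1, by = 17, length.out = 31),
                     rep("+", 31), c(rep(0, 15), 1, rep(0, 15)))
  sm <- smooth_track(imp, 5, 3)
  expect_equal(sm$ratio[16], 19 / 125)
  expect_lte(max(sm$ratio), 1)

  set.seed(5)
  r <- probe_track(rep("c", 200), seq(1, by = 17, length.out = 200),
                   rep("+", 200), rnorm(200))
  expect_lte(max(smooth_track(r, 5, 3)$ratio), max(r$ratio))
})

test_that("SER calling enforces the consecutive-run and binomial rules", {
  # flat track: no SERs
  flat <- probe_track(rep("c", 100), seq(1, by = 17, length.out = 100),
                      rep("+", 100), rep(0.01, 100))
  expect_equal(nrow(call_sers(flat)), 0)

  # exactly 3 consecutive high probes among noise: below the 4-probe minimum
  set.seed(6)
  vals <- rnorm(400, 0, 0.2)
  vals[200:202] <- 5
  tr3 <- probe_track(rep("c", 400), seq(1, by = 17, length.out = 400),
                     rep("+", 400), vals)
  sers3 <- call_sers(tr3)
  expect_false(any(sers3$start_bp <= tr3$start[200] &
                     sers3$end_bp >= tr3$start[202]))

  # noiseless planted peak: one SER, apex at the planted position
  tr <- toy_peak_track(height = 3, noise_sd = 0)
  set.seed(7)
  tr$ratio <- tr$ratio + rnorm(nrow(tr), 0, 0.15)
  sers <- call_sers(tr)
  expect_equal(nrow(sers), 1)
  expect_lte(abs(sers$apex_bp - 5000), 100)

  # every SER probe run is above the threshold
  fx <- chip_fixture()
  sers <- call_sers(fx$track)
  thr <- attr(sers, "threshold")
  for (i in seq_len(min(10, nrow(sers)))) {
    sel <- fx$track$chrom == sers$chrom[i] &
      fx$track$start >= sers$start_bp[i] &
      fx$track$start <= sers$end_bp[i] - 49
    expect_true(all(fx$track$ratio[sel] > thr))
    expect_gte(sum(sel), 4)
  }
  # short track warns
  short <- probe_track(rep("c", 5), seq(1, by = 17, length.out = 5),
                       rep("+", 5), rnorm(5))
  expect_warning(out <- call_sers(short), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("SER calls are invariant under a constant shift of the track", {
  fx <- chip_fixture()
  shifted <- fx$track
  shifted$ratio <- shifted$ratio + 5
  a <- call_sers(fx$track)
  b <- call_sers(shifted)
  expect_equal(a$apex_bp, b$apex_bp)
  expect_equal(a$level + 5, b$level, tolerance = 1e-9)
})

test_that("apex finding takes the smoothed maximum, leftmost on ties", {
  tr <- probe_track(rep("c", 9), seq(1, by = 17, length.out = 9),
                    rep("+", 9), c(0, 1, 2, 3, 2, 1, 0, 0, 0))
  ap <- find_apex(list(chrom = "c", start_bp = 1, end_bp = 200),
                  tr)  # unsmoothed symmetric input
  expect_equal(ap$apex_bp, tr$start[4] + 25)
  # monotone ramp: apex at last probe
  ramp <- probe_track(rep("c", 9), seq(1, by = 17, length.out = 9),
                      rep("+", 9), 1:9)
  ap2 <- find_apex(list(chrom = "c", start_bp = 1, end_bp = 200), ramp)
  expect_equal(ap2$apex_bp, ramp$start[9] + 25)
  # two equal maxima: leftmost
  tie <- probe_track(rep("c", 9), seq(1, by = 17, length.out = 9),
                     rep("+", 9), c(0, 1, 3, 1, 0, 1, 3, 1, 0))
  ap3 <- find_apex(list(chrom = "c", start_bp = 1, end_bp = 200), tie)
  expect_equal(ap3$apex_bp, tie$start[3] + 25)
})

test_that("permutation FDR is near 1 for noise and small for signal", {
  set.seed(8)
  noise <- probe_track(rep("c", 3000), seq(1, by = 17, length.out = 3000),
                       rep("+", 3000), rnorm(3000, 0, 0.3))
  f <- estimate_fdr(noise, n_perm = 20, seed = 1)
  if (f$observed > 0) expect_gte(f$fdr, 0.5)

  fx <- chip_fixture()
  fs <- estimate_fdr(fx$track, n_perm = 20, seed = 1)
  expect_lt(fs$fdr, 0.04)
  expect_error(estimate_fdr(fx$track, n_perm = 0), "at least 20")
})
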