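rand_analytic <- function(n, seed = 1) {
  set.seed(seed)
  complex(real = rnorm(n), imaginary = rnorm(n))
}

test_that("orthogonalization satisfies its algebraic identities", {
  x <- rand_analytic(64)
  expect_true(all(orthogonalize(x, x) == 0))
  expect_equal(as.numeric(orthogonalize(1i * x, x)), Mod(x),
               tolerance = 1e-14)

  # elementwise oracle, written out sample by sample
  y <- rand_analytic(64, seed = 2)
  want <- vapply(seq_along(x), function(t) {
    Im(y[t] * Conj(x[t]) / Mod(x[t]))
  }, numeric(1))
  expect_lt(max(abs(orthogonalize(y, x) - want)), 1e-12)

  # insensitive to positive real rescaling of the reference
  expect_equal(as.numeric(orthogonalize(y, 7.3 * x)),
               as.numeric(orthogonalize(y, x)), tolerance = 1e-12)
})

test_that("near-zero reference samples are guarded, not propagated", {
  x <- rand_analytic(32)
  y <- rand_analytic(32, seed = 5)
  x[c(4, 9)] <- 0
  d <- orthogonalize(y, x)
  expect_identical(attr(d, "excluded"), c(4L, 9L))
  expect_true(all(is.finite(d)))
  expect_true(all(d[c(4, 9)] == 0))
})

test_that("envelope is the elementwise modulus", {
  expect_equal(envelope(complex(real = 3, imaginary = 4)), 5)
  expect_equal(envelope(0 + 0i), 0)
  z <- rand_analytic(200, seed = 3)
  expect_equal(envelope(z), sqrt(Re(z)^2 + Im(z)^2), tolerance = 1e-15)
})

test_that("identical and purely-leaked signals give null pair correlation", {
  set.seed(21)
  ts <- roi_timeseries(matrix(rnorm(2 * 10000), 2), fs = 250)
  sig <- analytic_band(ts, "alpha")
  win <- make_windows(ncol(sig$data), sig$fs, offset = sig$transient)
  x <- sig$data[1, ]

  # Y = X: the orthogonalized residual has zero envelope, value 0 by
  # convention
  expect_equal(as.numeric(pair_correlation(x, x, win)), 0)

  # Y = a X, a > 0: pure zero-lag leakage of a single source
  expect_lt(abs(pair_correlation(x, 2.5 * x, win)), 0.05)
})

test_that("shared envelope modulation at kappa = 0.8 is recovered", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    fs <- 250
    T <- 120 * fs
    carriers <- bandpass(roi_timeseries(matrix(rnorm(2 * T), 2), fs),
                         "alpha")
    slow <- bandpass(roi_timeseries(matrix(rnorm(3 * T), 3), fs),
                     band_spec("slow", 0.1, 1), taper = 0.5)
    z <- slow$data / apply(slow$data, 1, sd)
    g <- z[3, ]
    sp <- function(v) log1p(exp(v))      # deep modulation, no noise floor
    a1 <- sp(2 * (sqrt(0.2) * z[1, ] + sqrt(0.8) * g))
    a2 <- sp(2 * (sqrt(0.2) * z[2, ] + sqrt(0.8) * g))
    s <- rbind(a1 * carriers$data[1, ], a2 * carriers$data[2, ])
    sig <- analytic_band(roi_timeseries(s, fs), "alpha")
    win <- make_windows(ncol(sig$data), fs, offset = sig$transient)
    r <- pair_correlation(sig$data[1, ], sig$data[2, ], win)
    if (r > 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("connectivity matrix is symmetric, matches the pairwise
          estimator, and is scale invariant", {
  spec <- cohort_spec(n_hc = 2, n_bd = 2, n_rois = 6, duration_s = 120,
                      fs = 250, seed = 5,
                      coupling = list(coupling_spec(
                        "alpha", rois = c(2, 5), coupling = 0.6,
                        subject_sd = 0)),
                      leakage = leakage_spec(0))
  ts <- simulate_subject(spec, "HC", 5)
  sig <- analytic_band(ts, "alpha")
  win <- make_windows(ncol(sig$data), sig$fs, offset = sig$transient)
  C <- connectivity_matrix(sig, win)

  expect_identical(C, t(C))
  expect_true(all(is.na(diag(C))))
  expect_true(all(abs(C[upper.tri(C)]) <= 1))

  # compiled all-pairs kernel agrees with the plain-R pairwise estimator
  for (pr in list(c(1, 2), c(2, 5), c(3, 6))) {
    expect_equal(C[pr[1], pr[2]],
                 as.numeric(pair_correlation(sig$data[pr[1], ],
                                             sig$data[pr[2], ], win)),
                 tolerance = 1e-10)
  }

  # positive rescaling of one ROI leaves the matrix unchanged
  ts2 <- ts
  ts2$data[3, ] <- 50 * ts2$data[3, ]
  C2 <- connectivity_matrix(analytic_band(ts2, "alpha"), win)
  expect_equal(C, C2, tolerance = 1e-9)

  # two ROIs: a single value replicated symmetrically
  sig2 <- analytic_band(roi_timeseries(ts$data[1:2, ], ts$fs), "alpha")
  C22 <- connectivity_matrix(sig2, win)
  expect_equal(C22[1, 2], C22[2, 1])
})

test_that("log-envelope variant stays bounded and tracks the default", {
  set.seed(12)
  ts <- roi_timeseries(matrix(rnorm(3 * 20000), 3), fs = 250)
  sig <- analytic_band(ts, "alpha")
  win <- make_windows(ncol(sig$data), sig$fs, offset = sig$transient)
  Craw <- connectivity_matrix(sig, win)
  Clog <- connectivity_matrix(sig, win, log_envelopes = TRUE)
  off <- upper.tri(Clog)
  expect_true(all(abs(Clog[off]) <= 1))
  expect_identical(Clog, t(Clog))
  # same null signals: both variants hover near zero
  expect_lt(max(abs(Clog[off])), 0.35)
  expect_lt(max(abs(Clog[off] - Craw[off])), 0.3)

  r <- pair_correlation(sig$data[1, ], sig$data[2, ], win,
                        log_envelopes = TRUE)
  expect_equal(as.numeric(r), Clog[1, 2], tolerance = 1e-12)
})

test_that("planted coupled pair holds the maximum off-diagonal entry", {
  hits <- 0L
  for (seed in 1:20) {
    spec <- cohort_spec(n_hc = 2, n_bd = 2, n_rois = 6, duration_s = 240,
                        fs = 250, seed = seed,
                        coupling = list(coupling_spec(
                          "alpha", rois = c(2, 5), coupling = 0.8,
                          subject_sd = 0)),
                        leakage = leakage_spec(0))
    ts <- simulate_subject(spec, "HC", seed)
    sig <- analytic_band(ts, "alpha")
    win <- make_windows(ncol(sig$data), sig$fs, offset = sig$transient)
    C <- connectivity_matrix(sig, win)
    ut <- which(upper.tri(C), arr.ind = TRUE)
    top <- ut[which.max(C[ut]), ]
    if (all(sort(top) == c(2, 5))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("median aggregation stays inside the window-value range and
          tightens with more windows", {
  set.seed(31)
  fs <- 250
  ts <- roi_timeseries(matrix(rnorm(2 * 95000), 2), fs)
  sig <- analytic_band(ts, "alpha")
  win60 <- make_windows(ncol(sig$data), fs, offset = sig$transient)
  expect_gte(nrow(win60), 60)
  r <- pair_correlation(sig$data[1, ], sig$data[2, ], win60)
  wv <- attr(r, "window_values")
  expect_gte(as.numeric(r), min(wv))
  expect_lte(as.numeric(r), max(wv))

  # estimator variance decreases with window count (10 vs 60 windows)
  r10 <- r60 <- numeric(12)
  for (k in 1:12) {
    set.seed(100 + k)
    tsk <- roi_timeseries(matrix(rnorm(2 * 95000), 2), fs)
    sk <- analytic_band(tsk, "alpha")
    wk <- make_windows(ncol(sk$data), fs, offset = sk$transient)
    r60[k] <- pair_correlation(sk$data[1, ], sk$data[2, ], wk)
    r10[k] <- pair_correlation(sk$data[1, ], sk$data[2, ], wk[1:10, ])
  }
  expect_lt(var(r60), var(r10))
})
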