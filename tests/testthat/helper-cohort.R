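# Shared fixtures, built in code. The heavier simulation studies are
# computed once and cached so several test files can assert against the
# same runs.

.cache <- new.env(parent = emptyenv())

# the desk-scale geometry used throughout the tests
desk_spec <- function(seed, ...) {
  cohort_spec(n_hc = 10, n_bd = 10, n_rois = 60, duration_s = 120, fs = 250,
              seed = seed, ...)
}

# per-subject community edge counts for a whole cohort at one band
cohort_counts <- function(cohort, band, partition, density = 0.15) {
  lapply(cohort$subjects, subject_edge_counts, band = band,
         partition = partition, density = density)
}

# Recovery study: 20 desk-scale cohorts with the default planted
# patient-elevated left-LM high-beta coupling. For each replicate: the
# rank of the planted measure among the 105 by |t|, its t (HC - BD), and
# the within-BD Spearman rho between the planted count and the
# depression scores.
recovery_study <- function() {
  if (!is.null(.cache$recovery)) return(.cache$recovery)
  res <- lapply(1:20, function(seed) {
    spec <- desk_spec(seed)
    coh <- simulate_cohort(spec)
    counts <- cohort_counts(coh, "high_beta", spec$partition)
    comp <- edgewise_group_comparison(counts, coh$groups)
    ord <- order(-abs(comp$t))
    sc <- symptom_correlations(counts, coh$scores, "intra:LM_L",
                               scales = c("bdi", "hamd"))
    list(rank = which(comp$measure[ord] == "intra:LM_L"),
         t = comp$t[comp$measure == "intra:LM_L"],
         rho_bdi = sc$rho[sc$scale == "bdi"],
         rho_hamd = sc$rho[sc$scale == "hamd"])
  })
  .cache$recovery <- res
  res
}

# Null study: 6 cohorts with no group effect (multiplier 1), one band;
# pooled edgewise p-values / flags over 6 x 105 measures.
null_study <- function() {
  if (!is.null(.cache$null)) return(.cache$null)
  rows <- lapply(1:6, function(seed) {
    spec <- desk_spec(1000L + seed, coupling = list(
      coupling_spec("high_beta", community = "LM_L", coupling = 0.10,
                    group_multiplier = 1, subject_sd = 0.10)))
    coh <- simulate_cohort(spec)
    counts <- cohort_counts(coh, "high_beta", spec$partition)
    edgewise_group_comparison(counts, coh$groups)
  })
  .cache$null <- do.call(rbind, rows)
  .cache$null
}

# Leakage study: 20 single-subject replicates, 8 independent sources
# (kappa = 0) under nearest-neighbour instantaneous mixing at eps = 0.3;
# mean plain and orthogonalized AEC over the mixed adjacent pairs,
# >= 60 sliding windows each.
leakage_study <- function() {
  if (!is.null(.cache$leakage)) return(.cache$leakage)
  res <- t(vapply(1:20, function(seed) {
    spec <- cohort_spec(n_hc = 2, n_bd = 2, n_rois = 8, duration_s = 360,
                        fs = 250, seed = seed,
                        coupling = list(coupling_spec(
                          "alpha", rois = 1:8, coupling = 0, subject_sd = 0)),
                        leakage = leakage_spec(0.3, "knn", k = 1))
    ts <- simulate_subject(spec, "HC", seed)
    sig <- analytic_band(ts, "alpha")
    win <- make_windows(ncol(sig$data), sig$fs, offset = sig$transient)
    Co <- connectivity_matrix(sig, win)
    Cp <- connectivity_matrix(sig, win, method = "plain")
    nb <- abs(row(Co) - col(Co)) == 1
    c(n_windows = nrow(win), orth = mean(Co[nb]), plain = mean(Cp[nb]))
  }, numeric(3)))
  .cache$leakage <- res
  res
}

# brute-force Hilbert transform by direct O(n^2) DFT, independent of fft()
slow_hilbert <- function(x) {
  n <- length(x)
  ks <- 0:(n - 1)
  X <- vapply(ks, function(k) {
    sum(x * exp(-2i * pi * k * ks / n))
  }, complex(1))
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Z <- X * h
  vapply(ks, function(t) {
    sum(Z * exp(2i * pi * ks * t / n)) / n
  }, complex(1))
}
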