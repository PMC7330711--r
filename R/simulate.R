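# Synthetic cohort generator.
#
# Signal model, per band b carrying planted activity: each ROI i gets a
# band-limited unit-variance noise carrier c_i(t) and a slow positive
# envelope a_i(t) = softplus( sqrt(1-k) e_i(t) + sqrt(k) g(t) ), where e_i
# and g are independent low-pass (< 1 Hz) filtered Gaussian noises, k is
# the planted envelope coupling (shared modulator g within a coupled set),
# and the source signal is s_i(t) = sum_b a_i(t) c_i(t) + broadband noise.
# The observed series is X = M S with M an instantaneous (zero-phase-lag)
# mixing matrix emulating source leakage. Group effects multiply k in one
# group; clinical scores are linear in the per-subject k plus noise.

softplus <- function(z) {
  y <- log1p(exp(z))
  big <- z > 30                       # avoid overflow; softplus(z) ~ z there
  if (any(big)) y[big] <- z[big]
  y
}

#' Planted envelope-coupling specification
#'
#' @param band Canonical band name (see [band_table()]).
#' @param rois Integer ROI indices of the coupled set, or `NULL` to use
#'   `community`.
#' @param community Community name (e.g. `"LM_L"`) resolved against the
#'   cohort's partition.
#' @param coupling Target envelope-coupling level `k` in `[0, 1)`: the
#'   fraction of pre-rectification modulator variance shared within the set.
#' @param group_multiplier Factor applied to `coupling` for the patient
#'   group (default 1 = no group effect).
#' @param subject_sd SD of the per-subject coupling draw around the group
#'   mean (default 0.08; draws are clamped to `[0, 0.95]`).
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(band, rois = NULL, community = NULL, coupling,
                          group_multiplier = 1, subject_sd = 0.08) {
  band <- as_band_spec(band)$name
  if (!(coupling >= 0 && coupling < 1)) {
    stop("'coupling' must be in [0, 1), got ", coupling, call. = FALSE)
  }
  if (coupling * group_multiplier >= 1) {
    stop("coupling * group_multiplier must stay below 1", call. = FALSE)
  }
  if (is.null(rois) && is.null(community)) {
    stop("give either 'rois' or 'community'", call. = FALSE)
  }
  structure(list(band = band, rois = rois, community = community,
                 coupling = coupling, group_multiplier = group_multiplier,
                 subject_sd = subject_sd),
            class = "coupling_spec")
}

#' Instantaneous source-leakage mixing specification
#'
#' Mixing is real-valued and zero-phase-lag only — exactly the mechanism
#' orthogonalization is designed to cancel. Each row of the mixing matrix
#' has weight 1 on the ROI itself and `strength` on each neighbour, then is
#' normalized to unit sum of absolute weights, so `strength = 0` gives the
#' identity.
#'
#' @param strength Leakage strength `eps >= 0`.
#' @param structure `"all"` (every pair mixes) or `"knn"` (ROIs within `k`
#'   index positions).
#' @param k Neighbourhood half-width for `"knn"`.
#' @return Object of class `leakage_spec`.
#' @export
leakage_spec <- function(strength = 0, structure = c("all", "knn"), k = 2L) {
  structure <- match.arg(structure)
  stopifnot(strength >= 0, k >= 1)
  structure(list(strength = strength, structure = structure, k = as.integer(k)),
            class = "leakage_spec")
}

#' Mixing matrix implied by a leakage specification
#' @param n Number of ROIs.
#' @param leakage A [leakage_spec()].
#' @return `n x n` row-normalized mixing matrix (identity when
#'   `strength = 0`).
#' @export
mixing_matrix <- function(n, leakage) {
  stopifnot(inherits(leakage, "leakage_spec"))
  M <- diag(n)
  if (leakage$strength > 0) {
    if (leakage$structure == "all") {
      M[row(M) != col(M)] <- leakage$strength
    } else {
      d <- abs(row(M) - col(M))
      M[d >= 1 & d <= leakage$k] <- leakage$strength
    }
  }
  M / rowSums(abs(M))
}

#' Synthetic cohort specification
#'
#' Defaults mirror the emulated acquisition: 22 controls, 17 patients,
#' 7-minute recordings at 1000 Hz over 446 cortical ROIs, one planted
#' patient-elevated intra-community coupling in the left limbic community
#' at high beta, weak nearest-neighbour leakage, and clinical scales whose
#' depressive scores rise with the planted coupling. Tests and the worked
#' examples use a reduced desk geometry (fewer ROIs, shorter recordings,
#' 250 Hz) by overriding the size arguments; the model is unchanged.
#'
#' @param n_hc,n_bd Group sizes (controls, patients).
#' @param n_rois Number of ROIs.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed; fixes every random draw of the cohort.
#' @param coupling List of [coupling_spec()]s.
#' @param leakage A [leakage_spec()].
#' @param noise_sd Broadband noise SD added to every ROI (default 1; the
#'   band-limited signal has unit carrier variance, so in-band SNR is set
#'   by the band's share of the noise spectrum).
#' @param mod_depth Modulation depth: the pre-rectification modulator is
#'   `mod_depth * z` with `z` unit-variance, so the envelope is
#'   `softplus(mod_depth * z)`. Default 0.5, keeping the envelope
#'   coefficient of variation in a moderate, physiological range.
#' @param score_model Named list per clinical scale of
#'   `c(intercept, slope, sd)`; the score is
#'   `intercept + slope * k_subject + N(0, sd)`, truncated at 0 and rounded
#'   (scale scores are integers). `k_subject` is the subject's draw for
#'   `coupling[[score_coupling]]`.
#' @param score_coupling Index of the coupling spec the scores track.
#' @param labels Optional ROI labels.
#' @param partition Optional `network_partition`; default
#'   [make_default_partition()] over the labels.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 22L, n_bd = 17L, n_rois = 446L,
                        duration_s = 420, fs = 1000, seed = 1L,
                        coupling = list(
                          coupling_spec("high_beta", community = "LM_L",
                                        coupling = 0.10,
                                        group_multiplier = 4.2,
                                        subject_sd = 0.10)),
                        leakage = leakage_spec(0.1, "knn", k = 2L),
                        noise_sd = 1, mod_depth = 0.5,
                        score_model = list(
                          bdi  = c(intercept = 2,   slope = 80, sd = 4),
                          hamd = c(intercept = 1,   slope = 30, sd = 2),
                          asrm = c(intercept = 3.5, slope = 0,  sd = 4),
                          ymrs = c(intercept = 0.5, slope = 0,  sd = 1.5)),
                        score_coupling = 1L,
                        labels = NULL, partition = NULL) {
  stopifnot(n_hc > 0, n_bd > 0, n_rois > 0, duration_s > 0, fs > 0,
            noise_sd >= 0, mod_depth > 0)
  if (is.null(labels)) labels <- sprintf("roi_%03d", seq_len(n_rois))
  stopifnot(length(labels) == n_rois)
  if (is.null(partition)) partition <- make_default_partition(labels)
  stopifnot(length(partition) == n_rois)
  for (cs in coupling) {
    stopifnot(inherits(cs, "coupling_spec"))
    if (!is.null(cs$community) && !cs$community %in% partition) {
      stop("coupling references community '", cs$community,
           "' which is empty in the partition", call. = FALSE)
    }
    if (!is.null(cs$rois) && any(cs$rois < 1 | cs$rois > n_rois)) {
      stop("coupling references ROI indices outside 1..", n_rois,
           call. = FALSE)
    }
  }
  structure(list(n_hc = as.integer(n_hc), n_bd = as.integer(n_bd),
                 n_rois = as.integer(n_rois), duration_s = duration_s,
                 fs = fs, seed = as.integer(seed), coupling = coupling,
                 leakage = leakage, noise_sd = noise_sd,
                 mod_depth = mod_depth, score_model = score_model,
                 score_coupling = as.integer(score_coupling),
                 labels = labels, partition = partition),
            class = "cohort_spec")
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 104729 * as.double(i)) %% 2147483399) + 1L
}

.coupled_rois <- function(cs, spec) {
  if (!is.null(cs$rois)) return(as.integer(cs$rois))
  which(unname(spec$partition) == cs$community)
}

# Stationary Gaussian noise with a prescribed band-limited spectrum,
# synthesized directly in the frequency domain (equivalent in law to
# filtering white noise with the same gain): independent complex-Gaussian
# Fourier coefficients shaped by the gain, Hermitian-mirrored, inverse
# transformed, and column-normalized to zero mean / unit variance.
.spectral_noise <- function(n_samples, n_series, fs, gain_fun) {
  T <- as.integer(n_samples)
  k_half <- (T - 1L) %/% 2L
  f_pos <- (1:k_half) / T * fs
  g <- gain_fun(f_pos)
  act <- which(g > 0)
  Z <- matrix(0 + 0i, T, n_series)
  if (length(act)) {
    draws <- matrix(rnorm(2L * length(act) * n_series), ncol = n_series)
    zp <- complex(real = draws[seq_along(act), , drop = FALSE],
                  imaginary = draws[length(act) + seq_along(act), , drop = FALSE])
    dim(zp) <- c(length(act), n_series)
    Z[1L + act, ] <- zp * g[act]
    Z[T + 1L - act, ] <- Conj(Z[1L + act, , drop = FALSE])
  }
  if (T %% 2L == 0L) {
    gn <- gain_fun(fs / 2)
    if (gn > 0) Z[T / 2L + 1L, ] <- gn * rnorm(n_series)
  }
  y <- Re(stats::mvfft(Z, inverse = TRUE))
  .center_scale(y)
}

# column-wise zero mean / unit SD, in place by column to avoid sweeps
.center_scale <- function(y) {
  Tn <- nrow(y)
  mu <- colMeans(y)
  s2 <- colSums(y * y) / Tn - mu^2
  sdy <- sqrt(pmax(s2, 0) * Tn / (Tn - 1))
  sdy[sdy == 0] <- 1
  for (k in seq_len(ncol(y))) y[, k] <- (y[, k] - mu[k]) / sdy[k]
  y
}

# Low-pass (< 1 Hz) unit-variance modulator noise, generated at a reduced
# internal rate (8 Hz) and linearly interpolated up to fs: the modulator
# has no content above 2 Hz, so the decimated grid resolves it fully.
.slow_noise <- function(n_samples, n_series, fs) {
  fs_slow <- 8
  if (fs <= fs_slow) {
    return(.spectral_noise(n_samples, n_series, fs,
                           function(f) .bp_gain(f + 1, 1, 2, 1)))
  }
  T_s <- max(32L, as.integer(ceiling(n_samples * fs_slow / fs)) + 2L)
  ys <- .spectral_noise(T_s, n_series, fs_slow,
                        function(f) .bp_gain(f + 1, 1, 2, 1))  # lp at 1 Hz
  t_hi <- (seq_len(n_samples) - 1L) / fs
  t_lo <- (seq_len(T_s) - 1L) / fs_slow
  y <- matrix(0, n_samples, n_series)
  for (k in seq_len(n_series)) {
    y[, k] <- approx(t_lo, ys[, k], xout = t_hi, rule = 2L)$y
  }
  .center_scale(y)
}

# Band-limited unit-variance carrier noise.
.carrier_noise <- function(n_samples, n_series, fs, band) {
  .spectral_noise(n_samples, n_series, fs,
                  function(f) .bp_gain(f, band$f_low, band$f_high, 0.5))
}

#' Simulate one subject's ROI time series
#'
#' Bit-identical output for identical `(spec, group, subject_seed)`. The
#' per-subject coupling draws are returned in the `kappa` attribute (one
#' value per coupling spec), which [simulate_cohort()] feeds into the
#' clinical-score model.
#'
#' @param spec A [cohort_spec()].
#' @param group `"HC"` or `"BD"`; the patient group gets
#'   `coupling * group_multiplier`.
#' @param subject_seed Integer seed fixing all draws for this subject.
#' @return A [roi_timeseries()] with attribute `kappa`.
#' @export
simulate_subject <- function(spec, group, subject_seed) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% c("HC", "BD"))
  set.seed(as.integer(subject_seed))
  n <- spec$n_rois
  T <- as.integer(round(spec$duration_s * spec$fs))

  # per-subject coupling draws (fixed order: one per coupling spec)
  kappa <- vapply(spec$coupling, function(cs) {
    mu <- cs$coupling * if (group == "BD") cs$group_multiplier else 1
    min(max(rnorm(1L, mu, cs$subject_sd), 0), 0.95)
  }, numeric(1L))

  S <- matrix(rnorm(n * T, sd = spec$noise_sd), nrow = n)  # broadband noise

  bands <- unique(vapply(spec$coupling, `[[`, "", "band"))
  for (bn in bands) {
    band <- band_spec(bn)
    if (band$f_high + 0.5 >= spec$fs / 2) {
      stop("band '", bn, "' is invalid for fs = ", spec$fs, " Hz",
           call. = FALSE)
    }
    specs_b <- which(vapply(spec$coupling, `[[`, "", "band") == bn)
    k_roi <- numeric(n)                       # coupling per ROI in this band
    set_id <- integer(n)                      # which coupled set, 0 = none
    for (s in specs_b) {
      members <- .coupled_rois(spec$coupling[[s]], spec)
      k_roi[members] <- kappa[s]
      set_id[members] <- s
    }
    E <- .slow_noise(T, n, spec$fs)           # private modulators e_i
    G <- .slow_noise(T, length(specs_b), spec$fs)  # shared modulators g
    colnames(G) <- as.character(specs_b)
    C <- .carrier_noise(T, n, spec$fs, band)
    for (i in seq_len(n)) {
      z <- if (set_id[i] > 0L) {
        sqrt(1 - k_roi[i]) * E[, i] +
          sqrt(k_roi[i]) * G[, as.character(set_id[i])]
      } else E[, i]
      S[i, ] <- S[i, ] + softplus(spec$mod_depth * z) * C[, i]
    }
  }

  M <- mixing_matrix(n, spec$leakage)
  X <- M %*% S
  out <- roi_timeseries(X, fs = spec$fs, labels = spec$labels, group = group)
  attr(out, "kappa") <- kappa
  out
}

#' Simulate a full cohort with clinical scores
#'
#' Controls first, then patients; subject seeds are derived
#' deterministically from `spec$seed`, so identical specs give bit-identical
#' cohorts. Clinical scores follow the linear score model on the subject's
#' planted coupling, truncated at 0 and rounded to integers; observer-rated
#' scales (`hamd`, `ymrs`) are reported for patients only.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (list of [roi_timeseries()]), `scores`
#'   (data frame: `subject_id`, `group`, `kappa`, one column per scale) and
#'   `groups` (character vector).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_hc + spec$n_bd < 4L) {
    stop("cohort must have at least 4 subjects for downstream statistics",
         call. = FALSE)
  }
  groups <- c(rep("HC", spec$n_hc), rep("BD", spec$n_bd))
  ids <- sprintf("sub-%02d", seq_along(groups))
  subjects <- vector("list", length(groups))
  kappa <- numeric(length(groups))
  for (i in seq_along(groups)) {
    subjects[[i]] <- simulate_subject(spec, groups[i], derive_seed(spec$seed, i))
    subjects[[i]]$subject_id <- ids[i]
    kappa[i] <- attr(subjects[[i]], "kappa")[spec$score_coupling]
  }
  set.seed(derive_seed(spec$seed, length(groups) + 1L))
  scores <- data.frame(subject_id = ids, group = groups, kappa = kappa,
                       stringsAsFactors = FALSE)
  for (sc in names(spec$score_model)) {
    p <- spec$score_model[[sc]]
    raw <- p[["intercept"]] + p[["slope"]] * kappa +
      rnorm(length(kappa), 0, p[["sd"]])
    scores[[sc]] <- round(pmax(raw, 0))
  }
  if ("hamd" %in% names(scores)) scores$hamd[groups == "HC"] <- NA_real_
  if ("ymrs" %in% names(scores)) scores$ymrs[groups == "HC"] <- NA_real_
  list(subjects = subjects, scores = scores, groups = groups)
}

#' Write cohort clinical scores as TSV
#' @param scores Score data frame from [simulate_cohort()].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort score TSV
#' @param path Path written by [write_scores()].
#' @return Data frame.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}
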