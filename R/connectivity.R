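# Orthogonalized amplitude-envelope correlation (AEC).
#
# The estimator removes the zero-phase-lag component of one analytic signal
# with respect to the other before envelope extraction, so instantaneous
# source leakage cannot produce spurious correlation; the two
# orthogonalization directions are averaged and window values are reduced
# by the median.

#' Orthogonalize one analytic signal with respect to another
#'
#' `Y_perp_X(t) = Im( Y(t) * Conj(X(t)) / |X(t)| )`: the component of `Y`
#' in quadrature with `X`, i.e. with the instantaneous zero-lag part along
#' `X` removed. The result is unchanged by any positive real rescaling of
#' `X`. Samples where `|X| < 1e-12 * max|X|` carry no usable phase
#' reference; they are set to 0 and their indices returned in the
#' `excluded` attribute (correlation routines drop them).
#'
#' @param Y,X Complex vectors of equal length.
#' @return Real vector of the same length, with attribute `excluded`
#'   (integer indices of guarded samples, possibly empty).
#' @export
#' @examples
#' x <- complex(real = rnorm(8), imaginary = rnorm(8))
#' all(orthogonalize(x, x) == 0)        # Y = X has no quadrature part
#' all.equal(orthogonalize(1i * x, x), as.numeric(Mod(x)))
orthogonalize <- function(Y, X) {
  stopifnot(length(Y) == length(X))
  Y <- as.complex(Y)
  X <- as.complex(X)
  ax <- Mod(X)
  bad <- which(ax < 1e-12 * max(ax, 0))
  out <- numeric(length(X))
  ok <- setdiff(seq_along(X), bad)
  out[ok] <- Im(Y[ok] * Conj(X[ok]) / ax[ok])
  attr(out, "excluded") <- bad
  out
}

#' Power envelope of an analytic signal
#'
#' The elementwise modulus `|X| = sqrt(X * Conj(X))`. For the (real-valued)
#' orthogonalized series the envelope is likewise its absolute value.
#'
#' @param X Complex (or real) vector.
#' @return Nonnegative real vector.
#' @export
envelope <- function(X) Mod(X)

# Pearson correlation with the zero-variance convention: a window where
# either envelope has no variance contributes 0 (flagged by the caller).
.pearson0 <- function(a, b) {
  if (length(a) < 2L) return(list(r = 0, degenerate = TRUE))
  va <- var(a)
  vb <- var(b)
  if (!is.finite(va) || !is.finite(vb) || va <= 0 || vb <= 0) {
    return(list(r = 0, degenerate = TRUE))
  }
  list(r = cor(a, b), degenerate = FALSE)
}

#' Windowed envelope correlation for one ROI pair
#'
#' For each window the orthogonalized estimator computes
#' `r1 = Pearson(Env(Y_perp_X), Env(X))` and
#' `r2 = Pearson(Env(X_perp_Y), Env(Y))`, takes `(r1 + r2)/2`, and the
#' final value is the median across windows. `method = "plain"` correlates
#' the raw envelopes `|X|`, `|Y|` instead (no leakage correction) — kept as
#' the internal comparison the leakage-robustness checks are phrased
#' against. Windows where an envelope is constant contribute 0 to that
#' direction and are counted in the `n_degenerate` attribute.
#'
#' @param X,Y Complex vectors (analytic signals) of equal length.
#' @param windows Data frame from [make_windows()] (0-based half-open
#'   `start`, `stop`).
#' @param method `"orthogonalized"` (default) or `"plain"`.
#' @param log_envelopes Correlate log-transformed envelopes instead of raw
#'   ones (default `FALSE`, the reference behaviour). Envelope values are
#'   floored at `1e-12` of their window maximum before the log.
#' @return Scalar in `[-1, 1]` with attributes `window_values` and
#'   `n_degenerate`.
#' @export
pair_correlation <- function(X, Y, windows,
                             method = c("orthogonalized", "plain"),
                             log_envelopes = FALSE) {
  method <- match.arg(method)
  stopifnot(length(X) == length(Y), nrow(windows) >= 1L)
  env_tr <- if (log_envelopes) {
    function(e) log(pmax(e, 1e-12 * max(e, 0), 1e-300))
  } else identity
  vals <- numeric(nrow(windows))
  ndeg <- 0L
  for (w in seq_len(nrow(windows))) {
    idx <- (windows$start[w] + 1L):windows$stop[w]
    xs <- X[idx]
    ys <- Y[idx]
    if (method == "plain") {
      p <- .pearson0(env_tr(Mod(xs)), env_tr(Mod(ys)))
      ndeg <- ndeg + p$degenerate
      vals[w] <- p$r
    } else {
      # a residual negligible relative to the source (e.g. Y proportional
      # to X) carries no orthogonal information: rounding noise must not
      # be correlated
      d1 <- orthogonalize(ys, xs)
      keep1 <- setdiff(seq_along(xs), attr(d1, "excluded"))
      p1 <- if (max(abs(d1)) < 1e-10 * max(Mod(ys))) {
        list(r = 0, degenerate = TRUE)
      } else .pearson0(env_tr(abs(d1[keep1])), env_tr(Mod(xs[keep1])))
      d2 <- orthogonalize(xs, ys)
      keep2 <- setdiff(seq_along(ys), attr(d2, "excluded"))
      p2 <- if (max(abs(d2)) < 1e-10 * max(Mod(xs))) {
        list(r = 0, degenerate = TRUE)
      } else .pearson0(env_tr(abs(d2[keep2])), env_tr(Mod(ys[keep2])))
      ndeg <- ndeg + p1$degenerate + p2$degenerate
      vals[w] <- (p1$r + p2$r) / 2
    }
  }
  out <- median(vals)
  attr(out, "window_values") <- vals
  attr(out, "n_degenerate") <- ndeg
  out
}

#' Band-specific connectivity matrix
#'
#' Evaluates [pair_correlation()] for every unordered ROI pair of an
#' [analytic()] signal (via a compiled all-pairs kernel for the
#' orthogonalized estimator) and returns the symmetric matrix of
#' window-median values, diagonal `NA`.
#'
#' @param signals An `analytic_signal` (see [analytic()]).
#' @param windows Data frame from [make_windows()]; defaults to the
#'   standard 30 s / 1/6-stride scheme on the post-transient region.
#' @param method `"orthogonalized"` (default) or `"plain"`.
#' @param log_envelopes Correlate log envelopes (default `FALSE`; see
#'   [pair_correlation()]). The non-default transform runs through the
#'   plain-R pairwise path and is intended for small ROI counts.
#' @return An `n x n` numeric matrix with ROI labels as dimnames and
#'   attributes `band`, `n_windows`, `n_degenerate`.
#' @export
connectivity_matrix <- function(signals, windows = NULL,
                                method = c("orthogonalized", "plain"),
                                log_envelopes = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(signals, "analytic_signal"))
  n <- nrow(signals$data)
  if (n < 2L) stop("need at least 2 ROIs", call. = FALSE)
  if (is.null(windows)) {
    windows <- make_windows(ncol(signals$data), signals$fs,
                            offset = signals$transient)
  }
  if (method == "orthogonalized" && log_envelopes) {
    C <- matrix(NA_real_, n, n)
    ndeg <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- pair_correlation(signals$data[i, ], signals$data[j, ],
                              windows, log_envelopes = TRUE)
        ndeg <- ndeg + attr(r, "n_degenerate")
        C[i, j] <- C[j, i] <- as.numeric(r)
      }
    }
  } else if (method == "orthogonalized") {
    res <- env_corr_cpp(Re(signals$data), Im(signals$data),
                        as.integer(windows$start), as.integer(windows$stop))
    C <- apply(res$values, c(1, 2), median)
    ndeg <- res$zero_var
  } else {
    W <- nrow(windows)
    vals <- array(NA_real_, c(n, n, W))
    ndeg <- 0L
    E <- Mod(signals$data)
    for (w in seq_len(W)) {
      idx <- (windows$start[w] + 1L):windows$stop[w]
      Ew <- t(E[, idx, drop = FALSE])
      if (log_envelopes) Ew <- log(pmax(Ew, 1e-12 * max(Ew), 1e-300))
      sds <- apply(Ew, 2L, sd)
      degen <- sds <= 0
      ndeg <- ndeg + sum(degen) * (n - 1L)
      Ew[, degen] <- rnorm(nrow(Ew) * sum(degen)) * 0  # keep cor() finite
      Cw <- suppressWarnings(cor(Ew))
      Cw[degen, ] <- 0
      Cw[, degen] <- 0
      vals[, , w] <- Cw
    }
    C <- apply(vals, c(1, 2), median)
    diag(C) <- NA_real_
  }
  dimnames(C) <- list(signals$labels, signals$labels)
  attr(C, "band") <- signals$band
  attr(C, "n_windows") <- nrow(windows)
  attr(C, "n_degenerate") <- ndeg
  C
}
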