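# Empirical mode decomposition. Sifting subtracts the mean of the cubic
# spline envelopes through local maxima/minima until the normalized squared
# difference sum((s-d)^2 / s^2) drops to the stop threshold; the outer loop
# peels IMFs off the residual until the requested count is reached or the
# remainder is (numerically) linear / lacks extrema.

#' Local extrema of a signal
#'
#' A local maximum (minimum) is a sample strictly greater (smaller) than
#' both neighbors; plateaus contribute their first sample.
#'
#' @param x Numeric vector.
#' @return List with integer index vectors `maxima` and `minima`.
#' @export
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(), minima = integer()))
  d <- diff(x)
  s <- sign(d)
  # carry the sign of the last nonzero difference across plateaus so the
  # plateau's first sample is the extremum
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  ds <- diff(s)
  idx <- which(ds != 0) + 1L
  maxima <- idx[ds[idx - 1L] < 0]
  minima <- idx[ds[idx - 1L] > 0]
  # plateau first-sample convention: step back over equal-valued runs
  shift_back <- function(ii) {
    vapply(ii, function(i) {
      while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
      i
    }, integer(1))
  }
  list(maxima = shift_back(maxima), minima = shift_back(minima))
}

# cubic-spline envelope through extrema, endpoints handled by mirroring the
# two nearest extrema beyond each signal end (anti-drift boundary rule)
spline_envelope <- function(x, idx) {
  n <- length(x)
  ti <- idx
  vi <- x[idx]
  k <- min(2L, length(idx))
  left_t <- 2 * 1 - rev(ti[seq_len(k)])
  left_v <- rev(vi[seq_len(k)])
  right_t <- 2 * n - rev(ti)[seq_len(k)]
  right_v <- rev(vi)[seq_len(k)]
  tt <- c(left_t, ti, rev(right_t))
  vv <- c(left_v, vi, rev(right_v))
  keep <- !duplicated(tt)
  stats::splinefun(tt[keep], vv[keep], method = "fmm")(seq_len(n))
}

is_numerically_linear <- function(x, tol = 1e-10) {
  n <- length(x)
  if (n < 3L) return(TRUE)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  scale <- max(abs(x), 1e-300)
  max(abs(fit$residuals)) <= tol * scale
}

#' Empirical mode decomposition of a signal
#'
#' @param x Numeric signal, length >= 10.
#' @param rate Sampling rate (carried through for downstream use).
#' @param max_imfs Maximum number of IMFs to extract.
#' @param epsilon Stop threshold for one IMF's sifting: sifting ends when
#'   `sum((s - d)^2 / s^2) <= epsilon` (with a tiny floor guarding zeros of
#'   `s`). Default 0.2, the customary sifting threshold.
#' @param max_sift Hard cap on sifting iterations per IMF.
#' @return An `imf_set`: list with `imfs` (list of signals, IMF 1 = highest
#'   frequency), `residual`, `epsilon`, `rate`, and `status` (`"ok"`,
#'   `"constant"`, or `"monotonic"` when no IMF could be extracted).
#' @export
emd <- function(x, rate = 1, max_imfs = 10L, epsilon = 0.2, max_sift = 200L) {
  stopifnot(length(x) >= 10L, epsilon > 0)
  scale <- max(abs(x - mean(x)))
  floor_sq <- (.Machine$double.eps * max(scale, 1e-300))^2
  imfs <- list()
  resid <- x
  status <- "ok"
  if (scale == 0) {
    return(structure(list(imfs = list(), residual = x, epsilon = epsilon,
                          rate = rate, status = "constant"),
                     class = "imf_set"))
  }
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(resid)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L ||
        is_numerically_linear(resid)) {
      if (k == 1L) status <- "monotonic"
      break
    }
    s <- resid
    for (it in seq_len(max_sift)) {
      ex <- local_extrema(s)
      if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
      env_max <- spline_envelope(s, ex$maxima)
      env_min <- spline_envelope(s, ex$minima)
      m <- (env_max + env_min) / 2
      d <- s - m
      crit <- sum((s - d)^2 / (s^2 + floor_sq))
      s <- d
      if (crit <= epsilon) break
    }
    imfs[[k]] <- s
    resid <- resid - s
  }
  structure(list(imfs = imfs, residual = resid, epsilon = epsilon,
                 rate = rate, status = status),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set>", length(x$imfs), "IMF(s), status:", x$status, "\n")
  invisible(x)
}

#' EMD-based high-pass filtering of a recording
#'
#' Per channel, decomposes the signal and recomposes the contiguous IMF
#' subset `first_imf ... first_imf + n_imfs - 1` (IMF 1 holds the highest
#' frequency content, so recomposing leading IMFs acts as a high-pass).
#' IMFs beyond what the signal yields are treated as absent.
#'
#' @param rec An `hfo_recording`.
#' @param first_imf 1-based index of the first IMF to keep.
#' @param n_imfs Number of consecutive IMFs to sum.
#' @param epsilon Sifting stop threshold, see [emd()].
#' @return An `hfo_recording` of the recomposed signals.
#' @export
emd_highpass <- function(rec, first_imf = 1L, n_imfs = 1L, epsilon = 0.2) {
  stopifnot(first_imf >= 1L, n_imfs >= 1L)
  map_channels(rec, function(x, rate, name) {
    dec <- emd(x, rate, max_imfs = first_imf + n_imfs - 1L, epsilon = epsilon)
    keep <- seq.int(first_imf, min(first_imf + n_imfs - 1L, length(dec$imfs)))
    out <- numeric(length(x))
    if (length(dec$imfs) >= first_imf) {
      for (k in keep) out <- out + dec$imfs[[k]]
    }
    out
  })
}
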