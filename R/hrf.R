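# Hemodynamic response modeling and regressor construction.

#' Gamma-family hemodynamic response function
#'
#' Discrete samples of the canonical gamma-variate impulse response
#' \deqn{h(t) = ((t-\delta)/\tau)^{n-1} e^{-(t-\delta)/\tau} / (\tau (n-1)!)}
#' for `t >= delta` and 0 before, normalized to unit peak. With the default
#' parameters (`n = 3`, `tau = 1.25` s, `delta = 2` s) the kernel peaks at
#' `delta + (n - 1) * tau = 4.5` s after the driving event.
#'
#' @param n Shape exponent (positive integer).
#' @param tau_s Time constant in seconds (positive).
#' @param delta_s Onset delay in seconds (non-negative).
#' @param dt_s Sampling step in seconds (positive); use the repetition time
#'   when the kernel is destined for a design matrix.
#' @param span_s Kernel support in seconds.
#' @return An object of class `hrf`: list with `kernel`, `t`, `dt_s` and the
#'   shape parameters.
#' @export
make_hrf <- function(n = 3, tau_s = 1.25, delta_s = 2, dt_s = DEFAULT_TR_S,
                     span_s = 32) {
  if (tau_s <= 0) stop("`tau_s` must be positive")
  if (dt_s <= 0) stop("`dt_s` must be positive")
  if (delta_s < 0) stop("`delta_s` must be non-negative")
  t <- seq(0, span_s, by = dt_s)
  u <- (t - delta_s) / tau_s
  h <- ifelse(t < delta_s, 0,
              u^(n - 1) * exp(-u) / (tau_s * factorial(n - 1)))
  h <- h / max(h)
  structure(list(kernel = h, t = t, dt_s = dt_s,
                 params = list(n = n, tau_s = tau_s, delta_s = delta_s)),
            class = "hrf")
}

# Convolve a set of (possibly amplitude-modulated) boxcars with the HRF at
# frame resolution. Onsets are rounded to the nearest frame; a boxcar spans
# max(1, round(duration/tr)) frames. Returns a length-`n_frames` regressor.
hrf_regressor <- function(onsets, durations, amplitudes, n_frames, tr_s,
                          hrf) {
  if (abs(hrf$dt_s - tr_s) > 1e-9)
    stop("HRF sampling step must equal the repetition time")
  if (any(durations <= 0)) stop("boxcar durations must be positive")
  len <- pmax(1L, as.integer(round(durations / tr_s)))
  first <- as.integer(round(onsets / tr_s)) + 1L
  s <- numeric(n_frames + length(hrf$kernel))
  for (i in seq_along(onsets)) {
    idx <- first[i]:(first[i] + len[i] - 1L)
    idx <- idx[idx >= 1L & idx <= length(s)]
    s[idx] <- s[idx] + amplitudes[i]
  }
  r <- convolve(s, rev(hrf$kernel), type = "open")[seq_len(n_frames)]
  r
}
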