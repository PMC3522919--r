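#' Movement index from an acceleration magnitude series
#'
#' Reduces a uniformly sampled acceleration waveform to one movement-index
#' value per second: the waveform is segmented at its zero crossings, each
#' pair of consecutive crossings together with the largest-magnitude sample
#' between them defines a triangle (base = time between the crossings,
#' height = the extremum's absolute value), and the MI of a second is the
#' mean area of the triangles whose apex falls inside that second. Seconds
#' containing no triangle apex get MI 0. Zero crossings are located by
#' sign-change detection with linear interpolation of the crossing time;
#' samples that are exactly zero are crossing points themselves. This
#' triangle construction is a reconstruction of the feature-point rule the
#' original sensor firmware uses.
#'
#' MI is non-negative, invariant to a sign flip of the signal, and scales
#' linearly with signal amplitude.
#'
#' @param accel Numeric vector, the acceleration magnitude series sampled
#'   uniformly at `rate` samples per second.
#' @param rate Sampling rate in Hz (`>= 2`); the series must cover at least
#'   one second.
#' @return A tibble with columns `second` (1-based index) and `mi`.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)[-401]
#' tri <- function(ph) ifelse(ph < .25, 4 * ph,
#'   ifelse(ph < .75, 2 - 4 * ph, 4 * ph - 4))
#' movement_index(tri((t / 0.5) %% 1), rate = 200)
#' @export
movement_index <- function(accel, rate) {
  stopifnot(is.numeric(accel))
  if (!all(is.finite(accel))) stop("acceleration series must be finite", call. = FALSE)
  if (length(rate) != 1L || rate < 2) stop("`rate` must be >= 2 samples/s", call. = FALSE)
  n <- length(accel)
  if (n < rate) stop("series shorter than one second", call. = FALSE)
  t <- (seq_len(n) - 1) / rate
  n_sec <- floor(n / rate)

  cross <- zero_crossing_times(accel, t)
  areas <- apex_t <- numeric(0)
  if (length(cross) >= 2) {
    for (i in seq_len(length(cross) - 1)) {
      lo <- cross[i]
      hi <- cross[i + 1]
      inside <- which(t > lo & t < hi)
      if (!length(inside)) next
      ext <- inside[which.max(abs(accel[inside]))]
      areas <- c(areas, 0.5 * (hi - lo) * abs(accel[ext]))
      apex_t <- c(apex_t, t[ext])
    }
  }
  mi <- vapply(seq_len(n_sec), function(s) {
    in_sec <- apex_t >= (s - 1) & apex_t < s
    if (any(in_sec)) mean(areas[in_sec]) else 0
  }, numeric(1))
  tibble::tibble(second = seq_len(n_sec), mi = mi)
}

# Times where the signal crosses zero: exact-zero samples (runs collapse to
# their first sample) and sign changes between adjacent samples, linearly
# interpolated.
zero_crossing_times <- function(s, t) {
  zero <- s == 0
  zero_start <- which(zero & !c(FALSE, zero[-length(zero)]))
  times <- t[zero_start]
  i <- which(s[-length(s)] * s[-1] < 0)
  if (length(i)) {
    frac <- s[i] / (s[i] - s[i + 1])
    times <- c(times, t[i] + frac * (t[i + 1] - t[i]))
  }
  sort(times)
}
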