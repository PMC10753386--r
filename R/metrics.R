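#' Action-potential metrics of a single beat
#'
#' Quantifies one stimulated action potential sampled at 1 kHz. The timing
#' reference is the moment of maximal upstroke velocity: the earliest sample
#' (ties to the earliest) of maximal 1-ms forward difference at or after the
#' stimulus tick. The resting potential is the mean of up to `rest_window`
#' ms preceding the stimulus (the first sample if none precede it). The x%
#' repolarization level is `V_peak - x * (V_peak - V_rest)`; crossing times
#' are located by linear interpolation between the bracketing samples, and
#' `APD_x` is the crossing time minus the upstroke-velocity moment. A
#' fraction whose level is never crossed before the end of the trace is
#' reported as `NA`.
#'
#' @param trace Numeric vector of membrane potential, mV, uniform 1-ms
#'   sampling; time of sample `i` is `i - 1` ms.
#' @param fractions Repolarization fractions for APD measurement.
#' @param stim_tick 1-based sample index of the pacing stimulus.
#' @param rest_window Width of the pre-stimulus resting window, ms.
#' @return List of class `apqr_ap_metrics` with fields `t_dvdt_max`,
#'   `dvdt_max`, `V_peak`, `V_rest`, `APD` (named by fraction, ms) and
#'   `t_repol` (absolute crossing times from trace start, ms).
#' @examples
#' m <- ap_metrics(triangular_model(1.3)$values)
#' m$APD[["0.9"]]  # ~59.4 ms
#' @export
ap_metrics <- function(trace, fractions = c(0.2, 0.3, 0.5, 0.9),
                       stim_tick = 1L, rest_window = 50L) {
  n <- length(trace)
  if (n < stim_tick + 2L) stop("trace too short for the given stimulus tick")
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  fractions <- sort(fractions)
  dv <- diff(trace)
  cand <- stim_tick:(n - 1L)
  k <- cand[which.max(dv[cand])]          # earliest maximal forward difference
  t_dvdt <- k - 1L                        # time of the earlier bracketing sample
  pre <- trace[max(1L, stim_tick - rest_window):(stim_tick - 1L)]
  v_rest <- if (stim_tick > 1L) mean(pre) else trace[1L]
  peak_idx <- which.max(trace[k:n]) + k - 1L
  v_peak <- trace[peak_idx]
  apd <- t_rep <- stats::setNames(rep(NA_real_, length(fractions)),
                                  format(fractions))
  for (j in seq_along(fractions)) {
    lev <- v_peak - fractions[j] * (v_peak - v_rest)
    idx <- peak_idx
    hit <- NA_real_
    while (idx < n) {
      if (trace[idx] > lev && trace[idx + 1L] <= lev) {
        hit <- (idx - 1L) + (trace[idx] - lev) / (trace[idx] - trace[idx + 1L])
        break
      }
      idx <- idx + 1L
    }
    t_rep[j] <- hit
    apd[j] <- hit - t_dvdt
  }
  structure(list(t_dvdt_max = t_dvdt, dvdt_max = max(dv[cand]),
                 V_peak = v_peak, V_rest = v_rest,
                 APD = apd, t_repol = t_rep),
            class = "apqr_ap_metrics")
}

#' @export
print.apqr_ap_metrics <- function(x, ...) {
  cat(sprintf("AP: dV/dt_max %.1f mV/ms at %g ms, V_peak %.1f, V_rest %.1f mV\n",
              x$dvdt_max, x$t_dvdt_max, x$V_peak, x$V_rest))
  cat("  APD (ms):", paste(names(x$APD), round(x$APD, 1), sep = "=",
                           collapse = "  "), "\n")
  invisible(x)
}

#' Membrane-potential error trace over an analysis window
#'
#' Element-wise difference (measured minus reference) restricted to a time
#' window, by convention the interval between the moment of maximal upstroke
#' velocity and the moment of 90% repolarization.
#'
#' @param trace Measured beat, mV, 1-ms sampling (sample `i` at `i - 1` ms).
#' @param reference Reference values on the same tick grid (numeric vector
#'   or `apqr_setpoint`).
#' @param window `c(t0, t1)` in ms from trace start; `NULL` for the full
#'   common length.
#' @return Numeric error vector, mV.
#' @export
vm_error <- function(trace, reference, window = NULL) {
  if (inherits(reference, "apqr_setpoint")) reference <- reference$values
  n <- min(length(trace), length(reference))
  err <- trace[seq_len(n)] - reference[seq_len(n)]
  if (is.null(window)) return(err)
  if (any(!is.finite(window)) || length(window) != 2L)
    stop("analysis window is undefined")
  idx <- which(seq_len(n) - 1 >= window[1] & seq_len(n) - 1 <= window[2])
  err[idx]
}

#' Summary statistics of pooled membrane-potential errors
#'
#' Frequency distribution of error samples in 5-mV bins centred on zero
#' (centre bin \[-2.5, +2.5) mV), the median error, the fraction of samples
#' within +/-2.5 mV (exactly the centre-bin mass), and the maximal absolute
#' error with its sample offset.
#'
#' @param errors Numeric vector of pooled error samples, mV.
#' @param bin_width Bin width, mV.
#' @return List of class `apqr_error_stats` with `median`,
#'   `frac_within_2p5`, `histogram` (data frame of bin edges and counts),
#'   `max_error`, `t_max_error`.
#' @export
error_stats <- function(errors, bin_width = 5) {
  if (length(errors) == 0L) stop("no error samples supplied")
  if (any(!is.finite(errors))) stop("error samples must be finite")
  half <- bin_width / 2
  kmax <- max(1, ceiling((max(abs(errors)) + half) / bin_width))
  edges <- seq(-half - kmax * bin_width, half + kmax * bin_width,
               by = bin_width)
  counts <- vapply(seq_len(length(edges) - 1L), function(i)
    sum(errors >= edges[i] & errors < edges[i + 1L]), integer(1))
  centre <- which(abs(edges[-length(edges)] + half) < 1e-9)
  imax <- which.max(abs(errors))
  structure(list(
    median = stats::median(errors),
    frac_within_2p5 = counts[centre] / length(errors),
    histogram = data.frame(lower = edges[-length(edges)],
                           upper = edges[-1L], count = counts),
    max_error = errors[imax], t_max_error = imax - 1L,
    n = length(errors)), class = "apqr_error_stats")
}

#' @export
print.apqr_error_stats <- function(x, ...) {
  cat(sprintf(
    "V_m error: n = %d, median %.2f mV, %.1f%% within +/-2.5 mV, max %.1f mV\n",
    x$n, x$median, 100 * x$frac_within_2p5, x$max_error))
  invisible(x)
}

#' Compare action-potential durations between two groups
#'
#' Mean and standard deviation of APD differences. With equal-length inputs
#' the difference is taken pairwise (per beat); with printed group means as
#' scalar inputs this reduces to the difference of means.
#'
#' @param group_a,group_b Numeric vectors of APD values, ms.
#' @return `list(mean_diff, sd_diff, n)`.
#' @examples
#' compare_apd(429.9, 289.8)$mean_diff  # 140.1 ms
#' @export
compare_apd <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty APD group")
  if (length(group_a) == length(group_b)) {
    d <- group_a - group_b
    list(mean_diff = mean(d),
         sd_diff = if (length(d) > 1) stats::sd(d) else NA_real_,
         n = length(d))
  } else {
    list(mean_diff = mean(group_a) - mean(group_b), sd_diff = NA_real_,
         n = c(length(group_a), length(group_b)))
  }
}
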