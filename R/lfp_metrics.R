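#' Evoked LFP trace
#'
#' One evoked local-field-potential waveform: uniformly sampled voltage
#' over (typically) the 100-ms window after test-stimulus onset. Auditory
#' cortex traces show three lobes: an early negative component A (the
#' quantified one), a late positive component B, and a small final negative
#' component C.
#'
#' @param time_ms Uniformly spaced sample times in milliseconds from
#'   stimulus onset (length >= 2).
#' @param voltage_mv Voltage in millivolts, same length as `time_ms`.
#' @return An object of class `evoked_trace`.
#' @export
evoked_trace <- function(time_ms, voltage_mv) {
  stopifnot(is.numeric(time_ms), is.numeric(voltage_mv),
            length(time_ms) == length(voltage_mv), length(time_ms) >= 2L)
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    stop("evoked_trace: time base must be uniform and increasing")
  structure(list(time_ms = as.numeric(time_ms),
                 voltage_mv = as.numeric(voltage_mv)),
            class = "evoked_trace")
}

#' Block-average evoked traces
#'
#' Averages each successive, non-overlapping block of `k` traces sharing an
#' identical time base; the standard noise-reduction step before peak
#' measurement (k = 5 by default). A trailing partial block is dropped.
#'
#' @param traces List of [evoked_trace] objects with identical time bases.
#' @param k Block size (default 5).
#' @return List of averaged [evoked_trace] objects
#'   (`floor(length(traces) / k)` of them).
#' @export
average_traces <- function(traces, k = 5L) {
  stopifnot(length(traces) >= k, k >= 1L,
            all(vapply(traces, inherits, logical(1), "evoked_trace")))
  tb <- traces[[1L]]$time_ms
  same <- vapply(traces, function(tr)
    length(tr$time_ms) == length(tb) && all(abs(tr$time_ms - tb) < 1e-9),
    logical(1))
  if (!all(same))
    stop("average_traces: traces have mismatched time bases")
  n_blocks <- length(traces) %/% k
  lapply(seq_len(n_blocks), function(b) {
    block <- traces[((b - 1L) * k + 1L):(b * k)]
    v <- rowMeans(vapply(block, `[[`, numeric(length(tb)), "voltage_mv"))
    evoked_trace(tb, v)
  })
}

#' Negative-peak amplitude and latency of an evoked trace
#'
#' Finds the most negative voltage within a search window (default
#' 2--20 ms, skipping the stimulus artifact and bracketing the ~5 ms
#' component-A latency) and returns its magnitude and latency. Ties go to
#' the earliest sample. A trace with no negative-going deflection in the
#' window still returns `|min|` but is flagged.
#'
#' @param trace An [evoked_trace] object.
#' @param window Numeric length-2 vector, search window in ms.
#' @return List with `amplitude_mv` (magnitude, >= 0), `latency_ms`, and
#'   `negative_going` (logical: was the extremum actually negative?).
#' @export
negative_peak <- function(trace, window = c(2, 20)) {
  stopifnot(inherits(trace, "evoked_trace"), length(window) == 2L)
  sel <- which(trace$time_ms >= window[1L] & trace$time_ms <= window[2L])
  if (length(sel) == 0L)
    stop("negative_peak: search window [", window[1L], ", ", window[2L],
         "] ms contains no samples")
  v <- trace$voltage_mv[sel]
  i <- which.min(v)  # earliest index on ties
  list(amplitude_mv = abs(v[i]), latency_ms = trace$time_ms[sel[i]],
       negative_going = v[i] < 0)
}

#' Time-stamped negative-peak amplitude series for one electrode
#'
#' Peak magnitudes per test pulse at one site, either for the tetanised
#' (TS) pathway or the distant non-TS excitability-monitor pathway, in the
#' pre- or post-tetanus session. Times are minutes relative to tetanic
#' stimulation: negative in the `pre` session, positive in `post`.
#'
#' @param times_min Sorted sample times (minutes relative to TS).
#' @param amplitude_mv Non-negative peak magnitudes (mV).
#' @param site_row,site_col Electrode grid coordinates.
#' @param stim_role `"TS"` or `"nonTS"`.
#' @param session `"pre"` or `"post"`.
#' @return An object of class `peak_series`.
#' @export
peak_series <- function(times_min, amplitude_mv, site_row = NA_integer_,
                        site_col = NA_integer_,
                        stim_role = c("TS", "nonTS"),
                        session = c("pre", "post")) {
  stim_role <- match.arg(stim_role)
  session <- match.arg(session)
  stopifnot(is.numeric(times_min), is.numeric(amplitude_mv),
            length(times_min) == length(amplitude_mv))
  if (is.unsorted(times_min, strictly = FALSE))
    stop("peak_series: times must be sorted")
  if (any(amplitude_mv < 0))
    stop("peak_series: amplitudes are magnitudes and must be >= 0")
  if (session == "pre" && any(times_min >= 0))
    stop("peak_series: pre-session times must be < 0 (minutes before TS)")
  if (session == "post" && any(times_min <= 0))
    stop("peak_series: post-session times must be > 0 (minutes after TS)")
  structure(list(times_min = as.numeric(times_min),
                 amplitude_mv = as.numeric(amplitude_mv),
                 site_row = as.integer(site_row),
                 site_col = as.integer(site_col),
                 stim_role = stim_role, session = session),
            class = "peak_series")
}

# Nearest-sample lookup within +/- tol_min of a requested time.
.peak_at <- function(series, t_min, tol_min = 1) {
  d <- abs(series$times_min - t_min)
  i <- which.min(d)
  if (d[i] > tol_min)
    stop("no peak sample within +/-", tol_min, " min of t = ", t_min,
         " min (nearest at ", series$times_min[i], " min)")
  series$amplitude_mv[i]
}

#' Ratio index of post- over pre-tetanus peak amplitude
#'
#' RI(t) = Vpost(t) / Vpre(t_ref), the plasticity readout: the
#' negative-peak magnitude `t_post` minutes after tetanic stimulation
#' divided by the baseline magnitude `t_ref` minutes before it (default
#' 5 min). Requested times are matched to the nearest sample within
#' +/- 1 min (test pulses are delivered every 10--20 s, so anchors are
#' dense).
#'
#' @param post Post-session [peak_series].
#' @param pre Pre-session [peak_series].
#' @param t_post Minutes after TS at which to evaluate the ratio.
#' @param t_ref Minutes before TS of the baseline reference (default 5).
#' @return Dimensionless RI (fraction, not percent).
#' @export
ratio_index <- function(post, pre, t_post, t_ref = 5) {
  stopifnot(inherits(post, "peak_series"), inherits(pre, "peak_series"),
            post$session == "post", pre$session == "pre")
  v_pre <- .peak_at(pre, -abs(t_ref))
  if (v_pre == 0)
    stop("ratio_index: baseline peak Vpre(", t_ref, ") is zero")
  vapply(t_post, function(tp) .peak_at(post, tp) / v_pre, numeric(1))
}

#' Baseline stability criterion
#'
#' A recording is usable only if baseline peak amplitudes are stable:
#' the relative variation (max - min) / mean over the pre-tetanus session
#' must not exceed `max_variation` (15% by default).
#'
#' @param pre Pre-session [peak_series] with at least 3 samples.
#' @param max_variation Maximum admissible relative variation (fraction).
#' @return `TRUE` if stable, `FALSE` otherwise (with a warning when the
#'   mean amplitude is zero).
#' @export
stability_check <- function(pre, max_variation = 0.15) {
  stopifnot(inherits(pre, "peak_series"))
  if (length(pre$amplitude_mv) < 3L)
    stop("stability_check: need at least 3 pre-session samples")
  m <- mean(pre$amplitude_mv)
  if (m == 0) {
    warning("stability_check: zero mean baseline amplitude")
    return(FALSE)
  }
  (max(pre$amplitude_mv) - min(pre$amplitude_mv)) / m <= max_variation
}

#' Whole-slice excitability quality control (non-TS 70% rule)
#'
#' The tetanus must not depress the pathway stimulated from the distant
#' non-TS site: if the non-TS ratio index drops below `threshold` (70%) at
#' any point of the post-tetanus session, overall slice excitability has
#' degraded and the recording is discarded. RI exactly at the threshold
#' keeps the recording (strict-less rule).
#'
#' @param nonTS_post Post-session non-TS [peak_series].
#' @param nonTS_pre Pre-session non-TS [peak_series].
#' @param threshold Discard threshold on the non-TS RI (default 0.70).
#' @param t_ref Baseline reference time (minutes before TS).
#' @return List with `keep` (logical), `min_ri`, and `t_min_ri` (time of
#'   the minimum non-TS RI).
#' @export
excitability_qc <- function(nonTS_post, nonTS_pre, threshold = 0.70,
                            t_ref = 5) {
  stopifnot(inherits(nonTS_post, "peak_series"),
            inherits(nonTS_pre, "peak_series"))
  if (nonTS_post$stim_role != "nonTS" || nonTS_pre$stim_role != "nonTS")
    stop("excitability_qc: expects non-TS monitor series")
  v_pre <- .peak_at(nonTS_pre, -abs(t_ref))
  if (v_pre == 0) stop("excitability_qc: zero baseline amplitude")
  ri <- nonTS_post$amplitude_mv / v_pre
  i <- which.min(ri)
  list(keep = ri[i] >= threshold, min_ri = ri[i],
       t_min_ri = nonTS_post$times_min[i])
}

#' Current source density profile down an electrode column
#'
#' Second spatial difference of the LFP along one vertical electrode
#' column: \eqn{CSD_j = (V_{j-1} - 2 V_j + V_{j+1}) / h^2} per time point,
#' for interior sites only, with `h` the electrode pitch (150 um). Used to
#' locate laminar sources and sinks.
#'
#' @param column_traces Either a numeric matrix (rows = sites ordered by
#'   depth, columns = time points) or a list of [evoked_trace] objects with
#'   identical time bases, ordered by depth. At least 3 sites.
#' @param spacing_um Electrode pitch in micrometres (default 150).
#' @return Numeric matrix of CSD values (mV / um^2): one row per interior
#'   site, one column per time point.
#' @export
csd_profile <- function(column_traces, spacing_um = 150) {
  v <- if (is.matrix(column_traces)) {
    column_traces
  } else {
    stopifnot(all(vapply(column_traces, inherits, logical(1), "evoked_trace")))
    t(vapply(column_traces, `[[`,
             numeric(length(column_traces[[1L]]$time_ms)), "voltage_mv"))
  }
  if (nrow(v) < 3L)
    stop("csd_profile: need at least 3 sites in the column")
  n <- nrow(v)
  out <- (v[1:(n - 2L), , drop = FALSE] - 2 * v[2:(n - 1L), , drop = FALSE] +
            v[3:n, , drop = FALSE]) / spacing_um^2
  rownames(out) <- rownames(v)[2:(n - 1L)]
  out
}
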