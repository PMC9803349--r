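#' Event detection threshold for a spine-specific trace
#'
#' The default rule is `max(0.15, 3.5 * RMS)`: a 15% dF/F floor combined
#' with 3.5 times the root-mean-square of the trace. Because whole-trace
#' RMS includes the calcium transients themselves, a robust alternative
#' estimates the noise scale instead, from a low quantile of the absolute
#' first differences (the 25th percentile, scaled for a Gaussian), which
#' stays noise-dominated even when transients occupy much of the trace
#' (`method = "mad"`). The pure variants (`"rms"` without the floor,
#' `"floor"` without the RMS term) are also available.
#'
#' @param trace spine-specific dF/F trace
#' @param method `"rms_floor"` (default), `"mad"`, `"rms"`, or `"floor"`
#' @param floor threshold floor in dF/F units (default 0.15)
#' @param k multiplier on the scale estimate (default 3.5)
#' @return scalar threshold in dF/F units
#' @examples
#' eventThreshold(rep(0.2, 100))            # 3.5 * 0.2 = 0.7
#' eventThreshold(numeric(100))             # floor, 0.15
#' @export
eventThreshold <- function(trace, method = c("rms_floor", "mad", "rms",
                                             "floor"),
                           floor = 0.15, k = 3.5) {
    if (!length(trace)) stop("empty trace")
    method <- match.arg(method)
    switch(method,
        rms_floor = max(floor, k * sqrt(mean(trace^2))),
        rms = k * sqrt(mean(trace^2)),
        floor = floor,
        mad = max(floor, k * quantile(abs(diff(trace)), 0.25, names = FALSE) /
                             (stats::qnorm(0.625) * sqrt(2))))
}

#' Detect supra-threshold calcium response events
#'
#' Each maximal contiguous run of samples above `threshold` is one event:
#' onset is the first supra-threshold sample, peak the argmax within the
#' run, offset the last supra-threshold sample. Runs separated by at least
#' one sub-threshold sample are distinct events; single-sample events are
#' allowed and there is no refractory period.
#'
#' @param trace spine-specific dF/F trace
#' @param threshold detection threshold (> 0), see [eventThreshold()]
#' @param rate sampling rate, Hz
#' @param splitPeaks when `TRUE`, resolve distinct response peaks within a
#'   single supra-threshold run: a run is split at internal valleys whose
#'   depth below both flanking local maxima exceeds `minProminence`, so
#'   that transients whose decaying tails overlap are counted as separate
#'   responses (peak detection). The default `FALSE` treats each run as
#'   one event.
#' @param minProminence minimum peak prominence (dF/F) for splitting
#' @return data.frame with `onset_s`, `peak_s`, `offset_s`, `amplitude`
#'   (area above threshold, dF/F x s), one row per event
#' @export
detectEvents <- function(trace, threshold, rate, splitPeaks = FALSE,
                         minProminence = 0.06) {
    stopifnot(threshold > 0)
    above <- trace > threshold
    if (!any(above))
        return(data.frame(onset_s = numeric(), peak_s = numeric(),
                          offset_s = numeric(), amplitude = numeric()))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ei <- which(r$values)
    onset <- integer(); offset <- integer()
    for (j in seq_along(ei)) {
        i0 <- starts[ei[j]]; i1 <- ends[ei[j]]
        if (splitPeaks && i1 - i0 >= 2L) {
            segs <- splitRunAtValleys(trace[i0:i1], minProminence)
            onset <- c(onset, i0 - 1L + segs$start)
            offset <- c(offset, i0 - 1L + segs$end)
        } else {
            onset <- c(onset, i0); offset <- c(offset, i1)
        }
    }
    peak <- vapply(seq_along(onset), function(j)
        onset[j] + which.max(trace[onset[j]:offset[j]]) - 1L, integer(1))
    amp <- vapply(seq_along(onset), function(j)
        trapezoidArea(trace[onset[j]:offset[j]], threshold, rate),
        numeric(1))
    data.frame(onset_s = (onset - 1L) / rate, peak_s = (peak - 1L) / rate,
               offset_s = (offset - 1L) / rate, amplitude = amp)
}

# Split one supra-threshold run into per-peak segments. Local maxima are
# merged greedily while the valley between an adjacent pair is shallower
# than minProminence below the lower peak; boundaries fall at the deepest
# remaining valleys.
splitRunAtValleys <- function(v, minProminence) {
    m <- length(v)
    pk <- which(diff(sign(diff(v))) < 0) + 1L
    if (v[1] > v[2]) pk <- c(1L, pk)
    if (v[m] > v[m - 1]) pk <- c(pk, m)
    pk <- sort(unique(pk))
    if (length(pk) < 2L)
        return(list(start = 1L, end = m))
    repeat {
        if (length(pk) < 2L) break
        nv <- length(pk) - 1L
        valley <- vapply(seq_len(nv), function(i)
            min(v[pk[i]:pk[i + 1L]]), numeric(1))
        prom <- pmin(v[pk[-length(pk)]], v[pk[-1]]) - valley
        worst <- which.min(prom)
        if (prom[worst] >= minProminence) break
        drop <- if (v[pk[worst]] <= v[pk[worst + 1L]]) worst else worst + 1L
        pk <- pk[-drop]
    }
    if (length(pk) < 2L)
        return(list(start = 1L, end = m))
    cuts <- vapply(seq_len(length(pk) - 1L), function(i)
        pk[i] + which.min(v[pk[i]:pk[i + 1L]]) - 1L, integer(1))
    list(start = c(1L, cuts + 1L), end = c(cuts, m))
}

trapezoidArea <- function(v, threshold, rate) {
    ex <- pmax(v - threshold, 0)
    if (length(ex) == 1L) return(ex / rate)
    (sum(ex) - (ex[1] + ex[length(ex)]) / 2) / rate
}

#' Area above threshold of one detected event
#'
#' Trapezoidal integral of `trace - threshold` (clipped below at zero)
#' over the event's `[onset, offset]` span; strictly positive for events
#' from [detectEvents()]. A single-sample event contributes a rectangle of
#' one sample width.
#'
#' @param trace the trace the event was detected on
#' @param event one-row data.frame from [detectEvents()]
#' @param threshold the detection threshold used
#' @param rate sampling rate, Hz
#' @return event amplitude in dF/F x s
#' @export
eventAmplitude <- function(trace, event, threshold, rate) {
    i0 <- round(event$onset_s * rate) + 1L
    i1 <- round(event$offset_s * rate) + 1L
    trapezoidArea(trace[i0:i1], threshold, rate)
}

#' Session activity metrics for one spine
#'
#' Frequency is the number of detected response peaks per second over the
#' whole session; amplitude the mean per-event area above threshold
#' (`NA` and flagged missing when there are no events); the activity
#' integral the summed area of all events; a spine is active in a session
#' if it has at least one supra-threshold response.
#'
#' @param events data.frame from [detectEvents()]
#' @param duration_s session duration in seconds
#' @return one-row data.frame: `nEvents`, `meanAmplitude`, `frequency`,
#'   `integral`, `active`
#' @export
sessionMetrics <- function(events, duration_s) {
    n <- nrow(events)
    data.frame(
        nEvents = n,
        meanAmplitude = if (n) mean(events$amplitude) else NA_real_,
        frequency = n / duration_s,
        integral = if (n) sum(events$amplitude) else 0,
        active = n >= 1)
}

#' Detect events for every spine in a session
#'
#' Runs thresholding and event detection on each spine-specific trace of a
#' preprocessed session. A short causal boxcar smoother (default 0.2 s)
#' is applied before detection to suppress noise-induced fragmentation of
#' single transients into multiple threshold crossings; set
#' `smooth_s = 0` to detect on the raw spine-specific trace.
#'
#' @param x a preprocessed [SpineExperiment] (assay `resid` present)
#' @param method threshold rule passed to [eventThreshold()]; the pipeline
#'   default is the robust noise-scale variant
#' @param smooth_s causal boxcar width in seconds (0 disables smoothing)
#' @param splitPeaks resolve overlapping transients within one run into
#'   separate response peaks (see [detectEvents()]); pipeline default TRUE
#' @return list with `events` (per-event table with `spine` column),
#'   `metrics` (per-spine [sessionMetrics()] rows with `spine` and
#'   `threshold`), and `traces` (the smoothed spine-specific matrix used
#'   for detection)
#' @export
detectSessionEvents <- function(x, method = "mad", smooth_s = 0.2,
                                splitPeaks = TRUE) {
    stopifnot(is(x, "SpineExperiment"), "resid" %in% assayNames(x))
    rate <- metadata(x)$samplingRate
    sp <- spineRows(x)
    resid <- assay(x, "resid")[sp, , drop = FALSE]
    dur <- ncol(resid) / rate
    w <- max(1L, round(smooth_s * rate))
    evs <- vector("list", length(sp))
    met <- vector("list", length(sp))
    for (k in seq_along(sp)) {
        tr <- if (w > 1L) causalBoxcar(resid[k, ], w) else resid[k, ]
        resid[k, ] <- tr
        thr <- eventThreshold(tr, method)
        ev <- detectEvents(tr, thr, rate, splitPeaks = splitPeaks)
        if (nrow(ev)) ev$spine <- rownames(resid)[k]
        evs[[k]] <- ev
        m <- sessionMetrics(ev, dur)
        m$spine <- rownames(resid)[k]
        m$threshold <- thr
        met[[k]] <- m
    }
    events <- as.data.frame(data.table::rbindlist(evs, fill = TRUE))
    metrics <- as.data.frame(data.table::rbindlist(met))
    metrics <- metrics[, c("spine", "nEvents", "meanAmplitude", "frequency",
                           "integral", "active", "threshold")]
    list(events = events, metrics = metrics, traces = resid)
}
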