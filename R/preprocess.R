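#' Remove slow fluorescence drift with a rolling 8th-percentile baseline
#'
#' Subtracts from each sample the 8th-percentile value of the fluorescence
#' distribution in a +/-`halfWindow` s window centred on that sample.
#' Windows shrink at the trace ends (no padding, so no fabricated data).
#'
#' @param raw numeric raw fluorescence trace
#' @param rate sampling rate, Hz
#' @param halfWindow half window width, s (default 15 s, i.e. 451 samples
#'   at 15 Hz)
#' @param percentile baseline percentile (default 0.08)
#' @return list with `corrected` (raw minus rolling percentile) and
#'   `baseline` (the rolling percentile series)
#' @examples
#' x <- rep(5, 1000)
#' all(removeSlowDrift(x, 15)$corrected == 0)
#' @export
removeSlowDrift <- function(raw, rate, halfWindow = 15, percentile = 0.08) {
    hw <- round(halfWindow * rate)
    minLen <- 2L * hw + 1L
    if (length(raw) < minLen)
        stop("trace too short for drift removal: need at least ", minLen,
             " samples (2 x ", halfWindow, " s at ", rate, " Hz), got ",
             length(raw))
    baseline <- .rollingPercentile(as.numeric(raw), hw, percentile)
    list(corrected = raw - baseline, baseline = baseline)
}

#' Compute dF/F from a raw fluorescence trace
#'
#' F0 is the rolling 8th-percentile baseline from [removeSlowDrift()];
#' dF/F(t) = (raw(t) - F0(t)) / max(F0(t), eps) with eps equal to 1% of
#' the trace's median fluorescence, so the result is invariant under
#' positive rescaling of the raw trace.
#'
#' @inheritParams removeSlowDrift
#' @return list with `dff` and `baseline`
#' @export
computeDff <- function(raw, rate, halfWindow = 15, percentile = 0.08) {
    med <- median(raw)
    if (!is.finite(med) || med <= 0)
        stop("median fluorescence must be positive; not a plausible ",
             "fluorescence trace")
    dr <- removeSlowDrift(raw, rate, halfWindow, percentile)
    eps <- 0.01 * med
    list(dff = dr$corrected / pmax(dr$baseline, eps), baseline = dr$baseline)
}

#' Robust regression slope of spine dF/F on dendrite dF/F
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685 times the MAD-based residual scale), intercept
#' included and discarded; at most `maxIter` iterations, convergence when
#' the slope changes by less than `tol`.
#'
#' @param spineDff,dendriteDff equal-length dF/F traces
#' @param maxIter,tol iteration cap and slope-convergence tolerance
#' @return list with `alpha` (slope), `intercept`, `weights` (final robust
#'   weights in `[0,1]`), `iterations`, `converged`
#' @examples
#' x <- sin(seq(0, 20, length.out = 500))
#' robustSlope(0.6 * x, x)$alpha
#' @export
robustSlope <- function(spineDff, dendriteDff, maxIter = 50L, tol = 1e-8) {
    y <- as.numeric(spineDff); x <- as.numeric(dendriteDff)
    if (length(y) != length(x))
        stop("spine and dendrite traces must have equal length")
    if (var(x) == 0 || !is.finite(var(x)))
        stop("degenerate regressor: dendrite trace has zero variance")
    wls <- function(w) {
        sw <- sum(w)
        mx <- sum(w * x) / sw; my <- sum(w * y) / sw
        xc <- x - mx
        b <- sum(w * xc * (y - my)) / sum(w * xc^2)
        c(b, my - b * mx)
    }
    co <- wls(rep(1, length(x)))
    iter <- 0L; converged <- FALSE
    w <- rep(1, length(x))
    repeat {
        iter <- iter + 1L
        r <- y - co[1] * x - co[2]
        s <- median(abs(r - median(r))) / 0.6745
        if (s <= .Machine$double.eps) { converged <- TRUE; break }
        u <- r / (4.685 * s)
        w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
        if (sum(w) == 0) break
        newco <- wls(w)
        if (abs(newco[1] - co[1]) < tol) {
            co <- newco; converged <- TRUE; break
        }
        co <- newco
        if (iter >= maxIter) break
    }
    list(alpha = co[1], intercept = co[2], weights = w,
         iterations = iter, converged = converged)
}

#' Subtract the scaled dendritic signal from the spine signal
#'
#' The spine-specific signal is the exact sample-wise linear combination
#' `spineDff - alpha * dendriteDff`.
#'
#' @param spineDff,dendriteDff equal-length dF/F traces
#' @param alpha finite bleed slope (from [robustSlope()])
#' @return numeric spine-specific dF/F trace
#' @export
subtractDendrite <- function(spineDff, dendriteDff, alpha) {
    if (length(spineDff) != length(dendriteDff))
        stop("spine and dendrite traces must have equal length")
    if (!is.finite(alpha)) stop("alpha must be finite")
    spineDff - alpha * dendriteDff
}

#' Preprocess a session: dF/F and spine-specific signals
#'
#' Applies [computeDff()] to every ROI trace and, for each spine, robustly
#' subtracts its paired dendrite ROI ([robustSlope()] +
#' [subtractDendrite()]). Adds assays `dff` (all ROIs) and `resid`
#' (spine-specific dF/F; `NA` for dendrite rows) and rowData columns
#' `alphaHat`, `alphaIter`, `alphaConverged`.
#'
#' @param x a [SpineExperiment]
#' @param halfWindow rolling-baseline half window, s
#' @return the updated [SpineExperiment]
#' @export
preprocessSession <- function(x, halfWindow = 15) {
    stopifnot(is(x, "SpineExperiment"))
    raw <- assay(x, "fluor")
    rate <- metadata(x)$samplingRate
    dff <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
    for (i in seq_len(nrow(raw)))
        dff[i, ] <- computeDff(raw[i, ], rate, halfWindow)$dff
    sp <- spineRows(x)
    dn <- pairedDendrite(x)
    resid <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
    alphaHat <- rep(NA_real_, nrow(raw))
    alphaIter <- rep(NA_integer_, nrow(raw))
    alphaConv <- rep(NA, nrow(raw))
    for (k in seq_along(sp)) {
        fit <- robustSlope(dff[sp[k], ], dff[dn[k], ])
        alphaHat[sp[k]] <- fit$alpha
        alphaIter[sp[k]] <- fit$iterations
        alphaConv[sp[k]] <- fit$converged
        resid[sp[k], ] <- subtractDendrite(dff[sp[k], ], dff[dn[k], ],
                                           fit$alpha)
    }
    assay(x, "dff") <- dff
    assay(x, "resid") <- resid
    rowData(x)$alphaHat <- alphaHat
    rowData(x)$alphaIter <- alphaIter
    rowData(x)$alphaConverged <- alphaConv
    x
}
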