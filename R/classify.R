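#' Binarize a stimulus schedule onto the imaging time axis
#'
#' 1 while a presentation of the given modality is on screen, 0 otherwise.
#'
#' @param schedule a [StimulusSchedule]
#' @param modality `"gratings"`, `"sparse_noise"` or `"auditory"`
#' @param time_s imaging frame times, s
#' @return integer 0/1 vector, same length as `time_s`
#' @export
binarizeStimulus <- function(schedule, modality, time_s) {
    p <- schedule@presentations
    p <- p[p$modality == modality, ]
    track <- integer(length(time_s))
    for (j in seq_len(nrow(p)))
        track[time_s >= p$onset[j] & time_s < p$onset[j] + p$duration[j]] <- 1L
    track
}

#' Correlation of a spine trace with a binarized stimulus track
#'
#' Pearson correlation with a two-sided parametric (t-distribution)
#' p-value. A spine is "significantly positively" correlated when `r > 0`
#' and `p < 0.05`.
#'
#' @param trace spine dF/F trace
#' @param track binarized stimulus track, same length
#' @return list with `r` and `p`
#' @export
stimCorrelation <- function(trace, track) {
    if (length(trace) != length(track))
        stop("trace and track must have equal length")
    if (var(track) == 0) stop("no stimulus in epoch: track is constant")
    ct <- cor.test(trace, track)
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Percentage of presentations with a time-locked response
#'
#' A presentation is time-locked when at least one detected event onset
#' falls within `window_s` (default 500 ms) of the presentation onset.
#'
#' @param eventOnsets detected event onset times, s
#' @param presentationOnsets stimulus presentation onset times, s
#' @param window_s response window after each onset, s
#' @return percentage in `[0, 100]`
#' @export
timelockedPct <- function(eventOnsets, presentationOnsets, window_s = 0.5) {
    if (!length(presentationOnsets)) stop("at least one presentation required")
    hit <- vapply(presentationOnsets, function(t0)
        any(eventOnsets >= t0 & eventOnsets <= t0 + window_s), logical(1))
    100 * mean(hit)
}

#' Dummy-stimulus false-positive threshold
#'
#' The per-spine chance level of time-locking: the time-locked percentage
#' of the spine's dark-epoch events against dummy presentation onsets laid
#' over the dark epoch. With several dummy layouts the estimate is the
#' mean across layouts, which stabilises the per-spine chance level.
#'
#' @param darkEventOnsets event onsets within the dark epoch, s
#' @param dummyOnsets numeric vector of dummy onsets, or a list of such
#'   vectors (one per dummy layout)
#' @param window_s response window, s
#' @return false-positive percentage in `[0, 100]`
#' @export
falsePositiveThreshold <- function(darkEventOnsets, dummyOnsets,
                                   window_s = 0.5) {
    if (!is.list(dummyOnsets)) dummyOnsets <- list(dummyOnsets)
    if (!length(dummyOnsets) || !any(lengths(dummyOnsets) > 0))
        stop("dummy track has no presentations")
    mean(vapply(dummyOnsets, function(on)
        timelockedPct(darkEventOnsets, on, window_s), numeric(1)))
}

# Dummy presentation layouts over the dark epoch, with the same
# inter-onset interval as the real grating presentations and a random
# phase per layout; deterministic given the seed.
makeDummyOnsets <- function(schedule, nReps, seed, window_s = 0.5) {
    dk <- epochWindow(schedule, "dark")
    if (is.null(dk)) stop("missing dark epoch: cannot build dummy tracks")
    if (diff(dk) < 120) stop("dark epoch must be at least 120 s")
    gr <- presentationOnsets(schedule, "gratings")
    ioi <- if (length(gr) > 1) median(diff(gr)) else 6
    lapply(seq_len(nReps), function(rep)
        withSeed(deriveSeed(seed, "dummy", rep), {
            phase <- runif(1, 0, ioi)
            on <- seq(dk[1] + phase, dk[2] - window_s, by = ioi)
            on
        }))
}

#' Leave-one-out network signal
#'
#' The unweighted mean of all other spines' spine-specific dF/F traces in
#' the imaged region, over all conditions (stimulation and darkness); the
#' indexed spine contributes nothing.
#'
#' @param residMat spines-by-time matrix of spine-specific dF/F
#' @param index row index of the spine of interest
#' @return numeric reference trace
#' @export
networkSignal <- function(residMat, index) {
    if (nrow(residMat) < 3)
        stop("need at least 3 spines to form a network reference")
    colSums(residMat[-index, , drop = FALSE]) / (nrow(residMat) - 1)
}

# Circular-shift permutation test for the correlation of x with y: the
# null distribution is the correlation at every circular lag outside a
# guard band around zero, which preserves the autocorrelation of both
# series. Exact and deterministic via FFT cross-correlation; the returned
# p is two-sided (matching the conventional two-sided Pearson test).
shiftCorTest <- function(fx, fy, sdx, sdy, n, guard) {
    cc <- Re(fft(fx * Conj(fy), inverse = TRUE)) / n
    r_all <- cc / (n - 1) / (sdx * sdy)
    r0 <- r_all[1]
    lags <- seq_len(n) - 1L
    valid <- lags >= guard & lags <= n - guard
    m <- sum(valid)
    pPos <- (1 + sum(r_all[valid] >= r0)) / (1 + m)
    pNeg <- (1 + sum(r_all[valid] <= r0)) / (1 + m)
    list(r = r0, p = min(1, 2 * min(pPos, pNeg)))
}

circularShiftTest <- function(x, ref, guard = 75L) {
    n <- length(x)
    xc <- x - mean(x)
    rc <- ref - mean(ref)
    shiftCorTest(fft(xc), fft(rc), sd(x), sd(ref), n, guard)
}

#' Correlation of a spine trace with the network signal
#'
#' Pearson r of the spine-specific trace against the leave-one-out network
#' reference. With `method = "parametric"` the p-value is the conventional
#' two-sided t-test; with `method = "shift"` (recommended for
#' autocorrelated calcium traces) it is a two-sided circular-shift
#' permutation p over all time lags outside a guard band, so the temporal
#' autocorrelation of both series is preserved under the null.
#'
#' @param trace spine-specific dF/F trace
#' @param reference network reference trace from [networkSignal()]
#' @param method `"parametric"` or `"shift"`
#' @param guard_s guard band around zero lag for the shift null, s
#' @param rate sampling rate (needed for `guard_s`), Hz
#' @return list with `r` and `p`
#' @export
networkCorrelation <- function(trace, reference,
                               method = c("parametric", "shift"),
                               guard_s = 5, rate = 15) {
    method <- match.arg(method)
    if (method == "parametric") return(stimCorrelation(trace, reference))
    circularShiftTest(trace, reference, guard = round(guard_s * rate))
}

# Robust bivariate Gaussian fit by iterative trimming. The initial fit
# uses coordinatewise medians and MADs (a plain sample covariance is
# masked by even a modest fraction of responsive trials); subsequent
# passes refit mean and covariance on the points inside the 99th
# chi-square percentile of the current fit. Returns squared Mahalanobis
# distances of all points under the final (noise) fit.
robustMahalanobis2 <- function(X, passes = 3L) {
    cut99 <- stats::qchisq(0.99, df = 2)
    mu <- apply(X, 2, median)
    sds <- pmax(apply(X, 2, mad), 1e-12)
    S <- diag(sds^2)
    d2 <- stats::mahalanobis(X, mu, S)
    for (it in seq_len(passes)) {
        keep <- d2 <= cut99
        if (sum(keep) < 10) break
        mu <- colMeans(X[keep, , drop = FALSE])
        S <- stats::cov(X[keep, , drop = FALSE])
        if (any(!is.finite(S)) || det(S) <= 0)
            S <- diag(pmax(diag(S), 1e-12))
        d2 <- stats::mahalanobis(X, mu, S)
    }
    d2
}

#' Sparse-noise responsiveness of a spine
#'
#' For each sparse-noise frame the response feature is the pair of dF/F
#' derivatives (one-frame forward differences) immediately after frame
#' onset and ~100 ms later (nearest frame, +2 frames at 15 Hz). A robust
#' bivariate Gaussian is fit to the trial cloud; trials with Mahalanobis
#' distance beyond four standard deviations are responsive. The spine is
#' sparse-noise responsive when its responsive-trial count exceeds the
#' one-sided binomial 95% bound for the chance rate implied by the 4-SD
#' cut (`P(chi2_2 > 16)`).
#'
#' @param trace spine dF/F trace
#' @param schedule session [StimulusSchedule] containing a sparse-noise
#'   epoch
#' @param rate sampling rate, Hz
#' @param sdCut outlier cut in standard deviations (default 4)
#' @param chanceRate the spine's spontaneous event rate (Hz, e.g. its
#'   dark-epoch detected rate); spontaneous transients landing on a frame
#'   onset by chance produce genuine derivative outliers, so the null
#'   outlier rate is the Gaussian tail plus this coincidence rate over the
#'   ~4-frame feature window. 0 (default) uses the pure Gaussian null.
#' @param alphaLevel one-sided binomial level for the responder decision
#' @return list: `responsive` (decision), `trialFlags` (per-trial logical),
#'   `nResponsive`, `criticalCount`, `nTrials`
#' @export
sparseNoiseResponsive <- function(trace, schedule, rate, sdCut = 4,
                                  chanceRate = 0, alphaLevel = 0.001) {
    on <- presentationOnsets(schedule, "sparse_noise")
    if (length(on) < 50)
        stop("insufficient trials: need at least 50 sparse-noise frames")
    f <- round(on * rate) + 1L
    lag2 <- round(0.1 * rate)  # nearest frame to +100 ms
    ok <- f + lag2 + 1L <= length(trace)
    f <- f[ok]
    d1 <- (trace[f + 1L] - trace[f]) * rate
    d2 <- (trace[f + lag2 + 1L] - trace[f + lag2]) * rate
    X <- cbind(d1, d2)
    md2 <- robustMahalanobis2(X)
    flags <- md2 > sdCut^2
    pNull <- stats::pchisq(sdCut^2, df = 2, lower.tail = FALSE) +
        (1 - exp(-chanceRate * 4 / rate))
    crit <- qbinom(1 - alphaLevel, length(f), pNull)
    list(responsive = sum(flags) > crit, trialFlags = flags,
         nResponsive = sum(flags), criticalCount = crit,
         nTrials = length(f))
}

#' Correlation of a spine trace with a behavioral regressor
#'
#' Generic hook for behavioral covariates (pupil position or diameter,
#' whisker movement, ...): Pearson r with a two-sided parametric p-value.
#' The regressor series is supplied by the caller, aligned to the imaging
#' time axis.
#'
#' @param trace spine dF/F trace
#' @param regressor behavioral series, same length
#' @return list with `r` and `p`
#' @export
behavioralRegressorCorrelation <- function(trace, regressor) {
    if (var(regressor) == 0)
        stop("degenerate regressor: constant series")
    stimCorrelation(trace, regressor)
}

# "Time-locked above chance": the real time-locked count is significantly
# above the spine's dummy-stimulus chance rate (one-sided binomial test at
# alpha), and the raw percentage exceeds the chance percentage. The level
# is 0.5%: the per-spine chance rate is itself an estimate, thousands of
# spines are tested without a multiplicity correction, and genuine
# responders sit far above chance, so the stricter level costs no
# sensitivity while keeping the expected number of falsely "sensory"
# spines small.
aboveChance <- function(count, nPres, fpPct, alpha = 0.005,
                        fpFloorPct = 0.5) {
    p0 <- pmax(fpPct, fpFloorPct) / 100
    pval <- pbinom(count - 1L, nPres, p0, lower.tail = FALSE)
    (pval < alpha) & (100 * count / nPres > fpPct)
}

#' Assign a functional class from classification diagnostics
#'
#' Decision order: (1) visually responsive when the gratings correlation
#' is significantly positive and the time-locked percentage is above the
#' spine's dummy-stimulus chance level, or the spine is sparse-noise
#' responsive; (2) auditory responsive (RSC) by the same rule on the
#' auditory track; (3) network-correlated when the network correlation is
#' significantly positive and neither sensory rule fired; (4) unclassified
#' otherwise; (5) a non-sensory spine whose time-locked percentage is
#' above chance without a significant stimulus correlation is excluded
#' from further analysis.
#'
#' @param diagnostics data.frame of per-spine diagnostics (as produced by
#'   [classifySession()]): columns `rVis`, `pVis`, `aboveChanceVis`,
#'   `sparseResponsive`, and for RSC `rAud`, `pAud`, `aboveChanceAud`,
#'   plus `rNet`, `pNet`.
#' @param region `"V1"` or `"RSC"`
#' @return character vector of labels: `visually_responsive`,
#'   `auditory_responsive`, `network_correlated`, `unclassified`,
#'   `excluded`
#' @export
classifySpine <- function(diagnostics, region = "V1") {
    d <- diagnostics
    visSig <- !is.na(d$rVis) & d$rVis > 0 & d$pVis < 0.05
    sparse <- if ("sparseResponsive" %in% names(d))
        d$sparseResponsive %in% TRUE else rep(FALSE, nrow(d))
    vis <- (visSig & d$aboveChanceVis) | sparse
    if (region == "RSC" && "rAud" %in% names(d)) {
        audSig <- !is.na(d$rAud) & d$rAud > 0 & d$pAud < 0.05
        audAbove <- d$aboveChanceAud
        aud <- !vis & audSig & audAbove
    } else {
        audSig <- rep(FALSE, nrow(d))
        audAbove <- rep(FALSE, nrow(d))
        aud <- rep(FALSE, nrow(d))
    }
    netSig <- !is.na(d$rNet) & d$rNet > 0 & d$pNet < 0.05
    label <- ifelse(vis, "visually_responsive",
             ifelse(aud, "auditory_responsive",
             ifelse(netSig, "network_correlated", "unclassified")))
    # exclusion: non-sensory label but above-chance time-locking without a
    # significant stimulus correlation
    excl <- label %in% c("network_correlated", "unclassified") &
        ((d$aboveChanceVis & !visSig) | (audAbove & !audSig))
    label[excl] <- "excluded"
    label
}

#' Classify every spine of a session
#'
#' Full functional classification of a preprocessed session: binarized
#' stimulus correlations per modality, time-locked percentages of detected
#' event onsets, the per-spine dummy-stimulus false-positive threshold
#' from the dark epoch, the leave-one-out network-signal correlation
#' (circular-shift permutation p by default), sparse-noise responsiveness
#' when a sparse-noise epoch is present, and the final label.
#'
#' @param x a preprocessed [SpineExperiment]
#' @param detection result of [detectSessionEvents()]; computed if `NULL`
#' @param netMethod `"shift"` (default) or `"parametric"`, see
#'   [networkCorrelation()]
#' @param nDummy number of dummy-stimulus layouts averaged for the
#'   false-positive threshold
#' @param window_s time-locking window, s
#' @return data.frame with per-spine diagnostics (`rVis`, `pVis`,
#'   `timelockedVis`, `fpPct`, `rNet`, `pNet`, `sparseResponsive`, RSC
#'   auditory columns) and `label`
#' @export
classifySession <- function(x, detection = NULL,
                            netMethod = c("shift", "parametric"),
                            nDummy = 20L, window_s = 0.5) {
    stopifnot(is(x, "SpineExperiment"))
    netMethod <- match.arg(netMethod)
    if (is.null(detection)) detection <- detectSessionEvents(x)
    sch <- stimulusSchedule(x)
    rate <- metadata(x)$samplingRate
    time_s <- colData(x)$time_s
    sp <- spineRows(x)
    resid <- assay(x, "resid")[sp, , drop = FALSE]
    spines <- rownames(resid)
    n <- length(spines)
    ev <- detection$events
    onsetsBy <- split(ev$onset_s, factor(ev$spine, levels = spines))

    nT <- ncol(resid)
    guard <- round(5 * rate)
    grOn <- presentationOnsets(sch, "gratings")
    visTrack <- binarizeStimulus(sch, "gratings", time_s)
    tlCountVis <- vapply(onsetsBy, function(on)
        sum(vapply(grOn, function(t0)
            any(on >= t0 & on <= t0 + window_s), logical(1))), integer(1))

    hasAud <- "auditory" %in% sch@epochs$modality
    if (hasAud) {
        audOn <- presentationOnsets(sch, "auditory")
        audTrack <- binarizeStimulus(sch, "auditory", time_s)
        tlCountAud <- vapply(onsetsBy, function(on)
            sum(vapply(audOn, function(t0)
                any(on >= t0 & on <= t0 + window_s), logical(1))), integer(1))
    }

    # per-spine chance level from the dark epoch
    dk <- epochWindow(sch, "dark")
    if (is.null(dk)) stop("missing dark epoch: cannot set chance levels")
    cfg <- simConfig(x)
    dummySeed <- if (!is.null(cfg)) cfg@seed else 1L
    dummies <- makeDummyOnsets(sch, nDummy, dummySeed, window_s)
    fpPct <- vapply(onsetsBy, function(on)
        falsePositiveThreshold(on[on >= dk[1] & on < dk[2]], dummies,
                               window_s), numeric(1))

    # stimulus and leave-one-out network correlations; with the shift
    # method every test for one spine reuses the spine's single FFT
    S <- colSums(resid)
    rNet <- numeric(n); pNet <- numeric(n)
    rVis <- numeric(n); pVis <- numeric(n)
    rAud <- numeric(n); pAud <- numeric(n)
    visCT <- rowCorTest(resid, visTrack)
    rVis <- visCT$r; pVis <- visCT$p
    if (hasAud) {
        audCT <- rowCorTest(resid, audTrack)
        rAud <- audCT$r; pAud <- audCT$p
    }
    if (netMethod == "shift") {
        fS <- fft(S - mean(S))
        for (i in seq_len(n)) {
            x <- resid[i, ]
            fx <- fft(x - mean(x))
            ref <- (S - x) / (n - 1)
            fr <- (fS - fx) / (n - 1)
            nc <- shiftCorTest(fx, fr, sd(x), sd(ref), nT, guard)
            rNet[i] <- nc$r; pNet[i] <- nc$p
        }
    } else {
        refAll <- (matrix(S, n, nT, byrow = TRUE) - resid) / (n - 1)
        for (i in seq_len(n)) {
            nc <- stimCorrelation(resid[i, ], refAll[i, ])
            rNet[i] <- nc$r; pNet[i] <- nc$p
        }
    }

    hasSparse <- "sparse_noise" %in% sch@epochs$modality &&
        length(presentationOnsets(sch, "sparse_noise")) >= 50
    sparseResp <- rep(NA, n)
    if (hasSparse) {
        darkDur <- dk[2] - dk[1]
        darkRate <- vapply(onsetsBy, function(on)
            sum(on >= dk[1] & on < dk[2]) / darkDur, numeric(1))
        sparseResp <- vapply(seq_len(n), function(i)
            sparseNoiseResponsive(resid[i, ], sch, rate,
                                  chanceRate = darkRate[i])$responsive,
            logical(1))
    }

    diag <- data.frame(
        spine = spines,
        rVis = rVis, pVis = pVis,
        timelockedVis = 100 * tlCountVis / length(grOn),
        nVisPres = length(grOn),
        fpPct = fpPct,
        rNet = rNet, pNet = pNet,
        sparseResponsive = if (hasSparse) sparseResp else NA,
        stringsAsFactors = FALSE)
    diag$aboveChanceVis <- aboveChance(tlCountVis, length(grOn), fpPct)
    if (hasAud) {
        diag$rAud <- rAud; diag$pAud <- pAud
        diag$timelockedAud <- 100 * tlCountAud / length(audOn)
        diag$nAudPres <- length(audOn)
        diag$aboveChanceAud <- aboveChance(tlCountAud, length(audOn), fpPct)
    }
    region <- if (!is.null(cfg)) cfg@region else
        unique(rowData(x)$region)[1]
    diag$label <- classifySpine(diag, region)
    diag
}

#' Per-class summary of a classification table
#'
#' @param diag result of [classifySession()]
#' @return list with `n` (included spines), `nExcluded`, `pct` (named
#'   class percentages over included spines) and `pctNetworkSignificant`
#'   (spines with a significant positive network correlation)
#' @export
classifySummary <- function(diag) {
    inc <- diag$label != "excluded"
    lv <- c("visually_responsive", "auditory_responsive",
            "network_correlated", "unclassified")
    pct <- 100 * vapply(lv, function(l) mean(diag$label[inc] == l),
                        numeric(1))
    list(n = sum(inc), nExcluded = sum(!inc), pct = pct,
         pctNetworkSignificant =
             100 * mean(diag$rNet[inc] > 0 & diag$pNet[inc] < 0.05))
}
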