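## Event-level and trace-level synthesis. A study plan fixes everything
## that persists across sessions (class labels, branch layout, bleed
## slopes, coupling, preferred directions, deprivation draws); each session
## then draws its own event trains and rendering noise.

lognormPars <- function(mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

deprivedModality <- function(paradigm)
    switch(paradigm, enucleation = "visual", dark_exposure = "visual",
           ear_plug = "auditory", sham = NA_character_)

# Orientation tuning of evoked responses: full response probability at
# the preferred orientation, falling off toward the orthogonal
# orientation. Spine tuning is broader than cellular tuning, so the
# orthogonal response is small but nonzero.
gratingResponseProb <- function(direction, prefDir, pmax) {
    d <- abs(direction - prefDir) %% 180
    dOri <- pmin(d, 180 - d)
    pmax * c("0" = 1, "45" = 0.75, "90" = 0.25,
             "135" = 0.75)[as.character(dOri)]
}

#' Study-level ground-truth plan
#'
#' Draws the per-spine attributes that are fixed across all sessions of a
#' study: functional class (deterministic largest-remainder counts from the
#' configured mixture, randomly permuted), dendritic branch layout with
#' positions assigned independently of class, true bleed slope alpha,
#' network coupling weight, preferred grating direction for visually
#' responsive spines, sparse-noise responder flags (calibrated so the
#' expected sparse/gratings responder overlap equals `snOverlap`), and the
#' latent uniform draws that decide silencing and reactivation under
#' deprivation.
#'
#' @param config a [SpineSimConfig]
#' @return data.frame with one row per spine and the branch table as the
#'   `"branches"` attribute
#' @export
studyPlan <- function(config) {
    n <- config@nSpines
    withSeed(deriveSeed(config@seed, "plan"), {
        counts <- apportion(config@classMixture,  n)
        classes <- sample(rep(names(config@classMixture), counts))
        # branch layout: sizes uniform in branchSizeRange, class-independent
        szr <- config@branchSizeRange
        sizes <- integer()
        while (sum(sizes) < n)
            sizes <- c(sizes, sample(seq(szr[1], szr[2]), 1))
        branch <- rep(seq_along(sizes), sizes)[seq_len(n)]
        position <- unlist(lapply(table(branch), seq_len), use.names = FALSE)
        alpha <- runif(n, config@alphaRange[1], config@alphaRange[2])
        coupling <- ifelse(classes == "unclassified", 0, config@couplingWeight)
        prefDir <- ifelse(classes == "visual",
                          sample(seq(0, 315, by = 45), n, replace = TRUE),
                          NA_real_)
        # visually responsive spines respond to sparse noise; a small
        # subset responds to sparse noise only (no gratings responses),
        # sized so the expected sparse/gratings responder overlap equals
        # snOverlap
        sparseResponder <- classes == "visual"
        gratResponder <- classes == "visual"
        nSparseOnly <- round(sum(sparseResponder) * (1 - config@snOverlap))
        if (nSparseOnly > 0)
            gratResponder[sample(which(sparseResponder), nSparseOnly)] <- FALSE
        uSilence <- runif(n)
        uReact <- runif(n)
        baseF <- rlnorm(n, log(100), 0.2)
        baseFDend <- rlnorm(n, log(100), 0.2)
        nb <- length(unique(branch))
        branches <- data.frame(
            branch = seq_len(nb),
            prefDir = sample(seq(0, 315, by = 45), nb, replace = TRUE),
            size = as.integer(table(branch)))
        plan <- data.frame(
            spine = sprintf("sp%04d", seq_len(n)),
            class = classes, branch = branch, position = position,
            alpha = alpha, coupling = coupling, prefDir = prefDir,
            sparseResponder = sparseResponder,
            gratResponder = gratResponder,
            uSilence = uSilence, uReact = uReact,
            baseF = baseF, baseFDend = baseFDend,
            region = config@region, stringsAsFactors = FALSE)
        attr(plan, "branches") <- branches
        plan
    })
}

# Which spines are silenced in the session at `timepoint`. The silenced
# fraction per class is exact (largest-remainder count, ranked by the
# spine's latent uniform draw) so the population inactive fraction
# reflects the configured probabilities rather than an extra layer of
# binomial sampling noise; reactivation stays a per-spine draw.
silencedAt <- function(config, plan, timepoint) {
    dep <- config@deprivation
    if (dep$paradigm == "sham" || timepoint < dep$onsetHr)
        return(rep(FALSE, nrow(plan)))
    silenced12 <- rep(FALSE, nrow(plan))
    for (cl in unique(plan$class)) {
        idx <- which(plan$class == cl)
        p <- dep$inactivationProb[[cl]]
        k <- round(p * length(idx))
        if (k > 0)
            silenced12[idx[order(plan$uSilence[idx])[seq_len(k)]]] <- TRUE
    }
    key <- as.character(timepoint)
    react <- if (key %in% names(dep$reactivation)) dep$reactivation[[key]] else 0
    silenced12 & plan$uReact >= react
}

ampFactor <- function(config, class, timepoint) {
    dep <- config@deprivation
    if (dep$paradigm == "sham" || isTRUE(dep$tnfBlocked) ||
        timepoint < dep$onsetHr)
        return(rep(1, length(class)))
    key <- as.character(timepoint)
    vapply(class, function(cl) {
        sc <- dep$ampScaling[[cl]]
        if (!is.null(sc) && key %in% names(sc)) sc[[key]] else 1
    }, numeric(1))
}

#' Simulate ground-truth event trains for one session
#'
#' Every spine receives a homogeneous Poisson background train; spines with
#' nonzero coupling additionally inherit each event of a session-wide
#' latent network train with probability equal to their coupling weight;
#' sensory-responsive spines emit an event within the latency-jitter window
#' of each preferred presentation of their modality with probability
#' `stimResponseProb` (preferred-orientation gratings, i.e. the preferred
#' direction and its opposite; every auditory burst; sparse-noise frames at
#' the per-frame trial response probability). For sessions at or after the
#' deprivation onset, silenced spines lose all events, the deprived
#' modality's evoked events are removed when the paradigm is irreversible,
#' and per-event amplitudes are scaled by the class- and timepoint-specific
#' factor (identity when TNF-alpha signalling is blocked).
#'
#' @param config a [SpineSimConfig]
#' @param plan the [studyPlan()] table
#' @param schedule the session [StimulusSchedule]
#' @param timepoint session time in hours relative to deprivation
#' @return list with elements `events` (data.frame: `spine`, `t`, `amp`,
#'   `source`), `dendrite` (branch-level train: `branch`, `t`, `amp`,
#'   `source`), `latent` (latent event times) and `silenced` (per spine)
#' @export
simulateEvents <- function(config, plan, schedule, timepoint) {
    tpIndex <- match(timepoint, config@timepoints)
    if (is.na(tpIndex))
        stop("timepoint ", timepoint, " is not in the configured timepoints")
    Tdur <- sessionDuration(config)
    lp <- lognormPars(config@eventAmpMean, config@eventAmpCV)
    dep <- config@deprivation
    depMod <- deprivedModality(dep$paradigm)
    postOnset <- dep$paradigm != "sham" && timepoint >= dep$onsetHr
    dropEvoked <- postOnset && isTRUE(dep$removeEvoked)
    withSeed(deriveSeed(config@seed, "events", tpIndex), {
        nLat <- rpois(1, config@latentRate * Tdur)
        latent <- sort(runif(nLat, 0, Tdur))
        grat <- schedule@presentations[
            schedule@presentations$modality == "gratings", ]
        aud <- presentationOnsets(schedule, "auditory")
        sn <- presentationOnsets(schedule, "sparse_noise")
        n <- nrow(plan)
        silenced <- silencedAt(config, plan, timepoint)
        fac <- ampFactor(config, plan$class, timepoint)
        out <- vector("list", n)
        for (i in seq_len(n)) {
            ts <- list(); src <- list()
            nb <- rpois(1, config@backgroundRate * Tdur)
            ts$bg <- runif(nb, 0, Tdur)
            src$bg <- rep("background", nb)
            if (plan$coupling[i] > 0 && nLat > 0) {
                keep <- runif(nLat) < plan$coupling[i]
                ts$lat <- latent[keep]
                src$lat <- rep("latent", sum(keep))
            }
            if (plan$class[i] == "visual" && plan$gratResponder[i] &&
                nrow(grat)) {
                pr <- gratingResponseProb(grat$direction, plan$prefDir[i],
                                          config@stimResponseProb)
                resp <- runif(nrow(grat)) < pr
                tv <- grat$onset[resp] +
                    runif(sum(resp), 0, config@latencyJitter)
                if (!(dropEvoked && identical(depMod, "visual"))) {
                    ts$vis <- tv; src$vis <- rep("evoked_vis", length(tv))
                }
            }
            if (plan$class[i] == "auditory" && length(aud)) {
                resp <- runif(length(aud)) < config@stimResponseProb
                ta <- aud[resp] + runif(sum(resp), 0, config@latencyJitter)
                if (!(dropEvoked && identical(depMod, "auditory"))) {
                    ts$aud <- ta; src$aud <- rep("evoked_aud", length(ta))
                }
            }
            if (plan$sparseResponder[i] && length(sn)) {
                resp <- runif(length(sn)) < config@snTrialProb
                tsn <- sn[resp] + runif(sum(resp), 0, 0.05)
                if (!(dropEvoked && identical(depMod, "visual"))) {
                    ts$sn <- tsn; src$sn <- rep("evoked_sparse", length(tsn))
                }
            }
            tt <- unlist(ts, use.names = FALSE)
            if (is.null(tt)) tt <- numeric(0)
            srcv <- unlist(src, use.names = FALSE)
            if (is.null(srcv)) srcv <- character(0)
            amps <- rlnorm(length(tt), lp$meanlog, lp$sdlog) * fac[i]
            evk <- startsWith(srcv, "evoked")
            amps[evk] <- amps[evk] * config@evokedAmpFactor
            df <- data.frame(spine = rep(plan$spine[i], length(tt)),
                             t = tt, amp = amps, source = srcv,
                             stringsAsFactors = FALSE)
            if (silenced[i]) df <- df[0, ]
            out[[i]] <- df[order(df$t), ]
        }
        events <- as.data.frame(data.table::rbindlist(out))
        # branch-level global (bAP-like) train: the branch's own
        # spontaneous spiking plus its stimulus-evoked responses. The
        # spontaneous train is independent of the region-wide latent
        # train: the global dendritic signal reflects the cell's output,
        # not the shared input. Post-deprivation, spontaneous bAP
        # amplitudes scale with the network-correlated input
        # strengthening (the amplified intrinsic drive).
        branches <- attr(plan, "branches")
        netFac <- ampFactor(config, rep("network_only", nrow(branches)),
                            timepoint)
        dout <- vector("list", nrow(branches))
        for (b in seq_len(nrow(branches))) {
            nBap <- rpois(1, config@bapRate * Tdur)
            tt <- sort(runif(nBap, 0, Tdur))
            src <- rep("bap", nBap)
            if (nrow(grat) && !(dropEvoked && identical(depMod, "visual"))) {
                pr <- gratingResponseProb(grat$direction,
                                          branches$prefDir[b],
                                          config@stimResponseProb)
                resp <- runif(nrow(grat)) < pr
                tv <- grat$onset[resp] +
                    runif(sum(resp), 0, config@latencyJitter)
                tt <- c(tt, tv); src <- c(src, rep("evoked_vis", length(tv)))
            }
            if (config@region == "RSC" && length(aud) &&
                !(dropEvoked && identical(depMod, "auditory"))) {
                resp <- runif(length(aud)) < config@stimResponseProb
                ta <- aud[resp] + runif(sum(resp), 0, config@latencyJitter)
                tt <- c(tt, ta); src <- c(src, rep("evoked_aud", length(ta)))
            }
            amps <- rlnorm(length(tt), lp$meanlog, lp$sdlog) *
                config@dendAmpFactor
            amps[src == "bap"] <- amps[src == "bap"] * netFac[b]
            o <- order(tt)
            dout[[b]] <- data.frame(branch = branches$branch[b], t = tt[o],
                                    amp = amps[o], source = src[o],
                                    stringsAsFactors = FALSE)
        }
        dendrite <- as.data.frame(data.table::rbindlist(dout))
        list(events = events, dendrite = dendrite, latent = latent,
             silenced = silenced)
    })
}

# FFT convolution of an impulse train (times/amps) with the transient
# kernel on the session sampling grid.
convolveTrain <- function(t, amp, n, rate, kernFFT, nfft) {
    imp <- numeric(nfft)
    if (length(t)) {
        idx <- pmin(pmax(round(t * rate) + 1L, 1L), n)
        tab <- rowsum(amp, idx)
        imp[as.integer(rownames(tab))] <- tab[, 1]
    }
    Re(fft(fft(imp) * kernFFT, inverse = TRUE))[seq_len(n)] / nfft
}

#' Render fluorescence traces for one session
#'
#' Converts ground-truth event trains into an ROI-by-time raw fluorescence
#' matrix. The dendrite ROI of each spine carries the branch-level global
#' component (latent plus evoked events convolved with the unit-peak
#' transient kernel); the spine ROI carries the spine's own event train
#' plus `alpha` times the branch dendritic component (bleed-through), and
#' every ROI receives an independent slow sinusoidal drift and white
#' Gaussian noise on top of a strictly positive baseline fluorescence.
#'
#' @param config a [SpineSimConfig]
#' @param plan the [studyPlan()] table
#' @param schedule session [StimulusSchedule]
#' @param trains result of [simulateEvents()]
#' @param timepoint session time in hours
#' @return a [SpineExperiment] with assay `fluor` and the full ground truth
#'   in `metadata()`
#' @export
renderTraces <- function(config, plan, schedule, trains, timepoint) {
    tpIndex <- match(timepoint, config@timepoints)
    rate <- config@samplingRate
    Tdur <- sessionDuration(config)
    n <- round(Tdur * rate)
    nsp <- nrow(plan)
    kern <- transientKernel(config)
    nfft <- stats::nextn(n + length(kern) - 1L, c(2L, 3L, 5L))
    kernFFT <- fft(c(kern, numeric(nfft - length(kern))))
    tsec <- (seq_len(n) - 1L) / rate
    branches <- attr(plan, "branches")
    withSeed(deriveSeed(config@seed, "traces", tpIndex), {
        branchComp <- matrix(0, nrow(branches), n)
        dtr <- trains$dendrite
        for (b in seq_len(nrow(branches))) {
            sel <- dtr$branch == branches$branch[b]
            branchComp[b, ] <- convolveTrain(dtr$t[sel], dtr$amp[sel],
                                             n, rate, kernFFT, nfft)
        }
        ev <- trains$events
        evBySpine <- split(seq_len(nrow(ev)), factor(ev$spine,
                                                     levels = plan$spine))
        mat <- matrix(0, 2L * nsp, n)
        phases <- runif(nsp, 0, 2 * pi)
        periods <- runif(nsp, config@driftPeriod, 3 * config@driftPeriod)
        for (i in seq_len(nsp)) {
            sel <- evBySpine[[i]]
            own <- convolveTrain(ev$t[sel], ev$amp[sel], n, rate,
                                 kernFFT, nfft)
            d <- branchComp[plan$branch[i], ]
            # slow drift is shared by a spine and its adjacent dendrite
            # ROI (same optical micro-locus), but independent across
            # spine/dendrite pairs
            drift <- config@driftAmp * sin(2 * pi * tsec / periods[i] +
                                           phases[i])
            mat[i, ] <- plan$baseF[i] *
                (1 + own + plan$alpha[i] * d + drift +
                 rnorm(n, 0, config@noiseSd))
            mat[nsp + i, ] <- plan$baseFDend[i] *
                (1 + d + drift + rnorm(n, 0, config@noiseSd))
        }
        roiS <- plan$spine
        roiD <- sub("^sp", "dn", plan$spine)
        rownames(mat) <- c(roiS, roiD)
        rd <- DataFrame(
            roi = c(roiS, roiD),
            roiType = rep(c("spine", "dendrite"), each = nsp),
            spine = rep(plan$spine, 2),
            pairedRoi = c(roiD, roiS),
            branch = rep(plan$branch, 2),
            position = rep(plan$position, 2),
            region = config@region,
            trueClass = rep(plan$class, 2),
            trueAlpha = rep(plan$alpha, 2),
            trueCoupling = rep(plan$coupling, 2),
            prefDir = rep(plan$prefDir, 2),
            silenced = rep(trains$silenced, 2))
        epoch <- character(n)
        for (j in seq_len(nrow(schedule@epochs)))
            epoch[tsec >= schedule@epochs$start[j] &
                  tsec < schedule@epochs$start[j] +
                         schedule@epochs$duration[j]] <-
                schedule@epochs$modality[j]
        cd <- DataFrame(time_s = tsec, epoch = epoch,
                        stationary = TRUE)
        se <- SummarizedExperiment(assays = list(fluor = mat),
                                   rowData = rd, colData = cd)
        out <- new("SpineExperiment", se)
        metadata(out) <- list(
            config = config, schedule = schedule, timepoint = timepoint,
            samplingRate = rate,
            groundTruth = cbind(plan, silenced = trains$silenced),
            trueEvents = trains$events, trueDendrite = trains$dendrite,
            latent = trains$latent)
        out
    })
}

#' Simulate one complete session
#'
#' Convenience wrapper: [makeSchedule()], [simulateEvents()] and
#' [renderTraces()] for the session at `timepoint`.
#'
#' @inheritParams simulateEvents
#' @param plan optional precomputed [studyPlan()]; rebuilt if `NULL`
#' @return a [SpineExperiment]
#' @examples
#' cfg <- buildConfig("V1", "V1-baseline", list(nSpines = 8))
#' se <- simulateSession(cfg, -1)
#' se
#' @export
simulateSession <- function(config, timepoint = config@timepoints[1],
                            plan = NULL) {
    if (is.null(plan)) plan <- studyPlan(config)
    sch <- makeSchedule(config, match(timepoint, config@timepoints))
    trains <- simulateEvents(config, plan, sch, timepoint)
    renderTraces(config, plan, sch, trains, timepoint)
}

#' Simulate all sessions of a study
#'
#' @param config a [SpineSimConfig]
#' @return named list of [SpineExperiment], one per configured timepoint
#' @export
simulateStudy <- function(config) {
    plan <- studyPlan(config)
    out <- lapply(config@timepoints, simulateSession, config = config,
                  plan = plan)
    names(out) <- paste0(config@timepoints, "hr")
    out
}
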