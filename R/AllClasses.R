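#' Generator configuration for synthetic spine recordings
#'
#' Full parameterization of a synthetic longitudinal spine-imaging study:
#' functional class mixture, stimulus session layout, event-generating rates,
#' calcium transient kernel, noise and drift, dendritic bleed-through, and
#' the sensory-deprivation model. Built by [buildConfig()]; all invariants
#' are enforced by the class validity method.
#'
#' @slot seed integer master seed; every generator output is a pure function
#'   of the configuration including this seed.
#' @slot nSpines number of spines to simulate.
#' @slot region imaged region, `"V1"` or `"RSC"`. V1 configurations must
#'   have a zero auditory class proportion.
#' @slot classMixture named proportions over
#'   `visual`, `auditory`, `network_only`, `unclassified`; sums to 1.
#' @slot samplingRate imaging frame rate in Hz.
#' @slot sessionLayout ordered list of epochs; each epoch is a list with at
#'   least `modality` (`"gratings"`, `"sparse_noise"`, `"auditory"`,
#'   `"dark"`) and `duration` in seconds, plus modality parameters.
#' @slot timepoints session times in hours relative to deprivation onset.
#' @slot backgroundRate per-spine Poisson background event rate (Hz).
#' @slot stimResponseProb probability a responsive spine emits a time-locked
#'   event per preferred presentation.
#' @slot latencyJitter evoked-event latency, uniform on `[0, latencyJitter]` s.
#' @slot couplingWeight probability a network-coupled spine inherits each
#'   latent network event.
#' @slot latentRate rate of the shared latent network event train (Hz).
#' @slot kernelRise,kernelDecay transient rise/decay time constants (s) of
#'   the difference-of-exponentials kernel (unit peak).
#' @slot eventAmpMean,eventAmpCV mean and coefficient of variation of the
#'   lognormal per-event peak amplitude (dF/F units).
#' @slot noiseSd additive Gaussian noise, dF/F units.
#' @slot driftAmp,driftPeriod amplitude (fluorescence units, relative to a
#'   unit baseline) and minimum period (s) of the slow sinusoidal baseline
#'   wander; each ROI draws its period uniformly from
#'   `[driftPeriod, 3 * driftPeriod]` and its own phase.
#' @slot evokedAmpFactor multiplier on the amplitude of stimulus-evoked
#'   events relative to spontaneous ones.
#' @slot dendAmpFactor multiplier on dendritic (global, bAP-like) event
#'   amplitudes relative to spine events.
#' @slot bapRate rate (Hz) of the branch's spontaneous global
#'   (back-propagating action potential) events, independent of the
#'   region-wide latent train.
#' @slot alphaRange range of the per-spine dendritic bleed slope (uniform).
#' @slot snOverlap target fraction of sparse-noise responders that are also
#'   gratings-responsive.
#' @slot snTrialProb per-frame response probability of a sparse-noise
#'   responsive spine.
#' @slot branchSizeRange spines per dendritic branch (uniform integer range).
#' @slot deprivation list describing the deprivation model (`paradigm`,
#'   `onsetHr`, `inactivationProb`, `reactivation`, `ampScaling`,
#'   `tnfBlocked`, `removeEvoked`).
#' @seealso [buildConfig()], [simulateSession()]
#' @export
setClass("SpineSimConfig", representation(
    seed = "integer",
    nSpines = "integer",
    region = "character",
    classMixture = "numeric",
    samplingRate = "numeric",
    sessionLayout = "list",
    timepoints = "numeric",
    backgroundRate = "numeric",
    stimResponseProb = "numeric",
    latencyJitter = "numeric",
    couplingWeight = "numeric",
    latentRate = "numeric",
    kernelRise = "numeric",
    kernelDecay = "numeric",
    eventAmpMean = "numeric",
    eventAmpCV = "numeric",
    noiseSd = "numeric",
    driftAmp = "numeric",
    driftPeriod = "numeric",
    evokedAmpFactor = "numeric",
    dendAmpFactor = "numeric",
    bapRate = "numeric",
    alphaRange = "numeric",
    snOverlap = "numeric",
    snTrialProb = "numeric",
    branchSizeRange = "numeric",
    deprivation = "list"
))

validSpineSimConfig <- function(object) {
    msg <- character()
    mix <- object@classMixture
    need <- c("visual", "auditory", "network_only", "unclassified")
    if (!identical(sort(names(mix)), sort(need)))
        msg <- c(msg, "classMixture must be named over visual, auditory, network_only, unclassified")
    else {
        if (any(mix < 0)) msg <- c(msg, "classMixture entries must be nonnegative")
        if (abs(sum(mix) - 1) > 1e-9) msg <- c(msg, "classMixture must sum to 1 (within 1e-9)")
        if (object@region == "V1" && mix[["auditory"]] != 0)
            msg <- c(msg, "auditory proportion must be 0 when region is V1")
    }
    if (!object@region %in% c("V1", "RSC"))
        msg <- c(msg, "region must be 'V1' or 'RSC'")
    pos <- c(samplingRate = object@samplingRate,
             backgroundRate = object@backgroundRate,
             latentRate = object@latentRate,
             kernelRise = object@kernelRise, kernelDecay = object@kernelDecay,
             eventAmpMean = object@eventAmpMean,
             driftPeriod = object@driftPeriod,
             evokedAmpFactor = object@evokedAmpFactor,
             dendAmpFactor = object@dendAmpFactor,
             bapRate = object@bapRate)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
        msg <- c(msg, paste0("field(s) must be strictly positive: ",
                             paste(bad, collapse = ", ")))
    prb <- c(stimResponseProb = object@stimResponseProb,
             couplingWeight = object@couplingWeight,
             snTrialProb = object@snTrialProb, snOverlap = object@snOverlap)
    bad <- names(prb)[!is.finite(prb) | prb < 0 | prb > 1]
    if (length(bad))
        msg <- c(msg, paste0("probability field(s) must lie in [0,1]: ",
                             paste(bad, collapse = ", ")))
    if (length(object@alphaRange) != 2 || any(object@alphaRange < 0) ||
        diff(object@alphaRange) < 0)
        msg <- c(msg, "alphaRange must be an increasing pair of nonnegative slopes")
    durs <- vapply(object@sessionLayout, function(e) e$duration, numeric(1))
    if (any(!is.finite(durs) | durs <= 0))
        msg <- c(msg, "epoch durations must be strictly positive")
    dep <- object@deprivation
    if (!dep$paradigm %in% c("enucleation", "dark_exposure", "ear_plug", "sham"))
        msg <- c(msg, "deprivation paradigm must be enucleation, dark_exposure, ear_plug or sham")
    ip <- unlist(dep$inactivationProb)
    if (any(ip < 0 | ip > 1))
        msg <- c(msg, "inactivationProb entries must lie in [0,1]")
    sc <- unlist(dep$ampScaling)
    if (any(sc <= 0))
        msg <- c(msg, "ampScaling factors must be > 0")
    if (dep$paradigm == "sham") {
        if (any(ip != 0) || any(sc != 1) || isTRUE(dep$removeEvoked))
            msg <- c(msg, "sham requires zero inactivation, unit scaling and removeEvoked = FALSE")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SpineSimConfig", validSpineSimConfig)

#' Stimulus schedule for one imaging session
#'
#' Epoch table plus per-presentation attributes for a session: drifting
#' grating directions, auditory burst times, sparse-noise frame
#' specifications and the dark epoch.
#'
#' @slot epochs data.frame with `modality`, `start`, `duration` (s).
#' @slot presentations data.frame with `modality`, `onset`, `duration`,
#'   and `direction` (degrees; `NA` for non-grating presentations).
#' @slot sparseFrames list of per-frame square specifications
#'   (`cx`, `cy` centers in degrees, `size`, `polarity`).
#' @export
setClass("StimulusSchedule", representation(
    epochs = "data.frame",
    presentations = "data.frame",
    sparseFrames = "list"
))

setValidity("StimulusSchedule", function(object) {
    msg <- character()
    pr <- object@presentations
    for (m in unique(pr$modality)) {
        p <- pr[pr$modality == m, ]
        if (is.unsorted(p$onset))
            msg <- c(msg, paste0(m, " presentations must be sorted by onset"))
        if (nrow(p) > 1 &&
            any(p$onset[-1] < (p$onset + p$duration)[-nrow(p)] - 1e-9))
            msg <- c(msg, paste0(m, " presentations must not overlap"))
    }
    gr <- pr[pr$modality == "gratings", ]
    if (nrow(gr) && any(gr$direction %% 45 != 0))
        msg <- c(msg, "grating directions must be multiples of 45 degrees")
    if (length(msg)) msg else TRUE
})

#' Spine imaging session container
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the ROI-by-time fluorescence matrix of one imaging session.
#' Rows are ROIs (each spine ROI paired with a dendrite ROI on the same
#' branch), columns are imaging frames. The `fluor` assay holds raw
#' fluorescence; [preprocessSession()] adds `dff` (drift-corrected dF/F)
#' and `resid` (spine-specific signal after robust dendritic subtraction;
#' `NA` for dendrite rows). The stimulus schedule, generator configuration
#' and, for synthetic sessions, the ground truth live in `metadata()`.
#'
#' @export
setClass("SpineExperiment", contains = "SummarizedExperiment")

setValidity("SpineExperiment", function(object) {
    msg <- character()
    rd <- rowData(object)
    need <- c("roi", "roiType", "spine", "branch", "position")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste0("rowData must contain: ", paste(need, collapse = ", ")))
    if (!"fluor" %in% assayNames(object))
        msg <- c(msg, "assay 'fluor' is required")
    if (!"time_s" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain time_s")
    if (length(msg)) msg else TRUE
})
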