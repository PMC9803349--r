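## Generator presets. The class mixtures encode the published baseline
## population proportions for monocular V1 (visual 24%, network-correlated
## 65%, unclassified 11%) and RSC (visual 18.7%, auditory 15.9%,
## network-only 57.4%, unclassified 8%); the V1 deprivation model encodes
## the ~20% population silencing observed 12 h after enucleation and the
## TNF-alpha-dependent amplitude scaling of network-correlated spines.

gratingsEpoch <- function(duration = 240, stimDur = 3, gapDur = 3)
    list(modality = "gratings", duration = duration,
         stimDur = stimDur, gapDur = gapDur)

sparseNoiseEpoch <- function(duration = 60, frameDur = 0.25,
                             nSquares = c(8, 12), squareSize = 8)
    list(modality = "sparse_noise", duration = duration, frameDur = frameDur,
         nSquares = nSquares, squareSize = squareSize)

auditoryEpoch <- function(duration = 180, burstDur = 0.5,
                          minInterval = 3, maxInterval = 5)
    list(modality = "auditory", duration = duration, burstDur = burstDur,
         minInterval = minInterval, maxInterval = maxInterval)

darkEpoch <- function(duration = 360)
    list(modality = "dark", duration = duration)

shamDeprivation <- function() list(
    paradigm = "sham", onsetHr = 0,
    inactivationProb = c(visual = 0, auditory = 0, network_only = 0,
                         unclassified = 0),
    reactivation = c("24" = 0, "48" = 0),
    ampScaling = list(
        visual = c("12" = 1, "24" = 1, "48" = 1),
        auditory = c("12" = 1, "24" = 1, "48" = 1),
        network_only = c("12" = 1, "24" = 1, "48" = 1),
        unclassified = c("12" = 1, "24" = 1, "48" = 1)),
    tnfBlocked = FALSE, removeEvoked = FALSE)

v1Deprivation <- function(tnfBlocked = FALSE) list(
    paradigm = "enucleation", onsetHr = 0,
    inactivationProb = c(visual = 0.35, auditory = 0, network_only = 0.17,
                         unclassified = 0.15),
    reactivation = c("24" = 0.5, "48" = 0.75),
    ampScaling = list(
        visual = c("12" = 1, "24" = 1, "48" = 1),
        auditory = c("12" = 1, "24" = 1, "48" = 1),
        network_only = c("12" = 1.1, "24" = 1.2, "48" = 1.3),
        unclassified = c("12" = 1, "24" = 1, "48" = 1)),
    tnfBlocked = tnfBlocked, removeEvoked = TRUE)

## RSC studies image twice at baseline (-1 and 0 hr) and once 48 hr after
## the (reversible) deprivation starts, so the onset sits just after 0 hr.
rscDeprivation <- function(paradigm, tnfBlocked = FALSE) list(
    paradigm = paradigm, onsetHr = 1,
    inactivationProb = c(visual = 0, auditory = 0, network_only = 0,
                         unclassified = 0),
    reactivation = c("48" = 0),
    ampScaling = list(
        visual = c("48" = 1),
        auditory = c("48" = 1),
        network_only = c("48" = 1.3),
        unclassified = c("48" = 1)),
    tnfBlocked = tnfBlocked, removeEvoked = FALSE)

v1Mixture <- c(visual = 0.24, auditory = 0, network_only = 0.65,
               unclassified = 0.11)
rscMixture <- c(visual = 0.187, auditory = 0.159, network_only = 0.574,
                unclassified = 0.08)

v1Layout <- function() list(gratingsEpoch(), sparseNoiseEpoch(), darkEpoch())
rscLayout <- function() list(gratingsEpoch(), auditoryEpoch(), darkEpoch())

presetTable <- function() list(
    "V1-baseline" = list(region = "V1", classMixture = v1Mixture,
        sessionLayout = v1Layout(), timepoints = -1,
        deprivation = shamDeprivation()),
    "V1-enucleation" = list(region = "V1", classMixture = v1Mixture,
        sessionLayout = v1Layout(), timepoints = c(-24, -1, 12, 24, 48),
        deprivation = v1Deprivation()),
    "V1-enucleation-TNF" = list(region = "V1", classMixture = v1Mixture,
        sessionLayout = v1Layout(), timepoints = c(-24, -1, 12, 24, 48),
        deprivation = v1Deprivation(tnfBlocked = TRUE)),
    "RSC-baseline" = list(region = "RSC", classMixture = rscMixture,
        sessionLayout = rscLayout(), timepoints = -1,
        deprivation = shamDeprivation()),
    "RSC-dark" = list(region = "RSC", classMixture = rscMixture,
        sessionLayout = rscLayout(), timepoints = c(-1, 0, 48),
        deprivation = rscDeprivation("dark_exposure")),
    "RSC-earplug" = list(region = "RSC", classMixture = rscMixture,
        sessionLayout = rscLayout(), timepoints = c(-1, 0, 48),
        deprivation = rscDeprivation("ear_plug")),
    "RSC-dark-TNF" = list(region = "RSC", classMixture = rscMixture,
        sessionLayout = rscLayout(), timepoints = c(-1, 0, 48),
        deprivation = rscDeprivation("dark_exposure", tnfBlocked = TRUE)),
    "sham" = list(region = "V1", classMixture = v1Mixture,
        sessionLayout = v1Layout(), timepoints = c(-24, -1, 12, 24, 48),
        deprivation = shamDeprivation())
)

#' Build a validated generator configuration
#'
#' Returns a fully populated [SpineSimConfig] for one of the named study
#' presets, optionally overriding any field. Identical
#' `(region, preset, overrides)` always yield an identical configuration.
#'
#' @param region imaged region, `"V1"` or `"RSC"`; must agree with the
#'   preset's region.
#' @param preset one of `"V1-baseline"`, `"V1-enucleation"`,
#'   `"V1-enucleation-TNF"`, `"RSC-baseline"`, `"RSC-dark"`,
#'   `"RSC-earplug"`, `"RSC-dark-TNF"`, `"sham"`.
#' @param overrides named list of field overrides (any slot of
#'   [SpineSimConfig]); invalid values raise a validity error naming
#'   the offending field.
#' @return a validated [SpineSimConfig]
#' @examples
#' cfg <- buildConfig("V1", "V1-baseline", list(nSpines = 50))
#' cfg
#' @export
buildConfig <- function(region = c("V1", "RSC"), preset,
                        overrides = list()) {
    region <- match.arg(region)
    presets <- presetTable()
    if (!preset %in% names(presets))
        stop("unknown preset '", preset, "'; valid presets: ",
             paste(names(presets), collapse = ", "))
    p <- presets[[preset]]
    if (!identical(p$region, region))
        stop("preset '", preset, "' is defined for region ", p$region,
             ", not ", region)
    defaults <- list(
        seed = 20221214L, nSpines = 500L, region = region,
        classMixture = p$classMixture, samplingRate = 15,
        sessionLayout = p$sessionLayout, timepoints = p$timepoints,
        backgroundRate = 0.113, stimResponseProb = 0.8,
        latencyJitter = 0.25, couplingWeight = 0.6, latentRate = 0.15,
        kernelRise = 0.18, kernelDecay = 1.8,
        eventAmpMean = 0.45, eventAmpCV = 0.3,
        noiseSd = 0.015, driftAmp = 0.2, driftPeriod = 120,
        evokedAmpFactor = 2, dendAmpFactor = 2, bapRate = 0.15,
        alphaRange = c(0.2, 0.8), snOverlap = 0.97, snTrialProb = 0.12,
        branchSizeRange = c(8, 15), deprivation = p$deprivation)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
        stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    fields <- defaults
    fields[names(overrides)] <- overrides
    fields$seed <- as.integer(fields$seed)
    fields$nSpines <- as.integer(fields$nSpines)
    do.call(new, c(list(Class = "SpineSimConfig"), fields))
}

sessionDuration <- function(config)
    sum(vapply(config@sessionLayout, function(e) e$duration, numeric(1)))

# Unit-peak difference-of-exponentials calcium transient kernel sampled
# on the imaging grid, with a smooth shoulder subtraction that brings the
# transient back to baseline in a few seconds: the ideal double
# exponential overstates the persistence of the indicator tail, whose
# late portion is indistinguishable from baseline noise in vivo and
# would otherwise contaminate low-percentile baseline estimates.
transientKernel <- function(config, shoulder = 0.12) {
    dt <- 1 / config@samplingRate
    tr <- config@kernelRise
    td <- config@kernelDecay
    tt <- seq(0, td * log(1e4), by = dt)
    k <- exp(-tt / td) - exp(-tt / tr)
    k <- k / max(k)
    k <- pmax(k - shoulder, 0) / (1 - shoulder)
    k[seq_len(max(which(k > 0)))]
}
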