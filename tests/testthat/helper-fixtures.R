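suppressPackageStartupMessages(library(SummarizedExperiment))

# Shared fixtures, built once per test run and cached. The large
# parameter-recovery fixtures used by the acceptance tests are expensive,
# so every block that needs one pulls it from here.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache)) {
        assign(name, builder(), envir = .fixtureCache)
    }
    get(name, envir = .fixtureCache)
}

# A small processed baseline session for unit-level checks.
smallV1Session <- function() cachedFixture("smallV1", function() {
    cfg <- buildConfig("V1", "V1-baseline", list(nSpines = 60, seed = 11L))
    se <- preprocessSession(simulateSession(cfg, -1))
    det <- detectSessionEvents(se)
    list(cfg = cfg, se = se, det = det)
})

# The canonical V1-baseline recovery fixture (full pipeline, n = 2000).
v1BaselineFixture <- function() cachedFixture("v1n2000", function() {
    cfg <- buildConfig("V1", "V1-baseline", list(nSpines = 2000L))
    se <- preprocessSession(simulateSession(cfg, -1))
    det <- detectSessionEvents(se)
    diag <- classifySession(se, det)
    list(summary = classifySummary(diag), diag = diag,
         truth = groundTruth(se),
         alphaErr = abs(rowData(se)$alphaHat[spineRows(se)] -
                        rowData(se)$trueAlpha[spineRows(se)]))
})

# The RSC-baseline recovery fixture (n = 2000).
rscBaselineFixture <- function() cachedFixture("rscn2000", function() {
    cfg <- buildConfig("RSC", "RSC-baseline", list(nSpines = 2000L))
    se <- preprocessSession(simulateSession(cfg, -1))
    det <- detectSessionEvents(se)
    diag <- classifySession(se, det)
    list(summary = classifySummary(diag), diag = diag,
         truth = groundTruth(se))
})

# Brute-force run-grouping oracle for event detection: mark supra-threshold
# samples, walk the trace, group consecutive marked samples.
bruteForceEvents <- function(trace, threshold, rate) {
    marked <- trace > threshold
    onsets <- integer(); offsets <- integer()
    inRun <- FALSE
    for (i in seq_along(marked)) {
        if (marked[i] && !inRun) { onsets <- c(onsets, i); inRun <- TRUE }
        if (!marked[i] && inRun) { offsets <- c(offsets, i - 1L); inRun <- FALSE }
    }
    if (inRun) offsets <- c(offsets, length(marked))
    data.frame(onset_s = (onsets - 1) / rate, offset_s = (offsets - 1) / rate)
}

# Random spiky test traces for detector property tests.
randomTrace <- function(n = 300) {
    x <- pmax(rnorm(n, 0, 0.1), 0)
    spikes <- sample(n, 5)
    x[spikes] <- x[spikes] + runif(5, 0.2, 1)
    stats::filter(c(x, 0, 0), rep(1 / 3, 3), sides = 1)[-(1:2)]
}
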