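#' Build the stimulus schedule for one session
#'
#' Lays out the configured epochs in order and draws the per-presentation
#' attributes: drifting-grating blocks (each block a random permutation of
#' the eight directions, 0 to 315 degrees in 45 degree steps), sparse-noise
#' frames (non-overlapping black/white squares on a grid, new frame every
#' 250 ms by default), auditory white-noise bursts with uniform
#' inter-burst intervals, and a stimulus-free dark epoch. The schedule is a
#' pure function of `(config, sessionIndex)`; the same stimulus paradigm
#' structure is used at every timepoint of a study.
#'
#' @param config a [SpineSimConfig]
#' @param sessionIndex 1-based session (timepoint) index; seeds the
#'   presentation-level randomness.
#' @return a [StimulusSchedule]
#' @examples
#' sch <- makeSchedule(buildConfig("V1", "V1-baseline"), 1)
#' head(sch@presentations)
#' @export
makeSchedule <- function(config, sessionIndex = 1L) {
    stopifnot(is(config, "SpineSimConfig"))
    withSeed(deriveSeed(config@seed, "schedule", sessionIndex), {
        start <- 0
        ep <- list(); pres <- list(); sparseFrames <- list()
        for (e in config@sessionLayout) {
            ep[[length(ep) + 1L]] <- data.frame(
                modality = e$modality, start = start, duration = e$duration)
            if (e$modality == "gratings") {
                cycle <- e$stimDur + e$gapDur
                nblocks <- floor(e$duration / (8 * cycle))
                dirs <- unlist(lapply(seq_len(nblocks),
                                      function(b) sample(seq(0, 315, by = 45))))
                onsets <- start + (seq_along(dirs) - 1) * cycle
                pres[[length(pres) + 1L]] <- data.frame(
                    modality = "gratings", onset = onsets,
                    duration = e$stimDur, direction = dirs)
            } else if (e$modality == "sparse_noise") {
                nframes <- floor(e$duration / e$frameDur)
                onsets <- start + (seq_len(nframes) - 1) * e$frameDur
                pres[[length(pres) + 1L]] <- data.frame(
                    modality = "sparse_noise", onset = onsets,
                    duration = e$frameDur, direction = NA_real_)
                grid <- expand.grid(
                    cx = seq(0, 96, by = e$squareSize),
                    cy = seq(0, 56, by = e$squareSize))
                sparseFrames <- c(sparseFrames, lapply(seq_len(nframes),
                    function(i) {
                        nsq <- sample(seq(e$nSquares[1], e$nSquares[2]), 1)
                        pick <- grid[sample.int(nrow(grid), nsq), ]
                        data.frame(cx = pick$cx, cy = pick$cy,
                                   size = e$squareSize,
                                   polarity = sample(c(-1, 1), nsq,
                                                     replace = TRUE))
                    }))
            } else if (e$modality == "auditory") {
                gaps <- runif(ceiling(e$duration / e$minInterval),
                              e$minInterval, e$maxInterval)
                onsets <- start + cumsum(gaps)
                onsets <- onsets[onsets + e$burstDur <= start + e$duration]
                pres[[length(pres) + 1L]] <- data.frame(
                    modality = "auditory", onset = onsets,
                    duration = e$burstDur, direction = NA_real_)
            }
            start <- start + e$duration
        }
        pres <- if (length(pres)) do.call(rbind, pres) else
            data.frame(modality = character(), onset = numeric(),
                       duration = numeric(), direction = numeric())
        new("StimulusSchedule", epochs = do.call(rbind, ep),
            presentations = pres, sparseFrames = sparseFrames)
    })
}

# Onsets of one modality's presentations.
presentationOnsets <- function(schedule, modality) {
    p <- schedule@presentations
    p$onset[p$modality == modality]
}

# Epoch window [start, end) for a modality (first match).
epochWindow <- function(schedule, modality) {
    e <- schedule@epochs
    i <- which(e$modality == modality)
    if (!length(i)) return(NULL)
    c(e$start[i[1]], e$start[i[1]] + e$duration[i[1]])
}
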