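#' @name spinescope-accessors
#' @title Accessors for SpineExperiment objects
#'
#' @description Convenience accessors: `spineRows()`/`dendriteRows()` give
#' row indices of spine/dendrite ROIs, `spineIds()` the spine identifiers,
#' `pairedDendrite()` the row index of each spine's dendrite ROI,
#' `stimulusSchedule()` the session's [StimulusSchedule], `simConfig()` the
#' generator configuration (synthetic sessions), `groundTruth()` the
#' per-spine ground-truth table, `samplingRate()` the frame rate in Hz and
#' `sessionTimepoint()` the session time in hours relative to deprivation.
#'
#' @param x a [SpineExperiment] object
#' @return see individual descriptions
NULL

#' @rdname spinescope-accessors
#' @export
setGeneric("spineRows", function(x) standardGeneric("spineRows"))
#' @rdname spinescope-accessors
#' @export
setGeneric("dendriteRows", function(x) standardGeneric("dendriteRows"))
#' @rdname spinescope-accessors
#' @export
setGeneric("spineIds", function(x) standardGeneric("spineIds"))
#' @rdname spinescope-accessors
#' @export
setGeneric("pairedDendrite", function(x) standardGeneric("pairedDendrite"))
#' @rdname spinescope-accessors
#' @export
setGeneric("stimulusSchedule", function(x) standardGeneric("stimulusSchedule"))
#' @rdname spinescope-accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @rdname spinescope-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname spinescope-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname spinescope-accessors
#' @export
setGeneric("sessionTimepoint", function(x) standardGeneric("sessionTimepoint"))

#' @rdname spinescope-accessors
setMethod("spineRows", "SpineExperiment", function(x)
    which(rowData(x)$roiType == "spine"))

#' @rdname spinescope-accessors
setMethod("dendriteRows", "SpineExperiment", function(x)
    which(rowData(x)$roiType == "dendrite"))

#' @rdname spinescope-accessors
setMethod("spineIds", "SpineExperiment", function(x)
    rowData(x)$spine[rowData(x)$roiType == "spine"])

#' @rdname spinescope-accessors
setMethod("pairedDendrite", "SpineExperiment", function(x) {
    rd <- rowData(x)
    sp <- which(rd$roiType == "spine")
    match(rd$pairedRoi[sp], rd$roi)
})

#' @rdname spinescope-accessors
setMethod("stimulusSchedule", "SpineExperiment", function(x)
    metadata(x)$schedule)

#' @rdname spinescope-accessors
setMethod("simConfig", "SpineExperiment", function(x) metadata(x)$config)

#' @rdname spinescope-accessors
setMethod("groundTruth", "SpineExperiment", function(x)
    metadata(x)$groundTruth)

#' @rdname spinescope-accessors
setMethod("samplingRate", "SpineExperiment", function(x)
    metadata(x)$samplingRate)

#' @rdname spinescope-accessors
setMethod("sessionTimepoint", "SpineExperiment", function(x)
    metadata(x)$timepoint)

setMethod("show", "SpineExperiment", function(object) {
    ns <- sum(rowData(object)$roiType == "spine")
    nd <- sum(rowData(object)$roiType == "dendrite")
    dur <- ncol(object) / metadata(object)$samplingRate
    cat("SpineExperiment:", ns, "spine +", nd, "dendrite ROIs,",
        ncol(object), sprintf("frames (%.0f s at %g Hz)\n", dur,
                              metadata(object)$samplingRate))
    tp <- metadata(object)$timepoint
    if (!is.null(tp)) cat("  timepoint:", tp, "hr\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    sch <- metadata(object)$schedule
    if (!is.null(sch))
        cat("  epochs:", paste(sch@epochs$modality, collapse = " > "), "\n")
    invisible(object)
})

setMethod("show", "SpineSimConfig", function(object) {
    mix <- object@classMixture
    cat("SpineSimConfig:", object@nSpines, "spines in", object@region,
        sprintf("(seed %d)\n", object@seed))
    cat("  mixture:", paste(sprintf("%s %.1f%%", names(mix), 100 * mix),
                            collapse = ", "), "\n")
    cat("  timepoints (hr):", paste(object@timepoints, collapse = ", "), "\n")
    cat("  deprivation:", object@deprivation$paradigm,
        if (isTRUE(object@deprivation$tnfBlocked)) "(TNF-alpha blocked)" else "",
        "\n")
    invisible(object)
})

setMethod("show", "StimulusSchedule", function(object) {
    cat("StimulusSchedule:",
        paste(sprintf("%s %.0fs", object@epochs$modality,
                      object@epochs$duration), collapse = " > "), "\n")
    cat("  presentations:", nrow(object@presentations), "\n")
    invisible(object)
})
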