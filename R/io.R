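## Session-bundle interchange: traces.csv (time_s + one column per ROI),
## rois.csv, schedule.json, ground_truth.csv, config.yaml.

configToList <- function(config) {
    out <- lapply(slotNames(config), function(s) slot(config, s))
    names(out) <- slotNames(config)
    # YAML drops names on atomic vectors; write named vectors as maps
    out$classMixture <- as.list(out$classMixture)
    dep <- out$deprivation
    dep$inactivationProb <- as.list(dep$inactivationProb)
    dep$reactivation <- as.list(dep$reactivation)
    dep$ampScaling <- lapply(dep$ampScaling, as.list)
    out$deprivation <- dep
    out
}

listToConfig <- function(lst) {
    lst$seed <- as.integer(lst$seed)
    lst$nSpines <- as.integer(lst$nSpines)
    lst$classMixture <- unlist(lst$classMixture)
    dep <- lst$deprivation
    dep$inactivationProb <- unlist(dep$inactivationProb)
    dep$reactivation <- unlist(dep$reactivation)
    dep$ampScaling <- lapply(dep$ampScaling, unlist)
    lst$deprivation <- dep
    do.call(new, c(list(Class = "SpineSimConfig"), lst))
}

scheduleToList <- function(schedule) {
    sf <- schedule@sparseFrames
    flat <- if (length(sf)) {
        do.call(rbind, lapply(seq_along(sf), function(i)
            cbind(frame = i, sf[[i]])))
    } else data.frame(frame = integer(), cx = numeric(), cy = numeric(),
                      size = numeric(), polarity = numeric())
    list(epochs = schedule@epochs,
         presentations = schedule@presentations,
         sparseFrames = flat)
}

listToSchedule <- function(lst) {
    pres <- as.data.frame(lst$presentations)
    if (!nrow(pres))
        pres <- data.frame(modality = character(), onset = numeric(),
                           duration = numeric(), direction = numeric())
    if (!"direction" %in% names(pres)) pres$direction <- NA_real_
    flat <- as.data.frame(lst$sparseFrames)
    frames <- if (nrow(flat))
        lapply(split(flat[, setdiff(names(flat), "frame")], flat$frame),
               function(x) { rownames(x) <- NULL; x })
    else list()
    new("StimulusSchedule", epochs = as.data.frame(lst$epochs),
        presentations = pres, sparseFrames = unname(frames))
}

#' Write a session bundle to disk
#'
#' Writes `traces.csv` (column `time_s`, then one column per ROI),
#' `rois.csv`, `schedule.json`, `config.yaml` and, for synthetic
#' sessions, `ground_truth.csv` and `true_events.csv`.
#'
#' @param x a [SpineExperiment]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeBundle <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mat <- assay(x, "fluor")
    tr <- data.table::data.table(time_s = colData(x)$time_s)
    for (i in seq_len(nrow(mat))) tr[[rownames(mat)[i]]] <- mat[i, ]
    data.table::fwrite(tr, file.path(dir, "traces.csv"))
    rd <- as.data.frame(rowData(x))
    sp <- rd[rd$roiType == "spine", ]
    rois <- data.frame(spine_id = sp$roi, dendrite_roi_id = sp$pairedRoi,
                       branch_id = sp$branch, position_index = sp$position,
                       region = sp$region)
    data.table::fwrite(rois, file.path(dir, "rois.csv"))
    sch <- stimulusSchedule(x)
    if (!is.null(sch))
        jsonlite::write_json(scheduleToList(sch),
                             file.path(dir, "schedule.json"),
                             dataframe = "columns", digits = NA)
    cfg <- simConfig(x)
    if (!is.null(cfg))
        yaml::write_yaml(configToList(cfg), file.path(dir, "config.yaml"))
    gt <- groundTruth(x)
    if (!is.null(gt))
        data.table::fwrite(gt, file.path(dir, "ground_truth.csv"))
    ev <- metadata(x)$trueEvents
    if (!is.null(ev))
        data.table::fwrite(ev, file.path(dir, "true_events.csv"))
    invisible(dir)
}

#' Read a session bundle from disk
#'
#' Counterpart of [writeBundle()]. `traces.csv`, `rois.csv` and
#' `schedule.json` are required; `config.yaml`, `ground_truth.csv` and
#' `true_events.csv` are restored when present.
#'
#' @param dir bundle directory
#' @param samplingRate frame rate (Hz); inferred from `config.yaml` or the
#'   time column when absent
#' @return a [SpineExperiment]
#' @export
readBundle <- function(dir, samplingRate = NULL) {
    need <- c("traces.csv", "rois.csv", "schedule.json")
    for (f in need)
        if (!file.exists(file.path(dir, f)))
            stop("bundle is missing required file: ", f)
    tr <- data.table::fread(file.path(dir, "traces.csv"))
    time_s <- tr$time_s
    mat <- t(as.matrix(tr[, -1]))
    rois <- data.table::fread(file.path(dir, "rois.csv"))
    sch <- listToSchedule(jsonlite::read_json(file.path(dir, "schedule.json"),
                                              simplifyVector = TRUE))
    cfg <- NULL
    if (file.exists(file.path(dir, "config.yaml")))
        cfg <- listToConfig(yaml::read_yaml(file.path(dir, "config.yaml")))
    if (is.null(samplingRate))
        samplingRate <- if (!is.null(cfg)) cfg@samplingRate else
            1 / median(diff(time_s))
    ord <- match(c(rois$spine_id, rois$dendrite_roi_id), rownames(mat))
    if (any(is.na(ord)))
        stop("rois.csv lists ROIs absent from traces.csv")
    mat <- mat[ord, , drop = FALSE]
    nsp <- nrow(rois)
    rd <- DataFrame(
        roi = rownames(mat),
        roiType = rep(c("spine", "dendrite"), each = nsp),
        spine = rep(rois$spine_id, 2),
        pairedRoi = c(rois$dendrite_roi_id, rois$spine_id),
        branch = rep(rois$branch_id, 2),
        position = rep(rois$position_index, 2),
        region = rep(rois$region, 2))
    epoch <- character(length(time_s))
    for (j in seq_len(nrow(sch@epochs)))
        epoch[time_s >= sch@epochs$start[j] &
              time_s < sch@epochs$start[j] + sch@epochs$duration[j]] <-
            sch@epochs$modality[j]
    se <- SummarizedExperiment(assays = list(fluor = mat), rowData = rd,
                               colData = DataFrame(time_s = time_s,
                                                   epoch = epoch,
                                                   stationary = TRUE))
    out <- new("SpineExperiment", se)
    md <- list(config = cfg, schedule = sch, samplingRate = samplingRate,
               timepoint = NA_real_)
    if (file.exists(file.path(dir, "ground_truth.csv")))
        md$groundTruth <- as.data.frame(
            data.table::fread(file.path(dir, "ground_truth.csv")))
    if (file.exists(file.path(dir, "true_events.csv")))
        md$trueEvents <- as.data.frame(
            data.table::fread(file.path(dir, "true_events.csv")))
    metadata(out) <- md
    out
}
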