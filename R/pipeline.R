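## End-to-end orchestration and the canonical parameter-recovery fixtures.

# Small polynomial rolling hash for the run manifest (stable across
# sessions; not cryptographic).
fnv1a <- function(s) {
    h <- 216613626
    for (b in utf8ToInt(s))
        h <- (h * 131 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Run the full pipeline on a study
#'
#' Executes preprocessing, event detection, baseline classification and the
#' longitudinal analyses for a study, writing all stage outputs and a run
#' manifest. The study is either simulated from a [SpineSimConfig] or read
#' from a session bundle directory ([readBundle()]).
#'
#' @param config a [SpineSimConfig] (exclusive with `bundleDir`)
#' @param bundleDir a bundle directory holding a single session
#' @param outDir output directory
#' @param netMethod network-correlation p-value method, see
#'   [classifySession()]
#' @param writeBundles also write each simulated session as a bundle
#' @return invisibly, a list with `sessions` (preprocessed), `detections`,
#'   `classes`, `longitudinal`, `summary`
#' @export
runPipeline <- function(config = NULL, bundleDir = NULL, outDir,
                        netMethod = "shift", writeBundles = FALSE) {
    if (is.null(config) == is.null(bundleDir))
        stop("give exactly one of config or bundleDir")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bundleDir)) {
        ses <- list(readBundle(bundleDir))
        names(ses) <- "0"
        config <- simConfig(ses[[1]])
    } else {
        ses <- simulateStudy(config)
        names(ses) <- as.character(config@timepoints)
    }
    detections <- list(); metricsList <- list()
    alphas <- NULL
    for (tp in names(ses)) {
        ses[[tp]] <- preprocessSession(ses[[tp]])
        det <- detectSessionEvents(ses[[tp]])
        detections[[tp]] <- det
        metricsList[[tp]] <- det$metrics
        ev <- det$events
        if (nrow(ev)) ev$timepoint_hr <- as.numeric(tp)
        data.table::fwrite(ev, file.path(outDir,
                                         paste0("events_", tp, "hr.csv")))
        rdx <- rowData(ses[[tp]])
        al <- data.frame(spine_id = rdx$roi[rdx$roiType == "spine"],
                         alpha = rdx$alphaHat[rdx$roiType == "spine"],
                         n_iter = rdx$alphaIter[rdx$roiType == "spine"],
                         converged = rdx$alphaConverged[rdx$roiType == "spine"],
                         timepoint_hr = as.numeric(tp))
        alphas <- rbind(alphas, al)
        if (writeBundles)
            writeBundle(ses[[tp]], file.path(outDir, paste0("bundle_", tp)))
    }
    data.table::fwrite(alphas, file.path(outDir, "alpha.csv"))
    allMetrics <- data.table::rbindlist(metricsList, idcol = "timepoint_hr")
    data.table::fwrite(allMetrics, file.path(outDir, "metrics.csv"))
    # classify on the latest pre-deprivation session
    tps <- as.numeric(names(ses))
    pre <- tps[tps < config@deprivation$onsetHr]
    baseTp <- as.character(if (length(pre)) max(pre) else tps[1])
    diag <- classifySession(ses[[baseTp]], detections[[baseTp]],
                            netMethod = netMethod)
    data.table::fwrite(diag, file.path(outDir, "classes.csv"))
    summ <- classifySummary(diag)
    labels <- setNames(diag$label, diag$spine)
    longTab <- alignLongitudinal(metricsList, labels)
    data.table::fwrite(longTab, file.path(outDir, "longitudinal.csv"))
    if (length(ses) > 1) {
        gc <- groupChangeTable(longTab)
        data.table::fwrite(gc, file.path(outDir, "group_changes.csv"))
    }
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
        package = as.character(utils::packageVersion("spinescope")),
        configHash = fnv1a(yaml::as.yaml(configToList(config))),
        seed = config@seed,
        sessions = names(ses),
        rows = list(classes = nrow(diag), metrics = nrow(allMetrics),
                    longitudinal = nrow(longTab)),
        classifiedAt = baseTp)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(sessions = ses, detections = detections, classes = diag,
                   longitudinal = longTab, summary = summ))
}

processedBaseline <- function(config) {
    se <- simulateSession(config, config@timepoints[1])
    se <- preprocessSession(se)
    det <- detectSessionEvents(se)
    list(se = se, det = det,
         diag = classifySession(se, det))
}

#' Canonical fixture quantities
#'
#' Recomputes, from freshly simulated fixtures, the population quantities
#' used for parameter-recovery validation: baseline class percentages and
#' network-significance rates in V1 and RSC, the dummy-stimulus
#' false-positive mean, the post-deprivation inactive fraction and the
#' sparse-noise/gratings responder overlap. Each quantity is computed by
#' the full pipeline (simulate, preprocess, detect, classify, summarize).
#'
#' @param seed integer seed for the fixture configurations
#' @param which character vector of quantity ids (`"t1"` ... `"t12"`),
#'   or `"all"`
#' @param nV1,nRSC,nOverlap fixture sizes
#' @return named list of lists with `value` and `n`
#' @export
fixtureQuantities <- function(seed = 20221214L, which = "all",
                              nV1 = 2000L, nRSC = 2000L, nOverlap = 1000L) {
    ids <- paste0("t", 1:12)
    if (identical(which, "all")) which <- ids
    bad <- setdiff(which, ids)
    if (length(bad))
        stop("unknown target id(s): ", paste(bad, collapse = ", "),
             "; valid ids: ", paste(ids, collapse = ", "))
    out <- list()
    if (any(c("t1", "t2", "t3", "t4") %in% which)) {
        cfg <- buildConfig("V1", "V1-baseline",
                           list(seed = seed, nSpines = nV1))
        pb <- processedBaseline(cfg)
        s <- classifySummary(pb$diag)
        out$t1 <- list(value = unname(s$pct["visually_responsive"]), n = nV1)
        out$t2 <- list(value = unname(s$pct["network_correlated"]), n = nV1)
        out$t3 <- list(value = unname(s$pct["unclassified"]), n = nV1)
        out$t4 <- list(value = s$pctNetworkSignificant, n = nV1)
        rm(pb); gc(FALSE)
    }
    if ("t5" %in% which) {
        out$t5 <- list(value = dummyFalsePositiveMean(seed, n = 2000L),
                       n = 2000L)
    }
    if ("t6" %in% which) {
        cfg <- buildConfig("V1", "V1-enucleation",
                           list(seed = seed, nSpines = nV1))
        plan <- studyPlan(cfg)
        metricsList <- list()
        for (tp in cfg@timepoints) {
            se <- simulateSession(cfg, tp, plan)
            se <- preprocessSession(se)
            metricsList[[as.character(tp)]] <-
                detectSessionEvents(se)$metrics
            rm(se); gc(FALSE)
        }
        longTab <- alignLongitudinal(metricsList)
        out$t6 <- list(value = inactiveFraction(longTab, 12), n = nV1)
    }
    if (any(c("t7", "t8", "t9", "t10", "t12") %in% which)) {
        cfg <- buildConfig("RSC", "RSC-baseline",
                           list(seed = seed, nSpines = nRSC))
        pb <- processedBaseline(cfg)
        s <- classifySummary(pb$diag)
        out$t7 <- list(value = unname(s$pct["visually_responsive"]), n = nRSC)
        out$t8 <- list(value = unname(s$pct["auditory_responsive"]), n = nRSC)
        out$t9 <- list(value = unname(s$pct["network_correlated"]), n = nRSC)
        out$t10 <- list(value = s$pctNetworkSignificant, n = nRSC)
        out$t12 <- list(value = unname(s$pct["unclassified"]), n = nRSC)
        rm(pb); gc(FALSE)
    }
    if ("t11" %in% which) {
        cfg <- buildConfig("V1", "V1-baseline",
                           list(seed = seed, nSpines = nOverlap))
        pb <- processedBaseline(cfg)
        d <- pb$diag
        gratResp <- !is.na(d$rVis) & d$rVis > 0 & d$pVis < 0.05 &
            d$aboveChanceVis
        sn <- d$sparseResponsive %in% TRUE
        out$t11 <- list(value = 100 * sum(sn & gratResp) / sum(sn),
                        n = nOverlap)
        rm(pb); gc(FALSE)
    }
    out[intersect(ids, which)]
}

# Population mean of the dummy-stimulus time-locked false-positive rate on
# background-only spines: 360 s dark epoch, Poisson background events at
# the configured rate, dummy track of 80 onsets with a 0.5 s window.
dummyFalsePositiveMean <- function(seed, n = 2000L, nOnsets = 80L) {
    cfg <- buildConfig("V1", "V1-baseline", list(
        seed = seed, nSpines = n,
        classMixture = c(visual = 0, auditory = 0, network_only = 0,
                         unclassified = 1),
        sessionLayout = list(darkEpoch(360)), timepoints = -1))
    se <- simulateSession(cfg, -1)
    se <- preprocessSession(se)
    det <- detectSessionEvents(se)
    dur <- 360
    ioi <- dur / nOnsets
    phase <- withSeed(deriveSeed(seed, "dummy", 999L), runif(1, 0, ioi - 0.5))
    dummy <- phase + (seq_len(nOnsets) - 1) * ioi
    onsetsBy <- split(det$events$onset_s,
                      factor(det$events$spine, levels = spineIds(se)))
    fp <- vapply(onsetsBy, falsePositiveThreshold, numeric(1),
                 dummyOnsets = dummy)
    mean(fp)
}

#' Recompute the canonical fixture quantities and compare with the
#' published population values
#'
#' Runs [fixtureQuantities()] for the requested ids and reports each
#' computed value against the corresponding published population quantity
#' at a 10% relative tolerance (the fixtures are stochastic).
#'
#' @inheritParams fixtureQuantities
#' @return data.frame: `id`, `description`, `computed`, `expected`,
#'   `tolerance`, `pass`
#' @export
reproduceTargets <- function(which = "all", seed = 20221214L) {
    expected <- c(t1 = 24, t2 = 65, t3 = 11, t4 = 89, t5 = 5.5, t6 = 20,
                  t7 = 18.7, t8 = 15.9, t9 = 57.4, t10 = 92, t11 = 97,
                  t12 = 8)
    descr <- c(
        t1 = "V1 visually responsive (%)",
        t2 = "V1 network-correlated (%)",
        t3 = "V1 unclassified (%)",
        t4 = "V1 network-significant (%)",
        t5 = "dummy-stimulus false-positive mean (%)",
        t6 = "inactive 12 h after enucleation (%)",
        t7 = "RSC visually responsive (%)",
        t8 = "RSC auditory responsive (%)",
        t9 = "RSC network-only (%)",
        t10 = "RSC network-significant (%)",
        t11 = "sparse-noise/gratings responder overlap (%)",
        t12 = "RSC unclassified (%)")
    q <- fixtureQuantities(seed = seed, which = which)
    ids <- names(q)
    comp <- vapply(q, function(x) x$value, numeric(1))
    tol <- pmax(0.1 * expected[ids], 2)
    data.frame(id = ids, description = unname(descr[ids]),
               computed = unname(comp), expected = unname(expected[ids]),
               tolerance = unname(tol),
               pass = unname(abs(comp - expected[ids]) <= tol))
}
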