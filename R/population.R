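#' Align per-session metrics into a longitudinal table
#'
#' Joins per-spine session metrics across timepoints, attaches the
#' baseline functional label (fixed; classification is done on baseline
#' sessions only), and flags inclusion (active in at least one timepoint)
#' and persistence (active at every timepoint).
#'
#' @param metricsList named list of per-spine metric tables (one per
#'   timepoint, names like `"-24"`, `"12"`; each a [detectSessionEvents()]
#'   `metrics` table)
#' @param labels optional named character vector of baseline labels
#'   (names = spine ids)
#' @return data.frame keyed by (`spine`, `timepoint_hr`) with metric
#'   columns plus `label`, `included`, `persistent`
#' @export
alignLongitudinal <- function(metricsList, labels = NULL) {
    tps <- names(metricsList)
    rows <- lapply(tps, function(tp) {
        m <- metricsList[[tp]]
        m$timepoint_hr <- as.numeric(tp)
        m
    })
    tab <- as.data.frame(data.table::rbindlist(rows))
    ids <- unique(tab$spine)
    if (!all(vapply(metricsList, function(m)
        setequal(m$spine, ids), logical(1))))
        stop("all sessions must contain the same spine ids")
    act <- tapply(tab$active, tab$spine, function(a)
        c(any = any(a), all = all(a)))
    included <- vapply(act, `[[`, logical(1), "any")
    persistent <- vapply(act, `[[`, logical(1), "all")
    tab$included <- included[tab$spine]
    tab$persistent <- persistent[tab$spine]
    tab$label <- if (is.null(labels)) NA_character_ else
        unname(labels[tab$spine])
    tab[tab$included, , drop = FALSE]
}

#' Baseline-normalized percent change of a metric
#'
#' `100 * (value_t - mean(baseline)) / mean(baseline)`; by construction
#' the baseline mean maps to 0%.
#'
#' @param values metric values, one per timepoint
#' @param timepoints timepoints (hr) matching `values`
#' @param baseline the baseline timepoints (default all negative ones)
#' @return percent change per timepoint; `NA` (flagged by attribute
#'   `"omitted"`) when the baseline mean is missing or nonpositive
#' @export
normalizedPctChange <- function(values, timepoints,
                                baseline = timepoints[timepoints < 0]) {
    b <- values[timepoints %in% baseline]
    bm <- mean(b[is.finite(b)])
    if (!is.finite(bm) || bm <= 0) {
        out <- rep(NA_real_, length(values))
        attr(out, "omitted") <- TRUE
        return(out)
    }
    100 * (values - bm) / bm
}

#' Fraction of included spines inactive at a timepoint
#'
#' @param longTab [alignLongitudinal()] table
#' @param timepoint timepoint in hours
#' @param classFilter optional baseline label to restrict to
#' @return percentage of included spines with no supra-threshold event
#' @export
inactiveFraction <- function(longTab, timepoint, classFilter = NULL) {
    t0 <- longTab[longTab$timepoint_hr == timepoint, ]
    if (!is.null(classFilter)) t0 <- t0[t0$label %in% classFilter, ]
    if (!nrow(t0)) return(NA_real_)
    100 * mean(!t0$active)
}

#' Per-class group change table
#'
#' Baseline-normalized percent change of one metric, averaged over spines
#' within each baseline class at each post-baseline timepoint.
#'
#' @param longTab [alignLongitudinal()] table with labels
#' @param metric column name (`"meanAmplitude"`, `"frequency"`,
#'   `"integral"`)
#' @param persistentOnly restrict to persistent spines (default TRUE, as
#'   for amplitude trajectories)
#' @return data.frame: `label`, `timepoint_hr`, `meanChange`, `sem`, `n`
#' @export
groupChangeTable <- function(longTab, metric = "meanAmplitude",
                             persistentOnly = TRUE) {
    tab <- if (persistentOnly) longTab[longTab$persistent, ] else longTab
    tps <- sort(unique(tab$timepoint_hr))
    out <- list()
    for (lab in unique(tab$label)) {
        sub <- tab[tab$label %in% lab, ]
        ch <- lapply(split(sub, sub$spine), function(s) {
            s <- s[order(s$timepoint_hr), ]
            normalizedPctChange(s[[metric]], s$timepoint_hr)
        })
        chm <- do.call(rbind, ch)
        for (j in seq_along(tps)) {
            v <- chm[, j]
            v <- v[is.finite(v)]
            out[[length(out) + 1L]] <- data.frame(
                label = lab, timepoint_hr = tps[j],
                meanChange = mean(v), sem = sd(v) / sqrt(length(v)),
                n = length(v))
        }
    }
    do.call(rbind, out)
}

#' Spatial clustering of functional classes along dendritic branches
#'
#' For each inter-spine distance `n` (positions along a branch), the
#' observed probability that a spine `n` positions away from a reference
#' spine matches its functional class (over all ordered pairs within
#' branches), compared with a null built by shuffling spine positions
#' within each branch.
#'
#' @param branch integer branch id per spine
#' @param position integer position along the branch per spine
#' @param labels functional class per spine
#' @param nShuffles number of position shuffles (default 1000)
#' @param seed RNG seed for the shuffles
#' @param maxDistanceQuantile distances above this quantile of branch
#'   lengths are suppressed as unstable (default 0.9)
#' @return data.frame: `distance`, `observed`, `shuffleMean`, `lo`, `hi`
#'   (2.5/97.5 shuffle percentiles), `nPairs`
#' @export
clusteringCurve <- function(branch, position, labels, nShuffles = 1000L,
                            seed = 1L, maxDistanceQuantile = 0.9) {
    stopifnot(length(branch) == length(position),
              length(branch) == length(labels))
    byBranch <- split(seq_along(branch), branch)
    sizes <- lengths(byBranch)
    if (all(sizes < 2)) stop("need at least one branch with 2 spines")
    maxd <- floor(quantile(sizes, maxDistanceQuantile)) - 1
    dists <- seq_len(max(1, maxd))
    matchAt <- function(lab) {
        sums <- numeric(length(dists)); cnts <- numeric(length(dists))
        for (idx in byBranch) {
            lb <- lab[idx][order(position[idx])]
            m <- length(lb)
            for (d in dists) {
                if (m <= d) next
                eq <- lb[seq_len(m - d)] == lb[seq_len(m - d) + d]
                sums[d] <- sums[d] + 2 * sum(eq)   # ordered pairs, both ways
                cnts[d] <- cnts[d] + 2 * (m - d)
            }
        }
        list(p = ifelse(cnts > 0, sums / cnts, NA_real_), n = cnts)
    }
    obs <- matchAt(labels)
    sh <- withSeed(deriveSeed(seed, "shuffle"), {
        vapply(seq_len(nShuffles), function(s) {
            lab2 <- labels
            for (idx in byBranch) lab2[idx] <- lab2[sample(idx)]
            matchAt(lab2)$p
        }, numeric(length(dists)))
    })
    sh <- matrix(sh, nrow = length(dists))
    data.frame(distance = dists, observed = obs$p,
               shuffleMean = rowMeans(sh, na.rm = TRUE),
               lo = apply(sh, 1, quantile, 0.025, na.rm = TRUE),
               hi = apply(sh, 1, quantile, 0.975, na.rm = TRUE),
               nPairs = obs$n)
}

#' Within-spine frequency/amplitude coupling
#'
#' Correlates the baseline-normalized change in event frequency at one
#' timepoint (12 h) with the normalized change in amplitude at a later
#' one (48 h) across persistent spines. Pearson when both changes pass a
#' Shapiro-Wilk normality check, Spearman otherwise; the method used is
#' recorded.
#'
#' @param longTab [alignLongitudinal()] table
#' @param freqTimepoint,ampTimepoint timepoints (hr) for the frequency and
#'   amplitude changes
#' @param classFilter optional baseline label filter
#' @return list: `r`, `p`, `method`, `n`
#' @export
freqAmpCoupling <- function(longTab, freqTimepoint = 12,
                            ampTimepoint = 48, classFilter = NULL) {
    tab <- longTab[longTab$persistent, ]
    if (!is.null(classFilter)) tab <- tab[tab$label %in% classFilter, ]
    per <- lapply(split(tab, tab$spine), function(s) {
        s <- s[order(s$timepoint_hr), ]
        df <- normalizedPctChange(s$frequency, s$timepoint_hr)
        da <- normalizedPctChange(s$meanAmplitude, s$timepoint_hr)
        c(df[s$timepoint_hr == freqTimepoint],
          da[s$timepoint_hr == ampTimepoint])
    })
    per <- do.call(rbind, per)
    per <- per[complete.cases(per), , drop = FALSE]
    if (nrow(per) < 4) stop("need at least 4 persistent spines")
    normal <- function(v) {
        v <- v[is.finite(v)]
        if (length(v) > 5000) v <- v[seq_len(5000)]
        length(unique(v)) > 2 && shapiro.test(v)$p.value > 0.05
    }
    method <- if (normal(per[, 1]) && normal(per[, 2])) "pearson" else
        "spearman"
    ct <- suppressWarnings(cor.test(per[, 1], per[, 2], method = method))
    list(r = unname(ct$estimate), p = ct$p.value, method = method,
         n = nrow(per))
}

#' Orientation selectivity index
#'
#' Folds the eight direction responses into four orientations (averaging
#' opposite directions); OSI = (R_pref - R_orth) / (R_pref + R_orth),
#' where R_pref is the largest orientation response and R_orth the
#' response at the orthogonal orientation. Invariant under uniform
#' scaling of the responses.
#'
#' @param directionMeans named numeric of mean evoked amplitudes for the
#'   8 directions (names: degrees, 0 to 315 in 45 steps)
#' @return OSI in `[0, 1]`, `NA` (flagged) when all responses are zero
#' @export
osi <- function(directionMeans) {
    stopifnot(length(directionMeans) == 8)
    if (any(directionMeans < 0)) stop("direction responses must be >= 0")
    if (all(directionMeans == 0)) {
        out <- NA_real_
        attr(out, "undefined") <- TRUE
        return(out)
    }
    dirs <- as.numeric(names(directionMeans))
    if (is.null(names(directionMeans)) || any(is.na(dirs)))
        dirs <- seq(0, 315, by = 45)
    ori <- tapply(directionMeans, dirs %% 180, mean)
    pref <- which.max(ori)
    orthDeg <- (as.numeric(names(ori))[pref] + 90) %% 180
    orth <- ori[as.character(orthDeg)]
    unname((ori[pref] - orth) / (ori[pref] + orth))
}

#' Global dendritic response analysis
#'
#' Quantifies each branch's global (dendritic) evoked response as the mean
#' event area within stimulus windows on the dendrite ROI dF/F trace,
#' computes its baseline-normalized change across timepoints, and
#' correlates the per-branch change with the mean change of each
#' functional spine class on that branch.
#'
#' @param sessions named list of preprocessed [SpineExperiment] objects
#'   (names = timepoints in hours)
#' @param labels named character vector of baseline spine labels
#' @param longTab [alignLongitudinal()] table for the same study
#' @param modality stimulus modality defining the evoked windows
#' @param changeTimepoint timepoint (hr) at which changes are compared
#' @return list: `branchChange` (per-branch normalized change),
#'   `correlations` (per class: `r`, `p`, `n`)
#' @export
globalDendriteAnalysis <- function(sessions, labels, longTab,
                                   modality = "gratings",
                                   changeTimepoint = 48) {
    tps <- as.numeric(names(sessions))
    branchAmp <- lapply(sessions, function(se) {
        rate <- metadata(se)$samplingRate
        sch <- stimulusSchedule(se)
        on <- presentationOnsets(sch, modality)
        pr <- sch@presentations
        dur <- unique(pr$duration[pr$modality == modality])[1]
        dn <- dendriteRows(se)
        dff <- assay(se, "dff")[dn, , drop = FALSE]
        branches <- rowData(se)$branch[dn]
        amps <- vapply(seq_along(dn), function(k) {
            tr <- causalBoxcar(dff[k, ], max(1L, round(0.2 * rate)))
            thr <- eventThreshold(tr, "mad")
            ev <- detectEvents(tr, thr, rate)
            if (!nrow(ev)) return(0)
            inWin <- vapply(ev$onset_s, function(t0)
                any(t0 >= on & t0 <= on + dur + 0.5), logical(1))
            if (!any(inWin)) 0 else mean(ev$amplitude[inWin])
        }, numeric(1))
        tapply(amps, branches, mean)
    })
    branchIds <- names(branchAmp[[1]])
    ampMat <- do.call(cbind, branchAmp)
    branchChange <- apply(ampMat, 1, function(v)
        normalizedPctChange(v, tps)[tps == changeTimepoint])
    # per-branch mean spine change by class
    sp0 <- sessions[[1]]
    spBranch <- setNames(rowData(sp0)$branch[spineRows(sp0)],
                         rowData(sp0)$roi[spineRows(sp0)])
    spineChange <- vapply(split(longTab, longTab$spine), function(s) {
        s <- s[order(s$timepoint_hr), ]
        normalizedPctChange(s$meanAmplitude,
                            s$timepoint_hr)[s$timepoint_hr == changeTimepoint]
    }, numeric(1))
    classes <- c(visually_responsive = "visually_responsive",
                 auditory_responsive = "auditory_responsive",
                 network_correlated = "network_correlated")
    correlations <- lapply(classes, function(cl) {
        ids <- names(labels)[labels == cl]
        ids <- intersect(ids, names(spineChange))
        if (!length(ids)) return(list(r = NA_real_, p = NA_real_, n = 0L))
        perBranch <- tapply(spineChange[ids], spBranch[ids],
                            mean, na.rm = TRUE)
        common <- intersect(names(perBranch), branchIds)
        ok <- common[is.finite(perBranch[common]) &
                     is.finite(branchChange[common])]
        if (length(ok) < 4) return(list(r = NA_real_, p = NA_real_,
                                        n = length(ok)))
        ct <- cor.test(branchChange[ok], perBranch[ok])
        list(r = unname(ct$estimate), p = ct$p.value, n = length(ok))
    })
    list(branchChange = branchChange, correlations = correlations)
}
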