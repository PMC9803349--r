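test_that("stimulus binarization covers exactly the presentation windows", {
    cfg <- buildConfig("V1", "V1-baseline", list(seed = 4L))
    sch <- makeSchedule(cfg, 1)
    time_s <- seq(0, spinescope:::sessionDuration(cfg) - 1e-9, by = 1 / 15)
    vis <- binarizeStimulus(sch, "gratings", time_s)
    expect_equal(length(vis), length(time_s))
    gr <- sch@presentations[sch@presentations$modality == "gratings", ]
    expect_equal(sum(vis) / 15, sum(gr$duration), tolerance = 0.01)
    dk <- spinescope:::epochWindow(sch, "dark")
    expect_true(all(vis[time_s >= dk[1]] == 0))
})

test_that("stimulus correlation flags identical and degenerate tracks", {
    track <- rep(c(0, 1), each = 50)
    ct <- stimCorrelation(as.numeric(track), track)
    expect_equal(ct$r, 1)
    expect_lt(ct$p, 1e-10)
    expect_error(stimCorrelation(rnorm(100), rep(1, 100)), "constant")
    expect_error(stimCorrelation(rnorm(50), track), "length")
})

test_that("time-locked percentage counts onset windows correctly", {
    pres <- c(10, 20, 30, 40)
    expect_equal(timelockedPct(pres + 0.2, pres), 100)
    expect_equal(timelockedPct(numeric(0), pres), 0)
    expect_equal(timelockedPct(c(10.4, 35), pres), 25)  # only first hits
    expect_error(timelockedPct(1, numeric(0)), "presentation")
})

test_that("time-locking of Poisson events matches the analytic rate", {
    # events at rate lambda hit a 0.5 s window with prob 1 - exp(-lambda/2)
    set.seed(8)
    lambda <- 0.113
    pres <- seq(5, 355, by = 4.5)
    hits <- replicate(400, {
        ev <- sort(runif(rpois(1, lambda * 360), 0, 360))
        timelockedPct(ev, pres) / 100
    })
    p <- mean(hits)
    expected <- 1 - exp(-lambda * 0.5)
    se3 <- 3 * sqrt(expected * (1 - expected) / (400 * length(pres)))
    expect_lt(abs(p - expected), se3)
})

test_that("the dummy-stimulus threshold averages layouts and needs onsets", {
    expect_equal(falsePositiveThreshold(numeric(0), list(c(1, 2, 3))), 0)
    expect_equal(falsePositiveThreshold(c(1.1), list(c(1, 5), c(1, 9, 13))),
                 mean(c(50, 100 / 3)))
    expect_error(falsePositiveThreshold(1, list()), "dummy")
})

test_that("network signal is the leave-one-out mean", {
    m <- matrix(rnorm(5 * 100), 5)
    ref <- networkSignal(m, 2)
    expect_equal(ref, colMeans(m[-2, ]))
    same <- matrix(rep(m[1, ], 4), 4, byrow = TRUE)
    expect_equal(networkSignal(same, 1), m[1, ])
    expect_error(networkSignal(m[1:2, ], 1), "3 spines")
})

test_that("network correlation respects sign and permutation null size", {
    set.seed(3)
    x <- as.numeric(stats::filter(rnorm(2000), rep(0.4, 5), sides = 1,
                                  method = "convolution"))
    x[is.na(x)] <- 0
    nc <- networkCorrelation(x, x, method = "shift")
    expect_equal(nc$r, 1)
    expect_lt(nc$p, 0.01)
    ncNeg <- networkCorrelation(x, -x, method = "shift")
    expect_equal(ncNeg$r, -1)
    # independent autocorrelated traces: r > 0 & p < 0.05 at ~2.5% rate,
    # where the parametric test is badly anticonservative
    sig <- replicate(300, {
        a <- as.numeric(stats::filter(rnorm(800), rep(1, 8), sides = 1))
        b <- as.numeric(stats::filter(rnorm(800), rep(1, 8), sides = 1))
        a[is.na(a)] <- 0; b[is.na(b)] <- 0
        nc <- networkCorrelation(a, b, method = "shift", rate = 15)
        nc$r > 0 && nc$p < 0.05
    })
    expect_lt(mean(sig), 0.06)
})

test_that("sparse-noise responsiveness finds injected trials only", {
    rate <- 15
    cfg <- buildConfig("V1", "V1-baseline", list(seed = 6L))
    sch <- makeSchedule(cfg, 1)
    on <- spinescope:::presentationOnsets(sch, "sparse_noise")
    n <- round(spinescope:::sessionDuration(cfg) * rate)
    tt <- (seq_len(n) - 1) / rate
    set.seed(31)
    noise <- rnorm(n, 0, 0.015)
    expect_false(sparseNoiseResponsive(noise, sch, rate)$responsive)
    # inject kernel responses on 30 known, well-separated trials,
    # amplitude >> noise
    resp <- seq(1, 233, by = 8)
    tr <- noise
    for (t0 in on[resp]) {
        idx <- which(tt >= t0 & tt < t0 + 3)
        tr[idx] <- tr[idx] + 0.5 *
            (exp(-(tt[idx] - t0) / 1.8) - exp(-(tt[idx] - t0) / 0.18)) / 0.697
    }
    res <- sparseNoiseResponsive(tr, sch, rate)
    expect_true(res$responsive)
    expect_gte(sum(res$trialFlags[resp]), 28)
    # trials riding the steep early decay of an injected transient can be
    # genuine derivative outliers; they must stay a small minority
    expect_lte(sum(res$trialFlags[-resp]), 20)
    expect_gt(mean(res$trialFlags[resp]), 5 * mean(res$trialFlags[-resp]))
    # too few trials is an error
    shortSch <- sch
    shortSch@presentations <-
        sch@presentations[sch@presentations$modality != "sparse_noise" |
                          sch@presentations$onset < 250, ]
    expect_error(sparseNoiseResponsive(tr, shortSch, rate), "insufficient")
})

test_that("behavioral regressor hook mirrors the correlation contract", {
    x <- rnorm(500)
    expect_equal(behavioralRegressorCorrelation(x, x)$r, 1)
    expect_error(behavioralRegressorCorrelation(x, rep(2, 500)),
                 "degenerate")
    set.seed(9)
    sig <- replicate(400,
        behavioralRegressorCorrelation(rnorm(200), rnorm(200))$p < 0.05)
    expect_lt(abs(mean(sig) - 0.05), 0.03)
})

test_that("classification follows the decision order and exclusion rule", {
    d <- data.frame(
        spine = c("a", "b", "c", "d"),
        rVis = c(0.2, 0.01, -0.1, 0.05),
        pVis = c(1e-6, 0.8, 0.001, 0.2),
        aboveChanceVis = c(TRUE, FALSE, FALSE, TRUE),
        sparseResponsive = c(FALSE, FALSE, FALSE, FALSE),
        rNet = c(0.3, 0.25, 0.0, 0.4),
        pNet = c(1e-4, 1e-3, 0.7, 1e-5))
    lab <- classifySpine(d, region = "V1")
    # a: stimulus-correlated and time-locked above chance
    expect_equal(lab[1], "visually_responsive")
    # b: network-significant, time-locked at chance
    expect_equal(lab[2], "network_correlated")
    # c: nothing significant
    expect_equal(lab[3], "unclassified")
    # d: network-significant, above-chance time-locking but no significant
    # stimulus correlation: excluded from further analysis
    expect_equal(lab[4], "excluded")
    # sparse-noise responsiveness alone is sufficient for the visual class
    d$sparseResponsive[3] <- TRUE
    expect_equal(classifySpine(d, "V1")[3], "visually_responsive")
})

test_that("labels partition the population", {
    sm <- smallV1Session()
    diag <- classifySession(sm$se, sm$det)
    expect_equal(nrow(diag), 60)
    expect_true(all(diag$label %in%
        c("visually_responsive", "auditory_responsive",
          "network_correlated", "unclassified", "excluded")))
    s <- classifySummary(diag)
    expect_equal(unname(sum(s$pct)), 100, tolerance = 1e-9)
    expect_equal(s$n + s$nExcluded, 60)
})
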