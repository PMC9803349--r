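test_that("configuration validation enforces the study invariants", {
    cfg <- buildConfig("V1", "V1-baseline")
    expect_s4_class(cfg, "SpineSimConfig")
    expect_equal(sum(cfg@classMixture), 1)
    expect_equal(unname(cfg@classMixture["auditory"]), 0)

    expect_error(buildConfig("V1", "nope"), "unknown preset")
    expect_error(buildConfig("V1", "RSC-baseline"), "region")
    expect_error(buildConfig("V1", "V1-baseline",
        list(classMixture = c(visual = 0.5, auditory = 0,
                              network_only = 0.4, unclassified = 0.2))),
        "classMixture")
    expect_no_error(buildConfig("V1", "V1-baseline", list(noiseSd = 2)))
    expect_error(buildConfig("V1", "V1-baseline", list(couplingWeight = 1.2)),
        "couplingWeight")
})

test_that("named presets encode the published baseline proportions", {
    v1 <- buildConfig("V1", "V1-baseline")
    expect_equal(unname(v1@classMixture[c("visual", "network_only",
                                          "unclassified")]),
                 c(0.24, 0.65, 0.11))
    rsc <- buildConfig("RSC", "RSC-baseline")
    expect_equal(unname(rsc@classMixture), c(0.187, 0.159, 0.574, 0.08))
    sham <- buildConfig("V1", "sham")
    expect_true(all(unlist(sham@deprivation$ampScaling) == 1))
    expect_true(all(sham@deprivation$inactivationProb == 0))
    expect_false(sham@deprivation$removeEvoked)
})

test_that("schedules lay out gratings blocks, auditory intervals and dark", {
    cfg <- buildConfig("RSC", "RSC-baseline", list(seed = 5L))
    sch <- makeSchedule(cfg, 1)
    gr <- sch@presentations[sch@presentations$modality == "gratings", ]
    # each block of 8 is a permutation of the 8 directions
    blocks <- split(gr$direction, (seq_len(nrow(gr)) - 1) %/% 8)
    for (b in blocks)
        expect_setequal(b, seq(0, 315, by = 45))
    aud <- sch@presentations[sch@presentations$modality == "auditory", ]
    expect_true(all(diff(aud$onset) >= 3 - 1e-9))
    expect_true(all(diff(aud$onset) <= 5 + 1e-9))
    dk <- sch@epochs[sch@epochs$modality == "dark", ]
    expect_equal(dk$duration, 360)
    expect_false("dark" %in% sch@presentations$modality)
    # reproducible from (config, session index)
    expect_identical(makeSchedule(cfg, 1)@presentations, sch@presentations)
    expect_false(identical(makeSchedule(cfg, 2)@presentations,
                           sch@presentations))
})

test_that("background event counts match the configured Poisson rate", {
    cfg <- buildConfig("V1", "V1-baseline", list(
        nSpines = 250L, seed = 3L,
        classMixture = c(visual = 0, auditory = 0, network_only = 0,
                         unclassified = 1),
        sessionLayout = list(spinescope:::darkEpoch(360)), timepoints = -1))
    plan <- studyPlan(cfg)
    sch <- makeSchedule(cfg, 1)
    tr <- simulateEvents(cfg, plan, sch, -1)
    counts <- table(factor(tr$events$spine, levels = plan$spine))
    expected <- 0.113 * 360                     # 40.68 events per spine
    se3 <- 3 * sqrt(expected / length(counts))  # 3 SE of the mean
    expect_lt(abs(mean(counts) - expected), se3)
})

test_that("full coupling makes a spine inherit the latent train exactly", {
    cfg <- buildConfig("V1", "V1-baseline", list(
        nSpines = 20L, seed = 7L, couplingWeight = 1, backgroundRate = 1e-9,
        classMixture = c(visual = 0, auditory = 0, network_only = 1,
                         unclassified = 0)))
    plan <- studyPlan(cfg)
    sch <- makeSchedule(cfg, 1)
    tr <- simulateEvents(cfg, plan, sch, -1)
    for (s in plan$spine[1:5]) {
        ev <- tr$events[tr$events$spine == s & tr$events$source == "latent", ]
        expect_equal(sort(ev$t), tr$latent)
    }
})

test_that("enucleation removes evoked visual events but keeps background", {
    cfg <- buildConfig("V1", "V1-enucleation", list(nSpines = 80L, seed = 9L))
    plan <- studyPlan(cfg)
    sch <- makeSchedule(cfg, 5)
    tr <- simulateEvents(cfg, plan, sch, 48)
    visSpines <- plan$spine[plan$class == "visual" & !tr$silenced]
    ev <- tr$events[tr$events$spine %in% visSpines, ]
    expect_false(any(grepl("^evoked", ev$source)))
    expect_gt(sum(ev$source == "background"), 0)
    # baseline session still has evoked responses
    tr0 <- simulateEvents(cfg, plan, makeSchedule(cfg, 2), -1)
    ev0 <- tr0$events[tr0$events$spine %in% plan$spine[plan$class == "visual"], ]
    expect_gt(sum(ev0$source == "evoked_vis"), 0)
})

test_that("silenced spines lose all events and can reactivate later", {
    cfg <- buildConfig("V1", "V1-enucleation", list(nSpines = 300L, seed = 2L))
    plan <- studyPlan(cfg)
    sch <- makeSchedule(cfg, 3)
    tr12 <- simulateEvents(cfg, plan, sch, 12)
    expect_true(all(!tr12$events$spine %in% plan$spine[tr12$silenced]))
    frac <- mean(tr12$silenced)
    expect_gt(frac, 0.15); expect_lt(frac, 0.28)
    tr48 <- simulateEvents(cfg, plan, makeSchedule(cfg, 5), 48)
    expect_lt(mean(tr48$silenced), frac)  # inactive spines decrease over time
})

test_that("rendered transients reproduce the event amplitude", {
    cfg <- buildConfig("V1", "V1-baseline", list(
        nSpines = 5L, seed = 21L, noiseSd = 1e-12, driftAmp = 1e-12,
        backgroundRate = 1e-9, latentRate = 1e-9, bapRate = 1e-9,
        alphaRange = c(0, 1e-12),
        classMixture = c(visual = 0, auditory = 0, network_only = 0,
                         unclassified = 1),
        sessionLayout = list(spinescope:::darkEpoch(120)), timepoints = -1))
    plan <- studyPlan(cfg)
    sch <- makeSchedule(cfg, 1)
    A <- 0.8
    trains <- list(events = data.frame(spine = plan$spine[1], t = 60,
                                       amp = A, source = "background"),
                   dendrite = data.frame(branch = integer(), t = numeric(),
                                         amp = numeric(), source = character()),
                   latent = numeric(), silenced = rep(FALSE, 5))
    se <- renderTraces(cfg, plan, sch, trains, -1)
    tr <- assay(se, "fluor")[1, ] / groundTruth(se)$baseF[1] - 1
    expect_lt(abs(max(tr) - A) / A, 0.02)
})

test_that("zero bleed slope leaves spine and dendrite uncorrelated", {
    # drift is shared within an ROI pair by design, so it is disabled
    # here to probe the bleed path alone
    cfg <- buildConfig("V1", "V1-baseline", list(
        nSpines = 10L, seed = 13L, alphaRange = c(0, 1e-9),
        driftAmp = 1e-9,
        classMixture = c(visual = 0, auditory = 0, network_only = 0,
                         unclassified = 1)))
    se <- simulateSession(cfg, -1)
    raw <- assay(se, "fluor")
    r <- cor(raw[1, ], raw[11, ])
    expect_lt(abs(r), 0.05)
})

test_that("identical configurations give bit-identical sessions", {
    cfg <- buildConfig("V1", "V1-baseline", list(nSpines = 12L, seed = 77L))
    se1 <- simulateSession(cfg, -1)
    se2 <- simulateSession(cfg, -1)
    expect_identical(assay(se1, "fluor"), assay(se2, "fluor"))
    cfg2 <- buildConfig("V1", "V1-baseline", list(nSpines = 12L, seed = 78L))
    expect_false(identical(assay(simulateSession(cfg2, -1), "fluor"),
                           assay(se1, "fluor")))
})

test_that("branch layout assigns positions independently of class", {
    cfg <- buildConfig("V1", "V1-baseline", list(nSpines = 400L, seed = 31L))
    plan <- studyPlan(cfg)
    sizes <- table(plan$branch)
    expect_true(all(sizes >= 1 & sizes <= 15))
    expect_true(all(tapply(plan$position, plan$branch, function(p)
        identical(sort(p), seq_along(p)))))
})
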