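test_that("the default ablation grid has 11 conditions and sane errors", {
    ds <- smallCohort(30, seed = 3)
    excl <- defaultExclusions(ds)
    expect_length(excl, 11L)      # baseline + 8 measures + rotarod + open field
    expect_equal(sum(lengths(excl) == 0), 1L)

    rep <- ablateSingle(ds, seed = 3)
    expect_s3_class(rep, "ablation_report")
    expect_equal(nrow(rep), 11L)
    expect_true(is.na(rep$fisher_p_vs_baseline[rep$excluded == ""]))
    expect_true(all(!is.na(rep$fisher_p_vs_baseline[rep$excluded != ""])))
    expect_equal(attr(rep, "baseline_accuracy"),
                 rep$accuracy[rep$excluded == ""])

    expect_error(ablateSingle(ds, exclusions = list(all = measureNames(ds))),
                 "whole battery|fewer than 3")
    expect_error(ablateSingle(ds, exclusions = list(x = measureNames(ds)[1:6])),
                 "fewer than 3")
})

test_that("dropping a null measure leaves accuracy statistically unchanged", {
    ns <- vapply(1:30, function(s) {
        ds <- smallCohort(85, seed = 8000 + s)
        rep <- ablateSingle(ds, exclusions = list(center = "of_center_time"),
                            seed = s)
        rep$fisher_p_vs_baseline[rep$condition == "center"] > 0.05
    }, TRUE)
    expect_gte(mean(ns), 0.9)
})

test_that("dropping the strongest measures lowers mean accuracy", {
    res <- vapply(1:40, function(s) {
        ds <- smallCohort(60, seed = 9000 + s)
        rep <- ablateSingle(
            ds, exclusions = list(strong = c("marbles_buried", "forced_swim")),
            seed = s)
        c(base = attr(rep, "baseline_accuracy"),
          abl = rep$accuracy[rep$condition == "strong"])
    }, c(base = 1, abl = 1))
    expect_lt(mean(res["abl", ]), mean(res["base", ]))
})

test_that("subset scan enumerates the exact binomial counts", {
    ds <- smallCohort(25, seed = 12)
    sc <- scanSubsets(ds, seed = 12)
    expect_equal(nrow(sc$records), 219L)
    expect_equal(sc$summary$n_subsets, c(56, 70, 56, 28, 8, 1))
    expect_equal(sc$summary$n_subsets, choose(8, 3:8))
    expect_false(any(duplicated(sc$records$measures)))

    expect_error(scanSubsets(ds, kMin = 2), ">= 3")
    expect_error(scanSubsets(ds, kMin = 5, kMax = 9), "kMax")
})

test_that("mean subset accuracy increases with the number of measures", {
    curves <- sapply(1:5, function(s) {
        ds <- smallCohort(60, seed = 10000 + s)
        scanSubsets(ds, seed = s)$summary$mean_accuracy
    })
    avg <- rowMeans(curves)       # sizes 3..8
    expect_gt(avg[6], avg[1])
    expect_gt(cor(3:8, avg, method = "spearman"), 0.9)
})

test_that("partial profiles trade measures for animals coherently", {
    fx <- makeFixtures(file.path(tempdir(), "fx-partial"))
    ds1 <- readBehaviorDataset(fx[["dataset1"]], fx[["battery"]])
    all8 <- measureNames(ds1)
    reduced <- setdiff(all8, c("weight", "of_distance", "of_center_time",
                               "nest_building"))
    rep <- partialProfileConditions(ds1, list(full = all8, reduced = reduced),
                                    seed = 4)
    expect_gt(rep$n_animals[rep$condition == "reduced"],
              rep$n_animals[rep$condition == "full"])

    # the full-battery condition reproduces predictGenotype on complete cases
    cc <- completeCaseSubset(ds1)
    plan <- screenSexDependence(ds1)
    fit <- predictGenotype(cc, nPCs = 2, plan = plan, seed = 4)
    expect_equal(rep$accuracy[rep$condition == "full"],
                 accuracy(fit$clustering))
})

test_that("fewer measures lose more accuracy than extra animals recover", {
    block <- c("weight", "of_distance", "of_center_time", "nest_building")
    blocks <- stats::setNames(rep(list(block), 4), sprintf("c%02d", 7:10))
    res <- vapply(1:15, function(s) {
        cfg <- defaultSyntheticConfig(nPerGenotype = c(148, 138),
                                      nCohorts = 10, cohortSd = 0.3,
                                      missingBlocks = blocks)
        ds <- generateCohort(cfg, seed = 11000 + s)$dataset
        rep <- partialProfileConditions(
            ds, list(full8 = measureNames(ds),
                     reduced4 = setdiff(measureNames(ds), block)), seed = s)
        c(full = rep$accuracy[1], reduced = rep$accuracy[2])
    }, c(full = 1, reduced = 1))
    expect_lt(mean(res["reduced", ]), mean(res["full", ]))
})

test_that("the degenerate bootstrap configuration reproduces the full fit", {
    ds <- smallCohort(20, seed = 31)
    plan <- screenSexDependence(ds)
    bc <- bootstrapCurve(ds, nMin = 20, nMax = 20, trials = 1, nPCs = 2,
                         seed = 8, nInit = 50, replace = FALSE, plan = plan)
    fit <- predictGenotype(ds, nPCs = 2, plan = plan, seed = 8)
    expect_equal(bc$mean_accuracy, accuracy(fit$clustering))
})

test_that("bootstrap accuracy grows from n = 3 to n = 30", {
    ds <- smallCohort(85, seed = 51)
    bc <- bootstrapCurve(ds, nMin = 3, nMax = 30, trials = 150, seed = 9)
    expect_equal(bc$n, 3:30)
    expect_true(all(bc$mean_accuracy >= 50 & bc$mean_accuracy <= 100))
    expect_gt(bc$mean_accuracy[bc$n == 30], bc$mean_accuracy[bc$n == 3])
})

test_that("the false-positive control stays in the chance band", {
    cfg <- defaultSyntheticConfig(nPerGenotype = c(36, 0), sexRatio = 1)
    nulls <- generateCohort(cfg, seed = 61)$dataset
    fp <- falsePositiveControl(nulls, trials = 300, seed = 6)
    expect_true(fp$no_separation)
    expect_lt(fp$mean_accuracy, 65)
    expect_gt(fp$mean_accuracy, 50)

    # determinism
    fp2 <- falsePositiveControl(nulls, trials = 300, seed = 6)
    expect_identical(fp$accuracies, fp2$accuracies)

    # hugely separated data with randomized labels is still chance-level
    ds <- smallCohort(30, seed = 62)
    X <- measureMatrix(ds)
    flat <- BehaviorDataset(X, genotype = rep("WT", nrow(X)), sex = sexes(ds),
                            battery = batteryInfo(ds))
    fp3 <- falsePositiveControl(flat, trials = 200, seed = 7)
    expect_lt(fp3$mean_accuracy, 65)

    tiny <- BehaviorDataset(X[1:4, ], genotype = rep("WT", 4),
                            sex = sexes(ds)[1:4], battery = batteryInfo(ds))
    expect_error(falsePositiveControl(tiny), "at least 6")
})

test_that("treatment analysis recovers a partial rescue", {
    cfg <- defaultSyntheticConfig(nPerGenotype = c(34, 25), treatmentN = 32,
                                  rescueFraction = 0.5)
    ds <- generateCohort(cfg, seed = 71)$dataset
    tr <- treatmentAnalysis(ds, nPCs = 1, seed = 71)
    s <- tr$arm_summary
    expect_equal(nrow(s), 3L)
    expect_lt(s$mean_pc1[s$arm == "WT+control"],
              s$mean_pc1[s$arm == "AS+treatment"])
    expect_lt(s$mean_pc1[s$arm == "AS+treatment"],
              s$mean_pc1[s$arm == "AS+control"])
    tk <- tr$tukey
    p_wt_as <- tk$adjusted_p[tk$group_a == "WT+control" &
                             tk$group_b == "AS+control"]
    p_as_tr <- tk$adjusted_p[tk$group_a == "AS+control" &
                             tk$group_b == "AS+treatment"]
    expect_lt(p_wt_as, 0.001)
    expect_lt(p_as_tr, 0.05)
    expect_s4_class(tr$control_clustering, "ClusteringResult")
    expect_equal(length(clusterLabels(tr$control_clustering)), 34 + 25)
    expect_identical(sexStratifiedMeasures(tr$plan),
                     sexStratifiedMeasures(tr$plan))
    expect_equal(tr$plan@scope, "control-groups-only")
})

test_that("null and full rescue behave as designed", {
    cfg0 <- defaultSyntheticConfig(nPerGenotype = c(34, 25), treatmentN = 32,
                                   rescueFraction = 0)
    tr0 <- treatmentAnalysis(generateCohort(cfg0, seed = 81)$dataset, seed = 81)
    tk0 <- tr0$tukey
    expect_gt(tk0$adjusted_p[tk0$group_a == "AS+control" &
                             tk0$group_b == "AS+treatment"], 0.05)

    cfg1 <- defaultSyntheticConfig(nPerGenotype = c(34, 25), treatmentN = 32,
                                   rescueFraction = 1)
    tr1 <- treatmentAnalysis(generateCohort(cfg1, seed = 91)$dataset, seed = 91)
    tk1 <- tr1$tukey
    expect_gt(tk1$adjusted_p[tk1$group_a == "WT+control" &
                             tk1$group_b == "AS+treatment"], 0.05)

    ds2 <- smallCohort(10)
    expect_error(treatmentAnalysis(ds2), "group")
})

test_that("per-cohort runs mirror the single-cohort pipeline", {
    ds <- smallCohort(14, seed = 101, nCohorts = 1)
    plan <- screenSexDependence(ds)
    pcr <- perCohortRuns(ds, seed = 5, plan = plan)
    expect_equal(nrow(pcr), 1L)
    fit <- predictGenotype(ds, nPCs = 2, plan = plan, seed = 5)
    expect_equal(pcr$accuracy, accuracy(fit$clustering))

    ds3 <- smallCohort(3, seed = 102)
    pcr3 <- perCohortRuns(ds3, seed = 5, plan = plan)
    expect_true(all(pcr3$small_n))

    # a single-genotype cohort is skipped with a warning
    g <- genotypes(ds)
    co <- rep(c("cA", "cB"), length.out = length(g))
    co[g == "AS"] <- "cA"
    X <- measureMatrix(ds)
    ds_mix <- BehaviorDataset(X, g, sexes(ds), cohort = co,
                              battery = batteryInfo(ds))
    expect_warning(perCohortRuns(ds_mix, seed = 5, plan = plan),
                   "single genotype")
})

test_that("within-cohort accuracy beats cross-cohort resampling at matched n", {
    block_free <- defaultSyntheticConfig(nPerGenotype = c(84, 84),
                                         nCohorts = 6, cohortSd = 0.35)
    deltas <- vapply(1:12, function(s) {
        ds <- generateCohort(block_free, seed = 12000 + s)$dataset
        plan <- screenSexDependence(ds)
        pcr <- perCohortRuns(ds, seed = s, plan = plan)
        bc <- bootstrapCurve(ds, nMin = 14, nMax = 14, trials = 60,
                             seed = s, plan = plan)
        mean(pcr$accuracy) - bc$mean_accuracy
    }, 1)
    expect_gt(mean(deltas), 0)
})
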