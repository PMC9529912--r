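# Experiment drivers: ablation, exhaustive subset scan, partial-profile
# conditions, bootstrap sample-size curves, false-positive null control,
# three-arm treatment analysis, per-cohort runs.

# Pull the plain-matrix view used by the fast pipeline.
dsExtract <- function(ds) {
    list(X = measureMatrix(ds), sex = sexes(ds), genotype = genotypes(ds),
         directions = impairmentDirections(ds), ids = animalIds(ds))
}

#' Default ablation conditions
#'
#' One condition per single measure plus one per multi-measure behavioral
#' test (taken from the battery's \code{test} column), preceded by a baseline
#' with nothing excluded. For the default eight-measure battery this yields
#' 11 conditions (baseline + 8 measures + rotarod + open field). The
#' exclusion list is fully user-configurable in [ablateSingle()].
#'
#' @param ds a \linkS4class{BehaviorDataset}.
#' @return named list of character vectors of excluded measures.
#' @export
defaultExclusions <- function(ds) {
    bat <- batteryInfo(ds)
    out <- list(baseline = character(0))
    for (m in bat$name) out[[paste0("measure:", m)]] <- m
    for (tst in unique(bat$test)) {
        members <- bat$name[bat$test == tst]
        if (length(members) > 1L) out[[paste0("test:", tst)]] <- members
    }
    out
}

#' Single-exclusion ablation
#'
#' Re-runs the full pipeline on the same complete-case animal set under a
#' list of exclusion conditions, and compares each condition's
#' correct/incorrect counts against the no-exclusion baseline with Fisher's
#' exact test (condition vs baseline only, no multiplicity correction).
#'
#' @param ds a \linkS4class{BehaviorDataset}; reduced to complete cases for
#'   its full battery internally.
#' @param exclusions named list of measure sets to drop, each leaving >= 3
#'   measures; \code{NULL} uses [defaultExclusions()]. A baseline (empty set)
#'   is prepended when absent.
#' @param nPCs,seed,nInit clustering parameters (each condition uses the same
#'   seed).
#' @param plan standardization plan; \code{NULL} screens on the complete-case
#'   set and restricts the plan per condition.
#' @param alpha screening level when \code{plan} is \code{NULL}.
#' @return data.frame of class \code{"ablation_report"}: condition, excluded,
#'   n_measures, n_animals, accuracy, fisher_p_vs_baseline; the baseline
#'   accuracy is in \code{attr(, "baseline_accuracy")}.
#' @export
ablateSingle <- function(ds, exclusions = NULL, nPCs = 2, seed = 1L,
                         plan = NULL, alpha = 0.05, nInit = 50) {
    ds <- completeCaseSubset(ds)
    if (is.null(exclusions)) exclusions <- defaultExclusions(ds)
    if (!any(vapply(exclusions, length, 1L) == 0L))
        exclusions <- c(list(baseline = character(0)), exclusions)
    if (is.null(plan)) plan <- screenSexDependence(ds, alpha = alpha)
    e <- dsExtract(ds)
    all_meas <- colnames(e$X)
    res <- lapply(names(exclusions), function(cn) {
        excl <- exclusions[[cn]]
        bad <- setdiff(excl, all_meas)
        if (length(bad)) stop("unknown measure(s) in exclusion '", cn, "': ",
                              paste(bad, collapse = ", "))
        keep <- setdiff(all_meas, excl)
        if (length(keep) == 0L) stop("exclusion '", cn, "' removes the whole battery")
        if (length(keep) < 3L)
            stop("exclusion '", cn, "' leaves fewer than 3 measures")
        pa <- withSeed(seed, pipelineAccuracy(
            e$X[, keep, drop = FALSE], e$sex, e$genotype,
            intersect(plan@sexStratified, keep), e$directions[keep],
            nPCs, nInit))
        data.frame(condition = cn,
                   excluded = paste(excl, collapse = ","),
                   n_measures = length(keep), n_animals = pa$n,
                   accuracy = pa$accuracy, n_correct = pa$n_correct,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    b <- which(out$excluded == "")[1]
    out$fisher_p_vs_baseline <- NA_real_
    for (i in seq_len(nrow(out))) {
        if (i == b) next
        tab <- rbind(c(out$n_correct[b], out$n_animals[b] - out$n_correct[b]),
                     c(out$n_correct[i], out$n_animals[i] - out$n_correct[i]))
        out$fisher_p_vs_baseline[i] <- fisherExact2x2(tab)
    }
    attr(out, "baseline_accuracy") <- out$accuracy[b]
    class(out) <- c("ablation_report", "data.frame")
    out
}

#' Exhaustive measure-subset scan
#'
#' Runs the pipeline on every subset of \code{kMin} to \code{kMax} measures
#' (the same complete-case animals throughout) and summarizes accuracy by
#' subset size. For an eight-measure battery scanned over sizes 3-8 this
#' enumerates choose(8,3) + ... + choose(8,8) = 219 conditions.
#'
#' @param ds a \linkS4class{BehaviorDataset} (complete cases enforced).
#' @param kMin smallest subset size (>= 3: two-PC clustering needs a
#'   non-trivial PCA).
#' @param kMax largest subset size (default: whole battery).
#' @param nPCs,seed,plan,alpha,nInit as in [ablateSingle()].
#' @return list of class \code{"subset_scan"}: \code{records} (one row per
#'   subset: size, measures, accuracy) and \code{summary} (per size:
#'   n_subsets, mean_accuracy, sem_accuracy).
#' @export
scanSubsets <- function(ds, kMin = 3, kMax = NULL, nPCs = 2, seed = 1L,
                        plan = NULL, alpha = 0.05, nInit = 50) {
    ds <- completeCaseSubset(ds)
    m <- length(measureNames(ds))
    if (is.null(kMax)) kMax <- m
    if (kMin < 3) stop("kMin must be >= 3")
    if (kMin > kMax || kMax > m) stop("need 3 <= kMin <= kMax <= #measures")
    if (is.null(plan)) plan <- screenSexDependence(ds, alpha = alpha)
    e <- dsExtract(ds)
    all_meas <- colnames(e$X)
    rec <- list()
    for (k in kMin:kMax) {
        sets <- utils::combn(all_meas, k)
        accs <- apply(sets, 2, function(keep) {
            withSeed(seed, pipelineAccuracy(
                e$X[, keep, drop = FALSE], e$sex, e$genotype,
                intersect(plan@sexStratified, keep), e$directions[keep],
                min(nPCs, k), nInit))$accuracy
        })
        rec[[as.character(k)]] <- data.frame(
            size = k, measures = apply(sets, 2, paste, collapse = ","),
            accuracy = accs, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, c(rec, list(make.row.names = FALSE)))
    summary <- do.call(rbind, lapply(split(records, records$size), function(d)
        data.frame(size = d$size[1], n_subsets = nrow(d),
                   mean_accuracy = mean(d$accuracy),
                   sem_accuracy = if (nrow(d) > 1) sem(d$accuracy) else 0)))
    rownames(summary) <- NULL
    structure(list(records = records, summary = summary), class = "subset_scan")
}

#' @export
print.subset_scan <- function(x, ...) {
    cat(sprintf("Subset scan: %d conditions\n", nrow(x$records)))
    print(x$summary, row.names = FALSE)
    invisible(x)
}

#' Partial-profile conditions
#'
#' Trades measures for animals: each condition names a measure set, the
#' dataset is reduced to that condition's complete cases (so conditions with
#' fewer measures typically include more animals), and the pipeline runs per
#' condition. Fisher's exact test compares each condition's correct/incorrect
#' counts against the first condition.
#'
#' @param ds a \linkS4class{BehaviorDataset}, missingness allowed.
#' @param conditions named list of measure sets (>= 3 measures each).
#' @param nPCs,seed,nInit clustering parameters.
#' @param plan standardization plan; \code{NULL} screens each measure on its
#'   full per-measure complete cases in \code{ds}.
#' @param alpha screening level.
#' @return data.frame of class \code{"ablation_report"} (condition,
#'   n_measures, n_animals, accuracy, fisher_p_vs_baseline where the baseline
#'   is the first condition).
#' @export
partialProfileConditions <- function(ds, conditions, nPCs = 2, seed = 1L,
                                     plan = NULL, alpha = 0.05, nInit = 50) {
    stopifnot(is.list(conditions), length(conditions) >= 1L)
    if (is.null(names(conditions)))
        names(conditions) <- paste0("condition", seq_along(conditions))
    if (is.null(plan)) plan <- screenSexDependence(ds, alpha = alpha)
    res <- lapply(names(conditions), function(cn) {
        meas <- conditions[[cn]]
        if (length(meas) < 3L) stop("condition '", cn, "' has fewer than 3 measures")
        sub <- completeCaseSubset(ds, meas)
        e <- dsExtract(sub)
        pa <- withSeed(seed, pipelineAccuracy(
            e$X, e$sex, e$genotype, intersect(plan@sexStratified, meas),
            e$directions, min(nPCs, length(meas)), nInit))
        data.frame(condition = cn, n_measures = length(meas),
                   n_animals = pa$n, accuracy = pa$accuracy,
                   n_correct = pa$n_correct, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$fisher_p_vs_baseline <- NA_real_
    for (i in seq_len(nrow(out))[-1]) {
        tab <- rbind(c(out$n_correct[1], out$n_animals[1] - out$n_correct[1]),
                     c(out$n_correct[i], out$n_animals[i] - out$n_correct[i]))
        out$fisher_p_vs_baseline[i] <- fisherExact2x2(tab)
    }
    attr(out, "baseline_accuracy") <- out$accuracy[1]
    class(out) <- c("ablation_report", "data.frame")
    out
}

#' Bootstrap sample-size curve
#'
#' For each per-genotype sample size n, draws animals with replacement from
#' each genotype, re-runs the entire pipeline on the resample
#' (re-standardization, re-fit PCA, re-cluster) and records the clustering
#' accuracy; duplicated draws count as separate animals. The
#' sex-stratification plan is inherited from the full dataset rather than
#' re-screened per resample (screening is hopeless at n = 3); a stratified
#' measure whose resampled sex groups are degenerate falls back to pooled
#' standardization for that trial, and a resample with a zero pooled sd is
#' redrawn. Fallback and redraw counts are reported.
#'
#' @param ds a complete-case two-genotype \linkS4class{BehaviorDataset}.
#' @param nMin,nMax range of per-genotype sample sizes.
#' @param trials resamples per n.
#' @param nPCs number of PCs for clustering.
#' @param seed master seed (the whole curve is reproducible from it).
#' @param nInit k-means restarts per resample (small samples need few).
#' @param replace sample with replacement (TRUE, the bootstrap) or without.
#' @param plan standardization plan; \code{NULL} screens the full dataset.
#' @param alpha screening level.
#' @param keepTrials keep the full trials x n accuracy matrix in
#'   \code{attr(, "accuracies")}.
#' @return data.frame of class \code{"bootstrap_curve"}: n, mean_accuracy,
#'   sd_accuracy, trials; attributes \code{fallbacks} and \code{redraws}
#'   count standardization fallbacks and redrawn degenerate resamples.
#' @export
bootstrapCurve <- function(ds, nMin = 3, nMax = 30, trials = 10000, nPCs = 2,
                           seed = 1L, nInit = 10, replace = TRUE, plan = NULL,
                           alpha = 0.05, keepTrials = FALSE) {
    ds <- completeCaseSubset(ds)
    if (is.null(plan)) plan <- screenSexDependence(ds, alpha = alpha)
    e <- dsExtract(ds)
    lev <- sort(unique(e$genotype))
    if (length(lev) != 2L) stop("bootstrap needs exactly 2 genotypes")
    idx1 <- which(e$genotype == lev[1]); idx2 <- which(e$genotype == lev[2])
    if (min(length(idx1), length(idx2)) < nMin)
        stop("both genotypes need at least nMin animals")
    strat <- plan@sexStratified
    ns <- nMin:nMax
    acc <- matrix(NA_real_, trials, length(ns), dimnames = list(NULL, ns))
    fallbacks <- 0L; redraws <- 0L
    withSeed(seed, {
        for (j in seq_along(ns)) {
            n <- ns[j]
            for (t in seq_len(trials)) {
                pa <- NULL
                attempts <- 0L
                while (is.null(pa)) {
                    attempts <- attempts + 1L
                    if (attempts > 100L) stop("resample repeatedly degenerate at n = ", n)
                    take <- c(sample(idx1, n, replace = replace),
                              sample(idx2, n, replace = replace))
                    pa <- pipelineAccuracy(e$X[take, , drop = FALSE],
                                           e$sex[take], e$genotype[take],
                                           strat, e$directions, nPCs, nInit,
                                           fallback = TRUE)
                    if (is.null(pa)) redraws <- redraws + 1L
                }
                if (length(pa$fallback)) fallbacks <- fallbacks + 1L
                acc[t, j] <- pa$accuracy
            }
        }
    })
    out <- data.frame(n = ns, mean_accuracy = colMeans(acc),
                      sd_accuracy = apply(acc, 2, stats::sd), trials = trials)
    rownames(out) <- NULL
    attr(out, "fallbacks") <- fallbacks
    attr(out, "redraws") <- redraws
    if (keepTrials) attr(out, "accuracies") <- acc
    class(out) <- c("bootstrap_curve", "data.frame")
    out
}

#' Empirical chance band for two-cluster accuracy with no group structure
#'
#' Brute-force null oracle: spherical Gaussian data of matched size and
#' dimension are clustered with k-means and validated against random balanced
#' labels; the band is a pair of extreme quantiles of the resulting accuracy
#' distribution. Because the best-of-two cluster-genotype mapping is taken,
#' null accuracies always exceed 50% in finite samples, so this band - not a
#' naive 50% - is the correct no-signal reference.
#'
#' @param nAnimals total animals.
#' @param d clustering-space dimension (number of PCs).
#' @param trials Monte Carlo trials.
#' @param seed integer seed.
#' @param probs quantiles defining the band.
#' @return list: lo, hi, mean, n, d, trials, probs.
#' @export
nullChanceBand <- function(nAnimals, d = 2, trials = 2000, seed = 1L,
                           probs = c(0.005, 0.995)) {
    acc <- withSeed(seed, vapply(seq_len(trials), function(i) {
        X <- matrix(stats::rnorm(nAnimals * d), nAnimals, d)
        g <- sample(rep(c("g1", "g2"), length.out = nAnimals))
        km <- kmeans2_cpp(X, 10L, 100L, 1e-10)
        100 * bestMapping(km$labels, g)$agree / nAnimals
    }, 1))
    q <- stats::quantile(acc, probs, names = FALSE)
    list(lo = q[1], hi = q[2], mean = mean(acc), n = nAnimals, d = d,
         trials = trials, probs = probs)
}

#' False-positive control on a homogeneous sample
#'
#' Repeatedly assigns a single-genotype sample to two random balanced
#' pseudo-groups and runs the full pipeline (pooled standardization, PCA,
#' k-means, validation). With no true group structure the accuracy
#' distribution should sit inside the empirically calibrated chance band of
#' [nullChanceBand()]; the result carries a \code{no_separation} flag saying
#' whether the observed mean does.
#'
#' @param ds a single-genotype \linkS4class{BehaviorDataset} with >= 6
#'   complete-case animals.
#' @param trials number of random splits.
#' @param nPCs,seed,nInit clustering parameters.
#' @param band chance band (list with lo/hi); \code{NULL} uses the packaged
#'   band when the size and dimension match, otherwise recomputes one.
#' @return list of class \code{"null_control"}: accuracies, mean_accuracy,
#'   sd_accuracy, band, no_separation.
#' @export
falsePositiveControl <- function(ds, trials = 500, nPCs = 2, seed = 1L,
                                 nInit = 10, band = NULL) {
    ds <- completeCaseSubset(ds)
    if (length(unique(genotypes(ds))) != 1L)
        stop("false-positive control expects a single-genotype sample")
    e <- dsExtract(ds)
    n <- nrow(e$X)
    if (n < 6L) stop("need at least 6 animals")
    seeds <- deriveSeeds(seed, 2)
    acc <- withSeed(seeds[1], vapply(seq_len(trials), function(i) {
        g <- sample(rep(c("g1", "g2"), length.out = n))
        pipelineAccuracy(e$X, e$sex, g, character(0), e$directions, nPCs,
                         nInit)$accuracy
    }, 1))
    if (is.null(band)) band <- packagedNullBand(n, nPCs, seeds[2])
    mean_acc <- mean(acc)
    structure(list(accuracies = acc, mean_accuracy = mean_acc,
                   sd_accuracy = stats::sd(acc), band = band,
                   no_separation = mean_acc >= band$lo & mean_acc <= band$hi),
              class = "null_control")
}

# Use the shipped chance-band fixture when it matches (n, d), else recompute.
packagedNullBand <- function(n, d, seed) {
    path <- system.file("extdata", "null_chance_band.json", package = "mdba")
    if (nzchar(path)) {
        band <- jsonlite::read_json(path, simplifyVector = TRUE)
        if (identical(as.integer(band$n), as.integer(n)) &&
            identical(as.integer(band$d), as.integer(d))) return(band)
    }
    nullChanceBand(n, d, trials = 2000, seed = seed)
}

#' @export
print.null_control <- function(x, ...) {
    cat(sprintf("Null control: mean accuracy %.1f%% (sd %.1f) over %d trials\n",
                x$mean_accuracy, x$sd_accuracy, length(x$accuracies)))
    cat(sprintf("  chance band [%.1f, %.1f] -> %s\n", x$band$lo, x$band$hi,
                if (x$no_separation) "no separation (as expected under the null)"
                else "OUTSIDE the chance band"))
    invisible(x)
}

#' Three-arm treatment analysis in PC space
#'
#' For a design with a wildtype control arm, a mutant control arm and a mutant
#' treatment arm: sex differences are screened between the two control arms
#' only; all animals are standardized with that plan and projected into a
#' single PCA whose PC1 is oriented toward impairment (the severity score);
#' clustering validation runs on the control arms alone (the treatment arm
#' must not inform the genotype axis); and the treatment effect is assessed by
#' one-way ANOVA across the three arms on PC1 with Tukey post hoc contrasts.
#'
#' @param ds a complete-case \linkS4class{BehaviorDataset} whose \code{group}
#'   column defines exactly 3 arms over 2 genotype levels (the mutant
#'   genotype in two arms).
#' @param nPCs number of PCs for the control-arm clustering (default 1:
#'   clustering on the severity score).
#' @param seed,nInit clustering parameters.
#' @param alpha sex-screening level.
#' @param mutantControl name of the mutant control arm; by default the mutant
#'   arm whose label contains "control" (case-insensitive).
#' @return list of class \code{"treatment_report"}: \code{arm_summary} (n,
#'   mean and SEM of PC1 per arm), \code{anova}, \code{tukey},
#'   \code{control_clustering}, \code{pca}, \code{plan}.
#' @export
treatmentAnalysis <- function(ds, nPCs = 1, seed = 1L, alpha = 0.05,
                              nInit = 50, mutantControl = NULL) {
    grp <- armGroups(ds)
    if (anyNA(grp)) stop("every animal needs a treatment-arm 'group' label")
    arms <- unique(grp)
    if (length(arms) != 3L) stop("treatment analysis requires exactly 3 arms")
    gt <- genotypes(ds)
    lev <- unique(gt)
    if (length(lev) != 2L) stop("need exactly 2 genotype levels")
    arms_per_geno <- vapply(lev, function(g) length(unique(grp[gt == g])), 1L)
    if (!setequal(arms_per_geno, c(1L, 2L)))
        stop("expected one genotype in a single arm and the other in two arms")
    ref_geno <- lev[arms_per_geno == 1L]
    mut_geno <- lev[arms_per_geno == 2L]
    ref_arm <- unique(grp[gt == ref_geno])
    mut_arms <- unique(grp[gt == mut_geno])
    if (is.null(mutantControl)) {
        hit <- grepl("control", mut_arms, ignore.case = TRUE)
        if (sum(hit) != 1L)
            stop("cannot identify the mutant control arm; pass mutantControl=")
        mutantControl <- mut_arms[hit]
    }
    control_arms <- c(ref_arm, mutantControl)
    if (anyNA(measureMatrix(ds)))
        stop("dataset has missing values; apply completeCaseSubset() first")

    plan <- screenSexDependence(ds, alpha = alpha,
                                scope = "control-groups-only",
                                animals = animalIds(ds)[grp %in% control_arms])
    sm <- standardizeMeasures(ds, plan)
    model <- orientPC1(fitBehaviorPCA(sm), impairmentDirections(ds))
    pc1 <- pcScores(model)[, 1]

    ctrl <- grp %in% control_arms
    k <- min(nPCs, ncol(pcScores(model)))
    pts <- pcScores(model)[ctrl, seq_len(k), drop = FALSE]
    km <- kmeans2(pts, nInit = nInit, seed = seed)
    ctrl_cl <- validateClusters(km$labels, gt[ctrl],
                                ids = animalIds(ds)[ctrl], nPCs = k,
                                inertia = km$inertia)

    groups <- split(pc1, grp)[c(ref_arm, mutantControl,
                                setdiff(mut_arms, mutantControl))]
    an <- oneWayAnova(groups)
    tk <- tukeyHSD(groups)
    arm_summary <- data.frame(arm = names(groups),
                              n = vapply(groups, length, 1L),
                              mean_pc1 = vapply(groups, mean, 1),
                              sem_pc1 = vapply(groups, sem, 1),
                              stringsAsFactors = FALSE, row.names = NULL)
    structure(list(arm_summary = arm_summary, anova = an, tukey = tk,
                   control_clustering = ctrl_cl, pca = model, plan = plan),
              class = "treatment_report")
}

#' @export
print.treatment_report <- function(x, ...) {
    cat("Treatment analysis (PC1 severity score)\n")
    print(x$arm_summary, row.names = FALSE)
    f <- x$anova$F[1]; p <- x$anova$p[1]
    cat(sprintf("  one-way ANOVA: F(%d,%d) = %.2f, p = %.3g\n",
                x$anova$df[1], x$anova$df[2], f, p))
    cat(sprintf("  control-arm clustering accuracy: %.1f%%\n",
                accuracy(x$control_clustering)))
    invisible(x)
}

#' Per-cohort pipeline runs
#'
#' Runs the pipeline independently within each cohort that has complete
#' batteries and both genotypes; cohorts with one genotype (or no complete
#' cases) are skipped with a warning. Cohorts with fewer than 5 animals in
#' either genotype are flagged small-n.
#'
#' @param ds a \linkS4class{BehaviorDataset} with cohort labels.
#' @param nPCs,seed,nInit clustering parameters.
#' @param plan standardization plan; \code{NULL} screens on the full
#'   complete-case dataset (within-cohort screening has no power at cohort
#'   sizes).
#' @param alpha screening level.
#' @return data.frame: cohort, per-genotype n columns, accuracy, small_n.
#' @export
perCohortRuns <- function(ds, nPCs = 2, seed = 1L, plan = NULL, alpha = 0.05,
                          nInit = 50) {
    co <- cohorts(ds)
    if (all(is.na(co))) stop("dataset has no cohort labels")
    full <- completeCaseSubset(ds)
    if (is.null(plan)) plan <- screenSexDependence(full, alpha = alpha)
    lev <- sort(unique(genotypes(ds)))
    rows <- list()
    for (cname in unique(co)) {
        sub <- ds[, which(co == cname)]
        sub <- tryCatch(completeCaseSubset(sub), error = function(e) NULL)
        if (is.null(sub)) {
            warning("cohort ", cname, " has no complete cases; skipped")
            next
        }
        gt <- genotypes(sub)
        if (length(unique(gt)) < 2L) {
            warning("cohort ", cname, " has a single genotype; skipped")
            next
        }
        e <- dsExtract(sub)
        pa <- withSeed(seed, pipelineAccuracy(
            e$X, e$sex, e$genotype, intersect(plan@sexStratified, colnames(e$X)),
            e$directions, min(nPCs, ncol(e$X)), nInit))
        n1 <- sum(gt == lev[1]); n2 <- sum(gt == lev[2])
        row <- data.frame(cohort = cname, n1 = n1, n2 = n2,
                          accuracy = pa$accuracy,
                          small_n = min(n1, n2) < 5L, stringsAsFactors = FALSE)
        names(row)[2:3] <- paste0("n_", lev)
        rows[[cname]] <- row
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
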