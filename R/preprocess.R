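# Sex-dependence screening, (sex-stratified) z-standardization, and
# PC-space outlier exclusion.

#' Construct a StandardizationPlan
#'
#' @param sexStratified character vector of measures to z-score within each
#'   sex separately.
#' @param alpha screening significance level.
#' @param scope \code{"all-animals"} (default workflow) or
#'   \code{"control-groups-only"} (treatment workflow).
#' @param screen optional data.frame of screening p-values (one row per
#'   measure).
#' @return A \linkS4class{StandardizationPlan}.
#' @export
StandardizationPlan <- function(sexStratified = character(0), alpha = 0.05,
                                scope = "all-animals",
                                screen = data.frame()) {
    new("StandardizationPlan", sexStratified = as.character(sexStratified),
        alpha = alpha, scope = scope, screen = screen)
}

#' Screen measures for sex dependence
#'
#' For each measure, a two-way ANOVA with sex and genotype as factors is run
#' on that measure's complete cases (the full per-measure sample, not the
#' complete-battery subset). A measure is marked for sex-stratified
#' standardization when its sex main effect or sex-by-genotype interaction has
#' p below \code{alpha}.
#'
#' @param ds a \linkS4class{BehaviorDataset} containing both sexes and both
#'   genotype levels.
#' @param alpha screening level (default 0.05).
#' @param scope recorded in the plan; use \code{"control-groups-only"} when
#'   screening a treatment study on its control arms.
#' @param animals optional character vector of animal ids restricting the
#'   screen (used by [treatmentAnalysis()] to screen on control arms only).
#' @return A \linkS4class{StandardizationPlan}; its \code{screen} slot holds
#'   per-measure sex and interaction p-values and the n used.
#' @export
screenSexDependence <- function(ds, alpha = 0.05, scope = "all-animals",
                                animals = NULL) {
    if (!is.null(animals)) ds <- ds[, animalIds(ds) %in% animals]
    sx <- sexes(ds); gt <- genotypes(ds)
    if (length(unique(sx)) < 2L) stop("both sexes must be present to screen")
    if (length(unique(gt)) < 2L) stop("both genotypes must be present to screen")
    X <- measureMatrix(ds)
    rows <- lapply(colnames(X), function(m) {
        ok <- !is.na(X[, m])
        if (any(table(sx[ok], gt[ok]) == 0L))
            stop(sprintf("empty sex x genotype cell for measure '%s'", m))
        an <- twoWayAnova(X[ok, m], sx[ok], gt[ok],
                          term_names = c("sex", "genotype"))
        data.frame(measure = m, n = sum(ok),
                   p_sex = an$p[an$term == "sex"],
                   p_interaction = an$p[an$term == "sex:genotype"],
                   stringsAsFactors = FALSE)
    })
    screen <- do.call(rbind, rows)
    screen$stratified <- screen$p_sex < alpha | screen$p_interaction < alpha
    StandardizationPlan(sexStratified = screen$measure[screen$stratified],
                        alpha = alpha, scope = scope, screen = screen)
}

# Z-score the columns of an animals x measures matrix. Measures in `strat`
# are standardized within each sex. With fallback = TRUE a stratified measure
# whose sex groups are too small (< 2) or degenerate (zero sd) is pooled for
# this call instead of failing (bootstrap resamples at tiny n); a zero pooled
# sd returns NULL so the caller can redraw, unless fail = TRUE.
zscoreMatrix <- function(X, sex, strat, fallback = FALSE, fail = TRUE) {
    Z <- X
    fell_back <- character(0)
    for (j in colnames(X)) {
        x <- X[, j]
        stratify <- j %in% strat
        if (stratify && fallback) {
            bad <- FALSE
            for (s in unique(sex)) {
                xs <- x[sex == s]
                if (length(xs) < 2L || stats::sd(xs) == 0) bad <- TRUE
            }
            if (bad) { stratify <- FALSE; fell_back <- c(fell_back, j) }
        }
        if (stratify) {
            for (s in unique(sex)) {
                idx <- sex == s
                if (sum(idx) < 2L)
                    stop(sprintf("measure '%s': fewer than 2 animals of sex %s", j, s))
                sd_s <- stats::sd(x[idx])
                if (sd_s == 0) {
                    if (fail) stop(sprintf("measure '%s': zero sd in sex group %s", j, s))
                    return(NULL)
                }
                Z[idx, j] <- (x[idx] - mean(x[idx])) / sd_s
            }
        } else {
            sd_j <- stats::sd(x)
            if (!is.finite(sd_j) || sd_j == 0) {
                if (fail) stop(sprintf("measure '%s': zero sd", j))
                return(NULL)
            }
            Z[, j] <- (x - mean(x)) / sd_j
        }
    }
    attr(Z, "fallback") <- fell_back
    Z
}

#' Z-standardize a complete-case behavioral dataset
#'
#' Each measure is transformed to \code{z = (value - group mean) / group sd}
#' with the sample sd (n - 1 denominator). The group is the whole cohort for
#' ordinary measures and each sex separately for measures in the plan's
#' sex-stratified set, which removes sex differences while leaving
#' genotype-related structure in place. The dataset must be complete-case for
#' its battery (apply [completeCaseSubset()] first).
#'
#' @param ds a complete-case \linkS4class{BehaviorDataset}.
#' @param plan a \linkS4class{StandardizationPlan}; by default nothing is
#'   sex-stratified.
#' @return A \linkS4class{StandardizedMatrix}.
#' @export
standardizeMeasures <- function(ds, plan = StandardizationPlan()) {
    X <- measureMatrix(ds)
    if (anyNA(X))
        stop("dataset has missing values; apply completeCaseSubset() first")
    strat <- intersect(plan@sexStratified, colnames(X))
    sx <- sexes(ds)
    for (j in strat) {
        for (s in unique(sx)) if (sum(sx == s) < 2L)
            stop(sprintf("measure '%s': fewer than 2 animals of sex %s", j, s))
    }
    Z <- zscoreMatrix(X, sx, strat, fallback = FALSE, fail = TRUE)
    attr(Z, "fallback") <- NULL
    new("StandardizedMatrix", Z = Z, sex = sx, plan = plan)
}

#' Flag and drop PC-space outliers with Grubbs' test
#'
#' Standardizes the dataset, fits a PCA, and runs a single pass of Grubbs'
#' test (two-sided) on each of the first \code{nPCs} score columns. The union
#' of flagged animals is removed; downstream analyses should re-standardize
#' and re-fit PCA on the returned dataset.
#'
#' @param ds a complete-case \linkS4class{BehaviorDataset}.
#' @param plan a \linkS4class{StandardizationPlan}.
#' @param nPCs number of leading score columns to screen (>= 1).
#' @param alpha Grubbs' significance level per component (default 0.05).
#' @return list with \code{dataset} (flagged animals removed), \code{flagged}
#'   (character ids, possibly empty) and \code{tests} (one
#'   \code{grubbs_result} per screened component).
#' @export
excludePCOutliers <- function(ds, plan = StandardizationPlan(), nPCs = 2,
                              alpha = 0.05) {
    if (nPCs < 1) stop("nPCs must be >= 1")
    sm <- standardizeMeasures(ds, plan)
    model <- fitBehaviorPCA(sm)
    S <- pcScores(model)
    k <- min(nPCs, ncol(S))
    tests <- list()
    flagged <- character(0)
    for (j in seq_len(k)) {
        g <- grubbsTest(S[, j], alpha = alpha)
        tests[[paste0("PC", j)]] <- g
        if (g$flagged) flagged <- union(flagged, rownames(S)[g$index])
    }
    out <- if (length(flagged)) ds[, !animalIds(ds) %in% flagged] else ds
    list(dataset = out, flagged = flagged, tests = tests)
}
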