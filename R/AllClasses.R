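#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Behavioral cohort container
#'
#' A \code{BehaviorDataset} holds a rectangular animals-by-measures behavioral
#' table together with per-animal metadata. It extends
#' \linkS4class{SummarizedExperiment}: the single assay \code{"measures"}
#' stores measures in rows and animals in columns (missing cells are
#' \code{NA}), \code{rowData} carries the measure battery (units, expected
#' impairment direction, bounds, integer flag, parent test), and
#' \code{colData} carries \code{genotype}, \code{sex}, \code{cohort} and an
#' optional treatment-arm label \code{group}.
#'
#' Invariants enforced by the validity method: at least one measure and two
#' animals; unique animal identifiers; non-missing genotype and sex, with sex
#' coded \code{"M"}/\code{"F"}; impairment directions in \{-1, +1\}; bounds
#' \code{lo < hi} where both are given.
#'
#' @seealso [BehaviorDataset()], [readBehaviorDataset()], [completeCaseSubset()]
#' @export
setClass("BehaviorDataset", contains = "SummarizedExperiment")

setValidity("BehaviorDataset", function(object) {
    msg <- character(0)
    if (nrow(object) < 1L) msg <- c(msg, "need at least 1 measure")
    if (ncol(object) < 2L) msg <- c(msg, "need at least 2 animals")
    ids <- colnames(object)
    if (is.null(ids) || anyNA(ids) || any(ids == "")) {
        msg <- c(msg, "animal ids (colnames) must be present")
    } else if (anyDuplicated(ids)) {
        msg <- c(msg, sprintf("duplicate animal_id: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    cd <- colData(object)
    for (col in c("genotype", "sex")) {
        if (!col %in% colnames(cd)) {
            msg <- c(msg, sprintf("colData must contain '%s'", col))
        } else if (anyNA(cd[[col]])) {
            msg <- c(msg, sprintf("'%s' must be non-missing for every animal", col))
        }
    }
    if ("sex" %in% colnames(cd) && !anyNA(cd$sex) && !all(cd$sex %in% c("M", "F")))
        msg <- c(msg, "sex must be coded 'M'/'F'")
    rd <- rowData(object)
    if (!"impairment_direction" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain 'impairment_direction'")
    } else if (!all(rd$impairment_direction %in% c(-1, 1))) {
        msg <- c(msg, "impairment_direction must be -1 or +1")
    }
    if (all(c("lo", "hi") %in% colnames(rd))) {
        both <- !is.na(rd$lo) & !is.na(rd$hi)
        if (any(both & rd$lo >= rd$hi)) msg <- c(msg, "bounds must satisfy lo < hi")
    }
    if (length(msg)) msg else TRUE
})

#' Standardization plan
#'
#' Records which measures are z-scored separately within each sex (those with
#' a significant sex main effect or sex-by-genotype interaction in a two-way
#' ANOVA screen), the screening alpha, the screening scope, and the screening
#' p-values themselves.
#'
#' @seealso [screenSexDependence()], [standardizeMeasures()]
#' @export
setClass("StandardizationPlan",
         slots = c(sexStratified = "character",
                   alpha         = "numeric",
                   scope         = "character",
                   screen        = "data.frame"))

setValidity("StandardizationPlan", function(object) {
    msg <- character(0)
    if (length(object@alpha) != 1L || is.na(object@alpha) ||
        object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (!object@scope %in% c("all-animals", "control-groups-only"))
        msg <- c(msg, "scope must be 'all-animals' or 'control-groups-only'")
    if (length(msg)) msg else TRUE
})

#' Standardized (z-scored) behavioral matrix
#'
#' Complete-case animals-by-measures matrix of z-scores (rows are animals,
#' columns measures) together with the \linkS4class{StandardizationPlan} that
#' produced it and the per-animal sex labels needed to verify per-sex
#' centering. Every standardization group has mean ~0 and sample sd ~1.
#'
#' @seealso [standardizeMeasures()], [zMatrix()]
#' @export
setClass("StandardizedMatrix",
         slots = c(Z = "matrix", sex = "character", plan = "StandardizationPlan"))

setValidity("StandardizedMatrix", function(object) {
    msg <- character(0)
    Z <- object@Z
    if (anyNA(Z)) msg <- c(msg, "Z must not contain missing values")
    if (length(object@sex) != nrow(Z)) msg <- c(msg, "sex must align with rows of Z")
    if (is.null(rownames(Z)) || is.null(colnames(Z)))
        msg <- c(msg, "Z must carry animal ids (rownames) and measure names (colnames)")
    if (!length(msg)) {
        strat <- object@plan@sexStratified
        for (j in colnames(Z)) {
            if (j %in% strat) {
                for (s in unique(object@sex)) {
                    m <- mean(Z[object@sex == s, j])
                    if (abs(m) > 1e-10)
                        msg <- c(msg, sprintf("per-sex mean of '%s' not ~0", j))
                }
            } else if (abs(mean(Z[, j])) > 1e-10) {
                msg <- c(msg, sprintf("mean of '%s' not ~0", j))
            }
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' Principal component model of a standardized behavioral matrix
#'
#' Loadings (measures x components, orthonormal columns), per-animal scores,
#' the fraction of total variance carried by each component, the column means
#' removed before the fit, and whether PC1 has been oriented so that larger
#' values mean greater impairment (see [orientPC1()]).
#'
#' @seealso [fitBehaviorPCA()], [pcScores()], [pcLoadings()], [varianceExplained()]
#' @export
setClass("PCAModel",
         slots = c(loadings = "matrix", scores = "matrix",
                   varianceFraction = "numeric", center = "numeric",
                   pc1Oriented = "logical"))

setValidity("PCAModel", function(object) {
    msg <- character(0)
    L <- object@loadings
    G <- crossprod(L)
    if (max(abs(G - diag(ncol(L)))) > 1e-8)
        msg <- c(msg, "loading columns must be orthonormal")
    vf <- object@varianceFraction
    if (any(diff(vf) > 1e-12)) msg <- c(msg, "variance fractions must be non-increasing")
    if (sum(vf) > 1 + 1e-8) msg <- c(msg, "variance fractions must sum to <= 1")
    if (ncol(object@scores) != ncol(L)) msg <- c(msg, "scores/loadings mismatch")
    if (length(msg)) msg else TRUE
})

#' Result of cluster-to-genotype validation
#'
#' Per-animal k-means cluster labels (1/2), the cluster-to-genotype mapping
#' that maximizes agreement, the resulting accuracy in percent (>= 50 by
#' construction), the ids of misclassified animals, the number of principal
#' components used for clustering, and the within-cluster sum of squares.
#'
#' @seealso [validateClusters()], [predictGenotype()]
#' @export
setClass("ClusteringResult",
         slots = c(labels = "integer", mapping = "character",
                   accuracy = "numeric", misclassified = "character",
                   nPCs = "integer", inertia = "numeric"))

setValidity("ClusteringResult", function(object) {
    msg <- character(0)
    if (!all(object@labels %in% 1:2)) msg <- c(msg, "labels must be in {1, 2}")
    if (object@accuracy < 50 - 1e-9 || object@accuracy > 100 + 1e-9)
        msg <- c(msg, "accuracy must lie in [50, 100]")
    n <- length(object@labels)
    expected <- round((1 - object@accuracy / 100) * n)
    if (length(object@misclassified) != expected)
        msg <- c(msg, "misclassified count inconsistent with accuracy")
    if (!identical(sort(names(object@mapping)), c("1", "2")))
        msg <- c(msg, "mapping must name clusters '1' and '2'")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic behavioral-cohort generator
#'
#' Per-measure effect structure (impairment direction, genotype effect as
#' Cohen's d on the pooled within-genotype scale, sex effect d, loading on the
#' shared latent severity factor, residual sd, raw-scale base/scale/bounds and
#' integer flag), plus cohort structure, sex ratio, optional treatment arm
#' with a fractional rescue of all genotype effects, and block-wise
#' missingness (cohort name to set of absent measures).
#'
#' @seealso [syntheticConfig()], [defaultSyntheticConfig()], [generateCohort()]
#' @export
setClass("SyntheticConfig",
         slots = c(measures = "data.frame", nPerGenotype = "integer",
                   sexRatio = "numeric", nCohorts = "integer",
                   cohortSd = "numeric", treatmentN = "integer",
                   rescueFraction = "numeric", missingBlocks = "list",
                   genotypeLabels = "character",
                   cohortAllocation = "data.frame"))

setValidity("SyntheticConfig", function(object) {
    msg <- character(0)
    m <- object@measures
    need <- c("name", "test", "units", "impairment_direction", "genotype_effect_d",
              "sex_effect_d", "factor_loading", "residual_sd", "base", "scale",
              "lo", "hi", "integer_valued")
    miss <- setdiff(need, colnames(m))
    if (length(miss)) msg <- c(msg, paste("measures lacks columns:", paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (anyDuplicated(m$name)) msg <- c(msg, "measure names must be unique")
        if (!all(m$impairment_direction %in% c(-1, 1)))
            msg <- c(msg, "impairment_direction must be -1/+1")
        if (!all(is.finite(m$genotype_effect_d))) msg <- c(msg, "genotype_effect_d must be finite")
        if (any(m$factor_loading < 0 | m$factor_loading > 1))
            msg <- c(msg, "factor_loading must lie in [0, 1]")
        if (any(m$residual_sd <= 0)) msg <- c(msg, "residual_sd must be positive")
        if (any(!is.na(m$lo) & !is.na(m$hi) & m$lo >= m$hi)) msg <- c(msg, "bounds need lo < hi")
    }
    if (object@rescueFraction < 0 || object@rescueFraction > 1)
        msg <- c(msg, "rescueFraction must lie in [0, 1]")
    if (object@sexRatio < 0 || object@sexRatio > 1)
        msg <- c(msg, "sexRatio must lie in [0, 1]")
    if (any(object@nPerGenotype < 0)) msg <- c(msg, "nPerGenotype must be >= 0")
    if (length(object@genotypeLabels) != 2L ||
        object@genotypeLabels[1] == object@genotypeLabels[2])
        msg <- c(msg, "need two distinct genotype labels")
    if (length(msg)) msg else TRUE
})
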