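# Accessor and show methods.

#' @rdname mdba-accessors
#' @export
setMethod("measureNames", "BehaviorDataset", function(x) rownames(x))
#' @rdname mdba-accessors
#' @export
setMethod("measureNames", "StandardizedMatrix", function(x) colnames(x@Z))
#' @rdname mdba-accessors
#' @export
setMethod("animalIds", "BehaviorDataset", function(x) colnames(x))
#' @rdname mdba-accessors
#' @export
setMethod("animalIds", "StandardizedMatrix", function(x) rownames(x@Z))
#' @rdname mdba-accessors
#' @export
setMethod("genotypes", "BehaviorDataset", function(x) as.character(colData(x)$genotype))
#' @rdname mdba-accessors
#' @export
setMethod("sexes", "BehaviorDataset", function(x) as.character(colData(x)$sex))
#' @rdname mdba-accessors
#' @export
setMethod("cohorts", "BehaviorDataset", function(x) {
    cd <- colData(x)
    if ("cohort" %in% colnames(cd)) as.character(cd$cohort) else rep(NA_character_, ncol(x))
})
#' @rdname mdba-accessors
#' @export
setMethod("armGroups", "BehaviorDataset", function(x) {
    cd <- colData(x)
    if ("group" %in% colnames(cd)) as.character(cd$group) else rep(NA_character_, ncol(x))
})
#' @rdname mdba-accessors
#' @export
setMethod("measureMatrix", "BehaviorDataset", function(x) t(assay(x, "measures")))
#' @rdname mdba-accessors
#' @export
setMethod("batteryInfo", "BehaviorDataset", function(x) {
    rd <- as.data.frame(rowData(x))
    data.frame(name = rownames(x), rd, row.names = NULL, stringsAsFactors = FALSE)
})
#' @rdname mdba-accessors
#' @export
setMethod("impairmentDirections", "BehaviorDataset", function(x) {
    stats::setNames(as.numeric(rowData(x)$impairment_direction), rownames(x))
})
#' @rdname mdba-accessors
#' @export
setMethod("zMatrix", "StandardizedMatrix", function(x) x@Z)
#' @rdname mdba-accessors
#' @export
setMethod("pcScores", "PCAModel", function(x) x@scores)
#' @rdname mdba-accessors
#' @export
setMethod("pcLoadings", "PCAModel", function(x) x@loadings)
#' @rdname mdba-accessors
#' @export
setMethod("varianceExplained", "PCAModel", function(x) x@varianceFraction)
#' @rdname mdba-accessors
#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@labels)
#' @rdname mdba-accessors
#' @export
setMethod("clusterMapping", "ClusteringResult", function(x) x@mapping)
#' @rdname mdba-accessors
#' @export
setMethod("accuracy", "ClusteringResult", function(x) x@accuracy)
#' @rdname mdba-accessors
#' @export
setMethod("misclassifiedIds", "ClusteringResult", function(x) x@misclassified)
#' @rdname mdba-accessors
#' @export
setMethod("inertia", "ClusteringResult", function(x) x@inertia)
#' @rdname mdba-accessors
#' @export
setMethod("sexStratifiedMeasures", "StandardizationPlan", function(x) x@sexStratified)

setMethod("show", "BehaviorDataset", function(object) {
    cat(sprintf("BehaviorDataset: %d animals x %d measures\n",
                ncol(object), nrow(object)))
    gt <- table(genotypes(object))
    cat("  genotypes:", paste(sprintf("%s (n=%d)", names(gt), as.integer(gt)),
                              collapse = ", "), "\n")
    co <- cohorts(object)
    if (!all(is.na(co))) cat("  cohorts:", length(unique(co)), "\n")
    gr <- armGroups(object)
    if (!all(is.na(gr)))
        cat("  arms:", paste(unique(gr), collapse = ", "), "\n")
    nmiss <- sum(is.na(assay(object, "measures")))
    cat(sprintf("  measures: %s\n  missing cells: %d\n",
                paste(rownames(object), collapse = ", "), nmiss))
})

setMethod("show", "StandardizationPlan", function(object) {
    cat("StandardizationPlan (alpha =", object@alpha, ", scope =", object@scope, ")\n")
    if (length(object@sexStratified)) {
        cat("  sex-stratified:", paste(object@sexStratified, collapse = ", "), "\n")
    } else cat("  sex-stratified: none\n")
})

setMethod("show", "StandardizedMatrix", function(object) {
    cat(sprintf("StandardizedMatrix: %d animals x %d measures (z-scores)\n",
                nrow(object@Z), ncol(object@Z)))
    cat("  sex-stratified:",
        if (length(object@plan@sexStratified))
            paste(object@plan@sexStratified, collapse = ", ") else "none", "\n")
})

setMethod("show", "PCAModel", function(object) {
    vf <- round(100 * object@varianceFraction, 1)
    cat(sprintf("PCAModel: %d measures, %d components\n",
                nrow(object@loadings), ncol(object@loadings)))
    cat("  %% variance:", paste(vf, collapse = ", "), "\n")
    cat("  PC1 severity-oriented:", object@pc1Oriented, "\n")
})

setMethod("show", "ClusteringResult", function(object) {
    cat(sprintf("ClusteringResult: %d animals in %d-PC space\n",
                length(object@labels), object@nPCs))
    cat(sprintf("  accuracy: %.2f%% (%d misclassified)\n",
                object@accuracy, length(object@misclassified)))
    cat("  mapping:", paste(sprintf("cluster %s -> %s", names(object@mapping),
                                    object@mapping), collapse = ", "), "\n")
})

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf("SyntheticConfig: %d measures, n = %s per genotype (%s)\n",
                nrow(object@measures),
                paste(object@nPerGenotype, collapse = "/"),
                paste(object@genotypeLabels, collapse = "/")))
    cat(sprintf("  cohorts: %d (sd %.2f), treatment n = %d (rescue %.0f%%)\n",
                object@nCohorts, object@cohortSd, object@treatmentN,
                100 * object@rescueFraction))
})
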