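#' @name mdba-accessors
#' @title Accessors for mdba classes
#'
#' @description Slot accessors for the core S4 classes. \code{measureNames()}
#' and \code{animalIds()} work on both \linkS4class{BehaviorDataset} and
#' \linkS4class{StandardizedMatrix}; \code{genotypes()}, \code{sexes()},
#' \code{cohorts()} and \code{armGroups()} return per-animal metadata;
#' \code{measureMatrix()} returns the animals-by-measures value matrix;
#' \code{batteryInfo()} the measure battery as a data.frame;
#' \code{impairmentDirections()} the named -1/+1 direction vector;
#' \code{zMatrix()} the z-scored matrix; \code{pcScores()},
#' \code{pcLoadings()}, \code{varianceExplained()} the PCA components;
#' \code{clusterLabels()}, \code{clusterMapping()}, \code{accuracy()},
#' \code{misclassifiedIds()}, \code{inertia()} the clustering results; and
#' \code{sexStratifiedMeasures()} the sex-stratified measure set of a plan.
#'
#' @param x an mdba object
#' @return See description; vectors, matrices or data.frames as appropriate.
#' @examples
#' ds <- generateCohort(defaultSyntheticConfig(nPerGenotype = c(10, 10)),
#'                      seed = 1)$dataset
#' measureNames(ds)
#' head(animalIds(ds))
#' table(genotypes(ds), sexes(ds))
NULL

#' @rdname mdba-accessors
#' @export
setGeneric("measureNames", function(x) standardGeneric("measureNames"))
#' @rdname mdba-accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname mdba-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname mdba-accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))
#' @rdname mdba-accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))
#' @rdname mdba-accessors
#' @export
setGeneric("armGroups", function(x) standardGeneric("armGroups"))
#' @rdname mdba-accessors
#' @export
setGeneric("measureMatrix", function(x) standardGeneric("measureMatrix"))
#' @rdname mdba-accessors
#' @export
setGeneric("batteryInfo", function(x) standardGeneric("batteryInfo"))
#' @rdname mdba-accessors
#' @export
setGeneric("impairmentDirections", function(x) standardGeneric("impairmentDirections"))
#' @rdname mdba-accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @rdname mdba-accessors
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))
#' @rdname mdba-accessors
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))
#' @rdname mdba-accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname mdba-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname mdba-accessors
#' @export
setGeneric("clusterMapping", function(x) standardGeneric("clusterMapping"))
#' @rdname mdba-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname mdba-accessors
#' @export
setGeneric("misclassifiedIds", function(x) standardGeneric("misclassifiedIds"))
#' @rdname mdba-accessors
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))
#' @rdname mdba-accessors
#' @export
setGeneric("sexStratifiedMeasures", function(x) standardGeneric("sexStratifiedMeasures"))
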