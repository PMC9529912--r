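# Lossless serialization of result objects: tables go to CSV, structured
# results to JSON with a type tag so readResults() can reconstruct them.

matToList <- function(m) {
    list(values = unname(as.vector(t(m))), nrow = nrow(m), ncol = ncol(m),
         rownames = rownames(m), colnames = colnames(m))
}

listToMat <- function(l) {
    m <- matrix(as.numeric(unlist(l$values)), nrow = l$nrow, ncol = l$ncol,
                byrow = TRUE)
    rn <- unlist(l$rownames); cn <- unlist(l$colnames)
    if (!is.null(rn)) rownames(m) <- rn
    if (!is.null(cn)) colnames(m) <- cn
    m
}

resultToList <- function(obj) {
    if (methods::is(obj, "ClusteringResult")) {
        list(type = "ClusteringResult",
             labels = as.list(stats::setNames(obj@labels, names(obj@labels))),
             mapping = as.list(obj@mapping), accuracy = obj@accuracy,
             misclassified = as.list(obj@misclassified),
             n_pcs = obj@nPCs, inertia = obj@inertia)
    } else if (methods::is(obj, "PCAModel")) {
        list(type = "PCAModel", loadings = matToList(obj@loadings),
             scores = matToList(obj@scores),
             variance_fraction = obj@varianceFraction,
             center = as.list(stats::setNames(obj@center, names(obj@center))),
             pc1_oriented = obj@pc1Oriented)
    } else if (methods::is(obj, "StandardizationPlan")) {
        list(type = "StandardizationPlan",
             sex_stratified = as.list(obj@sexStratified), alpha = obj@alpha,
             scope = obj@scope, screen = obj@screen)
    } else if (inherits(obj, "grubbs_result")) {
        c(list(type = "grubbs_result"), unclass(obj))
    } else if (inherits(obj, "subset_scan")) {
        list(type = "subset_scan", records = obj$records, summary = obj$summary)
    } else if (inherits(obj, "null_control")) {
        c(list(type = "null_control"), unclass(obj))
    } else if (inherits(obj, "treatment_report")) {
        list(type = "treatment_report", arm_summary = obj$arm_summary,
             anova = as.data.frame(obj$anova), tukey = obj$tukey,
             control_clustering = resultToList(obj$control_clustering),
             pca = resultToList(obj$pca), plan = resultToList(obj$plan))
    } else if (is.list(obj)) {
        obj
    } else stop("unsupported result type: ", class(obj)[1])
}

resultFromList <- function(l) {
    ty <- l$type %||% ""
    df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
    switch(ty,
        ClusteringResult = new("ClusteringResult",
            labels = stats::setNames(as.integer(unlist(l$labels)), names(l$labels)),
            mapping = stats::setNames(as.character(unlist(l$mapping)), names(l$mapping)),
            accuracy = as.numeric(l$accuracy),
            misclassified = as.character(unlist(l$misclassified)),
            nPCs = as.integer(l$n_pcs), inertia = as.numeric(l$inertia)),
        PCAModel = new("PCAModel", loadings = listToMat(l$loadings),
            scores = listToMat(l$scores),
            varianceFraction = as.numeric(unlist(l$variance_fraction)),
            center = stats::setNames(as.numeric(unlist(l$center)), names(l$center)),
            pc1Oriented = isTRUE(l$pc1_oriented)),
        StandardizationPlan = StandardizationPlan(
            sexStratified = as.character(unlist(l$sex_stratified)),
            alpha = as.numeric(l$alpha), scope = l$scope,
            screen = if (length(l$screen)) df(l$screen) else data.frame()),
        grubbs_result = structure(l[setdiff(names(l), "type")],
                                  class = "grubbs_result"),
        subset_scan = structure(list(records = df(l$records),
                                     summary = df(l$summary)),
                                class = "subset_scan"),
        null_control = structure(l[setdiff(names(l), "type")],
                                 class = "null_control"),
        treatment_report = structure(list(
            arm_summary = df(l$arm_summary),
            anova = structure(df(l$anova), class = c("mdba_anova", "data.frame")),
            tukey = df(l$tukey),
            control_clustering = resultFromList(l$control_clustering),
            pca = resultFromList(l$pca), plan = resultFromList(l$plan)),
            class = "treatment_report"),
        l)
}

#' Write an analysis result to disk
#'
#' Tables (data.frames and matrices, including ablation reports and bootstrap
#' curves) are written as full-precision CSV; structured results
#' (\linkS4class{ClusteringResult}, \linkS4class{PCAModel},
#' \linkS4class{StandardizationPlan}, Grubbs results, subset scans, null
#' controls, treatment reports, plain lists) as JSON with a type tag.
#' [readResults()] reconstructs the object losslessly (numeric values
#' round-trip at full double precision).
#'
#' @param obj the result object.
#' @param path output path; the format follows the extension
#'   (\code{.csv}/\code{.json}) or, absent one, the object type.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(obj, path) {
    is_table <- (is.data.frame(obj) || is.matrix(obj)) &&
        grepl("\\.csv$", path, ignore.case = TRUE)
    if (is_table || (is.data.frame(obj) && !grepl("\\.json$", path))) {
        if (is.matrix(obj)) {
            df <- as.data.frame(obj)
            if (!is.null(rownames(obj)))
                df <- cbind(data.frame(row = rownames(obj),
                                       stringsAsFactors = FALSE), df)
            obj <- df
        }
        out <- as.data.frame(obj)
        for (j in seq_along(out))
            if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
        utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    } else {
        jsonlite::write_json(resultToList(obj), path, auto_unbox = TRUE,
                             digits = I(17), null = "null",
                             dataframe = "columns")
    }
    invisible(path)
}

#' Read back a result written by [writeResults()]
#'
#' @param path a \code{.csv} or \code{.json} file produced by
#'   [writeResults()].
#' @return The reconstructed object: a data.frame for CSV, the original
#'   result type for tagged JSON, a plain list otherwise.
#' @export
readResults <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
        utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
        resultFromList(jsonlite::read_json(path, simplifyVector = TRUE,
                                           simplifyMatrix = FALSE))
    }
}
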