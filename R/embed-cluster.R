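# PCA, k-means in PC space, and cluster-to-genotype validation.

#' @useDynLib mdba, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Core PCA on a plain animals x measures matrix: column-center, SVD, fix each
# component's sign so its largest-|loading| entry is positive.
pcaCore <- function(Z) {
    ctr <- colMeans(Z)
    Zc <- sweep(Z, 2, ctr)
    if (max(abs(Zc)) == 0) stop("matrix has rank 0 after centering")
    sv <- svd(Zc)
    d2 <- sv$d^2
    keep <- seq_len(min(nrow(Z) - 1L, ncol(Z)))
    L <- sv$v[, keep, drop = FALSE]
    for (j in keep) {
        i <- which.max(abs(L[, j]))
        if (L[i, j] < 0) L[, j] <- -L[, j]
    }
    S <- Zc %*% L
    dimnames(L) <- list(colnames(Z), paste0("PC", keep))
    dimnames(S) <- list(rownames(Z), paste0("PC", keep))
    list(loadings = L, scores = S, varfrac = d2[keep] / sum(d2), center = ctr)
}

#' Fit a principal component model
#'
#' Principal axes of the column-centered standardized matrix, computed by
#' singular value decomposition (numerically equivalent to an
#' eigendecomposition of the covariance matrix, and stabler). The fraction of
#' variance per component is \eqn{\lambda_j / \sum_k \lambda_k}. Component
#' signs follow the largest-|loading|-positive convention; use [orientPC1()]
#' to point PC1 toward greater impairment.
#'
#' @param Z a \linkS4class{StandardizedMatrix} or a numeric animals x measures
#'   matrix (>= 2 animals, >= 2 measures, all finite).
#' @return A \linkS4class{PCAModel}.
#' @export
fitBehaviorPCA <- function(Z) {
    M <- if (methods::is(Z, "StandardizedMatrix")) zMatrix(Z) else as.matrix(Z)
    if (nrow(M) < 2L || ncol(M) < 2L) stop("need >= 2 animals and >= 2 measures")
    if (!all(is.finite(M))) stop("Z must be finite")
    p <- pcaCore(M)
    new("PCAModel", loadings = p$loadings, scores = p$scores,
        varianceFraction = p$varfrac, center = p$center, pc1Oriented = FALSE)
}

#' Orient PC1 as a severity score
#'
#' The sign of a principal component is arbitrary; for PC1 to act as a
#' behavioral severity score, its loadings are aligned with the battery's
#' expected impairment directions: PC1 is negated when
#' \eqn{\sum_j loading_{j1} \cdot direction_j < 0}, so that larger PC1 means
#' more impaired. Other components are left untouched. A zero dot product
#' leaves the sign unchanged with a warning.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param directions named -1/+1 vector per measure (see
#'   [impairmentDirections()]), or a \linkS4class{BehaviorDataset}.
#' @return The oriented \linkS4class{PCAModel}.
#' @export
orientPC1 <- function(model, directions) {
    if (methods::is(directions, "BehaviorDataset"))
        directions <- impairmentDirections(directions)
    meas <- rownames(model@loadings)
    if (!is.null(names(directions))) {
        miss <- setdiff(meas, names(directions))
        if (length(miss)) stop("no impairment direction for: ",
                               paste(miss, collapse = ", "))
        directions <- directions[meas]
    } else if (length(directions) != length(meas)) {
        stop("directions must align with the model's measures")
    }
    dp <- sum(model@loadings[, 1] * directions)
    if (dp == 0) {
        warning("severity direction undetermined (zero dot product); PC1 sign unchanged")
    } else if (dp < 0) {
        model@loadings[, 1] <- -model@loadings[, 1]
        model@scores[, 1] <- -model@scores[, 1]
    }
    model@pc1Oriented <- TRUE
    model
}

#' Two-cluster k-means
#'
#' Lloyd iterations run to convergence (assignments unchanged or squared
#' centroid shift below \code{tol}) from \code{nInit} k-means++ seedings; the
#' labeling with the smallest within-cluster sum of squares is returned.
#' Deterministic given \code{seed}.
#'
#' @param points numeric matrix (rows = points) or vector, with at least two
#'   distinct points.
#' @param nInit number of restarts (default 50).
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @param tol squared centroid-shift convergence tolerance.
#' @param maxIter Lloyd iteration cap per restart.
#' @return list with integer \code{labels} in \{1, 2\} and \code{inertia}
#'   (within-cluster sum of squares).
#' @examples
#' kmeans2(c(-10, -9, 9, 10), seed = 1)
#' @export
kmeans2 <- function(points, nInit = 50, seed = NULL, tol = 1e-10,
                    maxIter = 100) {
    X <- as.matrix(points)
    storage.mode(X) <- "double"
    if (nrow(X) < 2L) stop("need at least 2 points")
    if (all(colSums(abs(sweep(X, 2, X[1, ]))) == 0))
        stop("all points are identical")
    res <- withSeed(seed, kmeans2_cpp(X, as.integer(nInit),
                                      as.integer(maxIter), tol))
    names(res$labels) <- rownames(X)
    res
}

# Best-of-two cluster <-> genotype mapping; ties (only possible at 50%)
# resolve to cluster 1 -> alphabetically first genotype, for determinism.
bestMapping <- function(labels, genotype) {
    lev <- sort(unique(genotype))
    agree1 <- sum((labels == 1L & genotype == lev[1]) |
                  (labels == 2L & genotype == lev[2]))
    agree2 <- length(labels) - agree1
    if (agree1 >= agree2) {
        list(mapping = c(`1` = lev[1], `2` = lev[2]), agree = agree1)
    } else {
        list(mapping = c(`1` = lev[2], `2` = lev[1]), agree = agree2)
    }
}

#' Validate clusters against genotype
#'
#' Of the two possible cluster-to-genotype assignments, the one maximizing
#' agreement is chosen (accuracy is therefore >= 50% by construction, and
#' invariant to relabeling the clusters); accuracy is the percentage of
#' animals whose mapped cluster matches their true genotype.
#'
#' @param labels integer cluster labels in \{1, 2\} (named by animal id, or
#'   supply \code{ids}).
#' @param genotype character/factor with exactly two levels.
#' @param ids animal ids aligned with \code{labels}.
#' @param nPCs,inertia bookkeeping copied into the result (optional).
#' @return A \linkS4class{ClusteringResult}.
#' @export
validateClusters <- function(labels, genotype, ids = names(labels),
                             nPCs = NA_integer_, inertia = NA_real_) {
    genotype <- as.character(genotype)
    if (length(unique(genotype)) != 2L)
        stop("validation requires exactly 2 genotype levels",
             " (use treatmentAnalysis() for 3-arm designs)")
    labels <- as.integer(labels)
    if (!all(labels %in% 1:2)) stop("labels must be in {1, 2}")
    if (is.null(ids)) ids <- as.character(seq_along(labels))
    bm <- bestMapping(labels, genotype)
    correct <- bm$mapping[as.character(labels)] == genotype
    new("ClusteringResult", labels = stats::setNames(labels, ids),
        mapping = bm$mapping, accuracy = 100 * mean(correct),
        misclassified = ids[!correct], nPCs = as.integer(nPCs),
        inertia = inertia)
}

# Fast internal pipeline on plain vectors/matrices: z-score -> PCA -> orient
# -> k-means on the first n_pcs scores -> best-mapping accuracy. Used by the
# resampling drivers; returns NULL when a zero pooled sd makes the resample
# degenerate (caller redraws).
pipelineAccuracy <- function(X, sex, genotype, strat, directions, n_pcs,
                             n_init = 50, fallback = FALSE) {
    Z <- zscoreMatrix(X, sex, strat, fallback = fallback, fail = !fallback)
    if (is.null(Z)) return(NULL)
    fell_back <- attr(Z, "fallback")
    attr(Z, "fallback") <- NULL
    p <- pcaCore(Z)
    dp <- sum(p$loadings[, 1] * directions)
    if (dp < 0) p$scores[, 1] <- -p$scores[, 1]
    k <- min(n_pcs, ncol(p$scores))
    pts <- p$scores[, seq_len(k), drop = FALSE]
    if (all(colSums(abs(sweep(pts, 2, pts[1, ]))) == 0)) return(NULL)
    km <- kmeans2_cpp(pts, as.integer(n_init), 100L, 1e-10)
    bm <- bestMapping(km$labels, genotype)
    list(accuracy = 100 * bm$agree / length(genotype), n_correct = bm$agree,
         n = length(genotype), fallback = fell_back)
}

#' Predict genotype from behavior
#'
#' The full multidimensional-analysis pipeline: (sex-aware) z-standardization,
#' PCA, severity orientation of PC1, k-means (k = 2) on the first \code{nPCs}
#' score columns, and validation of the clusters against genotype.
#'
#' @param ds a complete-case \linkS4class{BehaviorDataset} with two genotype
#'   levels.
#' @param nPCs number of principal components used for clustering (default 2;
#'   1 clusters on the severity score alone).
#' @param plan a \linkS4class{StandardizationPlan}; when \code{NULL}, the sex
#'   screen is run on \code{ds} at level \code{alpha} first.
#' @param seed integer seed for the k-means restarts.
#' @param alpha screening level used when \code{plan} is \code{NULL}.
#' @param nInit k-means restarts.
#' @return list with elements \code{pca} (\linkS4class{PCAModel}),
#'   \code{clustering} (\linkS4class{ClusteringResult}) and \code{plan}.
#' @examples
#' sim <- generateCohort(defaultSyntheticConfig(nPerGenotype = c(30, 30)),
#'                       seed = 7)
#' fit <- predictGenotype(sim$dataset, nPCs = 2, seed = 7)
#' fit$clustering
#' @export
predictGenotype <- function(ds, nPCs = 2, plan = NULL, seed = 1L,
                            alpha = 0.05, nInit = 50) {
    X <- measureMatrix(ds)
    if (anyNA(X))
        stop("dataset has missing values; apply completeCaseSubset() first")
    if (nPCs < 1 || nPCs > ncol(X))
        stop("nPCs must lie in [1, number of measures]")
    if (is.null(plan)) plan <- screenSexDependence(ds, alpha = alpha)
    sm <- standardizeMeasures(ds, plan)
    model <- orientPC1(fitBehaviorPCA(sm), impairmentDirections(ds))
    k <- min(nPCs, ncol(pcScores(model)))
    pts <- pcScores(model)[, seq_len(k), drop = FALSE]
    km <- kmeans2(pts, nInit = nInit, seed = seed)
    cl <- validateClusters(km$labels, genotypes(ds), ids = animalIds(ds),
                           nPCs = k, inertia = km$inertia)
    list(pca = model, clustering = cl, plan = plan)
}
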