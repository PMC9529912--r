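test_that("PCA recovers exact low-rank structure and normalizes variance", {
    x <- c(-2, -1, 0, 1, 2)
    Z <- cbind(m1 = x, m2 = x)          # perfectly collinear
    rownames(Z) <- paste0("a", 1:5)
    model <- fitBehaviorPCA(Z)
    expect_equal(varianceExplained(model)[1], 1, tolerance = 1e-12)
    expect_equal(varianceExplained(model)[2], 0, tolerance = 1e-12)
    expect_equal(unname(abs(pcLoadings(model)[, 1])), rep(1 / sqrt(2), 2),
                 tolerance = 1e-10)

    set.seed(21)
    Z2 <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(paste0("a", 1:40), paste0("m", 1:6)))
    m2 <- fitBehaviorPCA(Z2)
    expect_equal(sum(varianceExplained(m2)), 1, tolerance = 1e-10)
    # reconstruction with all components retained
    Zc <- sweep(Z2, 2, colMeans(Z2))
    expect_lt(max(abs(pcScores(m2) %*% t(pcLoadings(m2)) - Zc)), 1e-8)
    # orthonormal loadings (validity enforces; assert explicitly)
    G <- crossprod(pcLoadings(m2))
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)

    expect_error(fitBehaviorPCA(matrix(1, 5, 3)), "rank 0")
})

test_that("PC1 loadings recover a single latent factor", {
    set.seed(31)
    beta <- seq(0.3, 1.6, length.out = 8)   # well-spread loadings
    cors <- vapply(1:10, function(i) {
        s <- rnorm(170)
        X <- outer(s, beta) + matrix(rnorm(170 * 8), 170, 8)
        colnames(X) <- paste0("m", 1:8); rownames(X) <- paste0("a", 1:170)
        # population covariance is beta beta' + I, whose top eigenvector is
        # proportional to beta
        model <- fitBehaviorPCA(X)
        abs(cor(pcLoadings(model)[, 1], beta))
    }, 1)
    expect_gt(min(cors), 0.95)
})

test_that("orientPC1 aligns the severity axis with impairment directions", {
    set.seed(41)
    Z <- matrix(rnorm(30 * 4), 30, 4,
                dimnames = list(paste0("a", 1:30), paste0("m", 1:4)))
    model <- fitBehaviorPCA(Z)
    dirs <- sign(pcLoadings(model)[, 1])
    dirs[dirs == 0] <- 1
    up <- orientPC1(model, dirs)     # already aligned: unchanged
    expect_identical(pcLoadings(up), pcLoadings(model))
    down <- orientPC1(model, -dirs)  # all directions negated: PC1 negated
    expect_equal(pcLoadings(down)[, 1], -pcLoadings(model)[, 1])
    expect_equal(pcScores(down)[, 1], -pcScores(model)[, 1])
    expect_identical(pcLoadings(down)[, -1], pcLoadings(model)[, -1])

    # on disease-model cohorts the oriented PC1 ranks mutants above wildtypes
    higher <- vapply(1:50, function(s) {
        ds <- smallCohort(40, seed = 5000 + s)
        fit <- predictGenotype(ds, nPCs = 2, seed = s)
        pc1 <- pcScores(fit$pca)[, 1]
        mean(pc1[genotypes(ds) == "AS"]) > mean(pc1[genotypes(ds) == "WT"])
    }, TRUE)
    expect_gte(mean(higher), 0.99)
})

test_that("kmeans2 solves canonical instances exactly", {
    km <- kmeans2(c(-10, -9, 9, 10), seed = 1)
    expect_equal(km$inertia, 1.0, tolerance = 1e-12)
    expect_setequal(split(1:4, km$labels) |> lapply(sort) |> unname(),
                    list(1:2, 3:4))

    set.seed(6)
    X <- matrix(rnorm(16), 8, 2)
    kmX <- kmeans2(X, seed = 2)
    km2X <- kmeans2(rbind(X, X), seed = 2)
    expect_equal(km2X$inertia, 2 * kmX$inertia, tolerance = 1e-8)
    expect_equal(km2X$labels[1:8] == km2X$labels[9:16], rep(TRUE, 8),
                 ignore_attr = TRUE)

    expect_error(kmeans2(matrix(1, 4, 2)), "identical")
})

test_that("kmeans2 attains the brute-force optimal 2-partition", {
    set.seed(17)
    for (i in 1:60) {
        n <- sample(4:10, 1); d <- sample(1:3, 1)
        X <- matrix(rnorm(n * d), n, d)
        km <- kmeans2(X, seed = i)
        expect_equal(km$inertia, bruteForceKmeans2(X), tolerance = 1e-8)
    }
})

test_that("kmeans2 is at least as good as stats::kmeans on random instances", {
    set.seed(23)
    for (i in 1:20) {
        X <- matrix(rnorm(60 * 2), 60, 2)
        km <- kmeans2(X, seed = i)
        ref <- stats::kmeans(X, 2, nstart = 25)
        expect_lte(km$inertia, ref$tot.withinss + 1e-6)
    }
})

test_that("cluster validation maps labels to genotypes correctly", {
    g <- rep(c("WT", "AS"), each = 10)
    lab <- c(rep(1L, 10), rep(2L, 10))
    v <- validateClusters(lab, g, ids = paste0("a", 1:20))
    expect_equal(accuracy(v), 100)
    v_swap <- validateClusters(3L - lab, g, ids = paste0("a", 1:20))
    expect_equal(accuracy(v_swap), 100)     # mapping absorbs the swap
    expect_length(misclassifiedIds(v), 0)

    # 169 animals with 9 disagreements under the best mapping -> 160/169
    g169 <- c(rep("WT", 88), rep("AS", 81))
    lab169 <- ifelse(g169 == "WT", 1L, 2L)
    lab169[c(3, 20, 45, 90, 100, 120, 140, 150, 169)] <-
        3L - lab169[c(3, 20, 45, 90, 100, 120, 140, 150, 169)]
    v169 <- validateClusters(lab169, g169, ids = sprintf("a%03d", 1:169))
    expect_equal(accuracy(v169), 100 * 160 / 169, tolerance = 1e-12)
    expect_equal(round(accuracy(v169), 1), 94.7)
    expect_length(misclassifiedIds(v169), 9)

    # invariance under permuting animal order
    set.seed(9)
    perm <- sample(169)
    v_perm <- validateClusters(lab169[perm], g169[perm],
                               ids = sprintf("a%03d", 1:169)[perm])
    expect_equal(accuracy(v_perm), accuracy(v169))
    expect_setequal(misclassifiedIds(v_perm), misclassifiedIds(v169))

    expect_error(validateClusters(lab, c(g[-1], "HET")), "2 genotype levels")
})

test_that("one PC classifies nearly as well as two on calibrated cohorts", {
    diffs <- vapply(1:30, function(s) {
        ds <- smallCohort(85, seed = 6000 + s)
        a2 <- accuracy(predictGenotype(ds, nPCs = 2, seed = s)$clustering)
        a1 <- accuracy(predictGenotype(ds, nPCs = 1, seed = s)$clustering)
        a2 - a1
    }, 1)
    expect_lt(abs(mean(diffs)), 3)
})

test_that("accuracy collapses to chance when genotype effects are removed", {
    cfg <- defaultSyntheticConfig(nPerGenotype = c(85, 85))
    cfg@measures$genotype_effect_d <- 0
    accs <- vapply(1:200, function(s) {
        sim <- generateCohort(cfg, seed = 7000 + s)
        predictGenotype(sim$dataset, nPCs = 2, seed = s)$clustering |> accuracy()
    }, 1)
    expect_lt(mean(accs), 60)
})

test_that("the pipeline is invariant to affine rescaling and sign flips", {
    ds <- smallCohort(40, seed = 77)
    plan <- screenSexDependence(ds)
    base <- predictGenotype(ds, nPCs = 2, plan = plan, seed = 5)

    # positive affine transform per measure: z-scores absorb units
    X <- measureMatrix(ds)
    scales <- seq(0.5, 4, length.out = ncol(X))
    Xa <- sweep(sweep(X, 2, scales, "*"), 2, seq_len(ncol(X)), "+")
    ds_aff <- BehaviorDataset(Xa, genotypes(ds), sexes(ds),
                              battery = batteryInfo(ds))
    aff <- predictGenotype(ds_aff, nPCs = 2, plan = plan, seed = 5)
    expect_equal(accuracy(aff$clustering), accuracy(base$clustering))
    expect_identical(clusterLabels(aff$clustering),
                     clusterLabels(base$clustering))

    # sign flip of one measure: PCA absorbs the reflection
    Xs <- X
    Xs[, "marbles_buried"] <- -Xs[, "marbles_buried"]
    bat <- batteryInfo(ds)
    bat$lo[bat$name == "marbles_buried"] <- -20
    bat$hi[bat$name == "marbles_buried"] <- 0
    bat$impairment_direction[bat$name == "marbles_buried"] <-
        -bat$impairment_direction[bat$name == "marbles_buried"]
    ds_flip <- BehaviorDataset(Xs, genotypes(ds), sexes(ds), battery = bat)
    flip <- predictGenotype(ds_flip, nPCs = 2, plan = plan, seed = 5)
    expect_equal(accuracy(flip$clustering), accuracy(base$clustering))
})
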