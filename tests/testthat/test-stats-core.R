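test_that("two-way ANOVA handles degenerate and constructed designs", {
    # constant response everywhere: no variance to attribute
    y0 <- rep(5, 12)
    a <- rep(c("x", "y"), each = 6)
    b <- rep(c("u", "v"), 6)
    an0 <- twoWayAnova(y0, a, b)
    expect_equal(an0$F[1:3], c(0, 0, 0))
    expect_equal(an0$p[1:3], c(1, 1, 1))

    # pure additive A effect: interaction ~0 and A dominates B
    set.seed(1)
    cell <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"))
    y <- unlist(lapply(seq_len(4), function(i)
        ifelse(cell$a[i] == "a2", 1, 0) + rnorm(6, sd = 0.3)))
    aa <- rep(cell$a, each = 6); bb <- rep(cell$b, each = 6)
    an <- twoWayAnova(y, aa, bb)
    expect_lt(an$F[3], 1)
    expect_lt(an$p[1], an$p[2])
    expect_lt(an$p[1], 1e-6)

    expect_error(twoWayAnova(c(1, 2, 3, 4), c("a", "a", "a", "b"),
                             c("u", "u", "u", "u")), "2 levels")
    expect_error(twoWayAnova(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "b"),
                             c("u", "v", "u", "u", "u")), "empty cell")
})

test_that("unbalanced two-way ANOVA matches the nested least-squares oracle", {
    y <- c(3.1, 2.9, 3.4,          # a1 b1 (n = 3)
           4.0, 4.3, 3.8,          # a1 b2 (n = 3)
           5.2, 5.5, 5.1, 4.9,     # a2 b1 (n = 4)
           6.1, 6.4, 5.9, 6.3, 6.0) # a2 b2 (n = 5)
    a <- rep(c("a1", "a2"), c(6, 9))
    b <- c(rep(c("b1", "b2"), each = 3), rep(c("b1", "b2"), c(4, 5)))
    mine <- twoWayAnova(y, a, b)
    oracle <- anovaTypeIIOracle(y, a, b)
    expect_equal(mine$sum_sq[1:3], unname(oracle$ss), tolerance = 1e-8)
    expect_equal(mine$F[1:3], unname(oracle$F), tolerance = 1e-8)
    expect_equal(mine$p[1:3], unname(oracle$p), tolerance = 1e-8)

    # independent cross-check against car's Type II table
    if (requireNamespace("car", quietly = TRUE)) {
        fit <- stats::lm(y ~ af * bf,
                         data = data.frame(y = y, af = factor(a), bf = factor(b)))
        ca <- car::Anova(fit, type = 2)
        expect_equal(mine$sum_sq[1:3], ca[["Sum Sq"]][1:3], tolerance = 1e-8)
        expect_equal(mine$p[1:3], ca[["Pr(>F)"]][1:3], tolerance = 1e-8)
    }
})

test_that("balanced designs satisfy the exact sum-of-squares decomposition", {
    set.seed(7)
    for (i in 1:20) {
        na <- sample(2:3, 1); nb <- sample(2:3, 1); r <- sample(3:5, 1)
        a <- rep(paste0("a", seq_len(na)), each = nb * r)
        b <- rep(rep(paste0("b", seq_len(nb)), each = r), na)
        y <- rnorm(length(a)) + as.numeric(factor(a)) * rnorm(1) +
            as.numeric(factor(b)) * rnorm(1)
        an <- twoWayAnova(y, a, b)
        total <- sum((y - mean(y))^2)
        expect_equal(sum(an$sum_sq), total, tolerance = 1e-8 * total)
    }
})

test_that("one-way ANOVA matches direct sums-of-squares arithmetic", {
    g <- list(rep(1.5, 4), rep(1.5, 4), rep(1.5, 4))
    an0 <- oneWayAnova(g)
    expect_equal(an0$F[1], 0)
    expect_equal(an0$p[1], 1)

    set.seed(3)
    gsep <- list(rnorm(3, 0, 1e-3), rnorm(3, 10, 1e-3), rnorm(3, 20, 1e-3))
    expect_lt(oneWayAnova(gsep)$p[1], 1e-6)

    g3 <- list(c(2.1, 2.5, 1.9, 2.3, 2.2),
               c(3.3, 3.1, 3.6, 2.9, 3.4),
               c(1.2, 1.5, 1.1, 1.4, 1.3))
    an <- oneWayAnova(g3)
    gm <- mean(unlist(g3))
    ssb <- sum(vapply(g3, function(x) 5 * (mean(x) - gm)^2, 1))
    ssw <- sum(vapply(g3, function(x) sum((x - mean(x))^2), 1))
    expect_equal(an$F[1], (ssb / 2) / (ssw / 12), tolerance = 1e-10)

    expect_error(oneWayAnova(list(c(1, 2), c(3))), ">= 2 values")
})

test_that("Tukey-Kramer p-values match the studentized-range quadrature oracle", {
    g_eq <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
    expect_gt(tukeyHSD(g_eq)$adjusted_p, 0.999)

    set.seed(5)
    g3 <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6) + 15)
    tk <- tukeyHSD(g3)
    expect_lt(tk$adjusted_p[tk$group_a == "a" & tk$group_b == "c"], 0.001)
    expect_lt(tk$adjusted_p[tk$group_a == "b" & tk$group_b == "c"], 0.001)
    expect_gt(tk$adjusted_p[tk$group_a == "a" & tk$group_b == "b"], 0.9)

    set.seed(8)
    gb <- list(g1 = rnorm(5), g2 = rnorm(5) + 1.2, g3 = rnorm(5) + 0.4)
    tkb <- tukeyHSD(gb)
    an <- oneWayAnova(gb)
    dfw <- an$df[2]
    for (i in seq_len(nrow(tkb))) {
        expect_equal(tkb$adjusted_p[i], tukeyTailOracle(tkb$q[i], 3, dfw),
                     tolerance = 1e-4)
    }

    # base R's Tukey as an independent cross-check (balanced design)
    df <- data.frame(y = unlist(gb), g = rep(names(gb), each = 5))
    base_tk <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
    expect_equal(sort(tkb$adjusted_p), sort(unname(base_tk[, "p adj"])),
                 tolerance = 1e-6)
})

test_that("Tukey adjusted p dominates the unadjusted MSE-based t-test p", {
    # the unadjusted comparison sharing the ANOVA mean square (Fisher's LSD);
    # with k = 2 means the studentized range reduces to it exactly
    set.seed(13)
    for (i in 1:15) {
        k <- sample(3:4, 1); n <- sample(4:7, 1)
        g <- lapply(seq_len(k), function(j) rnorm(n, mean = rnorm(1)))
        names(g) <- paste0("g", seq_len(k))
        tk <- tukeyHSD(g)
        an <- oneWayAnova(g)
        mse <- an$sum_sq[2] / an$df[2]
        for (r in seq_len(nrow(tk))) {
            tstat <- abs(mean(g[[tk$group_b[r]]]) - mean(g[[tk$group_a[r]]])) /
                sqrt(mse * 2 / n)
            lsd_p <- 2 * stats::pt(tstat, an$df[2], lower.tail = FALSE)
            expect_gte(tk$adjusted_p[r], lsd_p - 1e-10)
        }
    }

    set.seed(14)
    g2 <- list(a = rnorm(6), b = rnorm(6) + 0.7)
    tk2 <- tukeyHSD(g2)
    an2 <- oneWayAnova(g2)
    mse2 <- an2$sum_sq[2] / an2$df[2]
    t2 <- abs(mean(g2$b) - mean(g2$a)) / sqrt(mse2 * 2 / 6)
    expect_equal(tk2$adjusted_p,
                 2 * stats::pt(t2, an2$df[2], lower.tail = FALSE),
                 tolerance = 1e-8)
})

test_that("Fisher's exact test matches enumeration and is symmetric", {
    expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1)
    expect_equal(fisherExact2x2(matrix(c(10, 0, 0, 10), 2)),
                 2 / choose(20, 10), tolerance = 1e-12)

    tab <- matrix(c(160, 154, 9, 15), 2)   # correct/incorrect in two conditions
    expect_equal(fisherExact2x2(tab), fisherEnumOracle(tab), tolerance = 1e-12)
    expect_equal(fisherExact2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)

    set.seed(2)
    for (i in 1:25) {
        t2 <- matrix(rpois(4, 12), 2)
        p <- fisherExact2x2(t2)
        expect_equal(p, fisherExact2x2(t(t2)), tolerance = 1e-12)
        expect_equal(p, fisherExact2x2(t2[2:1, 2:1]), tolerance = 1e-12)
        expect_equal(p, fisherEnumOracle(t2), tolerance = 1e-12)
    }
    expect_error(fisherExact2x2(matrix(c(1, 2, 3, -1), 2)), "non-negative")
    expect_error(fisherExact2x2(matrix(c(1, 2, 3, 4.5), 2)), "integer")
})

test_that("Grubbs' test flags gross outliers and matches its closed form", {
    g <- grubbsTest(c(0, 0.1, -0.1, 0.05, 100))
    expect_true(g$flagged)
    expect_equal(g$index, 5L)

    n <- 10; alpha <- 0.05
    g10 <- grubbsTest(rnorm(10), alpha = alpha)
    tq <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
    expect_equal(g10$G_crit, (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)),
                 tolerance = 1e-10)

    expect_error(grubbsTest(c(1, 2)), "n >= 3")
    expect_error(grubbsTest(rep(2, 5)), "zero standard deviation")
})

test_that("Grubbs' false-positive rate on null samples stays at or below alpha", {
    set.seed(99)
    flags <- vapply(seq_len(1000), function(i) grubbsTest(rnorm(50))$flagged,
                    TRUE)
    rate <- mean(flags)
    mc_err <- sqrt(0.05 * 0.95 / 1000)
    expect_lt(rate, 0.10)
    expect_lte(rate, 0.05 + 2 * mc_err)
})
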