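# Independent oracles used to check the package's own implementations.

# Globally optimal 2-partition by exhaustive enumeration (n <= ~12).
bruteForceKmeans2 <- function(X) {
    X <- as.matrix(X)
    n <- nrow(X)
    best <- Inf
    wss_of <- function(idx) {
        ctr <- colMeans(X[idx, , drop = FALSE])
        sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
    }
    # point 1 always in cluster A; iterate over memberships of points 2..n
    for (mask in 0:(2^(n - 1) - 1)) {
        inA <- c(TRUE, as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 2)), 1L)))
        if (all(inA)) next
        w <- wss_of(which(inA)) + wss_of(which(!inA))
        if (w < best) best <- w
    }
    best
}

# Type II two-way ANOVA by explicit normal equations (no lm machinery).
anovaTypeIIOracle <- function(y, a, b) {
    a <- droplevels(as.factor(a)); b <- droplevels(as.factor(b))
    dummy <- function(f) {
        lev <- levels(f)
        sapply(lev[-1], function(l) as.numeric(f == l))
    }
    Xa <- dummy(a); Xb <- dummy(b)
    inter <- NULL
    for (i in seq_len(ncol(Xa))) for (j in seq_len(ncol(Xb)))
        inter <- cbind(inter, Xa[, i] * Xb[, j])
    rss <- function(X) {
        X <- cbind(1, X)
        beta <- solve(t(X) %*% X, t(X) %*% y)
        sum((y - X %*% beta)^2)
    }
    rss_full <- rss(cbind(Xa, Xb, inter))
    rss_ab <- rss(cbind(Xa, Xb))
    rss_a <- rss(Xa); rss_b <- rss(Xb)
    df_res <- length(y) - nlevels(a) * nlevels(b)
    mse <- rss_full / df_res
    ss <- c(A = rss_b - rss_ab, B = rss_a - rss_ab, AB = rss_ab - rss_full)
    df <- c(nlevels(a) - 1, nlevels(b) - 1, (nlevels(a) - 1) * (nlevels(b) - 1))
    Fv <- (ss / df) / mse
    list(ss = ss, df = df, F = Fv,
         p = stats::pf(Fv, df, df_res, lower.tail = FALSE))
}

# Upper tail of the studentized range distribution by direct quadrature.
tukeyTailOracle <- function(q, k, df) {
    inner <- function(s) {
        stats::integrate(function(z)
            stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1),
            -8, 8, rel.tol = 1e-9)$value * k
    }
    # density of S = chi_df / sqrt(df)
    fs <- function(s) {
        exp((df / 2) * log(df) + (df - 1) * log(s) - df * s^2 / 2 -
            lgamma(df / 2) - (df / 2 - 1) * log(2))
    }
    cdf <- stats::integrate(function(sv) vapply(sv, function(s) fs(s) * inner(s), 1),
                            1e-6, 6, rel.tol = 1e-8, subdivisions = 400L)$value
    1 - cdf
}

# Two-sided Fisher p by explicit enumeration with binomial coefficients.
fisherEnumOracle <- function(tab) {
    n <- sum(tab); r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
    support <- max(0, r1 + c1 - n):min(r1, c1)
    lp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
    probs <- exp(lp)
    p_obs <- exp(lchoose(c1, tab[1, 1]) + lchoose(n - c1, r1 - tab[1, 1]) -
                 lchoose(n, r1))
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Small literal CSV fixture written at test time.
writeTempCsv <- function(lines) {
    path <- tempfile(fileext = ".csv")
    writeLines(lines, path)
    path
}

# Shared small synthetic cohort for fast tests.
smallCohort <- function(n = 30, seed = 11, ...) {
    generateCohort(defaultSyntheticConfig(nPerGenotype = c(n, n), ...),
                   seed = seed)$dataset
}
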