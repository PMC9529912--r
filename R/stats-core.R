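# Self-contained statistical primitives used throughout the pipeline.
# p-values come from base R distribution CDFs (pf, ptukey, qt, dhyper); the
# test statistics and sums of squares are computed here from first principles.

rssFit <- function(X, y) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
}

# Tolerance used to decide that a sum of squares is numerically zero.
ssTol <- function(y) 1e-10 * max(1, sum((y - mean(y))^2))

#' Two-way ANOVA with interaction (Type II sums of squares)
#'
#' Fits the full two-factor model with interaction by least squares and
#' computes Type II sums of squares by model comparison: each main effect is
#' adjusted for the other main effect, and the interaction is adjusted for
#' both. For balanced designs this reproduces the classical orthogonal
#' decomposition. F statistics use the full-model residual mean square and
#' p-values come from the F distribution.
#'
#' When the response carries no variance at all, every F is reported as 0 with
#' p = 1; a zero residual variance combined with non-zero effect sums of
#' squares is an error.
#'
#' @param y numeric response vector.
#' @param a,b factors (or coercible) with at least two levels each; every cell
#'   of the a-by-b design must contain at least one observation.
#' @param term_names length-2 character, names used for the two factors in the
#'   output table.
#' @return data.frame of class \code{"mdba_anova"} with columns \code{term},
#'   \code{sum_sq}, \code{df}, \code{F}, \code{p} and a final
#'   \code{Residuals} row (F and p are NA there).
#' @examples
#' y <- c(1, 2, 3, 4, 6, 8, 2, 3, 4, 9, 11, 13)
#' a <- rep(c("lo", "hi"), each = 6)
#' b <- rep(rep(c("x", "y"), each = 3), 2)
#' twoWayAnova(y, a, b, term_names = c("A", "B"))
#' @export
twoWayAnova <- function(y, a, b, term_names = c("A", "B")) {
    y <- as.numeric(y)
    a <- droplevels(as.factor(a))
    b <- droplevels(as.factor(b))
    stopifnot(length(y) == length(a), length(y) == length(b))
    if (anyNA(y) || anyNA(a) || anyNA(b)) stop("missing values not allowed")
    if (nlevels(a) < 2L || nlevels(b) < 2L) stop("each factor needs >= 2 levels")
    if (any(table(a, b) == 0L)) stop("empty cell in the a x b design")
    n <- length(y)
    df_res <- n - nlevels(a) * nlevels(b)
    if (df_res < 1L) stop("residual df < 1")

    rss_full <- rssFit(stats::model.matrix(~ a * b), y)
    rss_ab   <- rssFit(stats::model.matrix(~ a + b), y)
    rss_a    <- rssFit(stats::model.matrix(~ a), y)
    rss_b    <- rssFit(stats::model.matrix(~ b), y)

    ss <- pmax(c(rss_b - rss_ab, rss_a - rss_ab, rss_ab - rss_full), 0)
    df <- c(nlevels(a) - 1L, nlevels(b) - 1L,
            (nlevels(a) - 1L) * (nlevels(b) - 1L))
    tol <- ssTol(y)
    mse <- rss_full / df_res
    if (mse <= tol) {
        if (all(ss <= tol)) {
            Fv <- rep(0, 3); pv <- rep(1, 3)
        } else stop("zero residual variance")
    } else {
        Fv <- (ss / df) / mse
        pv <- stats::pf(Fv, df, df_res, lower.tail = FALSE)
    }
    out <- data.frame(
        term = c(term_names, paste(term_names, collapse = ":"), "Residuals"),
        sum_sq = c(ss, rss_full), df = c(df, df_res),
        F = c(Fv, NA), p = c(pv, NA), stringsAsFactors = FALSE)
    class(out) <- c("mdba_anova", "data.frame")
    out
}

#' One-way ANOVA
#'
#' Classical between/within decomposition; \code{F} is the ratio of the
#' between-group to within-group mean squares. Groups identical up to zero
#' between-group variance give F = 0, p = 1.
#'
#' @param groups list of numeric vectors, each with at least two values.
#' @return data.frame of class \code{"mdba_anova"} as in [twoWayAnova()], with
#'   a single \code{group} term.
#' @examples
#' oneWayAnova(list(a = rnorm(5), b = rnorm(5) + 2, c = rnorm(5)))
#' @export
oneWayAnova <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (any(vapply(groups, length, 1L) < 2L))
        stop("every group needs >= 2 values")
    y <- unlist(groups, use.names = FALSE)
    if (anyNA(y)) stop("missing values not allowed")
    k <- length(groups)
    n <- length(y)
    gm <- mean(y)
    means <- vapply(groups, mean, 1)
    ns <- vapply(groups, length, 1L)
    ss_b <- sum(ns * (means - gm)^2)
    ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
    df_b <- k - 1L
    df_w <- n - k
    tol <- ssTol(y)
    if (ss_w / df_w <= tol) {
        if (ss_b <= tol) { Fv <- 0; pv <- 1 } else stop("zero residual variance")
    } else {
        Fv <- (ss_b / df_b) / (ss_w / df_w)
        pv <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
    }
    out <- data.frame(term = c("group", "Residuals"),
                      sum_sq = c(ss_b, ss_w), df = c(df_b, df_w),
                      F = c(Fv, NA), p = c(pv, NA), stringsAsFactors = FALSE)
    class(out) <- c("mdba_anova", "data.frame")
    out
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' All pairwise comparisons after a one-way ANOVA, with unequal group sizes
#' handled by the Tukey-Kramer correction: the standard error for a pair
#' (i, j) is \code{sqrt(MSE/2 * (1/n_i + 1/n_j))} and the adjusted p-value is
#' the upper tail of the studentized range distribution with \code{k} means
#' and the within-group degrees of freedom.
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @return data.frame with one row per pair: \code{group_a}, \code{group_b},
#'   \code{mean_diff} (b minus a), \code{se}, \code{q} and \code{adjusted_p}.
#' @examples
#' tukeyHSD(list(wt = rnorm(8), het = rnorm(8) + 1, hom = rnorm(8) + 2))
#' @export
tukeyHSD <- function(groups) {
    if (is.null(names(groups)) || any(names(groups) == ""))
        names(groups) <- paste0("g", seq_along(groups))
    an <- oneWayAnova(groups)
    df_w <- an$df[an$term == "Residuals"]
    mse <- an$sum_sq[an$term == "Residuals"] / df_w
    k <- length(groups)
    means <- vapply(groups, mean, 1)
    ns <- vapply(groups, length, 1L)
    pairs <- utils::combn(names(groups), 2)
    out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                      mean_diff = NA_real_, se = NA_real_, q = NA_real_,
                      adjusted_p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(pairs))) {
        ga <- pairs[1, i]; gb <- pairs[2, i]
        diff <- means[gb] - means[ga]
        se <- sqrt(mse / 2 * (1 / ns[ga] + 1 / ns[gb]))
        if (se == 0) {
            q <- if (abs(diff) < 1e-12) 0 else Inf
        } else q <- abs(diff) / se
        out$mean_diff[i] <- diff
        out$se[i] <- se
        out$q[i] <- q
        out$adjusted_p[i] <- if (is.infinite(q)) 0 else
            stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    }
    out
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by point-probability summation: with all margins fixed,
#' the probabilities of every table at least as extreme as (i.e. with
#' hypergeometric probability no larger than) the observed one are summed.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisherExact2x2 <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
    if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
        stop("cells must be non-negative integers")
    n <- sum(tab)
    if (n < 1) stop("grand total must be >= 1")
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- stats::dhyper(support, c1, n - c1, r1)
    p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Grubbs' test for a single outlier (two-sided)
#'
#' The statistic is \code{G = max |x - mean(x)| / sd(x)}. The two-sided
#' critical value at level alpha is
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n - 2 + t^2}},}
#' with \code{t} the upper \code{alpha/(2n)} quantile of Student's t with
#' \code{n - 2} degrees of freedom. The most deviant observation is flagged
#' iff \code{G > G_crit}.
#'
#' @param x numeric vector, length >= 3, with positive sd.
#' @param alpha significance level (default 0.05).
#' @return list of class \code{"grubbs_result"}: \code{index} (position of the
#'   flagged value, or \code{NA} when none), \code{G}, \code{G_crit},
#'   \code{alpha}, \code{flagged}.
#' @examples
#' grubbsTest(c(0, 0.1, -0.1, 0.05, 100))
#' @export
grubbsTest <- function(x, alpha = 0.05) {
    x <- as.numeric(x)
    n <- length(x)
    if (n < 3L) stop("Grubbs' test needs n >= 3")
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) stop("zero standard deviation")
    dev <- abs(x - mean(x))
    idx <- which.max(dev)
    G <- dev[idx] / s
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    G_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    flagged <- G > G_crit
    structure(list(index = if (flagged) idx else NA_integer_,
                   G = G, G_crit = G_crit, alpha = alpha, flagged = flagged),
              class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
    cat(sprintf("Grubbs' test: G = %.4f, G_crit(alpha = %g) = %.4f -> %s\n",
                x$G, x$alpha, x$G_crit,
                if (x$flagged) sprintf("outlier at index %d", x$index)
                else "no outlier"))
    invisible(x)
}
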