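# Paired statistics: normality gate (D'Agostino-Pearson omnibus), paired t,
# exact Wilcoxon signed-rank, Benjamini-Hochberg adjustment.

#' D'Agostino-Pearson omnibus normality test
#'
#' The K2 omnibus statistic combining the transformed sample skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) z-scores; K2 ~ chi-squared with
#' 2 df under normality. Requires n >= 8 for the kurtosis transformation to
#' be defined.
#'
#' @param x numeric sample.
#' @return list with `k2`, `z.skew`, `z.kurt`, `p.value`.
#' @export
dagostinoK2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("the omnibus test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(k2 = k2, z.skew = z1, z.kurt = z2,
       p.value = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Normality gate for paired comparisons
#'
#' Decides between the parametric (paired t) and nonparametric (Wilcoxon
#' signed-rank) branch for a vector of paired differences. Small samples
#' (n < `minN`, default 20) are routed to the nonparametric branch outright,
#' a declared validity floor for the omnibus test; larger samples use the
#' D'Agostino-Pearson K2 test at level `alpha`.
#'
#' @param differences numeric vector of paired differences (n >= 3).
#' @param alpha omnibus test level (default 0.05).
#' @param minN sample-size floor below which the gate is nonparametric.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normalityGate <- function(differences, alpha = 0.05, minN = 20L) {
  d <- differences[is.finite(differences)]
  if (length(d) < 3) stop("the gate needs at least 3 differences")
  if (length(d) < minN) return("nonparametric")
  if (dagostinoK2(d)$p.value < alpha) "nonparametric" else "parametric"
}

#' Paired t test
#'
#' Classical two-sided paired t test on the differences (delegates to
#' [stats::t.test()]).
#'
#' @param x,y paired measurement vectors; or pass differences as `x` with
#'   `y = NULL`.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
pairedT <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 2) stop("paired t needs n >= 2")
  if (sd(d) == 0) stop("paired t is undefined for zero-variance differences")
  ht <- t.test(d)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

#' Wilcoxon signed-rank test (exact for small n, ties allowed)
#'
#' Matched-pairs signed-rank test: zero differences are dropped, tied
#' absolute differences receive average ranks. The two-sided p-value is exact
#' by enumeration of all sign assignments for n <= `exactMax` (default 12) --
#' also under ties -- and uses the normal approximation with tie correction
#' and continuity correction above. All differences zero returns p = 1 by
#' convention.
#'
#' @param x,y paired measurement vectors; or differences as `x` with
#'   `y = NULL`.
#' @param exactMax largest n for exact enumeration.
#' @return list with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n` (non-zero pairs), `exact` (logical).
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactMax = 12L) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p.value = 1, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  E <- sum(r) / 2
  if (n <= exactMax) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p <- mean(abs(Vs - E) >= abs(V - E) - 1e-9)
    return(list(statistic = V, p.value = p, n = n, exact = TRUE))
  }
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - E - sign(V - E) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = V, p.value = p, n = n, exact = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (delegates to
#' [stats::p.adjust()] after validation), returned in input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One normality-gated paired comparison
#'
#' Applies the gate, then the paired t test or the Wilcoxon signed-rank test
#' on the paired vectors, reporting which branch ran.
#'
#' @param x,y paired measurement vectors (same length).
#' @return list with `test` ("paired_t" or "wilcoxon"), `gate`, `statistic`,
#'   `p.value`, `n`.
#' @export
pairedComparison <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0))
    return(list(test = "wilcoxon", gate = "nonparametric", statistic = 0,
                p.value = 1, n = length(d)))
  gate <- if (length(d) < 3) "nonparametric" else normalityGate(d)
  if (gate == "parametric") {
    ht <- pairedT(d)
    list(test = "paired_t", gate = gate, statistic = ht$statistic,
         p.value = ht$p.value, n = length(d))
  } else {
    ht <- wilcoxonSignedRank(d)
    list(test = "wilcoxon", gate = gate, statistic = ht$statistic,
         p.value = ht$p.value, n = length(d))
  }
}
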