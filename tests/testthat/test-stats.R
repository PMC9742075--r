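# Paired statistics: normality gate, paired t, Wilcoxon signed-rank, BH.

test_that("D'Agostino-Pearson K2 matches an independent implementation on fixed data", {
  # frozen oracle values computed with an independent omnibus-test
  # implementation on the same data
  x <- c(0.12, 0.47, 0.93, 1.51, 2.22, 3.07, 4.05, 5.17, 6.43, 7.82,
         9.35, 11.02, 12.83, 14.77, 16.85, 19.07, 21.43, 23.92, 26.55, 29.32)
  res <- dagostinoK2(x)
  expect_equal(res$k2, 2.476623330222362, tolerance = 1e-9)
  expect_equal(res$p.value, 0.28987320808387723, tolerance = 1e-9)
  y <- sin(1:50)
  resy <- dagostinoK2(y)
  expect_equal(resy$k2, 43.26765816707633, tolerance = 1e-9)
  expect_lt(resy$p.value, 1e-9)
})

test_that("normality gate routes by sample size and distribution shape", {
  expect_error(normalityGate(c(1, 2)), "at least 3")
  # n = 10: nonparametric regardless of values (declared validity floor)
  expect_identical(normalityGate(rnorm(10)), "nonparametric")
  set.seed(42)
  expect_identical(normalityGate(rnorm(500)), "parametric")
  set.seed(42)
  expect_identical(normalityGate(rexp(500)), "nonparametric")
})

test_that("paired t matches the closed form and is sign-symmetric", {
  d <- c(1, 2, 3, 4)
  res <- pairedT(d)
  # t = mean/(sd/sqrt(n)) with df 3
  expect_equal(res$statistic, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(res$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(res$p.value, 2 * pt(-res$statistic, df = 3), tolerance = 1e-12)
  neg <- pairedT(-d)
  expect_equal(neg$statistic, -res$statistic)
  expect_equal(neg$p.value, res$p.value)
  expect_error(pairedT(5), "n >= 2")
  expect_error(pairedT(c(2, 2, 2)), "zero-variance")
})

test_that("Wilcoxon signed-rank: conventions, exactness, symmetry", {
  # all differences zero -> p = 1 by convention
  expect_equal(wilcoxonSignedRank(c(0, 0, 0))$p.value, 1)
  # n = 5 all positive, untied: exact two-sided p = 2/32
  res5 <- wilcoxonSignedRank(c(1, 2, 3, 4, 5))
  expect_true(res5$exact)
  expect_equal(res5$p.value, 0.0625)
  expect_equal(res5$statistic, 15)
  # sign-flip invariance of the two-sided p
  set.seed(7)
  for (i in 1:5) {
    d <- rnorm(9)
    expect_equal(wilcoxonSignedRank(d)$p.value,
                 wilcoxonSignedRank(-d)$p.value)
  }
})

test_that("Wilcoxon exact p agrees with brute-force enumeration and wilcox.test", {
  # independent brute-force oracle: walk all 2^n sign assignments explicitly
  bruteP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    E <- sum(r) / 2
    hits <- 0L
    for (mask in 0:(2^n - 1)) {
      signs <- as.integer(intToBits(mask))[1:n]
      Vm <- sum(r[signs == 1L])
      if (abs(Vm - E) >= abs(V - E) - 1e-9) hits <- hits + 1L
    }
    hits / 2^n
  }
  set.seed(11)
  for (n in c(4, 6, 8, 10)) {
    d <- round(rnorm(n), 2)
    expect_equal(wilcoxonSignedRank(d)$p.value, bruteP(d),
                 info = sprintf("untied n=%d", n))
    dt <- sample(c(-2, -1, 1, 2), n, replace = TRUE)  # heavy ties
    expect_equal(wilcoxonSignedRank(dt)$p.value, bruteP(dt),
                 info = sprintf("tied n=%d", n))
  }
  # tie-free case agrees with the standard exact implementation
  d <- c(1.3, -0.4, 2.2, -3.1, 0.6, 1.9, -2.6, 0.9)
  expect_equal(wilcoxonSignedRank(d)$p.value,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("BH adjustment: step-up arithmetic, permutation invariance, idempotence", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle
  stepUp <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(3)
  p <- runif(20)
  expect_equal(bhAdjust(p), stepUp(p))
  perm <- sample(20)
  expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  expect_equal(bhAdjust(bhAdjust(p)) >= bhAdjust(p), rep(TRUE, 20))
})

test_that("gated paired comparison reports branch and handles identical pairs", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  res <- pairedComparison(x + 0.5, x)
  expect_identical(res$test, "wilcoxon")   # n < 20 forces nonparametric
  expect_true(res$p.value <= 1)
  same <- pairedComparison(x, x)
  expect_equal(same$p.value, 1)
})
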