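mk <- function(v, state = "counts") {
  m <- matrix(v, nrow = length(v) / 2, byrow = TRUE,
              dimnames = list(paste0("t", seq_len(length(v) / 2)),
                              c("s1", "s2")))
  ExpressionMatrix(m, state = state)
}

test_that("fpkm follows count / (kb) / (million column fragments)", {
  m <- ExpressionMatrix(matrix(c(10, 999990), 2,
         dimnames = list(c("a", "b"), "s1")))
  v <- exprValues(fpkm(m, c(a = 1000, b = 500)))
  expect_equal(v["a", "s1"], 10)  # 10 / 1kb / 1M
  expect_equal(exprState(fpkm(m, c(a = 1000, b = 500))), "fpkm")
  # zero counts stay zero; zero-depth columns yield all zeros
  z <- ExpressionMatrix(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                        c("s1", "s2"))))
  expect_true(all(exprValues(fpkm(z, c(a = 100, b = 100))) == 0))
  expect_error(fpkm(m, c(a = 1000)), "missing length")
  expect_error(fpkm(fpkm(m, c(a = 1000, b = 500)), c(a = 1, b = 1)),
               "requires state")
})

test_that("fpkm is invariant to uniform depth scaling within a column", {
  set.seed(3)
  v <- matrix(rpois(20, 50), 5, 4,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
  len <- stats::setNames(sample(200:2000, 5), paste0("t", 1:5))
  a <- exprValues(fpkm(ExpressionMatrix(v), len))
  b <- exprValues(fpkm(ExpressionMatrix(v * 2), len))
  expect_equal(a, b)
})

test_that("floorLog2 zeroes values below 1 and logs the rest", {
  m <- ExpressionMatrix(matrix(c(0.99, 1, 8, 0), 4, 1,
         dimnames = list(paste0("t", 1:4), "s1")), state = "fpkm")
  v <- exprValues(floorLog2(m))
  expect_equal(unname(v[, 1]), c(0, 0, 3, 0))
  expect_equal(exprState(floorLog2(m)), "log2fpkm")
  expect_error(floorLog2(floorLog2(m)), "requires state")
})

test_that("dropAllZero removes exactly the silent rows", {
  m <- ExpressionMatrix(matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE,
         dimnames = list(c("dead", "alive"), c("s1", "s2"))),
         state = "log2fpkm")
  out <- dropAllZero(m)
  expect_equal(rownames(exprValues(out)), "alive")
  empty <- ExpressionMatrix(matrix(numeric(0), 0, 2,
            dimnames = list(NULL, c("s1", "s2"))), state = "log2fpkm")
  expect_equal(nrow(dropAllZero(empty)), 0L)
})

test_that("tau hits its defining values", {
  # one maximal sample, the rest at 20% of it
  expect_equal(tauScore(c(100, rep(20, 21))), 0.8)
  expect_equal(tauScore(c(5, rep(0, 21))), 1)
  expect_equal(tauScore(rep(3, 22)), 0)
  expect_error(tauScore(rep(0, 5)), "all-zero")
  expect_error(tauScore(3), "two samples")
  expect_error(tauScore(c(-1, 2)), "negative")
})

test_that("tau is scale-invariant, monotone, and matches the direct sum", {
  set.seed(7)
  for (i in 1:30) {
    x <- rexp(sample(3:30, 1))
    expect_equal(tauScore(x), oracle_tau(x))
    expect_equal(tauScore(x * runif(1, 0.1, 50)), tauScore(x))
    # moving mass from a non-maximal to the maximal sample raises tau
    jmax <- which.max(x)
    jlo <- which(x == min(x[-jmax]))[1]
    y <- x
    delta <- x[jlo] / 2
    y[jlo] <- y[jlo] - delta
    y[jmax] <- y[jmax] + delta
    expect_gte(tauScore(y), tauScore(x))
  }
})

test_that("tauScores matches per-row tauScore and rejects silent rows", {
  set.seed(8)
  v <- matrix(rexp(60), 10, 6,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  m <- ExpressionMatrix(v, state = "log2fpkm")
  tau <- tauScores(m)
  expect_equal(unname(tau), unname(apply(v, 1, tauScore)))
  v[3, ] <- 0
  expect_error(tauScores(ExpressionMatrix(v, state = "log2fpkm")),
               "all-zero")
})

test_that("welchT reproduces the Welch-Satterthwaite formulas", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    got <- welchT(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # antisymmetry
    swapped <- welchT(y, x)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
})

test_that("welchT separates near-constant groups and handles x == y", {
  x <- c(1, 2, 3)
  same <- welchT(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  lo <- c(0, 0, 0, 1e-4) + rnorm(4, sd = 1e-6)
  hi <- c(1, 1, 1, 1 - 1e-4) + rnorm(4, sd = 1e-6)
  expect_lt(welchT(lo, hi)$p, 1e-3)
  expect_error(welchT(c(1, 1), c(2, 2)), "degenerate")
  expect_error(welchT(1, c(1, 2)), "at least two")
})

test_that("pcaExpression orders components and reconstructs the input", {
  set.seed(10)
  v <- matrix(rexp(80), 10, 8,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  m <- ExpressionMatrix(v, state = "log2fpkm")
  p <- pcaExpression(m, k = 7)  # rank of 8 centered samples
  expect_true(all(diff(p$varianceFraction) <= 1e-12))
  expect_lte(sum(p$varianceFraction), 1 + 1e-8)
  # loadings orthogonal
  cross <- crossprod(p$loadings)
  expect_equal(cross, diag(ncol(cross)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction of the centered matrix
  centered <- scale(t(v), center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 input: first component carries all variance
  r1 <- outer(1:6, 1:4)
  dimnames(r1) <- list(paste0("t", 1:6), paste0("s", 1:4))
  p1 <- suppressWarnings(pcaExpression(
    ExpressionMatrix(r1, state = "fpkm"), k = 2))
  expect_equal(p1$varianceFraction[1], 1, tolerance = 1e-10)
  expect_warning(pcaExpression(ExpressionMatrix(r1, state = "fpkm"), k = 4),
                 "truncating")
})
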