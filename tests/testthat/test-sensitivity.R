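# Latin hypercube stratification, PRCC against a correlation-matrix
# inversion oracle, and the reduced-scale sensitivity run.

test_that("each parameter gets exactly one draw per stratum", {
  d <- lhs_sample(list(x = c(0, 1)), "linear", n = 4, seed = 9)
  strata <- findInterval(d$samples[, "x"], c(0, 0.25, 0.5, 0.75),
                         rightmost.closed = TRUE)
  expect_setequal(strata, 1:4)
  # and on a log scale the strata are decades
  d2 <- lhs_sample(list(x = c(1e-2, 1e2)), "log", n = 4, seed = 9)
  decades <- findInterval(log10(d2$samples[, "x"]), c(-2, -1, 0, 1))
  expect_setequal(decades, 1:4)
  expect_true(all(d2$samples >= 1e-2 & d2$samples <= 1e2))
})

test_that("degenerate ranges give flagged constant columns", {
  d <- lhs_sample(list(x = c(0, 1), y = c(3, 3)), "linear", n = 8, seed = 2)
  expect_true(all(d$samples[, "y"] == 3))
  expect_equal(unname(d$constant), c(FALSE, TRUE))
  expect_error(lhs_sample(list(x = c(2, 1)), "linear", n = 4, seed = 1),
               "lo <= hi")
  expect_error(lhs_sample(list(x = c(-1, 1)), "log", n = 4, seed = 1),
               "lo > 0")
})

test_that("designs are reproducible from the seed and differ across seeds", {
  ranges <- list(a = c(0.1, 10), b = c(1, 2))
  mats <- lapply(1:10, function(s) {
    lhs_sample(ranges, "log", n = 16, seed = s)$samples
  })
  for (s in 1:10) {
    again <- lhs_sample(ranges, "log", n = 16, seed = s)$samples
    expect_identical(mats[[s]], again)
  }
  expect_length(unique(lapply(mats, function(m) paste(m, collapse = ","))),
                10)
})

test_that("prcc saturates at +/-1 for perfect monotone dependence", {
  set.seed(5)
  x <- cbind(a = runif(40), b = runif(40), c = runif(40))
  up <- prcc(x, x[, "a"])
  expect_equal(up$table$prcc[up$table$parameter == "a"], 1,
               tolerance = 1e-6)
  down <- prcc(x, exp(-3 * x[, "a"]))
  expect_equal(down$table$prcc[down$table$parameter == "a"], -1,
               tolerance = 1e-6)
})

test_that("prcc matches the rank-correlation-matrix inversion oracle", {
  set.seed(20)
  x <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  y <- 2 * x[, 1] - 3 * x[, 2] + 0.5 * x[, 3] + rnorm(20, sd = 0.3)
  res <- prcc(x, y)
  # oracle: invert the full Spearman correlation matrix of (x, y); the
  # partial correlation of x_j and y given the rest is -P_jy/sqrt(P_jj P_yy)
  C <- stats::cor(cbind(apply(x, 2, rank), rank(y)))
  P <- solve(C)
  k <- ncol(x) + 1
  oracle <- vapply(seq_len(ncol(x)),
                   function(j) -P[j, k] / sqrt(P[j, j] * P[k, k]),
                   numeric(1))
  expect_equal(res$table$prcc, oracle, tolerance = 1e-10)
  # and the t-based p-values match a direct recomputation
  df <- 20 - 2 - 2
  tstat <- oracle * sqrt(df / (1 - oracle^2))
  expect_equal(res$table$p_value, 2 * stats::pt(-abs(tstat), df),
               tolerance = 1e-10)
})

test_that("prcc is invariant to monotone output transforms and row order", {
  set.seed(33)
  x <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  y <- x[, 1]^2 - x[, 2] + 0.2 * rnorm(30)
  base <- prcc(x, y)$table$prcc
  expect_equal(prcc(x, exp(5 * y))$table$prcc, base, tolerance = 1e-12)
  perm <- sample(30)
  expect_equal(prcc(x[perm, ], y[perm])$table$prcc, base,
               tolerance = 1e-12)
})

test_that("prcc signs track an additive monotone toy model", {
  set.seed(8)
  x <- matrix(runif(300), 100, 3,
              dimnames = list(NULL, c("up", "down", "up2")))
  y <- 3 * x[, "up"] - 2 * x[, "down"] + x[, "up2"] + rnorm(100, sd = 0.1)
  tab <- prcc(x, y)$table
  expect_gt(tab$prcc[tab$parameter == "up"], 0)
  expect_lt(tab$prcc[tab$parameter == "down"], 0)
  expect_gt(tab$prcc[tab$parameter == "up2"], 0)
  expect_true(all(tab$significant))
})

test_that("prcc rejects degenerate inputs", {
  x <- cbind(a = runif(20), b = runif(20), c = runif(20))
  expect_error(prcc(x, rep(1, 20)), "constant")
  expect_error(prcc(x, runif(19)), "one value per sample row")
  xc <- cbind(a = runif(20), b = rep(2, 20), c = runif(20))
  res <- prcc(xc, xc[, "a"] + rnorm(20, sd = 0.1))
  expect_true(res$table$constant[res$table$parameter == "b"])
  expect_true(is.na(res$table$prcc[res$table$parameter == "b"]))
  xdup <- cbind(a = runif(20))
  xdup <- cbind(xdup, a2 = xdup[, 1])
  expect_error(prcc(xdup, runif(20)), "rank-deficient|collinear")
})

test_that("sensitivity ranges span a decade, a factor of two for a and b", {
  r <- sensitivity_ranges()
  expect_length(r, 19)
  expect_equal(r$k1, c(0.05, 5))
  expect_equal(r$a, c(0.43 / 2, 0.86))
  expect_equal(r$b, c(1.02e-9 / 2, 2.04e-9))
  expect_false("d0" %in% names(r))
})

test_that("a reduced hypercube reproduces the dominant sign pattern", {
  res <- run_sensitivity(with_bacteria = TRUE, n = 50, seed = 1)
  tab <- res$table
  val <- function(p) tab$prcc[tab$parameter == p]
  expect_gt(val("a"), 0)
  expect_lt(val("k1"), 0)
  expect_lt(val("k2"), 0)
  expect_lt(val("s1"), 0)
  expect_equal(res$failures, 0)
  expect_match(res$output, "day 15")
})
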