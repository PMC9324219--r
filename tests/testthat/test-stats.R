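test_that("ICC(2,1) matches the hand-computed mean-squares oracle", {
  # oracle: two-way ANOVA table computed from first principles
  icc_oracle <- function(p) {
    n <- nrow(p); k <- ncol(p)
    gm <- mean(p)
    msr <- k * sum((rowMeans(p) - gm)^2) / (n - 1)
    msc <- n * sum((colMeans(p) - gm)^2) / (k - 1)
    sst <- sum((p - gm)^2)
    mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  p1 <- cbind(1:5, 2:6)
  r1 <- icc_agreement(p1)
  expect_equal(r1$icc, icc_oracle(p1), tolerance = 1e-12)
  set.seed(4)
  p2 <- cbind(rnorm(12, 10, 3), rnorm(12, 10, 3) + rnorm(12, 0, 0.5))
  expect_equal(icc_agreement(p2)$icc, icc_oracle(p2), tolerance = 1e-12)
  # identical columns: perfect agreement
  r3 <- icc_agreement(cbind(1:6, 1:6))
  expect_equal(r3$icc, 1)
  expect_equal(r3$label, "very strong")
  # broken pairing: near-zero ICC
  set.seed(8)
  a <- rnorm(20)
  r4 <- icc_agreement(cbind(a, a[c(11:20, 1:10)]))
  expect_lt(r4$icc, 0.3)
  expect_equal(r4$label, "lack")
  expect_error(icc_agreement(cbind(c(1, 1, 1), c(1, 1, 1))), "zero total")
  expect_error(icc_agreement(cbind(1:2, 2:3)), "3 subjects")
})

test_that("ICC is invariant to common affine rescaling", {
  set.seed(14)
  p <- cbind(rnorm(15), rnorm(15))
  expect_equal(icc_agreement(3 * p + 7)$icc, icc_agreement(p)$icc,
               tolerance = 1e-10)
})

test_that("Bland-Altman gives bias, SD and limits of agreement", {
  expect_equal(bland_altman(cbind(1:5, 1:5)),
               list(bias = 0, sd = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(cbind(1:5, 2:6))
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd, 0)
  set.seed(6)
  x <- rnorm(30); y <- x + rnorm(30, 0.3, 0.8)
  ba2 <- bland_altman(cbind(x, y))
  d <- y - x
  expect_equal(ba2$bias, mean(d))
  expect_equal(ba2$loa_high, mean(d) + 1.96 * sd(d))
})

test_that("Dice coefficient: identity, disjoint, partial, empty convention", {
  m <- matrix(FALSE, 4, 4)
  a <- m; a[1:2, 1:2] <- TRUE
  b <- m; b[3:4, 3:4] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0)
  cc <- m; cc[1:2, 2:3] <- TRUE            # |A|=|B|=4, overlap 2
  expect_equal(dice_coefficient(a, cc), 0.5)
  expect_equal(dice_coefficient(a, cc), dice_coefficient(cc, a))
  expect_equal(dice_coefficient(m, m), 1)
  expect_error(dice_coefficient(a, matrix(FALSE, 3, 3)), "different grids")
})

test_that("one-way ANOVA matches the sums-of-squares oracle and degenerate rules", {
  r <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$F, 13.5)                    # hand-computed
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE))
  rc <- anova_oneway(list(rep(2, 4), rep(2, 5)))
  expect_equal(c(rc$F, rc$p), c(0, 1))
  expect_error(anova_oneway(list(rep(1, 3), rep(2, 3))), "undefined")
  # invariance to adding a constant
  set.seed(10)
  g <- list(rnorm(6), rnorm(6, 0.5), rnorm(6, 1))
  expect_equal(anova_oneway(g)$F,
               anova_oneway(lapply(g, `+`, 100))$F, tolerance = 1e-9)
  expect_error(anova_oneway(list(1:3)), "length")
  expect_error(anova_oneway(list(1:3, 2)), "at least 2 observations")
})

test_that("ANOVA type-I error is near alpha under the null", {
  set.seed(123)
  reps <- 2000
  hits <- 0
  for (i in seq_len(reps)) {
    g <- list(rnorm(5), rnorm(5), rnorm(5))
    if (anova_oneway(g)$p < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / reps - 0.05), 0.02)
})

test_that("linear regression matches the normal-equations oracle", {
  x <- c(60, 75, 90, 105, 120)
  y <- c(0.53, 0.45, 0.38, 0.28, 0.20)
  r <- linreg(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  r2 <- linreg(1:5, 2 * (1:5))
  expect_equal(c(r2$slope, r2$r2), c(2, 1))
  r3 <- linreg(1:5, rep(3, 5))
  expect_equal(c(r3$slope, r3$r2), c(0, 0))
  expect_error(linreg(rep(1, 5), 1:5), "zero variance")
})
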