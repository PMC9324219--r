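# Agreement and group statistics: ICC(2,1) absolute agreement with
# qualitative labels, Bland-Altman, Dice overlap, one-way ANOVA and
# ordinary least-squares regression.

.icc_label <- function(icc) {
  if (icc <= 0.30) "lack"
  else if (icc <= 0.50) "weak"
  else if (icc <= 0.70) "moderate"
  else if (icc <= 0.90) "strong"
  else "very strong"
}

#' Two-way single-measurement absolute-agreement ICC
#'
#' Shrout-Fleiss ICC(2,1) from the two-way random-effects ANOVA mean
#' squares, with the qualitative agreement label (thresholds
#' 0.30/0.50/0.70/0.90: lack, weak, moderate, strong, very strong).
#' Regression and Bland-Altman statistics of the pairing are included.
#'
#' @param pairs numeric matrix or data frame, subjects in rows and the two
#'   measurements in columns (n >= 3, no missing values).
#' @return object of class `agreement_result` with `icc`, `label`, `bias`,
#'   `sd`, `loa_low`, `loa_high`, `slope`, `intercept`, `r2`.
#' @export
icc_agreement <- function(pairs) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs); k <- ncol(pairs)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(pairs)) stop("missing values not allowed")
  if (var(as.numeric(pairs)) == 0) stop("zero total variance")
  d <- data.frame(value = as.numeric(pairs),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  # suppressWarnings: perfect agreement is legal input and makes anova/lm
  # warn about zero-residual fits
  ms <- suppressWarnings(
    anova(aov(value ~ subject + rater, data = d))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  ba <- bland_altman(pairs)
  fit <- lm(pairs[, 2] ~ pairs[, 1])
  r2 <- if (var(pairs[, 2]) == 0) 0
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(icc = icc, label = .icc_label(icc),
                 bias = ba$bias, sd = ba$sd,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r2 = r2),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> ICC(2,1) = ", format(x$icc, digits = 3), " (",
      x$label, " agreement)\n  bias ", format(x$bias, digits = 3),
      " [LoA ", format(x$loa_low, digits = 3), ", ",
      format(x$loa_high, digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Mean and SD of the paired differences (second minus first column) and
#' the 95% limits of agreement `bias +/- 1.96 sd`.
#'
#' @param pairs two-column numeric matrix or data frame (n >= 2).
#' @return list with `bias`, `sd`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 2)
  d <- pairs[, 2] - pairs[, 1]
  bias <- mean(d); s <- sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return dimensionless overlap in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks are on different grids")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) return(1)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' One-way analysis of variance
#'
#' Standard one-way F statistic with p value from the F distribution.
#' Degenerate inputs: identical constant groups give F = 0, p = 1; zero
#' within-group variance with differing means is an error.
#'
#' @param groups list of numeric vectors (k >= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 observations")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); N <- length(values)
  ssb <- sum(tapply(values, g, length) *
               (tapply(values, g, mean) - mean(values))^2)
  ssw <- sum((values - ave(values, g))^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df1 = k - 1, df2 = N - k))
    stop("F undefined: zero within-group variance with differing means")
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = pf(f, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k)
}

#' Ordinary least-squares regression
#'
#' Slope, intercept, R^2 and the slope t-test p value. Constant `y` is
#' returned as slope 0 with R^2 = 0; constant `x` is an error.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with `slope`, `intercept`, `r2`, `p`.
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0) stop("zero variance in x")
  if (var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r2 = 0, p = 1))
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared, p = s$coefficients[2, 4])
}
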