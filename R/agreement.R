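## Rater-agreement and validation statistics for ordinal scores.

.asScoreMatrix <- function(x) {
  if (is(x, "RatingMatrix")) x <- x@scores
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(x)) stop("rating matrix must be complete (no missing cells)", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 items and 2 raters", call. = FALSE)
  }
  x
}

## two-way mean squares of an items x raters matrix; the residual sum of
## squares is accumulated from the two-way residuals themselves so that a
## noiseless matrix yields an exact zero (no cancellation residue)
.twoWayMeanSquares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  res <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  sse <- sum(res^2)
  list(
    n = n, k = k,
    msr = ssr / (n - 1),
    msc = ssc / (k - 1),
    mse = sse / ((n - 1) * (k - 1)),
    sst = sum((m - grand)^2)
  )
}

#' Two-way intraclass correlation coefficient
#'
#' Inter-rater reliability of a complete items-by-raters score matrix under
#' the two-way random-effects model (both items and raters regarded as
#' random samples from larger pools). Two flavors are available:
#' \emph{consistency}, which ignores systematic rater offsets (do raters
#' order the items the same way?), and \emph{agreement}, which penalizes
#' them (do raters give the items the same values?). Agreement is never
#' above consistency, with equality only when raters show no systematic
#' bias.
#'
#' Both single-measure coefficients (the reliability of one rater's score,
#' the unit of interest at the bedside) and average-measure coefficients
#' (the reliability of the panel mean) are supported. Confidence intervals
#' use the standard F-based interval for consistency and the
#' Satterthwaite-approximation interval for agreement.
#'
#' @param ratings A \code{\link{RatingMatrix}} or numeric matrix, items in
#'   rows, raters in columns, complete.
#' @param flavor \code{"consistency"} or \code{"agreement"}.
#' @param measure \code{"single"} (default) or \code{"average"}.
#' @param conf Confidence level for the interval; default 0.95.
#' @return An object of class \code{ICCResult}: a list with
#'   \code{estimate}, \code{ci_low}, \code{ci_high}, \code{flavor},
#'   \code{measure}, \code{f_value}, \code{df1}, \code{df2} and the
#'   underlying mean squares.
#' @export
#' @examples
#' m <- rbind(c(5, 5, 4), c(4, 4, 4), c(2, 3, 2), c(1, 1, 2))
#' icc(m, "consistency")
#' icc(m, "agreement")
icc <- function(ratings, flavor = c("consistency", "agreement"),
                measure = c("single", "average"), conf = 0.95) {
  flavor <- match.arg(flavor)
  measure <- match.arg(measure)
  m <- .asScoreMatrix(ratings)
  ms <- .twoWayMeanSquares(m)
  if (ms$sst == 0 || ms$msr == 0) {
    stop("degenerate variance: no between-item variance in the ratings", call. = FALSE)
  }
  n <- ms$n; k <- ms$k
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  alpha <- 1 - conf

  if (flavor == "consistency") {
    est1 <- (msr - mse) / (msr + (k - 1) * mse)
    fv <- if (mse > 0) msr / mse else Inf
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    if (is.finite(fv)) {
      fl <- fv / qf(1 - alpha / 2, df1, df2)
      fu <- fv * qf(1 - alpha / 2, df2, df1)
      ci1 <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      ci1 <- c(est1, est1)
    }
    est <- if (measure == "single") est1 else (msr - mse) / msr
    ci <- if (measure == "single") ci1 else {
      if (is.finite(fv)) c(1 - 1 / fl, 1 - 1 / fu) else c(est, est)
    }
  } else {
    est1 <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    ## the F test of zero reliability reduces to MSR/MSE; the CI uses the
    ## Satterthwaite degrees of freedom evaluated at the estimate
    fv <- if (mse > 0) msr / mse else Inf
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    if (est1 >= 1 || (mse == 0 && msc == 0)) {
      ci1 <- c(est1, est1)
    } else {
      a <- k * est1 / (n * (1 - est1))
      b <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
      denom <- a * msc + b * mse
      v <- denom^2 / ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- qf(1 - alpha / 2, n - 1, v)
      fu <- qf(1 - alpha / 2, v, n - 1)
      ci1 <- c(
        n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
        n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
      )
    }
    est <- if (measure == "single") est1 else (msr - mse) / (msr + (msc - mse) / n)
    ci <- if (measure == "single") ci1 else k * ci1 / (1 + (k - 1) * ci1)
  }

  structure(list(
    estimate = est, ci_low = ci[1], ci_high = ci[2],
    flavor = flavor, measure = measure, conf = conf,
    f_value = fv, df1 = df1, df2 = df2,
    ms = c(msr = msr, msc = msc, mse = mse), n_items = n, n_raters = k
  ), class = "ICCResult")
}

#' @export
print.ICCResult <- function(x, ...) {
  cat(sprintf("Two-way ICC (%s, %s measures): %.3f (%d%% CI %.3f, %.3f)\n",
              x$flavor, x$measure, x$estimate, round(100 * x$conf),
              x$ci_low, x$ci_high))
  cat(sprintf("  F = %.3g on %.4g and %.4g df; %d items x %d raters\n",
              x$f_value, x$df1, x$df2, x$n_items, x$n_raters))
  invisible(x)
}

#' Error-score regression against an expert
#'
#' Subtracts the expert's (true) score from every observed rater score and
#' regresses the resulting error scores on rater and item as categorical
#' predictors, asking whether particular raters or particular video
#' sequences systematically attract error. Returns the marginal F-test
#' p-value for each predictor.
#'
#' @param ratings A \code{\link{RatingMatrix}} or numeric matrix (items x
#'   raters).
#' @param expert Numeric vector of expert scores, one per item, in row
#'   order (or named by item).
#' @return An object of class \code{ErrorScoreRegression}: list with
#'   \code{degenerate} (TRUE when every error score is zero),
#'   \code{p_item}, \code{p_rater}, \code{r_squared} and the error-score
#'   data frame.
#' @export
errorScoreRegression <- function(ratings, expert) {
  m <- .asScoreMatrix(ratings)
  if (!is.null(names(expert)) && !is.null(rownames(m)) &&
      all(rownames(m) %in% names(expert))) {
    expert <- expert[rownames(m)]
  }
  if (length(expert) != nrow(m)) {
    stop("expert must supply one score per item", call. = FALSE)
  }
  err <- m - matrix(expert, nrow(m), ncol(m))
  d <- data.frame(
    error = as.vector(err),
    item = factor(rep(rownames(m) %||% seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(colnames(m) %||% seq_len(ncol(m)), each = nrow(m)))
  )
  if (all(d$error == 0)) {
    return(structure(list(degenerate = TRUE, p_item = NA_real_,
                          p_rater = NA_real_, r_squared = NA_real_,
                          errors = d),
                     class = "ErrorScoreRegression"))
  }
  fit <- lm(error ~ item + rater, data = d)
  dr <- stats::drop1(fit, test = "F")
  structure(list(
    degenerate = FALSE,
    p_item = dr["item", "Pr(>F)"],
    p_rater = dr["rater", "Pr(>F)"],
    r_squared = summary(fit)$r.squared,
    errors = d, fit = fit
  ), class = "ErrorScoreRegression")
}

#' @export
print.ErrorScoreRegression <- function(x, ...) {
  if (x$degenerate) {
    cat("Error-score regression: degenerate (all error scores are zero)\n")
  } else {
    cat(sprintf("Error-score regression: p(item) = %.4g, p(rater) = %.4g, R^2 = %.3f\n",
                x$p_item, x$p_rater, x$r_squared))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least-squares R-squared of score versus parameter
#'
#' Simple linear regression of a continuous microcirculatory parameter on
#' ordinal scores (or vice versa), reporting the coefficient of
#' determination and the two-sided slope p-value. For simple regression
#' the R-squared equals the squared Pearson correlation.
#'
#' @param x Predictor values (e.g. per-item scores); must not be constant.
#' @param y Response values, same length, at least 3 pairs.
#' @return An object of class \code{RegressionResult}: list with
#'   \code{r_squared}, \code{p_value}, \code{slope}, \code{intercept}.
#' @export
#' @examples
#' linearR2(1:5, c(2.1, 2.4, 2.2, 3.1, 3.0))
linearR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  if (var(x) == 0) stop("x is constant: slope undefined", call. = FALSE)
  if (var(y) == 0) {
    # a flat response carries no explainable variance
    return(structure(list(r_squared = 0, p_value = 1, slope = 0,
                          intercept = mean(y), n = length(x)),
                     class = "RegressionResult"))
  }
  fit <- lm(y ~ x)
  # an exactly collinear fixture is legitimate input (R^2 = 1); silence the
  # perfect-fit warning from summary.lm
  sm <- suppressWarnings(summary(fit))
  structure(list(
    r_squared = sm$r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)["(Intercept)"]),
    n = length(x)
  ), class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("Linear regression (n = %d): R^2 = %.3f, p = %.4g, y = %.3g + %.3g x\n",
              x$n, x$r_squared, x$p_value, x$intercept, x$slope))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Omnibus nonparametric comparison of a continuous parameter across score
#' groups, followed by Dunn's z tests on all group pairs using the pooled
#' ranks with tie correction. P-values are adjusted for multiplicity
#' (Bonferroni by default; the omnibus test names no correction, so the
#' adjustment is selectable).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as \code{values}; at least two
#'   distinct groups.
#' @param adjust Multiplicity adjustment for the pairwise p-values: any
#'   method accepted by \code{\link[stats]{p.adjust}}; default
#'   \code{"bonferroni"}.
#' @return An object of class \code{GroupComparison}: list with
#'   \code{kw_h}, \code{kw_df}, \code{kw_p} and a \code{pairwise} data
#'   frame with columns \code{group_a}, \code{group_b}, \code{z},
#'   \code{p_raw}, \code{p_adj}.
#' @export
#' @examples
#' kruskalDunn(c(1, 2, 3, 7, 8, 9, 4, 5, 6),
#'             rep(c("a", "b", "c"), each = 3))
kruskalDunn <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  if (length(values) != length(groups) || anyNA(values) || anyNA(groups)) {
    stop("values and groups must match and be complete", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  groups <- droplevels(groups)
  kw <- stats::kruskal.test(values, groups)

  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  tieTerm <- sum(tie^3 - tie)
  sigma2 <- N * (N + 1) / 12 - tieTerm / (12 * (N - 1))
  meanRank <- tapply(r, groups, mean)
  nPer <- tabulate(groups)
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (meanRank[i] - meanRank[j]) / sqrt(sigma2 * (1 / nPer[i] + 1 / nPer[j]))
  })
  pRaw <- 2 * pnorm(-abs(z))
  pairwise <- data.frame(
    group_a = lev[pairs[1, ]],
    group_b = lev[pairs[2, ]],
    z = as.numeric(z),
    p_raw = pRaw,
    p_adj = p.adjust(pRaw, method = adjust)
  )
  structure(list(
    kw_h = unname(kw$statistic), kw_df = unname(kw$parameter),
    kw_p = kw$p.value, pairwise = pairwise, adjust = adjust
  ), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$kw_h, x$kw_df, x$kw_p))
  cat(sprintf("Dunn pairwise comparisons (%s-adjusted):\n", x$adjust))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
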