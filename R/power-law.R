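# Log-log power-law fitting with bootstrap inference, and the spurious-ratio
# null model for ratio-versus-denominator regressions.

# Vectorized OLS slopes over bootstrap resamples: x, y are n-vectors and idx
# an n x B matrix of resampled row indices.
bootSlopes <- function(x, y, idx) {
  xb <- matrix(x[idx], nrow = nrow(idx))
  yb <- matrix(y[idx], nrow = nrow(idx))
  mx <- colMeans(xb)
  my <- colMeans(yb)
  (colMeans(xb * yb) - mx * my) / (colMeans(xb * xb) - mx * mx)
}

#' Fit a power law by OLS in log10-log10 space
#'
#' Regresses \code{log10(y)} on \code{log10(x)}. Pairs with missing or
#' non-positive values are excluded (and counted). Slope uncertainty is
#' reported two ways: a percentile confidence interval from a nonparametric
#' pair bootstrap, and t-tests of the slope against 0 and against -1 — the
#' exponent a pure hyperbolic ratio-versus-denominator relation (and the
#' linearized uptake kinetics) predict. With a fixed seed the output is
#' reproducible bit for bit.
#'
#' @param x,y paired positive values (e.g. tissue \%P and the As:P ratio).
#' @param nBoot bootstrap replicates (default 10000; 0 skips the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @param basis optional label carried into the report ("weight"/"molar").
#' @param confLevel confidence level for the percentile interval.
#' @return a [PowerLawFit-class].
#' @export
fitPowerLaw <- function(x, y, nBoot = 10000L, seed = 1L, basis = "",
                        confLevel = 0.95) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  excluded <- as.integer(sum(!ok))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("not fittable: fewer than 3 positive finite pairs")
  lx <- log10(x); ly <- log10(y)
  fit <- lm(ly ~ lx)
  cf <- summary(fit)$coefficients
  slope <- unname(cf["lx", "Estimate"])
  se <- unname(cf["lx", "Std. Error"])
  df <- n - 2L
  pZero <- unname(cf["lx", "Pr(>|t|)"])
  pMinusOne <- if (se > 0) 2 * pt(-abs((slope + 1) / se), df) else
    as.numeric(slope == -1)
  r2 <- summary(fit)$r.squared
  ciLow <- ciHigh <- NA_real_
  if (nBoot > 0L) {
    set.seed(childSeed(seed, "pair-bootstrap"))
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
    slopes <- bootSlopes(lx, ly, idx)
    slopes <- slopes[is.finite(slopes)]
    alpha <- (1 - confLevel) / 2
    qs <- quantile(slopes, c(alpha, 1 - alpha), names = FALSE)
    ciLow <- qs[1]; ciHigh <- qs[2]
  }
  new("PowerLawFit",
    slope = slope, intercept = unname(cf["(Intercept)", "Estimate"]),
    ciLow = ciLow, ciHigh = ciHigh, rSquared = r2, n = as.integer(n),
    pVsZero = pZero, pVsMinusOne = pMinusOne, seSlope = se,
    nBoot = as.integer(nBoot), seed = as.integer(seed), basis = basis,
    excludedNonpositive = excluded
  )
}

#' Null distribution of ratio-versus-denominator slopes
#'
#' For independent random variables a and b, a plot of the ratio a:b against
#' b is hyperbolic by construction: regressing \code{log(a/b)} on
#' \code{log(b)} gives slope
#' \eqn{Cov(\log a - \log b, \log b)/Var(\log b) = -1} when a and b are
#' independent. This function simulates that null — independent lognormal
#' a and b — and returns the distribution of fitted slopes, the benchmark
#' against which an observed ratio-denominator slope (e.g. As:P vs \%P)
#' must be compared.
#'
#' @param n points per simulated dataset (>= 10).
#' @param reps number of simulated datasets.
#' @param seed integer seed.
#' @param sdlog_a,sdlog_b lognormal shape parameters of a and b.
#' @return numeric vector of \code{reps} fitted slopes, with attribute
#'   \code{expected} = -1.
#' @export
spuriousRatioNull <- function(n, reps = 200L, seed = 1L,
                              sdlog_a = 0.5, sdlog_b = 0.5) {
  if (n < 10) stop("n must be >= 10")
  set.seed(childSeed(seed, "spurious-ratio-null"))
  slopes <- vapply(seq_len(reps), function(i) {
    a <- rlnorm(n, 0, sdlog_a)
    b <- rlnorm(n, 0, sdlog_b)
    lb <- log10(b)
    lr <- log10(a / b)
    unname(coef(lm(lr ~ lb))[2])
  }, numeric(1))
  attr(slopes, "expected") <- -1
  slopes
}

#' Pairwise associations among As, P, N and C tissue content
#'
#' Pearson correlations (with Fisher-z confidence intervals) among arsenic,
#' \%P, \%N and \%C, together with the companion ratio-versus-denominator
#' power-law fits As:P vs \%P, As:N vs \%N and As:C vs \%C. The fits make the
#' hyperbolic/non-hyperbolic contrast an output: a ratio whose numerator is
#' unrelated to the denominator fits slope about -1 (the pure spurious
#' value), while a mechanistic coupling such as arsenic riding phosphate
#' uptake pushes the As:P slope below -1.
#'
#' @param samples tissue data.frame with \code{as_ug_g, pct_P, pct_N, pct_C}.
#' @param nBoot bootstrap replicates passed to [fitPowerLaw()].
#' @param seed integer seed.
#' @return list with \code{correlations} (data.frame: var1, var2, n, r,
#'   ci_low, ci_high, p, flag) and \code{ratioFits} (named list of
#'   [PowerLawFit-class] for As_vs_P, As_vs_N, As_vs_C).
#' @export
correlationSummary <- function(samples, nBoot = 1000L, seed = 1L) {
  vars <- c(As = "as_ug_g", P = "pct_P", N = "pct_N", C = "pct_C")
  pairs <- t(combn(names(vars), 2))
  correlations <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- samples[[vars[pairs[i, 1]]]]
    b <- samples[[vars[pairs[i, 2]]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) {
      return(data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2],
                        n = sum(ok), r = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        flag = "insufficient pairs",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(cor.test(a[ok], b[ok]))
    ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
    data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2], n = sum(ok),
               r = unname(ct$estimate), ci_low = ci[1], ci_high = ci[2],
               p = ct$p.value, flag = "", stringsAsFactors = FALSE)
  }))
  ratioFit <- function(denom, tag) {
    d <- samples[[denom]]
    a <- samples$as_ug_g / 1e4  # percent dry weight
    ok <- is.finite(a) & is.finite(d) & a > 0 & d > 0
    if (sum(ok) < 3) return(NULL)
    fitPowerLaw(d[ok], a[ok] / d[ok], nBoot = nBoot,
                seed = childSeed(seed, tag), basis = "weight")
  }
  list(
    correlations = correlations,
    ratioFits = list(
      As_vs_P = ratioFit("pct_P", "asp"),
      As_vs_N = ratioFit("pct_N", "asn"),
      As_vs_C = ratioFit("pct_C", "asc")
    )
  )
}
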