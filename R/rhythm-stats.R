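#' 24-hour Fourier coefficient of condition effects
#'
#' For condition effects b_j measured at six equally spaced time points
#' t_j = 0, 4, ..., 20 h, the complex coefficient is
#' \deqn{f = (1/6) \sum_j b_j e^{-i 2\pi t_j / 24}.}
#' With this normalization a pure 24-h cosine of unit amplitude maps to
#' \code{amplitude = 2 |f| = 1}, and the peak time
#' \code{(24 / 2 pi) * atan2(-Im f, Re f) mod 24} recovers the ZT hour of
#' maximal signal.
#'
#' @param b Numeric vector of 6 condition effects, or a matrix with one row
#'   per fragment and 6 time-point columns.
#' @param times ZT hours of the columns; must be 6 equally spaced points
#'   spanning 24 h.
#' @return A list: \code{f} (complex), \code{amplitude}, \code{peak_time}
#'   (each a vector over fragments).
#' @examples
#' t <- seq(0, 20, by = 4)
#' fourier_coefficients(cos(2 * pi * (t - 16) / 24))$peak_time  # 16
#' @export
fourier_coefficients <- function(b, times = seq(0, 20, by = 4)) {
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  if (ncol(b) != length(times)) stop("'b' and 'times' dimensions differ")
  dt <- diff(sort(times))
  if (length(times) != 6L || any(abs(dt - dt[1]) > 1e-9))
    stop("exactly six equally spaced time points are required")
  omega <- 2 * pi / 24
  e <- exp(-1i * omega * times)
  f <- drop(b %*% e) / 6
  list(f = f,
       amplitude = 2 * Mod(f),
       peak_time = (atan2(-Im(f), Re(f)) / omega) %% 24)
}

#' Chi-square test for a 24-h rhythm
#'
#' Tests the null hypothesis that the real and imaginary parts of the Fourier
#' coefficient both have mean zero. Each part is a linear combination of the
#' condition effects, so its variance is propagated from the per-condition
#' standard errors with the cosine/sine weights; the two parts are
#' standardized jointly through their 2 x 2 covariance (which is diagonal for
#' homoscedastic standard errors, the cosine and sine vectors being
#' orthogonal on the equally spaced grid) and the statistic is referred to a
#' chi-square distribution with 2 degrees of freedom.
#'
#' @param b Condition effects (vector of 6, or fragments x 6 matrix).
#' @param se_b Matching standard errors (positive).
#' @param times ZT hours (6 equally spaced).
#' @return Data.frame with one row per fragment: \code{re}, \code{im},
#'   \code{amplitude}, \code{peak_time}, \code{chi2}, \code{p}. Fragments
#'   with 4 or 5 finite standard errors yield \code{NA} statistics; fewer
#'   than 4 is an error.
#' @export
rhythm_test <- function(b, se_b, times = seq(0, 20, by = 4)) {
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  if (is.vector(se_b)) se_b <- matrix(se_b, nrow = 1)
  stopifnot(dim(b) == dim(se_b))
  fc <- fourier_coefficients(b, times)
  if (any(se_b <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  n_ok <- rowSums(is.finite(se_b) & is.finite(b))
  if (any(n_ok < 4))
    stop("fewer than 4 time points with finite standard errors")
  omega <- 2 * pi / 24
  cw <- cos(omega * times) / 6
  sw <- sin(omega * times) / 6
  v <- se_b^2
  V11 <- drop(v %*% cw^2)
  V22 <- drop(v %*% sw^2)
  V12 <- -drop(v %*% (cw * sw))
  x1 <- Re(fc$f); x2 <- Im(fc$f)
  det <- V11 * V22 - V12^2
  chi2 <- (V22 * x1^2 - 2 * V12 * x1 * x2 + V11 * x2^2) / det
  chi2[n_ok < ncol(b)] <- NA_real_
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  data.frame(re = x1, im = x2, amplitude = fc$amplitude,
             peak_time = fc$peak_time, chi2 = chi2, p = p)
}

#' Two-condition differential contact statistics
#'
#' Per-fragment contrast of condition effects, e.g. ZT08 versus ZT20 or wild
#' type versus knockout: \code{delta_b = b1 - b2}, Z-score
#' \code{delta_b / sqrt(se1^2 + se2^2)}, a two-sided p-value from a
#' t-distribution with the local effective degrees of freedom, and the log2
#' fold change \code{delta_b / log10(2)} (the condition effects live on a
#' log10 contact scale).
#'
#' @param b1,b2 Condition effects (vectors over fragments).
#' @param se1,se2 Their standard errors.
#' @param df Degrees of freedom for the t reference (scalar or per-fragment);
#'   \code{Inf} gives a normal reference.
#' @param cov12 Covariance between the two condition-effect estimates
#'   (scalar or per-fragment). When both effects come from one joint
#'   sum-to-zero fit they are negatively coupled and the contrast variance is
#'   \code{se1^2 + se2^2 - 2 cov12}; the default 0 corresponds to
#'   independently fitted conditions.
#' @return Data.frame: \code{delta_b}, \code{z}, \code{p}, \code{log2fc}.
#'   Fragments degenerate on either side yield \code{NA} rows.
#' @export
compare_conditions <- function(b1, b2, se1, se2, df = Inf, cov12 = 0) {
  delta <- b1 - b2
  v <- se1^2 + se2^2 - 2 * cov12
  if (any(v <= 0, na.rm = TRUE)) stop("non-positive contrast variance")
  z <- ifelse(delta == 0, 0, delta / sqrt(v))
  p <- 2 * stats::pt(-abs(z), df = df)
  data.frame(delta_b = delta, z = z, p = p, log2fc = delta / log10(2))
}

#' Flag significantly rhythmic fragments and assign their phase
#'
#' Fragments with rhythm p-value below \code{alpha} (default 0.01, on the raw
#' p-value, matching genome-browser phase-coloring practice) are flagged and
#' carry their estimated peak time; all others carry \code{NA}. An optional
#' Benjamini-Hochberg correction can be switched on.
#'
#' @param results Data.frame from \code{\link{rhythm_test}} (needs columns
#'   \code{p}, \code{peak_time}).
#' @param alpha Significance threshold.
#' @param p_adjust Multiplicity correction passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}).
#' @return The input with added columns \code{rhythmic} (logical) and
#'   \code{color_time} (peak time where rhythmic, else \code{NA}).
#' @export
classify_rhythmic <- function(results, alpha = 0.01, p_adjust = "none") {
  padj <- stats::p.adjust(results$p, method = p_adjust)
  results$rhythmic <- !is.na(padj) & padj < alpha
  results$color_time <- ifelse(results$rhythmic, results$peak_time, NA_real_)
  results
}

#' Rhythm analysis of a smoothed time-course profile
#'
#' Extracts the per-time condition effects of one genotype from a
#' \code{\link{smoothed_profile}}, computes Fourier coefficients, the
#' chi-square rhythm test and the per-time log2 fold-change track (each time
#' point versus the temporal mean).
#'
#' @param profile A \code{\link{smoothed_profile}} fitted over six time-point
#'   conditions.
#' @param genotype Genotype to analyse when the profile holds several
#'   (\code{NULL} = profile conditions are already pure time points).
#' @param alpha Threshold for \code{\link{classify_rhythmic}}.
#' @return Data.frame with one row per unmasked fragment: coordinates,
#'   condition effects, \code{amplitude}, \code{peak_time}, \code{chi2},
#'   \code{p}, \code{rhythmic}, \code{color_time}, and \code{log2fc_ZT*}
#'   columns.
#' @export
rhythm_analysis <- function(profile, genotype = NULL, alpha = 0.01) {
  stopifnot(inherits(profile, "smoothed_profile"))
  tab <- profile$condition_table
  sel <- if (is.null(genotype)) seq_len(nrow(tab)) else which(tab$genotype == genotype)
  if (!length(sel)) stop(sprintf("no conditions for genotype '%s'", genotype))
  times <- tab$time[sel]
  if (anyDuplicated(times)) stop("conditions are not unique time points; pass 'genotype'")
  ord <- order(times)
  sel <- sel[ord]; times <- times[ord]
  keep <- !profile$mask & apply(is.finite(profile$se[, sel, drop = FALSE]), 1, all)
  b <- profile$b[keep, sel, drop = FALSE]
  se <- profile$se[keep, sel, drop = FALSE]
  # recentre on the temporal mean of the selected conditions: when the fit
  # included other genotypes the sum-zero constraint spans all of them
  b <- b - rowMeans(b)
  rt <- rhythm_test(b, se, times)
  rt <- classify_rhythmic(rt, alpha = alpha)
  fc <- b / log10(2)
  colnames(fc) <- sprintf("log2fc_ZT%02d", as.integer(times))
  out <- cbind(profile$map[keep, c("chrom", "start", "end", "id")],
               b, rt, fc)
  rownames(out) <- NULL
  out
}
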