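#' Smoothing weight scheme for the local regression
#'
#' The local fit at a genomic position weights each fragment by a Gaussian
#' kernel in distance (sigma = 2500 bp by default) truncated at
#' \code{truncation_radius}, and each (fragment, condition) cell by a data
#' quality weight equal to the fraction of replicates with a non-zero count.
#'
#' @param sigma Gaussian kernel bandwidth in bp.
#' @param truncation_radius Distance beyond which the kernel weight is set to
#'   exactly 0; must be at least \code{2 * sigma}. Weights beyond the default
#'   4 sigma are below 3.4e-4 and numerically irrelevant.
#' @return A list of class \code{weight_scheme}.
#' @export
weight_scheme <- function(sigma = 2500, truncation_radius = 4 * sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  if (truncation_radius < 2 * sigma)
    stop("'truncation_radius' must be at least 2 * sigma")
  structure(list(sigma = sigma, truncation_radius = truncation_radius),
            class = "weight_scheme")
}

#' Gaussian positional weight
#'
#' Unnormalized kernel: weight 1 at distance 0, \code{exp(-d^2 / (2 sigma^2))}
#' up to the truncation radius, exactly 0 beyond it.
#'
#' @param distance Non-negative distance(s) in bp.
#' @param scheme A \code{\link{weight_scheme}}.
#' @return Numeric weight(s) in \code{[0, 1]}.
#' @examples
#' gaussian_weight(2500, weight_scheme())  # exp(-1/2)
#' @export
gaussian_weight <- function(distance, scheme = weight_scheme()) {
  if (any(distance < 0)) stop("'distance' must be non-negative")
  w <- exp(-distance^2 / (2 * scheme$sigma^2))
  w[distance > scheme$truncation_radius] <- 0
  w
}

#' Condition weight from replicate detection
#'
#' Fragments detected in few replicates of a condition are unreliable; the
#' condition weight is the fraction of that condition's replicates with a
#' non-zero count on the fragment.
#'
#' @param counts Integer vector of replicate counts (one condition, one
#'   fragment).
#' @return Weight in \code{[0, 1]}.
#' @export
condition_weight <- function(counts) {
  if (length(counts) == 0L) stop("no replicates")
  mean(counts > 0)
}

#' Per-(fragment, condition) weight matrix
#'
#' @param counts Integer matrix, fragments x samples.
#' @param condition Factor over samples.
#' @return Matrix fragments x conditions of nonzero-replicate fractions.
#' @export
condition_weights <- function(counts, condition) {
  condition <- as.factor(condition)
  sapply(levels(condition), function(l)
    rowMeans(counts[, condition == l, drop = FALSE] > 0))
}

#' Normalize counts to cis fractions
#'
#' Each sample is scaled by its total count over unmasked fragments, so the
#' unmasked fractions sum to 1 per sample. Masked fragments (bait and flanks)
#' keep a fraction of 0.
#'
#' @param counts Integer matrix, fragments x samples.
#' @param mask Logical mask of excluded fragments (\code{NULL} for none).
#' @return Numeric matrix of fractions, same shape as \code{counts}.
#' @export
normalize_cis <- function(counts, mask = NULL) {
  counts <- as.matrix(counts)
  if (is.null(mask)) mask <- rep(FALSE, nrow(counts))
  tot <- colSums(counts[!mask, , drop = FALSE])
  if (any(tot == 0))
    stop(sprintf("sample(s) with no unmasked counts: %s",
                 paste(colnames(counts)[tot == 0], collapse = ", ")))
  frac <- sweep(counts, 2, tot, "/")
  frac[mask, ] <- 0
  frac
}

#' Variance-stabilizing log transform
#'
#' \code{Y = log10(c * p + 1)} maps contact fractions to a scale on which the
#' replicate variance is approximately constant across the dynamic range;
#' zero counts map to exactly 0.
#'
#' @param c Non-negative contact fraction(s).
#' @param p Pseudo-count scale factor (default 500).
#' @return Transformed value(s) \code{Y >= 0}.
#' @examples
#' variance_stabilize(1 / 500)  # log10(2)
#' @export
variance_stabilize <- function(c, p = 500) {
  if (any(c < 0)) stop("fractions must be non-negative")
  log10(c * p + 1)
}

# Local weighted solve of Y_ijr ~ a_i + b_j under sum(b) = 0.
#
# Inputs are window slices: SY (I x J sums of Y over replicates), SSY (sums of
# squares), R (replicates per condition, length J), W (I x J weights already
# combining kernel and condition weight). Solves the normal equations by
# eliminating the fragment effects (block-diagonal) and reducing to the
# (J - 1)-dimensional sum-zero parametrization.
.lwmr_solve <- function(SY, SSY, R, W) {
  I <- nrow(W); J <- ncol(W)
  WR <- sweep(W, 2, R, "*")          # W_ij * R_j
  A <- rowSums(WR)                   # a-block diagonal
  ok_i <- A > 0
  if (!any(ok_i)) stop("no fragment with positive weight in the window")
  live <- colSums(WR[ok_i, , drop = FALSE]) > 0
  res <- list(b = rep(NA_real_, J), se_b = rep(NA_real_, J),
              degenerate = !live, a = rep(NA_real_, I),
              cov_b = matrix(NA_real_, J, J),
              sigma2 = NA_real_, eff_df = NA_real_, rss = NA_real_)
  SYl <- SY[ok_i, live, drop = FALSE]
  SSYl <- SSY[ok_i, live, drop = FALSE]
  Wl <- W[ok_i, live, drop = FALSE]
  WRl <- WR[ok_i, live, drop = FALSE]
  Rl <- R[live]
  Al <- rowSums(WRl)
  Jl <- sum(live)
  u <- rowSums(Wl * SYl)             # a-block rhs
  v <- colSums(Wl * SYl)             # b-block rhs
  if (Jl >= 2L) {
    C <- stats::contr.sum(Jl)        # sum-zero parametrization
    B <- diag(colSums(WRl), Jl)
    Mt_Dinv_M <- crossprod(WRl / sqrt(Al), WRl / sqrt(Al)) # M' D^-1 M
    S_red <- crossprod(C, (B - Mt_Dinv_M) %*% C)
    rhs <- crossprod(C, v - crossprod(WRl, u / Al))
    qS <- tryCatch(solve(S_red), error = function(e) NULL)
    if (is.null(qS)) {
      res$degenerate[] <- TRUE
      return(res)
    }
    theta <- qS %*% rhs
    b <- drop(C %*% theta)
    Vb_unit <- C %*% qS %*% t(C)     # covariance of b per unit sigma^2
  } else {
    b <- 0
    Vb_unit <- matrix(0, 1, 1)
  }
  a <- (u - drop(WRl %*% b)) / Al
  # weighted residual sum of squares, accumulated from sufficient statistics
  mu <- outer(a, b, "+")
  rss <- sum(Wl * (SSYl - 2 * mu * SYl + sweep(mu^2, 2, Rl, "*")))
  rss <- max(rss, 0)
  sw <- sum(WRl)
  sw2 <- sum(sweep(Wl^2, 2, Rl, "*"))
  eff_df <- max(sw^2 / sw2 - (sum(ok_i) + Jl - 1), 1)
  sigma2 <- rss / eff_df
  se <- sqrt(pmax(diag(Vb_unit) * sigma2, 0))
  res$b[live] <- b
  res$se_b[live] <- se
  res$a[ok_i] <- a
  # full covariance of b: the sum-zero constraint couples the condition
  # effects (strongly negatively for few conditions), and contrasts must
  # account for it
  res$cov_b[live, live] <- Vb_unit * sigma2
  res$sigma2 <- sigma2
  res$eff_df <- eff_df
  res$rss <- rss
  res
}

#' Locally weighted multilinear regression at one position
#'
#' Fits the additive model \code{Y_ijr = a_i + b_j} over the fragments i
#' within the kernel truncation radius of \code{position}, conditions j and
#' replicates r, by minimizing the weighted sum of squared residuals with
#' weights \code{W_ij = w_g(distance_i) * w_s(i, j)}. The fragment effects
#' a_i absorb position-specific ligation/digestion biases; the condition
#' effects b_j (constrained to sum to zero across conditions) carry the
#' biological signal. Standard errors come from the weighted residual
#' variance and the inverse normal-equation matrix, with effective degrees of
#' freedom \code{(sum W)^2 / sum(W^2)} minus the local parameter count
#' (floored at 1).
#'
#' @param Y Numeric matrix of variance-stabilized signal, fragments x
#'   samples.
#' @param map A \code{\link{fragment_map}}.
#' @param condition Factor over samples (see \code{\link{sheet_conditions}}).
#' @param position Genomic position (bp) at which to centre the kernel.
#' @param scheme A \code{\link{weight_scheme}}.
#' @param mask Logical mask of fragments excluded from fitting.
#' @param counts Optional raw count matrix used for the condition weights;
#'   when \code{NULL}, \code{Y > 0} is used as the detection indicator
#'   (equivalent for the canonical transform, where Y = 0 iff count = 0).
#' @return A list: \code{b}, \code{se_b} (per condition; \code{NA} and
#'   flagged in \code{degenerate} for conditions with no weight in the
#'   window), \code{a} (per window fragment), \code{fitted} (smoothed signal
#'   per condition at the position: kernel-weighted mean of a plus b),
#'   \code{sigma2}, \code{eff_df}, \code{window} (fragment indices).
#' @export
fit_lwmr <- function(Y, map, condition, position, scheme = weight_scheme(),
                     mask = NULL, counts = NULL) {
  condition <- as.factor(condition)
  if (is.null(mask)) mask <- rep(FALSE, nrow(map))
  mid <- fragment_mid(map)
  d <- abs(mid - position)
  win <- which(d <= scheme$truncation_radius & !mask)
  if (!length(win)) stop("no unmasked fragment within the truncation radius")
  wg <- gaussian_weight(d[win], scheme)
  lev <- levels(condition)
  J <- length(lev)
  R <- as.numeric(table(condition)[lev])
  det <- if (is.null(counts)) Y[win, , drop = FALSE] > 0 else
    counts[win, , drop = FALSE] > 0
  SY <- SSY <- WS <- matrix(0, length(win), J)
  for (k in seq_len(J)) {
    cols <- condition == lev[k]
    yk <- Y[win, cols, drop = FALSE]
    SY[, k] <- rowSums(yk)
    SSY[, k] <- rowSums(yk^2)
    WS[, k] <- rowMeans(det[, cols, drop = FALSE])
  }
  fit <- .lwmr_solve(SY, SSY, R, wg * WS)
  names(fit$b) <- names(fit$se_b) <- names(fit$degenerate) <- lev
  dimnames(fit$cov_b) <- list(lev, lev)
  names(fit$a) <- map$id[win]
  ok <- is.finite(fit$a)
  fit$fitted <- stats::weighted.mean(fit$a[ok], wg[ok]) + fit$b
  fit$window <- win
  fit
}

#' Smooth a full experiment with the local regression model
#'
#' Runs \code{\link{fit_lwmr}} at the midpoint of every unmasked fragment,
#' assembling per-fragment condition effects, standard errors and smoothed
#' per-condition signal. This is the workhorse producing the
#' fragment-resolution smoothed 4C profiles from which rhythm and
#' differential statistics are computed.
#'
#' @param counts Integer matrix of raw counts, fragments x samples.
#' @param map A \code{\link{fragment_map}} with a bait.
#' @param sheet A \code{\link{sample_sheet}} matching the count columns.
#' @param condition_by Condition grouping passed to
#'   \code{\link{sheet_conditions}}.
#' @param scheme A \code{\link{weight_scheme}}.
#' @param p Variance-stabilization scale (see
#'   \code{\link{variance_stabilize}}).
#' @param n_flank Bait-adjacent fragments masked on each side.
#' @return An object of class \code{smoothed_profile}: list with \code{map},
#'   \code{mask}, \code{condition_table}, and per-fragment matrices/vectors
#'   \code{a}, \code{b}, \code{se}, \code{fitted}, \code{sigma2},
#'   \code{eff_df} (rows = fragments; masked rows are \code{NA}).
#' @export
smooth_profile <- function(counts, map, sheet,
                           condition_by = "genotype_time",
                           scheme = weight_scheme(), p = 500, n_flank = 5) {
  stopifnot(inherits(sheet, "sample_sheet"))
  if (!identical(colnames(counts), sheet$sample_id))
    counts <- counts[, sheet$sample_id, drop = FALSE]
  condition <- sheet_conditions(sheet, by = condition_by)
  cond_tab <- attr(condition, "condition_table")
  mask <- mask_bait_adjacent(map, n_flank)
  frac <- normalize_cis(counts, mask)
  Y <- variance_stabilize(frac, p)
  lev <- levels(condition)
  n <- nrow(map); J <- length(lev)
  b <- se <- fitted <- matrix(NA_real_, n, J, dimnames = list(map$id, lev))
  cov_b <- array(NA_real_, c(n, J, J), dimnames = list(map$id, lev, lev))
  a <- sigma2 <- eff_df <- rep(NA_real_, n)
  mid <- fragment_mid(map)
  # precompute per-condition sufficient statistics once
  R <- as.numeric(table(condition)[lev])
  SY <- SSY <- WS <- matrix(0, n, J)
  for (k in seq_len(J)) {
    cols <- condition == lev[k]
    yk <- Y[, cols, drop = FALSE]
    SY[, k] <- rowSums(yk)
    SSY[, k] <- rowSums(yk^2)
    WS[, k] <- rowMeans(counts[, cols, drop = FALSE] > 0)
  }
  idx_unmasked <- which(!mask)
  tr <- scheme$truncation_radius
  for (q in idx_unmasked) {
    lo <- findInterval(mid[q] - tr, mid, left.open = TRUE) + 1L
    hi <- findInterval(mid[q] + tr, mid)
    win <- (lo:hi)[!mask[lo:hi]]
    wg <- gaussian_weight(abs(mid[win] - mid[q]), scheme)
    fit <- .lwmr_solve(SY[win, , drop = FALSE], SSY[win, , drop = FALSE],
                       R, wg * WS[win, , drop = FALSE])
    b[q, ] <- fit$b
    se[q, ] <- fit$se_b
    cov_b[q, , ] <- fit$cov_b
    ok <- is.finite(fit$a)
    fitted[q, ] <- stats::weighted.mean(fit$a[ok], wg[ok]) + fit$b
    a[q] <- fit$a[win == q]
    sigma2[q] <- fit$sigma2
    eff_df[q] <- fit$eff_df
  }
  structure(list(map = map, mask = mask, condition_table = cond_tab,
                 scheme = scheme, p = p,
                 a = a, b = b, se = se, cov_b = cov_b, fitted = fitted,
                 sigma2 = sigma2, eff_df = eff_df),
            class = "smoothed_profile")
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf("smoothed_profile: %d fragments (%d masked), %d conditions [%s]\n",
              nrow(x$map), sum(x$mask), ncol(x$b),
              paste(colnames(x$b), collapse = ", ")))
  invisible(x)
}
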