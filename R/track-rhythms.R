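#' Bin a coverage track into fixed-width windows
#'
#' Each bin's value is the coverage-weighted mean of the records overlapping
#' it; bins with no overlapping record are \code{NA} (missing, never imputed
#' as zero).
#'
#' @param intervals Data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{value}, sorted by start.
#' @param bin_size Bin width in bp (default 500).
#' @param n_bins Number of bins; defaults to cover \code{max(end)}.
#' @return Data.frame \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @export
bin_signal <- function(intervals, bin_size = 500, n_bins = NULL) {
  if (bin_size <= 0) stop("'bin_size' must be positive")
  if (is.unsorted(intervals$start)) stop("coverage records must be sorted")
  if (is.null(n_bins)) n_bins <- ceiling(max(intervals$end) / bin_size)
  first <- intervals$start %/% bin_size
  last <- (intervals$end - 1) %/% bin_size
  nb <- last - first + 1L
  rec <- rep.int(seq_len(nrow(intervals)), nb)
  bin <- first[rec] + sequence(nb) - 1L
  ov <- pmin(intervals$end[rec], (bin + 1) * bin_size) -
        pmax(intervals$start[rec], bin * bin_size)
  keep <- bin >= 0 & bin < n_bins
  num <- rep(0, n_bins); den <- rep(0, n_bins)
  agg <- rowsum(cbind(intervals$value[rec][keep] * ov[keep], ov[keep]),
                group = bin[keep])
  at <- as.integer(rownames(agg)) + 1L
  num[at] <- agg[, 1]; den[at] <- agg[, 2]
  val <- ifelse(den > 0, num / den, NA_real_)
  starts <- (seq_len(n_bins) - 1) * bin_size
  data.frame(chrom = intervals$chrom[1L], start = starts,
             end = starts + bin_size, value = val)
}

#' Running average over neighbouring bins
#'
#' Smooths a binned track by replacing each bin with the mean of itself and
#' up to \code{half_width} bins on each side (7 bins by default). At track
#' edges the window shrinks to the available bins; missing bins are excluded
#' from the mean and stay missing only when the whole window is missing.
#'
#' @param values Numeric vector of bin values (may contain \code{NA}).
#' @param half_width Bins included on each side.
#' @return Smoothed numeric vector of the same length.
#' @export
running_average <- function(values, half_width = 3) {
  n <- length(values)
  ok <- !is.na(values)
  cs <- cumsum(c(0, ifelse(ok, values, 0)))
  cn <- cumsum(c(0, as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - half_width, 1L); hi <- pmin(i + half_width, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Harmonic regression with a 24-hour period
#'
#' Least-squares fit of \code{value = m + alpha cos(2 pi t / 24) +
#' beta sin(2 pi t / 24)} across time points, per bin. Amplitude is
#' \code{sqrt(alpha^2 + beta^2)}, peak time \code{(24 / 2 pi) atan2(beta,
#' alpha) mod 24}, and the p-value comes from the F-test of the joint null
#' \code{alpha = beta = 0}.
#'
#' @param values Numeric vector over time points, or a matrix with one row
#'   per bin and one column per time point. Rows with missing values are
#'   fitted on their complete time points when at least 3 remain, else
#'   \code{NA}.
#' @param times ZT hours (at least 3 distinct).
#' @return Data.frame per bin: \code{mean}, \code{alpha}, \code{beta},
#'   \code{amplitude}, \code{peak_time}, \code{p}.
#' @export
harmonic_fit <- function(values, times) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) != length(times)) stop("'values' and 'times' dimensions differ")
  if (length(unique(times)) < 3) stop("at least 3 distinct time points required")
  omega <- 2 * pi / 24
  X <- cbind(1, cos(omega * times), sin(omega * times))
  n <- nrow(values)
  out <- data.frame(mean = rep(NA_real_, n), alpha = NA_real_, beta = NA_real_,
                    amplitude = NA_real_, peak_time = NA_real_, p = NA_real_)
  fit_rows <- function(Y, X, rows) {
    # closed-form normal equations, shared design across rows
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) return(invisible(NULL))  # collinear design
    coef <- t(solve(XtX, crossprod(X, t(Y))))
    res <- Y - coef %*% t(X)
    rss1 <- rowSums(res^2)
    rss0 <- rowSums((Y - rowMeans(Y))^2)
    df2 <- ncol(Y) - 3L
    p <- if (df2 > 0) {
      Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
      pv <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
      pv[rss0 - rss1 <= 1e-12 * pmax(rss0, 1)] <- 1
      pmax(pv, 1e-300)
    } else rep(NA_real_, length(rss1))
    out$mean[rows] <<- coef[, 1]
    out$alpha[rows] <<- coef[, 2]
    out$beta[rows] <<- coef[, 3]
    out$amplitude[rows] <<- sqrt(coef[, 2]^2 + coef[, 3]^2)
    out$peak_time[rows] <<- (atan2(coef[, 3], coef[, 2]) / omega) %% 24
    out$p[rows] <<- p
    invisible(NULL)
  }
  complete <- rowSums(is.na(values)) == 0L
  if (any(complete))
    fit_rows(values[complete, , drop = FALSE], X, which(complete))
  for (r in which(!complete)) {
    okc <- !is.na(values[r, ])
    if (sum(okc) >= 3 && length(unique(times[okc])) >= 3)
      fit_rows(values[r, okc, drop = FALSE], X[okc, , drop = FALSE], r)
  }
  out
}

#' Default colour-encoding parameters
#'
#' @param hill_n Hill coefficient of the brightness saturation curves.
#' @param k_a Amplitude half-point (log2 CPM units).
#' @param k_p Half-point of \code{-log10(p)}.
#' @param saturation HSV saturation (fixed to 1 in browser tracks).
#' @return A list of class \code{color_params}.
#' @export
color_params <- function(hill_n = 5, k_a = 0.5, k_p = 4.5, saturation = 1) {
  if (hill_n <= 0 || k_a <= 0 || k_p <= 0) stop("Hill parameters must be positive")
  structure(list(hill_n = hill_n, k_a = k_a, k_p = k_p,
                 saturation = saturation), class = "color_params")
}

#' Hill saturation function
#'
#' \code{v = x^n / (k^n + x^n)}: 0 at \code{x = 0}, 0.5 at \code{x = k},
#' saturating towards 1. With \code{n = 5} the transition is steep, giving
#' smooth but decisive colour transitions between non-rhythmic (dark) and
#' rhythmic (bright) bins.
#'
#' @param x Non-negative statistic (amplitude, or \code{-log10(p)}).
#' @param k Half-point.
#' @param n Hill coefficient.
#' @return Value(s) in \code{[0, 1)}.
#' @examples
#' hill_value(0.5, 0.5)   # 0.5
#' hill_value(1, 0.5)     # 32/33
#' @export
hill_value <- function(x, k, n = 5) {
  if (any(x < 0, na.rm = TRUE)) stop("'x' must be non-negative")
  if (k <= 0) stop("'k' must be positive")
  x^n / (k^n + x^n)
}

#' Brightness of a harmonic fit
#'
#' Overall brightness is the more conservative of two Hill saturations: one
#' in amplitude (half-point \code{k_a}) and one in statistical significance
#' \code{-log10(p)} (half-point \code{k_p}); a bin must be both strongly and
#' significantly rhythmic to appear bright.
#'
#' @param amplitude Fitted amplitudes.
#' @param p Fitted p-values.
#' @param params A \code{\link{color_params}}.
#' @return Brightness value(s) in \code{[0, 1)}.
#' @export
track_brightness <- function(amplitude, p, params = color_params()) {
  pmin(hill_value(amplitude, params$k_a, params$hill_n),
       hill_value(-log10(p), params$k_p, params$hill_n))
}

#' Map peak time and brightness to an RGB colour
#'
#' HSV encoding: hue = peak_time / 24 (ZT0 red, ZT8 green, ZT16 blue, wrapping
#' back to red at ZT24), saturation fixed, value = brightness. Non-rhythmic
#' bins are black regardless of phase.
#'
#' @param peak_time ZT hours in \code{[0, 24)}.
#' @param value Brightness in \code{[0, 1]}.
#' @param params A \code{\link{color_params}}.
#' @return Character vector of hex colours (\code{"#RRGGBB"}).
#' @examples
#' phase_to_color(0, 1)   # "#FF0000"
#' phase_to_color(8, 1)   # "#00FF00"
#' @export
phase_to_color <- function(peak_time, value, params = color_params()) {
  if (any(peak_time < 0 | peak_time >= 24, na.rm = TRUE))
    stop("'peak_time' must lie in [0, 24)")
  grDevices::hsv(h = peak_time / 24, s = params$saturation, v = value)
}

#' Write a phase colour track as BED9
#'
#' One record per interval with \code{itemRgb} carrying the phase colour and
#' the score column carrying \code{round(1000 * brightness)}.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param color Hex colours (from \code{\link{phase_to_color}}).
#' @param brightness Brightness values in \code{[0, 1]}.
#' @param path Output path.
#' @param name Optional record names.
#' @return The path, invisibly.
#' @export
write_color_track <- function(chrom, start, end, color, brightness, path,
                              name = NULL) {
  keep <- !is.na(color) & !is.na(brightness)
  if (is.null(name)) name <- sprintf("bin_%06d", seq_along(start))
  chrom <- rep_len(chrom, length(start))
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start = start[keep] + 1,
                                                end = end[keep]),
                               name = name[keep],
                               score = round(1000 * brightness[keep]),
                               itemRgb = color[keep],
                               thick = IRanges::IRanges(start = start[keep] + 1,
                                                        end = end[keep]))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_color_track
#' @export
read_color_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = gr$name, score = gr$score,
             itemRgb = gr$itemRgb)
}

#' Rhythm analysis of a set of binned temporal tracks
#'
#' Full track pipeline: per-time 7-bin running-average smoothing, per-bin
#' 24-h harmonic regression, Hill brightness and HSV phase colour.
#'
#' @param tracks A \code{binned_track_set} (long data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{time}, \code{value}), e.g.
#'   from \code{\link{simulate_track}} or repeated \code{\link{bin_signal}}
#'   calls. All time points must share the same bin grid.
#' @param half_width Running-average half-width in bins.
#' @param params A \code{\link{color_params}}.
#' @return Data.frame per bin: coordinates, harmonic fit columns,
#'   \code{brightness}, \code{color}.
#' @export
track_rhythm_analysis <- function(tracks, half_width = 3,
                                  params = color_params()) {
  times <- sort(unique(tracks$time))
  grids <- split(tracks$start, tracks$time)
  if (length(unique(lapply(grids, unname))) != 1L)
    stop("inconsistent bin grids across time points")
  bins <- sort(unique(tracks$start))
  M <- sapply(times, function(t) {
    tr <- tracks[tracks$time == t, ]
    running_average(tr$value[order(tr$start)], half_width)
  })
  fit <- harmonic_fit(M, times)
  bsz <- unique(tracks$end - tracks$start)[1L]
  fit$brightness <- track_brightness(fit$amplitude, fit$p, params)
  col <- rep(NA_character_, nrow(fit))
  ok <- !is.na(fit$peak_time) & !is.na(fit$brightness)
  col[ok] <- phase_to_color(fit$peak_time[ok], fit$brightness[ok], params)
  fit$color <- col
  cbind(data.frame(chrom = tracks$chrom[1L], start = bins, end = bins + bsz),
        fit)
}
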