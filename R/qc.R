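#' Mask the bait fragment and its flanking fragments
#'
#' Fragments immediately adjacent to the bait are dominated by partially
#' digested and self-ligated products, so the bait fragment plus
#' \code{n_flank} fragments on each side are excluded from normalization
#' totals and from all model fitting. The window is clipped at chromosome
#' ends.
#'
#' @param map A \code{\link{fragment_map}} with a bait.
#' @param n_flank Number of fragments masked on each side of the bait.
#' @return Logical vector over the map, \code{TRUE} for masked fragments.
#' @examples
#' fm <- fragment_map("chrS", 0:29 * 100, 1:30 * 100, bait_index = 16)
#' sum(mask_bait_adjacent(fm))  # bait + 5 + 5 = 11
#' @export
mask_bait_adjacent <- function(map, n_flank = 5) {
  bi <- .require_bait(map)
  if (n_flank < 0) stop("'n_flank' must be non-negative")
  idx <- max(1L, bi - n_flank):min(nrow(map), bi + n_flank)
  mask <- rep(FALSE, nrow(map))
  mask[idx] <- TRUE
  mask
}

.window_fragments <- function(map, window_half_width) {
  bi <- .require_bait(map)
  mid <- fragment_mid(map)
  inw <- abs(mid - mid[bi]) <= window_half_width
  if (!any(inw)) stop("empty bait window")
  inw
}

#' Quality-control a single 4C-seq sample
#'
#' A library is considered failed when more than \code{max_zero_fraction} of
#' the restriction fragments in a bait-centred window (default +/- 1 Mb, i.e.
#' a 2 Mb region) carry no count at all -- the signature of a failed
#' circularization or very shallow library. QC runs on the full fragment
#' window, before bait-adjacent masking.
#'
#' @param map A \code{\link{fragment_map}} with a bait.
#' @param counts Integer vector of raw counts for one sample, in map order.
#' @param window_half_width Half-width of the QC window in bp.
#' @param max_zero_fraction Failure threshold on the zero-count fraction.
#' @return A one-row data.frame: \code{total_cis}, \code{window_counts},
#'   \code{zero_fraction}, \code{cis_window_fraction}, \code{pass}.
#' @export
qc_sample <- function(map, counts, window_half_width = 1e6,
                      max_zero_fraction = 0.75) {
  if (length(counts) != nrow(map)) stop("counts do not match the fragment map")
  inw <- .window_fragments(map, window_half_width)
  zero_fraction <- mean(counts[inw] == 0)
  total <- sum(counts)
  data.frame(total_cis = total,
             window_counts = sum(counts[inw]),
             zero_fraction = zero_fraction,
             cis_window_fraction = if (total > 0) sum(counts[inw]) / total else NA_real_,
             pass = zero_fraction <= max_zero_fraction)
}

#' Quality-control every sample of a count table
#'
#' @param map A \code{\link{fragment_map}}.
#' @param counts Integer matrix, fragments x samples.
#' @inheritParams qc_sample
#' @return Data.frame with one row per sample (rownames = sample ids).
#' @export
qc_experiment <- function(map, counts, window_half_width = 1e6,
                          max_zero_fraction = 0.75) {
  out <- do.call(rbind, lapply(seq_len(ncol(counts)), function(s)
    qc_sample(map, counts[, s], window_half_width, max_zero_fraction)))
  out <- cbind(data.frame(sample_id = colnames(counts)), out)
  rownames(out) <- NULL
  out
}

#' Fraction of cis counts falling in the bait window
#'
#' Measures how concentrated the 4C signal is around the viewpoint: the
#' ratio of counts on fragments whose midpoint lies within the bait-centred
#' window to all cis counts. Masked fragments are excluded from both
#' numerator and denominator.
#'
#' @param map A \code{\link{fragment_map}}.
#' @param counts Counts for one sample, in map order.
#' @param window_half_width Window half-width in bp.
#' @param mask Logical mask (e.g. from \code{\link{mask_bait_adjacent}});
#'   \code{NULL} for none.
#' @return The fraction in \code{[0, 1]}.
#' @export
cis_window_fraction <- function(map, counts, window_half_width = 1e6,
                                mask = NULL) {
  if (length(counts) != nrow(map)) stop("counts do not match the fragment map")
  inw <- .window_fragments(map, window_half_width)
  keep <- if (is.null(mask)) rep(TRUE, nrow(map)) else !mask
  denom <- sum(counts[keep])
  if (denom == 0) stop("undefined fraction: sample has no cis counts")
  sum(counts[inw & keep]) / denom
}
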