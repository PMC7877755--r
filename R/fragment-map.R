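#' Restriction-fragment map with a designated bait
#'
#' A fragment map is the coordinate universe of a bait-centric 4C-seq
#' analysis: the ordered restriction fragments of the cis chromosome (the
#' chromosome carrying the bait), stored as 0-based half-open intervals, with
#' exactly one fragment flagged as the bait (viewpoint).
#'
#' @param chrom Chromosome name (single string).
#' @param start,end Integer vectors of fragment boundaries, 0-based half-open,
#'   sorted and non-overlapping.
#' @param id Optional character vector of fragment identifiers; defaults to
#'   \code{frag_000001}, ... in map order.
#' @param bait_index Integer index (1-based, in map order) of the bait
#'   fragment, or \code{NA} if no bait is designated yet.
#'
#' @return A \code{data.frame} of class \code{fragment_map} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{id} and attribute
#'   \code{bait_index}.
#' @examples
#' fm <- fragment_map("chrS", c(0, 400, 900), c(400, 900, 1500), bait_index = 2)
#' bait_index(fm)
#' fragment_mid(fm)
#' @export
fragment_map <- function(chrom, start, end, id = NULL, bait_index = NA_integer_) {
  if (length(chrom) != 1L || !is.character(chrom))
    stop("'chrom' must be a single chromosome name")
  n <- length(start)
  if (length(end) != n) stop("'start' and 'end' lengths differ")
  if (n == 0L) stop("fragment map is empty")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start)) stop("every fragment must satisfy start < end")
  if (is.unsorted(start, strictly = TRUE)) stop("fragments must be sorted by start")
  if (any(start[-1L] < end[-n])) stop("fragments overlap")
  if (is.null(id)) id <- sprintf("frag_%06d", seq_len(n))
  if (anyDuplicated(id)) stop("fragment ids must be unique")
  if (!is.na(bait_index)) {
    bait_index <- as.integer(bait_index)
    if (bait_index < 1L || bait_index > n) stop("'bait_index' out of range")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    id = as.character(id), stringsAsFactors = FALSE)
  attr(out, "bait_index") <- bait_index
  class(out) <- c("fragment_map", "data.frame")
  out
}

#' Bait fragment index of a fragment map
#' @param map A \code{\link{fragment_map}}.
#' @return Integer index of the bait fragment (1-based), or \code{NA}.
#' @export
bait_index <- function(map) {
  stopifnot(inherits(map, "fragment_map"))
  attr(map, "bait_index")
}

#' Fragment midpoints
#' @param map A \code{\link{fragment_map}}.
#' @return Numeric vector of fragment midpoints in bp.
#' @export
fragment_mid <- function(map) (map$start + map$end) / 2

.require_bait <- function(map) {
  bi <- bait_index(map)
  if (is.na(bi)) stop("fragment map has no designated bait fragment")
  bi
}

#' @export
print.fragment_map <- function(x, ...) {
  bi <- attr(x, "bait_index")
  cat(sprintf("fragment_map: %d fragments on %s [%d, %d), bait %s\n",
              nrow(x), x$chrom[1L], as.integer(min(x$start)),
              as.integer(max(x$end)),
              if (is.na(bi)) "undesignated" else x$id[bi]))
  invisible(x)
}

# subsetting must not silently drop the bait bookkeeping
#' @export
`[.fragment_map` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- "data.frame"
    attr(out, "bait_index") <- NULL
  }
  out
}
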