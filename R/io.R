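#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

.map_to_granges <- function(map) {
  GenomicRanges::GRanges(map$chrom,
                         IRanges::IRanges(start = map$start + 1, end = map$end),
                         name = map$id)
}

#' Write / read a fragment map as BED4
#'
#' On disk the map is a plain BED4 file (chrom, start, end, fragment id;
#' 0-based half-open). The bait is not encoded in BED; it is re-designated on
#' read via its fragment id (normally taken from the sample sheet's
#' \code{bait} column).
#'
#' @param map A \code{\link{fragment_map}}.
#' @param path Output/input file path.
#' @param bait Fragment id of the bait, or \code{NA} to leave undesignated.
#' @return \code{read_fragment_map} returns a \code{\link{fragment_map}}.
#' @export
write_fragment_map <- function(map, path) {
  rtracklayer::export(.map_to_granges(map), path, format = "bed")
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path, bait = NA) {
  gr <- rtracklayer::import(path, format = "bed")
  id <- gr$name
  bi <- NA_integer_
  if (!is.na(bait)) {
    bi <- match(bait, id)
    if (is.na(bi)) stop(sprintf("bait fragment '%s' not found in %s", bait, path))
  }
  fragment_map(as.character(GenomicRanges::seqnames(gr)[1L]),
               GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
               id = id, bait_index = bi)
}

#' Write / read a count table as wide TSV
#'
#' Column 1 is \code{fragment_id}; remaining columns are samples.
#'
#' @param counts Integer matrix (fragments x samples) with fragment ids as
#'   rownames.
#' @param path File path.
#' @return \code{read_count_table} returns an integer matrix.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(fragment_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "fragment_id") stop("count table must start with a 'fragment_id' column")
  m <- as.matrix(df[-1L])
  if (any(m < 0)) stop("negative counts in count table")
  storage.mode(m) <- "integer"
  rownames(m) <- df$fragment_id
  m
}

#' Read a fragment map together with its counts
#'
#' Validates that every fragment id in the count table resolves against the
#' map and reorders the counts into map order.
#'
#' @param map_path BED4 fragment map.
#' @param counts_path Wide TSV count table.
#' @param bait Bait fragment id (optional).
#' @return List with elements \code{map} and \code{counts}.
#' @export
read_fragment_counts <- function(map_path, counts_path, bait = NA) {
  map <- read_fragment_map(map_path, bait = bait)
  counts <- read_count_table(counts_path)
  unknown <- setdiff(rownames(counts), map$id)
  if (length(unknown))
    stop(sprintf("fragment id(s) not in map: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  full <- matrix(0L, nrow(map), ncol(counts),
                 dimnames = list(map$id, colnames(counts)))
  full[rownames(counts), ] <- counts
  list(map = map, counts = full)
}

#' Write / read a sample sheet as TSV
#' @param sheet A \code{\link{sample_sheet}}.
#' @param path File path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "time", "replicate", "bait")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("sample sheet is missing column(s): %s", paste(miss, collapse = ", ")))
  sample_sheet(df$sample_id, df$genotype, df$time, df$replicate, df$bait)
}

#' Write a per-interval score track as bedGraph
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval coordinates.
#' @param score Numeric scores; intervals with non-finite score are dropped.
#' @param path Output path.
#' @export
write_bedgraph <- function(chrom, start, end, score, path) {
  keep <- is.finite(score)
  chrom <- rep_len(chrom, length(start))
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start = start[keep] + 1,
                                                end = end[keep]),
                               score = score[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             score = gr$score)
}
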