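#' Sample sheet for a 4C-seq experiment
#'
#' One row per sequencing library: genotype (e.g. wild type versus a clock
#' knockout), Zeitgeber time (ZT, hours after lights-on), replicate number and
#' bait name. The (genotype, time, replicate) triple must be unique.
#'
#' @param sample_id Character vector of sample identifiers (must match count
#'   table columns).
#' @param genotype Character vector, typically \code{"WT"} or \code{"KO"}.
#' @param time Numeric Zeitgeber times in hours, in \code{[0, 24)}.
#' @param replicate Integer replicate index within (genotype, time).
#' @param bait Bait name; recycled if scalar. Should match the id of the bait
#'   fragment in the accompanying fragment map.
#' @return A \code{data.frame} of class \code{sample_sheet}.
#' @examples
#' sample_sheet_grid(times = c(8, 20), n_replicates = 2)
#' @export
sample_sheet <- function(sample_id, genotype, time, replicate, bait = "bait") {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  time <- as.numeric(time)
  if (any(time < 0 | time >= 24)) stop("times must lie in [0, 24)")
  sheet <- data.frame(sample_id = as.character(sample_id),
                      genotype = as.character(genotype),
                      time = time,
                      replicate = as.integer(replicate),
                      bait = as.character(bait),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sheet[c("genotype", "time", "replicate")]))
    stop("(genotype, time, replicate) must be unique")
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Build a full-factorial sample sheet
#'
#' @param genotypes Character vector of genotypes.
#' @param times Numeric ZT hours.
#' @param n_replicates Replicates per (genotype, time).
#' @param bait Bait name.
#' @return A \code{\link{sample_sheet}} with one row per combination.
#' @export
sample_sheet_grid <- function(genotypes = "WT", times = seq(0, 20, by = 4),
                              n_replicates = 3, bait = "bait") {
  g <- expand.grid(replicate = seq_len(n_replicates), time = times,
                   genotype = genotypes, stringsAsFactors = FALSE)
  sample_sheet(
    sample_id = sprintf("%s_ZT%02d_r%d", g$genotype, as.integer(g$time), g$replicate),
    genotype = g$genotype, time = g$time, replicate = g$replicate, bait = bait)
}

#' Condition labels for model fitting
#'
#' The smoothing model estimates one condition effect per experimental
#' condition. A condition is a genotype--time combination by default; for a
#' single-genotype time course this reduces to the time point.
#'
#' @param sheet A \code{\link{sample_sheet}}.
#' @param by One of \code{"genotype_time"}, \code{"time"}, \code{"genotype"}.
#' @return A factor over the sheet rows; its levels carry a
#'   \code{condition_table} attribute (data.frame of level, genotype, time --
#'   time is \code{NA} when not part of the label).
#' @export
sheet_conditions <- function(sheet, by = c("genotype_time", "time", "genotype")) {
  by <- match.arg(by)
  lab <- switch(by,
    genotype_time = {
      if (length(unique(sheet$genotype)) == 1L)
        sprintf("ZT%02d", as.integer(sheet$time))
      else
        sprintf("%s_ZT%02d", sheet$genotype, as.integer(sheet$time))
    },
    time = sprintf("ZT%02d", as.integer(sheet$time)),
    genotype = sheet$genotype)
  f <- factor(lab, levels = unique(lab[order(sheet$genotype, sheet$time)]))
  tab <- unique(data.frame(level = lab,
                           genotype = if (by == "time") NA_character_ else sheet$genotype,
                           time = if (by == "genotype") NA_real_ else sheet$time,
                           stringsAsFactors = FALSE))
  tab <- tab[match(levels(f), tab$level), , drop = FALSE]
  rownames(tab) <- NULL
  attr(f, "condition_table") <- tab
  f
}
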