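# Non-overlapping window composition: repeat proportion and GC% of the
# repetitive and non-repetitive fractions along each chromosome.

#' Windowed composition of one chromosome
#'
#' Tiles `[0, length)` with non-overlapping windows of `window_size` bases
#' (the last window may be shorter; it is kept at its true length so that
#' window totals conserve the chromosome length) and counts, per window, the
#' repetitive, non-repetitive and ambiguous bases and the GC bases of each
#' unambiguous fraction.
#'
#' A fraction's GC% is `NA` ("missing") whenever that fraction has no bases
#' in the window; it is never reported as 0 for an empty fraction. Windows
#' whose unambiguous content falls below `min_unambiguous` are flagged
#' low-confidence but retained, so conservation invariants still hold.
#'
#' @param chrom A [masked_chromosome()].
#' @param window_size Window size in bases (>= 1). Default 100 kb.
#' @param min_unambiguous Minimum unambiguous fraction of a window (0-1)
#'   below which the window is flagged low-confidence.
#' @return A [tibble::tibble()] with one row per window: `chromosome`,
#'   `start`, `end` (0-based half-open), `n_total`, `n_repeat`,
#'   `n_nonrepeat`, `n_ambiguous`, `repeat_fraction` (% of unambiguous
#'   bases), `gc_repeat`, `gc_nonrepeat`, `gc_total` (%), `low_confidence`.
#' @export
window_chromosome <- function(chrom, window_size = 1e5, min_unambiguous = 0.5) {
  stopifnot(inherits(chrom, "masked_chromosome"))
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      is.na(window_size) || window_size < 1) {
    stop("window_size must be a single number >= 1")
  }
  window_size <- as.integer(window_size)
  len <- chrom$length
  codes <- .base_codes(chrom$seq)
  gc <- .gc_flags(chrom$seq)

  # cumulative counts allow every window's totals in O(1)
  cum_rep <- cumsum(codes == 1L)
  cum_non <- cumsum(codes == 2L)
  cum_amb <- cumsum(codes == 3L)
  cum_gc_rep <- cumsum(gc & codes == 1L)
  cum_gc_non <- cumsum(gc & codes == 2L)

  starts <- seq.int(0L, len - 1L, by = window_size)
  ends <- pmin(starts + window_size, len)
  at <- function(cum, i) ifelse(i > 0L, cum[pmax(i, 1L)], 0L)
  win <- function(cum) at(cum, ends) - at(cum, starts)

  n_repeat <- win(cum_rep)
  n_nonrepeat <- win(cum_non)
  n_ambiguous <- win(cum_amb)
  gc_rep_n <- win(cum_gc_rep)
  gc_non_n <- win(cum_gc_non)
  n_unamb <- n_repeat + n_nonrepeat
  n_total <- ends - starts

  tibble::tibble(
    chromosome = chrom$name,
    start = starts,
    end = as.integer(ends),
    n_total = as.integer(n_total),
    n_repeat = as.integer(n_repeat),
    n_nonrepeat = as.integer(n_nonrepeat),
    n_ambiguous = as.integer(n_ambiguous),
    repeat_fraction = ifelse(n_unamb > 0, 100 * n_repeat / n_unamb, NA_real_),
    gc_repeat = ifelse(n_repeat > 0, 100 * gc_rep_n / n_repeat, NA_real_),
    gc_nonrepeat = ifelse(n_nonrepeat > 0, 100 * gc_non_n / n_nonrepeat,
                          NA_real_),
    gc_total = ifelse(n_unamb > 0, 100 * (gc_rep_n + gc_non_n) / n_unamb,
                      NA_real_),
    low_confidence = n_unamb < min_unambiguous * n_total
  )
}

#' Window profiles for a whole assembly
#'
#' Runs [window_chromosome()] independently on every chromosome at one
#' window size. The same assembly can be profiled at several resolutions by
#' repeated calls; base-weighted aggregate GC is identical across window
#' sizes because the underlying counts are conserved.
#'
#' @param genome A `masked_genome` or nonempty list of [masked_chromosome()].
#' @inheritParams window_chromosome
#' @return A [tibble::tibble()] of window rows for all chromosomes, in input
#'   chromosome order.
#' @export
profile_assembly <- function(genome, window_size = 1e5, min_unambiguous = 0.5) {
  if (length(genome) == 0L) {
    stop("cannot profile an empty assembly")
  }
  dplyr::bind_rows(lapply(genome, window_chromosome,
                          window_size = window_size,
                          min_unambiguous = min_unambiguous))
}

#' Write a window profile as TSV
#'
#' Deterministic plain-text export of a profile table; identical input yields
#' byte-identical output.
#'
#' @param profile Output of [profile_assembly()] or [window_chromosome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(profile, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Export one profile column as bedGraph
#'
#' @param profile Output of [profile_assembly()].
#' @param column Name of the numeric column to export (e.g. `"gc_total"`).
#' @param path Output path (`.bedgraph`). Windows with a missing value are
#'   omitted, as bedGraph has no missing-data representation.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, column, path) {
  if (!column %in% names(profile) || !is.numeric(profile[[column]])) {
    stop("no numeric column '", column, "' in profile")
  }
  keep <- !is.na(profile[[column]])
  gr <- GenomicRanges::GRanges(
    seqnames = profile$chromosome[keep],
    ranges = IRanges::IRanges(start = profile$start[keep] + 1L,
                              end = profile$end[keep]),
    score = profile[[column]][keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
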