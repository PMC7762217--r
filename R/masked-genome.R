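# Soft-masked assembly I/O and per-base classification.
#
# Soft-masking convention: lowercase a/c/g/t marks repetitive sequence,
# uppercase A/C/G/T non-repetitive sequence; any other IUPAC letter (either
# case, N included) is ambiguous and excluded from GC and repeat-fraction
# denominators.

# byte lookup tables: class 0 = invalid, 1 = repeat, 2 = non-repeat,
# 3 = ambiguous; gc marks unambiguous G/C of either case
.base_luts <- local({
  cls <- integer(256L)
  gc <- logical(256L)
  idx <- function(ch) as.integer(charToRaw(ch)) + 1L
  for (ch in c("a", "c", "g", "t")) cls[idx(ch)] <- 1L
  for (ch in c("A", "C", "G", "T")) cls[idx(ch)] <- 2L
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  for (ch in c(amb, tolower(amb))) cls[idx(ch)] <- 3L
  for (ch in c("g", "c", "G", "C")) gc[idx(ch)] <- TRUE
  list(cls = cls, gc = gc)
})

# integer class codes (1/2/3 as above) for one sequence string
.base_codes <- function(seq) {
  .base_luts$cls[as.integer(charToRaw(seq)) + 1L]
}

.gc_flags <- function(seq) {
  .base_luts$gc[as.integer(charToRaw(seq)) + 1L]
}

#' Construct a soft-masked chromosome
#'
#' A `masked_chromosome` carries one assembly sequence together with its
#' per-base classification: repetitive (lowercase a/c/g/t), non-repetitive
#' (uppercase A/C/G/T) or ambiguous (any other IUPAC letter, e.g. N in
#' assembly gaps). Ambiguous bases are excluded from every GC and
#' repeat-fraction denominator.
#'
#' @param name Chromosome identifier (first word of the FASTA header).
#' @param seq Sequence as a single character string, case preserved.
#' @return An object of class `masked_chromosome` with elements `name`,
#'   `length` and `seq`.
#' @export
masked_chromosome <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    stop("chromosome '", name, "' has zero length")
  }
  codes <- .base_codes(seq)
  if (any(codes == 0L)) {
    bad <- unique(strsplit(seq, "")[[1]][codes == 0L])
    stop("chromosome '", name, "' contains non-IUPAC characters: ",
         paste(dQuote(bad, FALSE), collapse = ", "))
  }
  structure(
    list(name = name, length = nchar(seq), seq = seq),
    class = "masked_chromosome"
  )
}

#' @export
print.masked_chromosome <- function(x, ...) {
  cnt <- base_class_counts(x)
  cat(sprintf(
    "<masked_chromosome> %s: %s bp (%d repeat, %d non-repeat, %d ambiguous)\n",
    x$name, format(x$length, big.mark = ","),
    cnt[["repeat"]], cnt[["nonrepeat"]], cnt[["ambiguous"]]))
  invisible(x)
}

#' Per-base classification of a masked chromosome
#'
#' @param chrom A [masked_chromosome()].
#' @return Character vector of length `chrom$length` with values `"repeat"`,
#'   `"nonrepeat"` or `"ambiguous"`.
#' @export
base_classes <- function(chrom) {
  stopifnot(inherits(chrom, "masked_chromosome"))
  c("repeat", "nonrepeat", "ambiguous")[.base_codes(chrom$seq)]
}

#' @rdname base_classes
#' @return For `base_class_counts`, a named integer vector with components
#'   `repeat`, `nonrepeat` and `ambiguous` summing to the chromosome length.
#' @export
base_class_counts <- function(chrom) {
  stopifnot(inherits(chrom, "masked_chromosome"))
  codes <- .base_codes(chrom$seq)
  c("repeat" = sum(codes == 1L),
    nonrepeat = sum(codes == 2L),
    ambiguous = sum(codes == 3L))
}

#' Read a soft-masked FASTA assembly
#'
#' Reads a (possibly line-wrapped) FASTA file, preserving letter case, and
#' returns the chromosomes that pass the length and name filters in input
#' order. Excluded sequences are reported with a message. Sequence names are
#' the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param min_length Minimum sequence length in bases; shorter records are
#'   dropped. The default of 1 Mb discards unplaced scaffolds so that only
#'   assembled chromosomes remain.
#' @param name_filter Optional regular expression; sequences whose name does
#'   not match are dropped.
#' @return A `masked_genome`: a named list of [masked_chromosome()] objects.
#' @export
read_masked_fasta <- function(path, min_length = 1e6, name_filter = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records found in ", path)
  }
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  keep <- rep(TRUE, length(set))
  lens <- Biostrings::width(set)
  short <- lens < min_length
  if (any(short)) {
    message("dropping ", sum(short), " sequence(s) below ", min_length,
            " bp: ", paste(nms[short], collapse = ", "))
    keep <- keep & !short
  }
  if (!is.null(name_filter)) {
    miss <- !grepl(name_filter, nms)
    if (any(miss & keep)) {
      message("dropping ", sum(miss & keep),
              " sequence(s) failing name filter: ",
              paste(nms[miss & keep], collapse = ", "))
    }
    keep <- keep & !miss
  }
  chroms <- lapply(which(keep), function(i) {
    masked_chromosome(nms[i], as.character(set[[i]]))
  })
  names(chroms) <- nms[keep]
  structure(chroms, class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf("<masked_genome> %d chromosome(s), %s bp total\n",
              length(x), format(sum(chromosome_lengths(x)), big.mark = ",")))
  invisible(x)
}

#' Write a masked genome back to FASTA
#'
#' Letter case (and therefore the repeat annotation) is preserved, so a
#' write/read round trip reproduces identical per-base classes.
#'
#' @param genome A `masked_genome` or list of [masked_chromosome()].
#' @param path Output FASTA path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_masked_fasta <- function(genome, path, width = 80L) {
  seqs <- Biostrings::BStringSet(vapply(genome, `[[`, "", "seq"))
  names(seqs) <- vapply(genome, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a masked genome
#'
#' @param genome A `masked_genome`.
#' @return Named integer vector of lengths in bases.
#' @export
chromosome_lengths <- function(genome) {
  vapply(genome, function(ch) as.integer(ch$length), integer(1))
}

#' Assembly-level composition summary
#'
#' GC content and the repeat fraction are computed over unambiguous bases
#' only; N-rich assembly gaps therefore do not dilute GC%. If an assembly has
#' no unambiguous bases its GC is undefined and reported as `NA`, never 0.
#'
#' @param genome A `masked_genome` or nonempty list of [masked_chromosome()].
#' @return A one-row [tibble::tibble()] with columns `n_chromosomes`,
#'   `total_length`, `gc_percent_overall` (% of unambiguous bases that are
#'   G/C), `repeat_fraction` (% of unambiguous bases that are repetitive) and
#'   `ambiguous_fraction` (% of all bases).
#' @export
summarize_assembly <- function(genome) {
  if (length(genome) == 0L) {
    stop("cannot summarize an empty assembly")
  }
  tot <- n_rep <- n_non <- n_amb <- n_gc <- 0
  for (ch in genome) {
    stopifnot(inherits(ch, "masked_chromosome"))
    codes <- .base_codes(ch$seq)
    tot <- tot + ch$length
    n_rep <- n_rep + sum(codes == 1L)
    n_non <- n_non + sum(codes == 2L)
    n_amb <- n_amb + sum(codes == 3L)
    n_gc <- n_gc + sum(.gc_flags(ch$seq))
  }
  n_unamb <- n_rep + n_non
  tibble::tibble(
    n_chromosomes = length(genome),
    total_length = tot,
    gc_percent_overall = if (n_unamb > 0) 100 * n_gc / n_unamb else NA_real_,
    repeat_fraction = if (n_unamb > 0) 100 * n_rep / n_unamb else NA_real_,
    ambiguous_fraction = 100 * n_amb / tot
  )
}

#' Read annotation features from BED
#'
#' Parses a 3+ column BED file (0-based half-open coordinates, as stored
#' internally throughout the package) into a feature table. When a
#' chromosome set is supplied, features are validated against chromosome
#' names and bounds.
#'
#' @param path Path to a BED file (3-6 columns).
#' @param chromosomes Optional `masked_genome` or named vector of chromosome
#'   lengths used to validate feature bounds.
#' @return A [tibble::tibble()] with columns `chromosome`, `start`, `end`
#'   (0-based half-open) and `label` (BED name column, `NA` if absent).
#' @export
read_bed <- function(path, chromosomes = NULL) {
  lines <- readLines(path, warn = FALSE)
  content <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(content)) {
    return(tibble::tibble(chromosome = character(), start = integer(),
                          end = integer(), label = character()))
  }
  # pre-validate so malformed intervals are reported with their line number
  for (i in which(content)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("BED line ", i, ": fewer than 3 tab-separated fields")
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop("BED line ", i, ": non-numeric start/end")
    }
    if (s < 0 || s >= e) {
      stop("BED line ", i, ": invalid interval [", f[2], ", ", f[3],
           ") (need 0 <= start < end)")
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  feats <- tibble::tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  )
  if (!is.null(chromosomes)) {
    lens <- if (inherits(chromosomes, "masked_genome")) {
      chromosome_lengths(chromosomes)
    } else {
      chromosomes
    }
    line_no <- which(content)
    for (j in seq_len(nrow(feats))) {
      chr <- feats$chromosome[j]
      if (!chr %in% names(lens)) {
        stop("BED line ", line_no[j], ": unknown chromosome '", chr, "'")
      }
      if (feats$end[j] > lens[[chr]]) {
        stop("BED line ", line_no[j], ": feature end ", feats$end[j],
             " beyond end of ", chr, " (", lens[[chr]], " bp)")
      }
    }
  }
  feats
}
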