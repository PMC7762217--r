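# Independent oracles and fixture builders used across the suite.

# Brute-force per-base window counter: walks the sequence one character at
# a time, never touching the package's lookup tables or cumulative sums.
naive_window_stats <- function(seq, window_size) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  starts <- seq(0, len - 1, by = window_size)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_size, len)
    n_rep <- n_non <- n_amb <- gc_rep <- gc_non <- 0L
    for (i in (s + 1):e) {
      ch <- chars[i]
      if (ch %in% c("a", "c", "g", "t")) {
        n_rep <- n_rep + 1L
        if (ch %in% c("g", "c")) gc_rep <- gc_rep + 1L
      } else if (ch %in% c("A", "C", "G", "T")) {
        n_non <- n_non + 1L
        if (ch %in% c("G", "C")) gc_non <- gc_non + 1L
      } else {
        n_amb <- n_amb + 1L
      }
    }
    data.frame(start = s, end = e, n_repeat = n_rep, n_nonrepeat = n_non,
               n_ambiguous = n_amb, gc_bases_repeat = gc_rep,
               gc_bases_nonrepeat = gc_non)
  })
  do.call(rbind, rows)
}

# Random soft-masked sequence with some ambiguous letters mixed in.
random_masked_seq <- function(len, p_ambiguous = 0.05) {
  alphabet <- c("a", "c", "g", "t", "A", "C", "G", "T")
  amb <- c("N", "n", "R", "y")
  probs <- c(rep((1 - p_ambiguous) / 8, 8),
             rep(p_ambiguous / length(amb), length(amb)))
  paste(sample(c(alphabet, amb), len, replace = TRUE, prob = probs),
        collapse = "")
}

# Minimal FASTA writer independent of the package's writer.
write_fasta_raw <- function(seqs, path, wrap = NULL) {
  lines <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    body <- if (is.null(wrap)) {
      s
    } else {
      substring(s, seq(1, nchar(s), wrap),
                pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    }
    c(paste0(">", nm), body)
  }))
  writeLines(lines, path)
}

# A chromosome of pure uppercase bases at an exact GC layout: `gc_percents`
# gives the GC content (0-100, multiples applicable to window_size) of each
# consecutive window.
strata_chromosome <- function(name, gc_percents, window_size) {
  blocks <- vapply(gc_percents, function(p) {
    n_gc <- round(window_size * p / 100)
    paste(c(rep("G", n_gc), rep("A", window_size - n_gc)), collapse = "")
  }, "")
  masked_chromosome(name, paste(blocks, collapse = ""))
}
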