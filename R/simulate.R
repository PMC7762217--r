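# Seeded generators: soft-masked genomes with controlled composition,
# genome-record tables with controlled size-vs-GC trends, annotation
# features, and karyotype records with injected inconsistencies. Every
# generator is byte-deterministic under a fixed seed, and each emits a
# "truth" record of the realized (not merely targeted) composition so that
# expected values of downstream statistics can be computed without
# re-reading any output file.

#' Specification of a synthetic soft-masked genome
#'
#' The generated genome is partitioned into alternating repetitive and
#' non-repetitive blocks with geometrically distributed lengths (mimicking
#' interspersed repeats and exercising window-boundary handling). Within
#' each fraction, bases are drawn i.i.d. at that fraction's GC target with G
#' and C (and A and T) equally likely; ambiguous bases (N) are overlaid
#' independently at the target rate. Repetitive bases are written lowercase.
#'
#' @param chromosome_lengths Integer vector of chromosome lengths in bases.
#' @param repeat_fraction Target proportion of the genome that is
#'   repetitive, in `[0, 1]`.
#' @param repeat_block_mean Mean repetitive block length in bases
#'   (geometric).
#' @param gc_repeat,gc_nonrepeat Target GC proportion of each fraction, in
#'   `[0, 1]`.
#' @param n_fraction Target proportion of ambiguous (N) bases.
#' @param seed Integer seed; identical specs and seeds yield byte-identical
#'   output.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(chromosome_lengths = c(3e6, 2e6, 1e6),
                        repeat_fraction = 0.5,
                        repeat_block_mean = 500,
                        gc_repeat = 0.55,
                        gc_nonrepeat = 0.42,
                        n_fraction = 0.01,
                        seed = 1L) {
  props <- c(repeat_fraction, gc_repeat, gc_nonrepeat, n_fraction)
  if (any(is.na(props)) || any(props < 0) || any(props > 1)) {
    stop("all proportions must lie in [0, 1]")
  }
  if (any(chromosome_lengths < 1)) {
    stop("chromosome lengths must be positive")
  }
  if (repeat_block_mean >= min(chromosome_lengths)) {
    stop("infeasible spec: repeat_block_mean (", repeat_block_mean,
         ") must be smaller than the shortest chromosome (",
         min(chromosome_lengths), ")")
  }
  if (repeat_fraction > 0 && repeat_fraction < 1) {
    nonrep_mean <- repeat_block_mean * (1 - repeat_fraction) / repeat_fraction
    if (nonrep_mean < 1) {
      stop("infeasible spec: implied non-repeat block mean below 1 bp; ",
           "lower repeat_fraction or raise repeat_block_mean")
    }
  }
  structure(
    list(chromosome_lengths = as.integer(chromosome_lengths),
         repeat_fraction = repeat_fraction,
         repeat_block_mean = repeat_block_mean,
         gc_repeat = gc_repeat,
         gc_nonrepeat = gc_nonrepeat,
         n_fraction = n_fraction,
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# alternating repeat (TRUE) / non-repeat (FALSE) state per base
.repeat_states <- function(len, spec) {
  f <- spec$repeat_fraction
  if (f == 0) return(rep(FALSE, len))
  if (f == 1) return(rep(TRUE, len))
  mean_rep <- spec$repeat_block_mean
  mean_non <- mean_rep * (1 - f) / f
  # draw enough geometric blocks to cover the chromosome
  states <- logical(0)
  start_rep <- stats::runif(1) < f
  while (length(states) < len) {
    k <- max(64L, ceiling(2 * len / (mean_rep + mean_non)))
    rep_len <- stats::rgeom(k, 1 / mean_rep) + 1L
    non_len <- stats::rgeom(k, 1 / mean_non) + 1L
    lens <- as.vector(rbind(rep_len, non_len))
    vals <- rep(c(TRUE, FALSE), k)
    if (!start_rep) {
      lens <- as.vector(rbind(non_len, rep_len))
      vals <- rep(c(FALSE, TRUE), k)
    }
    states <- c(states, rep(vals, lens))
  }
  states[seq_len(len)]
}

.draw_bases <- function(is_repeat, spec) {
  len <- length(is_repeat)
  gc_p <- ifelse(is_repeat, spec$gc_repeat, spec$gc_nonrepeat)
  is_gc <- stats::runif(len) < gc_p
  pick <- stats::runif(len) < 0.5
  # codes: 1 g, 2 c, 3 a, 4 t (lowercase = repeat); 5-8 uppercase; 9 N
  code <- ifelse(is_gc, ifelse(pick, 1L, 2L), ifelse(pick, 3L, 4L))
  code <- code + ifelse(is_repeat, 0L, 4L)
  if (spec$n_fraction > 0) {
    code[stats::runif(len) < spec$n_fraction] <- 9L
  }
  c("g", "c", "a", "t", "G", "C", "A", "T", "N")[code]
}

#' Generate a synthetic soft-masked genome
#'
#' Draws a genome from a [genome_spec()] and records the realized per-base
#' composition as truth tables. Optionally writes the genome as soft-masked
#' FASTA and the truth as TSV sidecars.
#'
#' @param spec A [genome_spec()].
#' @param fasta Optional output FASTA path.
#' @param truth_prefix Optional path prefix for truth sidecars; writes
#'   `<prefix>_chromosomes.tsv` and `<prefix>_windows.tsv`.
#' @param truth_window_size Window size in bases for the per-window truth
#'   table.
#' @return A list of class `synthetic_genome`: `genome` (a `masked_genome`),
#'   `truth` (per-chromosome realized counts: repeat/non-repeat/ambiguous
#'   bases and GC bases per fraction), `window_truth` (the same per window,
#'   computed by a direct per-base pass at generation time), `spec`, and any
#'   paths written.
#' @export
generate_genome <- function(spec, fasta = NULL, truth_prefix = NULL,
                            truth_window_size = 1e5) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    chroms <- list()
    truth <- list()
    wtruth <- list()
    for (i in seq_along(spec$chromosome_lengths)) {
      len <- spec$chromosome_lengths[i]
      nm <- paste0("chr", i)
      is_repeat <- .repeat_states(len, spec)
      chars <- .draw_bases(is_repeat, spec)
      chroms[[nm]] <- masked_chromosome(nm, paste(chars, collapse = ""))
      is_n <- chars == "N"
      is_gc <- chars %in% c("g", "c", "G", "C")
      rep_eff <- is_repeat & !is_n
      non_eff <- !is_repeat & !is_n
      truth[[nm]] <- tibble::tibble(
        chromosome = nm, length = len,
        n_repeat = sum(rep_eff), n_nonrepeat = sum(non_eff),
        n_ambiguous = sum(is_n),
        gc_bases_repeat = sum(is_gc & rep_eff),
        gc_bases_nonrepeat = sum(is_gc & non_eff)
      )
      starts <- seq.int(0L, len - 1L, by = as.integer(truth_window_size))
      ends <- pmin(starts + as.integer(truth_window_size), len)
      bin <- findInterval(seq_len(len) - 1L, starts)
      tab <- function(x) as.integer(tapply(x, bin, sum))
      wtruth[[nm]] <- tibble::tibble(
        chromosome = nm, start = starts, end = as.integer(ends),
        n_repeat = tab(rep_eff), n_nonrepeat = tab(non_eff),
        n_ambiguous = tab(is_n),
        gc_bases_repeat = tab(is_gc & rep_eff),
        gc_bases_nonrepeat = tab(is_gc & non_eff)
      )
    }
  })
  genome <- structure(chroms, class = "masked_genome")
  out <- list(genome = genome,
              truth = dplyr::bind_rows(truth),
              window_truth = dplyr::bind_rows(wtruth),
              spec = spec)
  if (!is.null(fasta)) {
    write_masked_fasta(genome, fasta)
    out$fasta <- fasta
  }
  if (!is.null(truth_prefix)) {
    readr::write_tsv(out$truth, paste0(truth_prefix, "_chromosomes.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$window_truth, paste0(truth_prefix, "_windows.tsv"),
                     progress = FALSE)
    out$truth_paths <- paste0(truth_prefix,
                              c("_chromosomes.tsv", "_windows.tsv"))
  }
  class(out) <- "synthetic_genome"
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> seed", x$spec$seed, "\n")
  print(x$genome)
  invisible(x)
}

#' Specification of a two-group genome-record trend table
#'
#' Each group draws genome sizes log-uniformly within its size range and
#' GC% as `intercept + slope * log10(size) + Gaussian noise`, clipped to
#' (0, 100). The default size range spans one decade (300-3000 Mb),
#' matching the spread of chromosome-level teleost assemblies.
#'
#' @param groups A data frame with one row per group and columns `group`,
#'   `n` (>= 3), `size_min`, `size_max` (Mb), `slope` (% GC per log10 Mb),
#'   `intercept` (% GC at 1 Mb), `noise_sd` (%).
#' @param seed Integer seed.
#' @return A list of class `trend_spec`.
#' @export
trend_spec <- function(groups = tibble::tibble(
                         group = c("focal", "other"),
                         n = c(50L, 50L),
                         size_min = 300, size_max = 3000,
                         slope = c(2, -2),
                         intercept = c(35, 48),
                         noise_sd = 1),
                       seed = 1L) {
  need <- c("group", "n", "size_min", "size_max", "slope", "intercept",
            "noise_sd")
  if (!all(need %in% names(groups))) {
    stop("groups needs columns: ", paste(need, collapse = ", "))
  }
  if (any(groups$n < 3)) {
    stop("each group needs n >= 3 records")
  }
  if (any(groups$noise_sd < 0)) {
    stop("noise_sd must be >= 0")
  }
  if (any(groups$size_min <= 0 | groups$size_max < groups$size_min)) {
    stop("size ranges must satisfy 0 < size_min <= size_max")
  }
  structure(list(groups = tibble::as_tibble(groups), seed = as.integer(seed)),
            class = "trend_spec")
}

#' Generate a genome-record table with controlled trends
#'
#' @param spec A [trend_spec()].
#' @param path Optional output TSV path for the record table.
#' @param truth_path Optional output TSV path recording the generating
#'   parameters per group.
#' @return A list of class `synthetic_trend`: `records` (tibble `species`,
#'   `group`, `genome_size` in Mb, `gc_percent`), `truth` (the generating
#'   parameters), `spec`.
#' @export
generate_trend_table <- function(spec, path = NULL, truth_path = NULL) {
  stopifnot(inherits(spec, "trend_spec"))
  records <- withr::with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$groups)), function(i) {
      g <- spec$groups[i, ]
      size <- 10^stats::runif(g$n, log10(g$size_min), log10(g$size_max))
      gc <- g$intercept + g$slope * log10(size) +
        stats::rnorm(g$n, 0, g$noise_sd)
      gc <- pmin(pmax(gc, 1e-6), 100 - 1e-6)
      tibble::tibble(
        species = sprintf("%s_sp_%03d", g$group, seq_len(g$n)),
        group = g$group,
        genome_size = size,
        gc_percent = gc
      )
    })
    dplyr::bind_rows(rows)
  })
  out <- list(records = records, truth = spec$groups, spec = spec)
  if (!is.null(path)) {
    readr::write_tsv(records, path, progress = FALSE)
    out$path <- path
  }
  if (!is.null(truth_path)) {
    readr::write_tsv(spec$groups, truth_path, progress = FALSE)
    out$truth_path <- truth_path
  }
  class(out) <- "synthetic_trend"
  out
}

#' Generate random annotation features on a genome
#'
#' Convenience generator of BED-style features (e.g. stand-ins for rDNA
#' sites) placed uniformly on the given chromosomes.
#'
#' @param genome A `masked_genome` or named vector of chromosome lengths.
#' @param n Number of features.
#' @param width Feature width in bases.
#' @param label Feature label.
#' @param seed Integer seed.
#' @return A feature tibble as from [read_bed()].
#' @export
generate_features <- function(genome, n = 2L, width = 5000L,
                              label = "5S_rDNA", seed = 1L) {
  lens <- if (inherits(genome, "masked_genome")) {
    chromosome_lengths(genome)
  } else {
    genome
  }
  withr::with_seed(seed, {
    chr <- sample(names(lens), n, replace = TRUE)
    start <- vapply(chr, function(cn) {
      as.integer(floor(stats::runif(1, 0, max(1, lens[[cn]] - width))))
    }, integer(1))
    tibble::tibble(chromosome = chr, start = start,
                   end = as.integer(pmin(start + width, lens[chr])),
                   label = label)
  })
}

#' Inject inconsistencies into karyotype records
#'
#' Perturbs a fraction of the fully single-valued, internally consistent
#' rows of a karyotype table with one of three errors: NF shifted by +/- 2,
#' bi-armed and uni-armed counts swapped, or 2n shifted by 2. Rows with
#' ranged or missing counts are left untouched (an injected error there
#' would not be detectable as an inconsistency). The truth labels list
#' exactly which rows were perturbed and how, so detection by
#' [validate_record()] can be scored against them.
#'
#' @param records A table from [load_karyotype_table()].
#' @param error_rate Probability that an eligible row is perturbed, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: `records` (perturbed copy, formulas re-parsed) and
#'   `perturbed` (tibble `row`, `type`).
#' @export
perturb_karyotype_records <- function(records, error_rate, seed = 1L) {
  if (is.na(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("error_rate must lie in [0, 1]")
  }
  eligible <- vapply(seq_len(nrow(records)), function(i) {
    f <- records$formula[[i]]
    all(vapply(f, .count_is_single, logical(1))) &&
      f$biarmed$lo != f$uniarmed$lo &&
      nrow(validate_record(f)) == 0L
  }, logical(1))
  out <- records
  labels <- tibble::tibble(row = integer(), type = character())
  withr::with_seed(seed, {
    hit <- eligible & stats::runif(nrow(records)) < error_rate
    types <- c("nf_shift", "swap_arms", "two_n_shift")
    for (i in which(hit)) {
      type <- sample(types, 1)
      f <- records$formula[[i]]
      if (type == "nf_shift") {
        out$nf[i] <- as.character(f$nf$lo + sample(c(-2, 2), 1))
      } else if (type == "swap_arms") {
        out$m_sm[i] <- .format_count(f$uniarmed)
        out$st_a[i] <- .format_count(f$biarmed)
      } else {
        out$two_n[i] <- as.character(f$two_n$lo + 2)
      }
      labels <- dplyr::bind_rows(labels,
                                 tibble::tibble(row = i, type = type))
    }
  })
  out$formula <- lapply(seq_len(nrow(out)), function(i) {
    parse_formula(out$two_n[i], out$m_sm[i], out$st_a[i], out$nf[i])
  })
  out$nf_computed <- lapply(out$formula, compute_nf)
  list(records = out, perturbed = labels)
}
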