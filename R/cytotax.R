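# Karyotype arithmetic and the curated brown-trout (genus Salmo) karyotype
# review table.
#
# Chromosome morphology follows Levan's classes: metacentric (m) and
# submetacentric (sm) chromosomes are bi-armed; subtelocentric (st) and
# acrocentric (a) chromosomes are scored uni-armed. The fundamental number
# NF (Nombre Fondamental, the chromosome-arm count) is then
# NF = 2 * (m + sm) + (st + a).
#
# Count cells in the review table use three notations: a plain integer, a
# range "lo-hi" (an observed range across individuals), and a split "x/y"
# meaning both subclasses were determined (m/sm, or st/a). Ranges are kept
# in printed order (some sources print "62-60"); arithmetic uses min/max.

.parse_count <- function(token) {
  raw <- if (is.null(token) || length(token) == 0L) NA_character_ else token
  txt <- if (is.na(raw)) "" else trimws(raw)
  out <- list(text = txt, kind = "missing", a = NA_real_, b = NA_real_,
              lo = NA_real_, hi = NA_real_, parts = NULL)
  if (txt == "" || txt == "/") {
    return(out)
  }
  norm <- gsub("–|—", "-", txt)  # en/em dash -> hyphen
  if (grepl("^[0-9]+$", norm)) {
    v <- as.numeric(norm)
    out[c("kind", "a", "b", "lo", "hi")] <- list("single", v, v, v, v)
  } else if (grepl("^[0-9]+-[0-9]+$", norm)) {
    ab <- as.numeric(strsplit(norm, "-", fixed = TRUE)[[1]])
    out[c("kind", "a", "b")] <- list("range", ab[1], ab[2])
    out$lo <- min(ab)
    out$hi <- max(ab)
  } else if (grepl("^[0-9]+/[0-9]+$", norm)) {
    parts <- as.numeric(strsplit(norm, "/", fixed = TRUE)[[1]])
    v <- sum(parts)
    out[c("kind", "a", "b", "lo", "hi")] <- list("split", v, v, v, v)
    out$parts <- parts
  } else {
    stop("unparsable chromosome-count token: ", dQuote(txt, FALSE))
  }
  out
}

.format_count <- function(x) {
  switch(x$kind,
         missing = x$text,
         single = format(x$a, scientific = FALSE),
         range = paste0(x$a, "-", x$b),
         split = paste(x$parts, collapse = "/"))
}

.count_is_single <- function(x) x$kind %in% c("single", "split")

#' Parse a karyotype formula
#'
#' Parses the four printed cells of a karyotype record — diploid number (2n),
#' bi-armed count (m + sm), uni-armed count (st + a) and fundamental number
#' (NF) — into a structured formula. Notations: a plain integer; `"lo-hi"`
#' for an observed range (the printed order is preserved even when reversed);
#' `"x/y"` for a split where both subclasses were determined (e.g. `"14/8"`
#' is 14 m + 8 sm, a bi-armed total of 22); an empty cell or a lone `"/"`
#' for a value that was not reported.
#'
#' @param two_n_text,biarmed_text,uniarmed_text,nf_text The printed cell
#'   texts (character, possibly `NA`).
#' @return An object of class `karyotype_formula` with components `two_n`,
#'   `biarmed`, `uniarmed`, `nf`, each a parsed count with fields `text`,
#'   `kind` (`"single"`, `"range"`, `"split"`, `"missing"`), `lo`, `hi` and,
#'   for splits, `parts`.
#' @export
parse_formula <- function(two_n_text, biarmed_text, uniarmed_text, nf_text) {
  structure(
    list(two_n = .parse_count(two_n_text),
         biarmed = .parse_count(biarmed_text),
         uniarmed = .parse_count(uniarmed_text),
         nf = .parse_count(nf_text)),
    class = "karyotype_formula"
  )
}

#' @export
format.karyotype_formula <- function(x, ...) {
  vapply(x, .format_count, "")
}

#' @export
print.karyotype_formula <- function(x, ...) {
  f <- format(x)
  cat(sprintf("<karyotype_formula> 2n = %s; m/sm = %s; st/a = %s; NF = %s\n",
              f[["two_n"]], f[["biarmed"]], f[["uniarmed"]], f[["nf"]]))
  invisible(x)
}

#' Fundamental number from a karyotype formula
#'
#' NF = 2 * bi-armed + uni-armed, with st and a chromosomes scored as
#' uni-armed. Ranges propagate by interval arithmetic (minimum with minima,
#' maximum with maxima).
#'
#' @param formula A [parse_formula()] result, or anything coercible via
#'   `parse_formula` when `biarmed`/`uniarmed` are given as the two
#'   arguments of the convenience form `compute_nf(biarmed, uniarmed)`.
#' @param uniarmed Optional uni-armed count for the convenience form.
#' @return A single number when both counts are single-valued, a length-2
#'   numeric `c(lo, hi)` when a range is involved, and `NA` ("not
#'   computable") when either count is missing.
#' @export
compute_nf <- function(formula, uniarmed = NULL) {
  if (!inherits(formula, "karyotype_formula")) {
    if (is.null(uniarmed)) {
      stop("compute_nf needs a karyotype_formula or (biarmed, uniarmed)")
    }
    formula <- parse_formula(NA, as.character(formula),
                             as.character(uniarmed), NA)
  }
  b <- formula$biarmed
  u <- formula$uniarmed
  if (b$kind == "missing" || u$kind == "missing") {
    return(NA_real_)
  }
  lo <- 2 * b$lo + u$lo
  hi <- 2 * b$hi + u$hi
  if (lo == hi) lo else c(lo, hi)
}

#' Diploid number from per-category pair counts
#'
#' 2n = 2 * (total pairs), summed over morphology categories. Categories can
#' be split (e.g. two acrocentric size classes passed as separate entries).
#'
#' @param pairs Non-negative numeric vector of chromosome *pair* counts, one
#'   entry per category (names optional).
#' @return The diploid chromosome number 2n.
#' @export
compute_2n <- function(pairs) {
  if (any(is.na(pairs)) || any(pairs < 0)) {
    stop("pair counts must be non-negative and non-missing")
  }
  2 * sum(pairs)
}

#' Fundamental number from per-category chromosome counts
#'
#' Computes NF from counts of metacentric (m), submetacentric (sm),
#' subtelocentric (st) and acrocentric (a) chromosomes (not pairs). Under
#' the default scoring st and a are uni-armed. Some of the older literature
#' scores subtelocentrics as bi-armed, which inflates NF; `st_biarmed =
#' TRUE` reproduces that alternative so both conventions can be reported
#' side by side, but subtelocentrics are never promoted silently.
#'
#' @param m,sm,st,a Chromosome counts per morphology class.
#' @param st_biarmed Score subtelocentrics as bi-armed (alternative
#'   literature convention). Default `FALSE`.
#' @return The arm count NF.
#' @export
nf_from_counts <- function(m = 0, sm = 0, st = 0, a = 0, st_biarmed = FALSE) {
  counts <- c(m, sm, st, a)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("chromosome counts must be non-negative and non-missing")
  }
  biarmed <- m + sm + if (st_biarmed) st else 0
  uniarmed <- a + if (st_biarmed) 0 else st
  2 * biarmed + uniarmed
}

# is interval [alo, ahi] contained in [blo, bhi]?
.within <- function(alo, ahi, blo, bhi) alo >= blo && ahi <= bhi

.finding <- function(rule, severity, message) {
  tibble::tibble(rule = rule, severity = severity, message = message)
}

#' Consistency check of one karyotype record
#'
#' Validates the internal arithmetic of a record: the bi-armed and uni-armed
#' counts must sum to 2n, and the reported NF must equal the NF recomputed
#' under the uni-armed scoring of st/a. For ranged cells the reported
#' interval must lie within the interval-arithmetic bounds of the computed
#' one. Each check yields a finding naming the rule and the values involved;
#' findings with severity `"mismatch"` are genuine inconsistencies, findings
#' with severity `"info"` mark values that could not be checked (missing
#' counts). No check throws.
#'
#' @param record Either a `karyotype_formula` or a list/one-row tibble with
#'   a `formula` element (as in [load_karyotype_table()] rows).
#' @return A [tibble::tibble()] of findings: `rule`, `severity`, `message`.
#'   Zero rows mean the record is internally consistent.
#' @export
validate_record <- function(record) {
  f <- if (inherits(record, "karyotype_formula")) {
    record
  } else if (!is.null(record$formula)) {
    if (is.list(record$formula) &&
        !inherits(record$formula, "karyotype_formula")) {
      record$formula[[1]]
    } else {
      record$formula
    }
  } else {
    stop("record has no karyotype formula")
  }
  findings <- .finding(character(), character(), character())
  b <- f$biarmed
  u <- f$uniarmed
  counts_known <- b$kind != "missing" && u$kind != "missing"

  if (!counts_known) {
    findings <- dplyr::bind_rows(findings, .finding(
      "counts_missing", "info",
      "bi-armed and/or uni-armed counts not reported; 2n and NF not checkable"
    ))
    return(findings)
  }
  sum_lo <- b$lo + u$lo
  sum_hi <- b$hi + u$hi
  if (f$two_n$kind != "missing" &&
      !.within(f$two_n$lo, f$two_n$hi, sum_lo, sum_hi)) {
    findings <- dplyr::bind_rows(findings, .finding(
      "two_n_vs_arm_sum", "mismatch",
      sprintf("2n = %s but bi-armed + uni-armed = %s + %s = %s",
              .format_count(f$two_n), .format_count(b), .format_count(u),
              if (sum_lo == sum_hi) sum_lo else paste0(sum_lo, "-", sum_hi))
    ))
  }
  nf <- compute_nf(f)
  nf_lo <- nf[1]
  nf_hi <- nf[length(nf)]
  if (f$nf$kind == "missing") {
    findings <- dplyr::bind_rows(findings, .finding(
      "nf_missing", "info",
      sprintf("NF not reported; computed NF = %s",
              if (nf_lo == nf_hi) nf_lo else paste0(nf_lo, "-", nf_hi))
    ))
  } else if (!.within(f$nf$lo, f$nf$hi, nf_lo, nf_hi)) {
    findings <- dplyr::bind_rows(findings, .finding(
      "nf_vs_computed", "mismatch",
      sprintf(
        "reported NF = %s but 2*(m/sm) + (st/a) = 2*%s + %s = %s",
        .format_count(f$nf), .format_count(b), .format_count(u),
        if (nf_lo == nf_hi) nf_lo else paste0(nf_lo, "-", nf_hi))
    ))
  }
  findings
}

#' Load the packaged brown-trout karyotype review table
#'
#' The package ships a cell-for-cell transcription of the literature review
#' of Palearctic trout (genus *Salmo*) karyotypes: species/form, locality,
#' country, number of examined individuals, 2n, bi-armed (m/sm) and
#' uni-armed (st/a) counts, NF, reference ids and note codes. Count cells
#' keep the printed notation (ranges as `lo-hi`, splits as `x/y`); the
#' `taxon_flag` column carries the `*` marker (material analysed under the
#' name *S. trutta* but likely another *Salmo* species) and
#' `individuals_flag` the dagger marker (counts pooled over two taxa).
#'
#' @param path Path to a karyotype table TSV; defaults to the packaged
#'   fixture.
#' @return A [tibble::tibble()] with the printed columns plus a `formula`
#'   list-column of [parse_formula()] objects and an `nf_computed`
#'   list-column.
#' @export
load_karyotype_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "salmo_karyotypes.tsv",
                        package = "virtukaryo", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  needed <- c("basin", "species_or_form", "two_n", "m_sm", "st_a", "nf")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("karyotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$formula <- lapply(seq_len(nrow(tab)), function(i) {
    parse_formula(tab$two_n[i], tab$m_sm[i], tab$st_a[i], tab$nf[i])
  })
  tab$nf_computed <- lapply(tab$formula, compute_nf)
  tab
}

#' Aggregate report over a karyotype record table
#'
#' @param records A table from [load_karyotype_table()] (or a compatible
#'   subset).
#' @return A list of class `karyotype_summary`: `n_records`; `two_n_mode`
#'   (modal diploid number over single-valued records); `two_n_counts`
#'   (tibble of single-valued 2n tallies); `n_two_n_ranges` (records whose
#'   2n is an observed range, counted separately); `nf_range` (`c(min, max)`
#'   over reported or computed NF); `basin_counts`; `note_counts`.
#' @export
summarize_table <- function(records) {
  if (nrow(records) == 0L) {
    stop("cannot summarize an empty record table")
  }
  two_n <- lapply(records$formula, `[[`, "two_n")
  single <- vapply(two_n, .count_is_single, logical(1))
  vals <- vapply(two_n[single], `[[`, numeric(1), "lo")
  tally <- sort(table(vals), decreasing = TRUE)
  two_n_counts <- tibble::tibble(two_n = as.numeric(names(tally)),
                                 n = as.integer(tally))
  nf_bounds <- lapply(records$formula, function(f) {
    if (f$nf$kind != "missing") {
      c(f$nf$lo, f$nf$hi)
    } else {
      nf <- compute_nf(f)
      if (all(is.na(nf))) NULL else range(nf)
    }
  })
  nf_bounds <- do.call(rbind, nf_bounds)
  basin_counts <- if ("basin" %in% names(records)) {
    dplyr::count(records, .data$basin, name = "n")
  } else {
    tibble::tibble(basin = character(), n = integer())
  }
  notes <- if ("notes" %in% names(records)) {
    toks <- unlist(strsplit(records$notes[!is.na(records$notes)], ";\\s*"))
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    tbl <- sort(table(toks), decreasing = TRUE)
    tibble::tibble(note = names(tbl), n = as.integer(tbl))
  } else {
    tibble::tibble(note = character(), n = integer())
  }
  structure(
    list(n_records = nrow(records),
         two_n_mode = as.numeric(names(tally))[1],
         two_n_counts = two_n_counts,
         n_two_n_ranges = sum(!single &
                                vapply(two_n, function(x) x$kind == "range",
                                       logical(1))),
         nf_range = if (is.null(nf_bounds)) c(NA_real_, NA_real_) else
           c(min(nf_bounds[, 1]), max(nf_bounds[, 2])),
         basin_counts = basin_counts,
         note_counts = notes),
    class = "karyotype_summary"
  )
}

#' @export
print.karyotype_summary <- function(x, ...) {
  cat(sprintf(
    "<karyotype_summary> %d records; modal 2n = %g (%d range-valued); NF %g-%g\n",
    x$n_records, x$two_n_mode, x$n_two_n_ranges,
    x$nf_range[1], x$nf_range[2]))
  if (nrow(x$basin_counts) > 0) {
    cat("records per basin:\n")
    for (i in seq_len(nrow(x$basin_counts))) {
      cat(sprintf("  %-45s %d\n", x$basin_counts$basin[i],
                  x$basin_counts$n[i]))
    }
  }
  invisible(x)
}

#' Validate every record of a karyotype table
#'
#' @param records A table from [load_karyotype_table()].
#' @return A [tibble::tibble()] with one row per finding: `row`,
#'   `species_or_form`, `locality` plus the [validate_record()] columns.
#' @export
validate_table <- function(records) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    fnd <- validate_record(records$formula[[i]])
    if (nrow(fnd) == 0L) {
      return(NULL)
    }
    fnd$row <- i
    fnd$species_or_form <- records$species_or_form[i]
    fnd$locality <- if ("locality" %in% names(records)) {
      records$locality[i]
    } else {
      NA_character_
    }
    fnd[, c("row", "species_or_form", "locality", "rule", "severity",
            "message")]
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    tibble::tibble(row = integer(), species_or_form = character(),
                   locality = character(), rule = character(),
                   severity = character(), message = character())
  } else {
    out
  }
}
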