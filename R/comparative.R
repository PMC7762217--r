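# Genome size vs GC% comparison between a focal group (salmonids by
# default) and the remaining records (other teleosts).

# genera of Salmonidae; the default focal-group membership rule is a match
# of the species name's genus against this list
.salmonid_genera <- c(
  "Salmo", "Oncorhynchus", "Salvelinus", "Coregonus", "Thymallus",
  "Hucho", "Brachymystax", "Parahucho", "Stenodus", "Prosopium",
  "Salvethymus"
)

#' Load and curate a genome-record table
#'
#' Reads a TSV of species-level genome records in the dialect of the NCBI
#' genome browse export and applies the curation rules: rows with a missing
#' GC value are dropped; when an assembly-level column is mapped, rows not at
#' chromosome level (or better) are dropped; duplicated species keep the
#' first row. Every drop is logged with its reason and kept in the
#' `"dropped"` attribute of the result, so curation is transparent and
#' idempotent.
#'
#' @param path Path to a tab-separated table.
#' @param columns Named list mapping the roles `species`, `size`, `gc` and
#'   optionally `level` to column names in the file. Defaults follow the
#'   NCBI genome browse export headers.
#' @param size_unit `"Mb"` (default) or `"bp"`; sizes in bp are converted to
#'   Mb (bp / 1e6).
#' @param chromosome_levels Values of the level column accepted as
#'   chromosome-level.
#' @return A [tibble::tibble()] of `GenomeRecord`s with columns `species`,
#'   `genome_size` (Mb) and `gc_percent`, plus attribute `dropped` (tibble of
#'   `species`, `reason`).
#' @export
load_genome_table <- function(path,
                              columns = list(species = "#Organism Name",
                                             size = "Size(Mb)",
                                             gc = "GC%",
                                             level = "Level"),
                              size_unit = c("Mb", "bp"),
                              chromosome_levels = c("Chromosome",
                                                    "Complete Genome")) {
  size_unit <- match.arg(size_unit)
  raw <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  required <- c("species", "size", "gc")
  for (role in required) {
    if (is.null(columns[[role]]) || !columns[[role]] %in% names(raw)) {
      stop("cannot map required column for '", role, "': expected a header ",
           if (is.null(columns[[role]])) "mapping" else
             paste0("named ", dQuote(columns[[role]], FALSE)),
           "; available: ", paste(names(raw), collapse = ", "))
    }
  }
  rec <- tibble::tibble(
    species = as.character(raw[[columns$species]]),
    genome_size = suppressWarnings(as.numeric(raw[[columns$size]])),
    gc_percent = suppressWarnings(as.numeric(raw[[columns$gc]]))
  )
  if (size_unit == "bp") {
    rec$genome_size <- rec$genome_size / 1e6
  }
  dropped <- tibble::tibble(species = character(), reason = character())
  note <- function(who, why) {
    dropped <<- dplyr::bind_rows(dropped,
                                 tibble::tibble(species = who, reason = why))
  }
  keep <- rep(TRUE, nrow(rec))
  bad_gc <- is.na(rec$gc_percent)
  if (any(bad_gc)) {
    note(rec$species[bad_gc], "missing GC")
    keep <- keep & !bad_gc
  }
  if (!is.null(columns$level) && columns$level %in% names(raw)) {
    lvl <- as.character(raw[[columns$level]])
    bad_lvl <- !(lvl %in% chromosome_levels) & keep
    if (any(bad_lvl)) {
      note(rec$species[bad_lvl],
           paste0("not chromosome-level (", lvl[bad_lvl], ")"))
      keep <- keep & !bad_lvl
    }
  }
  dup <- duplicated(rec$species) & keep
  if (any(dup)) {
    note(rec$species[dup], "duplicate species (first kept)")
    keep <- keep & !dup
  }
  bad_size <- keep & (is.na(rec$genome_size) | rec$genome_size <= 0)
  if (any(bad_size)) {
    note(rec$species[bad_size], "missing or non-positive size")
    keep <- keep & !bad_size
  }
  out <- rec[keep, ]
  if (nrow(dropped) > 0) {
    message("curation dropped ", nrow(dropped), " record(s): ",
            paste(unique(dropped$reason), collapse = "; "))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Assign records to the focal or other group
#'
#' @param records Genome-record tibble with a `species` column.
#' @param focal_species Either a character vector of species names, or a
#'   single regular expression matched against species names. The default
#'   matches the genus against the salmonid genera.
#' @return `records` with a `group` column (`"focal"` / `"other"`).
#' @export
assign_groups <- function(records, focal_species = NULL) {
  if (is.null(focal_species)) {
    pattern <- paste0("^(", paste(.salmonid_genera, collapse = "|"), ")\\b")
    focal <- grepl(pattern, records$species)
  } else if (length(focal_species) == 1L && !focal_species %in%
             records$species) {
    focal <- grepl(focal_species, records$species)
  } else {
    focal <- records$species %in% focal_species
  }
  records$group <- ifelse(focal, "focal", "other")
  records
}

#' Per-group genome-size vs GC% trends
#'
#' For each group, correlates GC% against log10 genome size (Pearson and
#' Spearman) and fits the least-squares line GC% ~ log10(size in Mb); the
#' slope is therefore in percentage points of GC per tenfold change in
#' genome size. A difference-of-slopes report states whether the focal
#' group's slope sign opposes the other group's, with the slope difference
#' and its standard error from the interaction model.
#'
#' @param records Genome-record tibble with columns `species`, `genome_size`
#'   (Mb), `gc_percent` and either a `group` column or `focal_species` to
#'   derive one (see [assign_groups()]).
#' @param focal_species Passed to [assign_groups()] when `records` has no
#'   `group` column.
#' @return An object of class `group_trends`: list with `trends` (tibble:
#'   `group`, `n`, `pearson_r`, `pearson_p`, `spearman_rho`, `slope`,
#'   `slope_se`, `intercept`, `p_value`, `degenerate`) and `comparison`
#'   (list: `slope_difference`, `se`, `opposite_sign`).
#' @export
group_trends <- function(records, focal_species = NULL) {
  if (!"group" %in% names(records)) {
    records <- assign_groups(records, focal_species)
  }
  records$log_size <- log10(records$genome_size)
  groups <- sort(unique(records$group))
  rows <- lapply(groups, function(g) {
    d <- records[records$group == g, ]
    if (nrow(d) < 3) {
      stop("group '", g, "' has ", nrow(d),
           " record(s); at least 3 are required for a trend")
    }
    degenerate <- stats::sd(d$log_size) == 0 || stats::sd(d$gc_percent) == 0
    if (degenerate) {
      return(tibble::tibble(group = g, n = nrow(d), pearson_r = NA_real_,
                            pearson_p = NA_real_, spearman_rho = NA_real_,
                            slope = NA_real_, slope_se = NA_real_,
                            intercept = NA_real_, p_value = NA_real_,
                            degenerate = TRUE))
    }
    ct <- stats::cor.test(d$log_size, d$gc_percent, method = "pearson")
    rho <- stats::cor(d$log_size, d$gc_percent, method = "spearman")
    fit <- stats::lm(gc_percent ~ log_size, data = d)
    sm <- summary(fit)$coefficients
    tibble::tibble(
      group = g, n = nrow(d),
      pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
      spearman_rho = rho,
      slope = sm["log_size", "Estimate"],
      slope_se = sm["log_size", "Std. Error"],
      intercept = sm["(Intercept)", "Estimate"],
      p_value = sm["log_size", "Pr(>|t|)"],
      degenerate = FALSE
    )
  })
  trends <- dplyr::bind_rows(rows)
  comparison <- NULL
  if (all(c("focal", "other") %in% trends$group) &&
      !any(trends$degenerate)) {
    sf <- trends$slope[trends$group == "focal"]
    so <- trends$slope[trends$group == "other"]
    ifit <- stats::lm(gc_percent ~ log_size * group, data = records)
    ico <- summary(ifit)$coefficients
    irow <- grep(":", rownames(ico), value = TRUE)
    comparison <- list(
      slope_difference = sf - so,
      se = unname(ico[irow, "Std. Error"]),
      opposite_sign = sign(sf) * sign(so) == -1
    )
  }
  structure(list(trends = trends, comparison = comparison),
            class = "group_trends")
}

#' @export
print.group_trends <- function(x, ...) {
  cat("<group_trends>\n")
  print(x$trends)
  if (!is.null(x$comparison)) {
    cat(sprintf("focal - other slope: %.3f %% / log10(Mb) (SE %.3f); %s\n",
                x$comparison$slope_difference, x$comparison$se,
                if (x$comparison$opposite_sign) {
                  "slopes have opposite signs"
                } else {
                  "slopes share a sign"
                }))
  }
  invisible(x)
}

#' Scatter plot of GC% against genome size by group
#'
#' Points coloured by group on a log10 genome-size axis, with per-group
#' least-squares trend lines from [group_trends()]. The plotted point table
#' is written next to the image as a deterministic TSV.
#'
#' @param records Genome-record tibble with a `group` column (or
#'   `focal_species`).
#' @param trends Optional [group_trends()] result; computed when omitted and
#'   both groups have enough records.
#' @param output_prefix Path prefix; writes `<prefix>.pdf`, `<prefix>.png`
#'   and `<prefix>_points.tsv`.
#' @param focal_species Passed to [assign_groups()] when needed.
#' @return Invisibly, list with `plot`, `images`, `table`.
#' @export
render_scatter <- function(records, trends = NULL, output_prefix,
                           focal_species = NULL) {
  if (nrow(records) == 0L) {
    stop("no records to plot")
  }
  if (!"group" %in% names(records)) {
    records <- assign_groups(records, focal_species)
  }
  dir <- dirname(output_prefix)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir)
  }
  pts <- records[, c("species", "group", "genome_size", "gc_percent")]
  table_path <- paste0(output_prefix, "_points.tsv")
  readr::write_tsv(pts, table_path, progress = FALSE)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$genome_size,
                                         y = .data$gc_percent,
                                         colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Genome size (Mb, log scale)", y = "GC (%)",
                  colour = "Group") +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(trends)) {
    tr <- trends$trends[!trends$trends$degenerate, ]
    if (nrow(tr) > 0) {
      p <- p + ggplot2::geom_abline(
        data = tr,
        ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                     colour = .data$group))
    }
  }
  images <- character()
  for (ext in c("pdf", "png")) {
    f <- paste0(output_prefix, ".", ext)
    ggplot2::ggsave(f, p, width = 6, height = 4.5,
                    dpi = if (ext == "png") 150 else 300)
    images <- c(images, f)
  }
  invisible(list(plot = p, images = images, table = table_path))
}
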