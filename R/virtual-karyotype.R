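# Virtual karyotype: size-sorted chromosomes with windowed repeat/GC
# composition and annotation overlays, in the style of an ideogram computed
# from the assembly instead of observed under a microscope.

#' Assemble a virtual karyotype
#'
#' Orders chromosomes by assembled length (descending; ties broken by name,
#' ascending), assigns size ranks (rank 1 = largest) and attaches the window
#' profile, annotation features and assembly summary. Ranks let observations
#' be phrased the way cytogenetics phrases them, e.g. "the 5S rDNA cluster
#' sits on the fourth largest chromosome".
#'
#' @param genome A `masked_genome` (see [read_masked_fasta()]).
#' @param profile Window profile of `genome` from [profile_assembly()], all
#'   at one window size.
#' @param features Optional feature table from [read_bed()]; every feature's
#'   chromosome must exist in the genome.
#' @param window_size Window size of `profile` in bases; inferred from the
#'   profile when omitted.
#' @return An object of class `virtual_karyotype`: a list with elements
#'   `window_size`, `chromosomes` (tibble `name`, `length`, `rank`),
#'   `profile` (with `rank` joined), `features` (with `rank`), `summary`.
#' @export
build_virtual_karyotype <- function(genome, profile, features = NULL,
                                    window_size = NULL) {
  lens <- chromosome_lengths(genome)
  if (!all(unique(profile$chromosome) %in% names(lens))) {
    stop("profile contains chromosomes absent from the genome: ",
         paste(setdiff(unique(profile$chromosome), names(lens)),
               collapse = ", "))
  }
  if (is.null(window_size)) {
    window_size <- max(profile$end - profile$start)
  }
  ord <- order(-lens, names(lens))
  chroms <- tibble::tibble(
    name = names(lens)[ord],
    length = unname(lens[ord]),
    rank = seq_along(lens)
  )
  prof <- dplyr::left_join(profile,
                           chroms[, c("name", "rank")],
                           by = c(chromosome = "name"))
  prof <- dplyr::arrange(prof, .data$rank, .data$start)
  if (is.null(features)) {
    features <- tibble::tibble(chromosome = character(), start = integer(),
                               end = integer(), label = character())
  }
  if (nrow(features) > 0) {
    unknown <- !features$chromosome %in% chroms$name
    if (any(unknown)) {
      stop("feature(s) on unknown chromosome: ",
           paste(sprintf("%s [%d, %d)", features$chromosome[unknown],
                         features$start[unknown], features$end[unknown]),
                 collapse = "; "))
    }
  }
  feats <- dplyr::left_join(features, chroms[, c("name", "rank")],
                            by = c(chromosome = "name"))
  structure(
    list(window_size = window_size,
         chromosomes = chroms,
         profile = prof,
         features = feats,
         summary = summarize_assembly(genome)),
    class = "virtual_karyotype"
  )
}

#' @export
print.virtual_karyotype <- function(x, ...) {
  cat(sprintf(
    "<virtual_karyotype> %d chromosome(s), window %s bp, %d feature(s)\n",
    nrow(x$chromosomes), format(x$window_size, big.mark = ","),
    nrow(x$features)))
  cat(sprintf("  total %s bp, GC %.2f%%, repeats %.2f%% of unambiguous\n",
              format(x$summary$total_length, big.mark = ","),
              x$summary$gc_percent_overall, x$summary$repeat_fraction))
  invisible(x)
}

#' Render a virtual karyotype plot
#'
#' One panel per chromosome in size-rank order. Each window is drawn at its
#' genomic position with the vertical position giving its GC% and the fill
#' colour its repeat proportion on a fixed red (0%, non-repetitive) to green
#' (100%, repetitive) scale; the endpoints are never rescaled to the data, so
#' plots are comparable across genomes. Low-confidence windows (mostly
#' ambiguous sequence) are drawn grey. Annotation features appear as
#' arrowhead markers at their midpoints above the profile.
#'
#' The backing window table is written next to the image and is byte-identical
#' across runs on identical input; it is exactly the window profile of the
#' retained chromosomes, not a recomputation.
#'
#' @param vk A [build_virtual_karyotype()] result.
#' @param output_prefix Path prefix; writes `<prefix>.pdf`, `<prefix>.png`
#'   and `<prefix>_windows.tsv`.
#' @param colour_mode `"green_red"` (repeat green, non-repeat red, as in
#'   classic repeat/ideogram colouring) or `"viridis"`.
#' @param formats Image formats to write, subset of `c("pdf", "png")`.
#' @return Invisibly, a list with `plot` (the ggplot object), `images`
#'   (paths) and `table` (backing TSV path).
#' @export
render_karyotype <- function(vk, output_prefix,
                             colour_mode = c("green_red", "viridis"),
                             formats = c("pdf", "png")) {
  stopifnot(inherits(vk, "virtual_karyotype"))
  colour_mode <- match.arg(colour_mode)
  dir <- dirname(output_prefix)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir)
  }
  prof <- vk$profile
  table_path <- paste0(output_prefix, "_windows.tsv")
  write_profile_tsv(prof, table_path)

  prof$panel <- factor(sprintf("%d: %s", prof$rank, prof$chromosome),
                       levels = sprintf("%d: %s", vk$chromosomes$rank,
                                        vk$chromosomes$name))
  band <- 2  # vertical thickness of each window box, in GC% units
  ok <- !is.na(prof$gc_total)
  p <- ggplot2::ggplot(prof[ok, ]) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e6, xmax = .data$end / 1e6,
      ymin = .data$gc_total - band / 2, ymax = .data$gc_total + band / 2,
      fill = .data$repeat_fraction)) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "GC (%)",
                  fill = "Repeats (%)") +
    ggplot2::theme_minimal(base_size = 9)
  p <- p + switch(colour_mode,
    green_red = ggplot2::scale_fill_gradient(
      low = "#c0392b", high = "#1e8449", limits = c(0, 100)),
    viridis = ggplot2::scale_fill_viridis_c(limits = c(0, 100))
  )
  if (any(prof$low_confidence & ok)) {
    lc <- prof[prof$low_confidence & ok, ]
    p <- p + ggplot2::geom_rect(
      data = lc,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = .data$gc_total - band / 2,
                   ymax = .data$gc_total + band / 2),
      fill = "grey70")
  }
  if (nrow(vk$features) > 0) {
    feats <- vk$features
    feats$panel <- factor(sprintf("%d: %s", feats$rank, feats$chromosome),
                          levels = levels(prof$panel))
    ymax <- max(prof$gc_total, na.rm = TRUE)
    # stack overlapping markers
    feats <- dplyr::arrange(feats, .data$rank, .data$start)
    feats <- dplyr::group_by(feats, .data$rank)
    feats <- dplyr::mutate(feats, stack = dplyr::row_number() - 1L)
    feats <- dplyr::ungroup(feats)
    p <- p + ggplot2::geom_point(
      data = feats,
      ggplot2::aes(x = (.data$start + .data$end) / 2 / 1e6,
                   y = ymax + 2 + 1.5 * .data$stack,
                   colour = .data$label),
      shape = 25, size = 2, fill = "blue", na.rm = TRUE) +
      ggplot2::labs(colour = "Feature")
  }
  images <- character()
  if ("pdf" %in% formats) {
    f <- paste0(output_prefix, ".pdf")
    ggplot2::ggsave(f, p, width = 10, height = 7)
    images <- c(images, f)
  }
  if ("png" %in% formats) {
    f <- paste0(output_prefix, ".png")
    ggplot2::ggsave(f, p, width = 10, height = 7, dpi = 150)
    images <- c(images, f)
  }
  invisible(list(plot = p, images = images, table = table_path))
}

#' Within-chromosome GC homogeneity report
#'
#' Quantifies how homogeneous GC% is along each chromosome as the dispersion
#' (standard deviation and interquartile range) of window GC values, for the
#' total sequence and for the repetitive and non-repetitive fractions
#' separately. Only confident windows (not flagged low-confidence) with a
#' defined value enter each statistic. Chromosomes with fewer than
#' `min_windows` confident windows are flagged and their dispersion reported
#' as `NA`.
#'
#' @param vk A [build_virtual_karyotype()] result.
#' @param min_windows Minimum number of confident windows per chromosome.
#' @return A [tibble::tibble()] with one row per chromosome plus a final
#'   genome-wide row (`chromosome = "(genome)"`): columns `chromosome`,
#'   `rank`, `n_windows`, `n_confident`, `flagged`, and `sd_`/`iqr_` columns
#'   for `gc_total`, `gc_repeat` and `gc_nonrepeat`.
#' @export
homogeneity_report <- function(vk, min_windows = 2L) {
  stopifnot(inherits(vk, "virtual_karyotype"))
  prof <- vk$profile
  if (nrow(prof) == 0L) {
    return(tibble::tibble())
  }
  disp <- function(x, ok) {
    x <- x[ok & !is.na(x)]
    if (length(x) < min_windows) {
      c(sd = NA_real_, iqr = NA_real_)
    } else {
      c(sd = stats::sd(x), iqr = stats::IQR(x))
    }
  }
  one <- function(d, label, rank) {
    ok <- !d$low_confidence
    st <- disp(d$gc_total, ok)
    sr <- disp(d$gc_repeat, ok)
    sn <- disp(d$gc_nonrepeat, ok)
    tibble::tibble(
      chromosome = label, rank = rank,
      n_windows = nrow(d), n_confident = sum(ok),
      flagged = sum(ok) < min_windows,
      sd_gc_total = st[["sd"]], iqr_gc_total = st[["iqr"]],
      sd_gc_repeat = sr[["sd"]], iqr_gc_repeat = sr[["iqr"]],
      sd_gc_nonrepeat = sn[["sd"]], iqr_gc_nonrepeat = sn[["iqr"]]
    )
  }
  per <- lapply(seq_len(nrow(vk$chromosomes)), function(i) {
    nm <- vk$chromosomes$name[i]
    one(prof[prof$chromosome == nm, ], nm, vk$chromosomes$rank[i])
  })
  dplyr::bind_rows(c(per, list(one(prof, "(genome)", NA_integer_))))
}
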