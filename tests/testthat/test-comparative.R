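write_ncbi_tsv <- function(rows, path,
                           header = "#Organism Name\tSize(Mb)\tGC%\tLevel") {
  writeLines(c(header, rows), path)
}

test_that("curation drops missing GC, non-chromosome level and duplicates, logging each", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ncbi_tsv(c("Salmo trutta\t2400\t41.5\tChromosome",
                   "Esox lucius\t940\t\tChromosome",
                   "Danio rerio\t1370\t36.6\tChromosome",
                   "Danio rerio\t1373\t36.7\tChromosome",
                   "Takifugu rubripes\t390\t45.4\tScaffold"), tf)
  expect_message(rec <- load_genome_table(tf), "curation dropped")
  expect_equal(rec$species, c("Salmo trutta", "Danio rerio"))
  expect_equal(rec$genome_size[rec$species == "Danio rerio"], 1370)
  dropped <- attr(rec, "dropped")
  expect_equal(nrow(dropped), 3)
  expect_setequal(dropped$species,
                  c("Esox lucius", "Danio rerio", "Takifugu rubripes"))
})

test_that("curation is idempotent and bp sizes convert to Mb", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ncbi_tsv(c("Salmo trutta\t2400000000\t41.5\tChromosome",
                   "Danio rerio\t1370000000\t36.6\tChromosome",
                   "Esox lucius\t940000000\t43.1\tChromosome"), tf)
  rec <- load_genome_table(tf, size_unit = "bp")
  expect_equal(rec$genome_size, c(2400, 1370, 940))
  # write the curated table back out and re-curate: nothing further drops
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#Organism Name\tSize(Mb)\tGC%",
               sprintf("%s\t%g\t%g", rec$species, rec$genome_size,
                       rec$gc_percent)), tf2)
  rec2 <- load_genome_table(tf2, columns = list(species = "#Organism Name",
                                                size = "Size(Mb)",
                                                gc = "GC%"))
  expect_equal(nrow(attr(rec2, "dropped")), 0)
  expect_equal(rec2$genome_size, rec$genome_size)
})

test_that("unmappable required columns fail naming the expected headers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("organism\tmb\tgc", "x\t1\t2"), tf)
  expect_error(load_genome_table(tf), "species|#Organism Name")
})

test_that("perfect collinear groups give unit correlations and an opposite-sign report", {
  sizes <- c(400, 800, 1600, 3200)
  records <- tibble::tibble(
    species = sprintf("sp%d", 1:8),
    group = rep(c("focal", "other"), each = 4),
    genome_size = rep(sizes, 2),
    gc_percent = c(30 + 2 * log10(sizes), 50 - 2 * log10(sizes))
  )
  # a perfect fit legitimately trips lm's "perfect fit" warning
  tr <- suppressWarnings(group_trends(records))
  expect_equal(tr$trends$pearson_r[tr$trends$group == "focal"], 1)
  expect_equal(tr$trends$pearson_r[tr$trends$group == "other"], -1)
  expect_equal(tr$trends$slope, c(2, -2), tolerance = 1e-9)
  expect_true(tr$comparison$opposite_sign)
  expect_equal(tr$comparison$slope_difference, 4, tolerance = 1e-9)

  # a strictly monotone size transform preserves rank correlation exactly
  warped <- records
  warped$genome_size <- warped$genome_size^3
  tr2 <- suppressWarnings(group_trends(warped))
  expect_equal(abs(tr2$trends$spearman_rho), c(1, 1))
})

test_that("groups below three records are refused and degenerate groups flagged", {
  rec <- tibble::tibble(species = c("a", "b", "c", "d", "e"),
                        group = c("focal", "focal", "other", "other", "other"),
                        genome_size = c(100, 200, 100, 200, 400),
                        gc_percent = c(40, 41, 42, 41, 40))
  expect_error(group_trends(rec), "at least 3")

  const <- tibble::tibble(species = letters[1:6],
                          group = rep(c("focal", "other"), each = 3),
                          genome_size = c(100, 200, 400, 100, 200, 400),
                          gc_percent = c(40, 40, 40, 40, 41, 42))
  tr <- suppressWarnings(group_trends(const))
  expect_true(tr$trends$degenerate[tr$trends$group == "focal"])
  expect_true(is.na(tr$trends$slope[tr$trends$group == "focal"]))
})

test_that("salmonid genera are picked out by the default focal rule", {
  rec <- tibble::tibble(
    species = c("Salmo trutta", "Oncorhynchus mykiss", "Danio rerio",
                "Salvelinus alpinus", "Esox lucius"),
    genome_size = 1, gc_percent = 1)
  grouped <- assign_groups(rec)
  expect_equal(grouped$group,
               c("focal", "focal", "other", "focal", "other"))
})

test_that("generated trend tables recover their slopes within sampling error", {
  for (seed in c(2, 9, 23)) {
    st <- generate_trend_table(trend_spec(seed = seed))
    tr <- group_trends(st$records)
    for (g in c("focal", "other")) {
      row <- tr$trends[tr$trends$group == g, ]
      true_slope <- st$truth$slope[st$truth$group == g]
      expect_lt(abs(row$slope - true_slope), 3 * row$slope_se)
    }
    expect_true(tr$comparison$opposite_sign)
  }
})

test_that("scatter rendering writes image and deterministic point table", {
  st <- generate_trend_table(trend_spec(seed = 4))
  tr <- group_trends(st$records)
  dir <- withr::local_tempdir()
  out1 <- render_scatter(st$records, tr, file.path(dir, "s1"))
  out2 <- render_scatter(st$records, tr, file.path(dir, "s2"))
  expect_true(all(file.exists(out1$images)))
  expect_identical(readLines(out1$table), readLines(out2$table))
  # single-group input renders without a trend comparison
  solo <- st$records[st$records$group == "focal", ]
  out3 <- render_scatter(solo, NULL, file.path(dir, "s3"))
  expect_true(all(file.exists(out3$images)))
  expect_error(render_scatter(solo[0, ], NULL, file.path(dir, "s4")),
               "no records")
})
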