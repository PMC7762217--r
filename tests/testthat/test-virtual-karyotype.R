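make_genome <- function(lengths, names = paste0("chr", seq_along(lengths)),
                        seed = 1) {
  set.seed(seed)
  g <- lapply(seq_along(lengths), function(i) {
    masked_chromosome(names[i], random_masked_seq(lengths[i]))
  })
  names(g) <- names
  structure(g, class = "masked_genome")
}

test_that("chromosomes are ranked strictly by length, ties broken by name", {
  g <- make_genome(c(3000, 1000, 2000), c("x", "y", "z"))
  vk <- build_virtual_karyotype(g, profile_assembly(g, 500))
  expect_equal(vk$chromosomes$name, c("x", "z", "y"))
  expect_equal(vk$chromosomes$length, c(3000, 2000, 1000))
  expect_equal(vk$chromosomes$rank, 1:3)
  # rank is a bijection onto 1..n
  expect_setequal(vk$chromosomes$rank, seq_len(nrow(vk$chromosomes)))

  g2 <- make_genome(c(1000, 1000, 2000), c("b", "a", "c"))
  vk2 <- build_virtual_karyotype(g2, profile_assembly(g2, 500))
  expect_equal(vk2$chromosomes$name, c("c", "a", "b"))
})

test_that("features map to size ranks so rank statements match naming", {
  # chromosome named "1" is deliberately the 4th largest, as in assemblies
  # whose accession order does not follow size
  g <- make_genome(c(5000, 4500, 4000, 3500, 1000),
                   c("5", "2", "9", "1", "20"))
  feats <- tibble::tibble(chromosome = c("1", "20"),
                          start = c(100L, 10L), end = c(200L, 60L),
                          label = "5S_rDNA")
  vk <- build_virtual_karyotype(g, profile_assembly(g, 500), feats)
  expect_equal(vk$features$rank[vk$features$chromosome == "1"], 4L)
  expect_equal(vk$features$rank[vk$features$chromosome == "20"], 5L)

  bad <- tibble::tibble(chromosome = "nope", start = 0L, end = 10L,
                        label = "x")
  expect_error(build_virtual_karyotype(g, profile_assembly(g, 500), bad),
               "unknown chromosome: nope|nope")
  vk0 <- build_virtual_karyotype(g, profile_assembly(g, 500))
  expect_equal(nrow(vk0$features), 0)
})

test_that("rendering writes images plus a byte-stable backing table", {
  g <- make_genome(2500, "c1")
  prof <- profile_assembly(g, 500)
  vk <- build_virtual_karyotype(g, prof)
  dir <- withr::local_tempdir()
  out1 <- render_karyotype(vk, file.path(dir, "vk1"), formats = "png")
  expect_true(file.exists(out1$images))
  tab <- readr::read_tsv(out1$table, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(prof))
  # backing table is the profile, not a recomputation
  expect_equal(tab$n_repeat, prof$n_repeat)
  out2 <- render_karyotype(vk, file.path(dir, "vk2"), formats = "png")
  expect_identical(readLines(out1$table), readLines(out2$table))
  expect_error(render_karyotype(vk, file.path(dir, "nope", "vk")),
               "directory")
})

test_that("an all-repeat genome sits at the repeat end of the colour scale", {
  g <- list(c1 = masked_chromosome("c1", strrep("acgt", 500)))
  class(g) <- "masked_genome"
  vk <- build_virtual_karyotype(g, profile_assembly(g, 400))
  expect_true(all(vk$profile$repeat_fraction == 100))
})

test_that("constant-GC chromosomes report zero dispersion", {
  g <- list(c1 = strata_chromosome("c1", rep(60, 6), 500))
  class(g) <- "masked_genome"
  vk <- build_virtual_karyotype(g, profile_assembly(g, 500))
  hr <- homogeneity_report(vk)
  expect_equal(hr$sd_gc_total, c(0, 0))
  expect_equal(hr$iqr_gc_total, c(0, 0))
  expect_false(any(hr$flagged))
})

test_that("two-strata GC dispersion matches the mixture-SD oracle", {
  # half the windows drawn at 40% GC, half at 60%: the window-level SD must
  # approach the two-point mixture SD, with binomial within-window noise
  set.seed(19)
  wsize <- 5000
  k_half <- 40
  draw <- function(p, n) {
    paste(ifelse(stats::runif(n) < p, "G", "A"), collapse = "")
  }
  seq <- paste0(draw(0.4, k_half * wsize), draw(0.6, k_half * wsize))
  g <- list(c1 = masked_chromosome("c1", seq))
  class(g) <- "masked_genome"
  vk <- build_virtual_karyotype(g, profile_assembly(g, wsize))
  hr <- homogeneity_report(vk)
  n_win <- 2 * k_half
  oracle_sd <- sqrt(n_win / (n_win - 1)) * 10  # equal two-point mixture
  mc_se <- oracle_sd / sqrt(2 * (n_win - 1))
  expect_lt(abs(hr$sd_gc_total[1] - oracle_sd), 3 * mc_se)
})

test_that("greater stratum mixing increases GC dispersion on average", {
  wsize <- 2000
  n_win <- 60
  sd_at_mix <- function(pi_high, seed) {
    set.seed(seed)
    n_high <- round(pi_high * n_win)
    ps <- c(rep(0.4, n_win - n_high), rep(0.6, n_high))
    seq <- paste(vapply(ps, function(p) {
      paste(ifelse(stats::runif(wsize) < p, "G", "A"), collapse = "")
    }, ""), collapse = "")
    g <- list(c1 = masked_chromosome("c1", seq))
    class(g) <- "masked_genome"
    hr <- homogeneity_report(
      build_virtual_karyotype(g, profile_assembly(g, wsize)))
    hr$sd_gc_total[1]
  }
  seeds <- 1:8
  means <- vapply(c(0.05, 0.25, 0.5), function(pi_high) {
    mean(vapply(seeds, function(s) sd_at_mix(pi_high, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("chromosomes with too few confident windows are flagged", {
  g <- list(tiny = strata_chromosome("tiny", 50, 400),
            ok = strata_chromosome("ok", c(40, 50, 60), 400))
  class(g) <- "masked_genome"
  vk <- build_virtual_karyotype(g, profile_assembly(g, 400))
  hr <- homogeneity_report(vk)
  expect_true(hr$flagged[hr$chromosome == "tiny"])
  expect_true(is.na(hr$sd_gc_total[hr$chromosome == "tiny"]))
  expect_false(hr$flagged[hr$chromosome == "ok"])
})
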