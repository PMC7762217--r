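test_that("karyotype formula notations parse as printed", {
  f <- parse_formula("80", "18", "62", "98")
  expect_equal(f$two_n$kind, "single")
  expect_equal(f$biarmed$lo, 18)
  expect_equal(f$uniarmed$lo, 62)
  expect_equal(f$nf$lo, 98)

  f <- parse_formula("80", "14/8", "58", "102")
  expect_equal(f$biarmed$kind, "split")
  expect_equal(f$biarmed$parts, c(14, 8))
  expect_equal(f$biarmed$lo, 22)

  f <- parse_formula("78-80", "20", "58-60", "98-100")
  expect_equal(f$two_n$kind, "range")
  expect_equal(c(f$two_n$lo, f$two_n$hi), c(78, 80))
  expect_equal(c(f$uniarmed$lo, f$uniarmed$hi), c(58, 60))

  # a reversed printed range keeps its order but sorts its bounds
  f <- parse_formula("80", "18-20", "62-60", "100")
  expect_equal(c(f$uniarmed$a, f$uniarmed$b), c(62, 60))
  expect_equal(c(f$uniarmed$lo, f$uniarmed$hi), c(60, 62))

  # en dashes normalize to the ASCII hyphen notation
  f <- parse_formula("78–80", "20", "58–60", "98–100")
  expect_equal(c(f$two_n$lo, f$two_n$hi), c(78, 80))

  # lone slash and empty cells are typed missing, not zero
  f <- parse_formula("80", "/", NA, "104")
  expect_equal(f$biarmed$kind, "missing")
  expect_equal(f$uniarmed$kind, "missing")

  expect_error(parse_formula("80", "18+2", "62", "98"), "unparsable")
})

test_that("parse/format round trip reproduces every fixture cell", {
  tab <- load_karyotype_table()
  for (i in seq_len(nrow(tab))) {
    printed <- vapply(c("two_n", "m_sm", "st_a", "nf"), function(col) {
      v <- tab[[col]][i]
      if (is.na(v)) "" else v
    }, "")
    expect_equal(unname(format(tab$formula[[i]])), unname(printed),
                 info = paste("row", i))
  }
})

test_that("NF arithmetic follows the uni-armed scoring of st/a", {
  expect_equal(compute_nf(18, 62), 98)
  expect_equal(compute_nf(12, 70), 94)
  expect_equal(compute_nf(0, 0), 0)
  # split bi-armed counts contribute their sum
  expect_equal(compute_nf(parse_formula("80", "14/8", "58", NA)), 102)
  # ranges propagate by interval arithmetic
  expect_equal(compute_nf(parse_formula("80-82", "20-22", "60", NA)),
               c(100, 104))
  # missing counts are not computable, not an error
  expect_true(is.na(compute_nf(parse_formula("80", NA, "60", NA))))
})

test_that("NF and 2n agree with brute-force enumeration", {
  grid <- expand.grid(b = 0:100, u = 0:100)
  got <- vapply(seq_len(nrow(grid)), function(i) {
    compute_nf(grid$b[i], grid$u[i])
  }, numeric(1))
  expect_equal(got, 2 * grid$b + grid$u)
  expect_equal(compute_2n(c(m = 7, st = 5, a_large = 2, a = 26)), 80)
  expect_equal(compute_2n(c(0, 0, 0)), 0)
  expect_equal(compute_2n(c(10, 10, 20)), 80)
  expect_error(compute_2n(c(-1, 2)), "non-negative")
})

test_that("subtelocentrics are uni-armed unless the alternative scoring is requested", {
  # 14 m + 10 st + 56 a chromosomes
  expect_equal(nf_from_counts(m = 14, st = 10, a = 56), 94)
  expect_equal(nf_from_counts(m = 14, st = 10, a = 56, st_biarmed = TRUE),
               104)
})

test_that("record validation flags arithmetic inconsistencies and nothing else", {
  clean <- parse_formula("80", "18", "62", "98")
  expect_equal(nrow(validate_record(clean)), 0)

  bad_nf <- parse_formula("80", "18", "62", "100")
  fnd <- validate_record(bad_nf)
  expect_equal(fnd$rule, "nf_vs_computed")
  expect_match(fnd$message, "98")

  bad_2n <- parse_formula("82", "18", "62", "98")
  expect_equal(validate_record(bad_2n)$rule, "two_n_vs_arm_sum")

  # ranged rows are consistent when the reported interval sits inside the
  # interval-arithmetic bounds
  ranged <- parse_formula("80", "22-23", "57-58", "102-103")
  expect_equal(nrow(validate_record(ranged)), 0)

  missing <- parse_formula("80", NA, NA, "104")
  fnd <- validate_record(missing)
  expect_equal(fnd$severity, "info")
})

test_that("the flathead trout composition gives 2n = 80 and a surfaced NF discrepancy", {
  # 7 metacentric + 5 subtelocentric + 2 large and 26 moderate acrocentric
  # chromosome pairs
  expect_equal(compute_2n(c(m = 7, st = 5, a_large = 2, a = 26)), 80)
  # the literature NF of 96 does not follow from uni-armed st/a scoring:
  # 2*14 + 66 = 94, and validation must surface the discrepancy
  rec <- parse_formula("80", "14", "66", "96")
  fnd <- validate_record(rec)
  expect_equal(fnd$rule, "nf_vs_computed")
  expect_equal(fnd$severity, "mismatch")
  expect_match(fnd$message, "94")
})

test_that("the packaged review table is internally consistent", {
  tab <- load_karyotype_table()
  expect_equal(nrow(tab), 66)
  fnd <- validate_table(tab)
  # the only finding is informational: one historical record reports 2n and
  # NF without arm counts, so its arithmetic cannot be checked
  expect_equal(nrow(fnd[fnd$severity == "mismatch", ]), 0)
  expect_equal(fnd$species_or_form[fnd$severity == "info"], "S. letnica")
})

test_that("table aggregation reports the modal diploid number and basin counts", {
  tab <- load_karyotype_table()
  s <- summarize_table(tab)
  expect_equal(s$n_records, 66)
  expect_equal(s$two_n_mode, 80)
  expect_equal(s$basin_counts$n[s$basin_counts$basin == "Aral Sea Basin"], 3)
  # range-valued 2n records are tallied separately from single values
  expect_equal(s$n_two_n_ranges +
                 sum(s$two_n_counts$n), s$n_records)

  one <- tab[1, ]
  s1 <- summarize_table(one)
  expect_equal(s1$n_records, 1)
  expect_equal(s1$two_n_mode, 80)
  expect_equal(s1$nf_range, c(98, 98))
  expect_error(summarize_table(tab[0, ]), "empty")
})
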