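#!/usr/bin/env Rscript
# Stage 3: genome size vs GC% contrast between a focal group and the rest.
#
# Simulates a two-group genome-record table (focal group with a positive
# GC-vs-size slope, the other group negative, matching the qualitative
# contrast between salmonids and other teleosts), fits per-group trends,
# and renders the scatter plot. A real NCBI genome-browse export can be
# analysed the same way via load_genome_table() + group_trends().

suppressPackageStartupMessages({
  library(optparse)
  library(virtukaryo)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--table", type = "character", default = NULL,
              help = "optional real genome-record TSV (NCBI browse dialect)")
)))

dir.create("results", showWarnings = FALSE)

if (!is.null(opts$table)) {
  records <- assign_groups(load_genome_table(opts$table))
  source_label <- opts$table
} else {
  st <- generate_trend_table(trend_spec(seed = opts$seed),
                             path = "results/03_records.tsv",
                             truth_path = "results/03_truth.tsv")
  records <- st$records
  source_label <- "synthetic (trend_spec defaults)"
}

tr <- group_trends(records)
readr::write_tsv(tr$trends, "results/03_trends.tsv")
render_scatter(records, tr, "results/03_size_vs_gc")

jsonlite::write_json(
  list(stage = "03_comparative_trends", seed = opts$seed,
       source = source_label, n_records = nrow(records),
       opposite_sign = tr$comparison$opposite_sign,
       package_version = as.character(packageVersion("virtukaryo"))),
  "results/03_manifest.json", auto_unbox = TRUE, pretty = TRUE)

print(tr)
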