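#!/usr/bin/env Rscript
# Optional smoke check on a user-supplied, soft-masked, chromosome-level
# assembly (e.g. the Ensembl brown trout assembly). Not run by default:
# no assembly ships with the package and no specific assembly version is
# pinned, so the observations this reproduces (GC homogenization along
# chromosomes, the GC levels of the repeat and non-repeat fractions) are
# qualitative, not fixed expected values.
#
# Usage:
#   Rscript analysis/05_real_assembly_smoke.R --fasta <softmasked.fa> \
#       [--features <rdna.bed>] [--window 100000]

suppressPackageStartupMessages({
  library(optparse)
  library(virtukaryo)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--fasta", type = "character", default = NULL),
  make_option("--features", type = "character", default = NULL),
  make_option("--window", type = "double", default = 1e5),
  make_option("--min-length", type = "double", default = 1e6,
              dest = "min_length")
)))

if (is.null(opts$fasta)) {
  cat("no --fasta supplied; nothing to do.\n",
      "Provide a soft-masked chromosome-level assembly to profile it.\n")
  quit(status = 0)
}

dir.create("results", showWarnings = FALSE)

genome <- read_masked_fasta(opts$fasta, min_length = opts$min_length)
print(summarize_assembly(genome))

prof <- profile_assembly(genome, opts$window)
feats <- if (!is.null(opts$features)) {
  read_bed(opts$features, chromosomes = genome)
} else {
  NULL
}
vk <- build_virtual_karyotype(genome, prof, feats)
render_karyotype(vk, "results/05_real_karyotype")
hr <- homogeneity_report(vk)
readr::write_tsv(hr, "results/05_homogeneity.tsv")
print(hr[hr$chromosome == "(genome)", ])
cat("fraction GC (base-weighted):\n")
agg <- function(gc, n) sum(gc * n, na.rm = TRUE) / sum(n)
cat(sprintf("  repeats: %.2f%%  non-repeats: %.2f%%\n",
            agg(prof$gc_repeat, prof$n_repeat),
            agg(prof$gc_nonrepeat, prof$n_nonrepeat)))
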