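#!/usr/bin/env Rscript

# Step 2: preprocessing and moderated differential testing.
#
# Each chemistry is processed by its own rules: pY intensities are
# normalized on the summed lysate intensity of the matching digest run,
# pSTY intensities are log10-transformed and median-normalized. Sites are
# filtered to class I (localization probability >= 0.75, no decoys or
# contaminants), multiplicity is retained, missing values are imputed by a
# seeded Gaussian downshift, and each site is tested with the
# empirical-Bayes moderated t.

suppressMessages(library(inkaflow))

seed <- 1L
out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
design <- read_design_table("results/data/design.tsv")

for (ds in c("pY", "pSTY")) {
  rec <- read_sites_table(sprintf("results/data/sites_%s.txt", ds))
  filt <- filter_class1(rec)
  cat(sprintf("[%s] %d sites -> %d class-I\n", ds, nrow(rec), nrow(filt)))
  des <- design[design$dataset == ds, ]
  m <- build_multiplicity_matrix(filt)
  logmat <- if (ds == "pY") {
    log10_matrix(normalize_py(m, des))
  } else {
    normalize_psty(m)
  }
  logmat <- suppressMessages(filter_min_observed(logmat, des, 2L))
  imputed <- impute(logmat, "gaussian_downshift", seed = seed + 17L)
  res <- moderated_ttest(imputed, des)
  write_differential_tsv(res, file.path(out, sprintf("%s_differential.tsv", ds)))
  counts <- summarize_significant(res)
  cat(sprintf("[%s] %d rows tested: %d significant (p < 0.05), %d up / %d down\n",
              ds, nrow(res), counts["total"], counts["up"], counts["down"]))
}
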