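#!/usr/bin/env Rscript

# Step 5: phosphosite-signature enrichment on the rank-value statistic.
#
# The enrichment branch follows its own input convention: class-I sites,
# single-phosphorylation intensities only, missing values imputed by 1,
# log10 transform, moderated two-group test, and the per-site statistic
# rank value = 10 * sign(FC) * log10(p), exported as GCT and scored against
# the kinase-substrate signature collection.

suppressMessages(library(inkaflow))

seed <- 1L
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
design <- read_design_table("results/data/design.tsv")
sigdb <- read_gmt("results/data/signatures.gmt")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

for (ds in c("pY", "pSTY")) {
  filt <- filter_class1(read_sites_table(sprintf("results/data/sites_%s.txt", ds)))
  des <- design[design$dataset == ds, ]
  single <- log10_matrix(impute(select_single_phospho(filt), "constant_one"))
  res <- moderated_ttest(single, des)
  gct <- file.path(out, sprintf("%s_rank_values.gct", ds))
  export_rank_gct(res, gct)
  enr <- suppressMessages(suppressWarnings(
    ptm_sea(read_gct(gct), sigdb, n_perm = 1000, seed = seed + 29L)
  ))
  write_enrichment_tsv(enr, file.path(out, sprintf("%s_enrichment.tsv", ds)))
  sig <- enr$signature[enr$p_value < 0.05]
  cat(sprintf("[%s] %d signatures scored, %d with p < 0.05\n", ds,
              nrow(enr), length(sig)))
  if (length(sig)) {
    hit <- intersect(truth$hyperactive_kinases, sig)
    cat(sprintf("[%s] planted kinases among enriched signatures: %s\n", ds,
                if (length(hit)) paste(hit, collapse = ", ") else "none"))
  }
}
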