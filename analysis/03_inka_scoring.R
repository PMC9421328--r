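#!/usr/bin/env Rscript

# Step 3: INKA kinase-activity scoring.
#
# Per kinase and sample, four evidence arms are summed on the linear
# intensity scale: the kinase's own phosphosites (kinome), its
# activation-loop sites, and its substrate sites under curated (PSP) and
# predicted (NWK) edges. The combined score is the geometric mean of the
# kinase-centric and substrate-centric arm averages, scaled to 100 within
# each sample. The pY and pSTY tables are then combined as a direct sum of
# arm scores.

suppressMessages(library(inkaflow))

out <- "results/inka"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
design <- read_design_table("results/data/design.tsv")
ksr <- read_ksr_json("results/data/ksr_database.json")

tabs <- lapply(c("pY", "pSTY"), function(ds) {
  filt <- filter_class1(read_sites_table(sprintf("results/data/sites_%s.txt", ds)))
  des <- design[design$dataset == ds, ]
  m <- build_multiplicity_matrix(filt)
  lin <- if (ds == "pY") normalize_py(m, des) else
    delog_matrix(normalize_psty(m))
  tab <- suppressMessages(inka_table(lin, ksr))
  write_inka_tables(tab, file.path(out, ds))
  top1 <- tab[tab$rank == 1, ]
  cat(sprintf("[%s] top-ranked kinases per sample: %s\n", ds,
              paste(unique(top1$kinase), collapse = ", ")))
  tab
})

hybrid <- hybrid_direct_sum(tabs[[1]], tabs[[2]])
utils::write.table(hybrid, file.path(out, "hybrid_inka.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("hybrid pY+pSTY table:", length(unique(hybrid$kinase)), "kinases x",
    length(unique(hybrid$sample)), "samples\n")
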