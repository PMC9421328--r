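#!/usr/bin/env Rscript

# Step 4: group aggregation, differential kinase ranking, and networks.
#
# INKA scores are aggregated per sample group; kinases are ranked by the
# difference of group means (treated minus control). High-activity kinase
# sets (scaled score > 75) from the two chemistries are intersected, and
# the top differential kinases are exported as a kinase-substrate network.

suppressMessages(library(inkaflow))

out <- "results/group"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
design <- read_design_table("results/data/design.tsv")
ksr <- read_ksr_json("results/data/ksr_database.json")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
des1 <- design[design$dataset == "pY", ]

hybrid <- utils::read.delim("results/inka/hybrid_inka.tsv")
agg <- aggregate_group_scores(hybrid, des1)
utils::write.table(agg, file.path(out, "hybrid_aggregated.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

top <- rank_by_difference(agg, 10)
utils::write.table(top, file.path(out, "top10_differential.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
recall <- mean(truth$hyperactive_kinases %in% top$kinase)
cat("top 10 differential kinases:", paste(top$kinase, collapse = ", "), "\n")
cat(sprintf("planted kinases recovered in top 10: %.0f%% (%s)\n",
            100 * recall, paste(truth$hyperactive_kinases, collapse = ", ")))

py_tab <- utils::read.delim("results/inka/pY/inka_table.tsv")
psty_tab <- utils::read.delim("results/inka/pSTY/inka_table.tsv")
actives <- list(pY = select_active(py_tab, 75),
                pSTY = select_active(psty_tab, 75))
venn <- set_intersections(actives)
utils::write.table(venn, file.path(out, "active_kinase_overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("high-activity kinases (score > 75): pY", length(actives$pY),
    "/ pSTY", length(actives$pSTY), "\n")

# network over the top differential kinases, on the pSTY linear matrix
filt <- filter_class1(read_sites_table("results/data/sites_pSTY.txt"))
lin <- delog_matrix(normalize_psty(build_multiplicity_matrix(filt)))
net <- build_ksr_network(top$kinase, ksr, lin, agg)
write_ksr_network(net, file.path(out, "ksr_network_edges.tsv"),
                  file.path(out, "ksr_network.dot"))
cat("network:", igraph::vcount(net), "nodes,", igraph::ecount(net), "edges\n")
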