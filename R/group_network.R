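## Group-level extensions of INKA scoring: aggregated scores per sample
## group, difference-of-means ranking, high-activity kinase sets and their
## intersections, the hybrid pY+pSTY direct-sum table, and kinase-substrate
## network export.

#' Aggregate INKA scores over sample groups
#'
#' Per kinase, computes the mean scaled score within each of the two groups
#' and their difference (treated minus control). Kinase-sample pairs absent
#' from the table score 0: absence of evidence is informative for activity.
#'
#' @param tab an `inka_table`.
#' @param design design rows for the table's samples (columns sample_id,
#'   group); exactly two groups.
#' @param treated_group label of the group whose mean enters the difference
#'   positively; defaults to `"treated"` if present, else the second group
#'   level.
#' @param use_scaled aggregate scaled scores (default) or raw INKA scores.
#' @return data.frame with columns kinase, mean_<control>, mean_<treated>,
#'   diff_of_means, plus the per-sample scores as an attribute.
#' @export
aggregate_group_scores <- function(tab, design, treated_group = NULL,
                                   use_scaled = TRUE) {
  missing_samples <- setdiff(design$sample_id, unique(tab$sample))
  if (length(missing_samples)) {
    stop_input("design sample(s) missing from INKA table: ",
               paste(missing_samples, collapse = ", "))
  }
  groups <- sort(unique(design$group))
  if (length(groups) != 2L) stop_input("exactly two groups required")
  if (is.null(treated_group)) {
    treated_group <- if ("treated" %in% groups) "treated" else groups[2]
  }
  control_group <- setdiff(groups, treated_group)
  score_col <- if (use_scaled) "scaled_score" else "inka_score"

  kinases <- sort(unique(tab$kinase))
  ## complete kinase x sample score matrix, absent pairs = 0
  score <- matrix(0, length(kinases), nrow(design),
                  dimnames = list(kinases, design$sample_id))
  idx <- cbind(match(tab$kinase, kinases), match(tab$sample, design$sample_id))
  keep <- !is.na(idx[, 2])
  score[idx[keep, , drop = FALSE]] <- tab[[score_col]][keep]

  grp <- design$group[match(colnames(score), design$sample_id)]
  mean_c <- rowMeans(score[, grp == control_group, drop = FALSE])
  mean_t <- rowMeans(score[, grp == treated_group, drop = FALSE])
  out <- data.frame(
    kinase = kinases,
    mean_control = mean_c,
    mean_treated = mean_t,
    diff_of_means = mean_t - mean_c,
    stringsAsFactors = FALSE
  )
  names(out)[2:3] <- paste0("mean_", c(control_group, treated_group))
  rownames(out) <- NULL
  attr(out, "per_sample") <- score
  attr(out, "treated_group") <- treated_group
  out
}

#' Rank kinases by difference of group means
#'
#' @param aggregated data.frame from [aggregate_group_scores()].
#' @param top_n number of kinases to return (default 10).
#' @return The top `top_n` rows sorted by descending `diff_of_means`
#'   (most treated-elevated first), ties broken by kinase identifier.
#' @export
rank_by_difference <- function(aggregated, top_n = 10) {
  if (!is_count(top_n)) stop_config("top_n must be a count >= 1")
  ord <- order(-aggregated$diff_of_means, aggregated$kinase)
  out <- aggregated[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Select high-activity kinases
#'
#' Kinases whose maximum scaled score across the given samples is strictly
#' above `tau` (default 75, the conventional high-activity threshold on the
#' 0-100 scale).
#'
#' @param tab an `inka_table`.
#' @param tau scaled-score threshold (strict inequality).
#' @param samples restrict to these samples (default: all in the table).
#' @return Character vector of kinase identifiers.
#' @export
select_active <- function(tab, tau = 75, samples = NULL) {
  if (!is.null(samples)) tab <- tab[tab$sample %in% samples, , drop = FALSE]
  mx <- tapply(tab$scaled_score, tab$kinase, max)
  sort(names(mx)[mx > tau])
}

#' Intersection region counts for kinase sets
#'
#' Counts every intersection region (as in a Venn diagram) of two or more
#' named sets.
#'
#' @param sets named list of character vectors.
#' @return data.frame with one row per region: a membership pattern column
#'   per set (TRUE = inside) and the region count.
#' @export
set_intersections <- function(sets) {
  if (length(sets) < 2L) stop_input("need at least two sets")
  labels <- names(sets)
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, labels))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- labels
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  patterns$count <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(row) all(row == p[labels])))
  })
  rownames(patterns) <- NULL
  patterns
}

#' Hybrid pY+pSTY table as a direct sum
#'
#' Combines the INKA arm tables of the two enrichment chemistries by
#' componentwise addition of the four arm scores per (kinase, sample)
#' (absent entries contribute 0), recomputes the combined score from the
#' summed arms, and rescales per sample. `hybrid_mode = "sum_scores"` instead
#' adds the final INKA scores directly.
#'
#' @param py_tab,psty_tab `inka_table`s with identical sample labels.
#' @param hybrid_mode `"sum_arms"` (default) or `"sum_scores"`.
#' @return An `inka_table` for the hybrid dataset.
#' @export
hybrid_direct_sum <- function(py_tab, psty_tab,
                              hybrid_mode = c("sum_arms", "sum_scores")) {
  hybrid_mode <- match.arg(hybrid_mode)
  if (nrow(py_tab) == 0L) return(psty_tab)
  if (nrow(psty_tab) == 0L) return(py_tab)
  s1 <- sort(unique(py_tab$sample))
  s2 <- sort(unique(psty_tab$sample))
  if (!identical(s1, s2)) {
    stop_input("sample labels differ between the two tables: ",
               paste(setdiff(union(s1, s2), intersect(s1, s2)), collapse = ", "))
  }
  kinases <- sort(union(py_tab$kinase, psty_tab$kinase))
  grid <- expand.grid(kinase = kinases, sample = s1,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- function(tab, col) {
    v <- tab[[col]][match(paste(grid$kinase, grid$sample),
                          paste(tab$kinase, tab$sample))]
    ifelse(is.na(v), 0, v)
  }
  out <- grid
  for (col in c("kinome", "actloop", "psp", "nwk")) {
    out[[col]] <- pick(py_tab, col) + pick(psty_tab, col)
  }
  if (hybrid_mode == "sum_arms") {
    out$inka_score <- combine_inka(out$kinome, out$actloop, out$psp, out$nwk)
  } else {
    out$inka_score <- pick(py_tab, "inka_score") + pick(psty_tab, "inka_score")
  }
  scale_and_rank(out)
}

#' Build a kinase-substrate network
#'
#' Directed graph from the given kinases to their substrate sites observed
#' in the intensity matrix. Kinase nodes carry their aggregated score (0 when
#' absent from `scores`), substrate-site nodes their mean observed intensity,
#' and edges the PSP/NWK evidence label. Kinases without observed substrates
#' are retained as isolated nodes.
#'
#' @param kinases character vector of kinases to include (non-empty).
#' @param ksr a `ksr_database`.
#' @param matrix normalized linear-scale `intensity_matrix`.
#' @param scores data.frame with columns kinase and diff_of_means (or any
#'   score column named by `score_col`).
#' @param score_col column of `scores` used as the kinase node weight.
#' @return An igraph directed graph.
#' @export
build_ksr_network <- function(kinases, ksr, matrix, scores,
                              score_col = "diff_of_means") {
  if (length(kinases) == 0L) stop_input("kinase list must be non-empty")
  assert_linear(matrix)
  site_id <- paste0(matrix$site_info$protein, "_", matrix$site_info$position)
  mean_int <- rowMeans(matrix$values, na.rm = TRUE)
  mean_int[is.nan(mean_int)] <- 0
  obs_int <- tapply(mean_int, site_id, sum)   # sum over multiplicity rows

  ed <- ksr$edges[ksr$edges$kinase %in% kinases, , drop = FALSE]
  ed$site <- paste0(ed$substrate_protein, "_", ed$position, ed$residue)
  ed$site_id <- paste0(ed$substrate_protein, "_", ed$position)
  ed <- ed[ed$site_id %in% names(obs_int), , drop = FALSE]
  ed <- ed[!duplicated(ed[c("kinase", "site_id", "evidence")]), , drop = FALSE]

  site_nodes <- unique(ed$site)
  site_weight <- obs_int[ed$site_id[match(site_nodes, ed$site)]]
  kin_weight <- scores[[score_col]][match(kinases, scores$kinase)]
  kin_weight[is.na(kin_weight)] <- 0

  nodes <- data.frame(
    name = c(kinases, site_nodes),
    type = c(rep("kinase", length(kinases)), rep("site", length(site_nodes))),
    weight = c(kin_weight, unname(site_weight)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = ed$kinase, to = ed$site, evidence = ed$evidence,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Export a kinase-substrate network
#'
#' Writes the edge list as TSV (source, target, evidence, weight of the
#' source kinase) and the graph as Graphviz DOT.
#'
#' @param graph igraph object from [build_ksr_network()].
#' @param edge_path output TSV path.
#' @param dot_path output DOT path.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ksr_network <- function(graph, edge_path, dot_path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  nd <- igraph::as_data_frame(graph, what = "vertices")
  ed$weight <- nd$weight[match(ed$from, nd$name)]
  utils::write.table(
    ed[, c("from", "to", "evidence", "weight")], edge_path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("source", "target", "evidence", "weight")
  )
  igraph::write_graph(graph, dot_path, format = "dot")
  invisible(c(edge_path, dot_path))
}
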