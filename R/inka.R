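## INKA kinase-activity scoring.
##
## Per kinase and sample, four evidence arms are summed on the linear
## intensity scale: phosphorylation of the kinase itself ("kinome"), of its
## activation-loop sites ("actloop"), and of its substrate sites under
## curated ("PSP") and predicted ("NWK") kinase-substrate edges. The two
## kinase-centric arms and the two substrate-centric arms are each averaged,
## and the final score is the geometric mean of the two averages.

assert_linear <- function(matrix) {
  if (grepl("log", matrix$transform)) {
    stop_input("INKA scoring needs linear-scale intensities; got transform '",
               matrix$transform,
               "' (sums of log values have no intensity meaning)")
  }
}

## Sum observed intensities over a set of matrix rows, per sample.
sum_rows <- function(matrix, rows) {
  if (!length(rows)) {
    return(stats::setNames(numeric(ncol(matrix$values)), matrix$sample_ids))
  }
  colSums(matrix$values[rows, , drop = FALSE], na.rm = TRUE)
}

own_site_rows <- function(kinase, matrix, ksr) {
  protein <- unname(ksr$kinase_proteins[kinase])
  if (is.na(protein)) stop_input("unknown kinase: ", kinase)
  which(matrix$site_info$protein == protein)
}

#' Kinome arm: phosphorylation of the kinase itself
#'
#' @param kinase kinase identifier.
#' @param matrix normalized linear-scale `intensity_matrix`.
#' @param ksr a `ksr_database`.
#' @return Named numeric vector of per-sample scores (sum of observed
#'   intensities of the kinase's own phosphosites; 0 when none observed).
#' @export
kinome_score <- function(kinase, matrix, ksr) {
  assert_linear(matrix)
  sum_rows(matrix, own_site_rows(kinase, matrix, ksr))
}

#' Activation-loop arm
#'
#' Sum of observed intensities of the kinase's own sites whose position lies
#' within its annotated activation-loop interval. Kinases without a loop
#' annotation score 0.
#'
#' @inheritParams kinome_score
#' @param annotations data.frame of activation-loop intervals (kinase,
#'   loop_start, loop_end); defaults to the database's own annotations.
#' @return Named numeric vector of per-sample scores.
#' @export
activation_loop_score <- function(kinase, matrix, ksr,
                                  annotations = ksr$activation_loops) {
  assert_linear(matrix)
  rows <- own_site_rows(kinase, matrix, ksr)
  ann <- annotations[annotations$kinase == kinase, , drop = FALSE]
  if (nrow(ann) == 0L) {
    message("activation_loop_score: no loop annotation for ", kinase)
    return(stats::setNames(numeric(ncol(matrix$values)), matrix$sample_ids))
  }
  pos <- matrix$site_info$position[rows]
  in_loop <- pos >= ann$loop_start[1] & pos <= ann$loop_end[1]
  sum_rows(matrix, rows[in_loop])
}

#' Substrate arms: curated (PSP) and predicted (NWK) evidence
#'
#' @inheritParams kinome_score
#' @param nwk_min_score minimum prediction score for a predicted edge to
#'   count (default 2).
#' @return List with per-sample vectors `psp` and `nwk`.
#' @export
substrate_scores <- function(kinase, matrix, ksr, nwk_min_score = 2) {
  assert_linear(matrix)
  ed <- ksr$edges[ksr$edges$kinase == kinase, , drop = FALSE]
  site_id <- paste0(matrix$site_info$protein, "_", matrix$site_info$position)
  psp_sites <- paste0(ed$substrate_protein, "_", ed$position)[ed$evidence == "PSP"]
  nwk_keep <- ed$evidence == "NWK" & !is.na(ed$prediction_score) &
    ed$prediction_score >= nwk_min_score
  nwk_sites <- paste0(ed$substrate_protein, "_", ed$position)[nwk_keep]
  list(
    psp = sum_rows(matrix, which(site_id %in% psp_sites)),
    nwk = sum_rows(matrix, which(site_id %in% nwk_sites))
  )
}

#' Combine the four INKA arms
#'
#' Kinase-centric arm `C = (kinome + actloop) / 2`, substrate-centric arm
#' `S = (psp + nwk) / 2`, combined score `sqrt(C * S)` — zero whenever either
#' side is zero, so a kinase needs both self- and substrate-evidence to
#' score.
#'
#' @param kinome,actloop,psp,nwk non-negative arm scores (vectorized).
#' @return Combined INKA score(s).
#' @export
combine_inka <- function(kinome, actloop, psp, nwk) {
  if (any(c(kinome, actloop, psp, nwk) < 0)) {
    stop_input("arm scores must be non-negative")
  }
  kc <- (kinome + actloop) / 2
  sc <- (psp + nwk) / 2
  sqrt(kc * sc)
}

#' Full INKA table for all kinases and samples
#'
#' @param matrix normalized linear-scale `intensity_matrix`.
#' @param ksr a `ksr_database`.
#' @param nwk_min_score minimum NWK prediction score (default 2).
#' @return An `inka_table`: data.frame with one row per (kinase, sample) and
#'   columns kinase, sample, kinome, actloop, psp, nwk, inka_score,
#'   scaled_score, rank.
#' @export
inka_table <- function(matrix, ksr, nwk_min_score = 2) {
  assert_linear(matrix)
  kinases <- names(ksr$kinase_proteins)
  samples <- matrix$sample_ids
  rows <- lapply(kinases, function(k) {
    kin <- kinome_score(k, matrix, ksr)
    act <- suppressMessages(activation_loop_score(k, matrix, ksr))
    sub <- substrate_scores(k, matrix, ksr, nwk_min_score)
    data.frame(
      kinase = k, sample = samples,
      kinome = unname(kin), actloop = unname(act),
      psp = unname(sub$psp), nwk = unname(sub$nwk),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$inka_score <- combine_inka(tab$kinome, tab$actloop, tab$psp, tab$nwk)
  scale_and_rank(tab)
}

#' Scale scores within each sample and rank kinases
#'
#' Scaled score is `100 * inka_score / max(inka_score)` within the sample (0
#' when the sample maximum is 0); rank is by descending scaled score with
#' ties broken by kinase identifier.
#'
#' @param tab data.frame with columns kinase, sample, inka_score (and
#'   optionally the four arms).
#' @return The table with `scaled_score` and `rank` columns, classed
#'   `inka_table`.
#' @export
scale_and_rank <- function(tab) {
  tab$scaled_score <- NA_real_
  tab$rank <- NA_integer_
  for (s in unique(tab$sample)) {
    idx <- which(tab$sample == s)
    mx <- max(tab$inka_score[idx])
    tab$scaled_score[idx] <- if (mx > 0) 100 * tab$inka_score[idx] / mx else 0
    ord <- order(-tab$scaled_score[idx], tab$kinase[idx])
    tab$rank[idx][ord] <- seq_along(idx)
  }
  class(tab) <- c("inka_table", "data.frame")
  tab
}

#' Write INKA score tables
#'
#' Writes the full per-sample INKA table (`inka_table.tsv`) and the
#' activation-loop score table (`actloop_table.tsv`) into a directory.
#'
#' @param tab an `inka_table`.
#' @param dir output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_inka_tables <- function(tab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "inka_table.tsv")
  p2 <- file.path(dir, "actloop_table.tsv")
  utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab[, c("kinase", "sample", "actloop")], p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
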