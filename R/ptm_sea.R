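## Phosphosite-signature enrichment on a signed rank-value statistic.
##
## Sites are keyed by 15-mer flanking-sequence windows (phosphoresidue at
## position 8). A weighted Kolmogorov-Smirnov-style running sum is computed
## over the descending-sorted rank values; significance comes from random
## same-size site sets (site-label permutation: a single contrast column
## leaves no sample labels to permute).

#' Read a GMT signature file
#'
#' One signature per line: name TAB description TAB member... A `;u` / `;d`
#' suffix on a member marks directed (up/down) membership; members without a
#' suffix are unsigned. Duplicate members within a line are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return A `signature_db`: list with `signatures` (named list of
#'   data.frames with columns site_key, direction) and `category` (named
#'   character vector, from the description field).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- list()
  category <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop_format("malformed GMT line ", i, ": need name, description and ",
                  "at least one member")
    }
    members <- parts[-(1:2)]
    direction <- rep("unsigned", length(members))
    direction[grepl(";u$", members)] <- "up"
    direction[grepl(";d$", members)] <- "down"
    keys <- sub(";[ud]$", "", members)
    dup <- duplicated(keys)
    if (any(dup)) {
      warning("GMT line ", i, " (", parts[1], "): ", sum(dup),
              " duplicate member(s) dropped")
    }
    sigs[[parts[1]]] <- data.frame(site_key = keys[!dup],
                                   direction = direction[!dup],
                                   stringsAsFactors = FALSE)
    category[parts[1]] <- parts[2]
  }
  structure(list(signatures = sigs, category = category),
            class = "signature_db")
}

#' Write a signature database as GMT
#' @param db a `signature_db`.
#' @param path output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$signatures), function(nm) {
    sig <- db$signatures[[nm]]
    suffix <- c(unsigned = "", up = ";u", down = ";d")[sig$direction]
    paste(c(nm, db$category[[nm]] %||% "na",
            paste0(sig$site_key, suffix)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.signature_db <- function(x, ...) {
  cat("signature_db:", length(x$signatures), "signatures\n")
  invisible(x)
}

#' Match rank-matrix sites to signatures
#'
#' Case-insensitive equality of 15-mer flanking windows against signature
#' member keys. Signatures matching fewer than `min_overlap` sites are
#' excluded with a message.
#'
#' @param rank_df data.frame with columns `id` (flanking window) and one
#'   value column (see [read_gct()]).
#' @param db a `signature_db`.
#' @param min_overlap minimum matched sites for a signature to be scored.
#' @return Named list per retained signature: integer row indices `rows`
#'   into `rank_df` and the matched members' `direction`.
#' @export
match_sites <- function(rank_df, db, min_overlap = 5L) {
  ids <- tolower(rank_df$id)
  out <- list()
  for (nm in names(db$signatures)) {
    sig <- db$signatures[[nm]]
    hit <- match(tolower(sig$site_key), ids)
    ok <- !is.na(hit)
    if (sum(ok) < min_overlap) next
    out[[nm]] <- list(rows = hit[ok], direction = sig$direction[ok])
  }
  dropped <- length(db$signatures) - length(out)
  if (dropped > 0) {
    message("match_sites: ", dropped, " signature(s) below min_overlap = ",
            min_overlap)
  }
  if (length(out) == 0L) warning("no signatures passed the overlap filter")
  out
}

## Running-sum enrichment score over a descending-sorted value vector.
## hit: logical vector aligned with values. Returns the signed maximal
## deviation (first occurrence on ties); 0 for degenerate memberships.
running_sum_es <- function(values_sorted, hit, alpha) {
  n <- length(values_sorted)
  nh <- sum(hit)
  if (nh == 0L || nh == n) return(0)
  w <- abs(values_sorted)^alpha
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) return(0)
  ## running value at i: hit weight seen so far over total, minus the
  ## fraction of misses seen so far
  run <- cumsum(w) / tot - cumsum(!hit) / (n - nh)
  run[which.max(abs(run))]
}

#' Weighted enrichment score for one signature
#'
#' Sorts values descending (ties broken by site key for determinism),
#' flips the value sign of "down"-directed members before ranking, and
#' computes the weighted running-sum statistic: hits increment by
#' `|value|^alpha` normalized over hits, misses decrement by `1/(N - Nh)`;
#' the score is the running sum at its maximal absolute deviation.
#'
#' @param values numeric rank values.
#' @param member logical or integer membership over `values`.
#' @param alpha weighting exponent (0 gives the classical unweighted
#'   KS-style statistic; default 0.75).
#' @param direction optional per-member direction ("up"/"down"/"unsigned"),
#'   aligned with the member sites.
#' @param site_keys optional site keys used for deterministic tie-breaking.
#' @return Enrichment score in [-1, 1].
#' @export
enrichment_score <- function(values, member, alpha = 0.75,
                             direction = NULL, site_keys = NULL) {
  n <- length(values)
  hit <- logical(n)
  hit[member] <- TRUE
  if (!any(hit)) stop_input("membership is empty")
  v <- values
  if (!is.null(direction)) {
    midx <- if (is.logical(member)) which(member) else member
    down <- midx[direction == "down"]
    v[down] <- -v[down]
  }
  keys <- site_keys %||% as.character(seq_len(n))
  ord <- order(-v, keys)
  running_sum_es(v[ord], hit[ord], alpha)
}

#' Permutation significance for signature enrichment
#'
#' Builds a null from `n_perm` random same-size site sets, then computes a
#' same-sign permutation p-value and a normalized enrichment score
#' (observed score divided by the mean absolute null score of the same
#' sign).
#'
#' @param values numeric rank values.
#' @param member membership (logical or indices) over `values`.
#' @param alpha weighting exponent.
#' @param n_perm number of permutations (values below 100 warn).
#' @param seed integer seed.
#' @param direction,site_keys passed to [enrichment_score()].
#' @return list(es, nes, p_value, n_matched, n_same_sign); `nes` is NA
#'   (flagged) when no null score shares the observed sign.
#' @export
significance <- function(values, member, alpha = 0.75, n_perm = 1000L,
                         seed = 1L, direction = NULL, site_keys = NULL) {
  if (n_perm < 100L) warning("n_perm < 100 gives unstable p-values")
  es <- enrichment_score(values, member, alpha, direction, site_keys)
  n <- length(values)
  nh <- if (is.logical(member)) sum(member) else length(member)
  keys <- site_keys %||% as.character(seq_len(n))
  ord <- order(-values, keys)
  v_sorted <- values[ord]
  es_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, nh)] <- TRUE
      running_sum_es(v_sorted, hit, alpha)
    }, numeric(1))
  })
  same <- if (es >= 0) es_null >= 0 else es_null < 0
  n_same <- sum(same)
  p <- (1 + sum(same & abs(es_null) >= abs(es))) / (1 + n_same)
  nes <- if (n_same > 0 && mean(abs(es_null[same])) > 0) {
    es / mean(abs(es_null[same]))
  } else {
    NA_real_
  }
  list(es = es, nes = nes, p_value = p, n_matched = nh, n_same_sign = n_same)
}

#' Signature enrichment over a rank-value column
#'
#' Full PTM-SEA-style analysis: match signatures to the rank matrix by
#' flanking window, score each retained signature, and assess permutation
#' significance with Benjamini-Hochberg correction across signatures.
#'
#' @param rank_df data.frame with columns `id` (flanking window) and a
#'   numeric value column (the first non-id/description column is used).
#' @param db a `signature_db`.
#' @param alpha weighting exponent (default 0.75).
#' @param min_overlap minimum matched sites per signature (default 5).
#' @param n_perm permutations per signature (default 1000).
#' @param seed integer seed.
#' @return data.frame: signature, category, n_matched, es, nes, p_value,
#'   q_value, sorted by p then |nes| descending.
#' @export
ptm_sea <- function(rank_df, db, alpha = 0.75, min_overlap = 5L,
                    n_perm = 1000L, seed = 1L) {
  value_col <- setdiff(names(rank_df), c("id", "description"))[1]
  values <- rank_df[[value_col]]
  membership <- match_sites(rank_df, db, min_overlap)
  if (length(membership) == 0L) {
    return(data.frame(signature = character(), category = character(),
                      n_matched = integer(), es = numeric(), nes = numeric(),
                      p_value = numeric(), q_value = numeric()))
  }
  rows <- lapply(seq_along(membership), function(i) {
    nm <- names(membership)[i]
    mem <- membership[[i]]
    sig <- significance(values, mem$rows, alpha = alpha, n_perm = n_perm,
                        seed = seed + i, direction = mem$direction,
                        site_keys = rank_df$id)
    data.frame(signature = nm,
               category = unname(db$category[nm] %||% NA_character_),
               n_matched = sig$n_matched, es = sig$es, nes = sig$nes,
               p_value = sig$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#' @param results data.frame from [ptm_sea()].
#' @param path output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
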