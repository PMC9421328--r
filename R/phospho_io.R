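## Reading MaxQuant-style phosphosite tables and preparing intensity
## matrices: class-I filtering, dataset-specific normalization, imputation.

META_COLS <- c("protein_id", "gene", "position", "residue",
               "localization_prob", "sequence_window",
               "is_reverse", "is_contaminant")

## In-memory phosphosite records: one row per site, metadata columns plus
## per-(sample, multiplicity) intensity columns "I.<sample>.M<m>".
## Missing intensities are NA in memory and 0 on disk (MaxQuant convention).
as_phosphosite_records <- function(df, samples) {
  stopifnot(all(META_COLS %in% names(df)))
  structure(df, samples = samples,
            class = c("phosphosite_records", "data.frame"))
}

#' @export
print.phosphosite_records <- function(x, ...) {
  cat("phosphosite_records:", nrow(x), "sites,",
      length(attr(x, "samples")), "samples\n")
  invisible(x)
}

intensity_cols <- function(records) {
  grep("^I\\.", names(records), value = TRUE)
}

#' Write a MaxQuant-dialect phosphosite table
#'
#' Writes records as a tab-separated "Phospho (STY)Sites"-style table with
#' per-sample intensity columns carrying triple-underscore multiplicity
#' suffixes (`Intensity sample___1`). Missing values are written as 0 and
#' boolean flags as `"+"` / empty, following the MaxQuant dialect.
#'
#' @param records a `phosphosite_records` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_table <- function(records, path) {
  if (!inherits(records, "phosphosite_records") || nrow(records) == 0L) {
    stop_input("records must be a non-empty phosphosite_records object")
  }
  samples <- attr(records, "samples")
  out <- data.frame(
    Proteins = records$protein_id,
    `Gene names` = records$gene,
    `Positions within proteins` = records$position,
    `Amino acid` = records$residue,
    `Localization prob` = records$localization_prob,
    `Sequence window` = records$sequence_window,
    Reverse = ifelse(records$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(records$is_contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (s in samples) {
    for (m in 1:3) {
      v <- records[[paste0("I.", s, ".M", m)]]
      v[is.na(v)] <- 0
      out[[sprintf("Intensity %s___%d", s, m)]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_input("cannot write sites table to ", path)
  invisible(path)
}

#' Read a MaxQuant-dialect phosphosite table
#'
#' Parses a tab-separated "Phospho (STY)Sites"-style table. Intensity columns
#' are recognized under both the triple-underscore multiplicity suffix
#' written by MaxQuant (`Intensity s___1`) and the double-underscore variant
#' (`Intensity s__1`). Intensity cells of 0 are recorded as missing.
#'
#' @param path input path.
#' @return A `phosphosite_records` object.
#' @export
read_sites_table <- function(path) {
  if (!file.exists(path)) stop_input("sites table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  mandatory <- c("Proteins", "Gene names", "Positions within proteins",
                 "Amino acid", "Localization prob", "Sequence window",
                 "Reverse", "Potential contaminant")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    stop_format("sites table missing mandatory column(s): ",
                paste(absent, collapse = ", "))
  }
  parse_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(x %in% c("", "NA", "NaN")))
    if (length(bad)) {
      stop_format("malformed numeric cell(s) in column '", col, "' at row(s) ",
                  paste(utils::head(bad, 5), collapse = ", "))
    }
    v
  }
  rec <- data.frame(
    protein_id = raw$Proteins,
    gene = raw$`Gene names`,
    position = as.integer(parse_num(raw$`Positions within proteins`,
                                    "Positions within proteins")),
    residue = raw$`Amino acid`,
    localization_prob = parse_num(raw$`Localization prob`, "Localization prob"),
    sequence_window = raw$`Sequence window`,
    is_reverse = raw$Reverse == "+",
    is_contaminant = raw$`Potential contaminant` == "+",
    stringsAsFactors = FALSE
  )
  ## intensity columns under either underscore dialect
  icols <- grep("^Intensity .+_{2,3}[123]$", names(raw), value = TRUE)
  m <- regmatches(icols, regexec("^Intensity (.+?)_{2,3}([123])$", icols))
  samples <- character()
  for (j in seq_along(icols)) {
    s <- m[[j]][2]
    mult <- m[[j]][3]
    samples <- union(samples, s)
    v <- parse_num(raw[[icols[j]]], icols[j])
    v[!is.na(v) & v == 0] <- NA_real_
    rec[[paste0("I.", s, ".M", mult)]] <- v
  }
  ## guarantee all 3 multiplicity slots per sample
  for (s in samples) {
    for (mult in 1:3) {
      col <- paste0("I.", s, ".M", mult)
      if (is.null(rec[[col]])) rec[[col]] <- NA_real_
    }
  }
  as_phosphosite_records(rec, samples)
}

#' Retain class-I phosphosites
#'
#' Keeps sites whose localization probability meets the class-I threshold and
#' drops decoy (reverse) and contaminant entries, preserving order.
#'
#' @param records a `phosphosite_records` object.
#' @param min_loc_prob localization-probability threshold; sites with
#'   `localization_prob >= min_loc_prob` are retained (default 0.75, the
#'   standard class-I definition).
#' @return Filtered `phosphosite_records`.
#' @export
filter_class1 <- function(records, min_loc_prob = 0.75) {
  keep <- records$localization_prob >= min_loc_prob &
    !records$is_reverse & !records$is_contaminant
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    message("filter_class1: no records retained")
  }
  as_phosphosite_records(out, attr(records, "samples"))
}

new_intensity_matrix <- function(values, site_info, transform) {
  stopifnot(nrow(values) == nrow(site_info))
  rownames(values) <- site_info$site_key
  structure(
    list(values = values, site_info = site_info,
         sample_ids = colnames(values), transform = transform),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$values), "rows x", ncol(x$values),
      "samples, transform =", x$transform, "\n")
  invisible(x)
}

#' Single-phosphorylation intensity matrix
#'
#' Builds a sites-by-samples matrix from the multiplicity-1 (singly
#' phosphorylated) intensities only — the input convention of the
#' signature-enrichment branch.
#'
#' @param records class-I filtered `phosphosite_records`.
#' @return An `intensity_matrix` with `transform = "raw"`.
#' @export
select_single_phospho <- function(records) {
  samples <- attr(records, "samples")
  values <- sapply(samples, function(s) records[[paste0("I.", s, ".M1")]])
  values <- matrix(values, nrow = nrow(records),
                   dimnames = list(NULL, samples))
  site_info <- data.frame(
    site_key = make_site_key(records$protein_id, records$position,
                             records$residue, 1L),
    protein = records$protein_id,
    gene = records$gene,
    position = records$position,
    residue = records$residue,
    multiplicity = 1L,
    sequence_window = records$sequence_window,
    stringsAsFactors = FALSE
  )
  new_intensity_matrix(values, site_info, "raw")
}

#' Multiplicity-resolved intensity matrix
#'
#' One row per (site, multiplicity) combination with at least one observed
#' value — the "site multiplicity retained" convention of the differential
#' and kinase-activity branches.
#'
#' @param records class-I filtered `phosphosite_records`.
#' @return An `intensity_matrix` with `transform = "raw"`.
#' @export
build_multiplicity_matrix <- function(records) {
  samples <- attr(records, "samples")
  blocks <- lapply(1:3, function(m) {
    vals <- sapply(samples, function(s) records[[paste0("I.", s, ".M", m)]])
    vals <- matrix(vals, nrow = nrow(records),
                   dimnames = list(NULL, samples))
    keep <- rowSums(!is.na(vals)) > 0L
    list(
      values = vals[keep, , drop = FALSE],
      info = data.frame(
        site_key = make_site_key(records$protein_id[keep],
                                 records$position[keep],
                                 records$residue[keep], m),
        protein = records$protein_id[keep],
        gene = records$gene[keep],
        position = records$position[keep],
        residue = records$residue[keep],
        multiplicity = rep(m, sum(keep)),
        sequence_window = records$sequence_window[keep],
        stringsAsFactors = FALSE
      )
    )
  })
  values <- do.call(rbind, lapply(blocks, `[[`, "values"))
  info <- do.call(rbind, lapply(blocks, `[[`, "info"))
  new_intensity_matrix(values, info, "raw")
}

#' Lysate-total normalization for the pY dataset
#'
#' Divides each sample's intensities by the summed total intensity of the
#' corresponding lysate digest run, rescaled by the median lysate total
#' across samples so values keep intensity-like magnitudes. The rescaling
#' cancels in all downstream ratio statistics.
#'
#' @param matrix raw `intensity_matrix`.
#' @param design design rows covering the matrix samples (columns sample_id,
#'   lysate_total_intensity).
#' @return Normalized `intensity_matrix` (`transform = "lysate_normalized"`).
#' @export
normalize_py <- function(matrix, design) {
  if (matrix$transform != "raw") {
    stop_input("normalize_py expects a raw matrix, got ", matrix$transform)
  }
  idx <- match(matrix$sample_ids, design$sample_id)
  if (anyNA(idx)) {
    stop_input("design missing sample(s): ",
               paste(matrix$sample_ids[is.na(idx)], collapse = ", "))
  }
  totals <- design$lysate_total_intensity[idx]
  if (any(!is.finite(totals) | totals <= 0)) {
    stop_input("lysate_total_intensity must be positive for all samples")
  }
  scale <- stats::median(totals) / totals
  values <- sweep(matrix$values, 2L, scale, `*`)
  new_intensity_matrix(values, matrix$site_info, "lysate_normalized")
}

#' Log-median normalization for the pSTY dataset
#'
#' Log10-transforms intensities and shifts every sample column so its median
#' over observed values equals the grand median of the pre-shift column
#' medians. Rank order within each sample is preserved.
#'
#' @param matrix raw `intensity_matrix`.
#' @return Normalized matrix (`transform = "log10_median_normalized"`).
#' @export
normalize_psty <- function(matrix) {
  if (matrix$transform != "raw") {
    stop_input("normalize_psty expects a raw matrix, got ", matrix$transform)
  }
  values <- matrix$values
  values[!is.na(values) & values <= 0] <- NA_real_
  values <- log10(values)
  med <- apply(values, 2L, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  values <- sweep(values, 2L, med - target, `-`)
  new_intensity_matrix(values, matrix$site_info, "log10_median_normalized")
}

#' Convert a log10 matrix back to the linear intensity scale
#'
#' Kinase-activity scoring sums intensities on the linear scale; for the
#' median-normalized pSTY branch this helper exponentiates the normalized
#' log10 values back to intensity-like units.
#'
#' @param matrix an `intensity_matrix` on a log10 scale.
#' @return Linear-scale matrix (`transform = "normalized_linear"`).
#' @export
delog_matrix <- function(matrix) {
  if (!grepl("log10", matrix$transform)) {
    stop_input("delog_matrix expects a log10-scale matrix, got ",
               matrix$transform)
  }
  new_intensity_matrix(10^matrix$values, matrix$site_info, "normalized_linear")
}

#' Impute missing intensities
#'
#' @param matrix an `intensity_matrix`.
#' @param method one of:
#'   * `"constant_one"` — replace missing with 1 on the linear (pre-log)
#'     scale; the signature-enrichment branch convention, so imputed entries
#'     become 0 after log10.
#'   * `"half_min"` — per row, half the minimum observed value.
#'   * `"gaussian_downshift"` — per sample, draws from a normal centred 1.8
#'     column-SDs below the column mean with width 0.3 SD (for log-scale
#'     matrices; seeded).
#' @param seed integer seed used by `gaussian_downshift`.
#' @return Matrix without missing values; `transform` unchanged.
#' @export
impute <- function(matrix, method = c("gaussian_downshift", "constant_one",
                                      "half_min"), seed = 1L) {
  if (!is.character(method) ||
      !all(method %in% c("gaussian_downshift", "constant_one", "half_min"))) {
    stop_config("unknown imputation method: ",
                paste(setdiff(method, c("gaussian_downshift", "constant_one",
                                        "half_min")), collapse = ", "))
  }
  method <- match.arg(method)
  values <- matrix$values
  if (!anyNA(values)) return(matrix)
  if (method == "constant_one") {
    values[is.na(values)] <- 1
  } else if (method == "half_min") {
    for (i in seq_len(nrow(values))) {
      miss <- is.na(values[i, ])
      if (any(miss)) {
        obs <- values[i, !miss]
        values[i, miss] <- if (length(obs)) min(obs) / 2 else 0
      }
    }
  } else {
    with_seed(seed, {
      for (j in seq_len(ncol(values))) {
        miss <- is.na(values[, j])
        if (any(miss)) {
          mu <- mean(values[, j], na.rm = TRUE)
          sd_j <- stats::sd(values[, j], na.rm = TRUE)
          if (!is.finite(sd_j) || sd_j == 0) sd_j <- 1
          values[miss, j] <- stats::rnorm(sum(miss), mu - 1.8 * sd_j,
                                          0.3 * sd_j)
        }
      }
    })
  }
  new_intensity_matrix(values, matrix$site_info, matrix$transform)
}

#' Log10-transform a matrix
#'
#' @param matrix linear-scale `intensity_matrix` (values > 0 or missing).
#' @return Matrix with `transform = "log10"`.
#' @export
log10_matrix <- function(matrix) {
  if (grepl("log10", matrix$transform)) {
    stop_input("matrix is already on the log10 scale")
  }
  values <- matrix$values
  values[!is.na(values) & values <= 0] <- NA_real_
  new_intensity_matrix(log10(values), matrix$site_info, "log10")
}

#' Drop rows observed in too few samples per group
#'
#' Sites quantified in fewer than `min_per_group` samples in either group are
#' removed before differential testing.
#'
#' @param matrix an `intensity_matrix`.
#' @param design design rows for the matrix samples.
#' @param min_per_group minimum observed values required in each group.
#' @return Filtered matrix.
#' @export
filter_min_observed <- function(matrix, design, min_per_group = 2L) {
  groups <- design$group[match(matrix$sample_ids, design$sample_id)]
  keep <- rep(TRUE, nrow(matrix$values))
  for (g in unique(groups)) {
    n_obs <- rowSums(!is.na(matrix$values[, groups == g, drop = FALSE]))
    keep <- keep & n_obs >= min_per_group
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("filter_min_observed: dropped ", n_drop, " of ", length(keep),
            " rows")
  }
  new_intensity_matrix(matrix$values[keep, , drop = FALSE],
                       matrix$site_info[keep, , drop = FALSE],
                       matrix$transform)
}

#' Write an intensity matrix as TSV
#'
#' The transform state is recorded in a `# transform:` comment line ahead of
#' the header.
#'
#' @param matrix an `intensity_matrix`.
#' @param path output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# transform: ", matrix$transform), con)
  df <- cbind(matrix$site_info, as.data.frame(matrix$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
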