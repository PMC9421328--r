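## Two-group moderated differential testing of phosphosite intensities.
##
## The moderated t follows the empirical-Bayes scheme of Smyth (2004):
## per-row pooled variances are shrunk toward a prior variance s0^2 with d0
## prior degrees of freedom, both estimated by moment matching of log s^2
## against the scaled-F prior using digamma/trigamma identities.

## Newton inversion of the trigamma function (y = trigamma(x), y > 0).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

## Moment-match (d0, s0^2) from observed pooled variances s2 on d df.
## Returns list(df_prior, var_prior); df_prior may be Inf.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, var_prior = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(d / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Moderated two-group t-test
#'
#' Per matrix row, computes the difference of group means, the pooled
#' within-group variance, and an empirical-Bayes moderated t-statistic in
#' which the row variance is shrunk toward a prior estimated from the
#' ensemble of row variances. With `shrink = FALSE` (prior df forced to 0)
#' the statistic is the ordinary pooled two-sample t.
#'
#' @param matrix an imputed, log-scale `intensity_matrix`.
#' @param design design rows for the matrix samples; exactly two groups with
#'   at least two samples each.
#' @param alpha significance level used for the `significant` flag.
#' @param shrink apply empirical-Bayes variance moderation (default TRUE).
#' @param sign_convention `"as_printed"` keeps the rank-value formula
#'   verbatim (up-regulated significant sites get negative rank values);
#'   `"negated"` flips it.
#' @return data.frame with one row per matrix row: site_key,
#'   sequence_window, log2_fc (treated minus control on the log2 scale),
#'   t_mod, df_total, p_value, q_value (Benjamini-Hochberg), rank_value,
#'   significant.
#' @export
moderated_ttest <- function(matrix, design, alpha = 0.05, shrink = TRUE,
                            sign_convention = c("as_printed", "negated")) {
  sign_convention <- match.arg(sign_convention)
  if (!grepl("log", matrix$transform)) {
    stop_input("moderated_ttest expects a log-scale matrix, got ",
               matrix$transform)
  }
  groups <- design$group[match(matrix$sample_ids, design$sample_id)]
  if (anyNA(groups)) {
    stop_input("design missing sample(s): ",
               paste(matrix$sample_ids[is.na(groups)], collapse = ", "))
  }
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop_input("exactly two groups required")
  a_idx <- which(groups == lev[1])
  b_idx <- which(groups == lev[2])
  n_a <- length(a_idx)
  n_b <- length(b_idx)
  if (n_a < 2L || n_b < 2L) {
    stop_input("each group needs at least 2 samples")
  }
  v <- matrix$values
  if (anyNA(v)) stop_input("matrix must be imputed before testing")

  mean_a <- rowMeans(v[, a_idx, drop = FALSE])
  mean_b <- rowMeans(v[, b_idx, drop = FALSE])
  delta <- mean_b - mean_a
  ss_a <- rowSums((v[, a_idx, drop = FALSE] - mean_a)^2)
  ss_b <- rowSums((v[, b_idx, drop = FALSE] - mean_b)^2)
  d <- n_a + n_b - 2L
  s2 <- (ss_a + ss_b) / d

  if (shrink) {
    prior <- fit_variance_prior(s2, d)
  } else {
    prior <- list(df_prior = 0, var_prior = 0)
  }
  d0 <- prior$df_prior
  if (is.finite(d0) && d0 > 0) {
    s2_tilde <- (d0 * prior$var_prior + d * s2) / (d0 + d)
    df_total <- d + d0
  } else if (is.infinite(d0)) {
    s2_tilde <- rep(prior$var_prior, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- s2
    df_total <- d
  }

  se <- sqrt(s2_tilde * (1 / n_a + 1 / n_b))
  t_mod <- delta / se
  if (is.finite(df_total)) {
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  } else {
    p <- 2 * stats::pnorm(-abs(t_mod))
  }
  ## degenerate rows: zero variance with zero difference -> p = 1
  degenerate <- se == 0
  t_mod[degenerate & delta == 0] <- 0
  p[degenerate & delta == 0] <- 1
  t_mod[degenerate & delta != 0] <- sign(delta[degenerate & delta != 0]) * Inf
  p[degenerate & delta != 0] <- .Machine$double.xmin
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  ## difference of group means re-expressed on the log2 scale
  log2_fc <- if (grepl("log10", matrix$transform)) {
    delta / log10(2)
  } else {
    delta / log(2)
  }
  rank_value <- compute_rank_value(log2_fc, p,
                                   sign_convention = sign_convention)
  res <- data.frame(
    site_key = matrix$site_info$site_key,
    sequence_window = matrix$site_info$sequence_window,
    log2_fc = log2_fc,
    t_mod = t_mod,
    df_total = df_total,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    rank_value = rank_value,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  attr(res, "df_prior") <- d0
  attr(res, "var_prior") <- prior$var_prior
  res
}

#' Signed rank-value statistic
#'
#' The per-site enrichment input statistic: `10 * sign(FC) * log10(p)`, with
#' `sign(0) = 0`. As printed, up-regulated significant sites receive
#' *negative* values (log10 of a small p is negative); `sign_convention =
#' "negated"` flips the sign for consumers that expect up-regulation at the
#' top of the ranking.
#'
#' @param fc fold change (any base; only the sign is used).
#' @param p_value two-sided p-value in (0, 1].
#' @param sign_convention `"as_printed"` (default) or `"negated"`.
#' @return Numeric vector of rank values.
#' @export
compute_rank_value <- function(fc, p_value,
                               sign_convention = c("as_printed", "negated")) {
  sign_convention <- match.arg(sign_convention)
  if (any(!is.finite(p_value) | p_value <= 0 | p_value > 1)) {
    stop_input("p_value must lie in (0, 1]")
  }
  rv <- 10 * sign(fc) * log10(p_value)
  if (sign_convention == "negated") rv <- -rv
  rv
}

#' Count significant sites
#'
#' @param results data.frame from [moderated_ttest()].
#' @param alpha significance level.
#' @return Named numeric vector `c(total, up, down)`; `up`/`down` split the
#'   significant sites by fold-change sign (zero-FC significant rows are
#'   counted in neither and reported via a message).
#' @export
summarize_significant <- function(results, alpha = 0.05) {
  sig <- results$p_value < alpha
  up <- sum(sig & results$log2_fc > 0)
  down <- sum(sig & results$log2_fc < 0)
  zero <- sum(sig & results$log2_fc == 0)
  if (zero > 0) {
    message("summarize_significant: ", zero,
            " significant row(s) with zero fold change counted neither up nor down")
  }
  c(total = up + down, up = up, down = down)
}

#' Write differential results as TSV
#' @param results data.frame from [moderated_ttest()].
#' @param path output path.
#' @export
write_differential_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export rank values in GCT format
#'
#' Writes a single-column GCT matrix of rank values. Row ids are the
#' flanking-sequence site keys (15-mers with lower-case phosphoresidue) so
#' the file can feed signature enrichment directly; the Description column
#' carries the site key.
#'
#' @param results data.frame from [moderated_ttest()].
#' @param path output path.
#' @param column_name name of the single data column.
#' @export
export_rank_gct <- function(results, path, column_name = "rank_value") {
  ids <- flanking_key(results$sequence_window)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nrow(results), 1, sep = "\t"), con)
  writeLines(paste("id", "Description", column_name, sep = "\t"), con)
  writeLines(paste(ids, results$site_key,
                   formatC(results$rank_value, format = "g", digits = 17),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a GCT rank matrix
#'
#' Reads the GCT dialect written by [export_rank_gct()] (magic line, a
#' dimensions line with two or four numbers, a header, then
#' id/Description/value rows).
#'
#' @param path GCT file path.
#' @return data.frame with columns id, description, and one column per data
#'   column in the file.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop_input("GCT file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "#1.")) {
    stop_format("not a GCT file (missing #1.x magic line): ", path)
  }
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  n_row <- dims[1]
  header <- strsplit(lines[3], "\t")[[1]]
  body <- utils::read.delim(text = lines[4:(3 + n_row)], header = FALSE,
                            stringsAsFactors = FALSE)
  names(body) <- c("id", "description", header[-(1:2)])
  body
}
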