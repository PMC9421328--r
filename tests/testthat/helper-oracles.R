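# Independent brute-force oracles and tiny fixture builders. These are
# deliberately written from the definitions, not by calling package code.

# Classical pooled two-sample t and its two-sided p, straight from the
# textbook formula.
brute_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2))
}

# Four-arm combination, written out directly.
brute_inka <- function(kinome, actloop, psp, nwk) {
  sqrt(((kinome + actloop) / 2) * ((psp + nwk) / 2))
}

# Classical unweighted KS-style set-enrichment statistic via an explicit
# step-by-step walk down the ranked list.
brute_gsea_es <- function(values_sorted, hit) {
  n <- length(values_sorted)
  nh <- sum(hit)
  if (nh == 0 || nh == n) return(0)
  hits_seen <- 0
  miss_seen <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) hits_seen <- hits_seen + 1 else miss_seen <- miss_seen + 1
    run <- hits_seen / nh - miss_seen / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Minimal records object: one row per site, two groups of three samples,
# explicit intensities at multiplicity 1.
toy_records <- function(values, probs = NULL, proteins = NULL,
                        positions = NULL, residues = NULL,
                        samples = colnames(values)) {
  n <- nrow(values)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  res <- residues %||% rep("S", n)
  rec <- data.frame(
    protein_id = proteins %||% sprintf("P%02d", seq_len(n)),
    gene = sprintf("G%02d", seq_len(n)),
    position = positions %||% seq(10, by = 10, length.out = n),
    residue = res,
    localization_prob = probs %||% rep(0.95, n),
    sequence_window = vapply(res, function(r) {
      paste0("AAAAAAA", r, "AAAAAAA")
    }, character(1)),
    is_reverse = FALSE,
    is_contaminant = FALSE,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(samples)) {
    rec[[paste0("I.", samples[j], ".M1")]] <- values[, j]
    rec[[paste0("I.", samples[j], ".M2")]] <- NA_real_
    rec[[paste0("I.", samples[j], ".M3")]] <- NA_real_
  }
  inkaflow:::as_phosphosite_records(rec, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bare intensity matrix without going through records.
toy_matrix <- function(values, transform = "raw", proteins = NULL,
                       positions = NULL, residues = NULL, windows = NULL) {
  n <- nrow(values)
  res <- residues %||% rep("S", n)
  info <- data.frame(
    site_key = sprintf("P%02d_%d%s_M1", seq_len(n),
                       positions %||% seq(10, by = 10, length.out = n), res),
    protein = proteins %||% sprintf("P%02d", seq_len(n)),
    gene = sprintf("G%02d", seq_len(n)),
    position = positions %||% seq(10, by = 10, length.out = n),
    residue = res,
    multiplicity = 1L,
    sequence_window = windows %||% vapply(res, function(r) {
      paste0("AAAAAAA", r, "AAAAAAA")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  }
  inkaflow:::new_intensity_matrix(values, info, transform)
}

toy_design <- function(samples, groups, dataset = "pSTY",
                       lysate = NULL) {
  data.frame(
    sample_id = samples, group = groups, dataset = dataset,
    lysate_total_intensity = lysate %||% rep(1e9, length(samples)),
    stringsAsFactors = FALSE
  )
}

# Null dataset at roughly 2000 multiplicity-resolved rows, complete
# (no dropout), used for calibration checks of the moderated test.
null_calibration_matrix <- function(seed) {
  cfg <- simulation_config(n_kinases = 120, n_substrate_proteins = 400,
                           edges_per_kinase = 16, dropout_midpoint = -Inf,
                           seed = seed)
  ksr <- generate_ksr_database(cfg)
  sim <- simulate_dataset(ksr, cfg, ground_truth(character(), effect_size = 1))
  recs <- rbind(sim$records$pY, sim$records$pSTY)
  recs <- inkaflow:::as_phosphosite_records(recs, attr(sim$records$pY, "samples"))
  list(
    matrix = normalize_psty(build_multiplicity_matrix(filter_class1(recs))),
    design = sim$design[sim$design$dataset == "pY", ]
  )
}
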