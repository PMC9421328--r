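## Configuration-driven end-to-end orchestration:
## simulate -> preprocess -> differential -> INKA -> group/network -> enrichment.
## The pY and pSTY branches run separately (as the two enrichment
## chemistries are acquired separately) and are then combined as a hybrid
## direct sum.

#' Default pipeline configuration
#'
#' Every analysis threshold surfaces as a named key with its conventional
#' default: class-I localization 0.75, significance level 0.05,
#' high-activity score threshold 75, NWK prediction cutoff 2, signature
#' overlap minimum 5, enrichment weighting exponent 0.75.
#'
#' @param outdir output directory for all artifacts.
#' @param seed master seed for simulation, imputation and permutation.
#' @param simulate list of overrides for [simulation_config()] plus optional
#'   `n_hyperactive`, `hyperactive_kinases`, `effect_size`,
#'   `affected_fraction`; set to NULL when `paths` is given.
#' @param paths list of input paths (sites_py, sites_psty, design, ksr,
#'   signatures) used instead of simulation.
#' @param ... threshold overrides (min_loc_prob, alpha, tau, nwk_min_score,
#'   min_overlap, alpha_weight, n_perm, top_n, imputation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("inkaflow_"), seed = 1L,
                            simulate = list(), paths = NULL, ...) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = simulate,
    paths = paths,
    min_loc_prob = 0.75,
    alpha = 0.05,
    tau = 75,
    nwk_min_score = 2,
    min_overlap = 5L,
    alpha_weight = 0.75,
    n_perm = 1000L,
    top_n = 10L,
    imputation = "gaussian_downshift"
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Validate a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @return Character vector of violations; empty iff the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  p <- character()
  if (is.null(config$simulate) && is.null(config$paths)) {
    p <- c(p, "either a simulate block or input paths must be given")
  }
  if (!is.null(config$paths)) {
    needed <- c("sites_py", "sites_psty", "design", "ksr")
    for (f in needed) {
      if (is.null(config$paths[[f]])) {
        p <- c(p, paste0("paths$", f, ": required when simulate is absent"))
      } else if (!file.exists(config$paths[[f]])) {
        p <- c(p, paste0("paths$", f, ": file not found (",
                         config$paths[[f]], ")"))
      }
    }
  }
  for (f in c("min_loc_prob", "alpha")) {
    if (!is_prob(config[[f]])) p <- c(p, paste0(f, ": out of [0,1]"))
  }
  if (!is_number(config$tau) || config$tau < 0 || config$tau > 100) {
    p <- c(p, "tau: out of [0,100]")
  }
  if (!is_number(config$nwk_min_score)) p <- c(p, "nwk_min_score: not a number")
  if (!is_number(config$alpha_weight) || config$alpha_weight < 0) {
    p <- c(p, "alpha_weight: must be >= 0")
  }
  for (f in c("min_overlap", "n_perm", "top_n")) {
    if (!is_count(config[[f]])) p <- c(p, paste0(f, ": must be a count >= 1"))
  }
  if (!config$imputation %in% c("gaussian_downshift", "constant_one",
                                "half_min")) {
    p <- c(p, "imputation: unknown method")
  }
  p
}

#' Write / read a kinase-substrate database as JSON
#' @param ksr a `ksr_database`.
#' @param path JSON path.
#' @export
write_ksr_json <- function(ksr, path) {
  jsonlite::write_json(
    list(edges = ksr$edges, own_sites = ksr$own_sites,
         kinase_proteins = as.list(ksr$kinase_proteins),
         activation_loops = ksr$activation_loops),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_ksr_json
#' @export
read_ksr_json <- function(path) {
  if (!file.exists(path)) stop_input("KSR database not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      edges = as.data.frame(raw$edges, stringsAsFactors = FALSE),
      own_sites = as.data.frame(raw$own_sites, stringsAsFactors = FALSE),
      kinase_proteins = unlist(raw$kinase_proteins),
      activation_loops = as.data.frame(raw$activation_loops,
                                       stringsAsFactors = FALSE)
    ),
    class = "ksr_database"
  )
}

## per-dataset branch: preprocessing + INKA + differential + enrichment
run_dataset_branch <- function(ds, records, design, ksr, sigdb, config,
                               outdir) {
  ds_dir <- file.path(outdir, ds)
  dir.create(ds_dir, showWarnings = FALSE, recursive = TRUE)
  design_ds <- design[design$dataset == ds, , drop = FALSE]
  n_in <- nrow(records)
  filtered <- filter_class1(records, config$min_loc_prob)
  message(sprintf("[%s] class-I filter: %d -> %d records", ds, n_in,
                  nrow(filtered)))

  ## --- INKA branch: multiplicity-resolved, linear scale ---------------
  mmat <- build_multiplicity_matrix(filtered)
  linear <- if (ds == "pY") {
    normalize_py(mmat, design_ds)
  } else {
    delog_matrix(normalize_psty(mmat))
  }
  inka <- inka_table(linear, ksr, nwk_min_score = config$nwk_min_score)
  inka_files <- write_inka_tables(inka, ds_dir)

  ## --- differential branch: multiplicity retained, log scale ----------
  logmat <- if (ds == "pY") {
    log10_matrix(normalize_py(mmat, design_ds))
  } else {
    normalize_psty(mmat)
  }
  logmat <- suppressMessages(filter_min_observed(logmat, design_ds, 2L))
  imputed <- impute(logmat, config$imputation, seed = config$seed + 17L)
  diff_res <- moderated_ttest(imputed, design_ds, alpha = config$alpha)
  diff_path <- file.path(ds_dir, "differential.tsv")
  write_differential_tsv(diff_res, diff_path)
  counts <- summarize_significant(diff_res, config$alpha)
  counts_path <- file.path(ds_dir, "significant_counts.tsv")
  utils::write.table(
    data.frame(dataset = ds, total = counts["total"], up = counts["up"],
               down = counts["down"]),
    counts_path, sep = "\t", quote = FALSE, row.names = FALSE
  )

  ## --- enrichment branch: single-phospho, impute 1, log10, rank value --
  single <- select_single_phospho(filtered)
  single <- impute(single, "constant_one")
  single <- log10_matrix(single)
  enr_res <- moderated_ttest(single, design_ds, alpha = config$alpha)
  gct_path <- file.path(ds_dir, "rank_values.gct")
  export_rank_gct(enr_res, gct_path)
  rank_df <- read_gct(gct_path)
  enrich <- ptm_sea(rank_df, sigdb, alpha = config$alpha_weight,
                    min_overlap = config$min_overlap,
                    n_perm = config$n_perm, seed = config$seed + 29L)
  enrich_path <- file.path(ds_dir, "enrichment.tsv")
  write_enrichment_tsv(enrich, enrich_path)

  ## --- group aggregation ----------------------------------------------
  agg <- aggregate_group_scores(inka, design_ds)
  agg_path <- file.path(ds_dir, "aggregated_inka.tsv")
  utils::write.table(agg, agg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(
    inka = inka, linear = linear, aggregated = agg,
    differential = diff_res, counts = counts, enrichment = enrich,
    artifacts = c(inka_files, diff_path, counts_path, gct_path, enrich_path,
                  agg_path)
  )
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the pY and pSTY site tables, runs both dataset
#' branches (filtering, normalization, INKA scoring, moderated differential
#' testing, rank-value export, signature enrichment), aggregates INKA scores
#' per group, combines both chemistries as a hybrid direct sum, builds the
#' kinase-substrate network of the top differential kinases, and writes a
#' JSON manifest of all artifacts. A rerun with an identical configuration
#' reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop_config("invalid pipeline config: ", paste(problems, collapse = "; "))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    truth_args <- sim_args[intersect(names(sim_args),
                                     c("hyperactive_kinases", "effect_size",
                                       "affected_fraction"))]
    n_hyper <- sim_args$n_hyperactive %||% 0L
    sim_args[c("n_hyperactive", "hyperactive_kinases", "effect_size",
               "affected_fraction")] <- NULL
    scfg <- do.call(simulation_config, c(sim_args, list(seed = config$seed)))
    ksr <- generate_ksr_database(scfg)
    if (is.null(truth_args$hyperactive_kinases) && n_hyper > 0) {
      truth_args$hyperactive_kinases <- with_seed(
        config$seed + 7L,
        sample(names(ksr$kinase_proteins), n_hyper)
      )
    }
    truth <- do.call(ground_truth,
                     c(truth_args, list(seed = config$seed + 11L)))
    sim <- simulate_dataset(ksr, scfg, truth)
    sigdb <- generate_signature_db(ksr)

    in_dir <- file.path(outdir, "inputs")
    dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      sites_py = file.path(in_dir, "sites_pY.txt"),
      sites_psty = file.path(in_dir, "sites_pSTY.txt"),
      design = file.path(in_dir, "design.tsv"),
      ksr = file.path(in_dir, "ksr_database.json"),
      signatures = file.path(in_dir, "signatures.gmt"),
      truth = file.path(in_dir, "truth.json")
    )
    write_sites_table(sim$records$pY, paths$sites_py)
    write_sites_table(sim$records$pSTY, paths$sites_psty)
    write_design_table(sim$design, paths$design)
    write_ksr_json(ksr, paths$ksr)
    write_gmt(sigdb, paths$signatures)
    jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                         digits = NA)
    artifacts <- c(artifacts, unlist(paths))
  } else {
    paths <- config$paths
  }

  ## always go through the on-disk dialect so the reader is exercised
  records <- list(pY = read_sites_table(paths$sites_py),
                  pSTY = read_sites_table(paths$sites_psty))
  design <- read_design_table(paths$design)
  ksr <- if (inherits(paths$ksr, "ksr_database")) paths$ksr else
    read_ksr_json(paths$ksr)
  sigdb <- if (!is.null(paths$signatures)) read_gmt(paths$signatures) else
    generate_signature_db(ksr)

  branches <- lapply(c("pY", "pSTY"), function(ds) {
    run_dataset_branch(ds, records[[ds]], design, ksr, sigdb, config, outdir)
  })
  names(branches) <- c("pY", "pSTY")
  artifacts <- c(artifacts, branches$pY$artifacts, branches$pSTY$artifacts)

  ## high-activity sets and their overlap across chemistries
  actives <- list(pY = select_active(branches$pY$inka, config$tau),
                  pSTY = select_active(branches$pSTY$inka, config$tau))
  venn <- set_intersections(actives)
  venn_path <- file.path(outdir, "active_kinase_overlap.tsv")
  utils::write.table(venn, venn_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## hybrid direct sum and its group aggregation
  hybrid <- hybrid_direct_sum(branches$pY$inka, branches$pSTY$inka)
  hybrid_path <- file.path(outdir, "hybrid_inka.tsv")
  utils::write.table(hybrid, hybrid_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  design_one <- design[design$dataset == "pY", , drop = FALSE]
  hybrid_agg <- aggregate_group_scores(hybrid, design_one)
  hybrid_agg_path <- file.path(outdir, "hybrid_aggregated.tsv")
  utils::write.table(hybrid_agg, hybrid_agg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  top <- rank_by_difference(hybrid_agg, config$top_n)

  ## hybrid kinase-substrate network over the top differential kinases
  comb <- new_intensity_matrix(
    rbind(branches$pY$linear$values, branches$pSTY$linear$values),
    rbind(branches$pY$linear$site_info, branches$pSTY$linear$site_info),
    "normalized_linear"
  )
  net <- build_ksr_network(top$kinase, ksr, comb, hybrid_agg)
  net_paths <- write_ksr_network(net,
                                 file.path(outdir, "ksr_network_edges.tsv"),
                                 file.path(outdir, "ksr_network.dot"))
  artifacts <- c(artifacts, venn_path, hybrid_path, hybrid_agg_path,
                 net_paths)

  manifest <- list(
    package_version = as.character(utils::packageVersion("inkaflow")),
    seed = config$seed,
    thresholds = config[c("min_loc_prob", "alpha", "tau", "nwk_min_score",
                          "min_overlap", "alpha_weight", "n_perm", "top_n")],
    imputation = config$imputation,
    artifacts = lapply(unname(artifacts), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    significant_counts = list(pY = as.list(branches$pY$counts),
                              pSTY = as.list(branches$pSTY$counts)),
    top_differential_kinases = top$kinase
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
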