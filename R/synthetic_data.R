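## Synthetic phosphoproteomic data with planted kinase hyperactivity.
##
## The generator emulates the input side of a label-free phosphoproteomics
## experiment: a kinase-substrate database with curated (PSP) and predicted
## (NWK) edges, kinase autophosphorylation sites with activation-loop
## intervals, and MaxQuant-dialect site tables for two groups of samples with
## log-normal intensities and intensity-dependent (MNAR) dropout. Kinases
## declared hyperactive in the ground truth have their substrate and own
## sites multiplied by an effect size in the treated group.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous RNG state so
#' seeded helpers do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe a
#' small but realistic label-free phosphoproteomics experiment: two groups of
#' three samples, log10 intensities around 6.5 with spread 0.8, moderate
#' between-sample noise, and logistic missing-not-at-random dropout that
#' removes mostly low-abundance observations.
#'
#' @param n_kinases number of kinases in the generated database.
#' @param n_substrate_proteins number of non-kinase substrate proteins.
#' @param edges_per_kinase substrate-site edges per kinase.
#' @param predicted_edge_fraction probability that an edge carries predicted
#'   (NWK) rather than curated (PSP) evidence.
#' @param own_sites_per_kinase autophosphorylation sites per kinase (at least
#'   one falls inside the activation loop).
#' @param n_per_group samples per group.
#' @param baseline_log_mean,baseline_log_sd log10-intensity distribution of
#'   per-site baselines.
#' @param sample_log_sd per-observation multiplicative noise, as the SD of a
#'   normal deviate on the log10 scale.
#' @param dropout_midpoint,dropout_slope logistic MNAR dropout parameters: an
#'   observation with log10 intensity `x` is missing with probability
#'   `plogis((dropout_midpoint - x) * dropout_slope)`.
#' @param multiplicity_probs probabilities that a site is reported at peptide
#'   multiplicity 1, 2 or 3; must sum to 1.
#' @param loc_prob_below_frac fraction of sites drawn with localization
#'   probability below the class-I threshold of 0.75.
#' @param contaminant_fraction,reverse_fraction fractions of extra decoy rows
#'   (relative to true sites) flagged as contaminant / reverse.
#' @param seed integer seed for all randomness in database generation.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_kinases = 20,
                              n_substrate_proteins = 100,
                              edges_per_kinase = 10,
                              predicted_edge_fraction = 0.3,
                              own_sites_per_kinase = 3,
                              n_per_group = 3,
                              baseline_log_mean = 6.5,
                              baseline_log_sd = 0.8,
                              sample_log_sd = 0.25,
                              dropout_midpoint = 5.5,
                              dropout_slope = 1.5,
                              multiplicity_probs = c(0.7, 0.25, 0.05),
                              loc_prob_below_frac = 0.1,
                              contaminant_fraction = 0.02,
                              reverse_fraction = 0.02,
                              seed = 1L) {
  cfg <- structure(
    list(
      n_kinases = n_kinases,
      n_substrate_proteins = n_substrate_proteins,
      edges_per_kinase = edges_per_kinase,
      predicted_edge_fraction = predicted_edge_fraction,
      own_sites_per_kinase = own_sites_per_kinase,
      n_per_group = n_per_group,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      sample_log_sd = sample_log_sd,
      dropout_midpoint = dropout_midpoint,
      dropout_slope = dropout_slope,
      multiplicity_probs = multiplicity_probs,
      loc_prob_below_frac = loc_prob_below_frac,
      contaminant_fraction = contaminant_fraction,
      reverse_fraction = reverse_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
  problems <- validate_simulation_config(cfg)
  if (length(problems)) {
    stop_config("invalid simulation_config: ", paste(problems, collapse = "; "))
  }
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `simulation_config` (or bare list with the same fields).
#' @return Character vector of violations, each naming the offending field;
#'   empty when the configuration is valid.
#' @export
validate_simulation_config <- function(cfg) {
  p <- character()
  for (f in c("n_kinases", "n_substrate_proteins", "edges_per_kinase",
              "own_sites_per_kinase", "n_per_group")) {
    if (!is_count(cfg[[f]])) p <- c(p, paste0(f, ": must be a count >= 1"))
  }
  for (f in c("predicted_edge_fraction", "loc_prob_below_frac",
              "contaminant_fraction", "reverse_fraction")) {
    if (!is_prob(cfg[[f]])) p <- c(p, paste0(f, ": must be in [0,1]"))
  }
  if (!is_number(cfg$baseline_log_mean)) {
    p <- c(p, "baseline_log_mean: must be a finite number")
  }
  ## -Inf midpoint is the documented no-dropout degenerate case
  dm <- cfg$dropout_midpoint
  if (!(is.numeric(dm) && length(dm) == 1L && !is.na(dm) && dm < Inf)) {
    p <- c(p, "dropout_midpoint: must be a number (or -Inf for no dropout)")
  }
  for (f in c("baseline_log_sd", "sample_log_sd", "dropout_slope")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) {
      p <- c(p, paste0(f, ": must be a non-negative number"))
    }
  }
  mp <- cfg$multiplicity_probs
  if (!is.numeric(mp) || length(mp) != 3L || any(mp < 0) || any(mp > 1) ||
      abs(sum(mp) - 1) > 1e-8) {
    p <- c(p, "multiplicity_probs: must be 3 probabilities summing to 1")
  }
  if (!is_count(abs(cfg$seed) + 1)) p <- c(p, "seed: must be an integer")
  p
}

#' Ground truth for a planted-effect simulation
#'
#' @param hyperactive_kinases character vector of kinase identifiers whose
#'   substrate and autophosphorylation sites are elevated in the treated group.
#' @param effect_size multiplicative fold applied to linear intensities of
#'   affected sites in the treated group; must be > 0 (1 = null data).
#' @param affected_fraction fraction of each hyperactive kinase's substrate
#'   sites that carry the effect, in (0, 1].
#' @param seed integer seed governing which substrate sites are affected.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(hyperactive_kinases = character(),
                         effect_size = 4,
                         affected_fraction = 1,
                         seed = 1L) {
  if (!is_number(effect_size) || effect_size <= 0) {
    stop_config("effect_size: must be a positive number")
  }
  if (!is_number(affected_fraction) || affected_fraction <= 0 ||
      affected_fraction > 1) {
    stop_config("affected_fraction: must be in (0,1]")
  }
  structure(
    list(
      hyperactive_kinases = as.character(hyperactive_kinases),
      effect_size = effect_size,
      affected_fraction = affected_fraction,
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

random_window <- function(n, center_residue) {
  left <- matrix(sample(AA_ALPHABET, 7L * n, replace = TRUE), nrow = n)
  right <- matrix(sample(AA_ALPHABET, 7L * n, replace = TRUE), nrow = n)
  paste0(
    apply(left, 1L, paste0, collapse = ""),
    center_residue,
    apply(right, 1L, paste0, collapse = "")
  )
}

#' Generate a synthetic kinase-substrate database
#'
#' Builds a database of `n_kinases` kinases, each with exactly
#' `edges_per_kinase` substrate-site edges (curated PSP or predicted NWK
#' evidence), `own_sites_per_kinase` autophosphorylation sites, and one
#' activation-loop interval containing at least one own site. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `ksr_database` with elements `edges`,
#'   `own_sites`, `kinase_proteins`, `activation_loops`.
#' @export
generate_ksr_database <- function(cfg) {
  problems <- validate_simulation_config(cfg)
  if (length(problems)) {
    stop_config("invalid simulation_config: ", paste(problems, collapse = "; "))
  }
  with_seed(cfg$seed, {
    kinases <- sprintf("KIN%03d", seq_len(cfg$n_kinases))
    kinase_proteins <- stats::setNames(
      sprintf("KINPROT%03d", seq_len(cfg$n_kinases)), kinases
    )
    sub_proteins <- sprintf("SUBPROT%03d", seq_len(cfg$n_substrate_proteins))
    sub_genes <- stats::setNames(
      sprintf("SUB%03d", seq_len(cfg$n_substrate_proteins)), sub_proteins
    )

    ## own (autophosphorylation) sites; one per kinase is the loop anchor
    n_own <- cfg$own_sites_per_kinase
    own <- do.call(rbind, lapply(seq_along(kinases), function(i) {
      pos <- sort(sample(30:600, n_own))
      data.frame(
        kinase = kinases[i],
        protein = unname(kinase_proteins[i]),
        gene = kinases[i],
        position = pos,
        residue = sample(c("S", "T", "Y"), n_own, replace = TRUE,
                         prob = c(0.4, 0.2, 0.4)),
        stringsAsFactors = FALSE
      )
    }))
    own$sequence_window <- random_window(nrow(own), own$residue)
    loop_anchor <- vapply(split(seq_len(nrow(own)), own$kinase), function(idx) {
      idx[sample.int(length(idx), 1L)]
    }, integer(1))
    loop_anchor <- loop_anchor[kinases]   # kinase order
    loops <- data.frame(
      kinase = kinases,
      loop_start = pmax(1L, own$position[loop_anchor] - 15L),
      loop_end = own$position[loop_anchor] + 15L,
      stringsAsFactors = FALSE
    )
    own$in_loop <- FALSE
    for (i in seq_along(kinases)) {
      sel <- own$kinase == kinases[i]
      own$in_loop[sel] <- own$position[sel] >= loops$loop_start[i] &
        own$position[sel] <= loops$loop_end[i]
    }

    ## substrate-site edges; shared sites keep one residue / window
    site_registry <- new.env(parent = emptyenv())
    edges <- do.call(rbind, lapply(kinases, function(k) {
      prot <- sample(sub_proteins, cfg$edges_per_kinase, replace = TRUE)
      pos <- sample(20:800, cfg$edges_per_kinase)
      key <- paste0(prot, "_", pos)
      residue <- character(cfg$edges_per_kinase)
      window <- character(cfg$edges_per_kinase)
      for (j in seq_along(key)) {
        if (!is.null(site_registry[[key[j]]])) {
          residue[j] <- site_registry[[key[j]]]$residue
          window[j] <- site_registry[[key[j]]]$window
        } else {
          residue[j] <- sample(c("S", "T", "Y"), 1L, prob = c(0.45, 0.25, 0.3))
          window[j] <- random_window(1L, residue[j])
          site_registry[[key[j]]] <- list(residue = residue[j], window = window[j])
        }
      }
      predicted <- stats::runif(cfg$edges_per_kinase) < cfg$predicted_edge_fraction
      data.frame(
        kinase = k,
        substrate_protein = prot,
        substrate_gene = unname(sub_genes[prot]),
        position = pos,
        residue = residue,
        sequence_window = window,
        evidence = ifelse(predicted, "NWK", "PSP"),
        prediction_score = ifelse(predicted, stats::runif(cfg$edges_per_kinase, 1, 5), NA_real_),
        stringsAsFactors = FALSE
      )
    }))
    ## no duplicate (kinase, substrate-site, evidence) triples
    edges <- edges[!duplicated(edges[c("kinase", "substrate_protein",
                                       "position", "evidence")]), , drop = FALSE]
    rownames(edges) <- NULL
    rownames(own) <- NULL

    structure(
      list(
        edges = edges,
        own_sites = own,
        kinase_proteins = kinase_proteins,
        activation_loops = loops
      ),
      class = "ksr_database"
    )
  })
}

#' @export
print.ksr_database <- function(x, ...) {
  cat("ksr_database:", length(x$kinase_proteins), "kinases,",
      nrow(x$edges), "edges (",
      sum(x$edges$evidence == "PSP"), "PSP /",
      sum(x$edges$evidence == "NWK"), "NWK ),",
      nrow(x$own_sites), "own sites\n")
  invisible(x)
}

## All unique phosphosites implied by a database: own sites plus substrate
## sites (deduplicated by protein + position).
ksr_site_table <- function(ksr) {
  own <- data.frame(
    protein = ksr$own_sites$protein,
    gene = ksr$own_sites$gene,
    position = ksr$own_sites$position,
    residue = ksr$own_sites$residue,
    sequence_window = ksr$own_sites$sequence_window,
    stringsAsFactors = FALSE
  )
  sub <- data.frame(
    protein = ksr$edges$substrate_protein,
    gene = ksr$edges$substrate_gene,
    position = ksr$edges$position,
    residue = ksr$edges$residue,
    sequence_window = ksr$edges$sequence_window,
    stringsAsFactors = FALSE
  )
  sites <- rbind(own, sub)
  sites <- sites[!duplicated(paste0(sites$protein, "_", sites$position)), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

## Which unique sites carry the planted effect for a given truth.
affected_site_keys <- function(ksr, truth) {
  keys <- character()
  with_seed(truth$seed, {
    for (k in truth$hyperactive_kinases) {
      own <- ksr$own_sites[ksr$own_sites$kinase == k, , drop = FALSE]
      keys <- c(keys, paste0(own$protein, "_", own$position))
      ed <- ksr$edges[ksr$edges$kinase == k, , drop = FALSE]
      ekeys <- unique(paste0(ed$substrate_protein, "_", ed$position))
      n_aff <- ceiling(truth$affected_fraction * length(ekeys))
      if (n_aff > 0) {
        keys <- c(keys, sample(ekeys, n_aff))
      }
    }
  })
  unique(keys)
}

#' Simulate a two-group phosphoproteomics dataset
#'
#' Draws per-site log-normal baseline intensities, applies the planted
#' hyperactivity effect to affected sites in the treated group, adds
#' per-observation multiplicative noise, and removes observations by
#' intensity-dependent logistic dropout. Two datasets are produced from the
#' one shared truth by residue restriction: tyrosine sites form the pY
#' (immunoprecipitation-like) dataset and serine/threonine sites the pSTY
#' (global-enrichment-like) dataset, each acquired with independent noise.
#'
#' @param ksr a `ksr_database` from [generate_ksr_database()].
#' @param cfg a [simulation_config()].
#' @param truth a [ground_truth()]; its kinases must exist in `ksr`.
#' @return A list with elements `records` (named list of
#'   `phosphosite_records` for datasets `pY` and `pSTY`), `design` (a sample
#'   design data.frame with columns sample_id, group, dataset,
#'   lysate_total_intensity), and `truth`.
#' @export
simulate_dataset <- function(ksr, cfg, truth) {
  unknown <- setdiff(truth$hyperactive_kinases, names(ksr$kinase_proteins))
  if (length(unknown)) {
    stop_input("hyperactive kinases not in database: ",
               paste(unknown, collapse = ", "))
  }
  sites <- ksr_site_table(ksr)
  affected <- paste0(sites$protein, "_", sites$position) %in%
    affected_site_keys(ksr, truth)

  groups <- c(rep("control", cfg$n_per_group), rep("treated", cfg$n_per_group))
  sample_ids <- c(sprintf("ctrl_%d", seq_len(cfg$n_per_group)),
                  sprintf("trt_%d", seq_len(cfg$n_per_group)))

  with_seed(cfg$seed + 1000L, {
    baseline <- 10^stats::rnorm(nrow(sites), cfg$baseline_log_mean,
                                cfg$baseline_log_sd)
    multiplicity <- sample(1:3, nrow(sites), replace = TRUE,
                           prob = cfg$multiplicity_probs)
    below <- stats::runif(nrow(sites)) < cfg$loc_prob_below_frac
    loc_prob <- ifelse(below, stats::runif(nrow(sites), 0.2, 0.7499),
                       stats::runif(nrow(sites), 0.75, 1))

    build_records <- function(dataset, keep) {
      ds_sites <- sites[keep, , drop = FALSE]
      ds_base <- baseline[keep]
      ds_aff <- affected[keep]
      n <- nrow(ds_sites)
      values <- matrix(NA_real_, n, length(sample_ids),
                       dimnames = list(NULL, sample_ids))
      for (s in seq_along(sample_ids)) {
        fold <- ifelse(ds_aff & groups[s] == "treated", truth$effect_size, 1)
        v <- ds_base * fold * 10^stats::rnorm(n, 0, cfg$sample_log_sd)
        p_miss <- stats::plogis((cfg$dropout_midpoint - log10(v)) *
                                  cfg$dropout_slope)
        p_miss[is.nan(p_miss)] <- 0   # midpoint -Inf with slope 0
        v[stats::runif(n) < p_miss] <- NA_real_
        values[, s] <- v
      }
      rec <- data.frame(
        protein_id = ds_sites$protein,
        gene = ds_sites$gene,
        position = ds_sites$position,
        residue = ds_sites$residue,
        localization_prob = loc_prob[keep],
        sequence_window = ds_sites$sequence_window,
        is_reverse = FALSE,
        is_contaminant = FALSE,
        stringsAsFactors = FALSE
      )
      mult <- multiplicity[keep]
      for (s in sample_ids) {
        for (m in 1:3) {
          col <- paste0("I.", s, ".M", m)
          rec[[col]] <- ifelse(mult == m, values[, s], NA_real_)
        }
      }
      ## decoy / contaminant filler rows
      n_con <- round(cfg$contaminant_fraction * n)
      n_rev <- round(cfg$reverse_fraction * n)
      if (n_con + n_rev > 0) {
        junk_res <- sample(c("S", "T", "Y"), n_con + n_rev, replace = TRUE)
        junk <- data.frame(
          protein_id = sprintf("JUNK%04d", seq_len(n_con + n_rev)),
          gene = sprintf("JUNK%04d", seq_len(n_con + n_rev)),
          position = sample(20:400, n_con + n_rev, replace = TRUE),
          residue = junk_res,
          localization_prob = stats::runif(n_con + n_rev, 0.75, 1),
          sequence_window = random_window(n_con + n_rev, junk_res),
          is_reverse = rep(c(FALSE, TRUE), c(n_con, n_rev)),
          is_contaminant = rep(c(TRUE, FALSE), c(n_con, n_rev)),
          stringsAsFactors = FALSE
        )
        for (s in sample_ids) {
          for (m in 1:3) {
            col <- paste0("I.", s, ".M", m)
            junk[[col]] <- ifelse(
              m == 1L, 10^stats::rnorm(n_con + n_rev, cfg$baseline_log_mean,
                                       cfg$baseline_log_sd), NA_real_)
          }
        }
        rec <- rbind(rec, junk)
      }
      rownames(rec) <- NULL
      as_phosphosite_records(rec, sample_ids)
    }

    records <- list(
      pY = build_records("pY", sites$residue == "Y"),
      pSTY = build_records("pSTY", sites$residue %in% c("S", "T"))
    )

    design <- do.call(rbind, lapply(c("pY", "pSTY"), function(ds) {
      data.frame(
        sample_id = sample_ids,
        group = groups,
        dataset = ds,
        lysate_total_intensity = 10^stats::rnorm(length(sample_ids), 9, 0.15),
        stringsAsFactors = FALSE
      )
    }))
    rownames(design) <- NULL

    list(records = records, design = design, truth = truth)
  })
}

#' Kinase-substrate signatures for enrichment analysis
#'
#' Derives a signature database from a kinase-substrate database: one
#' signature per kinase, whose members are the flanking-sequence keys of the
#' kinase's substrate sites (15-mer windows with the phosphoresidue in lower
#' case). This mirrors how kinase-target signatures in phosphosite signature
#' collections are keyed.
#'
#' @param ksr a `ksr_database`.
#' @param direction membership direction recorded for every member:
#'   `"unsigned"` (default), `"up"` or `"down"`.
#' @return A `signature_db` object (see [read_gmt()]).
#' @export
generate_signature_db <- function(ksr, direction = "unsigned") {
  direction <- match.arg(direction, c("unsigned", "up", "down"))
  sigs <- lapply(split(ksr$edges, ksr$edges$kinase), function(ed) {
    keys <- unique(flanking_key(ed$sequence_window))
    data.frame(site_key = keys, direction = direction,
               stringsAsFactors = FALSE)
  })
  structure(
    list(
      signatures = sigs,
      category = stats::setNames(rep("kinase", length(sigs)), names(sigs))
    ),
    class = "signature_db"
  )
}

#' Write the sample design table
#' @param design design data.frame as returned by [simulate_dataset()].
#' @param path output TSV path.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#' @param path TSV with columns sample_id, group, dataset,
#'   lysate_total_intensity.
#' @return Design data.frame.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop_input("design table not found: ", path)
  design <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  needed <- c("sample_id", "group", "dataset", "lysate_total_intensity")
  missing <- setdiff(needed, names(design))
  if (length(missing)) {
    stop_format("design table missing column(s): ",
                paste(missing, collapse = ", "))
  }
  design
}
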