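# A hand-built two-kinase database used across the scoring tests.
tiny_ksr <- function() {
  structure(list(
    edges = data.frame(
      kinase = c("KA", "KA", "KA", "KB"),
      substrate_protein = c("SP1", "SP2", "SP3", "SP1"),
      substrate_gene = c("S1", "S2", "S3", "S1"),
      position = c(10L, 20L, 30L, 10L),
      residue = c("S", "S", "Y", "S"),
      sequence_window = rep("AAAAAAASAAAAAAA", 4),
      evidence = c("PSP", "PSP", "NWK", "PSP"),
      prediction_score = c(NA, NA, 2.5, NA),
      stringsAsFactors = FALSE
    ),
    own_sites = data.frame(
      kinase = c("KA", "KA", "KB"),
      protein = c("KPA", "KPA", "KPB"),
      gene = c("KA", "KA", "KB"),
      position = c(180L, 500L, 100L),
      residue = c("Y", "S", "S"),
      sequence_window = rep("AAAAAAAYAAAAAAA", 3),
      in_loop = c(TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE
    ),
    kinase_proteins = c(KA = "KPA", KB = "KPB"),
    activation_loops = data.frame(
      kinase = c("KA", "KB"),
      loop_start = c(175L, 90L),
      loop_end = c(205L, 110L),
      stringsAsFactors = FALSE
    )
  ), class = "ksr_database")
}

tiny_matrix <- function(values) {
  toy_matrix(
    values,
    proteins = c("KPA", "KPA", "KPB", "SP1", "SP2", "SP3"),
    positions = c(180L, 500L, 100L, 10L, 20L, 30L),
    residues = c("Y", "S", "S", "S", "S", "Y")
  )
}

test_that("arm scores sum observed intensities over the right site sets", {
  v <- matrix(c(3, 9, 2, 4, 4, 7), 6, 1)
  m <- tiny_matrix(v)

  expect_equal(unname(kinome_score("KA", m, tiny_ksr())), 12)  # 3 + 9
  expect_equal(unname(activation_loop_score("KA", m, tiny_ksr())), 3)
  expect_equal(unname(kinome_score("KB", m, tiny_ksr())), 2)

  sub <- substrate_scores("KA", m, tiny_ksr(), nwk_min_score = 2)
  expect_equal(unname(sub$psp), 8)                    # SP1 + SP2
  expect_equal(unname(sub$nwk), 7)                    # SP3 passes 2.5 >= 2
  expect_equal(unname(substrate_scores("KA", m, tiny_ksr(),
                                       nwk_min_score = 3)$nwk), 0)

  # missing values contribute nothing
  v2 <- v; v2[1] <- NA
  expect_equal(unname(kinome_score("KA", tiny_matrix(v2), tiny_ksr())), 9)

  # kinase with no observed own sites scores zero
  v3 <- v; v3[3] <- NA
  expect_equal(unname(kinome_score("KB", tiny_matrix(v3), tiny_ksr())), 0)

  expect_error(kinome_score("NOPE", m, tiny_ksr()), "unknown kinase",
               class = "inkaflow_input_error")
})

test_that("log-scale input is rejected for intensity summation", {
  m <- tiny_matrix(matrix(1, 6, 1))
  m$transform <- "log10_median_normalized"
  expect_error(kinome_score("KA", m, tiny_ksr()),
               class = "inkaflow_input_error")
  expect_error(inka_table(m, tiny_ksr()), class = "inkaflow_input_error")
})

test_that("arm combination follows the two-level mean/geometric rule", {
  expect_equal(combine_inka(10, 2, 8, 10), sqrt(54))
  expect_equal(combine_inka(0, 0, 8, 10), 0)          # zero propagation
  expect_equal(combine_inka(10, 2, 0, 0), 0)
  expect_equal(combine_inka(2, 10, 8, 10), combine_inka(10, 2, 8, 10))
  expect_error(combine_inka(-1, 0, 1, 1), class = "inkaflow_input_error")

  # brute-force oracle on random arm quadruples
  set.seed(12)
  arms <- matrix(runif(200, 0, 100), 50, 4)
  expect_equal(combine_inka(arms[, 1], arms[, 2], arms[, 3], arms[, 4]),
               brute_inka(arms[, 1], arms[, 2], arms[, 3], arms[, 4]),
               tolerance = 1e-12)
})

test_that("full table equals an independent per-kinase recomputation", {
  cfg <- simulation_config(n_kinases = 20, dropout_midpoint = -Inf, seed = 9)
  ksr <- generate_ksr_database(cfg)
  sim <- simulate_dataset(ksr, cfg, ground_truth(character(), effect_size = 1))
  m <- build_multiplicity_matrix(filter_class1(sim$records$pSTY))
  tab <- inka_table(m, ksr)

  site_id <- paste0(m$site_info$protein, "_", m$site_info$position)
  for (k in sample(names(ksr$kinase_proteins), 5)) {
    for (s in sample(m$sample_ids, 2)) {
      row <- tab[tab$kinase == k & tab$sample == s, ]
      vals <- m$values[, s]
      vals[is.na(vals)] <- 0
      own <- m$site_info$protein == ksr$kinase_proteins[[k]]
      loop <- ksr$activation_loops[ksr$activation_loops$kinase == k, ]
      in_loop <- own & m$site_info$position >= loop$loop_start &
        m$site_info$position <= loop$loop_end
      ed <- ksr$edges[ksr$edges$kinase == k, ]
      psp <- site_id %in% paste0(ed$substrate_protein, "_",
                                 ed$position)[ed$evidence == "PSP"]
      nwk_ed <- ed[ed$evidence == "NWK" & ed$prediction_score >= 2, ]
      nwk <- site_id %in% paste0(nwk_ed$substrate_protein, "_", nwk_ed$position)
      expect_equal(row$kinome, sum(vals[own]), tolerance = 1e-12)
      expect_equal(row$actloop, sum(vals[in_loop]), tolerance = 1e-12)
      expect_equal(row$psp, sum(vals[psp]), tolerance = 1e-12)
      expect_equal(row$nwk, sum(vals[nwk]), tolerance = 1e-12)
      expect_equal(row$inka_score,
                   brute_inka(row$kinome, row$actloop, row$psp, row$nwk),
                   tolerance = 1e-12)
      expect_lte(row$actloop, row$kinome)            # loop sites are a subset
    }
  }
})

test_that("scaling and ranking are per sample with deterministic ties", {
  tab <- data.frame(
    kinase = rep(c("KA", "KB", "KC"), 2),
    sample = rep(c("s1", "s2"), each = 3),
    inka_score = c(50, 25, 0, 7, 7, 7),
    stringsAsFactors = FALSE
  )
  out <- scale_and_rank(tab)
  s1 <- out[out$sample == "s1", ]
  expect_equal(s1$scaled_score, c(100, 50, 0))
  expect_equal(s1$rank, c(1L, 2L, 3L))
  s2 <- out[out$sample == "s2", ]
  expect_equal(s2$scaled_score, rep(100, 3))
  expect_equal(s2$rank, 1:3)                         # lexicographic ties

  # positive rescaling leaves scaled scores and ranks unchanged
  tab2 <- tab
  tab2$inka_score <- tab2$inka_score * 37.5
  out2 <- scale_and_rank(tab2)
  expect_equal(out2$scaled_score, out$scaled_score)
  expect_equal(out2$rank, out$rank)

  # all-zero sample
  tab3 <- data.frame(kinase = c("KA", "KB"), sample = "s1",
                     inka_score = c(0, 0), stringsAsFactors = FALSE)
  expect_equal(scale_and_rank(tab3)$scaled_score, c(0, 0))
})

test_that("raising any substrate intensity never lowers the kinase score", {
  set.seed(21)
  v <- matrix(runif(6, 1, 10), 6, 1)
  m <- tiny_matrix(v)
  base <- inka_table(m, tiny_ksr())
  base_ka <- base$inka_score[base$kinase == "KA"]
  for (row in 4:6) {                                 # KA substrate rows
    for (bump in c(1, 10, 100)) {
      v2 <- v
      v2[row] <- v2[row] + bump
      tab <- inka_table(tiny_matrix(v2), tiny_ksr())
      expect_gte(tab$inka_score[tab$kinase == "KA"], base_ka)
    }
  }
})

test_that("hyperactive kinases score higher in the treated group", {
  # one planted kinase per replicate; both chemistries combined so every
  # substrate residue contributes evidence
  for (seed in 1:10) {
    cfg <- simulation_config(n_kinases = 50, seed = seed)
    ksr <- generate_ksr_database(cfg)
    planted <- with_seed(seed + 300L,
                         sample(names(ksr$kinase_proteins), 1))
    sim <- simulate_dataset(ksr, cfg,
                            ground_truth(planted, effect_size = 4, seed = seed))
    tabs <- lapply(c("pY", "pSTY"), function(ds) {
      m <- build_multiplicity_matrix(filter_class1(sim$records[[ds]]))
      des <- sim$design[sim$design$dataset == ds, ]
      lin <- if (ds == "pY") normalize_py(m, des) else
        delog_matrix(normalize_psty(m))
      suppressMessages(inka_table(lin, ksr))
    })
    hybrid <- hybrid_direct_sum(tabs[[1]], tabs[[2]])
    agg <- aggregate_group_scores(hybrid,
                                  sim$design[sim$design$dataset == "pY", ])
    expect_gt(agg$diff_of_means[agg$kinase == planted], 0)
  }
})
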