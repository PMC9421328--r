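test_that("GMT parsing handles members, direction suffixes, and duplicates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "sig1\tkinase\tAAAAAAAsAAAAAAA\tCCCCCCCtCCCCCCC\tDDDDDDDyDDDDDDD",
    "sig2\tpath\tABCDEFGsHIJKLMN;u\tZZZZZZZsZZZZZZZ;d\tQQQQQQQsQQQQQQQ"
  ), path)
  db <- read_gmt(path)
  expect_length(db$signatures, 2)
  expect_equal(nrow(db$signatures$sig1), 3)
  expect_equal(db$signatures$sig2$site_key[1], "ABCDEFGsHIJKLMN")
  expect_equal(db$signatures$sig2$direction, c("up", "down", "unsigned"))
  expect_equal(unname(db$category["sig1"]), "kinase")

  writeLines(c("dup\tx\tAAA\tAAA\tBBB"), path)
  expect_warning(db2 <- read_gmt(path), "duplicate")
  expect_equal(db2$signatures$dup$site_key, c("AAA", "BBB"))

  writeLines("bad\tonly_description", path)
  expect_error(read_gmt(path), "line 1", class = "inkaflow_format_error")

  # write/read round trip preserves membership and direction
  db3 <- structure(list(
    signatures = list(s = data.frame(site_key = c("AAAAAAAsAAAAAAA",
                                                  "CCCCCCCyCCCCCCC"),
                                     direction = c("up", "unsigned"),
                                     stringsAsFactors = FALSE)),
    category = c(s = "kinase")
  ), class = "signature_db")
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db3, p2)
  expect_equal(read_gmt(p2)$signatures, db3$signatures)
})

test_that("site matching is case-insensitive with an overlap floor", {
  rank_df <- data.frame(id = c("AAAAAAAsAAAAAAA", "CCCCCCCtCCCCCCC"),
                        rank_value = c(1, -1), stringsAsFactors = FALSE)
  db <- structure(list(
    signatures = list(
      hit = data.frame(site_key = "AAAAAAASAAAAAAA", direction = "unsigned",
                       stringsAsFactors = FALSE),
      small = data.frame(site_key = "GGGGGGGsGGGGGGG", direction = "unsigned",
                         stringsAsFactors = FALSE)
    ),
    category = c(hit = "k", small = "k")
  ), class = "signature_db")
  mem <- suppressMessages(match_sites(rank_df, db, min_overlap = 1))
  expect_named(mem, "hit")
  expect_equal(mem$hit$rows, 1L)
  expect_warning(suppressMessages(match_sites(rank_df, db, min_overlap = 5)),
                 "no signatures")
})

test_that("enrichment scores match the running-sum definition", {
  # single hit at the top of the list is a full deviation
  expect_equal(enrichment_score(c(4, 3, 2, 1), 1, alpha = 0.75), 1)

  # frozen worked example at alpha = 0: hits at ranks 1 and 3
  expect_equal(enrichment_score(c(3, 1, -1, -3), c(1, 3), alpha = 0), 0.5)

  # degenerate set covering every position scores 0 by convention
  expect_equal(enrichment_score(c(2, 1), c(1, 2), alpha = 0.75), 0)
  expect_error(enrichment_score(c(2, 1), integer(0)),
               class = "inkaflow_input_error")
})

test_that("alpha = 0 reproduces the classical KS-style statistic exactly", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    values <- round(rnorm(n), 3)
    keys <- sprintf("k%02d", seq_len(n))
    member <- sample(n, sample(1:(n - 1), 1))
    es <- enrichment_score(values, member, alpha = 0, site_keys = keys)
    ord <- order(-values, keys)
    hit <- seq_len(n) %in% member
    expect_identical(es, brute_gsea_es(values[ord], hit[ord]))
  }
})

test_that("score invariances: rescaling at alpha 0, global sign flip", {
  set.seed(78)
  values <- rnorm(50)
  keys <- sprintf("k%02d", 1:50)
  member <- sample(50, 8)
  es <- enrichment_score(values, member, alpha = 0, site_keys = keys)
  expect_equal(enrichment_score(values * 13.7, member, alpha = 0,
                                site_keys = keys), es)
  # reversing every rank value negates the score for unsigned sets
  es_neg <- enrichment_score(-values, member, alpha = 0, site_keys = keys)
  expect_equal(es_neg, -es)
})

test_that("down-directed members contribute with flipped sign", {
  values <- c(5, 4, -4, -6)
  keys <- sprintf("k%d", 1:4)
  # member 4 is strongly negative; flipped it leads the ranking, so the two
  # members occupy the top two positions and the deviation is maximal
  mixed <- enrichment_score(values, c(1, 4), alpha = 0,
                            direction = c("up", "down"), site_keys = keys)
  expect_equal(mixed, 1)
  # unsigned treatment of the same membership scores lower
  unsigned <- enrichment_score(values, c(1, 4), alpha = 0, site_keys = keys)
  expect_lt(unsigned, mixed)
})

test_that("permutation significance is seeded and self-consistent", {
  set.seed(79)
  values <- rnorm(100)
  keys <- sprintf("k%03d", 1:100)
  member <- order(-values)[1:8]                       # strong planted signal
  s1 <- significance(values, member, n_perm = 500, seed = 4, site_keys = keys)
  s2 <- significance(values, member, n_perm = 500, seed = 4, site_keys = keys)
  expect_identical(s1, s2)
  expect_lt(s1$p_value, 0.05)
  expect_gt(s1$es, 0)
  expect_equal(s1$n_matched, 8)
  expect_warning(significance(values, member, n_perm = 50, seed = 1,
                              site_keys = keys), "n_perm")
})

test_that("stronger planted effects give larger normalized scores", {
  base_values <- with_seed(80, rnorm(200))
  keys <- sprintf("k%03d", 1:200)
  member <- 1:10
  nes_at <- vapply(c(0, 1, 3), function(shift) {
    v <- base_values
    v[member] <- v[member] + shift
    abs(significance(v, member, n_perm = 300, seed = 6,
                     site_keys = keys)$nes)
  }, numeric(1))
  expect_true(all(diff(nes_at) > 0))
})

test_that("full enrichment table is ordered with BH-adjusted q-values", {
  cfg <- simulation_config(n_kinases = 12, edges_per_kinase = 12,
                           dropout_midpoint = -Inf, seed = 14)
  ksr <- generate_ksr_database(cfg)
  planted <- "KIN001"
  sim <- simulate_dataset(ksr, cfg,
                          ground_truth(planted, effect_size = 8, seed = 14))
  filt <- filter_class1(sim$records$pSTY)
  single <- log10_matrix(impute(select_single_phospho(filt), "constant_one"))
  des <- sim$design[sim$design$dataset == "pSTY", ]
  res <- moderated_ttest(single, des)
  rank_df <- data.frame(id = flanking_key(res$sequence_window),
                        rank_value = res$rank_value,
                        stringsAsFactors = FALSE)
  out <- suppressMessages(
    ptm_sea(rank_df, generate_signature_db(ksr), n_perm = 300, seed = 3)
  )
  expect_true(all(c("signature", "n_matched", "es", "nes", "p_value",
                    "q_value") %in% names(out)))
  expect_true(all(abs(out$es) <= 1))
  expect_true(!is.unsorted(out$p_value))
  expect_true(all(out$q_value >= out$p_value - 1e-12))
})
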