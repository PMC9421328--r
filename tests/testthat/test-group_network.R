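make_inka_tab <- function(kinases, samples, scores) {
  tab <- expand.grid(kinase = kinases, sample = samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$kinome <- 1
  tab$actloop <- 1
  tab$psp <- 1
  tab$nwk <- 1
  tab$inka_score <- scores
  scale_and_rank(tab)
}

test_that("group aggregation averages per group and takes the difference", {
  tab <- data.frame(
    kinase = "KA",
    sample = sprintf("s%d", 1:6),
    scaled_score = c(40, 50, 45, 80, 90, 85),
    inka_score = c(40, 50, 45, 80, 90, 85),
    stringsAsFactors = FALSE
  )
  des <- toy_design(sprintf("s%d", 1:6), rep(c("control", "treated"), each = 3))
  agg <- aggregate_group_scores(tab, des)
  expect_equal(agg$mean_control, 45)
  expect_equal(agg$mean_treated, 85)
  expect_equal(agg$diff_of_means, 40)

  # permuting sample order leaves the result unchanged
  agg2 <- aggregate_group_scores(tab[sample(6), ], des)
  expect_equal(agg2, agg, ignore_attr = TRUE)

  # kinase absent from the table in one group scores 0 there
  tab_half <- tab[1:3, ]
  tab_half <- rbind(tab_half,
                    data.frame(kinase = "KB", sample = sprintf("s%d", 1:6),
                               scaled_score = 10, inka_score = 10,
                               stringsAsFactors = FALSE))
  agg3 <- aggregate_group_scores(tab_half, des)
  expect_equal(agg3$mean_treated[agg3$kinase == "KA"], 0)
  expect_equal(agg3$diff_of_means[agg3$kinase == "KA"], -45)

  expect_error(aggregate_group_scores(tab[tab$sample != "s1", ], des),
               "s1", class = "inkaflow_input_error")
})

test_that("difference ranking sorts, breaks ties, and truncates", {
  agg <- data.frame(kinase = c("A", "B", "C"),
                    diff_of_means = c(40, -10, 5),
                    stringsAsFactors = FALSE)
  expect_equal(rank_by_difference(agg, 2)$kinase, c("A", "C"))
  expect_equal(rank_by_difference(agg, 10)$kinase, c("A", "C", "B"))

  ties <- data.frame(kinase = c("Z", "A", "M"), diff_of_means = 1,
                     stringsAsFactors = FALSE)
  expect_equal(rank_by_difference(ties, 3)$kinase, c("A", "M", "Z"))
  expect_error(rank_by_difference(agg, 0), class = "inkaflow_config_error")
})

test_that("high-activity selection uses a strict threshold on the max score", {
  tab <- make_inka_tab("K1", sprintf("s%d", 1:3), c(76, 10, 5))
  tab$scaled_score <- c(76, 75, 10)
  tab$kinase <- c("K1", "K2", "K3")
  tab$sample <- "s1"
  expect_equal(select_active(tab, tau = 75), "K1")
  expect_equal(select_active(tab, tau = 100), character(0))
  expect_setequal(select_active(tab, tau = 0), c("K1", "K2", "K3"))
})

test_that("set intersections count every region", {
  out <- set_intersections(list(x = c("A", "B", "C"), y = c("B", "C", "D")))
  both <- out$count[out$x & out$y]
  only_x <- out$count[out$x & !out$y]
  only_y <- out$count[!out$x & out$y]
  expect_equal(both, 2)
  expect_equal(only_x, 1)
  expect_equal(only_y, 1)

  same <- set_intersections(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(same$count[same$x & same$y], 2)
  expect_equal(sum(same$count[xor(same$x, same$y)]), 0)

  disj <- set_intersections(list(x = "A", y = "B"))
  expect_equal(disj$count[disj$x & disj$y], 0)
  expect_error(set_intersections(list(x = "A")), class = "inkaflow_input_error")
})

test_that("hybrid direct sum adds arms then recombines and rescales", {
  py <- data.frame(kinase = "KA", sample = "s1", kinome = 10, actloop = 0,
                   psp = 20, nwk = 10, inka_score = combine_inka(10, 0, 20, 10),
                   stringsAsFactors = FALSE)
  py <- scale_and_rank(py)
  psty <- py
  psty[c("kinome", "actloop", "psp", "nwk")] <- 5
  psty$inka_score <- combine_inka(5, 5, 5, 5)
  psty <- scale_and_rank(psty)

  hyb <- hybrid_direct_sum(py, psty)
  expect_equal(hyb$kinome, 15)
  expect_equal(hyb$actloop, 5)
  expect_equal(hyb$psp, 25)
  expect_equal(hyb$nwk, 15)
  expect_equal(hyb$inka_score, sqrt(200))

  # commutative, and kinases present in only one table keep their arms
  psty2 <- psty
  psty2$kinase <- "KB"
  h1 <- hybrid_direct_sum(py, psty2)
  h2 <- hybrid_direct_sum(psty2, py)
  expect_equal(h1[order(h1$kinase), ], h2[order(h2$kinase), ],
               ignore_attr = TRUE)
  expect_equal(h1$kinome[h1$kinase == "KA"], 10)

  # empty partner degenerates to the other table
  empty <- py[0, ]
  expect_equal(hybrid_direct_sum(py, empty), py)

  # sum_scores mode adds the final scores instead
  hs <- hybrid_direct_sum(py, psty, hybrid_mode = "sum_scores")
  expect_equal(hs$inka_score, combine_inka(10, 0, 20, 10) + 5)

  bad <- py
  bad$sample <- "other"
  expect_error(hybrid_direct_sum(py, bad), class = "inkaflow_input_error")
})

test_that("kinase-substrate networks are assembled with observed sites", {
  ksr <- structure(list(
    edges = data.frame(
      kinase = c("KA", "KB", "KA"),
      substrate_protein = c("SP1", "SP1", "SP9"),
      substrate_gene = c("S1", "S1", "S9"),
      position = c(10L, 10L, 99L),
      residue = "S",
      sequence_window = "AAAAAAASAAAAAAA",
      evidence = "PSP",
      prediction_score = NA_real_,
      stringsAsFactors = FALSE
    ),
    own_sites = data.frame(),
    kinase_proteins = c(KA = "KPA", KB = "KPB"),
    activation_loops = data.frame()
  ), class = "ksr_database")
  # only SP1_10 is observed; SP9_99 is not in the matrix
  m <- toy_matrix(matrix(c(4, 6), 1, 2), proteins = "SP1", positions = 10L)
  scores <- data.frame(kinase = c("KA", "KB"), diff_of_means = c(3, -1),
                       stringsAsFactors = FALSE)
  g <- build_ksr_network(c("KA", "KB"), ksr, m, scores)
  expect_equal(igraph::vcount(g), 3)                 # 2 kinases + 1 site
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::V(g)$weight[igraph::V(g)$name == "KA"], 3)

  # kinase with no observed substrates stays as an isolated node
  g2 <- build_ksr_network("KB", ksr, toy_matrix(matrix(1, 1, 1),
                                                proteins = "OTHER"),
                          scores)
  expect_equal(igraph::vcount(g2), 1)
  expect_equal(igraph::ecount(g2), 0)

  expect_error(build_ksr_network(character(), ksr, m, scores),
               class = "inkaflow_input_error")

  # export: edge list TSV plus DOT
  ep <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".dot")
  write_ksr_network(g, ep, dp)
  ed <- utils::read.delim(ep)
  expect_equal(nrow(ed), 2)
  expect_named(ed, c("source", "target", "evidence", "weight"))
  expect_true(any(grepl("digraph", readLines(dp))))
})
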