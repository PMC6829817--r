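test_that("duplicate (miRNA, gene) pairs collapse to one interaction keeping the best score", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_table(path, list(
    c("miR-A", "G1", "-0.2"),
    c("miR-A", "G1", "-0.8"),
    c("miR-A", "G2", "-0.5")
  ), header = c("mirna", "gene", "score"))
  db <- suppressMessages(
    read_interactions(path, "predicted", dialect = dialect_canonical())
  )
  expect_equal(universe_size(db), 2)
  expect_equal(targets_of(db, "miR-A")$score[targets_of(db, "miR-A")$gene == "G1"], -0.8)
  expect_equal(db$n_evidence[db$gene == "G1"], 2L)
})

test_that("miRTarBase-style support types map to strong/weak evidence", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_table(path, list(
    c("hsa-miR-1-3p", "PTEN", "Functional MTI"),
    c("hsa-miR-1-3p", "TP53", "Functional MTI (Weak)"),
    c("hsa-miR-2-5p", "EGFR", "Non-Functional MTI (Weak)")
  ), header = c("miRNA", "Target Gene", "Support Type"))
  db <- suppressMessages(read_interactions(path, "validated"))
  expect_equal(sort(db$evidence), c("strong", "weak", "weak"))
  expect_equal(db$evidence[db$gene == "PTEN"], "strong")
})

test_that("a file missing a mapped column raises a format error naming the role", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_table(path, list(c("miR-A", "-0.5")),
                  header = c("mirna", "score"))
  expect_error(
    suppressMessages(
      read_interactions(path, "predicted", dialect = dialect_canonical())
    ),
    "gene", class = "mirten_error_format"
  )
  empty <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(character(0), empty)
  expect_error(
    read_interactions(empty, "predicted"),
    "empty", class = "mirten_error_format"
  )
})

test_that("gene symbols are matched case-insensitively, miRNA ids case-sensitively", {
  db <- interaction_db(
    data.frame(mirna = c("hsa-miR-1", "hsa-miR-1"),
               gene = c("pten", "PTEN")),
    source = "predicted"
  )
  expect_equal(universe_size(db), 1)
  expect_equal(db$gene, "PTEN")
  db2 <- interaction_db(
    data.frame(mirna = c("hsa-miR-1", "hsa-mir-1"), gene = "PTEN"),
    source = "predicted"
  )
  expect_equal(universe_size(db2), 2)
})

test_that("evidence filtering recomputes the universe and partitions it", {
  db <- interaction_db(
    data.frame(
      mirna = paste0("miR-", 1:8),
      gene = paste0("G", 1:8),
      evidence = rep(c("strong", "weak"), c(5, 3))
    ),
    source = "validated"
  )
  expect_equal(universe_size(filter_by_evidence(db, "strong")), 5)
  expect_equal(universe_size(filter_by_evidence(db, "weak")), 3)
  expect_equal(universe_size(filter_by_evidence(db, "strong_and_weak")), 8)
  expect_equal(
    universe_size(filter_by_evidence(db, "strong")) +
      universe_size(filter_by_evidence(db, "weak")),
    universe_size(filter_by_evidence(db, "strong_and_weak"))
  )
  only_strong <- filter_by_evidence(db, "strong")
  expect_s3_class(filter_by_evidence(only_strong, "weak"), "interaction_db")
  expect_equal(universe_size(filter_by_evidence(only_strong, "weak")), 0)
  expect_error(filter_by_evidence(toy_db("predicted"), "strong"),
               class = "mirten_error_usage")
})

test_that("top_targets ranks by score for predicted and by evidence multiplicity for validated", {
  db <- interaction_db(
    data.frame(mirna = "miR-A", gene = c("G1", "G2", "G3"),
               score = c(-0.9, -0.1, -0.5)),
    source = "predicted"
  )
  expect_equal(top_targets(db, "miR-A", 2), c("G1", "G3"))
  expect_equal(top_targets(db, "miR-A", 10), c("G1", "G3", "G2"))
  expect_error(top_targets(db, "miR-Z", 1), class = "mirten_error_lookup")

  # equal scores break ties lexicographically, stably across calls
  tied <- interaction_db(
    data.frame(mirna = "miR-T", gene = c("GB", "GA", "GC"), score = -0.5),
    source = "predicted"
  )
  expect_equal(top_targets(tied, "miR-T", 2), c("GA", "GB"))
  expect_identical(top_targets(tied, "miR-T", 2), top_targets(tied, "miR-T", 2))

  val <- interaction_db(
    data.frame(
      mirna = "miR-V",
      gene = c("G1", "G2", "G2", "G2", "G3", "G3"),
      evidence = "strong"
    ),
    source = "validated"
  )
  expect_equal(top_targets(val, "miR-V", 2), c("G2", "G3"))
})

test_that("synthetic databases are reproducible and respect the degree law", {
  a <- generate_synthetic_db(10, 1000, max_targets = 100, seed = 1)
  b <- generate_synthetic_db(10, 1000, max_targets = 100, seed = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(a),
    as.data.frame(generate_synthetic_db(10, 1000, max_targets = 100, seed = 2))
  ))

  # degenerate law: exactly 100 targets each
  fixed <- generate_synthetic_db(10, 1000, min_targets = 100,
                                 max_targets = 100, seed = 3)
  expect_equal(universe_size(fixed), 1000)
  counts <- dplyr::count(tibble::as_tibble(fixed), mirna)$n
  expect_true(all(counts == 100))

  expect_error(generate_synthetic_db(10, 50, max_targets = 100),
               class = "mirten_error_parameter")
})

test_that("generated target counts match the requested power-law exponent", {
  # continuous-MLE (Hill-type) estimate on the raw counts is an independent
  # check of the generator's tail behaviour
  kmin <- 5
  db <- generate_synthetic_db(500, 20000, exponent = 2.5,
                              min_targets = kmin, max_targets = 5000,
                              seed = 3)
  counts <- dplyr::count(tibble::as_tibble(db), mirna)$n
  hill <- 1 + length(counts) / sum(log(counts / (kmin - 0.5)))
  expect_lt(abs(hill - 2.5), 0.3)
})

test_that("the canonical table round-trips byte-for-byte through write/load", {
  db <- interaction_db(
    data.frame(
      mirna = c("miR-A", "miR-A", "miR-B"),
      gene = c("G1", "G1", "G2"),
      evidence = c("weak", "strong", "weak")
    ),
    source = "validated"
  )
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(db, f1)
  reloaded <- suppressMessages(
    read_interactions(f1, "validated", dialect = dialect_canonical())
  )
  write_interactions(reloaded, f2)
  expect_identical(readr::read_file(f1), readr::read_file(f2))
  expect_equal(reloaded$n_evidence, db$n_evidence)
})

test_that("per-miRNA index counts sum to the universe size", {
  db <- generate_synthetic_db(25, 800, max_targets = 80, seed = 5)
  per_mirna <- vapply(unique(db$mirna),
                      function(m) nrow(targets_of(db, m)), numeric(1))
  expect_equal(sum(per_mirna), universe_size(db))
  per_gene <- dplyr::count(tibble::as_tibble(db), gene)$n
  expect_equal(sum(per_gene), universe_size(db))
})
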