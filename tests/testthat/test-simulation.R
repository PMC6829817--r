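# small database reused across simulation tests: 40 miRNAs over 1500 genes
# with dense catalogues, so the planted-gene fraction is comparable to the
# full-scale conditions (about a quarter of the genome repressed)
small_db <- function(seed = 101) {
  generate_synthetic_db(40, 1500, exponent = 2, min_targets = 150,
                        max_targets = 500, seed = seed)
}

small_config <- function(seed = 1, alpha_grid = c(0.5, 1)) {
  sim_config(
    n_samples = 100, n_affected = 50, n_active = 2,
    target_counts = c(100, 300), alpha_grid = alpha_grid, seed = seed
  )
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_samples = 10, n_affected = 20),
               class = "mirten_error_parameter")
  expect_error(sim_config(n_active = 3, target_counts = c(10, 20)),
               class = "mirten_error_parameter")
  expect_error(sim_config(alpha_grid = c(0.5, -1)),
               class = "mirten_error_parameter")
})

test_that("simulation is reproducible and labels are consistent", {
  db <- small_db()
  cfg <- small_config(seed = 5)
  a <- simulate_expression(cfg, db, alpha = 0.5)
  b <- simulate_expression(cfg, db, alpha = 0.5)
  expect_identical(a$expression, b$expression)
  expect_identical(a$active_mirnas, b$active_mirnas)
  expect_equal(length(a$affected_samples), 50)
  expect_equal(dim(a$expression),
               c(length(unique(db$gene)), cfg$n_samples))
  expect_true(all(names(a$active_mirnas) %in% db$mirna))
  expect_equal(unname(a$active_mirnas), cfg$target_counts)
  # each active miRNA represses exactly its budget of top targets
  expect_equal(lengths(a$repressed_genes),
               setNames(c(100L, 300L), names(a$active_mirnas)))
  expect_identical(a$repressed_genes[[1]],
                   top_targets(db, names(a$active_mirnas)[1], 100))
})

test_that("a budget that exceeds every miRNA's catalogue is rejected", {
  db <- small_db()
  cfg <- sim_config(n_samples = 20, n_affected = 10, n_active = 1,
                    target_counts = 5000, alpha_grid = 1, seed = 1)
  expect_error(simulate_expression(cfg, db),
               class = "mirten_error_parameter")
})

test_that("baseline and repressed entries have the model's moments", {
  db <- small_db()
  cfg <- small_config(seed = 9)
  alpha <- 0.7
  ds <- simulate_expression(cfg, db, alpha = alpha)
  planted <- unique(unlist(ds$repressed_genes))
  unaffected <- setdiff(colnames(ds$expression), ds$affected_samples)

  base <- ds$expression[setdiff(rownames(ds$expression), planted), ]
  expect_equal(mean(base), 0, tolerance = 0.02)
  expect_equal(var(as.vector(base)), 1, tolerance = 0.05)

  # repressed entries: mean -alpha, variance 2 (difference of two standard
  # normals shifted by alpha)
  rep_block <- ds$expression[planted, ds$affected_samples]
  expect_equal(mean(rep_block), -alpha, tolerance = 0.06)
  expect_equal(var(as.vector(rep_block)), 2, tolerance = 0.12)
  # the same genes are untouched in unaffected samples
  expect_equal(mean(ds$expression[planted, unaffected]), 0, tolerance = 0.06)
})

test_that("derived gene lists recover planted targets at high activity", {
  db <- small_db()
  cfg <- small_config(seed = 3)
  ds <- simulate_expression(cfg, db, alpha = 1)
  genes <- derive_input_list(ds)
  expect_identical(genes, derive_input_list(ds))  # deterministic
  planted <- unique(unlist(ds$repressed_genes))
  recall <- length(intersect(genes, planted)) / length(planted)
  expect_gt(recall, 0.9)
})

test_that("with no planted effect the derived list stays near the FDR floor", {
  set.seed(77)
  genes <- sprintf("G%04d", 1:1500)
  null_ds <- structure(list(
    expression = matrix(rnorm(1500 * 60), nrow = 1500,
                        dimnames = list(genes, sprintf("S%03d", 1:60))),
    affected_samples = sprintf("S%03d", 1:30),
    active_mirnas = integer(0),
    repressed_genes = list(),
    alpha = NA_real_,
    config = small_config()
  ), class = "sim_dataset")
  expect_lt(length(derive_input_list(null_ds)) / 1500, 0.01)
})

test_that("welch statistics agree with stats::t.test row by row", {
  set.seed(13)
  mat <- matrix(rnorm(20 * 12), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  mine <- mirten:::welch_rows(mat, 1:6, 7:12)
  for (r in c(1, 7, 20)) {
    ref <- t.test(mat[r, 1:6], mat[r, 7:12], alternative = "less")
    expect_equal(mine$p_value[r], ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic[r], unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("roc_auc geometry: perfect, diagonal, and order invariance", {
  expect_equal(roc_auc(rep(0, 5), rep(1, 5)), 1)
  expect_equal(roc_auc(0.5, 0.5), 0.5)
  pts_fpr <- c(0.1, 0.4, 0.8)
  pts_tpr <- c(0.5, 0.7, 0.9)
  ord <- sample(3)
  expect_equal(roc_auc(pts_fpr, pts_tpr), roc_auc(pts_fpr[ord], pts_tpr[ord]))
  expect_error(roc_auc(c(0, 1.2), c(0, 1)), class = "mirten_error_domain")

  # coin-flip detector: a single operating point scattered around the
  # diagonal gives no discrimination on average
  set.seed(19)
  aucs <- purrr::map_dbl(1:500, function(i) {
    roc_auc(rbinom(1, 190, 0.5) / 190, rbinom(1, 10, 0.5) / 10)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("detection power grows with activity over replicate seeds", {
  db <- small_db()
  evals <- purrr::map(1:10, function(s) {
    evaluate_detection(db, small_config(seed = s, alpha_grid = c(0.3, 1)))
  })
  tpr_low <- purrr::map_dbl(evals, ~ .x$points$tpr[.x$points$alpha == 0.3])
  tpr_high <- purrr::map_dbl(evals, ~ .x$points$tpr[.x$points$alpha == 1])
  expect_gte(mean(tpr_high), mean(tpr_low))
  expect_gt(mean(tpr_high), 0.8)
  for (e in evals) {
    expect_true(all(e$points$tpr >= 0 & e$points$tpr <= 1))
    expect_true(all(e$points$fpr >= 0 & e$points$fpr <= 1))
    expect_equal(e$auc, roc_auc(e$points$fpr, e$points$tpr))
  }
})

test_that("the 75th-percentile rule selects strictly-above miRNAs after averaging repeats", {
  profile <- tibble::tibble(
    mirna = sprintf("hsa-miR-%03d", 1:100),
    expression = 1:100
  )
  sel <- select_representative_mirnas(profile, percentile = 75)
  # linear-interpolation quantile of 1..100 at 0.75 is 75.25
  expect_setequal(sel, sprintf("hsa-miR-%03d", 76:100))

  flat <- tibble::tibble(mirna = c("a", "b"), expression = c(3, 3))
  expect_length(select_representative_mirnas(flat), 0)

  repeats <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m3", "m4", "m4"),
    expression = c(100, 0, 10, 10, 4, 4, 2, 2)
  )
  # m1 averages to 50 and ranks top; the raw value 100 must not be used
  expect_setequal(select_representative_mirnas(repeats, 70), "m1")
  expect_error(select_representative_mirnas(profile, 100),
               class = "mirten_error_parameter")
})

test_that("representative proteins are the High-level entries", {
  prof <- tibble::tibble(
    gene = c("A", "B", "C", "D", "A"),
    level = c("High", "Medium", "high", "Not detected", "High")
  )
  expect_setequal(select_representative_proteins(prof), c("A", "C"))
})

test_that("PPV scores detected miRNAs against the representative set", {
  # 10 signal miRNAs all target the 10 input genes; 50 background miRNAs
  # target the rest of the genome, so only the signal miRNAs are detected
  input <- sprintf("G%03d", 1:10)
  signal <- data.frame(
    mirna = rep(sprintf("miR-%02d", 1:10), each = 10),
    gene = rep(input, 10)
  )
  noise <- data.frame(
    mirna = rep(sprintf("miR-bg-%02d", 1:50), each = 10),
    gene = sprintf("G%03d", 10 + seq_len(500) %% 90 + 1)
  )
  db <- interaction_db(rbind(signal, noise), source = "predicted")
  rep_mirnas <- sprintf("miR-%02d", 1:7)
  res <- ppv_evaluation(input, rep_mirnas, db)
  expect_equal(res$n_detected, 10)
  expect_equal(res$tp, 7)
  expect_equal(res$fp, 3)
  expect_equal(res$ppv, 0.7)
  expect_false(res$undefined)

  all_rep <- ppv_evaluation(input, sprintf("miR-%02d", 1:10), db)
  expect_equal(all_rep$ppv, 1)

  none_rep <- ppv_evaluation(input, "miR-99", db)
  expect_equal(none_rep$ppv, 0)

  # a single background gene enriches nothing: guarded division
  sparse <- ppv_evaluation("G015", rep_mirnas, db)
  expect_true(sparse$undefined)
  expect_true(is.na(sparse$ppv))
})
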