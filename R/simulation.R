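#' Simulation configuration
#'
#' Conditions for the planted-activity simulation: `n_samples` samples of
#' which `n_affected` are affected by miRNA repression; `n_active` miRNAs
#' planted as active, the j-th repressing its top `target_counts[j]`
#' targets; activity levels swept over `alpha_grid`. The defaults are the
#' full-scale study conditions: 100 samples, 50 affected, 10 active miRNAs
#' with target budgets 100, 200, ..., 1000, and alpha from 0.3 to 1 in
#' steps of 0.05.
#'
#' @param n_samples total number of samples.
#' @param n_affected number of samples affected by the planted repression
#'   (must not exceed `n_samples`).
#' @param n_active number of active miRNAs.
#' @param target_counts per-miRNA target budgets; length `n_active`.
#' @param alpha_grid positive activity levels to sweep.
#' @param seed master seed; per-alpha seeds are derived from it by fixed
#'   offsets.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, n_affected = 50, n_active = 10,
                       target_counts = seq(100, 1000, by = 100),
                       alpha_grid = seq(0.3, 1, by = 0.05), seed = 1L) {
  if (n_affected > n_samples || n_affected < 1 || n_samples < 2) {
    abort_parameter("need 1 <= n_affected <= n_samples and n_samples >= 2")
  }
  if (length(target_counts) != n_active) {
    abort_parameter("target_counts must have length n_active")
  }
  if (any(target_counts < 1)) {
    abort_parameter("target budgets must be positive")
  }
  if (length(alpha_grid) == 0 || any(alpha_grid <= 0)) {
    abort_parameter("alpha levels must be positive")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_affected = as.integer(n_affected),
      n_active = as.integer(n_active),
      target_counts = as.integer(target_counts),
      alpha_grid = as.numeric(alpha_grid),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate expression with planted miRNA activity
#'
#' Generates a genes-by-samples expression matrix over all genes of the
#' database. Every entry is drawn i.i.d. from a standard normal; then
#' `n_active` miRNAs, chosen uniformly at random among those with at least
#' `max(target_counts)` targets, are made active: for active miRNA j, each
#' of its top `target_counts[j]` targets g gets, in each affected sample s,
#' \deqn{E(g, s) = N(0,1) - (\alpha + N(0,1)),} i.e. the baseline is
#' reduced by the activity level \eqn{\alpha} plus standard-normal noise.
#' A repressed entry therefore has mean \eqn{-\alpha} and variance 2.
#'
#' @param config a [sim_config()].
#' @param db an [interaction_db] providing target ranks.
#' @param alpha activity level; defaults to the first grid point.
#' @param seed seed for this dataset; defaults to `config$seed`.
#' @return an object of class `sim_dataset`: list with the `expression`
#'   matrix (genes x samples), `active_mirnas` (named integer vector of
#'   budgets), `affected_samples`, `repressed_genes` (per-miRNA target
#'   lists), `alpha`, `config`.
#' @export
simulate_expression <- function(config, db, alpha = config$alpha_grid[1],
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), is_interaction_db(db))
  if (alpha <= 0) abort_parameter("alpha must be positive")
  max_budget <- max(config$target_counts)
  per_mirna <- dplyr::count(as_tibble(db), .data$mirna)
  eligible <- per_mirna$mirna[per_mirna$n >= max_budget]
  if (length(eligible) < config$n_active) {
    abort_parameter(sprintf(
      "only %d miRNAs have >= %d targets; need %d active miRNAs",
      length(eligible), max_budget, config$n_active
    ))
  }
  genes <- sort(unique(db$gene))
  n_genes <- length(genes)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  with_seed(seed, {
    active <- sample(eligible, config$n_active)
    budgets <- setNames(config$target_counts, active)
    affected <- sort(sample(samples, config$n_affected))
    expr <- matrix(
      rnorm(n_genes * config$n_samples),
      nrow = n_genes, dimnames = list(genes, samples)
    )
    repressed <- purrr::imap(budgets, function(k, m) top_targets(db, m, k))
    aff_idx <- match(affected, samples)
    for (targets in repressed) {
      rows <- match(targets, genes)
      m <- length(rows) * length(aff_idx)
      expr[rows, aff_idx] <- rnorm(m) - (alpha + rnorm(m))
    }
    structure(
      list(
        expression = expr,
        active_mirnas = budgets,
        affected_samples = affected,
        repressed_genes = repressed,
        alpha = alpha,
        config = config
      ),
      class = "sim_dataset"
    )
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d genes x %d samples, %d active miRNAs, alpha = %.2f\n",
    nrow(x$expression), ncol(x$expression), length(x$active_mirnas), x$alpha
  ))
  invisible(x)
}

# Vectorized Welch two-sample t-test over matrix rows; returns one-sided
# p-values for mean(group1) < mean(group2).
welch_rows <- function(mat, idx1, idx2) {
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- length(idx1)
  n2 <- length(idx2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble(
    gene = rownames(mat),
    statistic = unname(tstat),
    df = unname(df),
    p_value = unname(pt(tstat, df))
  )
}

#' Derive the down-regulated gene list from a simulated dataset
#'
#' Per-gene Welch two-sample t-test of affected vs unaffected samples,
#' one-sided for down-regulation (repression lowers expression in affected
#' samples), BH-adjusted. Genes passing the FDR threshold form the input
#' list fed to the enrichment stage. Deterministic given the dataset.
#'
#' @param dataset a `sim_dataset`.
#' @param fdr_threshold BH cutoff, default 0.05.
#' @return character vector of gene symbols.
#' @export
derive_input_list <- function(dataset, fdr_threshold = 0.05) {
  stopifnot(inherits(dataset, "sim_dataset"))
  samples <- colnames(dataset$expression)
  aff <- match(dataset$affected_samples, samples)
  unaff <- setdiff(seq_along(samples), aff)
  if (length(aff) < 2 || length(unaff) < 2) {
    abort_usage("need at least 2 affected and 2 unaffected samples")
  }
  tests <- welch_rows(dataset$expression, aff, unaff)
  tests$fdr <- adjust_fdr(tests$p_value)
  tests$gene[tests$fdr <= fdr_threshold]
}

#' Trapezoidal AUC of ROC points
#'
#' Sorts the operating points by false-positive rate, anchors them at
#' (0, 0) and (1, 1), takes the monotone staircase (running maximum of the
#' true-positive rate), and integrates by the trapezoidal rule. The result
#' does not depend on the order the points are supplied in.
#'
#' @param fpr,tpr numeric vectors in `[0, 1]` of equal length.
#' @return the area under the curve, in `[0, 1]`.
#' @export
roc_auc <- function(fpr, tpr) {
  if (length(fpr) != length(tpr)) {
    abort_usage("fpr and tpr must have equal length")
  }
  if (any(fpr < 0 | fpr > 1 | tpr < 0 | tpr > 1)) {
    abort_domain("rates must lie in [0, 1]")
  }
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord], 1)
  y <- cummax(c(0, tpr[ord], 1))
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Evaluate planted-miRNA detection over the activity grid
#'
#' For each activity level alpha in the configuration: simulate a dataset,
#' derive the down-regulated gene list, run the miRNA-target enrichment
#' under default parameters (FDR <= `detection_fdr`, overlap >= 1), and
#' call every surviving miRNA "detected". Sensitivity (TPR) is the fraction
#' of truly active miRNAs detected; the false-positive rate is the fraction
#' of inactive database miRNAs detected. The per-alpha points form a ROC
#' curve summarized by its trapezoidal AUC ([roc_auc()]).
#'
#' Each alpha level is simulated independently with a seed derived from the
#' master seed, so the sweep is reproducible and levels are uncoupled.
#'
#' @param db an [interaction_db].
#' @param config a [sim_config()].
#' @param detection_fdr enrichment FDR cutoff defining "detected";
#'   default 0.05.
#' @return an object of class `roc_eval`: list with `points` (tibble
#'   `alpha`, `n_input_genes`, `n_detected`, `tpr`, `fpr`), `auc`,
#'   `detected` (per-alpha miRNA sets), and `config`.
#' @export
evaluate_detection <- function(db, config, detection_fdr = 0.05) {
  stopifnot(is_interaction_db(db), inherits(config, "sim_config"))
  all_mirnas <- unique(db$mirna)
  detected_sets <- list()
  points <- purrr::map_dfr(seq_along(config$alpha_grid), function(i) {
    alpha <- config$alpha_grid[i]
    ds <- simulate_expression(
      config, db, alpha = alpha,
      seed = derive_seed(config$seed, i)
    )
    gene_list <- derive_input_list(ds)
    detected <- character(0)
    if (length(gene_list) > 0) {
      res <- enrich(db, gene_list, direction = "genes_in_mirnas_out")
      hits <- filter_results(res, threshold = detection_fdr, on = "fdr",
                             min_overlap = 1)
      detected <- hits$item
    }
    detected_sets[[as.character(alpha)]] <<- detected
    active <- names(ds$active_mirnas)
    inactive <- setdiff(all_mirnas, active)
    tibble(
      alpha = alpha,
      n_input_genes = length(gene_list),
      n_detected = length(detected),
      tpr = length(intersect(detected, active)) / length(active),
      fpr = if (length(inactive) == 0) 0 else
        length(intersect(detected, inactive)) / length(inactive)
    )
  })
  structure(
    list(
      points = points,
      auc = roc_auc(points$fpr, points$tpr),
      detected = detected_sets,
      config = config
    ),
    class = "roc_eval"
  )
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf(
    "<roc_eval> %d alpha levels, AUC = %.3f\n", nrow(x$points), x$auc
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roc_eval <- function(x, ...) as_tibble(x$points)

#' @exportS3Method generics::glance
glance.roc_eval <- function(x, ...) {
  tibble(
    auc = x$auc,
    n_alpha = nrow(x$points),
    n_active = x$config$n_active,
    n_samples = x$config$n_samples,
    seed = x$config$seed
  )
}

#' Select the most tissue-representative miRNAs from an expression profile
#'
#' Repeat measurements of the same miRNA are averaged into one profile;
#' miRNAs whose averaged expression is strictly greater than the given
#' percentile of the profile's distribution are selected. The percentile
#' uses the linear-interpolation quantile convention
#' ([stats::quantile()] type 7).
#'
#' @param profile a data frame with columns `mirna` and `expression`
#'   (several rows per miRNA allowed — they are repeat measurements).
#' @param percentile percentile cutoff in `[0, 100)`; default 75.
#' @return character vector of selected miRNA IDs.
#' @export
select_representative_mirnas <- function(profile, percentile = 75) {
  profile <- as_tibble(profile)
  if (!all(c("mirna", "expression") %in% names(profile)) ||
      nrow(profile) == 0) {
    abort_usage("profile needs non-empty 'mirna' and 'expression' columns")
  }
  if (percentile < 0 || percentile >= 100) {
    abort_parameter("percentile must lie in [0, 100)")
  }
  avg <- profile %>%
    mutate(mirna = normalize_mirna(.data$mirna)) %>%
    group_by(.data$mirna) %>%
    summarise(expression = mean(.data$expression), .groups = "drop")
  cutoff <- quantile(avg$expression, percentile / 100, type = 7,
                     names = FALSE)
  avg$mirna[avg$expression > cutoff]
}

#' Select the most tissue-representative proteins
#'
#' From an immunohistochemistry-style (gene, level) table, keeps genes
#' whose expression level is `"High"` (case-insensitive).
#'
#' @param profile a data frame with columns `gene` and `level`.
#' @return character vector of gene symbols.
#' @export
select_representative_proteins <- function(profile) {
  profile <- as_tibble(profile)
  if (!all(c("gene", "level") %in% names(profile))) {
    abort_usage("profile needs 'gene' and 'level' columns")
  }
  unique(normalize_gene(profile$gene[tolower(profile$level) == "high"]))
}

#' Positive predictive value of representative-miRNA detection
#'
#' Runs the gene-list enrichment under default parameters on the most
#' tissue-representative proteins and scores the detected miRNAs against
#' the most tissue-representative miRNAs: detected miRNAs in the
#' representative set are true positives, the rest false positives, and
#' \deqn{PPV = TP / (TP + FP)} — 1 in a perfect test. When no miRNA is
#' detected the PPV is undefined and returned as `NA` with
#' `undefined = TRUE`.
#'
#' @param representative_proteins character vector of gene symbols.
#' @param representative_mirnas character vector of miRNA IDs.
#' @param db an [interaction_db].
#' @param detection_fdr enrichment FDR cutoff, default 0.05.
#' @return a one-row tibble of class `ppv_result`: `tp`, `fp`,
#'   `n_detected`, `ppv`, `undefined`.
#' @export
ppv_evaluation <- function(representative_proteins, representative_mirnas,
                           db, detection_fdr = 0.05) {
  stopifnot(is_interaction_db(db))
  if (length(representative_proteins) == 0 ||
      length(representative_mirnas) == 0) {
    abort_usage("representative protein and miRNA sets must be non-empty")
  }
  res <- enrich(db, representative_proteins,
                direction = "genes_in_mirnas_out")
  detected <- filter_results(res, threshold = detection_fdr, on = "fdr",
                             min_overlap = 1)$item
  truth <- unique(normalize_mirna(representative_mirnas))
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  out <- tibble(
    tp = tp,
    fp = fp,
    n_detected = length(detected),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    undefined = tp + fp == 0
  )
  class(out) <- c("ppv_result", class(out))
  out
}
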