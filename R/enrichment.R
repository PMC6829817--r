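#' Upper-tail hypergeometric p-value
#'
#' The over-representation statistic: the probability of observing at least
#' `X` marked items when drawing `N` items without replacement from a
#' universe of `M` items of which `K` are marked,
#' \deqn{p = 1 - \sum_{i=0}^{X-1} \frac{\binom{K}{i}\binom{M-K}{N-i}}
#'   {\binom{M}{N}}.}
#' The sum is evaluated on the upper tail in log space (via `lchoose`), so
#' it is numerically stable for universes up to millions of interactions.
#' All arguments are vectorized and recycled.
#'
#' @param M universe size.
#' @param K marked items in the universe (an item's interactions).
#' @param N draw size (input-list length).
#' @param X observed marked items in the draw (overlap).
#' @return `P(count >= X)`, in `[0, 1]`.
#' @examples
#' hypergeom_pvalue(10, 4, 5, 3) # 66/252
#' @export
hypergeom_pvalue <- function(M, K, N, X) {
  n <- max(length(M), length(K), length(N), length(X))
  M <- rep_len(as.numeric(M), n)
  K <- rep_len(as.numeric(K), n)
  N <- rep_len(as.numeric(N), n)
  X <- rep_len(as.numeric(X), n)
  ok <- !is.na(M) & !is.na(K) & !is.na(N) & !is.na(X) &
    M >= 0 & K >= 0 & N >= 0 & X >= 0 &
    K <= M & N <= M & X <= pmin(K, N) &
    M == floor(M) & K == floor(K) & N == floor(N) & X == floor(X)
  if (!all(ok)) {
    abort_domain(
      "hypergeom_pvalue needs integers with 0 <= K <= M, 0 <= N <= M, 0 <= X <= min(K, N)"
    )
  }
  vapply(seq_len(n), function(j) {
    if (X[j] == 0) {
      return(1)
    }
    i <- seq(X[j], min(K[j], N[j]))
    lt <- lchoose(K[j], i) + lchoose(M[j] - K[j], N[j] - i) -
      lchoose(M[j], N[j])
    min(1, sum(exp(lt)))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), order-preserving with
#' the input and clipped to 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_domain("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' miRNA-target over-representation analysis
#'
#' Tests each candidate item for over-representation of its interactions in
#' the input list. With a gene list in input, candidates are the database's
#' miRNAs (which miRNAs' targets are over-represented among these genes?);
#' with a miRNA list in input, candidates are target genes (which genes are
#' over-represented as targets of these miRNAs?).
#'
#' For each candidate, `K` is its number of interactions in the database,
#' `X` how many of them fall in the input list, `N` the deduplicated
#' input-list length, and `M` the universe size. The default
#' (`universe = "interactions"`) takes `M` as the total number of
#' interactions in the database. The alternative `universe = "entities"`
#' uses a self-consistent urn instead: `M` is the number of distinct
#' partner entities in the database (genes for a gene-list input, miRNAs
#' for a miRNA-list input) and `N` counts only input members present in the
#' database.
#'
#' Raw p-values come from [hypergeom_pvalue()]; FDR adjustment (BH) is
#' performed over all candidates present in the database (`K >= 1`), not
#' only those overlapping the input. Input identifiers absent from the
#' database are not dropped silently: they are kept in the `unmatched`
#' attribute and reported as a message.
#'
#' @param db an [interaction_db].
#' @param input_list character vector of gene symbols or mature miRNA IDs
#'   (deduplicated internally).
#' @param direction `"genes_in_mirnas_out"` or `"mirnas_in_genes_out"`.
#' @param universe `"interactions"` (classic convention: M = total
#'   interactions) or `"entities"` (M = distinct partner entities).
#' @return a tibble of class `mirna_enrichment` with one row per candidate
#'   with `X >= 1`, sorted by `p_value` then item: columns `item`, `M`,
#'   `N`, `K`, `X`, `p_value`, `fdr`, and list-column `overlap`.
#'   Attributes: `direction`, `universe`, `unmatched`, `n_candidates`.
#' @examples
#' db <- interaction_db(
#'   data.frame(
#'     mirna = rep(c("miR-A", "miR-B"), c(3, 2)),
#'     gene = c("G1", "G2", "G3", "G4", "G5")
#'   ),
#'   source = "predicted"
#' )
#' enrich(db, c("G1", "G2", "G3"))
#' @export
enrich <- function(db, input_list,
                   direction = c("genes_in_mirnas_out",
                                 "mirnas_in_genes_out"),
                   universe = c("interactions", "entities")) {
  stopifnot(is_interaction_db(db))
  direction <- match.arg(direction)
  universe <- match.arg(universe)
  genes_in <- direction == "genes_in_mirnas_out"

  input <- if (genes_in) normalize_gene(input_list) else
    normalize_mirna(input_list)
  input <- unique(input[nzchar(input)])
  if (length(input) == 0) {
    abort_usage("input list is empty after deduplication")
  }
  member_col <- if (genes_in) "gene" else "mirna"
  item_col <- if (genes_in) "mirna" else "gene"

  known <- unique(db[[member_col]])
  unmatched <- setdiff(input, known)
  if (length(unmatched) > 0) {
    inform(sprintf(
      "enrich: %d of %d input identifiers not found in the database",
      length(unmatched), length(input)
    ))
  }
  # crude identifier-type check: gene lists should not look like miRBase IDs
  looks_mirna <- mean(stringr::str_detect(input, stringr::regex(
    "mir|let-7", ignore_case = TRUE
  ))) > 0.5
  if (genes_in && looks_mirna) {
    warn("input looks like miRNA identifiers but direction is genes_in_mirnas_out")
  }
  if (!genes_in && !looks_mirna) {
    warn("input looks like gene symbols but direction is mirnas_in_genes_out")
  }

  M <- if (universe == "interactions") nrow(db) else length(known)
  N <- if (universe == "interactions") length(input) else
    length(intersect(input, known))
  if (N > M) {
    abort_usage("input list is longer than the universe")
  }

  tab <- tibble(item = db[[item_col]], member = db[[member_col]]) %>%
    group_by(.data$item) %>%
    summarise(
      K = dplyr::n(),
      X = sum(.data$member %in% input),
      overlap = list(sort(.data$member[.data$member %in% input])),
      .groups = "drop"
    ) %>%
    mutate(
      M = M,
      N = N,
      p_value = hypergeom_pvalue(M, .data$K, N, .data$X),
      fdr = adjust_fdr(.data$p_value)
    )
  n_candidates <- nrow(tab)
  out <- tab %>%
    filter(.data$X >= 1) %>%
    arrange(.data$p_value, .data$item) %>%
    select("item", "M", "N", "K", "X", "p_value", "fdr", "overlap")
  class(out) <- c("mirna_enrichment", class(out))
  attr(out, "direction") <- direction
  attr(out, "universe") <- universe
  attr(out, "unmatched") <- unmatched
  attr(out, "n_candidates") <- n_candidates
  out
}

#' Filter enrichment results
#'
#' Keeps rows whose significance metric passes a threshold and whose
#' overlap with the input list is large enough.
#'
#' @param rows an enrichment table from [enrich()] or [ora()].
#' @param threshold significance cutoff in `(0, 1]`.
#' @param on `"fdr"` (default) or `"p_value"`.
#' @param min_overlap minimum overlap count `X` (or `hits`), >= 1.
#' @return the filtered table, attributes preserved.
#' @export
filter_results <- function(rows, threshold = 0.05,
                           on = c("fdr", "p_value"), min_overlap = 1) {
  on <- match.arg(on)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort_parameter("threshold must lie in (0, 1]")
  }
  if (min_overlap < 1) {
    abort_parameter("min_overlap must be >= 1")
  }
  count_col <- if ("X" %in% names(rows)) "X" else "hits"
  keep <- rows[[on]] <= threshold & rows[[count_col]] >= min_overlap
  out <- rows[keep, , drop = FALSE]
  for (a in c("direction", "universe", "unmatched", "n_candidates")) {
    attr(out, a) <- attr(rows, a)
  }
  out
}

#' Write an enrichment table as tab-delimited text
#'
#' Overlap members are semicolon-joined so the file opens cleanly in
#' spreadsheet programs.
#'
#' @param rows a `mirna_enrichment` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  readr::write_tsv(tidy_enrichment(rows), path, progress = FALSE)
  invisible(path)
}

tidy_enrichment <- function(x) {
  out <- as_tibble(x)
  if ("overlap" %in% names(out) && is.list(out$overlap)) {
    out$overlap <- purrr::map_chr(out$overlap, paste, collapse = ";")
  }
  out
}

#' @exportS3Method generics::tidy
tidy.mirna_enrichment <- function(x, ...) tidy_enrichment(x)

#' @exportS3Method generics::glance
glance.mirna_enrichment <- function(x, ...) {
  tibble(
    direction = attr(x, "direction") %||% NA_character_,
    universe = attr(x, "universe") %||% NA_character_,
    M = if (nrow(x) > 0) x$M[1] else NA_integer_,
    N = if (nrow(x) > 0) x$N[1] else NA_integer_,
    n_candidates = attr(x, "n_candidates") %||% NA_integer_,
    n_enriched = nrow(x),
    n_unmatched = length(attr(x, "unmatched"))
  )
}

#' @export
print.mirna_enrichment <- function(x, ...) {
  cat(sprintf(
    "<mirna_enrichment> %s, %d of %d candidates with overlap, %d unmatched input ids\n",
    attr(x, "direction") %||% "?", nrow(x),
    attr(x, "n_candidates") %||% NA_integer_,
    length(attr(x, "unmatched"))
  ))
  NextMethod()
}
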