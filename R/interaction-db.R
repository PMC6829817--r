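#' Interaction databases
#'
#' An interaction database is a deduplicated tibble of miRNA-target
#' interactions — one row per (miRNA, gene) pair — that serves as the
#' statistical universe for enrichment analysis. Columns:
#'
#' * `mirna` — mature miRNA identifier (miRBase style, case-sensitive);
#' * `gene` — official gene symbol, upper-cased on ingestion;
#' * `source` — `"predicted"` or `"validated"`;
#' * `evidence` — `"strong"`/`"weak"` for validated interactions, `"none"`
#'   for predicted ones;
#' * `score` — ranking score for predicted interactions (TargetScan
#'   context++ convention: more negative means stronger predicted
#'   repression); `NA` for validated;
#' * `family` — optional miRNA family/seed annotation;
#' * `n_evidence` — number of raw support rows collapsed into the pair
#'   (used to rank "top targets" of a validated database).
#'
#' The universe size M of the hypergeometric test is `nrow(db)`.
#'
#' @param records a data frame with at least `mirna` and `gene` columns.
#' @param source `"predicted"` or `"validated"`.
#' @return a tibble of class `interaction_db`.
#' @examples
#' db <- interaction_db(
#'   data.frame(
#'     mirna = c("hsa-miR-1-3p", "hsa-miR-1-3p"),
#'     gene = c("PTEN", "tp53"),
#'     score = c(-0.4, -0.1)
#'   ),
#'   source = "predicted"
#' )
#' universe_size(db)
#' @export
interaction_db <- function(records, source = c("predicted", "validated")) {
  source <- match.arg(source)
  records <- as_tibble(records)
  if (!all(c("mirna", "gene") %in% names(records))) {
    abort_format("records need 'mirna' and 'gene' columns")
  }
  records <- records %>%
    mutate(
      mirna = normalize_mirna(.data$mirna),
      gene = normalize_gene(.data$gene)
    ) %>%
    filter(nzchar(.data$mirna), nzchar(.data$gene))
  if (!"score" %in% names(records)) records$score <- NA_real_
  if (!"evidence" %in% names(records)) {
    records$evidence <- if (source == "predicted") "none" else "strong"
  }
  if (!"family" %in% names(records)) records$family <- NA_character_
  records$score <- as.numeric(records$score)
  records$evidence <- tolower(as.character(records$evidence))
  if (!"n_evidence" %in% names(records)) records$n_evidence <- 1L
  records$n_evidence <- as.integer(records$n_evidence)

  if (source == "predicted") {
    records$evidence <- "none"
    # several predicted sites per pair collapse to the best (most negative)
    # score
    dedup <- records %>%
      group_by(.data$mirna, .data$gene) %>%
      arrange(.data$score, .by_group = TRUE) %>%
      summarise(
        score = .data$score[1],
        evidence = "none",
        family = .data$family[1],
        n_evidence = sum(.data$n_evidence),
        .groups = "drop"
      )
  } else {
    bad <- setdiff(unique(records$evidence), c("strong", "weak"))
    if (length(bad) > 0) {
      abort_format(paste0(
        "validated evidence must be 'strong' or 'weak', got: ",
        paste(bad, collapse = ", ")
      ))
    }
    # duplicates keep the strongest evidence; evidence multiplicity is kept
    # as the surrogate ranking key for top_targets()
    dedup <- records %>%
      group_by(.data$mirna, .data$gene) %>%
      summarise(
        score = NA_real_,
        evidence = if (any(.data$evidence == "strong")) "strong" else "weak",
        family = .data$family[1],
        n_evidence = sum(.data$n_evidence),
        .groups = "drop"
      )
  }
  out <- dedup %>%
    mutate(source = source) %>%
    select(
      "mirna", "gene", "source", "evidence", "score", "family", "n_evidence"
    ) %>%
    arrange(.data$mirna, .data$gene)
  class(out) <- c("interaction_db", class(out))
  out
}

#' @rdname interaction_db
#' @param x an object.
#' @export
is_interaction_db <- function(x) inherits(x, "interaction_db")

#' @rdname interaction_db
#' @param db an `interaction_db`.
#' @export
universe_size <- function(db) {
  stopifnot(is_interaction_db(db))
  nrow(db)
}

db_source <- function(db) {
  if (nrow(db) == 0) "predicted" else db$source[1]
}

#' Column dialects for interaction tables
#'
#' A dialect maps the columns of a delimited interaction table onto the
#' canonical fields. Each entry is a character vector of candidate header
#' names tried in order; `NULL` means the field is absent. Ready-made
#' dialects cover TargetScan-style predicted tables (`"miR Family"` /
#' `"miRNA"`, `"Gene Symbol"`, context++ score columns), miRTarBase-style
#' validated tables (`"miRNA"`, `"Target Gene"`, `"Support Type"`), and the
#' canonical format written by [write_interactions()].
#'
#' @param mirna,gene,score,evidence,family candidate column names.
#' @return a named list usable as the `dialect` argument of
#'   [read_interactions()].
#' @export
dialect <- function(mirna, gene, score = NULL, evidence = NULL, family = NULL) {
  list(mirna = mirna, gene = gene, score = score, evidence = evidence,
       family = family)
}

#' @rdname dialect
#' @export
dialect_targetscan <- function() {
  dialect(
    mirna = c("miRNA", "miR Family"),
    gene = c("Gene Symbol"),
    score = c(
      "Cumulative weighted context++ score",
      "weighted context++ score",
      "context++ score",
      "Context++ score"
    ),
    family = c("miR Family", "Seed match")
  )
}

#' @rdname dialect
#' @export
dialect_mirtarbase <- function() {
  dialect(
    mirna = c("miRNA"),
    gene = c("Target Gene"),
    evidence = c("Support Type")
  )
}

#' @rdname dialect
#' @export
dialect_canonical <- function() {
  dialect(
    mirna = "mirna", gene = "gene", score = "score",
    evidence = "evidence", family = "family"
  )
}

pick_column <- function(header, candidates, role, required = TRUE) {
  if (is.null(candidates)) {
    return(NULL)
  }
  hit <- candidates[candidates %in% header]
  if (length(hit) == 0) {
    if (required) {
      abort_format(paste0(
        "no column for '", role, "' found; looked for: ",
        paste(candidates, collapse = ", ")
      ))
    }
    return(NULL)
  }
  hit[1]
}

# miRTarBase support-type strings: anything flagged "(Weak)" is weak
# evidence, everything else (e.g. "Functional MTI") is strong.
map_support_type <- function(x) {
  ifelse(stringr::str_detect(x, stringr::fixed("(Weak)")), "weak", "strong")
}

#' Read a miRNA-target interaction table
#'
#' Loads a delimited text file with a header row, maps its columns through a
#' [dialect], normalizes identifiers, collapses duplicate (miRNA, gene)
#' pairs — keeping the best score for predicted tables and the strongest
#' evidence for validated ones — and returns an indexed [interaction_db].
#' A load report (rows read, rows dropped, duplicates collapsed) is emitted
#' as a message.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param source `"predicted"` or `"validated"`.
#' @param dialect a column mapping from [dialect()]; defaults to the
#'   TargetScan dialect for predicted sources and the miRTarBase dialect for
#'   validated ones.
#' @param delim field delimiter; `NULL` auto-detects tab vs comma from the
#'   header line.
#' @return an [interaction_db].
#' @export
read_interactions <- function(path, source = c("predicted", "validated"),
                              dialect = NULL, delim = NULL) {
  source <- match.arg(source)
  if (!file.exists(path)) {
    abort_usage(paste0("interaction table not found: ", path))
  }
  if (is.null(dialect)) {
    dialect <- if (source == "predicted") dialect_targetscan() else
      dialect_mirtarbase()
  }
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    abort_format(paste0("empty interaction file: ", path))
  }
  if (is.null(delim)) {
    delim <- if (stringr::str_detect(first, "\t")) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0) {
    abort_format(paste0("interaction file has a header but no rows: ", path))
  }
  header <- names(raw)
  col_mirna <- pick_column(header, dialect$mirna, "mirna")
  col_gene <- pick_column(header, dialect$gene, "gene")
  col_score <- pick_column(header, dialect$score, "score", required = FALSE)
  col_evid <- pick_column(header, dialect$evidence, "evidence",
                          required = source == "validated")
  col_family <- pick_column(header, dialect$family, "family", required = FALSE)

  records <- tibble(
    mirna = raw[[col_mirna]],
    gene = raw[[col_gene]],
    score = if (!is.null(col_score)) {
      suppressWarnings(as.numeric(raw[[col_score]]))
    } else NA_real_,
    family = if (!is.null(col_family)) raw[[col_family]] else NA_character_
  )
  if ("n_evidence" %in% header) {
    records$n_evidence <- suppressWarnings(as.integer(raw[["n_evidence"]]))
  }
  if (source == "validated") {
    ev <- raw[[col_evid]]
    records$evidence <- ifelse(
      tolower(ev) %in% c("strong", "weak"), tolower(ev), map_support_type(ev)
    )
  }
  n_read <- nrow(records)
  keep <- nzchar(stringr::str_trim(records$mirna %||% "")) &
    nzchar(stringr::str_trim(records$gene %||% ""))
  keep[is.na(keep)] <- FALSE
  n_dropped <- sum(!keep)
  db <- interaction_db(records[keep, , drop = FALSE], source = source)
  n_dup <- (n_read - n_dropped) - nrow(db)
  inform(sprintf(
    "read_interactions: %d rows read, %d dropped (missing ids), %d duplicate pairs collapsed, universe M = %d",
    n_read, n_dropped, n_dup, nrow(db)
  ))
  db
}

#' Write the canonical interaction table
#'
#' Writes the deduplicated database as a tab-separated file with the
#' canonical column names, re-readable via
#' `read_interactions(dialect = dialect_canonical())`.
#'
#' @param db an [interaction_db].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(db, path) {
  stopifnot(is_interaction_db(db))
  out <- as_tibble(db)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter a validated database by evidence category
#'
#' Restricts a validated interaction database to interactions supported by
#' strong experimental methods (e.g. luciferase assay, western blot), weak
#' ones (e.g. CLIP), or both. The universe size is recomputed.
#'
#' @param db a validated [interaction_db].
#' @param mode `"strong"`, `"weak"`, or `"strong_and_weak"`.
#' @return a filtered [interaction_db].
#' @export
filter_by_evidence <- function(db,
                               mode = c("strong", "weak", "strong_and_weak")) {
  stopifnot(is_interaction_db(db))
  mode <- match.arg(mode)
  if (nrow(db) > 0 && db_source(db) != "validated") {
    abort_usage("evidence filtering applies to validated databases only")
  }
  keep <- switch(mode,
    strong = db$evidence == "strong",
    weak = db$evidence == "weak",
    strong_and_weak = db$evidence %in% c("strong", "weak")
  )
  out <- db[keep, , drop = FALSE]
  class(out) <- unique(c("interaction_db", class(out)))
  out
}

#' Look up targets of a miRNA or regulators of a gene
#'
#' @param db an [interaction_db].
#' @param mirna,gene identifier to look up (gene symbols are matched
#'   case-insensitively).
#' @return the matching rows of `db`.
#' @export
targets_of <- function(db, mirna) {
  stopifnot(is_interaction_db(db))
  db[db$mirna == normalize_mirna(mirna), , drop = FALSE]
}

#' @rdname targets_of
#' @export
regulators_of <- function(db, gene) {
  stopifnot(is_interaction_db(db))
  db[db$gene == normalize_gene(gene), , drop = FALSE]
}

#' Top-ranked targets of a miRNA
#'
#' Returns the `k` best-ranked target genes of a miRNA. Predicted databases
#' rank by ascending score (context++ convention: more negative first);
#' validated databases, which carry no score, rank by descending evidence
#' multiplicity (number of raw support rows collapsed at load time). Ties
#' break lexicographically by gene symbol, so the ranking is deterministic.
#'
#' @param db an [interaction_db].
#' @param mirna a miRNA present in `db`.
#' @param k positive number of targets wanted; fewer are returned if the
#'   miRNA has fewer targets.
#' @return a character vector of at most `k` gene symbols.
#' @export
top_targets <- function(db, mirna, k) {
  stopifnot(is_interaction_db(db))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort_parameter("k must be a positive integer")
  }
  rows <- targets_of(db, mirna)
  if (nrow(rows) == 0) {
    abort_lookup(paste0("miRNA not in database: ", mirna))
  }
  if (db_source(db) == "predicted") {
    ord <- order(rows$score, rows$gene)
  } else {
    ord <- order(-rows$n_evidence, rows$gene)
  }
  head(rows$gene[ord], k)
}

#' Generate a synthetic interaction database
#'
#' Builds a reproducible bipartite interaction table whose per-miRNA target
#' counts follow a truncated discrete power law \eqn{P(k) \propto
#' k^{-\gamma}} on `[min_targets, max_targets]` — emulating the heavy-tailed
#' target catalogues of real prediction databases — with a synthetic
#' negative ranking score per interaction (more negative = stronger).
#'
#' @param n_mirnas number of miRNAs (>= 1).
#' @param n_genes size of the gene pool; must be at least `max_targets`.
#' @param exponent power-law exponent of the target-count law (> 1).
#' @param min_targets,max_targets bounds on per-miRNA target counts.
#' @param seed integer seed for reproducibility.
#' @return a predicted-source [interaction_db].
#' @examples
#' db <- generate_synthetic_db(10, 500, max_targets = 100, seed = 1)
#' universe_size(db)
#' @export
generate_synthetic_db <- function(n_mirnas, n_genes, exponent = 2,
                                  min_targets = 10, max_targets = 1000,
                                  seed = NULL) {
  if (n_mirnas < 1) abort_parameter("n_mirnas must be >= 1")
  if (min_targets < 1 || max_targets < min_targets) {
    abort_parameter("need 1 <= min_targets <= max_targets")
  }
  if (n_genes < max_targets) {
    abort_parameter("n_genes must be at least max_targets")
  }
  if (exponent <= 1) abort_parameter("exponent must be > 1")
  with_seed(seed, {
    mirnas <- sprintf("syn-miR-%04d-5p", seq_len(n_mirnas))
    genes <- sprintf("SYNG%05d", seq_len(n_genes))
    counts <- rpowerlaw_trunc(n_mirnas, exponent, min_targets, max_targets)
    records <- purrr::map2_dfr(mirnas, counts, function(m, k) {
      tibble(
        mirna = m,
        gene = sample(genes, k, replace = FALSE),
        score = round(-runif(k, 0.01, 1), 4)
      )
    })
    interaction_db(records, source = "predicted")
  })
}

# Truncated discrete power-law sampler: inverse-CDF on the continuous Pareto
# restricted to [kmin, kmax + 1), floored to integers.
rpowerlaw_trunc <- function(n, exponent, kmin, kmax) {
  if (kmin == kmax) {
    return(rep(as.integer(kmin), n))
  }
  a <- 1 - exponent
  u <- runif(n)
  lo <- kmin^a
  hi <- (kmax + 1)^a
  x <- (lo + u * (hi - lo))^(1 / a)
  pmin(as.integer(floor(x)), as.integer(kmax))
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf(
    "<interaction_db> %s source, %d interactions, %d miRNAs, %d genes\n",
    db_source(x), nrow(x), dplyr::n_distinct(x$mirna),
    dplyr::n_distinct(x$gene)
  ))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.interaction_db <- function(x, ...) {
  tibble(
    source = db_source(x),
    n_interactions = nrow(x),
    n_mirnas = dplyr::n_distinct(x$mirna),
    n_genes = dplyr::n_distinct(x$gene)
  )
}
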