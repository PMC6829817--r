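#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line — name, description, then member gene
#' symbols, tab-separated. Duplicate members within a line are counted
#' once; gene symbols are upper-cased to match the package's identifier
#' conventions.
#'
#' @param path path to a GMT file.
#' @return an object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `universe` (the union of all
#'   members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort_usage(paste0("GMT file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  if (length(lines) == 0) {
    abort_format(paste0("empty GMT file: ", path))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- stringr::str_split_1(lines[i], "\t")
    if (length(fields) < 3) {
      abort_format(sprintf(
        "GMT line %d has %d fields; need name, description and at least one gene",
        i, length(fields)
      ))
    }
    members <- unique(normalize_gene(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort_format(sprintf("GMT line %d has no gene members", i))
    }
    sets[[fields[1]]] <- members
  }
  new_gene_set_collection(sets)
}

new_gene_set_collection <- function(sets) {
  structure(
    list(sets = sets, universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection"
  )
}

#' @rdname read_gmt
#' @param sets a named list of character vectors of gene symbols.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) == 0 || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_usage("sets must be a non-empty named list")
  }
  sets <- purrr::map(sets, ~ unique(normalize_gene(.x)))
  if (any(lengths(sets) == 0)) {
    abort_usage("empty categories are not allowed")
  }
  new_gene_set_collection(sets)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d categories, %d genes in universe\n",
    length(x$sets), length(x$universe)
  ))
  invisible(x)
}

#' Gene-set over-representation analysis
#'
#' Tests each category of a collection for over-representation in a target
#' gene set (typically the targets of one enriched miRNA) with the same
#' hypergeometric statistic used for miRNA-target enrichment: `M` is the
#' background size, `K` the category size within the background, `N` the
#' number of target genes in the background, `X` the hits. P-values are
#' BH-adjusted over all categories.
#'
#' `gene_ratio` is reported as hits over the category's total gene count
#' (within the background). The more common hits-over-input convention is
#' available with `ratio = "input"`; the convention used is recorded in the
#' `ratio` attribute of the result.
#'
#' @param target_genes character vector of gene symbols (e.g. from
#'   [top_targets()] or an enrichment overlap).
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param background optional background gene set; defaults to the
#'   collection's universe (union of all category members).
#' @param ratio `"category"` (hits / category size) or `"input"`
#'   (hits / input size).
#' @return a tibble of class `functional_enrichment`, sorted by p-value:
#'   columns `category`, `hits`, `category_size`, `n_input`, `p_value`,
#'   `fdr`, `gene_ratio`, and list-column `genes`.
#' @export
ora <- function(target_genes, collection, background = NULL,
                ratio = c("category", "input")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ratio <- match.arg(ratio)
  targets <- unique(normalize_gene(target_genes))
  targets <- targets[nzchar(targets)]
  if (length(targets) == 0) {
    abort_usage("target_genes is empty")
  }
  background <- if (is.null(background)) collection$universe else
    unique(normalize_gene(background))
  targets_bg <- intersect(targets, background)
  if (length(targets_bg) == 0) {
    abort_usage(paste0(
      "no target gene is in the background; unmatched: ",
      paste(head(setdiff(targets, background), 10), collapse = ", ")
    ))
  }
  M <- length(background)
  N <- length(targets_bg)
  rows <- purrr::imap_dfr(collection$sets, function(members, name) {
    cat_bg <- intersect(members, background)
    hit_genes <- intersect(cat_bg, targets_bg)
    tibble(
      category = name,
      hits = length(hit_genes),
      category_size = length(cat_bg),
      n_input = N,
      genes = list(sort(hit_genes))
    )
  }) %>%
    filter(.data$category_size > 0) %>%
    mutate(
      p_value = hypergeom_pvalue(M, .data$category_size, N, .data$hits),
      fdr = adjust_fdr(.data$p_value),
      gene_ratio = if (ratio == "category") {
        .data$hits / .data$category_size
      } else {
        .data$hits / .data$n_input
      }
    ) %>%
    arrange(.data$p_value, .data$category) %>%
    select("category", "hits", "category_size", "n_input", "p_value",
           "fdr", "gene_ratio", "genes")
  class(rows) <- c("functional_enrichment", class(rows))
  attr(rows, "ratio") <- ratio
  attr(rows, "M") <- M
  rows
}

#' @exportS3Method generics::tidy
tidy.functional_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  out$genes <- purrr::map_chr(out$genes, paste, collapse = ";")
  out
}

#' @exportS3Method generics::glance
glance.functional_enrichment <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_significant = sum(x$fdr <= 0.05),
    background_size = attr(x, "M") %||% NA_integer_,
    ratio_convention = attr(x, "ratio") %||% NA_character_
  )
}

#' Write a functional-enrichment table as tab-delimited text
#'
#' The ratio convention in use is recorded in the `gene_ratio` column name.
#'
#' @param rows a `functional_enrichment` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_functional_enrichment <- function(rows, path) {
  out <- tidy(rows)
  conv <- attr(rows, "ratio") %||% "category"
  names(out)[names(out) == "gene_ratio"] <-
    paste0("gene_ratio_over_", conv)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
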