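#' Build the bipartite miRNA-target network
#'
#' Turns filtered enrichment results into a bipartite regulatory network:
#' nodes are the surviving items plus their overlap partners, edges are the
#' overlap interactions only (each edge joins a miRNA-role node to a
#' gene-role node). Evidence and score annotations are propagated from the
#' database.
#'
#' @param db the [interaction_db] the enrichment was run against.
#' @param enriched_rows a filtered `mirna_enrichment` table.
#' @param input_list the input identifiers (unused for edge selection —
#'   edges are already pinned down by the overlap sets — but kept for
#'   interface symmetry).
#' @return an object of class `mirna_network`: a list with tibbles `nodes`
#'   (`node`, `role`) and `edges` (`mirna`, `gene`, `evidence`, `score`).
#' @export
build_network <- function(db, enriched_rows, input_list = NULL) {
  stopifnot(is_interaction_db(db))
  direction <- attr(enriched_rows, "direction") %||% "genes_in_mirnas_out"
  genes_in <- direction == "genes_in_mirnas_out"
  if (nrow(enriched_rows) == 0) {
    warn("no enriched rows: returning an empty network")
    return(new_mirna_network(
      tibble(node = character(0), role = character(0)),
      tibble(mirna = character(0), gene = character(0),
             evidence = character(0), score = numeric(0))
    ))
  }
  pairs <- enriched_rows %>%
    select("item", "overlap") %>%
    tidyr::unnest_longer("overlap", values_to = "partner")
  edges <- if (genes_in) {
    tibble(mirna = pairs$item, gene = pairs$partner)
  } else {
    tibble(mirna = pairs$partner, gene = pairs$item)
  }
  edges <- edges %>%
    distinct(.data$mirna, .data$gene) %>%
    left_join(
      as_tibble(db)[, c("mirna", "gene", "evidence", "score")],
      by = c("mirna", "gene")
    ) %>%
    arrange(.data$mirna, .data$gene)
  nodes <- dplyr::bind_rows(
    tibble(node = unique(edges$mirna), role = "mirna"),
    tibble(node = unique(edges$gene), role = "gene")
  )
  new_mirna_network(nodes, edges)
}

new_mirna_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf(
    "<mirna_network> %d miRNAs, %d genes, %d edges\n",
    sum(x$nodes$role == "mirna"), sum(x$nodes$role == "gene"),
    nrow(x$edges)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mirna_network <- function(x, ...) as_tibble(x$edges)

#' @exportS3Method generics::glance
glance.mirna_network <- function(x, ...) {
  tibble(
    n_mirnas = sum(x$nodes$role == "mirna"),
    n_genes = sum(x$nodes$role == "gene"),
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = if (nrow(x$nodes) == 0) 0L else
      igraph::count_components(as_igraph(x))
  )
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene")], directed = FALSE,
    vertices = net$nodes[, "node", drop = FALSE]
  )
  igraph::set_vertex_attr(g, "role", value = net$nodes$role)
}

#' Per-node topological properties
#'
#' Computes, for every node, the metrics used to spot central players in
#' the regulatory network: degree, betweenness, closeness, average shortest
#' path length, eccentricity, and the local (triangle-based) clustering
#' coefficient. Distances are unweighted shortest paths; for disconnected
#' networks, closeness, average shortest path and eccentricity are computed
#' within each node's connected component, and closeness is the classical
#' definition scaled by (component size - 1). The triangle-based clustering
#' coefficient is identically 0 on a bipartite network (no odd cycles);
#' `clustering = "square"` substitutes the square-clustering coefficient,
#' which counts four-cycles and can be informative on bipartite graphs.
#'
#' @param net a `mirna_network`.
#' @param normalized_betweenness if `TRUE`, scale betweenness by
#'   `2 / ((n - 1) (n - 2))`; default reports raw path counts.
#' @param clustering `"triangle"` (standard local coefficient) or
#'   `"square"`.
#' @return a tibble with one row per node: `node`, `role`, `degree`,
#'   `betweenness`, `closeness`, `avg_shortest_path`, `eccentricity`,
#'   `clustering`.
#' @export
node_topology <- function(net, normalized_betweenness = FALSE,
                          clustering = c("triangle", "square")) {
  stopifnot(inherits(net, "mirna_network"))
  clustering <- match.arg(clustering)
  n <- nrow(net$nodes)
  if (n == 0) {
    return(tibble(
      node = character(0), role = character(0), degree = integer(0),
      betweenness = numeric(0), closeness = numeric(0),
      avg_shortest_path = numeric(0), eccentricity = numeric(0),
      clustering = numeric(0)
    ))
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = normalized_betweenness)
  d <- igraph::distances(g)
  # per-node component views of the distance matrix
  per_node <- purrr::map_dfr(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    comp_size <- length(di) + 1
    tibble(
      closeness = if (comp_size > 1) (comp_size - 1) / sum(di) else 0,
      avg_shortest_path = if (comp_size > 1) mean(di) else 0,
      eccentricity = if (comp_size > 1) max(di) else 0
    )
  })
  cl <- if (clustering == "triangle") {
    igraph::transitivity(g, type = "localundirected", isolates = "zero")
  } else {
    square_clustering(g)
  }
  tibble(
    node = net$nodes$node,
    role = net$nodes$role,
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    closeness = per_node$closeness,
    avg_shortest_path = per_node$avg_shortest_path,
    eccentricity = per_node$eccentricity,
    clustering = as.numeric(cl)
  )
}

# Square (four-cycle) clustering coefficient, the bipartite analogue of the
# triangle-based one: for node v, the fraction of possible four-cycles
# through each pair of neighbours that are realized.
square_clustering <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  vapply(seq_len(n), function(v) {
    nb <- as.integer(adj[[v]])
    if (length(nb) < 2) {
      return(0)
    }
    pairs <- utils::combn(nb, 2)
    num <- 0
    den <- 0
    for (j in seq_len(ncol(pairs))) {
      u <- pairs[1, j]
      w <- pairs[2, j]
      common <- setdiff(intersect(as.integer(adj[[u]]),
                                  as.integer(adj[[w]])), v)
      q <- length(common)
      num <- num + q
      den <- den + q + (length(adj[[u]]) - 1 - q) +
        (length(adj[[w]]) - 1 - q)
    }
    if (den == 0) 0 else num / den
  }, numeric(1))
}

#' Degree distribution of a network
#'
#' The probability distribution of node degrees over the whole network.
#' Accepts a `mirna_network` or a raw vector of node degrees; the support
#' contains observed degrees only and the probabilities sum to 1.
#'
#' @param x a `mirna_network` or an integer vector of degrees.
#' @return a tibble with columns `degree`, `count`, `probability`.
#' @export
degree_dist <- function(x) {
  degrees <- if (inherits(x, "mirna_network")) {
    if (nrow(x$nodes) == 0) {
      abort_usage("cannot compute a degree distribution of an empty network")
    }
    as.integer(igraph::degree(as_igraph(x)))
  } else if (is.numeric(x)) {
    if (length(x) == 0) {
      abort_usage("no degrees supplied")
    }
    as.integer(x)
  } else {
    abort_usage("x must be a mirna_network or a numeric vector of degrees")
  }
  tibble(degree = degrees) %>%
    count(.data$degree, name = "count") %>%
    mutate(probability = .data$count / sum(.data$count)) %>%
    arrange(.data$degree)
}

#' Power-law fit of a degree distribution
#'
#' Fits \eqn{P(k) \propto k^{-\gamma}} by ordinary least squares of
#' \eqn{\log_{10} P(k)} on \eqn{\log_{10} k} — the straight line on the
#' log-log plot. Zero-probability degrees are excluded (their log is
#' undefined); degree 0 nodes, if any, are likewise outside the support of
#' the power law and dropped.
#'
#' @param dist a degree distribution from [degree_dist()] (columns
#'   `degree`, `probability`), or a `mirna_network` (converted internally).
#' @return an object of class `power_law_fit` with fields `exponent`
#'   (\eqn{\gamma}, positive for decaying distributions), `intercept`,
#'   `r_squared`, `n_points`, and the fitted points in `data`.
#' @examples
#' d <- tibble::tibble(degree = c(1, 2, 4, 8),
#'                     probability = c(1, 1 / 4, 1 / 16, 1 / 64) / 1.328125)
#' fit_power_law(d)$exponent
#' @export
fit_power_law <- function(dist) {
  if (inherits(dist, "mirna_network")) {
    dist <- degree_dist(dist)
  }
  if (!all(c("degree", "probability") %in% names(dist))) {
    abort_usage("dist needs 'degree' and 'probability' columns")
  }
  pts <- as_tibble(dist) %>%
    filter(.data$probability > 0, .data$degree > 0)
  if (dplyr::n_distinct(pts$degree) < 2) {
    abort_domain(
      "degenerate degree distribution: need at least 2 distinct degrees with nonzero probability"
    )
  }
  fit <- stats::lm(log10(probability) ~ log10(degree), data = pts)
  # summary.lm warns on exactly collinear (zero-residual) input; that case
  # is legitimate here
  s <- suppressWarnings(summary(fit))
  structure(
    list(
      exponent = -unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = s$r.squared,
      n_points = nrow(pts),
      data = pts
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> P(k) ~ k^-%.3f, r-squared = %.3f (%d points)\n",
    x$exponent, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("exponent", "intercept"),
    estimate = c(x$exponent, x$intercept)
  )
}

#' @exportS3Method generics::glance
glance.power_law_fit <- function(x, ...) {
  tibble(
    exponent = x$exponent,
    intercept = x$intercept,
    r_squared = x$r_squared,
    n_points = x$n_points
  )
}

#' Write network tables as tab-delimited text
#'
#' @param net a `mirna_network`.
#' @param topology_path,edges_path,degree_path output paths; `NULL` skips a
#'   table.
#' @return invisibly, a named list of the written tibbles.
#' @export
write_network <- function(net, topology_path = NULL, edges_path = NULL,
                          degree_path = NULL) {
  out <- list()
  if (!is.null(edges_path)) {
    out$edges <- tidy(net)
    readr::write_tsv(out$edges, edges_path, progress = FALSE)
  }
  if (!is.null(topology_path)) {
    out$topology <- node_topology(net)
    readr::write_tsv(out$topology, topology_path, progress = FALSE)
  }
  if (!is.null(degree_path)) {
    out$degree <- degree_dist(net)
    readr::write_tsv(out$degree, degree_path, progress = FALSE)
  }
  invisible(out)
}
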