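# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so they can arbitrate correctness.

# Exhaustive hypergeometric upper tail: enumerate all C(M, N) draws from a
# universe where items 1..K are marked and count draws with >= X marked.
hyper_enum <- function(M, K, N, X) {
  if (X == 0) {
    return(1)
  }
  if (N == 0) {
    return(0)
  }
  draws <- utils::combn(M, N)
  marked <- colSums(draws <= K)
  mean(marked >= X)
}

# Direct BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, mapped back to the
# input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# All-pairs BFS distances on an undirected graph given as an edge list over
# nodes 1..n. Returns an n x n matrix with Inf across components.
bfs_distances <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]
    b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Brute-force betweenness via shortest-path counting: sigma[s, v] = number
# of shortest s-v paths (DP over BFS layers); a node v lies on a shortest
# s-t path iff d(s,v) + d(v,t) == d(s,t).
brute_topology <- function(n, edges) {
  d <- bfs_distances(n, edges)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      preds <- which(d[s, ] == d[s, v] - 1)
      preds <- preds[vapply(preds, function(p) {
        any((edges[, 1] == p & edges[, 2] == v) |
              (edges[, 2] == p & edges[, 1] == v))
      }, logical(1))]
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || is.infinite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  degree <- vapply(seq_len(n), function(v) {
    sum(edges[, 1] == v) + sum(edges[, 2] == v)
  }, numeric(1))
  per_node <- t(vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) {
      c(closeness = 0, avg = 0, ecc = 0)
    } else {
      c(closeness = length(dv) / sum(dv), avg = mean(dv), ecc = max(dv))
    }
  }, numeric(3)))
  list(
    degree = degree, betweenness = btw,
    closeness = per_node[, 1], avg_shortest_path = per_node[, 2],
    eccentricity = per_node[, 3]
  )
}

# Random connected-or-not bipartite graph with <= 12 nodes, returned as a
# mirna_network built through the package constructor-free path.
random_bipartite_net <- function() {
  n_m <- sample(1:4, 1)
  n_g <- sample(1:8, 1)
  mirnas <- paste0("miR-", LETTERS[seq_len(n_m)])
  genes <- paste0("G", seq_len(n_g))
  all_pairs <- expand.grid(mirna = mirnas, gene = genes,
                           stringsAsFactors = FALSE)
  keep <- runif(nrow(all_pairs)) < 0.4
  if (!any(keep)) keep[sample(nrow(all_pairs), 1)] <- TRUE
  edges <- tibble::as_tibble(all_pairs[keep, ])
  edges$evidence <- "none"
  edges$score <- NA_real_
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = unique(edges$mirna), role = "mirna"),
    tibble::tibble(node = unique(edges$gene), role = "gene")
  )
  structure(list(nodes = nodes, edges = edges), class = "mirna_network")
}

# Toy interaction table writer for reader tests.
write_toy_table <- function(path, rows, header) {
  readr::write_lines(c(paste(header, collapse = "\t"),
                       vapply(rows, paste, "", collapse = "\t")), path)
  path
}

# Small two-miRNA toy database used across enrichment tests:
# miR-A -> {G1, G2, G3}, miR-B -> {G4, G5}.
toy_db <- function(source = "predicted") {
  records <- data.frame(
    mirna = rep(c("miR-A", "miR-B"), c(3, 2)),
    gene = c("G1", "G2", "G3", "G4", "G5"),
    score = c(-0.9, -0.5, -0.1, -0.7, -0.3)
  )
  if (source == "validated") {
    records$score <- NULL
    records$evidence <- c("strong", "weak", "strong", "weak", "strong")
  }
  interaction_db(records, source = source)
}
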