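# Independent brute-force oracles and random fixtures.
# These recompute quantities by direct enumeration over edge lists, never
# through the package's own data structures or formulas' code paths.

# edges: data.frame(a, b[, weight])
oracle_neighbors <- function(edges, v) {
  unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))
}

oracle_ecc <- function(edges, u, v) {
  nu <- oracle_neighbors(edges, u)
  nv <- oracle_neighbors(edges, v)
  if (length(nu) <= 1 || length(nv) <= 1) return(0)
  common <- 0
  for (x in nu) if (x %in% nv) common <- common + 1
  common^2 / ((length(nu) - 1) * (length(nv) - 1))
}

oracle_weighted_density <- function(edges, members) {
  if (length(members) < 2) return(0)
  inside <- edges$a %in% members & edges$b %in% members
  w <- edges$weight[inside]
  if (length(w) == 0) return(0)
  (2 * sum(w)) / (max(w) * length(members) * (length(members) - 1))
}

oracle_matching_score <- function(a, b) {
  common <- 0
  for (x in unique(a)) if (x %in% unique(b)) common <- common + 1
  common^2 / (length(unique(a)) * length(unique(b)))
}

# Upper-tail hypergeometric P(X >= k) by explicit enumeration.
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  total <- 0
  for (j in seq(k, min(K, n))) {
    total <- total + choose(K, j) * choose(N - K, n - j)
  }
  total / choose(N, n)
}

# Random undirected simple graph as an edge data frame with weights.
random_edges <- function(n_nodes, p = 0.4, weighted = TRUE) {
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  on <- runif(nrow(pairs)) < p
  edges <- data.frame(a = pairs[on, 1], b = pairs[on, 2],
                      stringsAsFactors = FALSE)
  edges$weight <- if (weighted) round(runif(nrow(edges), 0.05, 1), 3) else 1
  edges
}

random_network <- function(n_nodes, p = 0.4) {
  edges <- random_edges(n_nodes, p)
  while (nrow(edges) == 0) edges <- random_edges(n_nodes, p)
  list(edges = edges,
       network = weighted_network(edges$a, edges$b, edges$weight))
}

as_ppi_edgelist <- function(edges) {
  df <- data.frame(a = pmin(edges$a, edges$b), b = pmax(edges$a, edges$b),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), ]
  attr(df, "n_dropped") <- 0L
  class(df) <- c("ppi_edgelist", "data.frame")
  df
}

write_lines_tmp <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}
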