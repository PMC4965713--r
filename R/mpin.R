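#' Edge clustering coefficient of a protein pair
#'
#' The ECC weights a physical interaction by the squared number of common
#' neighbors of its endpoints, normalised by the product of (degree - 1)
#' terms:
#' \deqn{ECC(v_i, v_j) = |N_i \cap N_j|^2 / ((|N_i| - 1)(|N_j| - 1))}
#' when both endpoints have degree > 1, and 0 when either endpoint has degree
#' 1. Neighborhood sets are taken from the PPI graph, so for an interacting
#' pair each endpoint is a member of the other's neighborhood.
#'
#' @param neighbors_i,neighbors_j Character vectors: the PPI-graph neighbor
#'   sets of the two proteins.
#' @return Non-negative numeric weight.
#' @examples
#' # a triangle a-b-c, edge (a, b):
#' ecc_weight(c("b", "c"), c("a", "c"))  # 1
#' @export
ecc_weight <- function(neighbors_i, neighbors_j) {
  ni <- length(unique(neighbors_i))
  nj <- length(unique(neighbors_j))
  if (ni <= 1L || nj <= 1L) return(0)
  k <- length(intersect(neighbors_i, neighbors_j))
  k^2 / ((ni - 1) * (nj - 1))
}

#' GO annotation overlap weight of a protein pair
#'
#' Strength of sharing annotations within one GO aspect:
#' \deqn{W(v_i, v_j) = |T_i \cap T_j|^2 / (|T_i| \cdot |T_j|)}
#' when both term sets are non-empty, else 0. The same formula is applied to
#' biological-process, molecular-function and cellular-component term sets.
#'
#' @param terms_i,terms_j Character vectors of GO term identifiers.
#' @return Weight in `[0, 1]`.
#' @examples
#' go_overlap_weight(c("g1", "g2", "g3"), c("g1", "g2"))  # 4/6
#' @export
go_overlap_weight <- function(terms_i, terms_j) {
  ti <- unique(terms_i)
  tj <- unique(terms_j)
  if (length(ti) == 0L || length(tj) == 0L) return(0)
  length(intersect(ti, tj))^2 / (length(ti) * length(tj))
}

#' Build the weighted multi-relationship protein interaction network
#'
#' Combines PPI topology with GO annotation overlap into a single
#' multi-relationship network over the PPI protein universe. A protein pair
#' may carry up to four typed parallel edges:
#'
#' * `PPI`: every input physical interaction whose [ecc_weight()] is
#'   positive, weighted by the ECC. Interactions with ECC zero (no common
#'   neighbor, or a degree-1 endpoint) are removed as likely false positives.
#' * `BP`, `MF`, `CC`: a share-edge in aspect A joins proteins that have at
#'   least two common aspect-A terms *and* at least one common neighbor in
#'   the original (unfiltered) PPI graph, weighted by [go_overlap_weight()].
#'   Pairs with a single common function, or with no common PPI neighbor,
#'   receive no share-edge: newly generated relations are filtered more
#'   stringently than physical ones.
#'
#' Share-edges do not require a physical interaction between the pair; the
#' common-neighbor condition confines them to two-hop pairs of the PPI graph.
#'
#' @param ppi A `ppi_edgelist` from [read_ppi()].
#' @param go A `go_annotations` object from [read_go_annotations()].
#' @return An `mpin` object: list with `proteins` (character vector, the PPI
#'   vertex universe) and `edges` (data frame `a`, `b`, `relation`
#'   in `{PPI, BP, MF, CC}`, `weight` > 0).
#' @export
build_mpin <- function(ppi, go) {
  if (nrow(ppi) == 0L) stop("cannot build a network from an empty PPI graph")
  proteins <- ppi_proteins(ppi)
  nbr <- split(c(ppi$b, ppi$a), c(ppi$a, ppi$b))

  ecc <- mapply(function(a, b) ecc_weight(nbr[[a]], nbr[[b]]), ppi$a, ppi$b,
                USE.NAMES = FALSE)
  ppi_edges <- data.frame(a = ppi$a, b = ppi$b, relation = "PPI",
                          weight = ecc, stringsAsFactors = FALSE)
  ppi_edges <- ppi_edges[ppi_edges$weight > 0, , drop = FALSE]

  pairs <- two_hop_pairs(nbr)
  share <- list()
  for (aspect in GO_ASPECTS) {
    sets <- go$sets[[aspect]]
    if (length(sets) == 0L || nrow(pairs) == 0L) next
    w <- numeric(nrow(pairs))
    keep <- logical(nrow(pairs))
    ta <- sets[pairs$a]
    tb <- sets[pairs$b]
    for (i in seq_len(nrow(pairs))) {
      si <- ta[[i]]
      sj <- tb[[i]]
      if (is.null(si) || is.null(sj)) next
      if (length(intersect(si, sj)) >= 2L) {
        keep[i] <- TRUE
        w[i] <- go_overlap_weight(si, sj)
      }
    }
    if (any(keep)) {
      share[[aspect]] <- data.frame(a = pairs$a[keep], b = pairs$b[keep],
                                    relation = aspect, weight = w[keep],
                                    stringsAsFactors = FALSE)
    }
  }
  edges <- rbind(ppi_edges, do.call(rbind, unname(share)))
  rownames(edges) <- NULL
  structure(list(proteins = proteins, edges = edges), class = "mpin")
}

# All unordered pairs of proteins with >= 1 common neighbor in the PPI graph:
# exactly the pairs of neighbors of some vertex.
two_hop_pairs <- function(nbr) {
  acc_a <- character(0)
  acc_b <- character(0)
  for (v in names(nbr)) {
    ns <- sort(unique(nbr[[v]]))
    k <- length(ns)
    if (k < 2L) next
    idx <- utils::combn(k, 2L)
    acc_a <- c(acc_a, ns[idx[1L, ]])
    acc_b <- c(acc_b, ns[idx[2L, ]])
  }
  if (length(acc_a) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  lo <- pmin(acc_a, acc_b)
  hi <- pmax(acc_a, acc_b)
  dup <- duplicated(paste(lo, hi, sep = "\t"))
  data.frame(a = lo[!dup], b = hi[!dup], stringsAsFactors = FALSE)
}

#' @export
print.mpin <- function(x, ...) {
  cat("Multi-relationship protein interaction network\n")
  cat(" proteins:", length(x$proteins), "\n")
  for (r in c("PPI", "BP", "MF", "CC")) {
    cat(sprintf("  %-3s edges: %d\n", r, sum(x$edges$relation == r)))
  }
  invisible(x)
}

#' Dump an MPIN as a TSV
#'
#' Columns `protein_a`, `protein_b`, `relation`, `weight` (six decimals).
#' @param mpin An `mpin` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mpin_tsv <- function(mpin, path) {
  df <- data.frame(protein_a = mpin$edges$a, protein_b = mpin$edges$b,
                   relation = mpin$edges$relation,
                   weight = sprintf("%.6f", mpin$edges$weight))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RELATION_NETWORKS <- c(PPI = "PPIN", BP = "BPN", MF = "MFN", CC = "CCN")

#' Decompose an MPIN into four single-relation weighted networks
#'
#' Splits the multi-relationship network by edge type into PPIN (physical
#' interactions, ECC weights), BPN, MFN and CCN (shared biological process /
#' molecular function / cellular component, overlap weights). The
#' decomposition is a lossless partition: each typed edge appears in exactly
#' one output network with its weight preserved, and each network's vertex
#' set is the endpoints of its edges.
#'
#' @param mpin An `mpin` object from [build_mpin()].
#' @return Named list of `weighted_network` objects, in the fixed order
#'   `PPIN`, `BPN`, `MFN`, `CCN` (possibly empty networks).
#' @export
decompose_mpin <- function(mpin) {
  out <- lapply(names(RELATION_NETWORKS), function(r) {
    sub <- mpin$edges[mpin$edges$relation == r, , drop = FALSE]
    weighted_network(sub$a, sub$b, sub$weight,
                     relation = unname(RELATION_NETWORKS[[r]]))
  })
  names(out) <- unname(RELATION_NETWORKS)
  out
}

#' Construct a single-relation weighted network
#'
#' @param a,b Character vectors: edge endpoints.
#' @param weight Numeric vector of positive, finite edge weights.
#' @param relation Label, one of `"PPIN"`, `"BPN"`, `"MFN"`, `"CCN"` (or any
#'   string for ad-hoc networks).
#' @return A `weighted_network`: wraps an igraph graph together with a
#'   precomputed adjacency-weight index used by the detection routines.
#' @export
weighted_network <- function(a, b, weight, relation = "PPIN") {
  stopifnot(length(a) == length(b), length(a) == length(weight))
  if (any(a == b)) stop("self-loops are not allowed in a weighted network")
  if (length(weight) > 0 && (any(!is.finite(weight)) || any(weight <= 0))) {
    stop("edge weights must be finite and positive")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = weight, stringsAsFactors = FALSE),
    directed = FALSE
  )
  if (igraph::any_multiple(g)) stop("duplicate edges in a weighted network")
  adj <- adjacency_weights(a, b, weight)
  structure(list(graph = g, relation = relation, adj = adj),
            class = "weighted_network")
}

# Named list: protein -> named numeric vector of incident edge weights.
adjacency_weights <- function(a, b, weight) {
  adj <- split(stats::setNames(c(weight, weight), c(b, a)), c(a, b))
  lapply(adj, function(x) x[order(names(x))])
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("Weighted network [%s]: %d proteins, %d edges\n", x$relation,
              length(x$adj), igraph::ecount(x$graph)))
  invisible(x)
}

#' Vertices of a weighted network
#' @param network A `weighted_network`.
#' @return Sorted character vector of protein identifiers.
#' @export
network_proteins <- function(network) {
  sort(names(network$adj))
}

#' Neighbors of a protein in a weighted network
#' @param network A `weighted_network`.
#' @param protein Protein identifier.
#' @return Named numeric vector: neighbor identifier -> edge weight (empty if
#'   the protein is absent or isolated).
#' @export
network_neighbors <- function(network, protein) {
  out <- network$adj[[protein]]
  if (is.null(out)) stats::setNames(numeric(0), character(0)) else out
}
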