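#' Detection parameters for the MINE procedure
#'
#' @param wdt Weighted-density threshold in `[0, 1]` governing neighbor
#'   acceptance during candidate growth. The default 0.05 is the value at
#'   which detection performance peaks on yeast interaction data.
#' @param overlap_threshold Matching-score threshold in `[0, 1]` above which
#'   (inclusive) one member of a pair of predicted complexes is discarded as
#'   redundant; conventionally 0.8.
#' @param min_size Minimum complex size; candidates smaller than this are
#'   dropped before insertion. Default 2.
#' @return A `mine_params` list.
#' @export
mine_params <- function(wdt = 0.05, overlap_threshold = 0.8, min_size = 2L) {
  stopifnot(is.numeric(wdt), length(wdt) == 1L, is.finite(wdt))
  if (wdt < 0 || wdt > 1) stop("wdt must lie in [0, 1]")
  if (overlap_threshold < 0 || overlap_threshold > 1) {
    stop("overlap_threshold must lie in [0, 1]")
  }
  min_size <- as.integer(min_size)
  if (min_size < 1L) stop("min_size must be >= 1")
  structure(list(wdt = wdt, overlap_threshold = overlap_threshold,
                 min_size = min_size), class = "mine_params")
}

#' Weighted density of a vertex set
#'
#' For the subgraph induced by `members` with edge weights `w(e)`,
#' \deqn{WD = 2 \sum_e w(e) / (\max_e w(e) \cdot |V| (|V| - 1))}
#' with sum and maximum taken over the induced subgraph's own edges. A single
#' edge always has density 1; a complete subgraph with equal weights has
#' density 1. Sets with fewer than two members, or whose induced subgraph has
#' no edges, have density 0 (they cannot cohere).
#'
#' @param members Character vector of protein identifiers.
#' @param network A `weighted_network`.
#' @return Density in `[0, 1]`.
#' @export
weighted_density <- function(members, network) {
  members <- unique(members)
  n <- length(members)
  if (n < 2L) return(0)
  wsum <- 0
  wmax <- 0
  m <- 0L
  for (u in members) {
    inc <- network$adj[[u]]
    if (is.null(inc)) next
    # count each induced edge once, from its lexicographically smaller end
    inc <- inc[names(inc) > u & names(inc) %in% members]
    if (length(inc) == 0L) next
    wsum <- wsum + sum(inc)
    wmax <- max(wmax, max(inc))
    m <- m + length(inc)
  }
  if (m == 0L) return(0)
  (2 * wsum) / (wmax * n * (n - 1))
}

#' Sub-network weighted degree
#'
#' Sum of the edge weights from `u` to members of `targets`:
#' \deqn{SWD(u, G) = \sum_{v \in targets, (u,v) \in E} w(u, v)}
#' Zero when `u` has no edges into `targets`.
#'
#' @param u Protein identifier.
#' @param targets Character vector of protein identifiers.
#' @param network A `weighted_network`.
#' @return Non-negative numeric.
#' @export
swd <- function(u, targets, network) {
  inc <- network$adj[[u]]
  if (is.null(inc) || length(targets) == 0L) return(0)
  sum(inc[names(inc) %in% setdiff(targets, u)])
}

#' Grow a candidate complex from a seed
#'
#' The seed starts the candidate set CCS, then the seed's neighbors are
#' inserted one by one in descending order of their edge weight to the seed
#' (ties broken lexicographically). After each insertion the weighted density
#' of CCS is evaluated; if it falls below the threshold `wdt`, the newly
#' added neighbor is removed again. Growth is confined to the seed's
#' neighborhood: candidates are generated from the neighborhood graphs of all
#' proteins, not by recursive frontier expansion.
#'
#' @param seed Protein identifier present in the network.
#' @param network A `weighted_network`.
#' @param params A [mine_params()] object.
#' @return A `candidate_complex`: list with `members` (sorted), `seed`,
#'   `relation`, and `wd` (weighted density on this network).
#' @export
grow_candidate <- function(seed, network, params = mine_params()) {
  inc <- network$adj[[seed]]
  if (is.null(inc)) stop("seed '", seed, "' is not in the network")
  ord <- order(-inc, names(inc))
  ccs <- seed
  for (v in names(inc)[ord]) {
    trial <- c(ccs, v)
    if (weighted_density(trial, network) >= params$wdt) ccs <- trial
  }
  candidate_complex(ccs, seed, network)
}

#' Construct a candidate complex record
#'
#' @param members Character vector of member identifiers (must include the
#'   seed).
#' @param seed The seed protein the candidate is anchored to.
#' @param network The `weighted_network` the candidate lives on; its label
#'   and the recomputed weighted density are stored on the record.
#' @return A `candidate_complex` list: `members` (sorted), `seed`,
#'   `relation`, `wd`.
#' @export
candidate_complex <- function(members, seed, network) {
  if (!seed %in% members) stop("the seed must be a member of the candidate")
  structure(list(members = sort(unique(members)), seed = seed,
                 relation = network$relation,
                 wd = weighted_density(members, network)),
            class = "candidate_complex")
}

#' Remove high-coupling members from a candidate complex
#'
#' A predicted complex should be well separated from the rest of the network.
#' Let NS be the external neighbor set of the candidate CCS (vertices outside
#' CCS adjacent to at least one member). Every non-seed member `u` whose
#' weighted degree inside the candidate, `swd(u, CCS \ {u})`, is strictly
#' smaller than its weighted degree into the neighbor set, `swd(u, NS)`, is
#' coupled more strongly to the outside than the inside and is removed. The
#' rule is iterated to a fixed point, recomputing NS after each pass; ties
#' retain the member, and the seed is never removed.
#'
#' @param candidate A `candidate_complex` from [grow_candidate()].
#' @param network The `weighted_network` the candidate was grown on.
#' @return The pruned `candidate_complex` (weighted density recomputed).
#' @export
prune_coupling <- function(candidate, network) {
  ccs <- candidate$members
  repeat {
    ns <- neighbor_set(ccs, network)
    drop <- vapply(setdiff(ccs, candidate$seed), function(u) {
      swd(u, setdiff(ccs, u), network) < swd(u, ns, network)
    }, logical(1))
    if (!any(drop)) break
    ccs <- setdiff(ccs, names(drop)[drop])
  }
  candidate_complex(ccs, candidate$seed, network)
}

# External neighbor set NS: vertices outside `members` adjacent to a member.
neighbor_set <- function(members, network) {
  nbrs <- unlist(lapply(members, function(u) names(network$adj[[u]])),
                 use.names = FALSE)
  setdiff(unique(nbrs), members)
}

#' Matching score of two protein sets
#'
#' \deqn{MS(A, B) = |A \cap B|^2 / (|A| \cdot |B|)}
#' MS is symmetric and lies in `[0, 1]`; MS = 1 means set equality. It is
#' used both for redundancy filtering among predictions (threshold 0.8) and
#' for benchmark matching (threshold 0.2).
#'
#' @param a,b Non-empty character vectors of protein identifiers.
#' @return Numeric in `[0, 1]`.
#' @export
matching_score <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("matching score is undefined for empty sets")
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Filter redundant complexes by pairwise overlap
#'
#' Vertices with similar neighborhood graphs yield heavily overlapping
#' candidates. For every pair with matching score at or above
#' `overlap_threshold`, the member with the smaller size is discarded; at
#' equal size, the one with the lower weighted density (on its own source
#' network); at equal density, the lexicographically later member tuple.
#' Pairs are processed in the deterministic output order (size descending,
#' density descending, member tuple ascending), so the survivor of each
#' conflict is the pair's earlier element.
#'
#' @param sc A `complex_set` (or list of `candidate_complex`).
#' @param overlap_threshold Threshold in `[0, 1]`; default 0.8.
#' @return The filtered `complex_set`, in output order; no surviving pair has
#'   matching score >= `overlap_threshold`.
#' @export
redundancy_filter <- function(sc, overlap_threshold = 0.8) {
  sc <- sort_complexes(sc)
  kept <- list()
  for (cand in sc) {
    ok <- TRUE
    for (k in kept) {
      if (matching_score(cand$members, k$members) >= overlap_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- cand
  }
  structure(kept, class = "complex_set")
}

sort_complexes <- function(sc) {
  if (length(sc) == 0L) return(structure(list(), class = "complex_set"))
  size <- vapply(sc, function(x) length(x$members), integer(1))
  wd <- vapply(sc, function(x) x$wd, numeric(1))
  key <- vapply(sc, function(x) paste(x$members, collapse = " "), character(1))
  structure(unclass(sc)[order(-size, -wd, key)], class = "complex_set")
}

#' Detect protein complexes from single-relation weighted networks
#'
#' The full MINE detection procedure. The networks are visited in the order
#' given (canonically PPIN, BPN, MFN, CCN from [decompose_mpin()]); within
#' each network every vertex serves as a seed, in lexicographic order. Each
#' seed's candidate is grown under the weighted-density threshold
#' ([grow_candidate()]), pruned of high-coupling members
#' ([prune_coupling()]), dropped if smaller than `min_size`, and inserted
#' into the global complex set SC unless it is a subset of (or equal to) a
#' complex already in SC. SC is shared across all networks. Finally the
#' pairwise redundancy filter ([redundancy_filter()]) is applied and the
#' result sorted by size (descending), weighted density (descending) and
#' member tuple. The procedure is deterministic: identical inputs and
#' parameters give identical output.
#'
#' @param networks A `weighted_network` or list of them (e.g. from
#'   [decompose_mpin()]).
#' @param params A [mine_params()] object.
#' @return A `complex_set`: list of `candidate_complex` records, each with
#'   `members`, `seed`, `relation` and `wd` (weighted density on the source
#'   network).
#' @export
mine_complexes <- function(networks, params = mine_params()) {
  if (inherits(networks, "weighted_network")) networks <- list(networks)
  if (length(networks) == 0L) stop("at least one network is required")
  sc <- list()
  keys <- list()  # member sets of accepted complexes, for the subset screen
  for (network in networks) {
    for (seed in network_proteins(network)) {
      cand <- prune_coupling(grow_candidate(seed, network, params), network)
      if (length(cand$members) < params$min_size) next
      subsumed <- any(vapply(keys, function(k) all(cand$members %in% k),
                             logical(1)))
      if (subsumed) next
      sc[[length(sc) + 1L]] <- cand
      keys[[length(keys) + 1L]] <- cand$members
    }
  }
  redundancy_filter(sc, params$overlap_threshold)
}

#' @export
print.complex_set <- function(x, ...) {
  cat("Complex set:", length(x), "predicted complexes\n")
  if (length(x) > 0) {
    sizes <- vapply(x, function(c) length(c$members), integer(1))
    cat(" sizes: [", min(sizes), ",", max(sizes), "]; by relation:\n")
    print(table(vapply(x, function(c) c$relation, character(1))))
  }
  invisible(x)
}

#' @export
as.data.frame.complex_set <- function(x, ...) {
  data.frame(
    complex_id = if (length(x)) paste0("C", seq_along(x)) else character(0),
    size = vapply(x, function(c) length(c$members), integer(1)),
    weighted_density = vapply(x, function(c) c$wd, numeric(1)),
    source_relation = vapply(x, function(c) c$relation, character(1)),
    members = vapply(x, function(c) paste(c$members, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' Member sets of a complex set
#' @param sc A `complex_set`.
#' @return A `complex_list` of member-ID vectors, in the same order.
#' @export
as_complex_list <- function(sc) {
  structure(lapply(sc, function(c) c$members), class = "complex_list")
}
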