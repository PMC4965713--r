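#' Specification for a synthetic planted-complex benchmark
#'
#' Describes a random PPI network with planted dense complexes plus noise,
#' and GO annotations correlated with complex membership. The generator
#' emulates the two structural premises of complex detection: complexes
#' correspond to dense subgraphs of the interaction network, and their
#' members share annotation terms.
#'
#' Defaults define the package's reference study conditions: 10 disjoint
#' complexes of 4-8 proteins wired internally at density 0.95, background
#' noise edges at 0.01, two GO terms per complex and aspect shared by all
#' members, and a 5% leak rate scattering those terms onto outsiders.
#'
#' @param n_complexes Number of planted complexes.
#' @param size_range Length-2 integer vector: inclusive complex-size range
#'   (sizes >= 2).
#' @param p_in Intra-complex edge probability (Erdos-Renyi within each
#'   planted complex).
#' @param p_out Background edge probability for all other protein pairs;
#'   must satisfy `0 <= p_out < p_in <= 1`.
#' @param n_noise_proteins Proteins belonging to no planted complex.
#' @param terms_per_aspect GO terms created per complex per aspect (each
#'   assigned to every member); >= 2 so that members pass the two-common-term
#'   share-edge filter.
#' @param leak_rate Probability that a complex's term is also assigned to any
#'   given outside protein (annotation noise).
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_complexes = 10L, size_range = c(4L, 8L),
                           p_in = 0.95, p_out = 0.01,
                           n_noise_proteins = 40L, terms_per_aspect = 2L,
                           leak_rate = 0.05, seed = 1L) {
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] > size_range[2]) {
    stop("size_range must be an increasing pair")
  }
  if (size_range[1] < 2L) stop("complex sizes must be >= 2")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (n_complexes < 1L) stop("need at least one planted complex")
  if (terms_per_aspect < 1L) stop("terms_per_aspect must be >= 1")
  if (leak_rate < 0 || leak_rate > 1) stop("leak_rate must lie in [0, 1]")
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = size_range, p_in = p_in, p_out = p_out,
                 n_noise_proteins = as.integer(n_noise_proteins),
                 terms_per_aspect = as.integer(terms_per_aspect),
                 leak_rate = leak_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic planted-complex bundle
#'
#' Samples complex sizes, wires intra-complex pairs at `p_in` and all other
#' pairs at `p_out`, and assigns each complex `terms_per_aspect` fresh GO
#' terms per aspect to all of its members, leaking each term to outside
#' proteins at `leak_rate`. Protein identifiers are zero-padded (`P0001`,
#' ...) so lexicographic tie-breaking is predictable. A planted member left
#' without any intra-complex edge by the sampling is connected to its
#' complex's first member, keeping every ground-truth complex inside the PPI
#' vertex set. All randomness derives from `spec$seed`; the same spec yields
#' an identical bundle on every run.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_bundle`: list with `ppi` (a `ppi_edgelist`), `go`
#'   (a `go_annotations`), `complexes` (ground-truth `complex_list`) and
#'   `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed, {
    size_pool <- seq(spec$size_range[1], spec$size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), spec$n_complexes,
                                  replace = TRUE)]
    n_prot <- sum(sizes) + spec$n_noise_proteins
    ids <- sprintf("P%04d", seq_len(n_prot))
    bounds <- cumsum(c(0L, sizes))
    complexes <- lapply(seq_len(spec$n_complexes), function(i) {
      ids[(bounds[i] + 1L):bounds[i + 1L]]
    })
    membership <- integer(n_prot)  # 0 = noise
    for (i in seq_along(complexes)) {
      membership[match(complexes[[i]], ids)] <- i
    }

    # wire all pairs in one deterministic sweep
    idx <- utils::combn(n_prot, 2L)
    same <- membership[idx[1L, ]] != 0L &
      membership[idx[1L, ]] == membership[idx[2L, ]]
    p <- ifelse(same, spec$p_in, spec$p_out)
    on <- stats::runif(ncol(idx)) < p
    a <- ids[idx[1L, on]]
    b <- ids[idx[2L, on]]

    # re-attach members the sampling left without intra-complex edges
    for (cx in complexes) {
      deg_in <- vapply(cx, function(u) {
        sum((a == u & b %in% cx) | (b == u & a %in% cx))
      }, integer(1))
      for (u in cx[deg_in == 0L]) {
        v <- setdiff(cx, u)[1L]
        a <- c(a, min(u, v))
        b <- c(b, max(u, v))
      }
    }
    dup <- duplicated(paste(a, b, sep = "\t"))
    ppi <- data.frame(a = a[!dup], b = b[!dup], stringsAsFactors = FALSE)
    ord <- order(ppi$a, ppi$b)
    ppi <- ppi[ord, , drop = FALSE]
    rownames(ppi) <- NULL
    attr(ppi, "n_dropped") <- 0L
    class(ppi) <- c("ppi_edgelist", "data.frame")

    # annotations: per complex and aspect, fresh terms shared by all members
    ann <- list(protein = character(0), term = character(0),
                aspect = character(0))
    for (i in seq_len(spec$n_complexes)) {
      for (aspect in GO_ASPECTS) {
        for (t in seq_len(spec$terms_per_aspect)) {
          term <- sprintf("GO:%s:%04d:%d", aspect, i, t)
          carriers <- complexes[[i]]
          outsiders <- setdiff(ids, carriers)
          leaked <- outsiders[stats::runif(length(outsiders)) < spec$leak_rate]
          carriers <- c(carriers, leaked)
          ann$protein <- c(ann$protein, carriers)
          ann$term <- c(ann$term, rep(term, length(carriers)))
          ann$aspect <- c(ann$aspect, rep(aspect, length(carriers)))
        }
      }
    }
    go <- go_annotation_table(ann$protein, ann$term, ann$aspect)

    structure(list(ppi = ppi, go = go,
                   complexes = structure(complexes, class = "complex_list"),
                   spec = spec),
              class = "synthetic_bundle")
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic planted-complex bundle:\n")
  cat(" ", length(ppi_proteins(x$ppi)), "proteins,", nrow(x$ppi),
      "PPI edges,", length(x$complexes), "planted complexes\n")
  invisible(x)
}

#' Write a synthetic bundle to standard-format files
#'
#' Writes `ppi.tsv` (edge list), `go.tsv` (protein, term, aspect) and
#' `complexes.txt` (one complex per line) into `dir`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             go = file.path(dir, "go.tsv"),
             complexes = file.path(dir, "complexes.txt"))
  utils::write.table(bundle$ppi, paths[["ppi"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$go$table, paths[["go"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_complex_list(bundle$complexes, paths[["complexes"]])
  invisible(paths)
}

#' Worked-example network for coupling-based pruning
#'
#' A six-protein weighted network reproducing the textbook configuration for
#' high-coupling removal: a candidate set CCS = \{A, B, C, D\} in which D has
#' a single edge of weight 0.2 into the candidate (to C) and two edges of
#' weights 0.3 and 0.4 to the external neighbor set NS = \{E, F\}. D's
#' weighted degree inside the candidate (0.2) is smaller than into NS (0.7),
#' so [prune_coupling()] removes exactly D.
#'
#' @return List with `network` (a `weighted_network`), `ccs`, `ns`, `seed`
#'   (`"A"`), and `candidate` (the CCS as a `candidate_complex`).
#' @export
fig4_fixture <- function() {
  network <- weighted_network(
    a = c("A", "A", "B", "C", "D", "D"),
    b = c("B", "C", "C", "D", "E", "F"),
    weight = c(0.5, 0.5, 0.5, 0.2, 0.3, 0.4),
    relation = "PPIN"
  )
  ccs <- c("A", "B", "C", "D")
  list(network = network, ccs = ccs, ns = c("E", "F"), seed = "A",
       candidate = candidate_complex(ccs, "A", network))
}
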