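#' Match predicted complexes against a benchmark catalogue
#'
#' A predicted complex matches a benchmark complex when their
#' [matching_score()] is at least `threshold` (conventionally 0.2). The
#' report counts:
#'
#' * `N_cp` — predicted complexes matched by some benchmark complex;
#' * `N_cb` — benchmark complexes matched by some predicted complex;
#' * `N_pcp` — predicted complexes matching a benchmark complex perfectly
#'   (matching score exactly 1, i.e. set equality).
#'
#' Precision is `N_cp / |P|`, recall `N_cb / |B|`, and the F-measure their
#' harmonic mean (0 when both are 0).
#'
#' @param predicted,benchmark Non-empty `complex_list` objects (or plain
#'   lists of member-ID vectors).
#' @param threshold Matching-score threshold; default 0.2.
#' @return A `match_report` list: `n_predicted`, `n_benchmark`, `N_cp`,
#'   `N_cb`, `N_pcp`, `precision`, `recall`, `f_measure`, `threshold`.
#' @export
match_counts <- function(predicted, benchmark, threshold = 0.2) {
  if (length(predicted) == 0L || length(benchmark) == 0L) {
    stop("both the predicted and the benchmark complex list must be non-empty")
  }
  ms <- outer(seq_along(predicted), seq_along(benchmark),
              Vectorize(function(i, j) {
                matching_score(predicted[[i]], benchmark[[j]])
              }))
  n_cp <- sum(apply(ms >= threshold, 1L, any))
  n_cb <- sum(apply(ms >= threshold, 2L, any))
  n_pcp <- sum(apply(ms == 1, 1L, any))
  precision <- n_cp / length(predicted)
  recall <- n_cb / length(benchmark)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(n_predicted = length(predicted),
                 n_benchmark = length(benchmark),
                 N_cp = n_cp, N_cb = n_cb, N_pcp = n_pcp,
                 precision = precision, recall = recall, f_measure = f,
                 threshold = threshold),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Benchmark matching (MS >= %g):\n", x$threshold))
  cat(sprintf("  PC = %d  N_cp = %d  N_cb = %d  N_pcp = %d  (|B| = %d)\n",
              x$n_predicted, x$N_cp, x$N_cb, x$N_pcp, x$n_benchmark))
  cat(sprintf("  precision = %.3f  recall = %.3f  F-measure = %.3f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Functional enrichment of one complex
#'
#' For every GO term annotating at least one member, computes the
#' hypergeometric upper-tail probability of observing at least `k` annotated
#' members in a complex of size `n` drawn from a background of `N` proteins
#' of which `K` carry the term, and returns the minimum over all terms and
#' aspects. A low p-value indicates that the co-occurrence of commonly
#' annotated proteins in the complex is unlikely by chance. P-values are not
#' corrected for multiple testing here; see [enrichment_report()].
#'
#' @param members Character vector of complex member identifiers (should be a
#'   subset of `background`).
#' @param go A `go_annotations` object.
#' @param background Character vector: the annotation universe, canonically
#'   all proteins of the input PPI network.
#' @return List with `p` (minimal p-value; 1 when no member is annotated),
#'   `term` (best term, `NA` if none) and `aspect`.
#' @export
complex_enrichment <- function(members, go, background) {
  members <- unique(members)
  background <- unique(background)
  n_bg <- length(background)
  n <- length(intersect(members, background))
  best <- list(p = 1, term = NA_character_, aspect = NA_character_)
  tab <- go$table[go$table$protein %in% background, , drop = FALSE]
  tab <- unique(tab[tab$protein %in% members, c("term", "aspect"),
                    drop = FALSE])
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    ann <- go$table[go$table$term == row$term & go$table$aspect == row$aspect,
                    "protein"]
    K <- length(intersect(ann, background))
    k <- length(intersect(ann, members))
    p <- stats::phyper(k - 1L, K, n_bg - K, n, lower.tail = FALSE)
    if (p < best$p) best <- list(p = p, term = row$term, aspect = row$aspect)
  }
  best
}

#' Per-complex enrichment p-values and summary statistics
#'
#' Runs [complex_enrichment()] on every complex and summarises statistical
#' significance: the number of significant complexes (minimal p below
#' `cutoff`), their proportion, and the p-score. With `adjust = "BH"` the
#' per-complex minimal p-values are Benjamini-Hochberg adjusted across
#' complexes before the cutoff is applied (off by default; the conventional
#' scoring uses raw p-values with cutoff 0.01).
#'
#' @param complexes A `complex_list` (or list of member-ID vectors).
#' @param go A `go_annotations` object.
#' @param background Character vector: annotation universe.
#' @param cutoff Significance cutoff on the p-value; default 0.01 (strict).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An `enrichment_report`: data frame `per_complex` (`complex`,
#'   `size`, `p_value`, `best_term`, `aspect`) plus `SC_count`, `proportion`
#'   and `p_score`.
#' @export
enrichment_report <- function(complexes, go, background, cutoff = 0.01,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  res <- lapply(complexes, complex_enrichment, go = go,
                background = background)
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  per <- data.frame(
    complex = seq_along(complexes),
    size = lengths(complexes),
    p_value = p,
    best_term = vapply(res, `[[`, character(1), "term"),
    aspect = vapply(res, `[[`, character(1), "aspect"),
    stringsAsFactors = FALSE
  )
  structure(list(per_complex = per,
                 SC_count = significant_count(p, cutoff),
                 proportion = significant_count(p, cutoff) / length(p),
                 p_score = p_score(p, cutoff)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "Functional enrichment: PC = %d  SC = %d  proportion = %.2f%%  p-score = %.3f\n",
    nrow(x$per_complex), x$SC_count, 100 * x$proportion, x$p_score))
  invisible(x)
}

#' p-score of a set of enrichment p-values
#'
#' The mean of `-log10(p)` over the complexes whose p-value is below the
#' significance cutoff:
#' \deqn{p\text{-}score = \frac{1}{n} \sum_i -\lg(p_i) \mid p_i < 0.01}
#' with `n` the number of significant complexes; 0 when none is significant.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @param cutoff Significance cutoff (strict); default 0.01.
#' @return Non-negative numeric score.
#' @examples
#' p_score(c(1e-4, 0.5))  # 4: only the significant p-value is averaged
#' @export
p_score <- function(p_values, cutoff = 0.01) {
  check_pvalues(p_values)
  sig <- p_values[p_values < cutoff]
  if (length(sig) == 0L) return(0)
  mean(-log10(sig))
}

#' Number of significant p-values
#' @inheritParams p_score
#' @return Integer count of p-values strictly below `cutoff`.
#' @export
significant_count <- function(p_values, cutoff = 0.01) {
  check_pvalues(p_values)
  sum(p_values < cutoff)
}

check_pvalues <- function(p) {
  if (length(p) > 0 && (any(!is.finite(p)) || any(p <= 0) || any(p > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  invisible(p)
}
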