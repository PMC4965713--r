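#' Read a PPI network from a two-column edge list
#'
#' Reads a tab- or whitespace-separated edge list of physical protein-protein
#' interactions. The first two fields of each line are protein identifiers;
#' extra fields are ignored. Lines starting with `#` are comments.
#' Self-interactions and repeated interactions (in either orientation) are
#' filtered out, which is the standard cleaning step applied to interaction
#' datasets such as DIP or Krogan before complex detection.
#'
#' @param path Path to the edge-list file.
#' @return A `ppi_edgelist`: a data frame with character columns `a` and `b`
#'   (each pair stored with `a < b` lexicographically), carrying an attribute
#'   `n_dropped` with the number of self-interactions and duplicate records
#'   removed.
#' @examples
#' tf <- tempfile()
#' writeLines(c("p1\tp2", "p2\tp1", "p3\tp3"), tf)
#' ppi <- read_ppi(tf)
#' attr(ppi, "n_dropped")  # 2
#' @export
read_ppi <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    stop("PPI edge list '", path, "' contains no data lines")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("malformed PPI edge list line ", attr(lines, "lineno")[bad],
         " in '", path, "': expected at least 2 fields")
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("empty protein identifier in '", path, "'")
  }
  n_in <- length(a)
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  dup <- duplicated(paste(lo, hi, sep = "\t"))
  edges <- data.frame(a = lo[!dup], b = hi[!dup], stringsAsFactors = FALSE)
  attr(edges, "n_dropped") <- n_in - nrow(edges)
  class(edges) <- c("ppi_edgelist", "data.frame")
  edges
}

#' All proteins occurring in a PPI edge list
#' @param ppi A `ppi_edgelist`.
#' @return Sorted character vector of protein identifiers.
#' @export
ppi_proteins <- function(ppi) {
  sort(unique(c(ppi$a, ppi$b)))
}

# Read non-empty, non-comment lines, remembering original line numbers.
# Content is kept untrimmed (GAF lines legitimately end in empty columns);
# only a trailing carriage return is stripped.
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  raw <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  out <- raw[keep]
  attr(out, "lineno") <- which(keep)
  out
}

GO_ASPECTS <- c("BP", "MF", "CC")

#' Read GO annotations
#'
#' Reads Gene Ontology annotations either from a GAF 2.x file (aspect codes
#' P/F/C in column 9, protein identifier in column 2, GO term in column 5) or
#' from a three-column TSV (`protein`, `term`, `aspect`), where the aspect is
#' one of `P`/`F`/`C` or `BP`/`MF`/`CC`. Duplicate (protein, term, aspect)
#' triples are collapsed. Terms are used exactly as annotated; no ancestor
#' propagation through the ontology graph is performed.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return A `go_annotations` object: per-protein GO term sets for the three
#'   aspects BP (biological process), MF (molecular function) and CC (cellular
#'   component). Query it with [go_terms()].
#' @export
read_go_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- read_data_lines(path)
  if (format == "gaf") {
    # GAF lines beginning with "!" are headers; "#" already stripped
    is_hdr <- startsWith(lines, "!")
    lineno <- attr(lines, "lineno")[!is_hdr]
    lines <- lines[!is_hdr]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 15L)) {
      bad <- which(nf < 15L)[1L]
      stop("GAF line ", lineno[bad], " in '", path,
           "' has ", nf[bad], " columns; GAF 2.x requires at least 15")
    }
    protein <- vapply(fields, `[[`, character(1), 2L)
    term <- vapply(fields, `[[`, character(1), 5L)
    aspect <- vapply(fields, `[[`, character(1), 9L)
  } else {
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      bad <- which(nf < 3L)[1L]
      stop("annotation TSV line ", attr(lines, "lineno")[bad], " in '", path,
           "' has fewer than 3 columns (protein, term, aspect)")
    }
    protein <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
    aspect <- vapply(fields, `[[`, character(1), 3L)
  }
  go_annotation_table(protein, term, aspect)
}

#' Build a GO annotation table from vectors
#'
#' @param protein,term,aspect Equal-length character vectors; `aspect` uses
#'   GAF codes `P`/`F`/`C` or the long forms `BP`/`MF`/`CC`.
#' @return A `go_annotations` object.
#' @export
go_annotation_table <- function(protein, term, aspect) {
  map <- c(P = "BP", F = "MF", C = "CC", BP = "BP", MF = "MF", CC = "CC")
  unknown <- setdiff(unique(aspect), names(map))
  if (length(unknown) > 0L) {
    stop("unknown GO aspect code(s): ", paste(unknown, collapse = ", "))
  }
  aspect <- unname(map[aspect])
  tab <- unique(data.frame(protein = protein, term = term, aspect = aspect,
                           stringsAsFactors = FALSE))
  sets <- lapply(GO_ASPECTS, function(a) {
    sub <- tab[tab$aspect == a, , drop = FALSE]
    if (nrow(sub) == 0L) return(list())
    split(sub$term, sub$protein)
  })
  names(sets) <- GO_ASPECTS
  structure(list(table = tab, sets = sets), class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("GO annotations:", nrow(x$table), "(protein, term, aspect) triples;",
      length(unique(x$table$protein)), "proteins\n")
  invisible(x)
}

#' GO term set of a protein in one aspect
#'
#' @param go A `go_annotations` object.
#' @param protein Protein identifier.
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @return Character vector of GO term identifiers (empty if unannotated).
#' @export
go_terms <- function(go, protein, aspect) {
  aspect <- match.arg(aspect, GO_ASPECTS)
  out <- go$sets[[aspect]][[protein]]
  if (is.null(out)) character(0) else out
}

#' Read a complex list (one complex per line)
#'
#' Each line holds the whitespace-separated member identifiers of one complex
#' (the format used by the CYC2008 benchmark catalogue). Empty lines are
#' skipped with a warning; duplicate identifiers within a line are collapsed.
#'
#' @param path Path to the file.
#' @return A `complex_list`: a list of character vectors of member IDs.
#' @export
read_complex_list <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!startsWith(trimws(raw), "#") | !nzchar(trimws(raw))]
  blank <- !nzchar(trimws(raw))
  if (any(blank)) {
    warning("skipped ", sum(blank), " empty line(s) in '", path, "'")
  }
  members <- lapply(strsplit(trimws(raw[!blank]), "[ \t]+"), unique)
  structure(members, class = "complex_list")
}

#' Write a complex list (one complex per line)
#'
#' Inverse of [read_complex_list()]: `read_complex_list(write_complex_list(x))`
#' preserves member sets and order.
#'
#' @param complexes A `complex_list` or plain list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_list <- function(complexes, path) {
  writeLines(vapply(complexes, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' @export
print.complex_list <- function(x, ...) {
  sizes <- lengths(x)
  cat("Complex list:", length(x), "complexes; sizes",
      if (length(x)) paste0("[", min(sizes), ", ", max(sizes), "]") else "[]", "\n")
  invisible(x)
}

#' Write predicted complexes as an annotated TSV
#'
#' Columns: `complex_id`, `size`, `weighted_density`, `source_relation`,
#' `members` (semicolon-joined). Weighted densities are written with six
#' decimal places.
#'
#' @param sc A `complex_set` as returned by [mine_complexes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_table <- function(sc, path) {
  df <- as.data.frame(sc)
  df$weighted_density <- sprintf("%.6f", df$weighted_density)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a predicted-complex TSV
#'
#' @param path Path written by [write_complex_table()].
#' @return A `complex_list` with the member sets, in file order.
#' @export
read_complex_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(strsplit(df$members, ";", fixed = TRUE), class = "complex_list")
}
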