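#' Read a proteome FASTA file
#'
#' Reads amino-acid sequences via \pkg{Biostrings} and applies the record-id
#' convention used throughout the reconstruction workflow: the record id is
#' the first whitespace-delimited token of the header.  Duplicate ids are an
#' error (the reciprocal homology tables key on them); an empty file yields
#' an empty set with a warning.
#'
#' @param path Path to a FASTA file of peptide sequences.
#' @param stripVersion If \code{TRUE}, a trailing \code{.N} version suffix
#'   is removed from each id (versioned transcript ids are common in draft
#'   genome annotations, while homology tables may carry unversioned ids).
#' @return An [Biostrings::AAStringSet-class] named by record id.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a description", "MKV", ">b", "MA"), f)
#' names(readProteinFasta(f))
#' @export
readProteinFasta <- function(path, stripVersion = FALSE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning("no sequences in ", path)
    return(seqs)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (stripVersion) ids <- sub("\\.[0-9]+$", "", ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence(s) in ", path, ": ",
         paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Summarize protein sequence lengths
#'
#' Five-number summary, mean and a fixed-width histogram of the peptide
#' lengths of a proteome -- the standard first look at a genome annotation
#' before homology mapping (fragmented assemblies show up as an excess of
#' short peptides).
#'
#' @param proteins An [Biostrings::AAStringSet-class] (as returned by
#'   [readProteinFasta()]) or an integer vector of lengths.
#' @param binWidth Histogram bin width in residues (>= 1).
#' @return A list with elements \code{n}, \code{min}, \code{q1},
#'   \code{median}, \code{q3}, \code{max}, \code{mean} and
#'   \code{histogram} (a \code{data.frame} with \code{lower}, \code{upper},
#'   \code{count}; bins are \code{[lower, upper)} except the last, which is
#'   closed).
#' @examples
#' lengthSummary(c(10L, 20L, 30L), binWidth = 10)$median
#' @export
lengthSummary <- function(proteins, binWidth = 50L) {
  lens <- if (is.numeric(proteins)) as.integer(proteins)
          else Biostrings::width(proteins)
  if (length(lens) == 0L) stop("cannot summarize an empty protein set")
  stopifnot(binWidth >= 1L)
  q <- stats::quantile(lens, c(0.25, 0.5, 0.75), names = FALSE)
  edges <- seq(0L, (max(lens) %/% binWidth + 1L) * binWidth, by = binWidth)
  counts <- tabulate(lens %/% binWidth + 1L, nbins = length(edges) - 1L)
  list(n = length(lens), min = min(lens), q1 = q[1L], median = q[2L],
       q3 = q[3L], max = max(lens), mean = mean(lens),
       histogram = data.frame(lower = edges[-length(edges)],
                              upper = edges[-1L], count = counts))
}

#' Read and write homology search results in BLAST tabular format
#'
#' \code{readHomologyTable} parses the standard 12-column tab-separated
#' protein-search output (\code{outfmt 6}: \code{qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore}) into a
#' [HomologyTable-class]; lines starting with \code{#} are ignored.
#' \code{writeHomologyTable} emits the same dialect, so generated fixtures
#' and real search output are interchangeable.  An E-value of \code{0.0} is
#' legal (reported by the search tool when the value underflows) and ranks
#' as the strongest possible evidence.
#'
#' @param path File path.
#' @param direction \code{"target_to_template"} (queries are target-species
#'   proteins) or \code{"template_to_target"}.
#' @param table A [HomologyTable-class].
#' @return \code{readHomologyTable}: a [HomologyTable-class] with one hit
#'   per data line, in file order.  \code{writeHomologyTable}: \code{path},
#'   invisibly.
#' @name homology-io
#' @export
readHomologyTable <- function(path, direction = "target_to_template") {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(HomologyTable(direction = direction))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("line ", lineNo[bad], " of ", path, ": expected 12 tab-separated ",
         "columns, found ", nf[bad])
  }
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("line ", lineNo[which(is.na(v))[1L]], " of ", path,
           ": unparseable ", what, " '", m[which(is.na(v))[1L], col], "'")
    v
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    alignment_length = as.integer(num(4L, "alignment length")),
    mismatches = as.integer(num(5L, "mismatch count")),
    gap_opens = as.integer(num(6L, "gap-open count")),
    q_start = as.integer(num(7L, "query start")),
    q_end = as.integer(num(8L, "query end")),
    s_start = as.integer(num(9L, "subject start")),
    s_end = as.integer(num(10L, "subject end")),
    e_value = num(11L, "E-value"),
    bit_score = num(12L, "bit score"),
    stringsAsFactors = FALSE)
  HomologyTable(hits, direction = direction)
}

#' @rdname homology-io
#' @export
writeHomologyTable <- function(table, path) {
  stopifnot(is(table, "HomologyTable"))
  h <- table@hits
  fmt <- function(x) ifelse(x == 0, "0.0", sprintf("%.12g", x))
  lines <- if (nrow(h)) paste(
    h$query_id, h$subject_id, fmt(h$percent_identity),
    h$alignment_length, h$mismatches, h$gap_opens,
    h$q_start, h$q_end, h$s_start, h$s_end,
    fmt(h$e_value), fmt(h$bit_score), sep = "\t") else character(0L)
  writeLines(lines, path)
  invisible(path)
}
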