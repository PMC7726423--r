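#' Alignment-quality threshold predicate
#'
#' A hit is acceptable when its E-value is at most \code{maxE}, its
#' alignment length at least \code{minLen} residues, and its percent
#' identity at least \code{minIde}.  All three boundaries are inclusive:
#' the stated maximum E-value and minimum length/identity are themselves
#' acceptable.
#'
#' @param hits A hits \code{data.frame} (see [HomologyTable-class]) or a
#'   [HomologyTable-class].
#' @param params A [MappingParams-class].
#' @return Logical vector, one element per hit.
#' @examples
#' h <- data.frame(query_id = "t1", subject_id = "h1",
#'                 percent_identity = 80, alignment_length = 250L,
#'                 mismatches = 0L, gap_opens = 0L, q_start = 1L,
#'                 q_end = 250L, s_start = 1L, s_end = 250L,
#'                 e_value = 1e-50, bit_score = 500)
#' passesThresholds(h, mappingParams())
#' @export
passesThresholds <- function(hits, params = mappingParams()) {
  if (is(hits, "HomologyTable")) hits <- hits@hits
  hits$e_value <= params@maxE &
    hits$alignment_length >= params@minLen &
    hits$percent_identity >= params@minIde
}

## Deterministic hit ranking: E-value ascending, bit score descending,
## subject id ascending (lexicographic), original order last.
hitOrder <- function(h) {
  order(h$e_value, -h$bit_score, h$subject_id, seq_len(nrow(h)),
        method = "radix")
}

#' Collapse multiple HSPs to one hit per (query, subject) pair
#'
#' A protein search can report several high-scoring pairs (HSPs) for the
#' same query/subject combination.  For gene mapping only one representative
#' per pair is used: the one with the lowest E-value, ties broken by higher
#' bit score.  Idempotent.
#'
#' @param table A [HomologyTable-class].
#' @return A [HomologyTable-class] with at most one hit per
#'   (query, subject) pair.
#' @export
collapseHsps <- function(table) {
  stopifnot(is(table, "HomologyTable"))
  h <- table@hits
  if (nrow(h) == 0L) return(table)
  h <- h[hitOrder(h), , drop = FALSE]
  h <- h[!duplicated(h[, c("query_id", "subject_id")]), , drop = FALSE]
  h <- h[order(h$query_id, h$subject_id, method = "radix"), , drop = FALSE]
  rownames(h) <- NULL
  HomologyTable(h, direction = table@direction)
}

#' Best hit per query
#'
#' For each query, keep only the hit with the lowest E-value across all
#' subjects; ties are broken by higher bit score, then by lexicographically
#' smaller subject id.  This is the per-direction reduction used by
#' strictness 3 (reciprocal best hits).
#'
#' @param table A [HomologyTable-class].
#' @return A \code{data.frame} of hits, one row per query, ordered by query
#'   id.
#' @export
bestHits <- function(table) {
  stopifnot(is(table, "HomologyTable"))
  h <- table@hits
  if (nrow(h) == 0L) return(h)
  h <- h[hitOrder(h), , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  h <- h[order(h$query_id, method = "radix"), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Map orthologs from reciprocal homology searches
#'
#' Turns the two directions of a reciprocal protein search into a set of
#' (target gene, template gene) ortholog pairs under one of three
#' strictness regimes:
#'
#' \describe{
#'   \item{strictness 1}{a pair is accepted when a threshold-passing hit
#'     exists in \emph{both} directions (one-to-many mapping allowed);}
#'   \item{strictness 2}{a threshold-passing hit in \emph{at least one}
#'     direction suffices;}
#'   \item{strictness 3}{each direction is first reduced to the best
#'     (lowest-E-value) hit per query; a pair is accepted when the two best
#'     hits point at each other and both pass the thresholds -- best
#'     reciprocal hits, a one-to-one partial matching.}
#' }
#'
#' HSPs are collapsed per (query, subject) pair before any predicate is
#' evaluated.  At strictness 3 the thresholds are applied \emph{after} best
#' hit selection: a best hit that fails them kills the pair rather than
#' promoting the runner-up.  For fixed inputs the accepted sets nest:
#' strictness 3 \eqn{\subseteq} 1 \eqn{\subseteq} 2.
#'
#' @param fwd [HomologyTable-class] with direction
#'   \code{"target_to_template"}.
#' @param rev [HomologyTable-class] with direction
#'   \code{"template_to_target"}.
#' @param params A [MappingParams-class] carrying the strictness and the
#'   thresholds.
#' @return An [OrthologMap-class].
#' @examples
#' fwd <- HomologyTable(data.frame(
#'   query_id = "t1", subject_id = "h1", percent_identity = 80,
#'   alignment_length = 250L, mismatches = 0L, gap_opens = 0L,
#'   q_start = 1L, q_end = 250L, s_start = 1L, s_end = 250L,
#'   e_value = 1e-50, bit_score = 500), "target_to_template")
#' rev <- HomologyTable(data.frame(
#'   query_id = "h1", subject_id = "t1", percent_identity = 78,
#'   alignment_length = 240L, mismatches = 0L, gap_opens = 0L,
#'   q_start = 1L, q_end = 240L, s_start = 1L, s_end = 240L,
#'   e_value = 1e-45, bit_score = 480), "template_to_target")
#' orthologPairs(mapOrthologs(fwd, rev, mappingParams(strictness = 1)))
#' @export
mapOrthologs <- function(fwd, rev, params = mappingParams()) {
  stopifnot(is(fwd, "HomologyTable"), is(rev, "HomologyTable"),
            is(params, "MappingParams"))
  if (fwd@direction == rev@direction)
    stop("fwd and rev tables have the same direction flag ('",
         fwd@direction, "'); a reciprocal pair of tables is required")
  if (fwd@direction != "target_to_template") { tmp <- fwd; fwd <- rev; rev <- tmp }

  cf <- collapseHsps(fwd)@hits   # query = target, subject = template
  cr <- collapseHsps(rev)@hits   # query = template, subject = target

  if (params@strictness == 3L) {
    bf <- bestHits(collapseHsps(fwd))
    br <- bestHits(collapseHsps(rev))
    bf <- bf[passesThresholds(bf, params), , drop = FALSE]
    br <- br[passesThresholds(br, params), , drop = FALSE]
    key <- paste(bf$query_id, bf$subject_id, sep = "\r")
    rkey <- paste(br$subject_id, br$query_id, sep = "\r")
    keep <- key %in% rkey
    pairs <- data.frame(target = bf$query_id[keep],
                        template = bf$subject_id[keep],
                        stringsAsFactors = FALSE)
  } else {
    pf <- cf[passesThresholds(cf, params), , drop = FALSE]
    pr <- cr[passesThresholds(cr, params), , drop = FALSE]
    fwdPairs <- data.frame(target = pf$query_id, template = pf$subject_id,
                           stringsAsFactors = FALSE)
    revPairs <- data.frame(target = pr$subject_id, template = pr$query_id,
                           stringsAsFactors = FALSE)
    pairs <- if (params@strictness == 1L) {
      fwdPairs[paste(fwdPairs$target, fwdPairs$template, sep = "\r") %in%
                 paste(revPairs$target, revPairs$template, sep = "\r"), ,
               drop = FALSE]
    } else {
      unique(rbind(fwdPairs, revPairs))
    }
  }
  pairs <- unique(pairs)

  evidence <- rbind(
    evidenceRows(cf, pairs, direction = "target_to_template",
                 tgt = cf$query_id, tpl = cf$subject_id),
    evidenceRows(cr, pairs, direction = "template_to_target",
                 tgt = cr$subject_id, tpl = cr$query_id))
  OrthologMap(pairs = pairs, evidence = evidence, params = params)
}

evidenceRows <- function(hits, pairs, direction, tgt, tpl) {
  sel <- paste(tgt, tpl, sep = "\r") %in%
    paste(pairs$target, pairs$template, sep = "\r")
  data.frame(target = tgt[sel], template = tpl[sel],
             direction = rep_len(direction, sum(sel)),
             e_value = hits$e_value[sel], bit_score = hits$bit_score[sel],
             percent_identity = hits$percent_identity[sel],
             alignment_length = hits$alignment_length[sel],
             stringsAsFactors = FALSE)
}

#' Summarize an ortholog map
#'
#' @param map An [OrthologMap-class].
#' @return A list with \code{n_pairs}, \code{n_target_genes},
#'   \code{n_template_genes} and \code{n_template_multi} (template genes
#'   carrying more than one target ortholog -- expected under one-to-many
#'   regimes for lineages with whole-genome duplication, and always 0 at
#'   strictness 3).
#' @export
mapSummary <- function(map) {
  stopifnot(is(map, "OrthologMap"))
  p <- map@pairs
  multi <- table(p$template)
  list(n_pairs = nrow(p),
       n_target_genes = length(unique(p$target)),
       n_template_genes = length(unique(p$template)),
       n_template_multi = sum(multi > 1L))
}
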