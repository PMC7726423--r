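#' @import methods
NULL

## ---------------------------------------------------------------------------
## GEModel
## ---------------------------------------------------------------------------

#' Genome-scale metabolic model container
#'
#' An S4 container for a genome-scale metabolic model (GEM): compartments,
#' genes, metabolites, reactions with stoichiometry, flux bounds, subsystem
#' labels and gene-protein-reaction (GPR) rules, plus free-form provenance.
#' Referential integrity is enforced by the validity method and is rejected,
#' never silently repaired: a reaction citing an unknown metabolite, a
#' metabolite citing an unknown compartment, or a GPR leaf citing an unknown
#' gene all fail validation with a message listing the offenders.
#'
#' @slot id Model identifier.
#' @slot compartments \code{data.frame} with columns \code{id}, \code{name}.
#' @slot genes \code{data.frame} with columns \code{id}, \code{name},
#'   \code{putative} (logical; \code{TRUE} flags family-level placeholder
#'   genes introduced by gap curation rather than homology evidence).
#' @slot metabolites \code{data.frame} with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula}.
#' @slot reactions \code{data.frame} with columns \code{id}, \code{name},
#'   \code{lower}, \code{upper} (flux bounds), \code{subsystem}, \code{gpr}
#'   (canonical GPR rule string; \code{""} means no gene association).
#' @slot stoichiometry Named list parallel to \code{reactions}: for each
#'   reaction id a named numeric vector of metabolite id -> signed
#'   coefficient (negative = consumed).
#' @slot provenance Free-form list of metadata (source file, build
#'   parameters, merge tags, ...).
#'
#' @seealso [GEModel()] for construction, [readGEM()]/[writeGEM()] for I/O,
#'   [modelStats()] for summary counts.
#' @export
setClass("GEModel", representation(
  id            = "character",
  compartments  = "data.frame",
  genes         = "data.frame",
  metabolites   = "data.frame",
  reactions     = "data.frame",
  stoichiometry = "list",
  provenance    = "list"
))

emptyFrame <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(type) vector(type, 0L)),
                stringsAsFactors = FALSE)
}

checkIds <- function(ids, what) {
  msgs <- character(0L)
  if (anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, paste0("empty or NA ", what, " id"))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate ", what, " id(s): ",
                           paste(dup, collapse = ", ")))
  msgs
}

validGEModel <- function(object) {
  msgs <- character(0L)
  cmp <- object@compartments; gen <- object@genes
  met <- object@metabolites;  rxn <- object@reactions
  msgs <- c(msgs,
            checkIds(cmp$id, "compartment"), checkIds(gen$id, "gene"),
            checkIds(met$id, "metabolite"),  checkIds(rxn$id, "reaction"))
  bad <- setdiff(met$compartment, cmp$id)
  if (length(bad))
    msgs <- c(msgs, paste0("metabolite compartment(s) not in model: ",
                           paste(bad, collapse = ", ")))
  if (!identical(names(object@stoichiometry), as.character(rxn$id)))
    msgs <- c(msgs, "stoichiometry list names must equal reaction ids, in order")
  for (rid in names(object@stoichiometry)) {
    s <- object@stoichiometry[[rid]]
    if (!is.numeric(s) || length(s) == 0L || is.null(names(s))) {
      msgs <- c(msgs, paste0("reaction ", rid,
                             ": stoichiometry must be a non-empty named numeric vector"))
      next
    }
    unknown <- setdiff(names(s), met$id)
    if (length(unknown))
      msgs <- c(msgs, paste0("reaction ", rid, " cites unknown metabolite(s): ",
                             paste(unknown, collapse = ", ")))
    if (any(s == 0))
      msgs <- c(msgs, paste0("reaction ", rid, ": zero stoichiometric coefficient"))
  }
  if (nrow(rxn)) {
    for (i in seq_len(nrow(rxn))) {
      leaves <- tryCatch(gprGenes(parseGpr(rxn$gpr[i])),
                         error = function(e) {
                           msgs <<- c(msgs, paste0("reaction ", rxn$id[i], ": ",
                                                   conditionMessage(e)))
                           character(0L)
                         })
      unknown <- setdiff(leaves, gen$id)
      if (length(unknown))
        msgs <- c(msgs, paste0("reaction ", rxn$id[i],
                               " GPR cites unknown gene(s): ",
                               paste(unknown, collapse = ", ")))
    }
    if (any(rxn$lower > rxn$upper))
      msgs <- c(msgs, "reaction with lower bound above upper bound")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("GEModel", validGEModel)

#' Construct a GEModel
#'
#' @param id Model identifier.
#' @param compartments,genes,metabolites,reactions Data frames as described
#'   in [GEModel-class]; missing optional columns (\code{name},
#'   \code{formula}, \code{putative}, \code{subsystem}) are filled with
#'   defaults.
#' @param stoichiometry Named list of named numeric vectors, one per
#'   reaction id (same order as \code{reactions}).
#' @param provenance List of free-form metadata.
#' @return A validated [GEModel-class] object.
#' @examples
#' m <- GEModel("toy",
#'   compartments  = data.frame(id = "c", name = "cytosol"),
#'   genes         = data.frame(id = c("g1", "g2")),
#'   metabolites   = data.frame(id = c("A", "B"), compartment = "c"),
#'   reactions     = data.frame(id = "R1", gpr = "g1 or g2"),
#'   stoichiometry = list(R1 = c(A = -1, B = 1)))
#' modelStats(m)
#' @export
GEModel <- function(id = "model",
                    compartments  = emptyFrame(id = "character", name = "character"),
                    genes         = emptyFrame(id = "character"),
                    metabolites   = emptyFrame(id = "character", compartment = "character"),
                    reactions     = emptyFrame(id = "character"),
                    stoichiometry = stats::setNames(list(), character(0L)),
                    provenance    = list()) {
  compartments <- fillCols(compartments, name = compartments$id)
  genes        <- fillCols(genes, name = genes$id, putative = FALSE)
  metabolites  <- fillCols(metabolites, name = metabolites$id, formula = "")
  reactions    <- fillCols(reactions, name = reactions$id,
                           lower = -1000, upper = 1000,
                           subsystem = "", gpr = "")
  if (is.null(names(stoichiometry)) && length(stoichiometry) == nrow(reactions))
    names(stoichiometry) <- reactions$id
  new("GEModel", id = id,
      compartments  = normFrame(compartments, c("id", "name")),
      genes         = normFrame(genes, c("id", "name", "putative")),
      metabolites   = normFrame(metabolites, c("id", "name", "compartment", "formula")),
      reactions     = normFrame(reactions, c("id", "name", "lower", "upper",
                                             "subsystem", "gpr")),
      stoichiometry = stoichiometry,
      provenance    = provenance)
}

fillCols <- function(df, ...) {
  defaults <- list(...)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep_len(defaults[[nm]], nrow(df))
  df
}

normFrame <- function(df, cols) {
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  df$id <- as.character(df$id)
  df
}

setMethod("show", "GEModel", function(object) {
  st <- modelStats(object)
  cat("GEModel '", object@id, "': ",
      st$n_reactions, " reactions, ", st$n_metabolites, " metabolites, ",
      st$n_genes, " genes, ", st$n_compartments, " compartments, ",
      st$n_subsystems, " subsystems\n", sep = "")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## HomologyTable
## ---------------------------------------------------------------------------

homologyCols <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "e_value", "bit_score")

#' Bidirectional protein-homology search results
#'
#' Holds one direction of a reciprocal protein homology search in the
#' standard 12-column BLAST tabular layout (\code{outfmt 6}).  A table may
#' carry several high-scoring pairs (HSPs) for the same (query, subject)
#' pair; [collapseHsps()] reduces them to one representative.
#'
#' @slot direction \code{"target_to_template"} or
#'   \code{"template_to_target"}.
#' @slot hits \code{data.frame} with columns \code{query_id},
#'   \code{subject_id}, \code{percent_identity}, \code{alignment_length},
#'   \code{mismatches}, \code{gap_opens}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end}, \code{e_value}, \code{bit_score}.
#' @seealso [readHomologyTable()], [mapOrthologs()]
#' @export
setClass("HomologyTable", representation(
  direction = "character",
  hits      = "data.frame"
))

setValidity("HomologyTable", function(object) {
  msgs <- character(0L)
  if (!object@direction %in% c("target_to_template", "template_to_target"))
    msgs <- c(msgs, "direction must be 'target_to_template' or 'template_to_target'")
  if (!identical(colnames(object@hits), homologyCols))
    msgs <- c(msgs, paste0("hits must have columns: ",
                           paste(homologyCols, collapse = ", ")))
  else {
    h <- object@hits
    if (any(h$e_value < 0)) msgs <- c(msgs, "negative E-value")
    if (any(h$percent_identity < 0 | h$percent_identity > 100))
      msgs <- c(msgs, "percent identity outside [0, 100]")
    if (any(h$alignment_length < 1))
      msgs <- c(msgs, "alignment length below 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HomologyTable-class Construct a homology table from a hits
#'   data frame (columns as above; extra columns dropped, order enforced).
#' @param hits Data frame of alignment records.
#' @param direction Search direction flag.
#' @export
HomologyTable <- function(hits = emptyHits(), direction = "target_to_template") {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  missing <- setdiff(homologyCols, colnames(hits))
  if (length(missing))
    stop("missing homology column(s): ", paste(missing, collapse = ", "))
  hits <- hits[, homologyCols, drop = FALSE]
  rownames(hits) <- NULL
  hits$query_id <- as.character(hits$query_id)
  hits$subject_id <- as.character(hits$subject_id)
  new("HomologyTable", direction = direction, hits = hits)
}

emptyHits <- function() {
  emptyFrame(query_id = "character", subject_id = "character",
             percent_identity = "numeric", alignment_length = "integer",
             mismatches = "integer", gap_opens = "integer",
             q_start = "integer", q_end = "integer",
             s_start = "integer", s_end = "integer",
             e_value = "numeric", bit_score = "numeric")
}

setMethod("show", "HomologyTable", function(object) {
  cat("HomologyTable (", object@direction, "): ", nrow(object@hits),
      " hits, ", length(unique(object@hits$query_id)), " queries\n", sep = "")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## MappingParams
## ---------------------------------------------------------------------------

#' Ortholog-mapping strictness and thresholds
#'
#' Bundles the strictness regime and the three alignment-quality thresholds
#' applied during gene mapping.  The defaults are the standard homology-
#' transfer settings for this workflow: maximum E-value \code{1e-30},
#' minimum alignment length 200 residues, minimum identity 40 percent.  All
#' threshold boundaries are inclusive (the stated maximum/minimum itself is
#' acceptable).
#'
#' Strictness regimes: \code{1} -- a gene pair is accepted when a passing
#' hit exists in both search directions; \code{2} -- in at least one
#' direction; \code{3} -- reciprocal best hits only: each direction is first
#' reduced to the lowest-E-value hit per query, and a pair is accepted when
#' the two best hits point at each other and both pass the thresholds.
#'
#' @slot strictness Integer 1, 2 or 3.
#' @slot maxE Maximum acceptable E-value (inclusive).
#' @slot minLen Minimum acceptable alignment length in residues (inclusive).
#' @slot minIde Minimum acceptable percent identity, 0-100 (inclusive).
#' @export
setClass("MappingParams", representation(
  strictness = "integer",
  maxE   = "numeric",
  minLen = "integer",
  minIde = "numeric"
))

setValidity("MappingParams", function(object) {
  msgs <- character(0L)
  if (!object@strictness %in% 1:3) msgs <- c(msgs, "strictness must be 1, 2 or 3")
  if (object@maxE < 0) msgs <- c(msgs, "maxE must be >= 0")
  if (object@minLen < 1) msgs <- c(msgs, "minLen must be >= 1")
  if (object@minIde < 0 || object@minIde > 100)
    msgs <- c(msgs, "minIde must be in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MappingParams-class Constructor with the default thresholds.
#' @param strictness Strictness regime (1, 2 or 3).
#' @param maxE,minLen,minIde Threshold values; see slots.
#' @export
mappingParams <- function(strictness = 1L, maxE = 1e-30, minLen = 200L,
                          minIde = 40) {
  new("MappingParams", strictness = as.integer(strictness), maxE = maxE,
      minLen = as.integer(minLen), minIde = as.numeric(minIde))
}

setMethod("show", "MappingParams", function(object) {
  cat("MappingParams: strictness=", object@strictness,
      ", maxE=", format(object@maxE), ", minLen=", object@minLen,
      ", minIde=", object@minIde, "%\n", sep = "")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## OrthologMap
## ---------------------------------------------------------------------------

#' Target-template ortholog map
#'
#' The outcome of [mapOrthologs()]: the accepted (target gene, template
#' gene) pairs, the alignment evidence supporting each pair in each
#' direction, and the [MappingParams-class] used.
#'
#' @slot pairs \code{data.frame} with columns \code{target}, \code{template};
#'   rows unique.
#' @slot evidence \code{data.frame} of supporting hits with columns
#'   \code{target}, \code{template}, \code{direction}, \code{e_value},
#'   \code{bit_score}, \code{percent_identity}, \code{alignment_length}.
#' @slot params The [MappingParams-class] the map was built under.
#' @seealso [mapOrthologs()], [mapSummary()], [orthologPairs()]
#' @export
setClass("OrthologMap", representation(
  pairs    = "data.frame",
  evidence = "data.frame",
  params   = "MappingParams"
))

setValidity("OrthologMap", function(object) {
  msgs <- character(0L)
  if (!identical(colnames(object@pairs), c("target", "template")))
    msgs <- c(msgs, "pairs must have columns target, template")
  else if (anyDuplicated(object@pairs))
    msgs <- c(msgs, "duplicate ortholog pairs")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OrthologMap-class Construct an ortholog map from a pair
#'   data frame (columns \code{target}, \code{template}).
#' @param pairs Data frame of accepted pairs.
#' @param evidence Data frame of supporting hits (may be empty).
#' @param params The [MappingParams-class] used.
#' @export
OrthologMap <- function(pairs = emptyFrame(target = "character", template = "character"),
                        evidence = emptyEvidence(),
                        params = mappingParams()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs$target <- as.character(pairs$target)
  pairs$template <- as.character(pairs$template)
  pairs <- pairs[, c("target", "template"), drop = FALSE]
  pairs <- pairs[order(pairs$target, pairs$template, method = "radix"), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  new("OrthologMap", pairs = pairs, evidence = evidence, params = params)
}

emptyEvidence <- function() {
  emptyFrame(target = "character", template = "character",
             direction = "character", e_value = "numeric",
             bit_score = "numeric", percent_identity = "numeric",
             alignment_length = "integer")
}

#' Extract the accepted pairs of an ortholog map
#'
#' @param map An [OrthologMap-class].
#' @return \code{data.frame} with columns \code{target}, \code{template}.
#' @export
orthologPairs <- function(map) map@pairs

setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap: ", nrow(object@pairs), " pairs (",
      length(unique(object@pairs$target)), " target genes, ",
      length(unique(object@pairs$template)),
      " template genes), strictness=", object@params@strictness, "\n", sep = "")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## GapReport
## ---------------------------------------------------------------------------

gapStatuses <- c("auto", "filled_spontaneous", "filled_family", "missing")

#' Per-subsystem gap analysis report
#'
#' Classifies every template reaction of one subsystem relative to a draft
#' model: \code{auto} -- present in the automatically generated draft;
#' \code{filled_spontaneous} -- gap filled as a spontaneous (enzyme-free)
#' reaction by a curation rule; \code{filled_family} -- gap filled with a
#' family-level placeholder gene; \code{missing} -- still absent.  The four
#' statuses always partition the subsystem's template reaction set.
#'
#' @slot subsystem Subsystem label.
#' @slot states \code{data.frame} with columns \code{reaction_id},
#'   \code{status} (one of the four above), \code{placeholder_gene}
#'   (\code{NA} except for \code{filled_family} rows).
#' @seealso [subsystemDiff()], [applyCuration()], [exportReactionStates()]
#' @export
setClass("GapReport", representation(
  subsystem = "character",
  states    = "data.frame"
))

setValidity("GapReport", function(object) {
  msgs <- character(0L)
  st <- object@states
  if (!all(c("reaction_id", "status") %in% colnames(st)))
    msgs <- c(msgs, "states must have columns reaction_id, status")
  else {
    if (anyDuplicated(st$reaction_id))
      msgs <- c(msgs, "duplicate reaction ids in gap report")
    if (!all(st$status %in% gapStatuses))
      msgs <- c(msgs, paste0("status must be one of: ",
                             paste(gapStatuses, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GapReport-class Construct a gap report from a states data
#'   frame (columns \code{reaction_id}, \code{status}, optionally
#'   \code{placeholder_gene}).
#' @param subsystem Subsystem label.
#' @param states Data frame of per-reaction statuses.
#' @export
GapReport <- function(subsystem, states) {
  if (is.null(states$placeholder_gene))
    states$placeholder_gene <- rep(NA_character_, nrow(states))
  states <- states[, c("reaction_id", "status", "placeholder_gene"),
                   drop = FALSE]
  rownames(states) <- NULL
  new("GapReport", subsystem = subsystem, states = states)
}

#' Status counts of a gap report
#'
#' @param report A [GapReport-class].
#' @return Named integer vector over the four statuses.
#' @export
gapSummary <- function(report) {
  tab <- table(factor(report@states$status, levels = gapStatuses))
  stats::setNames(as.integer(tab), gapStatuses)
}

#' Reaction statuses of a gap report
#'
#' @param report A [GapReport-class].
#' @return \code{data.frame} with columns \code{reaction_id}, \code{status},
#'   \code{placeholder_gene}.
#' @export
gapStates <- function(report) report@states

setMethod("show", "GapReport", function(object) {
  s <- gapSummary(object)
  cat("GapReport for subsystem '", object@subsystem, "': ",
      sum(s), " reactions (", paste(names(s), s, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(NULL)
})
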