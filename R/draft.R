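#' Rewrite a template GPR rule onto target-species genes
#'
#' Replaces template gene ids in a GPR rule by their target-species
#' orthologs, under one of two policies:
#'
#' \describe{
#'   \item{\code{"or_of_orthologs"}}{the result is a flat OR over every
#'     target gene mapped to any leaf of the rule (empty if none).  Homology
#'     evidence cannot confirm complex stoichiometry, so any mapped enzyme
#'     is treated as sufficient -- matching the reaction-inclusion rule of
#'     [extractDraft()].}
#'   \item{\code{"preserve_logic"}}{each leaf becomes an OR over its
#'     orthologs; a leaf with no ortholog is deleted, and an AND node that
#'     loses any child becomes empty (strict complex semantics).  Emptiness
#'     propagates upward through AND and is dropped from OR.}
#' }
#'
#' @param expr A GPR expression over template gene ids (see [parseGpr()]).
#' @param map An [OrthologMap-class] (or a \code{data.frame} with columns
#'   \code{target}, \code{template}).
#' @param mode \code{"or_of_orthologs"} (default) or
#'   \code{"preserve_logic"}.
#' @return A normalized GPR expression over target gene ids (possibly
#'   \code{NULL}, the empty rule).
#' @examples
#' map <- data.frame(target = c("c1", "c3"), template = c("h1", "h3"))
#' serializeGpr(rewriteGpr(parseGpr("h1 or h3"), map))
#' @export
rewriteGpr <- function(expr, map, mode = c("or_of_orthologs", "preserve_logic")) {
  mode <- match.arg(mode)
  pairs <- if (is(map, "OrthologMap")) map@pairs else map
  orthologsOf <- function(g) sort(pairs$target[pairs$template == g])
  if (mode == "or_of_orthologs") {
    targets <- sort(unique(pairs$target[pairs$template %in% gprGenes(expr)]))
    if (length(targets) == 0L) return(NULL)
    return(gprNode("or", as.list(targets)))
  }
  rewrite <- function(e) {
    if (is.null(e)) return(NULL)
    if (isGprLeaf(e)) {
      orth <- orthologsOf(e)
      if (length(orth) == 0L) return(NULL)
      return(gprNode("or", as.list(orth)))
    }
    kids <- lapply(e$args, rewrite)
    lost <- vapply(kids, is.null, logical(1L))
    if (e$op == "and" && any(lost)) return(NULL)  # incomplete complex
    kids <- kids[!lost]
    if (length(kids) == 0L) return(NULL)
    gprNode(e$op, kids)
  }
  rewrite(expr)
}

#' Extract a draft model from a template via an ortholog map
#'
#' The homology-transfer step of draft reconstruction: a template reaction
#' is carried into the draft if at least one gene of its original GPR has a
#' mapped target ortholog (the inclusion test uses the \emph{original}
#' template rule, so complexes with partially mapped subunits are kept).
#' Kept reactions have their GPR rewritten by [rewriteGpr()]; stoichiometry,
#' bounds and subsystem labels are copied verbatim; metabolites and
#' compartments are restricted to those the kept reactions use; the draft
#' gene set is exactly the target genes appearing in a rewritten rule.
#'
#' Reactions with no gene association at all (spontaneous, transport,
#' exchange) are excluded by default -- homology provides no evidence for
#' them; gap curation ([applyCuration()]) is the sanctioned route to re-add
#' them.
#'
#' @param template A [GEModel-class] template.
#' @param map An [OrthologMap-class] whose template ids are drawn from the
#'   template's gene set (unknown ids produce a warning and are ignored).
#' @param gprMode Passed to [rewriteGpr()].
#' @param includeNonGeneReactions If \code{TRUE}, template reactions with an
#'   empty GPR are also carried over (with an empty GPR).
#' @return A list with elements \code{model} (the draft [GEModel-class])
#'   and \code{report} (the mapped-gene report: a \code{data.frame} with
#'   one row per contributing template gene -- columns
#'   \code{template_gene}, \code{orthologs} (comma-separated),
#'   \code{n_orthologs}, \code{n_reactions} carried).
#' @export
extractDraft <- function(template, map,
                         gprMode = c("or_of_orthologs", "preserve_logic"),
                         includeNonGeneReactions = FALSE) {
  stopifnot(is(template, "GEModel"))
  gprMode <- match.arg(gprMode)
  pairs <- if (is(map, "OrthologMap")) map@pairs else map

  unknown <- setdiff(pairs$template, template@genes$id)
  if (length(unknown)) {
    warning("ignoring ", length(unknown), " mapped template gene(s) absent ",
            "from the template model: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
    pairs <- pairs[!pairs$template %in% unknown, , drop = FALSE]
  }
  mappedTemplates <- unique(pairs$template)

  rxn <- template@reactions
  gprSets <- lapply(rxn$gpr, function(g) gprGenes(parseGpr(g)))
  hasGpr <- lengths(gprSets) > 0L
  if (nrow(rxn) && !any(hasGpr) && !includeNonGeneReactions)
    stop("template has no gene associations at all; set ",
         "includeNonGeneReactions = TRUE to transfer it wholesale")
  keep <- vapply(gprSets, function(g) any(g %in% mappedTemplates), logical(1L))
  if (includeNonGeneReactions) keep <- keep | !hasGpr

  draftRxn <- rxn[keep, , drop = FALSE]
  newGpr <- vapply(draftRxn$gpr, function(g)
    serializeGpr(rewriteGpr(parseGpr(g), pairs, gprMode)),
    character(1L), USE.NAMES = FALSE)
  draftRxn$gpr <- newGpr
  rownames(draftRxn) <- NULL

  stoich <- template@stoichiometry[draftRxn$id]
  usedMets <- unique(unlist(lapply(stoich, names)))
  mets <- template@metabolites[template@metabolites$id %in% usedMets, ,
                               drop = FALSE]
  cmps <- template@compartments[
    template@compartments$id %in% unique(mets$compartment), , drop = FALSE]
  draftGenes <- sort(unique(unlist(lapply(newGpr, function(g)
    gprGenes(parseGpr(g))))))

  model <- GEModel(
    id = paste0(template@id, "_draft"),
    compartments = cmps,
    genes = data.frame(id = draftGenes %||% character(0L),
                       stringsAsFactors = FALSE),
    metabolites = mets,
    reactions = draftRxn,
    stoichiometry = stoich,
    provenance = list(template = template@id, gpr_mode = gprMode,
                      include_non_gene_reactions = includeNonGeneReactions,
                      n_ortholog_pairs = nrow(pairs)))

  contrib <- intersect(mappedTemplates, unique(unlist(gprSets[keep])))
  report <- do.call(rbind, lapply(sort(contrib), function(g) {
    orth <- sort(pairs$target[pairs$template == g])
    data.frame(template_gene = g,
               orthologs = paste(orth, collapse = ","),
               n_orthologs = length(orth),
               n_reactions = sum(vapply(gprSets[keep], function(s) g %in% s,
                                        logical(1L))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(report))
    report <- emptyFrame(template_gene = "character", orthologs = "character",
                         n_orthologs = "integer", n_reactions = "integer")
  list(model = model, report = report)
}

#' Venn partition of mapped template genes across drafts
#'
#' Given the mapped-gene reports of drafts built from several genome
#' annotations, computes the exact sizes of all \eqn{2^k - 1} Venn regions
#' over the mapped template-gene sets -- the standard way to compare what
#' each annotation contributes.
#'
#' @param drafts Named list (length >= 2) of mapped-gene reports (as
#'   returned by [extractDraft()]) or plain character vectors of template
#'   gene ids.
#' @return Named integer vector; names are region labels such as
#'   \code{"A"}, \code{"A&B"} built from the draft names, values the number
#'   of template genes exclusive to that region.  Regions are disjoint and
#'   sum to the size of the union.
#' @examples
#' genePartition(list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2"))
#' @export
genePartition <- function(drafts) {
  if (length(drafts) < 2L)
    stop("need at least two drafts to compare")
  if (is.null(names(drafts)) || any(!nzchar(names(drafts))))
    stop("drafts must be a named list")
  sets <- lapply(drafts, function(d)
    unique(if (is.data.frame(d)) d$template_gene else as.character(d)))
  all <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all %in% s, logical(length(all)))
  if (length(all) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  labels <- apply(member, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  k <- length(sets)
  regionNames <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(regionNames)), regionNames)
  tab <- table(labels)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Merge draft models built from complementary annotations
#'
#' Combines drafts of the same template-reaction namespace: the baseline
#' (typically the draft from the most complete annotation) is kept in full,
#' then each complement, in the given order, contributes the reactions whose
#' ids are not yet present.  When a reaction id occurs on both sides its GPR
#' rules are unioned (OR of both, normalized); the stoichiometries must
#' agree, since template-derived drafts cannot disagree about a template
#' reaction.  Metabolites, compartments and genes are added as needed; every
#' entity carries a source tag.
#'
#' @param baseline A [GEModel-class].
#' @param complements Named list of [GEModel-class] complements; order
#'   matters and is recorded in the provenance.
#' @return A list with elements \code{model} (merged [GEModel-class]) and
#'   \code{sources} (a \code{data.frame} with columns \code{entity},
#'   \code{id}, \code{source}; source is \code{"baseline"} or a complement
#'   name).
#' @export
mergeDrafts <- function(baseline, complements) {
  stopifnot(is(baseline, "GEModel"))
  if (is(complements, "GEModel")) complements <- list(complement = complements)
  if (is.null(names(complements)) || any(!nzchar(names(complements))))
    names(complements) <- paste0("complement", seq_along(complements))

  rxn <- baseline@reactions
  stoich <- baseline@stoichiometry
  mets <- baseline@metabolites
  cmps <- baseline@compartments
  gens <- baseline@genes
  sources <- data.frame(entity = "reaction", id = rxn$id,
                        source = "baseline", stringsAsFactors = FALSE)

  for (nm in names(complements)) {
    comp <- complements[[nm]]
    stopifnot(is(comp, "GEModel"))
    for (i in seq_len(nrow(comp@reactions))) {
      r <- comp@reactions[i, ]
      s <- comp@stoichiometry[[r$id]]
      if (r$id %in% rxn$id) {
        have <- stoich[[r$id]]
        if (!isTRUE(all.equal(have[sort(names(have))],
                              s[sort(names(s))], tolerance = 1e-9)))
          stop("conflicting stoichiometry for reaction ", r$id,
               " between baseline and complement '", nm, "'")
        j <- match(r$id, rxn$id)
        rxn$gpr[j] <- serializeGpr(
          gprOr(parseGpr(rxn$gpr[j]), parseGpr(r$gpr)))
      } else {
        rxn <- rbind(rxn, r)
        stoich[[r$id]] <- s
        sources <- rbind(sources, data.frame(
          entity = "reaction", id = r$id, source = nm,
          stringsAsFactors = FALSE))
      }
    }
    newMet <- setdiff(comp@metabolites$id, mets$id)
    mets <- rbind(mets, comp@metabolites[comp@metabolites$id %in% newMet, ,
                                         drop = FALSE])
    newCmp <- setdiff(comp@compartments$id, cmps$id)
    cmps <- rbind(cmps, comp@compartments[comp@compartments$id %in% newCmp, ,
                                          drop = FALSE])
    if (length(newMet))
      sources <- rbind(sources, data.frame(entity = "metabolite", id = newMet,
                                           source = nm, stringsAsFactors = FALSE))
    newGen <- setdiff(comp@genes$id, gens$id)
    gens <- rbind(gens, comp@genes[comp@genes$id %in% newGen, , drop = FALSE])
    if (length(newGen))
      sources <- rbind(sources, data.frame(entity = "gene", id = newGen,
                                           source = nm, stringsAsFactors = FALSE))
  }

  model <- GEModel(
    id = paste0(baseline@id, "_merged"),
    compartments = cmps, genes = gens, metabolites = mets,
    reactions = rxn, stoichiometry = stoich[rxn$id],
    provenance = list(baseline = baseline@id,
                      complements = names(complements)))
  list(model = model, sources = sources)
}
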