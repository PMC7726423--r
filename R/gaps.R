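#' Per-subsystem gap analysis of a draft against its template
#'
#' Classifies every template reaction of one subsystem as \code{auto}
#' (present in the draft) or \code{missing} (a gap).  The result is the
#' starting point for rule-driven curation with [applyCuration()].
#'
#' @param template A [GEModel-class] template.
#' @param draft A [GEModel-class] draft derived from it.
#' @param subsystem Subsystem label; must exist in the template (the error
#'   for an unknown label lists the available ones).
#' @return A [GapReport-class].
#' @export
subsystemDiff <- function(template, draft, subsystem) {
  stopifnot(is(template, "GEModel"), is(draft, "GEModel"))
  labels <- unique(template@reactions$subsystem)
  labels <- labels[nzchar(labels)]
  if (!subsystem %in% labels)
    stop("subsystem '", subsystem, "' not in template; available: ",
         paste(sort(labels), collapse = ", "))
  ids <- template@reactions$id[template@reactions$subsystem == subsystem]
  GapReport(subsystem, data.frame(
    reaction_id = ids,
    status = ifelse(ids %in% draft@reactions$id, "auto", "missing"),
    stringsAsFactors = FALSE))
}

#' Curation rules for gap filling
#'
#' Gap filling is driven by declarative rules rather than ad hoc edits, so
#' that manual curation stays reproducible and diffable.  Two rule types
#' are supported: \code{spontaneous} -- the reaction proceeds without
#' enzymatic catalysis and is included with an empty GPR; \code{family} --
#' the reaction chemistry clearly implicates an enzyme family (for example
#' the cytochrome P450 monooxygenases) although no specific gene homolog
#' was mapped, so it is included with a family-level placeholder gene.  The
#' two sets must be disjoint on reaction ids.
#'
#' \code{readCurationRules} reads a 3-column tab-separated file
#' (\code{reaction_id}, \code{rule_type}, \code{placeholder_gene}, with
#' \code{-} for no placeholder); \code{curationRules} builds the same
#' structure in code.
#'
#' @param spontaneous Character vector of template reaction ids to include
#'   as enzyme-free.
#' @param familyAssignments Named character vector: template reaction id ->
#'   placeholder gene id.
#' @param path Path to a rules file.
#' @return A \code{list} with elements \code{spontaneous} and
#'   \code{family_assignments}, of class \code{"CurationRules"}.
#' @export
curationRules <- function(spontaneous = character(0L),
                          familyAssignments = stats::setNames(character(0L), character(0L))) {
  spontaneous <- as.character(spontaneous)
  if (length(familyAssignments) && is.null(names(familyAssignments)))
    stop("familyAssignments must be named by reaction id")
  overlap <- intersect(spontaneous, names(familyAssignments))
  if (length(overlap))
    stop("reaction(s) under both rule types: ",
         paste(overlap, collapse = ", "))
  if (length(familyAssignments) && any(!nzchar(familyAssignments)))
    stop("family rule without a placeholder gene id")
  structure(list(spontaneous = spontaneous,
                 family_assignments = familyAssignments),
            class = "CurationRules")
}

#' @rdname curationRules
#' @export
readCurationRules <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("reaction_id", "rule_type",
                                        "placeholder_gene"))
  bad <- setdiff(df$rule_type, c("spontaneous", "family"))
  if (length(bad))
    stop("unknown rule type(s) in ", path, ": ", paste(bad, collapse = ", "))
  fam <- df[df$rule_type == "family", , drop = FALSE]
  curationRules(
    spontaneous = df$reaction_id[df$rule_type == "spontaneous"],
    familyAssignments = stats::setNames(fam$placeholder_gene,
                                        fam$reaction_id))
}

#' Apply curation rules to a gap report
#'
#' Fills gaps of a [GapReport-class] according to [curationRules()]:
#' missing reactions named spontaneous are copied from the template into
#' the draft with an empty GPR and become \code{filled_spontaneous};
#' missing reactions with a family assignment are copied with the
#' placeholder gene as their GPR (the placeholder is added to the draft
#' gene set with the \code{putative} flag) and become \code{filled_family}.
#' Reactions already in the draft (\code{auto}) are never touched: a rule
#' citing one produces a warning and is ignored; a rule citing a reaction
#' absent from the template is an error.  Applying the same rules twice is
#' a no-op the second time.
#'
#' @param report A [GapReport-class] from [subsystemDiff()].
#' @param rules A \code{CurationRules} object.
#' @param template,draft The models the report was computed from.
#' @return A list with elements \code{report} (updated [GapReport-class])
#'   and \code{model} (the draft with the filled reactions added).
#' @export
applyCuration <- function(report, rules, template, draft) {
  stopifnot(is(report, "GapReport"), inherits(rules, "CurationRules"),
            is(template, "GEModel"), is(draft, "GEModel"))
  ruleIds <- c(rules$spontaneous, names(rules$family_assignments))
  absent <- setdiff(ruleIds, template@reactions$id)
  if (length(absent))
    stop("curation rule(s) cite reaction(s) absent from the template: ",
         paste(absent, collapse = ", "))

  states <- report@states
  onAuto <- intersect(ruleIds, states$reaction_id[states$status == "auto"])
  if (length(onAuto))
    warning("rule(s) for reaction(s) already in the draft, ignored: ",
            paste(onAuto, collapse = ", "))

  missingIds <- states$reaction_id[states$status == "missing"]
  fillSpont <- intersect(rules$spontaneous, missingIds)
  fillFam <- intersect(names(rules$family_assignments), missingIds)

  rxn <- draft@reactions
  stoich <- draft@stoichiometry
  mets <- draft@metabolites
  cmps <- draft@compartments
  gens <- draft@genes

  addReaction <- function(rid, gpr) {
    r <- template@reactions[template@reactions$id == rid, , drop = FALSE]
    r$gpr <- gpr
    rxn <<- rbind(rxn, r)
    stoich[[rid]] <<- template@stoichiometry[[rid]]
    need <- setdiff(names(template@stoichiometry[[rid]]), mets$id)
    mets <<- rbind(mets, template@metabolites[
      template@metabolites$id %in% need, , drop = FALSE])
    needCmp <- setdiff(mets$compartment, cmps$id)
    cmps <<- rbind(cmps, template@compartments[
      template@compartments$id %in% needCmp, , drop = FALSE])
  }

  for (rid in fillSpont) {
    addReaction(rid, "")
    states$status[states$reaction_id == rid] <- "filled_spontaneous"
  }
  for (rid in fillFam) {
    placeholder <- rules$family_assignments[[rid]]
    if (!placeholder %in% gens$id)
      gens <- rbind(gens, data.frame(id = placeholder, name = placeholder,
                                     putative = TRUE,
                                     stringsAsFactors = FALSE))
    addReaction(rid, placeholder)
    states$status[states$reaction_id == rid] <- "filled_family"
    states$placeholder_gene[states$reaction_id == rid] <- placeholder
  }

  model <- GEModel(id = draft@id, compartments = cmps, genes = gens,
                   metabolites = mets, reactions = rxn,
                   stoichiometry = stoich[rxn$id],
                   provenance = c(draft@provenance,
                                  list(curated_subsystem = report@subsystem)))
  list(report = GapReport(report@subsystem, states), model = model)
}

#' Export reaction gap states for map visualization
#'
#' Writes the status partition of a [GapReport-class] in two forms:
#' a CSV of \code{reaction_id,status} rows, and a JSON object mapping
#' reaction id to a numeric state code (\code{auto} = 1,
#' \code{filled_spontaneous} = 2, \code{filled_family} = 3,
#' \code{missing} = 0) loadable as "reaction data" by the Escher pathway
#' viewer to color a subsystem map.
#'
#' @param report A [GapReport-class].
#' @param path Output path prefix: \code{<path>.csv} and \code{<path>.json}
#'   are written.
#' @return Character vector of the two file paths, invisibly.
#' @export
exportReactionStates <- function(report, path) {
  stopifnot(is(report, "GapReport"))
  st <- report@states
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(st[, c("reaction_id", "status")], csv, row.names = FALSE,
                   quote = FALSE)
  codes <- c(auto = 1L, filled_spontaneous = 2L, filled_family = 3L,
             missing = 0L)
  obj <- stats::setNames(as.list(codes[st$status]), st$reaction_id)
  jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
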