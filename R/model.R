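#' Model accessors
#'
#' Accessor functions for [GEModel-class] slots.  Use these instead of
#' \code{@} access; the internal layout is not part of the API.
#'
#' @param model A [GEModel-class].
#' @return \code{modelId}: character scalar.  \code{modelCompartments},
#'   \code{modelGenes}, \code{modelMetabolites}, \code{modelReactions}:
#'   the corresponding \code{data.frame}.  \code{modelStoichiometry}: named
#'   list of named numeric vectors.  \code{modelProvenance}: list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
modelId <- function(model) model@id

#' @rdname accessors
#' @export
modelCompartments <- function(model) model@compartments

#' @rdname accessors
#' @export
modelGenes <- function(model) model@genes

#' @rdname accessors
#' @export
modelMetabolites <- function(model) model@metabolites

#' @rdname accessors
#' @export
modelReactions <- function(model) model@reactions

#' @rdname accessors
#' @export
modelStoichiometry <- function(model) model@stoichiometry

#' @rdname accessors
#' @export
modelProvenance <- function(model) model@provenance

#' Summary statistics of a model
#'
#' Counts of genes, reactions, metabolites, compartments and distinct
#' non-empty subsystem labels.  Each count equals the cardinality of the
#' corresponding entity set and is invariant under reordering of the entity
#' tables.
#'
#' @param model A [GEModel-class].
#' @return An object of class \code{ModelStats}: a list with elements
#'   \code{n_genes}, \code{n_reactions}, \code{n_metabolites},
#'   \code{n_compartments}, \code{n_subsystems}.
#' @examples
#' modelStats(GEModel("empty"))
#' @export
modelStats <- function(model) {
  stopifnot(is(model, "GEModel"))
  subs <- model@reactions$subsystem
  structure(list(
    n_genes        = nrow(model@genes),
    n_reactions    = nrow(model@reactions),
    n_metabolites  = nrow(model@metabolites),
    n_compartments = nrow(model@compartments),
    n_subsystems   = length(unique(subs[nzchar(subs)]))
  ), class = "ModelStats")
}

#' @export
print.ModelStats <- function(x, ...) {
  labels <- c(n_genes = "Genes", n_reactions = "Reactions",
              n_metabolites = "Metabolites", n_compartments = "Compartments",
              n_subsystems = "Subsystems")
  for (nm in names(labels))
    cat(formatC(labels[[nm]], width = -13), x[[nm]], "\n")
  invisible(x)
}

#' @export
format.ModelStats <- function(x, ...) {
  paste0(names(unlist(x)), "=", unlist(x), collapse = ", ")
}
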