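#' Overlay differential gene expression on model reactions
#'
#' Projects gene-level differential-expression results onto the reactions
#' of a reconstructed model through the GPR rules, classifying each
#' reaction's regulation.  For a reaction, the \emph{contributing} records
#' are the significant measurements of genes appearing in its GPR; the
#' state is \code{up} when all contributing log2 fold changes are positive,
#' \code{down} when all are negative, \code{mixed} otherwise, and
#' \code{none} when no significant measured gene is in the rule (in
#' particular for GPR-less reactions).  The score is a signed aggregate of
#' the contributing fold changes: \code{"max_abs"} keeps the value of
#' largest magnitude with its sign (reasoning from the strongest
#' responder), \code{"mean"} averages them.
#'
#' Unmeasured genes are silently excluded from each reaction's evidence and
#' counted once in the \code{unmeasured_genes} attribute of the result.
#' Significance is a caller-provided flag; differential-expression testing
#' is upstream of this tool.
#'
#' @param model A [GEModel-class].
#' @param table \code{data.frame} with columns \code{gene_id},
#'   \code{log2fc}, \code{significant} (logical); gene ids must be unique.
#' @param aggregation \code{"max_abs"} (default) or \code{"mean"}.
#' @return \code{data.frame} with one row per model reaction, in model
#'   order: \code{reaction_id}, \code{state}, \code{score},
#'   \code{n_contributing}, \code{genes} (comma-separated
#'   \code{gene:log2fc} entries of the contributing genes).  Attribute
#'   \code{unmeasured_genes}: number of distinct GPR genes with no row in
#'   \code{table}.
#' @examples
#' m <- GEModel("toy",
#'   compartments = data.frame(id = "c"),
#'   genes = data.frame(id = c("c1", "c2")),
#'   metabolites = data.frame(id = c("A", "B"), compartment = "c"),
#'   reactions = data.frame(id = "R1", gpr = "c1 or c2"),
#'   stoichiometry = list(R1 = c(A = -1, B = 1)))
#' expr <- data.frame(gene_id = c("c1", "c2"), log2fc = c(2, 1),
#'                    significant = TRUE)
#' overlayExpression(m, expr)
#' @export
overlayExpression <- function(model, table,
                              aggregation = c("max_abs", "mean")) {
  stopifnot(is(model, "GEModel"),
            all(c("gene_id", "log2fc", "significant") %in% colnames(table)))
  aggregation <- match.arg(aggregation)
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene_id in expression table: ",
         paste(unique(table$gene_id[duplicated(table$gene_id)]),
               collapse = ", "))
  table$gene_id <- as.character(table$gene_id)
  measured <- table$gene_id

  rxn <- model@reactions
  allGprGenes <- character(0L)
  rows <- lapply(seq_len(nrow(rxn)), function(i) {
    genes <- gprGenes(parseGpr(rxn$gpr[i]))
    allGprGenes <<- c(allGprGenes, genes)
    rec <- table[table$gene_id %in% genes & table$significant, , drop = FALSE]
    rec <- rec[order(-abs(rec$log2fc), rec$gene_id, method = "radix"), ,
               drop = FALSE]
    if (nrow(rec) == 0L) {
      state <- "none"; score <- 0
    } else {
      state <- if (all(rec$log2fc > 0)) "up"
               else if (all(rec$log2fc < 0)) "down"
               else "mixed"
      score <- if (aggregation == "max_abs") rec$log2fc[1L]
               else mean(rec$log2fc)
    }
    data.frame(reaction_id = rxn$id[i], state = state, score = score,
               n_contributing = nrow(rec),
               genes = paste(sprintf("%s:%g", rec$gene_id, rec$log2fc),
                             collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    emptyFrame(reaction_id = "character", state = "character",
               score = "numeric", n_contributing = "integer",
               genes = "character")
  rownames(out) <- NULL
  attr(out, "unmeasured_genes") <-
    length(setdiff(unique(allGprGenes), measured))
  out
}

#' Summarize regulation states along named reaction routes
#'
#' Aggregates the per-reaction states of [overlayExpression()] over named
#' sets of reactions ("routes", e.g. the activation branch versus the
#' conjugation branch of a biotransformation pathway), enabling branch-level
#' contrasts such as an upregulated activation route against a
#' down-regulated clearance route.
#'
#' @param regulations The \code{data.frame} returned by
#'   [overlayExpression()].
#' @param reactionSets Named list of character vectors of reaction ids.
#'   Ids absent from \code{regulations} produce a warning and are skipped.
#' @return \code{data.frame} with columns \code{route}, \code{up},
#'   \code{down}, \code{mixed}, \code{none}.
#' @export
routeSummary <- function(regulations, reactionSets) {
  stopifnot(is.data.frame(regulations), is.list(reactionSets))
  if (is.null(names(reactionSets)) || any(!nzchar(names(reactionSets))))
    stop("reactionSets must be a named list")
  states <- stats::setNames(regulations$state, regulations$reaction_id)
  out <- do.call(rbind, lapply(names(reactionSets), function(nm) {
    ids <- as.character(reactionSets[[nm]])
    unknown <- setdiff(ids, names(states))
    if (length(unknown))
      warning("route '", nm, "': skipping unknown reaction id(s): ",
              paste(unknown, collapse = ", "))
    ids <- setdiff(ids, unknown)
    tab <- table(factor(states[ids], levels = c("up", "down", "mixed", "none")))
    data.frame(route = nm, up = as.integer(tab[["up"]]),
               down = as.integer(tab[["down"]]),
               mixed = as.integer(tab[["mixed"]]),
               none = as.integer(tab[["none"]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
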