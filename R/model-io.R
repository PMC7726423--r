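#' Read and write genome-scale models
#'
#' \code{readGEM} parses a model file into a [GEModel-class];
#' \code{writeGEM} serializes one back out.  Two dialects are supported:
#'
#' \describe{
#'   \item{\code{"sbml"}}{SBML Level 3 Version 1 with the
#'     flux-balance-constraints (fbc) package for gene products and flux
#'     bounds.  On input, models whose gene associations live in reaction
#'     \code{notes} fields (\code{GENE_ASSOCIATION: ...}) instead of fbc
#'     elements are also understood -- HMR-derived templates predate uniform
#'     fbc usage.  Subsystem labels are carried in reaction notes
#'     (\code{SUBSYSTEM: ...}).}
#'   \item{\code{"json"}}{The community COBRA JSON schema: entities keyed by
#'     id, stoichiometry as metabolite-id to coefficient maps.  Convenient
#'     for hand-written fixtures.}
#' }
#'
#' Entity identifiers in SBML are written with the conventional \code{R_},
#' \code{M_}, \code{G_}, \code{C_} prefixes (non-SId characters escaped as
#' \code{__<code>__}); on reading, a prefix is stripped only when every id
#' of that entity class carries it.  A read/write round trip preserves ids,
#' stoichiometry, bounds, subsystem labels and canonical GPR strings.
#' Referential integrity of the parsed model is enforced (dangling
#' references raise an error listing the offenders, they are never
#' repaired).
#'
#' @param path File path.
#' @param format \code{"sbml"} or \code{"json"}; by default inferred from
#'   the file extension (\code{.xml}/\code{.sbml} vs \code{.json}).
#' @param model A [GEModel-class].
#' @return \code{readGEM}: a validated [GEModel-class].  \code{writeGEM}:
#'   \code{path}, invisibly.
#' @examples
#' m <- makeTemplate(fixtureSpec(seed = 1))
#' f <- tempfile(fileext = ".xml")
#' writeGEM(m, f)
#' identical(modelStats(readGEM(f)), modelStats(m))
#' @name model-io
NULL

inferFormat <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("sbml", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "sbml")) "sbml"
  else if (ext == "json") "json"
  else stop("cannot infer model format from extension '.", ext,
            "'; pass format = \"sbml\" or \"json\"")
}

#' @rdname model-io
#' @export
readGEM <- function(path, format = NULL) {
  format <- inferFormat(path, format)
  if (!file.exists(path)) stop("no such file: ", path)
  model <- if (format == "sbml") readSBML(path) else readJSONModel(path)
  model@provenance$source_file <- path
  model@provenance$source_format <- format
  validObject(model)
  model
}

#' @rdname model-io
#' @export
writeGEM <- function(model, path, format = NULL) {
  stopifnot(is(model, "GEModel"))
  validObject(model)
  format <- inferFormat(path, format)
  if (format == "sbml") writeSBML(model, path) else writeJSONModel(model, path)
  invisible(path)
}

## --------------------------------------------------------------------------
## SId escaping (cobrapy-style __<charcode>__ encoding) and class prefixes
## --------------------------------------------------------------------------

toSId <- function(ids, prefix) {
  enc <- vapply(ids, function(id) {
    chars <- strsplit(id, "", fixed = TRUE)[[1L]]
    paste(vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch else sprintf("__%d__", utf8ToInt(ch))
    }, character(1L)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  paste0(prefix, enc)
}

fromSId <- function(sids, prefix) {
  ids <- sids
  if (length(ids) && all(startsWith(ids, prefix)))
    ids <- substring(ids, nchar(prefix) + 1L)
  vapply(ids, function(id) {
    m <- gregexpr("__([0-9]+)__", id)[[1L]]
    if (m[1L] == -1L) return(id)
    codes <- regmatches(id, gregexpr("__([0-9]+)__", id))[[1L]]
    for (code in unique(codes)) {
      ch <- intToUtf8(as.integer(gsub("__", "", code, fixed = TRUE)))
      id <- gsub(code, ch, id, fixed = TRUE)
    }
    id
  }, character(1L), USE.NAMES = FALSE)
}

## --------------------------------------------------------------------------
## SBML
## --------------------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS  <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

writeSBML <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = toSId(model@id, ""), "fbc:strict" = "false")

  if (nrow(model@compartments)) {
    lst <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (i in seq_len(nrow(model@compartments)))
      xml2::xml_add_child(lst, "compartment",
                          id = toSId(model@compartments$id[i], "C_"),
                          name = model@compartments$name[i],
                          constant = "true")
  }

  if (nrow(model@metabolites)) {
    lst <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model@metabolites))) {
      sp <- xml2::xml_add_child(lst, "species",
        id = toSId(model@metabolites$id[i], "M_"),
        name = model@metabolites$name[i],
        compartment = toSId(model@metabolites$compartment[i], "C_"),
        hasOnlySubstanceUnits = "false",
        boundaryCondition = "false", constant = "false")
      if (nzchar(model@metabolites$formula[i]))
        xml2::xml_set_attr(sp, "fbc:chemicalFormula",
                           model@metabolites$formula[i])
    }
  }

  bounds <- sort(unique(c(model@reactions$lower, model@reactions$upper)))
  if (length(bounds)) {
    lst <- xml2::xml_add_child(mdl, "listOfParameters")
    for (i in seq_along(bounds))
      xml2::xml_add_child(lst, "parameter",
                          id = paste0("bound_", i),
                          value = formatNum(bounds[i]),
                          constant = "true")
  }
  boundId <- function(v) paste0("bound_", match(v, bounds))

  if (nrow(model@genes)) {
    lst <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(model@genes))) {
      gp <- xml2::xml_add_child(lst, "fbc:geneProduct",
        "fbc:id" = toSId(model@genes$id[i], "G_"),
        "fbc:label" = model@genes$id[i],
        "fbc:name" = model@genes$name[i])
      if (isTRUE(model@genes$putative[i]))
        addNotes(gp, "PUTATIVE_FAMILY_ASSIGNMENT: true")
    }
  }

  if (nrow(model@reactions)) {
    lst <- xml2::xml_add_child(mdl, "listOfReactions")
    for (i in seq_len(nrow(model@reactions))) {
      r <- model@reactions[i, ]
      rx <- xml2::xml_add_child(lst, "reaction",
        id = toSId(r$id, "R_"), name = r$name,
        reversible = tolower(as.character(r$lower < 0)),
        fast = "false",
        "fbc:lowerFluxBound" = boundId(r$lower),
        "fbc:upperFluxBound" = boundId(r$upper))
      if (nzchar(r$subsystem))
        addNotes(rx, paste0("SUBSYSTEM: ", r$subsystem))
      s <- model@stoichiometry[[r$id]]
      subs <- s[s < 0]; prods <- s[s > 0]
      if (length(subs)) {
        lr <- xml2::xml_add_child(rx, "listOfReactants")
        for (m in names(subs))
          xml2::xml_add_child(lr, "speciesReference",
                              species = toSId(m, "M_"),
                              stoichiometry = formatNum(abs(subs[[m]])),
                              constant = "true")
      }
      if (length(prods)) {
        lp <- xml2::xml_add_child(rx, "listOfProducts")
        for (m in names(prods))
          xml2::xml_add_child(lp, "speciesReference",
                              species = toSId(m, "M_"),
                              stoichiometry = formatNum(prods[[m]]),
                              constant = "true")
      }
      expr <- parseGpr(r$gpr)
      if (!is.null(expr)) {
        ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
        addGprXml(ga, expr)
      }
    }
  }
  xml2::write_xml(doc, path)
}

formatNum <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         sprintf("%d", as.integer(x)), sprintf("%.12g", x))
}

addNotes <- function(node, text) {
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(notes, "body",
                              xmlns = "http://www.w3.org/1999/xhtml")
  xml2::xml_add_child(body, "p", text)
}

addGprXml <- function(parent, expr) {
  if (isGprLeaf(expr)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = toSId(expr, "G_"))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", expr$op))
    for (a in expr$args) addGprXml(node, a)
  }
}

readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("invalid SBML XML in ", path, ": ",
                                           conditionMessage(e)))
  mdl <- xml1(doc, "model")
  if (is.na(mdl)) stop("no <model> element in ", path)

  attrOf <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }

  cmpNodes <- xmlAll(mdl, "compartment")
  cmpIds <- vapply(cmpNodes, xml2::xml_attr, character(1L), attr = "id")
  compartments <- data.frame(
    id = fromSId(cmpIds, "C_"),
    name = orDefault(vapply(cmpNodes, xml2::xml_attr, character(1L),
                            attr = "name"), fromSId(cmpIds, "C_")),
    stringsAsFactors = FALSE)

  spNodes <- xmlAll(mdl, "species")
  spIds <- vapply(spNodes, xml2::xml_attr, character(1L), attr = "id")
  metabolites <- data.frame(
    id = fromSId(spIds, "M_"),
    name = orDefault(vapply(spNodes, xml2::xml_attr, character(1L),
                            attr = "name"), fromSId(spIds, "M_")),
    compartment = fromSId(vapply(spNodes, xml2::xml_attr, character(1L),
                                 attr = "compartment"), "C_"),
    formula = orDefault(vapply(spNodes, attrOf, character(1L),
                               name = "chemicalFormula"), ""),
    stringsAsFactors = FALSE)
  spLookup <- stats::setNames(metabolites$id, spIds)

  parNodes <- xmlAll(mdl, "parameter")
  parVals <- stats::setNames(
    as.numeric(vapply(parNodes, xml2::xml_attr, character(1L), attr = "value")),
    vapply(parNodes, xml2::xml_attr, character(1L), attr = "id"))

  gpNodes <- xmlAll(mdl, "geneProduct")
  gpIds <- vapply(gpNodes, attrOf, character(1L), name = "id")
  geneIds <- fromSId(gpIds, "G_")
  genes <- data.frame(
    id = geneIds,
    name = orDefault(vapply(gpNodes, attrOf, character(1L), name = "name"),
                     geneIds),
    putative = vapply(gpNodes, function(n)
      grepl("PUTATIVE_FAMILY_ASSIGNMENT", notesText(n)), logical(1L)),
    stringsAsFactors = FALSE)
  gpLookup <- stats::setNames(geneIds, gpIds)

  rxNodes <- xmlAll(mdl, "reaction")
  rxn <- emptyFrame(id = "character", name = "character", lower = "numeric",
                    upper = "numeric", subsystem = "character",
                    gpr = "character")
  stoich <- list()
  for (node in rxNodes) {
    sid <- xml2::xml_attr(node, "id")
    lbRef <- attrOf(node, "lowerFluxBound")
    ubRef <- attrOf(node, "upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(parVals)) {
      lower <- parVals[[lbRef]]; upper <- parVals[[ubRef]]
    } else {
      rev <- identical(xml2::xml_attr(node, "reversible"), "true")
      lower <- if (rev) -1000 else 0; upper <- 1000
    }
    notes <- notesText(node)
    sub <- regmatches(notes, regexpr("SUBSYSTEM:[^\n]*", notes))
    sub <- if (length(sub)) trimws(sub("SUBSYSTEM:", "", sub)) else ""
    gpr <- readGprXml(node, gpLookup)
    if (is.null(gpr)) {
      ga <- regmatches(notes, regexpr("GENE[ _]ASSOCIATION:[^\n]*", notes))
      if (length(ga))
        gpr <- parseGpr(trimws(sub("GENE[ _]ASSOCIATION:", "", ga)))
    }
    s <- numeric(0L)
    for (sr in xmlAll(node, "speciesReference")) {
      mid <- spLookup[[xml2::xml_attr(sr, "species")]]
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      isProduct <- identical(xml2::xml_name(xml2::xml_parent(sr)),
                             "listOfProducts")
      s[mid] <- (if (isProduct) 1 else -1) * coef + (s[mid] %||% 0)
    }
    rxn <- rbind(rxn, data.frame(
      id = sid, name = xml2::xml_attr(node, "name"),
      lower = lower, upper = upper, subsystem = sub,
      gpr = serializeGpr(gpr), stringsAsFactors = FALSE))
    stoich[[sid]] <- s
  }
  rxn$id <- fromSId(rxn$id, "R_")
  names(stoich) <- rxn$id
  if (nrow(rxn)) rxn$name <- orDefault(rxn$name, rxn$id)

  ## models that carry GPRs only in notes declare no gene products
  undeclared <- setdiff(unique(unlist(lapply(rxn$gpr, function(g)
    gprGenes(parseGpr(g))))), genes$id)
  if (length(undeclared))
    genes <- rbind(genes, data.frame(id = undeclared, name = undeclared,
                                     putative = FALSE,
                                     stringsAsFactors = FALSE))

  id <- xml2::xml_attr(mdl, "id")
  GEModel(id = if (is.na(id)) "model" else fromSId(id, ""),
          compartments = compartments, genes = genes,
          metabolites = metabolites, reactions = rxn,
          stoichiometry = stoich)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

orDefault <- function(x, default) ifelse(is.na(x), default, x)

## namespace-prefix-agnostic lookup: match on local element name
xmlAll <- function(node, localName) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", localName, "']"))
}

xml1 <- function(node, localName) {
  xml2::xml_find_first(node, paste0(".//*[local-name()='", localName, "']"))
}

notesText <- function(node) {
  n <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (is.na(n)) "" else paste(xml2::xml_text(
    xml2::xml_find_all(n, ".//*[local-name()='p']")), collapse = "\n")
}

readGprXml <- function(rxNode, gpLookup) {
  ga <- xml2::xml_find_first(
    rxNode, "./*[local-name()='geneProductAssociation']")
  if (is.na(ga)) return(NULL)
  kids <- xml2::xml_children(ga)
  if (length(kids) == 0L) return(NULL)
  normalizeGpr(gprFromXml(kids[[1L]], gpLookup))
}

gprFromXml <- function(node, gpLookup) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    if (is.na(ref)) ref <- xml2::xml_attr(node, "fbc:geneProduct")
    return(gpLookup[[ref]] %||% fromSId(ref, "G_"))
  }
  if (!nm %in% c("and", "or"))
    stop("unsupported element in gene association: ", nm)
  structure(list(op = nm,
                 args = lapply(xml2::xml_children(node), gprFromXml,
                               gpLookup = gpLookup)),
            class = "gpr_node")
}

## --------------------------------------------------------------------------
## COBRA-style JSON
## --------------------------------------------------------------------------

writeJSONModel <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model@reactions)), function(i) {
    r <- model@reactions[i, ]
    list(id = r$id, name = r$name,
         metabolites = as.list(model@stoichiometry[[r$id]]),
         lower_bound = r$lower, upper_bound = r$upper,
         subsystem = r$subsystem, gene_reaction_rule = r$gpr)
  })
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         formula = m$formula)
  })
  gens <- lapply(seq_len(nrow(model@genes)), function(i) {
    g <- model@genes[i, ]
    out <- list(id = g$id, name = g$name)
    if (isTRUE(g$putative))
      out$notes <- list(putative_family_assignment = TRUE)
    out
  })
  obj <- list(
    id = model@id,
    compartments = stats::setNames(as.list(model@compartments$name),
                                   model@compartments$id),
    genes = gens, metabolites = mets, reactions = rxns, version = "1")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}

readJSONModel <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("invalid JSON in ", path, ": ",
                                           conditionMessage(e)))
  getf <- function(x, nm, default = "") x[[nm]] %||% default
  compartments <- data.frame(
    id = names(obj$compartments %||% list()),
    name = unlist(obj$compartments %||% list(), use.names = FALSE) %||% character(0L),
    stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(obj$genes %||% list(), function(g)
    data.frame(id = g$id, name = getf(g, "name", g$id),
               putative = isTRUE(g$notes$putative_family_assignment),
               stringsAsFactors = FALSE)))
  metabolites <- do.call(rbind, lapply(obj$metabolites %||% list(), function(m)
    data.frame(id = m$id, name = getf(m, "name", m$id),
               compartment = getf(m, "compartment"),
               formula = getf(m, "formula"), stringsAsFactors = FALSE)))
  rxn <- do.call(rbind, lapply(obj$reactions %||% list(), function(r)
    data.frame(id = r$id, name = getf(r, "name", r$id),
               lower = as.numeric(getf(r, "lower_bound", -1000)),
               upper = as.numeric(getf(r, "upper_bound", 1000)),
               subsystem = getf(r, "subsystem"),
               gpr = serializeGpr(parseGpr(getf(r, "gene_reaction_rule"))),
               stringsAsFactors = FALSE)))
  stoich <- lapply(obj$reactions %||% list(), function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) s <- numeric(0L)
    s
  })
  names(stoich) <- if (length(stoich))
    vapply(obj$reactions, function(r) r$id, character(1L)) else character(0L)
  GEModel(id = getf(obj, "id", "model"),
          compartments = compartments %||% NULL,
          genes = genes %||% emptyFrame(id = "character"),
          metabolites = metabolites %||%
            emptyFrame(id = "character", compartment = "character"),
          reactions = rxn %||% emptyFrame(id = "character"),
          stoichiometry = stoich)
}
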