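#' Gene-protein-reaction (GPR) Boolean rules
#'
#' A GPR rule states which gene products enable a reaction as a Boolean
#' expression over gene identifiers: \code{and} joins subunits of a complex,
#' \code{or} joins isoenzymes.  Within this package a rule is represented as
#' a rooted tree: a leaf is a gene id (a length-one character vector), an
#' internal node is a list with elements \code{op} (\code{"and"} or
#' \code{"or"}) and \code{args} (two or more children), and the empty rule --
#' no gene association at all -- is \code{NULL}.
#'
#' Trees handled by the package are always in normal form: nested nodes of
#' the same operator are flattened, duplicate children are removed,
#' single-child nodes are collapsed to their child, and children are ordered
#' lexicographically by their serialized text.  \code{parseGpr} and the
#' constructors \code{gprAnd}/\code{gprOr} normalize on the way in, so two
#' logically re-associated rules compare \code{identical()}.
#'
#' @param text A GPR rule string, e.g. \code{"g1 and (g2 or g3)"}.  Operator
#'   tokens are case-insensitive; gene ids are maximal runs of
#'   non-whitespace, non-parenthesis characters.  Empty or all-whitespace
#'   input yields the empty rule.
#' @param expr A GPR expression tree as described above.
#' @param ... Children of the node: gene id strings or sub-expressions.
#' @return \code{parseGpr}: a normalized expression tree (or \code{NULL}).
#'   \code{serializeGpr}: the canonical rule string (\code{""} for the empty
#'   rule).  \code{gprGenes}: a sorted character vector of the distinct leaf
#'   gene ids.  \code{gprAnd}/\code{gprOr}: a normalized expression tree.
#' @examples
#' parseGpr("g1 and (g2 or g3)")
#' serializeGpr(gprOr("g3", "g1"))      # "g1 or g3"
#' gprGenes(parseGpr("(a and b) or a"))
#' @name gpr
NULL

gprNode <- function(op, args) {
  stopifnot(op %in% c("and", "or"))
  normalizeGpr(structure(list(op = op, args = args), class = "gpr_node"))
}

isGprNode <- function(x) inherits(x, "gpr_node")

isGprLeaf <- function(x) is.character(x) && length(x) == 1L

#' @rdname gpr
#' @export
gprAnd <- function(...) gprNode("and", list(...))

#' @rdname gpr
#' @export
gprOr <- function(...) gprNode("or", list(...))

## Normal form: flatten same-op nesting, drop duplicates, sort children by
## serialized text, collapse single-child nodes.  NULL children are dropped
## (callers that need strict AND semantics handle emptiness before this).
normalizeGpr <- function(x) {
  if (is.null(x)) return(NULL)
  if (isGprLeaf(x)) {
    if (!nzchar(x)) stop("GPR leaf gene id must be non-empty")
    return(x)
  }
  if (!isGprNode(x)) stop("not a GPR expression: ", class(x)[1L])
  kids <- list()
  for (child in x$args) {
    child <- normalizeGpr(child)
    if (is.null(child)) next
    if (isGprNode(child) && child$op == x$op) {
      kids <- c(kids, child$args)       # flatten same-operator nesting
    } else {
      kids <- c(kids, list(child))
    }
  }
  if (length(kids) == 0L) return(NULL)
  keys <- vapply(kids, serializeGpr, character(1L))
  kids <- kids[!duplicated(keys)]
  kids <- kids[order(keys[!duplicated(keys)], method = "radix")]
  if (length(kids) == 1L) return(kids[[1L]])
  structure(list(op = x$op, args = kids), class = "gpr_node")
}

#' @rdname gpr
#' @export
parseGpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- tokenizeGpr(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- parseOrExpr(st, text)
  if (st$pos <= nrow(st$toks)) {
    tok <- st$toks$tok[st$pos]
    stop("GPR parse error at position ", st$toks$at[st$pos],
         if (tok == ")") ": unbalanced ')'" else
           paste0(": unexpected '", tok, "'"),
         " in \"", text, "\"")
  }
  normalizeGpr(expr)
}

tokenizeGpr <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  tok <- character(0L); at <- integer(0L)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tok <- c(tok, ch); at <- c(at, i); i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^\\s$", chars[j]) && !chars[j] %in% c("(", ")"))
      j <- j + 1L
    tok <- c(tok, paste0(chars[i:(j - 1L)], collapse = ""))
    at <- c(at, i)
    i <- j
  }
  data.frame(tok = tok, at = at, stringsAsFactors = FALSE)
}

peekTok <- function(st) if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA_character_

takeTok <- function(st) {
  t <- peekTok(st)
  st$pos <- st$pos + 1L
  t
}

parseOrExpr <- function(st, text) {
  args <- list(parseAndExpr(st, text))
  while (!is.na(peekTok(st)) && tolower(peekTok(st)) == "or") {
    at <- st$toks$at[st$pos]
    takeTok(st)
    if (is.na(peekTok(st)))
      stop("GPR parse error at position ", at,
           ": dangling 'or' in \"", text, "\"")
    args <- c(args, list(parseAndExpr(st, text)))
  }
  if (length(args) == 1L) args[[1L]] else
    structure(list(op = "or", args = args), class = "gpr_node")
}

parseAndExpr <- function(st, text) {
  args <- list(parseFactor(st, text))
  while (!is.na(peekTok(st)) && tolower(peekTok(st)) == "and") {
    at <- st$toks$at[st$pos]
    takeTok(st)
    if (is.na(peekTok(st)))
      stop("GPR parse error at position ", at,
           ": dangling 'and' in \"", text, "\"")
    args <- c(args, list(parseFactor(st, text)))
  }
  if (length(args) == 1L) args[[1L]] else
    structure(list(op = "and", args = args), class = "gpr_node")
}

parseFactor <- function(st, text) {
  t <- peekTok(st)
  if (is.na(t))
    stop("GPR parse error: unexpected end of input in \"", text, "\"")
  at <- st$toks$at[st$pos]
  if (t == "(") {
    takeTok(st)
    inner <- parseOrExpr(st, text)
    if (is.na(peekTok(st)) || peekTok(st) != ")")
      stop("GPR parse error at position ", at,
           ": unbalanced '(' in \"", text, "\"")
    takeTok(st)
    return(inner)
  }
  if (t == ")")
    stop("GPR parse error at position ", at,
         ": unbalanced ')' in \"", text, "\"")
  if (tolower(t) %in% c("and", "or"))
    stop("GPR parse error at position ", at,
         ": dangling '", t, "' in \"", text, "\"")
  takeTok(st)
  t
}

#' @rdname gpr
#' @export
serializeGpr <- function(expr) {
  if (is.null(expr)) return("")
  if (isGprLeaf(expr)) return(expr)
  if (!isGprNode(expr)) stop("not a GPR expression: ", class(expr)[1L])
  parts <- vapply(expr$args, function(a) {
    s <- serializeGpr(a)
    if (isGprNode(a)) paste0("(", s, ")") else s
  }, character(1L))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' @rdname gpr
#' @export
gprGenes <- function(expr) {
  if (is.null(expr)) return(character(0L))
  if (isGprLeaf(expr)) return(expr)
  sort(unique(unlist(lapply(expr$args, gprGenes))))
}

## Evaluate a rule under a gene-presence assignment (character vector of
## present genes).  Empty rule evaluates NA: "no gene association" is not a
## truth value.  Used by tests and the expression overlay.
evalGpr <- function(expr, present) {
  if (is.null(expr)) return(NA)
  if (isGprLeaf(expr)) return(expr %in% present)
  vals <- vapply(expr$args, evalGpr, logical(1L), present = present)
  if (expr$op == "and") all(vals) else any(vals)
}
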