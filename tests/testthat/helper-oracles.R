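## Independent brute-force oracles.  These re-derive expected results by
## literal enumeration, deliberately sharing no code with the package
## internals they check.

## Literal evaluation of the three strictness predicates over every
## (target, template) pair in the cross product of observed gene ids.
oracleStrictness <- function(fwd, rev, strictness,
                             maxE = 1e-30, minLen = 200, minIde = 40) {
  fh <- fwd@hits; rh <- rev@hits
  pass <- function(row) row$e_value <= maxE &&
    row$alignment_length >= minLen && row$percent_identity >= minIde

  ## one representative per (query, subject): lowest E, then highest bit
  bestOfGroup <- function(h) {
    if (nrow(h) == 0L) return(NULL)
    best <- h[1L, ]
    for (i in seq_len(nrow(h))[-1L]) {
      r <- h[i, ]
      if (r$e_value < best$e_value ||
          (r$e_value == best$e_value && r$bit_score > best$bit_score))
        best <- r
    }
    best
  }
  collapsed <- function(h, q, s)
    bestOfGroup(h[h$query_id == q & h$subject_id == s, , drop = FALSE])

  ## best hit per query across subjects: lowest E, highest bit, smallest
  ## subject id
  bestPerQuery <- function(h, q) {
    sub <- h[h$query_id == q, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    best <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      r <- sub[i, ]
      better <- r$e_value < best$e_value ||
        (r$e_value == best$e_value && r$bit_score > best$bit_score) ||
        (r$e_value == best$e_value && r$bit_score == best$bit_score &&
           r$subject_id < best$subject_id)
      if (better) best <- r
    }
    best
  }

  targets <- sort(unique(c(fh$query_id, rh$subject_id)))
  templates <- sort(unique(c(fh$subject_id, rh$query_id)))
  out <- list()
  for (t in targets) for (g in templates) {
    cf <- collapsed(fh, t, g)
    cr <- collapsed(rh, g, t)
    fwdPass <- !is.null(cf) && pass(cf)
    revPass <- !is.null(cr) && pass(cr)
    keep <- if (strictness == 1) {
      fwdPass && revPass
    } else if (strictness == 2) {
      fwdPass || revPass
    } else {
      bf <- bestPerQuery(fh, t); br <- bestPerQuery(rh, g)
      !is.null(bf) && !is.null(br) &&
        bf$subject_id == g && br$subject_id == t && pass(bf) && pass(br)
    }
    if (keep) out[[length(out) + 1L]] <- data.frame(
      target = t, template = g, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(target = character(0L), template = character(0L))
}

## Type-7 sample quantile from first principles on the sorted vector.
oracleQuantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

## Venn region sizes by per-element membership counting.
oracleVenn <- function(sets) {
  elements <- sort(unique(unlist(sets)))
  counts <- list()
  for (el in elements) {
    label <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                      logical(1L))], collapse = "&")
    counts[[label]] <- (counts[[label]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Group-by minimum for HSP collapsing: per (query, subject) the row with
## minimal E-value (ties: max bit score).
oracleCollapse <- function(hits) {
  keys <- unique(paste(hits$query_id, hits$subject_id, sep = "\r"))
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    g <- hits[hits$query_id == parts[1L] & hits$subject_id == parts[2L], ,
              drop = FALSE]
    g <- g[order(g$e_value, -g$bit_score), , drop = FALSE]
    g[1L, ]
  })
  do.call(rbind, rows)
}
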