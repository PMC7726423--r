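#' Deterministic synthetic fixtures for the reconstruction pipeline
#'
#' The fixture generator produces the whole chain of inputs the pipeline
#' consumes -- a toy template model with subsystems and GPR rules,
#' reciprocal homology tables with planted ortholog pairs and controlled
#' decoys, and differential-expression tables -- together with the ground
#' truth, so every stage is testable end to end without external data.
#' Identical spec and seed give byte-identical outputs.
#'
#' @param seed Integer seed; every random draw in the generators derives
#'   from it.
#' @param nTemplateGenes,nTargetGenes Gene counts for the two species.
#' @param plantedFraction Fraction of template genes given a true target
#'   ortholog.
#' @param decoyHits Number of decoy alignment records.  Decoys either fail
#'   at least one default threshold outright or pass in one direction only,
#'   and are always weaker (higher E-value) than every planted hit of the
#'   same query, so best-reciprocal recovery of the planted pairs is exact
#'   by construction.
#' @param nReactions,nSubsystems Template network size.  One subsystem is
#'   always labeled \code{"Metabolism of xenobiotics by cytochrome P450"}
#'   so gap-analysis fixtures have a realistic label to target.
#' @param fractionNoGpr Fraction of reactions with no gene association
#'   (spontaneous/transport-like).
#' @param fractionComplex Fraction of reactions whose GPR is an AND complex
#'   of two genes.
#' @return \code{fixtureSpec}: a validated spec (list of class
#'   \code{"FixtureSpec"}).
#' @examples
#' spec <- fixtureSpec(seed = 42, nReactions = 10, fractionNoGpr = 0.2)
#' sum(modelReactions(makeTemplate(spec))$gpr == "")
#' @export
fixtureSpec <- function(seed = 1L, nTemplateGenes = 30L, nTargetGenes = 40L,
                        plantedFraction = 0.6, decoyHits = 0L,
                        nReactions = 40L, nSubsystems = 4L,
                        fractionNoGpr = 0.1, fractionComplex = 0.3) {
  spec <- list(seed = as.integer(seed),
               nTemplateGenes = as.integer(nTemplateGenes),
               nTargetGenes = as.integer(nTargetGenes),
               plantedFraction = plantedFraction,
               decoyHits = as.integer(decoyHits),
               nReactions = as.integer(nReactions),
               nSubsystems = as.integer(nSubsystems),
               fractionNoGpr = fractionNoGpr,
               fractionComplex = fractionComplex)
  stopifnot(spec$nTemplateGenes >= 1L, spec$nTargetGenes >= 1L,
            spec$nReactions >= 1L, spec$nSubsystems >= 1L,
            spec$decoyHits >= 0L,
            spec$plantedFraction >= 0, spec$plantedFraction <= 1,
            spec$fractionNoGpr >= 0, spec$fractionNoGpr <= 1,
            spec$fractionComplex >= 0, spec$fractionComplex <= 1)
  structure(spec, class = "FixtureSpec")
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

resetRows <- function(df) { rownames(df) <- NULL; df }

templateGeneIds <- function(n) sprintf("h%03d", seq_len(n))
targetGeneIds <- function(n) sprintf("t%03d", seq_len(n))

#' Generate a toy template model
#'
#' Builds a connected toy metabolic network: a linear pathway through a
#' cytosolic metabolite chain fed by an extracellular uptake, split into
#' named subsystems (one of them the cytochrome P450 xenobiotics
#' subsystem), with a deterministic mixture of single-gene, isoenzyme (OR),
#' complex (AND) and gene-less reactions.  The model passes full
#' referential-integrity validation.
#'
#' @param spec A [fixtureSpec()].
#' @return A [GEModel-class].
#' @export
makeTemplate <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  nR <- spec$nReactions
  nNoGpr <- round(spec$fractionNoGpr * nR)
  nComplex <- round(spec$fractionComplex * nR)
  if (nNoGpr + nComplex > nR)
    stop("infeasible fixture spec: ", nNoGpr, " GPR-less + ", nComplex,
         " complex reactions exceed ", nR, " reactions")
  genes <- templateGeneIds(spec$nTemplateGenes)

  withSeed(spec$seed, {
    noGpr <- sort(sample.int(nR, nNoGpr))
    complexRxn <- sort(sample(setdiff(seq_len(nR), noGpr), nComplex))
    ## cycle genes so every reaction with a GPR draws from the full pool
    pool <- rep_len(sample(genes), 2L * nR)
    gprs <- character(nR)
    k <- 0L
    for (i in seq_len(nR)) {
      if (i %in% noGpr) { gprs[i] <- ""; next }
      if (i %in% complexRxn) {
        gprs[i] <- serializeGpr(gprAnd(pool[k + 1L], pool[k + 2L]))
        k <- k + 2L
      } else if (stats::runif(1) < 0.4) {
        gprs[i] <- serializeGpr(gprOr(pool[k + 1L], pool[k + 2L]))
        k <- k + 2L
      } else {
        gprs[i] <- pool[k + 1L]
        k <- k + 1L
      }
    }

    mets <- data.frame(
      id = c("x_e", sprintf("m%03d_c", seq_len(nR))),
      compartment = c("e", rep("c", nR)), stringsAsFactors = FALSE)
    stoich <- vector("list", nR)
    for (i in seq_len(nR)) {
      from <- if (i == 1L) "x_e" else sprintf("m%03d_c", i - 1L)
      stoich[[i]] <- stats::setNames(c(-1, 1),
                                     c(from, sprintf("m%03d_c", i)))
    }
    subsystems <- c("Metabolism of xenobiotics by cytochrome P450",
                    if (spec$nSubsystems > 1L)
                      paste("Subsystem", seq_len(spec$nSubsystems - 1L)))
    subLabels <- subsystems[(seq_len(nR) - 1L) %% spec$nSubsystems + 1L]

    rxn <- data.frame(
      id = sprintf("R%03d", seq_len(nR)),
      lower = ifelse(stats::runif(nR) < 0.3, -1000, 0), upper = 1000,
      subsystem = subLabels, gpr = gprs, stringsAsFactors = FALSE)
    names(stoich) <- rxn$id

    GEModel(id = sprintf("toy_template_seed%d", spec$seed),
            compartments = data.frame(id = c("c", "e"),
                                      name = c("cytosol", "extracellular"),
                                      stringsAsFactors = FALSE),
            genes = data.frame(id = genes, stringsAsFactors = FALSE),
            metabolites = mets, reactions = rxn, stoichiometry = stoich,
            provenance = list(generator = "makeTemplate",
                              seed = spec$seed))
  })
}

#' Generate reciprocal homology tables with planted orthology
#'
#' Emits the two directions of a reciprocal protein search in which a known
#' subset of (target, template) gene pairs is planted as strong reciprocal
#' hits (E-value at most 1e-40, identity at least 60 percent, alignment at
#' least 250 residues -- comfortably inside the default thresholds), plus
#' the requested number of decoy hits.  Decoy design: half fail the default
#' E-value/identity/length thresholds outright; half pass the thresholds
#' but exist in one direction only; every decoy has a higher E-value than
#' any planted hit sharing its query.  The ground-truth pairs are returned
#' alongside the tables.
#'
#' @param spec A [fixtureSpec()].
#' @param templateGenes,targetGenes Gene id vectors; default to the ids
#'   used by [makeTemplate()].
#' @return List with elements \code{fwd} and \code{rev}
#'   ([HomologyTable-class]) and \code{planted} (a \code{data.frame} with
#'   columns \code{target}, \code{template}).
#' @export
makeHomology <- function(spec,
                         templateGenes = templateGeneIds(spec$nTemplateGenes),
                         targetGenes = targetGeneIds(spec$nTargetGenes)) {
  stopifnot(inherits(spec, "FixtureSpec"))
  nPlanted <- round(spec$plantedFraction * length(templateGenes))
  if (nPlanted > length(targetGenes))
    stop("infeasible fixture spec: ", nPlanted,
         " planted pairs need at least as many target genes")

  withSeed(spec$seed + 1L, {
    tpl <- sample(templateGenes, nPlanted)
    tgt <- sample(targetGenes, nPlanted)
    planted <- data.frame(target = tgt, template = tpl,
                          stringsAsFactors = FALSE)

    mkHit <- function(q, s, e, ide, len) {
      len <- as.integer(len)
      data.frame(query_id = q, subject_id = s, percent_identity = ide,
                 alignment_length = len,
                 mismatches = as.integer(round(len * (100 - ide) / 100)),
                 gap_opens = 0L, q_start = 1L, q_end = len,
                 s_start = 1L, s_end = len, e_value = e,
                 bit_score = round(2 * len * ide / 100 + stats::runif(1), 1),
                 stringsAsFactors = FALSE)
    }

    fwd <- list(); rev <- list()
    for (i in seq_len(nPlanted)) {
      e1 <- 10^-stats::runif(1, 41, 180)
      e2 <- 10^-stats::runif(1, 41, 180)
      ide <- stats::runif(1, 60, 95)
      len <- round(stats::runif(1, 250, 600))
      fwd[[length(fwd) + 1L]] <- mkHit(tgt[i], tpl[i], e1, ide, len)
      rev[[length(rev) + 1L]] <- mkHit(tpl[i], tgt[i], e2,
                                       ide - stats::runif(1, 0, 2), len)
    }

    if (spec$decoyHits > 0L) {
      plantedKey <- paste(planted$target, planted$template)
      for (d in seq_len(spec$decoyHits)) {
        repeat {
          q <- sample(targetGenes, 1L)
          s <- sample(templateGenes, 1L)
          if (!paste(q, s) %in% plantedKey) break
        }
        if (d %% 2L == 0L) {
          ## fails thresholds: weak E-value and identity, short alignment
          hit <- mkHit(q, s, 10^-stats::runif(1, 5, 20),
                       stats::runif(1, 20, 35), round(stats::runif(1, 50, 150)))
          if (d %% 4L == 0L) rev[[length(rev) + 1L]] <-
              mkHit(s, q, hit$e_value, hit$percent_identity,
                    hit$alignment_length)
          else fwd[[length(fwd) + 1L]] <- hit
        } else {
          ## passes thresholds but only in the forward direction, and is
          ## weaker than every planted hit (E > 1e-40)
          fwd[[length(fwd) + 1L]] <- mkHit(q, s, 10^-stats::runif(1, 31, 38),
                                           stats::runif(1, 45, 60),
                                           round(stats::runif(1, 250, 400)))
        }
      }
    }

    list(fwd = HomologyTable(do.call(rbind, c(fwd, list(emptyHits()))),
                             direction = "target_to_template"),
         rev = HomologyTable(do.call(rbind, c(rev, list(emptyHits()))),
                             direction = "template_to_target"),
         planted = resetRows(planted[order(planted$target, planted$template,
                                           method = "radix"), , drop = FALSE]))
  })
}

#' Generate a differential-expression table for a model
#'
#' Genes listed as up- or down-regulated receive a significant log2 fold
#' change of the stated sign with magnitude drawn in [1, 3]; all other
#' model genes receive small non-significant noise in [-0.3, 0.3].
#'
#' @param spec A [fixtureSpec()].
#' @param model The [GEModel-class] whose genes are measured.
#' @param upGenes,downGenes Disjoint character vectors of gene ids drawn
#'   from the model.
#' @return \code{data.frame} with columns \code{gene_id}, \code{log2fc},
#'   \code{significant}.
#' @export
makeExpression <- function(spec, model, upGenes = character(0L),
                           downGenes = character(0L)) {
  stopifnot(inherits(spec, "FixtureSpec"), is(model, "GEModel"))
  overlap <- intersect(upGenes, downGenes)
  if (length(overlap))
    stop("gene(s) listed as both up- and down-regulated: ",
         paste(overlap, collapse = ", "))
  ids <- model@genes$id
  unknown <- setdiff(c(upGenes, downGenes), ids)
  if (length(unknown))
    stop("gene(s) not in model: ", paste(unknown, collapse = ", "))
  withSeed(spec$seed + 2L, {
    lfc <- stats::runif(length(ids), -0.3, 0.3)
    sig <- rep(FALSE, length(ids))
    up <- ids %in% upGenes; down <- ids %in% downGenes
    lfc[up] <- stats::runif(sum(up), 1, 3)
    lfc[down] <- -stats::runif(sum(down), 1, 3)
    sig[up | down] <- TRUE
    data.frame(gene_id = ids, log2fc = lfc, significant = sig,
               stringsAsFactors = FALSE)
  })
}
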