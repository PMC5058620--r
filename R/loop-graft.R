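## Fragment-database CDR loop prediction: filter candidate fragments by
## anchor Calpha separation and substitution score, rank by anchor RMSD
## after a joint two-sided anchor superposition, graft the winner, and fall
## back through the staged cascade (CDR-specific db -> Fv-wide db ->
## sequence-similar length match -> ab initio hook).

blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}

#' Substitution score between two equal-length loop sequences
#'
#' Position-wise BLOSUM62 sum, the package's stand-in for an
#' environment-specific substitution score. The scorer is used as a filter;
#' candidate ranking is by anchor RMSD, not by this score.
#'
#' @param target,fragment equal-length amino-acid strings.
#' @return integer score.
#' @export
substitutionScore <- function(target, fragment) {
  if (nchar(target) != nchar(fragment))
    stop("sequences must have equal length (", nchar(target), " vs ",
         nchar(fragment), ")")
  m <- blosum62()
  a <- strsplit(target, "")[[1]]; b <- strsplit(fragment, "")[[1]]
  as.integer(sum(m[cbind(a, b)]))
}

## anchors for a CDR slot of the current model, located from the CDR
## definition interval so they exist even while the loop is absent
anchorsForCdr <- function(model, chain, cdr, nAnchor,
                          set = model@cdrDefinition) {
  defs <- cdrDefinitions(set)
  d <- defs[defs$chain == chain & defs$cdr == cdr, ]
  r <- residueTable(model)
  r <- r[r$chain == chain, ]
  nSide <- r$key[r$pos < d$start]
  cSide <- r$key[r$pos > d$end]
  if (length(nSide) < nAnchor || length(cSide) < nAnchor)
    stop("insufficient anchor residues around ", chain, cdr)
  nKeys <- tail(nSide, nAnchor); cKeys <- head(cSide, nAnchor)
  nBB <- backboneBlock(model@atoms, nKeys)
  cBB <- backboneBlock(model@atoms, cKeys)
  if (is.null(nBB) || is.null(cBB))
    stop("anchor residues around ", chain, cdr, " lack backbone atoms")
  span <- sqrt(sum((nBB[paste(nKeys[nAnchor], "CA"), ] -
                      cBB[paste(cKeys[1], "CA"), ])^2))
  list(nKeys = nKeys, cKeys = cKeys, nBB = nBB, cBB = cBB, span = span)
}

decoyFor <- function(frag, anchors, target, stage) {
  fit <- kabschSuperpose(rbind(frag$nBB, frag$cBB),
                         rbind(anchors$nBB, anchors$cBB))
  list(fragment = frag, score = substitutionScore(target, frag$sequence),
       anchorRmsd = fit$rmsd, spanMismatch = frag$span - anchors$span,
       stage = stage, transform = fit)
}

#' Rank loop decoys
#'
#' Total order used everywhere a "best" decoy is chosen: ascending anchor
#' RMSD, ties broken by higher substitution score, then better source
#' resolution, then fragment id.
#'
#' @param decoys list of decoys (as produced by [candidateDecoys()]).
#' @return the list, reordered.
#' @export
rankDecoys <- function(decoys) {
  if (length(decoys) < 2L) return(decoys)
  o <- order(vapply(decoys, `[[`, numeric(1), "anchorRmsd"),
             -vapply(decoys, `[[`, numeric(1), "score"),
             vapply(decoys, function(d) d$fragment$resolution, numeric(1)),
             vapply(decoys, function(d) d$fragment$id, character(1)))
  decoys[o]
}

#' Search a fragment store for loop decoys
#'
#' Keeps length-matched fragments whose anchor Calpha separation is within
#' `spanTolerance` of the model's and whose substitution score reaches
#' `scoreThreshold`; superimposes each fragment's two anchors jointly (as
#' one rigid body) onto the model anchors and ranks the survivors by the
#' resulting anchor RMSD.
#'
#' @param target target loop amino-acid sequence.
#' @param anchors model anchor geometry (from the internal anchor locator;
#'   [modelCdr()] supplies this).
#' @param store a [FragmentStore-class].
#' @param spanTolerance maximum |span mismatch| in Angstrom (default 0.8).
#' @param scoreThreshold minimum substitution score (default 25).
#' @param stage provenance tag stored on the decoys.
#' @param excludeSources source structure ids whose fragments are ignored
#'   (leave-one-out searches).
#' @return ranked list of decoys (possibly empty).
#' @export
candidateDecoys <- function(target, anchors, store, spanTolerance = 0.8,
                            scoreThreshold = 25, stage = "cdr-db",
                            excludeSources = character(0)) {
  len <- nchar(target)
  keep <- Filter(function(f)
    !(f$sourceId %in% excludeSources) &&
      f$length == len && abs(f$span - anchors$span) <= spanTolerance,
    store@fragments)
  decoys <- lapply(keep, decoyFor, anchors = anchors, target = target,
                   stage = stage)
  decoys <- Filter(function(d) d$score >= scoreThreshold, decoys)
  rankDecoys(decoys)
}

#' Graft a loop decoy onto the model
#'
#' Applies the decoy's joint-anchor transform to its loop backbone and
#' substitutes it for the model's current CDR backbone; anchor residues
#' keep their model coordinates and the grafted residues take the *target*
#' residue identities (side chains are completed later). Grafting a
#' fragment cut from the model itself therefore leaves coordinates
#' unchanged.
#'
#' @param model current [FvStructure-class].
#' @param decoy a decoy from [candidateDecoys()].
#' @param chain,cdr the CDR slot being modelled.
#' @param targetLoop data.frame (`pos`, `ins`, `aa`) of the target loop
#'   residues, in order.
#' @return the updated [FvStructure-class].
#' @export
graftLoop <- function(model, decoy, chain, cdr, targetLoop) {
  frag <- decoy$fragment
  if (nrow(targetLoop) != frag$length)
    stop("fragment length ", frag$length, " does not match target loop (",
         nrow(targetLoop), ")")
  loop <- applyTransform(frag$loopBB, decoy$transform)
  region <- paste0("CDR", cdr)
  a <- model@atoms
  drop <- a$chain == chain & !is.na(a$region) & a$region == region
  a <- a[!drop, ]
  n <- nrow(targetLoop)
  add <- data.frame(
    chain = chain, pos = rep(targetLoop$pos, each = 4),
    ins = rep(targetLoop$ins, each = 4),
    aa = rep(targetLoop$aa, each = 4), region = region,
    atom = rep(BACKBONE_ATOMS, n),
    element = rep(c("N", "C", "C", "O"), n),
    x = loop[, 1], y = loop[, 2], z = loop[, 3], occ = 1, b = 0,
    stringsAsFactors = FALSE)
  model@atoms <- orderAtoms(rbind(a, add))
  rownames(model@atoms) <- NULL
  # junction sanity: consecutive Calpha separation at both graft points
  anc <- anchorsForCdr(model, chain, cdr, 1L)
  caN <- anc$nBB[paste(anc$nKeys[1], "CA"), ]
  caC <- anc$cBB[paste(anc$cKeys[1], "CA"), ]
  dN <- sqrt(sum((caN - loop[2, ])^2))           # row 2 = first loop CA
  dC <- sqrt(sum((caC - loop[4 * (n - 1) + 2, ])^2))
  if (dN > 4.5) stop(sprintf("backbone break at the N-side junction of %s%d (CA-CA %.2f A)",
                             chain, cdr, dN))
  if (dC > 4.5) stop(sprintf("backbone break at the C-side junction of %s%d (CA-CA %.2f A)",
                             chain, cdr, dC))
  model
}

abInitioSignal <- function(chain, cdr, targetSeq, nearest) {
  structure(
    class = c("abInitioRequired", "error", "condition"),
    list(message = sprintf(
      "no length-matched fragment for CDR%s%d; ab initio modelling required",
      chain, cdr),
      call = sys.call(-1), chain = chain, cdr = cdr, targetSeq = targetSeq,
      nearestFragment = nearest))
}

## most sequence-similar fragment by global-alignment BLOSUM62 score
## (used only to annotate the ab initio hand-off)
nearestBySequence <- function(target, frags) {
  if (length(frags) == 0L) return(NULL)
  sc <- vapply(frags, function(f) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(target), Biostrings::AAString(f$sequence),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
  }, numeric(1))
  frags[[which.max(sc)]]
}

#' Model one CDR loop through the fallback cascade
#'
#' Searches the CDR-specific database first; if no suitable decoy passes
#' the span and score filters, the Fv-wide database is searched; failing
#' that, the most sequence-similar length-matched loop (BLOSUM62 score,
#' sources at resolution <= 2.5 A only, ties by anchor RMSD) is grafted
#' ignoring the filters; if no length-matched fragment exists at all, a
#' structured `abInitioRequired` condition is raised carrying the most
#' sequence-similar unequal-length fragment as a hook for an external loop
#' modeller.
#'
#' @param model current [FvStructure-class].
#' @param target target residue table ([numberTarget()]).
#' @param chain,cdr CDR slot.
#' @param stores fragment store list from [buildFragmentStores()].
#' @param spanTolerance,scoreThreshold filter settings.
#' @param seqSimilarResolution resolution gate for the sequence-similar
#'   fallback (default 2.5 A).
#' @param excludeSources source ids excluded from every stage.
#' @return list with `model` and `provenance` (one-row data.frame: stage,
#'   fragment id, score, anchor RMSD).
#' @export
modelCdr <- function(model, target, chain, cdr, stores, spanTolerance = 0.8,
                     scoreThreshold = 25, seqSimilarResolution = 2.5,
                     excludeSources = character(0)) {
  cdrStore <- stores[[paste0(chain, cdr)]]
  nAnchor <- cdrStore@nAnchor
  anchors <- anchorsForCdr(model, chain, cdr, nAnchor)
  defs <- cdrDefinitions(model@cdrDefinition)
  d <- defs[defs$chain == chain & defs$cdr == cdr, ]
  tl <- target[target$chain == chain & target$pos >= d$start &
                 target$pos <= d$end, c("pos", "ins", "aa")]
  if (nrow(tl) == 0L) stop("target has no residues in CDR", chain, cdr)
  targetSeq <- paste(tl$aa, collapse = "")
  finish <- function(decoy) {
    m <- graftLoop(model, decoy, chain, cdr, tl)
    list(model = m, provenance = data.frame(
      cdr = paste0(chain, cdr), stage = decoy$stage,
      fragment = decoy$fragment$id, score = decoy$score,
      anchorRmsd = decoy$anchorRmsd, stringsAsFactors = FALSE))
  }
  # a decoy whose graft breaks the backbone is rejected; the next-ranked
  # decoy is tried before falling through to the next cascade stage
  tryDecoys <- function(decoys) {
    for (d in decoys) {
      res <- tryCatch(finish(d), error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  dec <- candidateDecoys(targetSeq, anchors, cdrStore, spanTolerance,
                         scoreThreshold, stage = "cdr-db",
                         excludeSources = excludeSources)
  res <- tryDecoys(dec)
  if (!is.null(res)) return(res)
  dec <- candidateDecoys(targetSeq, anchors, stores$fv, spanTolerance,
                         scoreThreshold, stage = "fv-db",
                         excludeSources = excludeSources)
  res <- tryDecoys(dec)
  if (!is.null(res)) return(res)
  pool <- c(cdrStore@fragments, stores$fv@fragments)
  pool <- Filter(function(f) f$resolution <= seqSimilarResolution &&
                   !(f$sourceId %in% excludeSources), pool)
  lenMatch <- Filter(function(f) f$length == nchar(targetSeq), pool)
  if (length(lenMatch)) {
    decoys <- lapply(lenMatch, decoyFor, anchors = anchors,
                     target = targetSeq, stage = "seq-similar")
    o <- order(-vapply(decoys, `[[`, numeric(1), "score"),
               vapply(decoys, `[[`, numeric(1), "anchorRmsd"),
               vapply(decoys, function(x) x$fragment$id, character(1)))
    res <- tryDecoys(decoys[o])
    if (!is.null(res)) return(res)
  }
  stop(abInitioSignal(chain, cdr, targetSeq, nearestBySequence(targetSeq, pool)))
}

#' Model all CDR loops in the fixed order
#'
#' Loops are modelled in the order CDRL2, CDRH2, CDRL1, CDRH1, CDRL3,
#' CDRH3 (the better-predicted, less-contacting loops first); for a
#' single-domain target the order is conserved within the chain (a VHH
#' models H2, H1, H3). Each graft updates the model before the next search,
#' so anchors always reflect the current structure.
#'
#' @inheritParams modelCdr
#' @param ... passed on to [modelCdr()].
#' @return list with `model` and `provenance` (one row per CDR, in
#'   modelling order).
#' @export
modelAllCdrs <- function(model, target, stores, ...) {
  orderAll <- c("L2", "H2", "L1", "H1", "L3", "H3")
  chains <- unique(target$chain)
  slots <- orderAll[substr(orderAll, 1, 1) %in% chains]
  prov <- list()
  for (s in slots) {
    res <- modelCdr(model, target, substr(s, 1, 1),
                    as.integer(substr(s, 2, 2)), stores, ...)
    model <- res$model
    prov[[length(prov) + 1L]] <- res$provenance
  }
  list(model = model, provenance = do.call(rbind, prov))
}
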