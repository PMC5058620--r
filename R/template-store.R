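## Framework-template library, CDR-specific + Fv-specific fragment
## databases, and the all-vs-all framework superimposition table that powers
## confidence calibration.

#' Build a framework template store
#'
#' Filters candidate structures by crystallographic resolution (default
#' cutoff 2.5 Angstrom) and indexes their chains for global and hybrid
#' template search.
#'
#' @param structures list of numbered, region-assigned
#'   [FvStructure-class] objects.
#' @param resolutions numeric vector of resolutions (Angstrom), parallel to
#'   `structures`.
#' @param cutoff resolution cutoff; structures above it are dropped.
#' @return a [TemplateStore-class].
#' @export
buildTemplateStore <- function(structures, resolutions, cutoff = 2.5) {
  stopifnot(length(structures) == length(resolutions))
  keep <- which(resolutions <= cutoff)
  if (length(keep) == 0L)
    stop("no structures at resolution <= ", cutoff, " A: empty template store")
  records <- lapply(keep, function(i) {
    fv <- structures[[i]]
    list(id = fvId(fv), structure = fv, resolution = resolutions[i],
         chains = fvChains(fv), residues = residueTable(fv))
  })
  names(records) <- vapply(records, `[[`, character(1), "id")
  new("TemplateStore", records = records, cutoff = cutoff)
}

setMethod("show", "TemplateStore", function(object) {
  ch <- vapply(object@records, function(r) paste(r$chains, collapse = ""),
               character(1))
  cat(sprintf("TemplateStore: %d records (resolution <= %.2f A)\n",
              length(object@records), object@cutoff))
  print(table(chains = ch))
})

setMethod("show", "FragmentStore", function(object) {
  cat(sprintf("FragmentStore[%s]: %d fragments, %d anchor residues/side\n",
              object@cdrType, length(object@fragments), object@nAnchor))
  if (length(object@fragments))
    print(table(length = vapply(object@fragments, `[[`, numeric(1), "length")))
})

## backbone coordinates (residue-major, atoms N,CA,C,O) for a run of
## residue keys; NULL if any backbone atom is missing
backboneBlock <- function(a, keys) {
  akey <- paste(resKey(a$chain, a$pos, a$ins), a$atom)
  want <- as.vector(t(outer(keys, BACKBONE_ATOMS, paste)))
  i <- match(want, akey)
  if (anyNA(i)) return(NULL)
  m <- coordMatrix(a[i, ])
  rownames(m) <- want
  m
}

## anchor geometry around a CDR of one structure (or current model)
anchorCoords <- function(fv, chain, cdr, nAnchor) {
  a <- fv@atoms
  r <- residueTable(fv)
  r <- r[r$chain == chain, ]
  loop <- which(!is.na(r$region) & r$region == paste0("CDR", cdr))
  if (length(loop) == 0L) return(NULL)
  lo <- min(loop); hi <- max(loop)
  if (lo - nAnchor < 1L || hi + nAnchor > nrow(r)) return(NULL)
  nKeys <- r$key[(lo - nAnchor):(lo - 1L)]
  cKeys <- r$key[(hi + 1L):(hi + nAnchor)]
  nBB <- backboneBlock(a, nKeys); cBB <- backboneBlock(a, cKeys)
  if (is.null(nBB) || is.null(cBB)) return(NULL)
  # Calpha separation between innermost anchor residues
  span <- sqrt(sum((nBB[paste(nKeys[nAnchor], "CA"), ] -
                      cBB[paste(cKeys[1], "CA"), ])^2))
  list(nKeys = nKeys, cKeys = cKeys, loopKeys = r$key[loop],
       nBB = nBB, cBB = cBB, span = span,
       loopSeq = paste(r$aa[loop], collapse = ""))
}

fragmentFromRun <- function(fv, chain, loopKeys, nKeys, cKeys, cdrType,
                            resolution) {
  a <- fv@atoms
  nBB <- backboneBlock(a, nKeys)
  cBB <- backboneBlock(a, cKeys)
  loopBB <- backboneBlock(a, loopKeys)
  if (is.null(nBB) || is.null(cBB) || is.null(loopBB)) return(NULL)
  r <- residueTable(fv)
  span <- sqrt(sum((nBB[paste(nKeys[length(nKeys)], "CA"), ] -
                      cBB[paste(cKeys[1], "CA"), ])^2))
  list(id = paste0(fvId(fv), ":", cdrType, ":", loopKeys[1]),
       sourceId = fvId(fv), cdr = cdrType, length = length(loopKeys),
       sequence = paste(r$aa[match(loopKeys, r$key)], collapse = ""),
       loopBB = loopBB, nBB = nBB, cBB = cBB, span = span,
       resolution = resolution)
}

#' Build the CDR-specific and Fv-specific fragment databases
#'
#' One fragment database per CDR type (a CDRL1 database only contains CDRL1
#' fragments, etc.), built from the full redundant structure set so that
#' multiple conformations of sequence-identical loops are retained, plus an
#' Fv-wide fallback database of contiguous backbone fragments indexed by
#' length. Each fragment stores its loop backbone and `nAnchor` flanking
#' residues of backbone on each side.
#'
#' @param structures list of numbered, region-assigned
#'   [FvStructure-class] objects.
#' @param resolutions parallel numeric vector of source resolutions.
#' @param nAnchor anchor residues per side (default 5).
#' @param fvLengths loop lengths indexed in the Fv-wide store (default: all
#'   CDR lengths observed in `structures`).
#' @return named list of seven [FragmentStore-class] objects
#'   (`L1`,`L2`,`L3`,`H1`,`H2`,`H3`,`fv`).
#' @export
buildFragmentStores <- function(structures, resolutions, nAnchor = 5L,
                                fvLengths = NULL) {
  nAnchor <- as.integer(nAnchor)
  types <- c("L1", "L2", "L3", "H1", "H2", "H3")
  frags <- setNames(vector("list", 6), types)
  lens <- integer(0)
  for (i in seq_along(structures)) {
    fv <- structures[[i]]
    for (ch in fvChains(fv)) for (k in 1:3) {
      anc <- anchorCoords(fv, ch, k, nAnchor)
      ty <- paste0(ch, k)
      if (is.null(anc)) {
        if (any(residueTable(fv)$chain == ch))
          warning("fragment skipped (insufficient anchors): ",
                  fvId(fv), " ", ty)
        next
      }
      f <- fragmentFromRun(fv, ch, anc$loopKeys, anc$nKeys, anc$cKeys, ty,
                           resolutions[i])
      if (!is.null(f)) {
        frags[[ty]] <- c(frags[[ty]], list(f))
        lens <- c(lens, f$length)
      }
    }
  }
  if (is.null(fvLengths)) fvLengths <- sort(unique(lens))
  fvFrags <- list()
  for (i in seq_along(structures)) {
    fv <- structures[[i]]
    r <- residueTable(fv)
    for (ch in fvChains(fv)) {
      rc <- r[r$chain == ch, ]
      for (len in fvLengths) {
        starts <- seq_len(max(0L, nrow(rc) - len - 2L * nAnchor + 1L))
        for (s0 in starts) {
          loopIdx <- (s0 + nAnchor):(s0 + nAnchor + len - 1L)
          f <- fragmentFromRun(
            fv, ch, rc$key[loopIdx], rc$key[s0:(s0 + nAnchor - 1L)],
            rc$key[(s0 + nAnchor + len):(s0 + 2L * nAnchor + len - 1L)],
            "fv-any", resolutions[i])
          if (!is.null(f)) fvFrags <- c(fvFrags, list(f))
        }
      }
    }
  }
  out <- lapply(types, function(ty)
    new("FragmentStore", cdrType = ty, nAnchor = nAnchor,
        fragments = frags[[ty]] %||% list()))
  names(out) <- types
  out$fv <- new("FragmentStore", cdrType = "fv-any", nAnchor = nAnchor,
                fragments = fvFrags)
  out
}

recordIdentities <- function(target, rec) {
  idH <- if ("H" %in% unique(target$chain) && "H" %in% rec$chains)
    tryCatch(frameworkIdentity(target, rec$residues, "H"),
             error = function(e) NA_real_) else NA_real_
  idL <- if ("L" %in% unique(target$chain) && "L" %in% rec$chains)
    tryCatch(frameworkIdentity(target, rec$residues, "L"),
             error = function(e) NA_real_) else NA_real_
  c(H = idH, L = idL)
}

sameFullSequence <- function(target, rec) {
  tch <- unique(target$chain)
  if (!setequal(tch, rec$chains)) return(FALSE)
  for (ch in tch) {
    ts <- paste(target$aa[target$chain == ch], collapse = "")
    rs <- paste(rec$residues$aa[rec$residues$chain == ch], collapse = "")
    if (!identical(ts, rs)) return(FALSE)
  }
  TRUE
}

## deterministic "best" ordering: maximise identity, then better (lower)
## resolution, then lexicographic id
pickBest <- function(ids, score, resolution) {
  o <- order(-score, resolution, ids)
  o[1]
}

#' Select the framework template(s) for a target
#'
#' Global mode is used when a single record reaches the identity threshold
#' (default 80%) on *both* chains' frameworks, choosing the record that
#' maximises the minimum of the two identities; that one structure then
#' supplies both domains and the VH-VL orientation. Otherwise the mode is
#' hybrid: the best VH-identity record and the best VL-identity record are
#' used as donors and the orientation comes from the best global candidate
#' regardless of threshold. Single-domain targets (nanobody or light-only)
#' trivially select in global mode. Ties are broken by better resolution,
#' then lexicographic id, so selection is deterministic.
#'
#' @param target residue table from [numberTarget()] (or an
#'   [FvStructure-class]).
#' @param store a [TemplateStore-class].
#' @param threshold global-mode identity threshold in percent (default 80).
#' @param excludeIdentical drop records with 100% full-Fv sequence identity
#'   to the target (leave-self-out benchmarking).
#' @return a [TemplateSelection-class].
#' @export
selectFrameworkTemplate <- function(target, store, threshold = 80,
                                    excludeIdentical = FALSE) {
  if (is(target, "FvStructure")) target <- residueTable(target)
  recs <- store@records
  if (excludeIdentical)
    recs <- recs[!vapply(recs, sameFullSequence, logical(1), target = target)]
  if (length(recs) == 0L) stop("no candidate templates remain in the store")
  ids <- t(vapply(recs, recordIdentities, numeric(2), target = target))
  rid <- unname(vapply(recs, `[[`, character(1), "id"))
  res <- unname(vapply(recs, `[[`, numeric(1), "resolution"))
  tch <- unique(target$chain)
  if (length(tch) == 1L) {
    ok <- which(!is.na(ids[, tch]))
    if (!length(ok)) stop("no template offers chain ", tch)
    b <- ok[pickBest(rid[ok], ids[ok, tch], res[ok])]
    sel <- new("TemplateSelection", mode = "global",
               vh = if (tch == "H") rid[b] else NA_character_,
               vhIdentity = if (tch == "H") ids[b, "H"] else NA_real_,
               vl = if (tch == "L") rid[b] else NA_character_,
               vlIdentity = if (tch == "L") ids[b, "L"] else NA_real_,
               orientationSource = rid[b])
    return(sel)
  }
  both <- which(!is.na(ids[, "H"]) & !is.na(ids[, "L"]))
  orientation <- NA_character_; bestGlobal <- NA_integer_
  if (length(both)) {
    minId <- pmin(ids[both, "H"], ids[both, "L"])
    bestGlobal <- both[pickBest(rid[both], minId, res[both])]
    orientation <- rid[bestGlobal]
  }
  if (!is.na(bestGlobal) &&
      min(ids[bestGlobal, "H"], ids[bestGlobal, "L"]) >= threshold) {
    return(new("TemplateSelection", mode = "global",
               vh = rid[bestGlobal], vhIdentity = ids[bestGlobal, "H"],
               vl = rid[bestGlobal], vlIdentity = ids[bestGlobal, "L"],
               orientationSource = orientation))
  }
  okH <- which(!is.na(ids[, "H"])); okL <- which(!is.na(ids[, "L"]))
  if (!length(okH) || !length(okL))
    stop("no template offers both target chains for hybrid selection")
  bH <- okH[pickBest(rid[okH], ids[okH, "H"], res[okH])]
  bL <- okL[pickBest(rid[okL], ids[okL, "L"], res[okL])]
  new("TemplateSelection", mode = "hybrid",
      vh = rid[bH], vhIdentity = ids[bH, "H"],
      vl = rid[bL], vlIdentity = ids[bL, "L"],
      orientationSource = orientation)
}

setMethod("show", "TemplateSelection", function(object) {
  cat(sprintf("TemplateSelection (%s): VH %s (%.1f%%), VL %s (%.1f%%), orientation %s\n",
              object@mode, object@vh, object@vhIdentity, object@vl,
              object@vlIdentity, object@orientationSource))
})

## framework superposition RMSD between two structures over given chains
fwPairRmsd <- function(a, b, chains) {
  p <- pairedBackbone(a, b, chains = chains, regions = "FW")
  if (nrow(p$model) < 3L) return(NA_real_)
  kabschSuperpose(p$model, p$native)$rmsd
}

#' All-vs-all framework superimposition table
#'
#' Superimposes the framework regions of every unordered pair of structures
#' and reports framework sequence identity alongside backbone RMSD: the
#' Fv-Fv comparison fits both chains together, VH-VH and VL-VL fit each
#' chain separately. These tables drive the framework confidence
#' calibration.
#'
#' @param structures list of region-assigned [FvStructure-class] objects.
#' @param kind `"fv"`, `"vh"` or `"vl"`.
#' @return data.frame with columns `a`, `b`, `kind`, `identity`, `rmsd`.
#' @export
pairwiseSuperimpositionTable <- function(structures,
                                         kind = c("fv", "vh", "vl")) {
  kind <- match.arg(kind)
  chains <- switch(kind, fv = c("H", "L"), vh = "H", vl = "L")
  has <- vapply(structures, function(s) all(chains %in% fvChains(s)),
                logical(1))
  ss <- structures[has]
  if (length(ss) < 2L) stop("need at least 2 structures with the requested chains")
  rows <- list()
  for (i in seq_len(length(ss) - 1L)) for (j in (i + 1L):length(ss)) {
    ident <- if (kind == "fv") fvFrameworkIdentity(ss[[i]], ss[[j]])
      else frameworkIdentity(ss[[i]], ss[[j]], chains)
    rows[[length(rows) + 1L]] <- data.frame(
      a = fvId(ss[[i]]), b = fvId(ss[[j]]), kind = kind,
      identity = ident, rmsd = fwPairRmsd(ss[[i]], ss[[j]], chains),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
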