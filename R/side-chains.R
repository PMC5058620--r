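## Side-chain completion and clash control.
##
## Clash rule: two atoms clash when their distance is strictly less than
## 65% of the sum of their van der Waals radii (so two carbons, r = 1.7 A,
## clash below 2.21 A). Covalently bonded pairs and 1-3 neighbours are
## excluded, otherwise every bond would count as a clash.

## covalent adjacency (atom index pairs) for an atom table
bondGraph <- function(a) {
  n <- nrow(a)
  akey <- paste(resKey(a$chain, a$pos, a$ins), a$atom)
  idx <- function(keys) match(keys, akey)
  r <- residueTable(a)
  bonds <- list()
  addBond <- function(i, j) {
    ok <- !is.na(i) & !is.na(j)
    if (any(ok)) bonds[[length(bonds) + 1L]] <<- cbind(i[ok], j[ok])
  }
  # within-residue backbone + CB
  addBond(idx(paste(r$key, "N")), idx(paste(r$key, "CA")))
  addBond(idx(paste(r$key, "CA")), idx(paste(r$key, "C")))
  addBond(idx(paste(r$key, "C")), idx(paste(r$key, "O")))
  addBond(idx(paste(r$key, "CA")), idx(paste(r$key, "CB")))
  # peptide bonds between consecutive residues of a chain
  for (ch in unique(r$chain)) {
    rc <- r[r$chain == ch, ]
    if (nrow(rc) > 1L)
      addBond(idx(paste(rc$key[-nrow(rc)], "C")), idx(paste(rc$key[-1], "N")))
  }
  # side-chain bonds from the placement topology (+ ring closures)
  for (j in seq_len(nrow(r))) {
    aa <- r$aa[j]
    if (aa %in% c("G", "A", "X")) next
    specs <- TOPOLOGY[[aa]]
    for (s in specs[-1])          # first entry is CB, already bonded
      addBond(idx(paste(r$key[j], s$refs[3])), idx(paste(r$key[j], s$name)))
    for (b in EXTRA_BONDS[[aa]])
      addBond(idx(paste(r$key[j], b[1])), idx(paste(r$key[j], b[2])))
  }
  do.call(rbind, bonds)
}

## set of excluded pairs (bonded + 1-3), as i*n + j keys with i < j
excludedPairs <- function(a) {
  n <- nrow(a)
  b <- bondGraph(a)
  if (is.null(b) || nrow(b) == 0L) return(numeric(0))
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  pairs <- list(b)
  for (i in seq_len(n)) {        # 1-3: both partners of a shared neighbour
    nb <- adj[[i]]
    if (length(nb) > 1L) {
      cmb <- utils::combn(nb, 2)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
  }
  p <- do.call(rbind, pairs)
  lo <- pmin(p[, 1], p[, 2]); hi <- pmax(p[, 1], p[, 2])
  unique(lo * (n + 1) + hi)
}

#' Detect van der Waals clashes
#'
#' Pairwise check over all atoms, excluding covalently bonded pairs and 1-3
#' neighbours. Atoms i, j clash when `d(i,j) < factor * (r_i + r_j)`
#' (strict less-than).
#'
#' @param fv an [FvStructure-class].
#' @param factor clash factor (default 0.65).
#' @param radii named element -> radius vector (default [vdwRadii()]).
#' @return list with `clashes` (data.frame: atom1, atom2, distance,
#'   threshold), `clashFree` flag and `nClashes`.
#' @export
detectClashes <- function(fv, factor = 0.65, radii = vdwRadii()) {
  a <- fv@atoms
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop("element(s) missing from the radius table: ",
         paste(unknown, collapse = ", "))
  n <- nrow(a)
  r <- radii[a$element]
  d <- as.matrix(dist(coordMatrix(a)))
  th <- outer(r, r, "+") * factor
  hit <- which(d < th & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit)) {
    excl <- excludedPairs(a)
    keys <- hit[, 1] * (n + 1) + hit[, 2]
    hit <- hit[!(keys %in% excl), , drop = FALSE]
  }
  lab <- paste(resKey(a$chain, a$pos, a$ins), a$aa, a$atom)
  clashes <- data.frame(
    atom1 = lab[hit[, 1]], atom2 = lab[hit[, 2]],
    distance = d[hit], threshold = th[hit], stringsAsFactors = FALSE)
  list(clashes = clashes, clashFree = nrow(clashes) == 0L,
       nClashes = nrow(clashes))
}

## residues (keys) involved in at least one clash
clashingResidues <- function(report) {
  if (report$clashFree) return(character(0))
  k <- c(report$clashes$atom1, report$clashes$atom2)
  unique(vapply(strsplit(k, " "), function(p) p[1], character(1)))
}

## count clashes a candidate side chain (coords m, elements el) would make
## against the rest of the structure (own residue excluded)
countTrialClashes <- function(m, el, other, radii, factor = 0.65) {
  if (is.null(m) || nrow(other) == 0L) return(0L)
  oc <- coordMatrix(other)
  d2 <- outer(rowSums(m^2), rowSums(oc^2), "+") - 2 * m %*% t(oc)
  th <- outer(radii[el], radii[other$element], "+") * factor
  sum(d2 < th^2 - 1e-12)
}

## replace (or add) the side chain of one residue; backbone untouched
setSideChain <- function(fv, key, aa, sc) {
  a <- fv@atoms
  rk <- resKey(a$chain, a$pos, a$ins)
  own <- rk == key
  a$aa[own] <- aa
  keep <- !own | a$atom %in% BACKBONE_ATOMS
  a <- a[keep, ]
  if (!is.null(sc)) {
    proto <- fv@atoms[which(own)[1], ]
    add <- proto[rep(1, nrow(sc)), ]
    add$aa <- aa
    add$atom <- rownames(sc)
    add$element <- attr(sc, "element")
    add$x <- sc[, 1]; add$y <- sc[, 2]; add$z <- sc[, 3]
    add$occ <- 1; add$b <- 0
    a <- rbind(a, add)
  }
  fv@atoms <- orderAtoms(a)
  rownames(fv@atoms) <- NULL
  fv
}

## rebuild one residue's side chain from the library: highest-prior rotamer
## that introduces no clash, else the least-clashing one
sampleRotamer <- function(fv, key, aa, library, radii, factor = 0.65) {
  if (aa %in% c("G", "X")) return(setSideChain(fv, key, aa, NULL))
  a <- fv@atoms
  rk <- resKey(a$chain, a$pos, a$ins)
  own <- a[rk == key, ]
  bb <- list()
  for (nm in c("N", "CA", "C")) {
    i <- which(own$atom == nm)
    if (!length(i)) stop("residue ", key, " lacks backbone atom ", nm)
    bb[[nm]] <- c(own$x[i], own$y[i], own$z[i])
  }
  other <- a[rk != key, ]
  if (aa == "A") {
    sc <- buildSideChain("A", bb)
    return(setSideChain(fv, key, "A", sc))
  }
  rows <- library[library$aa == aa, , drop = FALSE]
  if (nrow(rows) == 0L) stop("residue type ", aa, " absent from rotamer library")
  rows <- rows[order(-rows$prob), , drop = FALSE]
  best <- NULL; bestClash <- Inf
  for (j in seq_len(nrow(rows))) {
    chis <- as.numeric(rows[j, c("chi1", "chi2", "chi3", "chi4")])
    sc <- buildSideChain(aa, bb, chis)
    ncl <- countTrialClashes(sc, attr(sc, "element"), other, radii, factor)
    if (ncl == 0L) { best <- sc; break }
    if (ncl < bestClash) { bestClash <- ncl; best <- sc }
  }
  setSideChain(fv, key, aa, best)
}

targetAaVector <- function(target) {
  if (is(target, "FvStructure")) target <- residueTable(target)
  if (is.data.frame(target)) {
    key <- if (!is.null(target$key)) target$key
      else resKey(target$chain, target$pos, target$ins)
    return(setNames(target$aa, key))
  }
  target                                  # already a named vector
}

#' Partial side-chain prediction
#'
#' Residues whose template side chain matches the target residue type (and
#' is chemically complete) keep the template rotamer verbatim; all other
#' residues are rebuilt from the rotamer library, taking the
#' highest-probability rotamer that introduces no new clash (falling back to
#' the least-clashing rotamer). Backbone atoms are never moved. Retaining
#' common residues' rotamers is more accurate than rebuilding everything,
#' which is why this is the pipeline default.
#'
#' @param fv model carrying template side chains.
#' @param target target residue identities: an [FvStructure-class], a
#'   residue data.frame, or a named (`chain:pos:ins`) character vector.
#' @param library rotamer library (default [rotamerLibrary()]).
#' @param factor clash factor.
#' @return the completed [FvStructure-class].
#' @export
partialSideChainPrediction <- function(fv, target, library = rotamerLibrary(),
                                       factor = 0.65) {
  tgt <- targetAaVector(target)
  radii <- vdwRadii()
  r <- residueTable(fv)
  for (j in seq_len(nrow(r))) {
    key <- r$key[j]
    aa <- tgt[key]
    if (is.na(aa)) next
    have <- fv@atoms$atom[resKey(fv@atoms$chain, fv@atoms$pos, fv@atoms$ins) == key]
    complete <- all(sideChainAtoms(aa) %in% have)
    if (r$aa[j] == aa && complete) next
    fv <- sampleRotamer(fv, key, unname(aa), library, radii, factor)
  }
  fv
}

#' Complete side-chain prediction
#'
#' Rebuilds every side chain (all residues with at least one chi angle)
#' from the rotamer library, ignoring any template rotamers. Gly and Ala
#' are left untouched. Provided for the retention-versus-rebuild accuracy
#' comparison; the pipeline default is [partialSideChainPrediction()].
#'
#' @inheritParams partialSideChainPrediction
#' @return the rebuilt [FvStructure-class].
#' @export
completeSideChainPrediction <- function(fv, target = NULL,
                                        library = rotamerLibrary(),
                                        factor = 0.65) {
  tgt <- if (is.null(target)) setNames(residueTable(fv)$aa, residueTable(fv)$key)
    else targetAaVector(target)
  radii <- vdwRadii()
  r <- residueTable(fv)
  for (j in seq_len(nrow(r))) {
    key <- r$key[j]
    aa <- unname(tgt[key])
    if (is.na(aa) || N_CHI[aa] %in% c(NA, 0)) next
    fv <- sampleRotamer(fv, key, aa, library, radii, factor)
  }
  fv
}

#' Staged clash resolution
#'
#' If the structure is clash-free, nothing is done (stage `"none"`).
#' Otherwise the clashing residues only are re-sampled greedily in
#' probability order (stage `"local"`); if clashes remain, every side chain
#' is re-sampled (stage `"global"`). The first clash-free result is
#' returned; failing that, the structure with the fewest clashes seen
#' (never more than the input had), with a warning.
#'
#' @inheritParams partialSideChainPrediction
#' @return list with `structure`, `stage` ("none"/"local"/"global") and
#'   `nClashes` remaining.
#' @export
resolveClashes <- function(fv, library = rotamerLibrary(), factor = 0.65) {
  radii <- vdwRadii()
  rep0 <- detectClashes(fv, factor, radii)
  if (rep0$clashFree)
    return(list(structure = fv, stage = "none", nClashes = 0L))
  resample <- function(s, keys) {
    r <- residueTable(s)
    for (key in keys) {
      aa <- r$aa[match(key, r$key)]
      if (is.na(aa) || N_CHI[aa] %in% c(NA, 0)) next
      s <- sampleRotamer(s, key, aa, library, radii, factor)
    }
    s
  }
  local <- resample(fv, clashingResidues(rep0))
  repL <- detectClashes(local, factor, radii)
  if (repL$clashFree)
    return(list(structure = local, stage = "local", nClashes = 0L))
  global <- resample(local, residueTable(local)$key)
  repG <- detectClashes(global, factor, radii)
  if (repG$clashFree)
    return(list(structure = global, stage = "global", nClashes = 0L))
  cand <- list(list(fv, rep0$nClashes), list(local, repL$nClashes),
               list(global, repG$nClashes))
  counts <- vapply(cand, function(x) x[[2]], numeric(1))
  best <- cand[[which.min(counts)]]
  warning("clashes remain after global relaxation: ", best[[2]])
  list(structure = best[[1]], stage = "global", nClashes = best[[2]])
}
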