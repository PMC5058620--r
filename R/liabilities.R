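## Developability sequence liabilities: motif scanning over the numbered
## sequence, solvent exposure by Shrake-Rupley accessible surface area, and
## the >10% relative-ASA reporting gate.

#' Default liability motif table
#'
#' Editable TSV (`inst/extdata/liability_motifs.tsv`) of sequence motifs
#' known to hinder antibody development: the N-glycosylation sequon
#' (Asn-X-Ser/Thr; X unrestricted by default, see `xNotProline`),
#' deamidation, Asp isomerization, Met/Trp oxidation, N-terminal
#' pyroglutamate formation, lysine glycation context, and cysteines outside
#' the conserved intra-domain disulfide pair. The table is a documented
#' default set, not an exhaustive catalogue; rows can be added or removed
#' freely.
#'
#' @param xNotProline if TRUE the N-glycosylation X position excludes
#'   proline (off by default; the plain sequon is the default definition).
#' @return data.frame with columns `name`, `pattern`, `regions`, `type`,
#'   `note`.
#' @export
liabilityMotifs <- function(xNotProline = FALSE) {
  t <- cachedTable("liability_motifs.tsv")
  if (xNotProline)
    t$pattern[t$name == "n_glycosylation"] <- "N-[^P]-[ST]"
  t
}

## "N-X-[ST]" -> list of allowed-residue character vectors per position
parsePattern <- function(pattern) {
  lapply(strsplit(pattern, "-", fixed = TRUE)[[1]], function(el) {
    if (el == "X") return(AA_ONE)
    if (grepl("^\\[\\^", el))
      return(setdiff(AA_ONE, strsplit(gsub("[][^]", "", el), "")[[1]]))
    if (grepl("^\\[", el)) return(strsplit(gsub("[][]", "", el), "")[[1]])
    el
  })
}

## conserved cysteine scheme positions of the bundled consensus
canonicalCysPositions <- function(chain) {
  cons <- consensusSequence(chain)
  cons$pos[cons$aa == "C"]
}

regionApplies <- function(regions, spanRegions) {
  switch(regions,
         all = TRUE,
         cdr = any(spanRegions %in% CDR_NAMES),
         fw = any(spanRegions == "FW"),
         FALSE)
}

#' Scan a numbered sequence for liability motifs
#'
#' Sequence-only matching over each domain (overlapping matches allowed;
#' each start position reported once per motif). Exposure is left unset;
#' apply [flagExposure()] with per-residue relative ASA to gate reporting
#' on solvent accessibility.
#'
#' @param target an [FvStructure-class] or a residue table
#'   ([numberTarget()]).
#' @param motifs motif table (default [liabilityMotifs()]).
#' @return data.frame of hits: `motif`, `chain`, `positions`, `residues`,
#'   `region`, `maxRelAsa` (NA), `exposed` (NA), plus a `keys` list-column
#'   of spanned residue keys.
#' @export
scanMotifs <- function(target, motifs = liabilityMotifs()) {
  r <- if (is(target, "FvStructure")) residueTable(target) else target
  if (is.null(r$key)) r$key <- resKey(r$chain, r$pos, r$ins)
  hits <- list()
  addHit <- function(motif, d, idx) {
    span <- d[idx, , drop = FALSE]
    hits[[length(hits) + 1L]] <<- data.frame(
      motif = motif, chain = span$chain[1],
      positions = paste(paste0(span$pos, span$ins), collapse = ","),
      residues = paste(span$aa, collapse = ""),
      region = span$region[1], maxRelAsa = NA_real_, exposed = NA,
      keys = I(list(span$key)), stringsAsFactors = FALSE)
  }
  for (ch in unique(r$chain)) {
    d <- r[r$chain == ch, , drop = FALSE]
    for (m in seq_len(nrow(motifs))) {
      mt <- motifs[m, ]
      if (mt$type == "pattern") {
        cls <- parsePattern(mt$pattern)
        L <- length(cls)
        if (nrow(d) < L) next
        for (s0 in seq_len(nrow(d) - L + 1L)) {
          idx <- s0:(s0 + L - 1L)
          if (all(mapply(function(a, allowed) a %in% allowed,
                         d$aa[idx], cls)) &&
              regionApplies(mt$regions, d$region[idx]))
            addHit(mt$name, d, idx)
        }
      } else if (mt$type == "nterm") {
        allowed <- parsePattern(mt$pattern)[[1]]
        if (d$aa[1] %in% allowed && regionApplies(mt$regions, d$region[1]))
          addHit(mt$name, d, 1L)
      } else if (mt$type == "unpaired_cys") {
        canon <- canonicalCysPositions(ch)
        for (idx in which(d$aa == "C" & !(d$pos %in% canon)))
          if (regionApplies(mt$regions, d$region[idx]))
            addHit(mt$name, d, idx)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(0), chain = character(0),
                      positions = character(0), residues = character(0),
                      region = character(0), maxRelAsa = numeric(0),
                      exposed = logical(0)))
  do.call(rbind, hits)
}

## deterministic near-uniform points on the unit sphere (golden spiral)
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue relative accessible surface area (Shrake-Rupley)
#'
#' Computes absolute solvent-accessible surface area with the Shrake-Rupley
#' sphere-point method (probe 1.4 A) and normalises each residue by its
#' maximum attainable ASA (the Miller et al. standard-state Gly-X-Gly
#' reference values, bundled as an editable table) to a percentage, so a
#' residue in a free extended tripeptide reads close to 100%. Structures
#' without side chains are scored on backbone + CB with a warning.
#'
#' @param fv an [FvStructure-class].
#' @param probe probe radius in Angstrom (default 1.4).
#' @param nPoints sphere points per atom (default 92).
#' @return data.frame with one row per residue: `key`, `chain`, `pos`,
#'   `ins`, `aa`, `asa` (A^2), `relAsa` (%).
#' @export
relativeAsa <- function(fv, probe = 1.4, nPoints = 92) {
  a <- fv@atoms
  maxAsa <- maxAsaTable()
  r <- residueTable(fv)
  bad <- setdiff(unique(r$aa), names(maxAsa))
  if (length(bad))
    stop("no max-ASA reference for residue type(s): ",
         paste(bad, collapse = ", "))
  if (!any(!a$atom %in% c(BACKBONE_ATOMS, "CB")))
    warning("structure has no side-chain atoms beyond CB; relative ASA is computed on backbone + CB only")
  radii <- vdwRadii()
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop("element(s) missing from the radius table: ",
         paste(unknown, collapse = ", "))
  xyz <- coordMatrix(a)
  rad <- radii[a$element] + probe
  n <- nrow(a)
  pts <- spherePoints(nPoints)
  d <- as.matrix(dist(xyz))
  atomAsa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj >= rad[j]^2
    }
    atomAsa[i] <- 4 * pi * rad[i]^2 * mean(free)
  }
  akey <- resKey(a$chain, a$pos, a$ins)
  asa <- tapply(atomAsa, akey, sum)
  r$asa <- as.numeric(asa[r$key])
  r$relAsa <- 100 * r$asa / maxAsa[r$aa]
  r[, c("key", "chain", "pos", "ins", "aa", "asa", "relAsa")]
}

#' Gate liability hits on solvent exposure
#'
#' A hit is exposed when any residue in its span has relative ASA strictly
#' greater than the threshold (default 10%); the original pipeline only
#' reports liabilities passing this gate.
#'
#' @param hits data.frame from [scanMotifs()].
#' @param relAsa data.frame from [relativeAsa()].
#' @param threshold exposure threshold in percent (default 10).
#' @return `hits` with `maxRelAsa` and `exposed` filled in.
#' @export
flagExposure <- function(hits, relAsa, threshold = 10) {
  if (nrow(hits) == 0L) return(hits)
  idx <- setNames(relAsa$relAsa, relAsa$key)
  hits$maxRelAsa <- vapply(hits$keys, function(k) max(idx[k]), numeric(1))
  hits$exposed <- hits$maxRelAsa > threshold
  hits
}
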