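## Fv data model: construction, accessors, PDB I/O, numbering and region
## assignment.

#' Construct an FvStructure
#'
#' Low-level constructor; most users will obtain structures from [readFv()]
#' or the fixture generator [makeIdealizedFv()].
#'
#' @param atoms data.frame with the columns documented in
#'   [FvStructure-class].
#' @param id provenance identifier.
#' @param scheme numbering-scheme tag.
#' @param cdrDefinition CDR definition-set tag ("" if regions unassigned).
#' @return an [FvStructure-class] object.
#' @export
fvStructure <- function(atoms, id = NA_character_, scheme = "consensus",
                        cdrDefinition = "") {
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$region)) atoms$region <- NA_character_
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms <- orderAtoms(atoms[, ATOM_COLS])
  rownames(atoms) <- NULL
  new("FvStructure", atoms = atoms, id = id, scheme = scheme,
      cdrDefinition = cdrDefinition)
}

#' @describeIn fvStructure atom table accessor.
#' @param fv an FvStructure.
#' @export
fvAtoms <- function(fv) fv@atoms

#' @describeIn fvStructure provenance id accessor.
#' @export
fvId <- function(fv) fv@id

#' @describeIn fvStructure chains present ("H", "L" or both).
#' @export
fvChains <- function(fv) intersect(c("H", "L"), unique(fv@atoms$chain))

#' @describeIn fvStructure one-letter sequence of one domain.
#' @param chain "H" or "L".
#' @export
fvSequence <- function(fv, chain) {
  r <- residueTable(fv)
  paste(r$aa[r$chain == chain], collapse = "")
}

setMethod("show", "FvStructure", function(object) {
  r <- residueTable(object)
  cat("FvStructure:", object@id, "\n")
  for (ch in fvChains(object)) {
    d <- r[r$chain == ch, ]
    reg <- if (all(is.na(d$region))) "regions unassigned"
      else paste0(sum(d$region == "FW", na.rm = TRUE), " FW + ",
                  sum(d$region != "FW", na.rm = TRUE), " CDR residues")
    cat(sprintf("  %s: %d residues (%s)\n", ch, nrow(d), reg))
  }
  cat(sprintf("  %d atoms; scheme %s", nrow(object@atoms), object@scheme))
  if (nzchar(object@cdrDefinition))
    cat("; CDR set", object@cdrDefinition)
  cat("\n")
})

#' Read an Fv structure from a PDB file
#'
#' Parses ATOM records (via bio3d) and maps the requested PDB chains onto
#' the heavy/light domains. Residues keep their author numbering and
#' insertion codes; region labels stay unset until [assignRegions()].
#' Non-standard residues are retained with code "X" (with a warning).
#'
#' @param path PDB-format file.
#' @param chainMap named character vector mapping PDB chain ids to "H"/"L",
#'   e.g. `c(A = "H", B = "L")`. Default expects chains named H and L.
#' @param id provenance id (defaults to the file name).
#' @param scheme numbering-scheme tag to record.
#' @return an [FvStructure-class].
#' @export
readFv <- function(path, chainMap = c(H = "H", L = "L"), id = NULL,
                   scheme = "consensus") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  missing <- setdiff(names(chainMap), unique(at$chain))
  if (length(missing))
    stop("chain(s) not present in ", path, ": ", paste(missing, collapse = ", "))
  at <- at[at$chain %in% names(chainMap), ]
  aa <- unname(AA_FROM_THREE[at$resid])
  if (anyNA(aa)) {
    warning("non-standard residue(s) kept with code X: ",
            paste(unique(at$resid[is.na(aa)]), collapse = ", "))
    aa[is.na(aa)] <- "X"
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  atoms <- data.frame(
    chain = unname(chainMap[at$chain]), pos = at$resno, ins = ins, aa = aa,
    region = NA_character_, atom = at$elety, element = toupper(elesy),
    x = at$x, y = at$y, z = at$z, occ = at$o, b = at$b,
    stringsAsFactors = FALSE)
  fvStructure(atoms, id = id %||% basename(path), scheme = scheme)
}

#' Write an Fv structure to a PDB file
#'
#' Emits standard ATOM records (3-decimal coordinates) with chains "H"/"L".
#'
#' @param fv an [FvStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFv <- function(fv, path) {
  a <- fv@atoms
  ins <- a$ins
  ins[ins == ""] <- NA
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = as.vector(t(coordMatrix(a))),
    resno = a$pos, resid = unname(AA_THREE[a$aa]),
    eleno = seq_len(nrow(a)), elety = a$atom, chain = a$chain,
    insert = ins, o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

#' Number a domain sequence against the bundled consensus
#'
#' Assigns scheme positions by global (Needleman-Wunsch) alignment of the
#' query against the pre-numbered consensus sequence for the chain type
#' (BLOSUM62, affine gaps). Query residues aligned to a consensus position
#' inherit that position; query residues inserted relative to the consensus
#' receive insertion codes A, B, ... on the preceding position; consensus
#' positions deleted in the query are simply absent. Deterministic for fixed
#' consensus and gap penalties.
#'
#' @param seq amino-acid string (one-letter codes).
#' @param chainType "H" or "L".
#' @param identityFloor minimum percent identity to the consensus below
#'   which the sequence is rejected as unnumberable (default 30).
#' @param gapOpening,gapExtension alignment gap penalties.
#' @return data.frame with columns `pos`, `ins`, `aa`.
#' @export
numberSequence <- function(seq, chainType = c("H", "L"), identityFloor = 30,
                           gapOpening = 10, gapExtension = 0.5) {
  chainType <- match.arg(chainType)
  if (nchar(seq) < 60 || nchar(seq) > 200)
    stop("sequence length ", nchar(seq),
         " is implausible for a variable domain")
  cons <- consensusSequence(chainType)
  consSeq <- paste(cons$aa, collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(consSeq),
    substitutionMatrix = get("BLOSUM62"), gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  if (Biostrings::pid(aln) < identityFloor)
    stop(sprintf("unnumberable: %.1f%% identity to the %s consensus is below the %.0f%% floor",
                 Biostrings::pid(aln), chainType, identityFloor))
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pos <- integer(0); insc <- character(0); aa <- character(0)
  consIdx <- 0L; lastPos <- 0L; insRun <- 0L
  for (i in seq_along(p)) {
    if (s[i] != "-") { consIdx <- consIdx + 1L }
    if (p[i] == "-") next
    if (s[i] == "-") {                      # insertion relative to consensus
      insRun <- insRun + 1L
      pos <- c(pos, lastPos); insc <- c(insc, LETTERS[insRun])
    } else {
      lastPos <- cons$pos[consIdx]; insRun <- 0L
      pos <- c(pos, lastPos); insc <- c(insc, "")
    }
    aa <- c(aa, p[i])
  }
  data.frame(pos = pos, ins = insc, aa = aa, stringsAsFactors = FALSE)
}

#' Assign framework/CDR region labels
#'
#' Labels every residue as `"FW"` or `"CDR1"`/`"CDR2"`/`"CDR3"` according to
#' a CDR definition set: residues whose scheme position falls inside a CDR
#' interval (inclusive on both ends, insertion codes included) are CDR; the
#' framework is the complement.
#'
#' @param fv an [FvStructure-class] (or a residue data.frame with `chain`,
#'   `pos` columns, labelled in place).
#' @param set CDR definition-set name (see [cdrDefinitions()]).
#' @return the input with region labels set.
#' @export
assignRegions <- function(fv, set = "north") {
  defs <- cdrDefinitions(set)
  lab <- function(a) {
    region <- rep("FW", nrow(a))
    for (k in seq_len(nrow(defs))) {
      d <- defs[k, ]
      hit <- a$chain == d$chain & a$pos >= d$start & a$pos <= d$end
      region[hit] <- paste0("CDR", d$cdr)
      if (d$chain %in% a$chain && !any(hit))
        warning(sprintf("empty CDR interval: %s CDR%d (%d-%d)",
                        d$chain, d$cdr, d$start, d$end))
    }
    region
  }
  if (is(fv, "FvStructure")) {
    fv@atoms$region <- lab(fv@atoms)
    fv@cdrDefinition <- set
    fv
  } else {
    fv$region <- lab(fv)
    fv
  }
}

#' Framework sequence identity between two structures
#'
#' Percent identity over the scheme positions labelled framework in both
#' structures (intersection of framework positions; positions present in
#' only one structure are excluded from both numerator and denominator).
#'
#' @param a,b [FvStructure-class] objects with regions assigned in the same
#'   scheme, or residue tables from `residueTable`-shaped data.frames.
#' @param chain "H" or "L".
#' @return identity percentage in \[0, 100\].
#' @export
frameworkIdentity <- function(a, b, chain) {
  ra <- if (is(a, "FvStructure")) residueTable(a) else a
  rb <- if (is(b, "FvStructure")) residueTable(b) else b
  ra <- ra[ra$chain == chain & ra$region == "FW", ]
  rb <- rb[rb$chain == chain & rb$region == "FW", ]
  if (nrow(ra) == 0L || nrow(rb) == 0L)
    stop("chain ", chain, " has no framework residues in one of the inputs")
  ka <- paste(ra$pos, ra$ins); kb <- paste(rb$pos, rb$ins)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L)
    stop("no shared framework positions on chain ", chain)
  100 * sum(ra$aa[match(shared, ka)] == rb$aa[match(shared, kb)]) /
    length(shared)
}

#' Fv framework identity over both chains
#'
#' Identity computed over the union of both chains' shared framework
#' positions (the two-chain combination used for global template search).
#'
#' @inheritParams frameworkIdentity
#' @return identity percentage.
#' @export
fvFrameworkIdentity <- function(a, b) {
  ra <- if (is(a, "FvStructure")) residueTable(a) else a
  rb <- if (is(b, "FvStructure")) residueTable(b) else b
  chains <- intersect(unique(ra$chain), unique(rb$chain))
  if (length(chains) == 0L) stop("no shared chains")
  num <- 0L; den <- 0L
  for (ch in chains) {
    fa <- ra[ra$chain == ch & ra$region == "FW", ]
    fb <- rb[rb$chain == ch & rb$region == "FW", ]
    ka <- paste(fa$pos, fa$ins); kb <- paste(fb$pos, fb$ins)
    shared <- intersect(ka, kb)
    num <- num + sum(fa$aa[match(shared, ka)] == fb$aa[match(shared, kb)])
    den <- den + length(shared)
  }
  if (den == 0L) stop("no shared framework positions")
  100 * num / den
}

#' Build a numbered, region-labelled target from plain sequences
#'
#' Numbers each provided domain sequence against the consensus and assigns
#' regions; the result is the sequence-level target description consumed by
#' [selectFrameworkTemplate()] and [buildModel()].
#'
#' @param heavy,light amino-acid strings (either may be NULL; at least one
#'   required; heavy-only describes a VHH nanobody).
#' @param set CDR definition set.
#' @param id target identifier.
#' @return data.frame of residues (`chain`, `pos`, `ins`, `aa`, `region`,
#'   `key`).
#' @export
numberTarget <- function(heavy = NULL, light = NULL, set = "north",
                         id = "target") {
  if (is.null(heavy) && is.null(light))
    stop("at least one of heavy/light is required")
  rows <- list()
  if (!is.null(heavy)) {
    n <- numberSequence(heavy, "H"); n$chain <- "H"; rows <- c(rows, list(n))
  }
  if (!is.null(light)) {
    n <- numberSequence(light, "L"); n$chain <- "L"; rows <- c(rows, list(n))
  }
  r <- do.call(rbind, rows)
  r <- assignRegions(r[, c("chain", "pos", "ins", "aa")], set)
  r$key <- resKey(r$chain, r$pos, r$ins)
  attr(r, "id") <- id
  attr(r, "set") <- set
  r
}
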