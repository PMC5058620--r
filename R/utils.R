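## Internal helpers: amino-acid alphabets, extdata caches, residue keys.

AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_THREE <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL")
names(AA_THREE) <- AA_ONE
AA_FROM_THREE <- setNames(AA_ONE, AA_THREE)

.pkgCache <- new.env(parent = emptyenv())

extdataFile <- function(name) {
  f <- system.file("extdata", name, package = "FvBuilder", mustWork = FALSE)
  if (!nzchar(f)) stop("bundled data file not found: ", name)
  f
}

cachedTable <- function(name) {
  if (is.null(.pkgCache[[name]]))
    .pkgCache[[name]] <- read.delim(extdataFile(name), stringsAsFactors = FALSE)
  .pkgCache[[name]]
}

#' Van der Waals radius table
#'
#' Named vector of van der Waals radii (Angstrom) per element, read from the
#' editable table `inst/extdata/vdw_radii.tsv`. Carbon is 1.7 A, so two
#' carbons clash (at the default 65% factor) below 2.21 A.
#'
#' @return named numeric vector (element -> radius, Angstrom).
#' @export
vdwRadii <- function() {
  t <- cachedTable("vdw_radii.tsv")
  setNames(t$radius, t$element)
}

#' CDR definition table
#'
#' Inclusive scheme-position intervals for CDR1/2/3 on each chain, for a
#' named definition set. Two sets ship with the package: `"north"` (default,
#' wider loop boundaries) and `"chothia"` (narrower H1/H2, used for the
#' alternate benchmarking mode). The table is an editable TSV under
#' `inst/extdata/`.
#'
#' @param set definition-set name.
#' @return data.frame with columns `chain`, `cdr`, `start`, `end`.
#' @export
cdrDefinitions <- function(set = "north") {
  t <- cachedTable("cdr_definitions.tsv")
  d <- t[t$scheme == set, c("chain", "cdr", "start", "end")]
  if (nrow(d) == 0L) stop("unknown CDR definition set: ", set)
  d
}

#' Bundled consensus domain sequence
#'
#' The pre-numbered consensus sequence used by [numberSequence()] to assign
#' scheme positions by global alignment.
#'
#' @param chainType "H" or "L".
#' @return data.frame with columns `pos`, `aa`.
#' @export
consensusSequence <- function(chainType = c("H", "L")) {
  chainType <- match.arg(chainType)
  cachedTable(if (chainType == "H") "consensus_heavy.tsv" else "consensus_light.tsv")
}

#' Backbone-independent rotamer library
#'
#' Small editable rotamer library (`inst/extdata/rotamer_library.tsv`):
#' per residue type, a handful of (chi1..chi4, prior probability) rows,
#' probabilities summing to 1. The interface accepts any table in the same
#' shape, so a finer (e.g. Dunbrack-style) library can be swapped in.
#'
#' @return data.frame with columns `aa`, `chi1`..`chi4`, `prob`.
#' @export
rotamerLibrary <- function() {
  t <- cachedTable("rotamer_library.tsv")
  s <- tapply(t$prob, t$aa, sum)
  if (any(abs(s - 1) > 1e-6))
    stop("rotamer probabilities must sum to 1 per residue")
  t
}

maxAsaTable <- function() {
  t <- cachedTable("max_asa.tsv")
  setNames(t$max_asa, t$aa)
}

resKey <- function(chain, pos, ins) paste(chain, pos, ins, sep = ":")

## canonical residue ordering: chain H before L, then position, then
## insertion code ("" sorts before "A")
orderAtoms <- function(a) {
  a[order(match(a$chain, c("H", "L")), a$pos,
          match(a$ins, c("", LETTERS))), , drop = FALSE]
}

## residue-level view: one row per residue, canonical order
residueTable <- function(fv) {
  a <- if (is(fv, "FvStructure")) fv@atoms else fv
  key <- resKey(a$chain, a$pos, a$ins)
  r <- a[!duplicated(key), c("chain", "pos", "ins", "aa", "region")]
  r$key <- key[!duplicated(key)]
  rownames(r) <- NULL
  r
}

coordMatrix <- function(a) {
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
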