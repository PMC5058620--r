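## Central S4 containers.
##
## An FvStructure stores one or two numbered variable domains as a flat atom
## table; residues are identified by (chain, scheme position, insertion code)
## so that structures numbered in the same scheme can be compared
## position-wise without alignment.

ATOM_COLS <- c("chain", "pos", "ins", "aa", "region", "atom", "element",
               "x", "y", "z", "occ", "b")
BACKBONE_ATOMS <- c("N", "CA", "C", "O")
CDR_NAMES <- c("CDR1", "CDR2", "CDR3")

#' FvStructure: numbered antibody variable domain(s)
#'
#' Holds the atoms of one or two antibody variable domains (heavy chain "H",
#' light chain "L"). Each atom row carries the residue's scheme position and
#' insertion code, its one-letter amino-acid code, and a region label
#' (`"FW"` or `"CDR1"`/`"CDR2"`/`"CDR3"`, `NA` until [assignRegions()] is
#' called).
#'
#' @slot atoms data.frame with columns `chain, pos, ins, aa, region, atom,
#'   element, x, y, z, occ, b`, ordered by chain, position, insertion code.
#' @slot id character provenance identifier.
#' @slot scheme numbering-scheme tag (the package default is the bundled
#'   consensus numbering, tag `"consensus"`).
#' @slot cdrDefinition name of the CDR interval set used for region labels
#'   (`""` until regions are assigned).
#' @seealso [fvStructure()], [readFv()], [assignRegions()]
#' @export
setClass("FvStructure",
  representation(atoms = "data.frame", id = "character",
                 scheme = "character", cdrDefinition = "character"),
  prototype(atoms = data.frame(), id = NA_character_,
            scheme = "consensus", cdrDefinition = ""))

setValidity("FvStructure", function(object) {
  a <- object@atoms
  if (!all(ATOM_COLS %in% names(a)))
    return(paste("atoms must have columns:", paste(ATOM_COLS, collapse = ", ")))
  if (nrow(a) == 0L) return("FvStructure must contain at least one atom")
  if (!all(a$chain %in% c("H", "L")))
    return("chain must be 'H' or 'L'")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  bad <- !(a$aa %in% c(AA_ONE, "X"))
  if (any(bad))
    return(paste("unknown amino-acid code:", paste(unique(a$aa[bad]), collapse = ",")))
  okreg <- is.na(a$region) | a$region %in% c("FW", CDR_NAMES)
  if (!all(okreg)) return("region labels must be FW, CDR1, CDR2, CDR3 or NA")
  # residues strictly ordered within each chain
  for (ch in unique(a$chain)) {
    d <- a[a$chain == ch, ]
    key <- paste(d$pos, d$ins)
    first <- !duplicated(key)
    o <- order(d$pos[first], d$ins[first])
    if (!identical(o, seq_len(sum(first))))
      return(sprintf("residues of chain %s are not ordered by scheme position", ch))
  }
  TRUE
})

#' TemplateStore: searchable framework-template library
#'
#' @slot records list; each record has `id`, `structure` (FvStructure),
#'   `resolution` (Angstrom), `chains` (subset of "H","L") and `fwSeq`
#'   (per-chain named residue vector over framework positions).
#' @slot cutoff resolution cutoff applied when the store was built.
#' @seealso [buildTemplateStore()], [selectFrameworkTemplate()]
#' @export
setClass("TemplateStore",
  representation(records = "list", cutoff = "numeric"),
  prototype(records = list(), cutoff = 2.5))

setValidity("TemplateStore", function(object) {
  if (length(object@records) == 0L) return("empty template store")
  res <- vapply(object@records, function(r) r$resolution, numeric(1))
  if (any(res > object@cutoff + 1e-9))
    return("store contains records beyond the resolution cutoff")
  TRUE
})

#' FragmentStore: loop fragments with anchor geometry
#'
#' One store per CDR type (`"L1"`..`"H3"`) plus the Fv-wide fallback store
#' (`"fv-any"`). Each fragment carries its loop backbone, the backbone of
#' `nAnchor` flanking residues on each side, and source metadata.
#'
#' @slot cdrType one of L1, L2, L3, H1, H2, H3 or "fv-any".
#' @slot nAnchor number of anchor residues per side.
#' @slot fragments list of fragment records.
#' @seealso [buildFragmentStores()], [candidateDecoys()]
#' @export
setClass("FragmentStore",
  representation(cdrType = "character", nAnchor = "integer",
                 fragments = "list"),
  prototype(cdrType = "fv-any", nAnchor = 5L, fragments = list()))

setValidity("FragmentStore", function(object) {
  if (!object@cdrType %in% c("L1", "L2", "L3", "H1", "H2", "H3", "fv-any"))
    return("invalid cdrType")
  if (object@nAnchor < 1L) return("nAnchor must be positive")
  TRUE
})

#' TemplateSelection: result of framework template search
#'
#' @slot mode `"global"` (one structure supplies both domains and their
#'   orientation) or `"hybrid"` (separate VH and VL donors re-oriented on the
#'   best global candidate).
#' @slot vh,vl donor template ids (`NA` for an absent chain).
#' @slot vhIdentity,vlIdentity framework sequence identity (%) to the target.
#' @slot orientationSource id of the structure providing the VH-VL
#'   orientation.
#' @export
setClass("TemplateSelection",
  representation(mode = "character", vh = "character", vhIdentity = "numeric",
                 vl = "character", vlIdentity = "numeric",
                 orientationSource = "character"))

setValidity("TemplateSelection", function(object) {
  if (!object@mode %in% c("global", "hybrid")) return("mode must be global or hybrid")
  if (object@mode == "global") {
    ids <- unname(c(object@vh, object@vl))
    ids <- ids[!is.na(ids)]
    if (length(unique(ids)) > 1L ||
        !all(ids == unname(object@orientationSource)))
      return("global mode requires a single donor that is also the orientation source")
  }
  TRUE
})

#' CalibrationTable: observations powering confidence estimates
#'
#' Pairs of a conditioning value (framework sequence identity in percent, or
#' CDR loop length) and an outcome backbone RMSD, from which conditional
#' probabilities P(RMSD <= x | s) are estimated.
#'
#' @slot data data.frame with columns `cond` and `rmsd`.
#' @slot kind label such as "VH-fw", "VL-fw", "CDRH3".
#' @slot condType `"identity"` (windowed at +/- 2.5 on a 1-unit grid) or
#'   `"length"` (exact match).
#' @seealso [calibrationTable()], [conditionalProbability()]
#' @export
setClass("CalibrationTable",
  representation(data = "data.frame", kind = "character",
                 condType = "character"))

setValidity("CalibrationTable", function(object) {
  d <- object@data
  if (!all(c("cond", "rmsd") %in% names(d))) return("data needs cond and rmsd")
  if (nrow(d) == 0L) return("empty calibration table")
  if (any(d$rmsd < 0)) return("rmsd outcomes must be non-negative")
  if (!object@condType %in% c("identity", "length"))
    return("condType must be identity or length")
  if (object@condType == "identity" && any(d$cond < 0 | d$cond > 100))
    return("identity conditioning values must lie in [0,100]")
  if (object@condType == "length" && any(d$cond <= 0 | d$cond != round(d$cond)))
    return("length conditioning values must be positive integers")
  TRUE
})
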