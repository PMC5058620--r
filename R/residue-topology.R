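## Idealised side-chain internal geometry and the NeRF atom placer.
##
## Each side-chain atom is placed from three previously placed reference
## atoms (A, B, C; the atom bonds to C) with an ideal bond length, bond
## angle, and a dihedral that is either fixed or one of the rotatable chi
## angles (possibly with a branch offset, e.g. "chi1+120"). Geometry is
## idealised (standard bond lengths/angles); it is self-consistent rather
## than crystallographically exact, which is all the rotamer and clash
## machinery requires.

at <- function(name, el, A, B, C, bond, angle, dihedral)
  list(name = name, el = el, refs = c(A, B, C), bond = bond, angle = angle,
       dihedral = dihedral)

CB <- at("CB", "C", "C", "N", "CA", 1.53, 110.5, "-146")

TOPOLOGY <- list(
  A = list(CB),
  S = list(CB, at("OG",  "O", "N", "CA", "CB", 1.42, 110.5, "chi1")),
  C = list(CB, at("SG",  "S", "N", "CA", "CB", 1.81, 114.0, "chi1")),
  T = list(CB, at("OG1", "O", "N", "CA", "CB", 1.43, 109.5, "chi1"),
               at("CG2", "C", "N", "CA", "CB", 1.52, 111.0, "chi1+240")),
  V = list(CB, at("CG1", "C", "N", "CA", "CB", 1.52, 111.0, "chi1"),
               at("CG2", "C", "N", "CA", "CB", 1.52, 111.0, "chi1+122")),
  I = list(CB, at("CG1", "C", "N", "CA", "CB", 1.53, 111.0, "chi1"),
               at("CG2", "C", "N", "CA", "CB", 1.53, 111.0, "chi1+240"),
               at("CD1", "C", "CA", "CB", "CG1", 1.52, 113.0, "chi2")),
  L = list(CB, at("CG",  "C", "N", "CA", "CB", 1.53, 116.0, "chi1"),
               at("CD1", "C", "CA", "CB", "CG", 1.52, 111.0, "chi2"),
               at("CD2", "C", "CA", "CB", "CG", 1.52, 111.0, "chi2+120")),
  D = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 112.0, "chi1"),
               at("OD1", "O", "CA", "CB", "CG", 1.25, 118.5, "chi2"),
               at("OD2", "O", "CA", "CB", "CG", 1.25, 118.5, "chi2+180")),
  N = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 112.5, "chi1"),
               at("OD1", "O", "CA", "CB", "CG", 1.23, 120.5, "chi2"),
               at("ND2", "N", "CA", "CB", "CG", 1.33, 116.5, "chi2+180")),
  E = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 114.0, "chi1"),
               at("CD",  "C", "CA", "CB", "CG", 1.52, 112.0, "chi2"),
               at("OE1", "O", "CB", "CG", "CD", 1.25, 118.5, "chi3"),
               at("OE2", "O", "CB", "CG", "CD", 1.25, 118.5, "chi3+180")),
  Q = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 114.0, "chi1"),
               at("CD",  "C", "CA", "CB", "CG", 1.52, 112.5, "chi2"),
               at("OE1", "O", "CB", "CG", "CD", 1.23, 120.5, "chi3"),
               at("NE2", "N", "CB", "CG", "CD", 1.33, 116.5, "chi3+180")),
  M = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 114.0, "chi1"),
               at("SD",  "S", "CA", "CB", "CG", 1.81, 112.5, "chi2"),
               at("CE",  "C", "CB", "CG", "SD", 1.79, 100.5, "chi3")),
  K = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 114.0, "chi1"),
               at("CD",  "C", "CA", "CB", "CG", 1.52, 111.5, "chi2"),
               at("CE",  "C", "CB", "CG", "CD", 1.52, 111.5, "chi3"),
               at("NZ",  "N", "CG", "CD", "CE", 1.49, 112.0, "chi4")),
  R = list(CB, at("CG",  "C", "N", "CA", "CB", 1.52, 114.0, "chi1"),
               at("CD",  "C", "CA", "CB", "CG", 1.52, 111.5, "chi2"),
               at("NE",  "N", "CB", "CG", "CD", 1.46, 112.0, "chi3"),
               at("CZ",  "C", "CG", "CD", "NE", 1.33, 124.0, "chi4"),
               at("NH1", "N", "CD", "NE", "CZ", 1.33, 120.0, "0"),
               at("NH2", "N", "CD", "NE", "CZ", 1.33, 120.0, "180")),
  H = list(CB, at("CG",  "C", "N", "CA", "CB", 1.50, 113.5, "chi1"),
               at("ND1", "N", "CA", "CB", "CG", 1.38, 122.5, "chi2"),
               at("CD2", "C", "CA", "CB", "CG", 1.36, 131.0, "chi2+180"),
               at("CE1", "C", "CB", "CG", "ND1", 1.32, 109.0, "180"),
               at("NE2", "N", "CB", "CG", "CD2", 1.37, 107.0, "180")),
  F = list(CB, at("CG",  "C", "N", "CA", "CB", 1.50, 114.0, "chi1"),
               at("CD1", "C", "CA", "CB", "CG", 1.39, 120.5, "chi2"),
               at("CD2", "C", "CA", "CB", "CG", 1.39, 120.5, "chi2+180"),
               at("CE1", "C", "CB", "CG", "CD1", 1.39, 120.5, "180"),
               at("CE2", "C", "CB", "CG", "CD2", 1.39, 120.5, "180"),
               at("CZ",  "C", "CG", "CD1", "CE1", 1.39, 120.0, "0")),
  Y = list(CB, at("CG",  "C", "N", "CA", "CB", 1.50, 114.0, "chi1"),
               at("CD1", "C", "CA", "CB", "CG", 1.39, 120.5, "chi2"),
               at("CD2", "C", "CA", "CB", "CG", 1.39, 120.5, "chi2+180"),
               at("CE1", "C", "CB", "CG", "CD1", 1.39, 120.5, "180"),
               at("CE2", "C", "CB", "CG", "CD2", 1.39, 120.5, "180"),
               at("CZ",  "C", "CG", "CD1", "CE1", 1.39, 120.0, "0"),
               at("OH",  "O", "CD1", "CE1", "CZ", 1.38, 120.0, "180")),
  W = list(CB, at("CG",  "C", "N", "CA", "CB", 1.50, 114.0, "chi1"),
               at("CD1", "C", "CA", "CB", "CG", 1.37, 127.0, "chi2"),
               at("CD2", "C", "CA", "CB", "CG", 1.43, 126.5, "chi2+180"),
               at("NE1", "N", "CB", "CG", "CD1", 1.38, 110.0, "180"),
               at("CE2", "C", "CB", "CG", "CD2", 1.41, 107.0, "180"),
               at("CE3", "C", "CB", "CG", "CD2", 1.40, 133.5, "0"),
               at("CZ2", "C", "CG", "CD2", "CE2", 1.40, 122.5, "180"),
               at("CZ3", "C", "CG", "CD2", "CE3", 1.39, 118.5, "180"),
               at("CH2", "C", "CD2", "CE2", "CZ2", 1.37, 117.5, "0")),
  # proline: CD is anchored on N so the pyrrolidine ring always closes;
  # the CG-CD bond is recorded in EXTRA_BONDS
  P = list(CB, at("CG",  "C", "N", "CA", "CB", 1.49, 104.5, "chi1"),
               at("CD",  "C", "C", "CA", "N", 1.47, 102.0, "90"))
)

## ring-closure / special covalent bonds not captured by the placement tree
EXTRA_BONDS <- list(
  F = list(c("CZ", "CE2")),
  Y = list(c("CZ", "CE2")),
  H = list(c("CE1", "NE2")),
  W = list(c("NE1", "CE2"), c("CZ2", "CH2"), c("CZ3", "CH2")),
  P = list(c("CG", "CD"))
)

## number of rotatable chi angles per residue type
N_CHI <- c(A = 0, G = 0, S = 1, C = 1, T = 1, V = 1, I = 2, L = 2, D = 2,
           N = 2, H = 2, F = 2, Y = 2, W = 2, P = 2, E = 3, Q = 3, M = 3,
           K = 4, R = 4)

#' Side-chain atom names for a residue type
#'
#' @param aa one-letter residue code.
#' @return character vector of heavy side-chain atom names (empty for Gly).
#' @export
sideChainAtoms <- function(aa) {
  if (aa %in% c("G", "X")) return(character(0))
  vapply(TOPOLOGY[[aa]], function(s) s$name, character(1))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' @param A,B,C reference coordinates; the new atom bonds to C.
#' @param bond bond length (Angstrom).
#' @param angle bond angle B-C-new (degrees).
#' @param dihedral dihedral A-B-C-new (degrees).
#' @return length-3 coordinate vector.
#' @export
placeAtom <- function(A, B, C, bond, angle, dihedral) {
  theta <- angle * pi / 180; phi <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(theta), bond * sin(theta) * cos(phi),
         bond * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

resolveDihedral <- function(spec, chis) {
  if (grepl("^chi", spec)) {
    k <- as.integer(substr(spec, 4, 4))
    off <- 0
    rest <- substr(spec, 5, nchar(spec))
    if (nzchar(rest)) off <- as.numeric(rest)
    chis[k] + off
  } else as.numeric(spec)
}

#' Build idealised side-chain coordinates for one residue
#'
#' Places CB and all further heavy side-chain atoms from ideal internal
#' geometry, with the rotatable dihedrals set to the supplied chi angles.
#'
#' @param aa one-letter residue code (not "G").
#' @param bb named list/matrix of backbone coordinates with entries
#'   `N`, `CA`, `C`.
#' @param chis numeric vector of chi angles in degrees (length >= number of
#'   chi angles of `aa`; extra values ignored).
#' @return matrix (atoms x 3) with rownames = atom names and an `element`
#'   attribute.
#' @export
buildSideChain <- function(aa, bb, chis = numeric(0)) {
  if (aa %in% c("G", "X")) return(NULL)
  specs <- TOPOLOGY[[aa]]
  if (is.null(specs)) stop("no topology for residue type ", aa)
  placed <- list(N = bb$N, CA = bb$CA, C = bb$C)
  el <- character(0)
  for (s in specs) {
    dih <- resolveDihedral(s$dihedral, chis)
    if (is.na(dih))
      stop("missing chi angle for ", aa, " atom ", s$name)
    placed[[s$name]] <- placeAtom(placed[[s$refs[1]]], placed[[s$refs[2]]],
                                  placed[[s$refs[3]]], s$bond, s$angle, dih)
    el <- c(el, s$el)
  }
  keep <- setdiff(names(placed), c("N", "CA", "C"))
  m <- do.call(rbind, placed[keep])
  attr(m, "element") <- el
  m
}
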