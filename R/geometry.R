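## Superposition and the region-wise RMSD protocols used to score models,
## plus dihedral machinery for side-chain (chi) angles.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation + translation minimising the RMSD between paired
#' coordinate sets, via SVD of the cross-covariance with a determinant
#' correction so the rotation is proper (det +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, row-paired, n >= 3.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `fitted = mobile %*% t(rotation) + translation`, and `rmsd` (Angstrom).
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("coordinate sets must be paired (equal length)")
  if (nrow(mobile) < 3L) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (svd(Q)$d[2] < 1e-8) stop("degenerate (collinear) reference coordinates")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' @describeIn kabschSuperpose apply a rigid transform to coordinates.
#' @param coords n x 3 matrix.
#' @param transform result of `kabschSuperpose`.
#' @export
applyTransform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        -transform$translation)
}

transformFv <- function(fv, transform, chain = NULL, rows = NULL) {
  a <- fv@atoms
  idx <- if (!is.null(rows)) rows
    else if (is.null(chain)) seq_len(nrow(a)) else which(a$chain %in% chain)
  a[idx, c("x", "y", "z")] <- applyTransform(coordMatrix(a[idx, ]), transform)
  fv@atoms <- a
  fv
}

## paired backbone coordinates over the shared residues of two structures;
## residues missing any requested atom in either structure are dropped with
## a warning
pairedBackbone <- function(model, native, chains = c("H", "L"),
                           regions = NULL, atoms = BACKBONE_ATOMS) {
  am <- model@atoms; an <- native@atoms
  pick <- function(a) {
    sel <- a$chain %in% chains & a$atom %in% atoms
    if (!is.null(regions)) sel <- sel & !is.na(a$region) & a$region %in% regions
    a[sel, ]
  }
  am <- pick(am); an <- pick(an)
  km <- paste(resKey(am$chain, am$pos, am$ins), am$atom)
  kn <- paste(resKey(an$chain, an$pos, an$ins), an$atom)
  shared <- intersect(km, kn)
  im <- match(shared, km); inn <- match(shared, kn)
  # drop residues that are missing any of the requested atoms
  rk <- resKey(am$chain[im], am$pos[im], am$ins[im])
  cnt <- table(rk)
  keep <- rk %in% names(cnt)[cnt == length(atoms)]
  if (!all(keep))
    warning(sum(!keep), " atoms dropped from residues with incomplete backbone")
  list(model = coordMatrix(am[im[keep], ]),
       native = coordMatrix(an[inn[keep], ]),
       keys = rk[keep])
}

rmsdReport <- function(region, n, rmsd, scope) {
  data.frame(region = region, nAtoms = n, rmsd = rmsd, scope = scope,
             stringsAsFactors = FALSE)
}

#' Fv backbone RMSD
#'
#' Superimposes all shared backbone atoms of both chains and reports the
#' RMSD over those same atoms.
#'
#' @param model,native [FvStructure-class] objects numbered in the same
#'   scheme.
#' @return one-row data.frame (`region`, `nAtoms`, `rmsd`, `scope`).
#' @export
fvRmsd <- function(model, native) {
  p <- pairedBackbone(model, native)
  if (nrow(p$model) < 3L) stop("fewer than 3 shared backbone atoms")
  fit <- kabschSuperpose(p$model, p$native)
  rmsdReport("Fv", nrow(p$model), fit$rmsd, "all backbone atoms, both chains")
}

#' Framework backbone RMSD for one chain
#'
#' Superimposes the framework backbone atoms of the requested chain and
#' reports the RMSD over them.
#'
#' @inheritParams fvRmsd
#' @param chain "H" or "L".
#' @return one-row data.frame report.
#' @export
frameworkRmsd <- function(model, native, chain) {
  p <- pairedBackbone(model, native, chains = chain, regions = "FW")
  if (nrow(p$model) < 3L) stop("fewer than 3 shared framework atoms")
  fit <- kabschSuperpose(p$model, p$native)
  rmsdReport(paste0("FW-", chain), nrow(p$model), fit$rmsd,
             paste("framework backbone,", chain, "chain"))
}

#' CDR loop backbone RMSD after a framework fit
#'
#' First superimposes the framework backbone atoms (of the loop's own chain
#' by default, or of both chains for the stricter variant), then computes
#' the RMSD over the loop backbone atoms without refitting.
#'
#' @inheritParams frameworkRmsd
#' @param cdr CDR index 1, 2 or 3.
#' @param bothChains if TRUE fit on both chains' framework.
#' @return one-row data.frame report.
#' @export
cdrRmsd <- function(model, native, chain, cdr, bothChains = FALSE) {
  fitChains <- if (bothChains) c("H", "L") else chain
  fw <- pairedBackbone(model, native, chains = fitChains, regions = "FW")
  if (nrow(fw$model) < 3L) stop("fewer than 3 shared framework atoms for the fit")
  fit <- kabschSuperpose(fw$model, fw$native)
  regionName <- paste0("CDR", chain, cdr)
  region <- paste0("CDR", cdr)
  sel <- function(fv) {
    a <- fv@atoms
    a[a$chain == chain & !is.na(a$region) & a$region == region &
        a$atom %in% BACKBONE_ATOMS, ]
  }
  lm <- sel(model); ln <- sel(native)
  km <- paste(resKey(lm$chain, lm$pos, lm$ins), lm$atom)
  kn <- paste(resKey(ln$chain, ln$pos, ln$ins), ln$atom)
  if (length(km) == 0L || length(kn) == 0L)
    stop("loop ", regionName, " absent from one structure")
  if (!setequal(km, kn))
    stop("loop length/position mismatch for ", regionName,
         ": no partial-loop RMSD is computed")
  mc <- applyTransform(coordMatrix(lm), fit)
  nc <- coordMatrix(ln[match(km, kn), ])
  rmsd <- sqrt(mean(rowSums((mc - nc)^2)))
  rmsdReport(regionName, length(km), rmsd,
             paste0("fit on ", if (bothChains) "both chains'" else
               paste0(chain, "-chain"), " framework; no refit"))
}

#' Dihedral angle through four points
#'
#' IUPAC sign convention; result in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

circularDiff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

## chi-angle atom quadruples ------------------------------------------------
CHI1_XG <- c(R = "CG", N = "CG", D = "CG", C = "SG", Q = "CG", E = "CG",
             H = "CG", I = "CG1", L = "CG", K = "CG", M = "CG", F = "CG",
             P = "CG", S = "OG", T = "OG1", W = "CG", Y = "CG", V = "CG1")
CHI2_XD <- c(R = "CD", N = "OD1", D = "OD1", Q = "CD", E = "CD", H = "ND1",
             I = "CD1", L = "CD1", K = "CD", M = "SD", F = "CD1", P = "CD",
             W = "CD1", Y = "CD1")

## measure chi-k for every residue of fv that has the needed atoms
measureChi <- function(fv, k = 1) {
  a <- fv@atoms
  r <- residueTable(fv)
  out <- rep(NA_real_, nrow(r))
  names(out) <- r$key
  akey <- paste(resKey(a$chain, a$pos, a$ins), a$atom)
  get1 <- function(key, atom) {
    i <- match(paste(key, atom), akey)
    if (is.na(i)) return(NULL)
    c(a$x[i], a$y[i], a$z[i])
  }
  for (j in seq_len(nrow(r))) {
    aa <- r$aa[j]
    quad <- if (k == 1) {
      xg <- CHI1_XG[aa]
      if (is.na(xg)) next
      c("N", "CA", "CB", unname(xg))
    } else {
      xg <- CHI1_XG[aa]; xd <- CHI2_XD[aa]
      if (is.na(xg) || is.na(xd)) next
      c("CA", "CB", unname(xg), unname(xd))
    }
    pts <- lapply(quad, get1, key = r$key[j])
    if (any(vapply(pts, is.null, logical(1)))) next
    out[j] <- dihedralAngle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }
  out
}

#' Side-chain chi1 (and chi1+2) accuracy
#'
#' Fraction of residues whose model chi1 angle lies within `cutoff` degrees
#' (circular difference) of the native value, over residues comparable in
#' both structures (same residue type with the required side-chain atoms;
#' Gly/Ala have no chi1 and are excluded). `chi12Accuracy` requires both
#' chi1 and chi2 to be within the cutoff.
#'
#' @param model,native [FvStructure-class] objects with side chains.
#' @param cutoff correctness cutoff in degrees (default 40).
#' @return percentage in \[0, 100\].
#' @export
chi1Accuracy <- function(model, native, cutoff = 40) {
  cm <- measureChi(model, 1); cn <- measureChi(native, 1)
  shared <- intersect(names(cm)[!is.na(cm)], names(cn)[!is.na(cn)])
  rm <- residueTable(model); rn <- residueTable(native)
  same <- rm$aa[match(shared, rm$key)] == rn$aa[match(shared, rn$key)]
  shared <- shared[same]
  if (length(shared) == 0L) stop("no comparable residues with chi1 angles")
  100 * mean(circularDiff(cm[shared], cn[shared]) <= cutoff)
}

#' @rdname chi1Accuracy
#' @export
chi12Accuracy <- function(model, native, cutoff = 40) {
  c1m <- measureChi(model, 1); c1n <- measureChi(native, 1)
  c2m <- measureChi(model, 2); c2n <- measureChi(native, 2)
  ok <- function(x) names(x)[!is.na(x)]
  shared <- Reduce(intersect, list(ok(c1m), ok(c1n), ok(c2m), ok(c2n)))
  rm <- residueTable(model); rn <- residueTable(native)
  shared <- shared[rm$aa[match(shared, rm$key)] == rn$aa[match(shared, rn$key)]]
  if (length(shared) == 0L) stop("no comparable residues with chi1+2 angles")
  100 * mean(circularDiff(c1m[shared], c1n[shared]) <= cutoff &
               circularDiff(c2m[shared], c2n[shared]) <= cutoff)
}
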