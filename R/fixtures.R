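## Synthetic fixture generator.
##
## Produces idealised, chemically complete Fv structures with known ground
## truth: framework residues lie on a regular helical path indexed by
## scheme position (so structures with the same scheme share framework
## coordinates exactly), CDR loops are laid on circular arcs between their
## anchor points with ~3.8 A Calpha spacing for any loop length, and side
## chains are placed from the rotamer library. Families derived from the
## consensus by mutation + coordinate noise give controlled pairwise
## identities and RMSDs for every test surface. The backbones are
## idealised, not physically folded: every pipeline contract under test is
## geometric or statistical, not energetic.

HELIX_RADIUS <- 8
HELIX_STEP <- 0.45            # radians per residue
HELIX_RISE <- 1.3             # Angstrom per residue
DOMAIN_OFFSET <- c(34, 0, 0)  # light-domain translation

helixPoint <- function(t) {
  cbind(HELIX_RADIUS * cos(HELIX_STEP * t),
        HELIX_RADIUS * sin(HELIX_STEP * t),
        HELIX_RISE * t)
}

helixTangent <- function(t) {
  v <- cbind(-HELIX_RADIUS * HELIX_STEP * sin(HELIX_STEP * t),
             HELIX_RADIUS * HELIX_STEP * cos(HELIX_STEP * t),
             HELIX_RISE)
  v / sqrt(rowSums(v^2))
}

## walk a dense polyline placing m points at an exact Euclidean step from
## the previous point (chord stepping)
chordStep <- function(p, q, m) {
  pts <- matrix(0, m, 3)
  cur <- p[1, ]; i <- 1L
  for (k in seq_len(m)) {
    while (i < nrow(p) && sqrt(sum((p[i + 1L, ] - cur)^2)) < q) i <- i + 1L
    if (i >= nrow(p)) { pts[k, ] <- p[nrow(p), ]; next }
    a <- p[i, ]; b <- p[i + 1L, ]
    d <- b - a; e <- a - cur
    A2 <- sum(d^2); B2 <- 2 * sum(d * e); C2 <- sum(e^2) - q^2
    f <- (-B2 + sqrt(max(B2^2 - 4 * A2 * C2, 0))) / (2 * A2)
    cur <- a + f * d
    pts[k, ] <- cur
    p[i, ] <- cur
  }
  pts
}

## m loop points on a tangent-continuous cubic Hermite curve from A to B,
## chord-stepped so every consecutive Calpha separation (including the two
## junctions) is ~`spacing`; the tangent scale s is solved so the final
## junction chord also lands on `spacing`
loopPoints <- function(A, B, m, TA, TB, spacing = 3.8) {
  chord <- sqrt(sum((B - A)^2))
  tt <- seq(0, 1, length.out = 512)
  h00 <- 2 * tt^3 - 3 * tt^2 + 1; h10 <- tt^3 - 2 * tt^2 + tt
  h01 <- -2 * tt^3 + 3 * tt^2;    h11 <- tt^3 - tt^2
  curve <- function(s)
    outer(h00, A) + outer(h10, s * TA) + outer(h01, B) + outer(h11, s * TB)
  gap <- function(s) {
    pts <- chordStep(curve(s), spacing, m)
    sqrt(sum((pts[m, ] - B)^2)) - spacing
  }
  L <- max(spacing * (m + 1), chord)
  s <- tryCatch(
    stats::uniroot(gap, c(chord / 4, 12 * L), extendInt = "yes",
                   tol = 1e-4)$root,
    error = function(e) L)
  chordStep(curve(s), spacing, m)
}

## CA path for one numbered domain: helix for FW, smooth anchored curves
## for the CDR loops
domainCaPath <- function(res, defs) {
  ca <- helixPoint(res$pos)
  for (k in 1:3) {
    d <- defs[defs$cdr == k, ]
    loop <- which(res$pos >= d$start & res$pos <= d$end)
    if (length(loop) == 0L) next
    A <- helixPoint(d$start - 1)[1, ]; B <- helixPoint(d$end + 1)[1, ]
    TA <- helixTangent(d$start - 1)[1, ]; TB <- helixTangent(d$end + 1)[1, ]
    ca[loop, ] <- loopPoints(A, B, length(loop), TA, TB)
  }
  ca
}

## backbone N, C, O from the CA trace via local frames
backboneFromCa <- function(ca) {
  n <- nrow(ca)
  prev <- rbind(2 * ca[1, ] - ca[2, ], ca[-n, ])
  nxt <- rbind(ca[-1, ], 2 * ca[n, ] - ca[n - 1, ])
  t <- nxt - prev
  t <- t / sqrt(rowSums(t^2))
  ref <- c(0, 0, 1)
  b <- cbind(t[, 2] * ref[3] - t[, 3] * ref[2],
             t[, 3] * ref[1] - t[, 1] * ref[3],
             t[, 1] * ref[2] - t[, 2] * ref[1])
  b <- b / sqrt(rowSums(b^2))
  nn <- cbind(b[, 2] * t[, 3] - b[, 3] * t[, 2],
              b[, 3] * t[, 1] - b[, 1] * t[, 3],
              b[, 1] * t[, 2] - b[, 2] * t[, 1])
  # alternate the carbonyl/side-chain direction as in a beta strand, so
  # consecutive side chains point to opposite faces and do not collide
  nn <- nn * rep_len(c(1, -1), n)
  list(N = ca - 1.2 * t + 0.5 * nn,
       C = ca + 1.2 * t + 0.5 * nn,
       O = ca + 1.2 * t + 0.5 * nn + 1.23 * b)
}

#' Fixture family specification
#'
#' Collects the generator parameters with defaults chosen to emulate a
#' desk-scale template library: per-member framework mutation rates span
#' the 80% identity threshold, per-residue coordinate noise grows linearly
#' with sequence distance (so pairwise framework RMSD trends with identity,
#' as in real template sets), the CDRH3 loop has two length variants, and
#' resolutions straddle the 2.5 A template cutoff.
#'
#' @param nStructures family size.
#' @param fwMutationRange range of per-member framework mutation rates.
#' @param cdrMutationRate per-position CDR mutation rate.
#' @param sigmaBase,sigmaSlope per-residue coordinate noise sigma (A) =
#'   `sigmaBase + sigmaSlope * fwRate`.
#' @param orientationJitter sd (degrees) of the random light-domain
#'   rotation.
#' @param h3InsertLengths candidate CDRH3 insertion lengths (0 = consensus
#'   length), sampled per member.
#' @param resolutionRange range of simulated crystallographic resolutions.
#' @param seed integer seed; every draw derives from it.
#' @return list of class parameters (plain list).
#' @export
fixtureSpec <- function(nStructures = 20, fwMutationRange = c(0.02, 0.35),
                        cdrMutationRate = 0.08, sigmaBase = 0.05,
                        sigmaSlope = 1.5, orientationJitter = 2,
                        h3InsertLengths = c(0, 2),
                        resolutionRange = c(1.2, 3.0), seed = 1) {
  stopifnot(nStructures > 0, sigmaBase >= 0, sigmaSlope >= 0)
  list(nStructures = nStructures, fwMutationRange = fwMutationRange,
       cdrMutationRate = cdrMutationRate, sigmaBase = sigmaBase,
       sigmaSlope = sigmaSlope, orientationJitter = orientationJitter,
       h3InsertLengths = h3InsertLengths,
       resolutionRange = resolutionRange, seed = seed)
}

rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Generate one idealised Fv structure
#'
#' Builds a chemically complete structure for the given (possibly mutated)
#' domain sequences: numbered against the consensus, framework on the
#' canonical helical path, CDR loops on anchor-to-anchor arcs, side chains
#' sampled from the rotamer library. Deterministic for a fixed seed.
#'
#' @param id structure id.
#' @param heavy,light domain sequences (default: the bundled consensus;
#'   NULL drops the chain - heavy-only gives a VHH).
#' @param seed integer seed for rotamer sampling and noise.
#' @param noiseSigma per-residue rigid displacement sd (A), applied to all
#'   atoms of a residue so internal geometry is preserved.
#' @param lightRotation small rotation (degrees) applied to the light
#'   domain about a random axis through its centroid (inter-domain
#'   orientation jitter).
#' @param sideChains build side chains (TRUE) or backbone only.
#' @param set CDR definition set.
#' @return an [FvStructure-class].
#' @export
makeIdealizedFv <- function(id = "fx", heavy = NULL, light = NULL,
                            seed = 1, noiseSigma = 0, lightRotation = 0,
                            sideChains = TRUE, set = "north") {
  if (is.null(heavy) && is.null(light)) {
    heavy <- paste(consensusSequence("H")$aa, collapse = "")
    light <- paste(consensusSequence("L")$aa, collapse = "")
  }
  set.seed(seed)
  lib <- rotamerLibrary()
  radii <- vdwRadii()
  defs <- cdrDefinitions(set)
  atoms <- NULL
  for (ch in c("H", "L")) {
    seq <- if (ch == "H") heavy else light
    if (is.null(seq)) next
    res <- numberSequence(seq, ch)
    ca <- domainCaPath(res, defs[defs$chain == ch, ])
    bb <- backboneFromCa(ca)
    if (ch == "L") {
      centroid <- colMeans(ca)
      R <- if (lightRotation != 0)
        rotationMatrix(rnorm(3), rnorm(1, 0, lightRotation)) else diag(3)
      mv <- function(m)
        sweep(sweep(m, 2, centroid) %*% t(R), 2, -(centroid + DOMAIN_OFFSET))
      ca <- mv(ca); bb <- lapply(bb, mv)
    }
    n <- nrow(res)
    resRow <- function(i, at, el) data.frame(
      chain = ch, pos = res$pos[i], ins = res$ins[i], aa = res$aa[i],
      region = NA_character_, atom = rownames(at), element = el,
      x = at[, 1], y = at[, 2], z = at[, 3], occ = 1, b = 0,
      stringsAsFactors = FALSE)
    cur <- do.call(rbind, lapply(seq_len(n), function(i)
      resRow(i, rbind(N = bb$N[i, ], CA = ca[i, ], C = bb$C[i, ],
                      O = bb$O[i, ]), c("N", "C", "C", "O"))))
    if (sideChains) {
      # place side chains sequentially, taking the first clash-free rotamer
      # in probability-weighted random order (least-clashing fallback)
      for (i in seq_len(n)) {
        aa <- res$aa[i]
        if (aa %in% c("G", "X")) next
        bbi <- list(N = bb$N[i, ], CA = ca[i, ], C = bb$C[i, ])
        other <- cur[!(cur$pos == res$pos[i] & cur$ins == res$ins[i]), ]
        cand <- lib[lib$aa == aa, , drop = FALSE]
        ord <- if (nrow(cand) > 1)
          sample.int(nrow(cand), prob = cand$prob) else seq_len(nrow(cand))
        best <- NULL; bestClash <- Inf
        for (j in if (aa == "A") 0L else ord) {
          chis <- if (j > 0)
            as.numeric(cand[j, c("chi1", "chi2", "chi3", "chi4")])
          else numeric(0)
          sc <- buildSideChain(aa, bbi, chis)
          ncl <- countTrialClashes(sc, attr(sc, "element"), other, radii)
          if (ncl < bestClash) { bestClash <- ncl; best <- sc }
          if (ncl == 0L) break
        }
        cur <- rbind(cur, resRow(i, best, attr(best, "element")))
      }
    }
    # per-residue rigid displacement preserves internal geometry; the
    # displacement field is smoothed along the chain (window 5) so that,
    # as in real structural variation, neighbouring residues move
    # together and the backbone stays contiguous
    w <- 5L
    raw <- matrix(rnorm(3 * (n + w - 1L)), n + w - 1L, 3)
    shift <- apply(raw, 2, function(x)
      as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[w:(n + w - 1L)])
    shift <- shift * sqrt(w) * noiseSigma
    ri <- match(paste(cur$pos, cur$ins), paste(res$pos, res$ins))
    cur[, c("x", "y", "z")] <- cur[, c("x", "y", "z")] + shift[ri, ]
    atoms <- rbind(atoms, cur)
  }
  fv <- fvStructure(atoms, id = id)
  assignRegions(fv, set)
}

## mutates an exact count of positions (round(rate * n)) so the realised
## identity to the base sequence is controlled, not merely expected
mutateSeq <- function(seq, idx, rate) {
  aa <- strsplit(seq, "")[[1]]
  k <- round(rate * length(idx))
  hit <- if (k > 0) sample(idx, k) else integer(0)
  for (i in hit) aa[i] <- sample(setdiff(AA_ONE, c(aa[i], "C", "P")), 1)
  paste(aa, collapse = "")
}

insertH3 <- function(seq, nIns) {
  if (nIns == 0) return(seq)
  cons <- paste(consensusSequence("H")$aa, collapse = "")
  d <- cdrDefinitions("north")
  d <- d[d$chain == "H" & d$cdr == 3, ]
  mid <- floor((d$start + d$end) / 2)
  ins <- paste(sample(c("G", "S", "Y", "D"), nIns, replace = TRUE),
               collapse = "")
  paste0(substr(seq, 1, mid), ins, substr(seq, mid + 1, nchar(seq)))
}

#' Generate a template family with controlled identity/RMSD structure
#'
#' Derives `nStructures` members from the consensus by per-member framework
#' mutation (rates spanning the global-template identity threshold), light
#' CDR mutation, optional CDRH3 length variation, per-residue coordinate
#' noise growing linearly with the framework mutation rate (the recorded
#' ground-truth trend), and a small random inter-domain rotation. Pairwise
#' framework RMSD therefore grows stochastically with sequence distance,
#' as in a real template library.
#'
#' @param spec a [fixtureSpec()].
#' @param chains `"HL"` for paired members, `"H"` for a VHH family.
#' @param sideChains build side chains (TRUE) or backbone-only members
#'   (faster; sufficient for backbone RMSD protocols).
#' @return list with `structures` (named list of [FvStructure-class]),
#'   `resolutions` (named numeric) and `truth` (data.frame of generating
#'   parameters per member).
#' @export
makeTemplateFamily <- function(spec = fixtureSpec(), chains = "HL",
                               sideChains = TRUE) {
  set.seed(spec$seed)
  consH <- paste(consensusSequence("H")$aa, collapse = "")
  consL <- paste(consensusSequence("L")$aa, collapse = "")
  defs <- cdrDefinitions("north")
  fwIdx <- function(seq, ch) {
    d <- defs[defs$chain == ch, ]
    idx <- seq_len(nchar(seq))
    inCdr <- rep(FALSE, nchar(seq))
    for (k in seq_len(nrow(d)))
      inCdr[d$start[k]:d$end[k]] <- TRUE
    idx[!inCdr]
  }
  cdrIdx <- function(seq, ch) setdiff(seq_len(nchar(seq)), fwIdx(seq, ch))
  structures <- list(); truth <- list()
  resolutions <- numeric(0)
  for (i in seq_len(spec$nStructures)) {
    id <- sprintf("fx%03d", i)
    fwRate <- runif(1, spec$fwMutationRange[1], spec$fwMutationRange[2])
    h3ins <- if (length(spec$h3InsertLengths) == 1L)
      spec$h3InsertLengths else sample(spec$h3InsertLengths, 1)
    h <- mutateSeq(consH, fwIdx(consH, "H"), fwRate)
    h <- mutateSeq(h, cdrIdx(consH, "H"), spec$cdrMutationRate)
    h <- insertH3(h, h3ins)
    l <- if (grepl("L", chains)) {
      l0 <- mutateSeq(consL, fwIdx(consL, "L"), fwRate)
      mutateSeq(l0, cdrIdx(consL, "L"), spec$cdrMutationRate)
    } else NULL
    sigma <- spec$sigmaBase + spec$sigmaSlope * fwRate
    res <- round(runif(1, spec$resolutionRange[1], spec$resolutionRange[2]), 2)
    fv <- makeIdealizedFv(
      id, heavy = if (grepl("H", chains)) h else NULL, light = l,
      seed = spec$seed * 1000L + i, noiseSigma = sigma,
      lightRotation = spec$orientationJitter, sideChains = sideChains)
    structures[[id]] <- fv
    resolutions[id] <- res
    truth[[i]] <- data.frame(id = id, fwRate = fwRate, sigma = sigma,
                             h3Insert = h3ins, resolution = res)
  }
  list(structures = structures, resolutions = resolutions,
       truth = do.call(rbind, truth))
}

#' Generate a synthetic calibration table with a known generating CDF
#'
#' Draws RMSD observations from per-bin exponential distributions so that
#' the estimated conditional probabilities can be checked against the
#' closed-form generating CDF `1 - exp(-rate * x)`.
#'
#' @param bins data.frame with columns `cond` and `rate` (exponential rate
#'   per conditioning bin).
#' @param n total number of rows (split evenly over bins).
#' @param seed integer seed.
#' @param kind,condType passed to [calibrationTable()].
#' @return a [CalibrationTable-class]; the generating parameters are
#'   attached as attribute `"truth"`.
#' @export
makeCalibrationTable <- function(bins, n, seed = 1, kind = "synthetic",
                                 condType = "identity") {
  if (n <= 0) stop("empty calibration table: n must be positive")
  set.seed(seed)
  bin <- sample(rep_len(seq_len(nrow(bins)), n))
  tab <- calibrationTable(bins$cond[bin], rexp(n, bins$rate[bin]),
                          kind, condType)
  attr(tab, "truth") <- bins
  tab
}
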