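# Shared fixtures, built once per test run.

consensusH <- function() paste(consensusSequence("H")$aa, collapse = "")
consensusL <- function() paste(consensusSequence("L")$aa, collapse = "")

# small paired family, all members within the 2.5 A template cutoff, with
# stores and an idealised noise-free reference structure
.fixtureCache <- new.env()

testFamily <- function() {
  if (is.null(.fixtureCache$fam)) {
    fam <- makeTemplateFamily(
      fixtureSpec(nStructures = 8, resolutionRange = c(1.3, 2.4),
                  seed = 301),
      sideChains = FALSE)
    .fixtureCache$fam <- list(
      fam = fam,
      templates = buildTemplateStore(fam$structures, fam$resolutions),
      fragments = buildFragmentStores(fam$structures, fam$resolutions))
  }
  .fixtureCache$fam
}

idealFv <- function() {
  if (is.null(.fixtureCache$ideal))
    .fixtureCache$ideal <- makeIdealizedFv("ideal", seed = 42)
  .fixtureCache$ideal
}

# minimal hand-built structure: a run of residues of one type on a
# straightish backbone, for chi-angle and clash micro-tests
miniChain <- function(aas, chis = NULL, spacing = 6) {
  rows <- list()
  for (i in seq_along(aas)) {
    off <- c((i - 1) * spacing, 0, 0)
    N <- off + c(0, 1.2, 0); CA <- off; C <- off + c(1.2, -0.8, 0)
    at <- rbind(N = N, CA = CA, C = C, O = C + c(0, -1.23, 0))
    el <- c("N", "C", "C", "O")
    if (!aas[i] %in% c("G", "X")) {
      sc <- buildSideChain(aas[i], list(N = N, CA = CA, C = C),
                           if (is.null(chis)) c(180, 180, 180, 180)
                           else chis[[i]])
      at <- rbind(at, sc)
      el <- c(el, attr(sc, "element"))
    }
    rows[[i]] <- data.frame(
      chain = "H", pos = i, ins = "", aa = aas[i], region = "FW",
      atom = rownames(at), element = el, x = at[, 1], y = at[, 2],
      z = at[, 3], occ = 1, b = 0, stringsAsFactors = FALSE)
  }
  fvStructure(do.call(rbind, rows), id = "mini", cdrDefinition = "north")
}

# independent quaternion-based superposition oracle (Horn 1987)
quaternionRmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}
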