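# two isolated "residues" carrying one carbon atom each, a set distance apart
twoCarbons <- function(d) {
  atoms <- data.frame(
    chain = "H", pos = c(1L, 5L), ins = "", aa = "G", region = "FW",
    atom = "CA", element = "C", x = c(0, d), y = 0, z = 0, occ = 1, b = 0,
    stringsAsFactors = FALSE)
  fvStructure(atoms, id = "cc", cdrDefinition = "north")
}

test_that("the 65% van der Waals rule gives a strict 2.21 A carbon threshold", {
  hit <- detectClashes(twoCarbons(2.20))
  expect_false(hit$clashFree)
  expect_equal(hit$nClashes, 1L)
  expect_equal(hit$clashes$threshold, 0.65 * (1.7 + 1.7))
  # exactly at the threshold: not a clash (strict less-than)
  expect_true(detectClashes(twoCarbons(2.21))$clashFree)
  expect_true(detectClashes(twoCarbons(3.0))$clashFree)
  # a different factor moves the threshold
  expect_false(detectClashes(twoCarbons(2.5), factor = 0.75)$clashFree)
})

test_that("clash detection excludes bonded and 1-3 pairs and errors on unknown elements", {
  fv <- miniChain(c("S", "S"), spacing = 30)
  # covalent N-CA, CA-C, C-O, CA-CB, CB-OG distances are all far below the
  # clash threshold, yet a well-formed residue reports clash-free
  expect_true(detectClashes(fv)$clashFree)
  bad <- fv
  bad@atoms$element[1] <- "ZZ"
  expect_error(detectClashes(bad), "ZZ")
})

test_that("clash detection agrees with the O(n^2) oracle on random clouds", {
  set.seed(21)
  radii <- vdwRadii()
  for (rep in 1:3) {
    n <- 120
    atoms <- data.frame(
      chain = "H", pos = seq_len(n) * 5L, ins = "", aa = "G", region = "FW",
      atom = "CA", element = sample(c("C", "N", "O", "S"), n, TRUE),
      x = runif(n, 0, 22), y = runif(n, 0, 22), z = runif(n, 0, 22),
      occ = 1, b = 0, stringsAsFactors = FALSE)
    fv <- fvStructure(atoms, id = "cloud", cdrDefinition = "north")
    got <- detectClashes(fv)$nClashes
    # residues are spaced 5 scheme positions apart: no bonds, no exclusions
    a <- fvAtoms(fv)
    brute <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d < 0.65 * (radii[a$element[i]] + radii[a$element[j]]) - 1e-9)
        brute <- brute + 1L
    }
    expect_equal(got, brute)
  }
})

test_that("clash detection is invariant under rigid motion", {
  fv <- idealFv()
  n0 <- detectClashes(fv)$nClashes
  set.seed(22)
  R <- randomRotation()
  moved <- fv
  a <- fvAtoms(moved)
  a[, c("x", "y", "z")] <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R),
                                 2, c(5, -3, 11), "+")
  moved@atoms <- a
  expect_equal(detectClashes(moved)$nClashes, n0)
})

test_that("partial prediction retains identical residues and only rebuilds changes", {
  fv <- idealFv()
  same <- partialSideChainPrediction(fv, fv)
  expect_equal(fvAtoms(same), fvAtoms(fv))
  # mutate one surface residue: only that residue's side chain changes
  r <- FvBuilder:::residueTable(fv)
  pick <- r[r$aa == "S" & r$chain == "H", ][1, ]
  tgt <- setNames(r$aa, r$key)
  tgt[pick$key] <- "L"
  out <- partialSideChainPrediction(fv, tgt)
  a0 <- fvAtoms(fv); a1 <- fvAtoms(out)
  k0 <- FvBuilder:::resKey(a0$chain, a0$pos, a0$ins)
  k1 <- FvBuilder:::resKey(a1$chain, a1$pos, a1$ins)
  expect_equal(a1[k1 != pick$key, ], a0[k0 != pick$key, ],
               ignore_attr = TRUE)
  expect_equal(sort(a1$atom[k1 == pick$key]),
               sort(c("N", "CA", "C", "O", sideChainAtoms("L"))))
  # backbone never moves
  bb0 <- a0[a0$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  bb1 <- a1[a1$atom %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  expect_equal(bb1, bb0, ignore_attr = TRUE)
})

test_that("a rebuilt unclashed residue takes the library's top rotamer", {
  fv <- miniChain(c("S", "S"), spacing = 30)
  r <- FvBuilder:::residueTable(fv)
  tgt <- setNames(c("C", "S"), r$key)   # mutate residue 1 to Cys
  out <- partialSideChainPrediction(fv, tgt)
  lib <- rotamerLibrary()
  top <- lib[lib$aa == "C", ]
  top <- top$chi1[which.max(top$prob)]
  chi <- FvBuilder:::measureChi(out, 1)
  expect_equal(unname(chi[r$key[1]]), top, tolerance = 1e-6)
})

test_that("complete prediction rebuilds everything except Gly and Ala", {
  fv <- idealFv()
  out <- completeSideChainPrediction(fv)
  a0 <- fvAtoms(fv); a1 <- fvAtoms(out)
  # Gly/Ala untouched
  for (aa in c("G", "A")) {
    expect_equal(a1[a1$aa == aa, ], a0[a0$aa == aa, ], ignore_attr = TRUE)
  }
  # atom counts match residue chemistry
  r <- FvBuilder:::residueTable(out)
  k1 <- FvBuilder:::resKey(a1$chain, a1$pos, a1$ins)
  for (i in sample(nrow(r), 20)) {
    expect_setequal(a1$atom[k1 == r$key[i]],
                    c("N", "CA", "C", "O", sideChainAtoms(r$aa[i])))
  }
})

test_that("clash resolution is staged and never increases the clash count", {
  clean <- miniChain(c("S", "S"), spacing = 30)
  res <- resolveClashes(clean)
  expect_equal(res$stage, "none")
  expect_equal(fvAtoms(res$structure), fvAtoms(clean))
  # craft a resolvable clash: two facing Met residues whose extended
  # rotamers collide; re-sampling the clashing residues fixes it
  lib <- rotamerLibrary()
  m <- lib[lib$aa == "M", ]
  fv <- miniChain(c("M", "M"), spacing = 10,
                  chis = list(c(-65, 180, 75, NA), c(-65, 180, 75, NA)))
  # rotate residue 2 to face residue 1 by mirroring its coordinates
  a <- fvAtoms(fv)
  i2 <- a$pos == 2
  a$x[i2] <- 20 - (a$x[i2] - 0)   # reflect about x = 10
  fv@atoms <- a
  n0 <- detectClashes(fv)$nClashes
  res2 <- resolveClashes(fv)
  expect_lte(res2$nClashes, n0)
  if (n0 > 0) expect_true(res2$stage %in% c("local", "global"))
})
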