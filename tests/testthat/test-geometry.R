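test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  fit <- kabschSuperpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 degrees about z
  Q <- sweep(P %*% t(R), 2, c(3, -2, 7), "+")
  fit <- kabschSuperpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(applyTransform(P, fit), Q, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches an independent quaternion-fit oracle", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    expect_equal(kabschSuperpose(P, Q)$rmsd, quaternionRmsd(P, Q),
                 tolerance = 1e-8)
  }
  # 4-point toy set with a single displaced coordinate
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Q <- P; Q[4, 3] <- 1.5
  expect_equal(kabschSuperpose(P, Q)$rmsd, quaternionRmsd(P, Q),
               tolerance = 1e-10)
})

test_that("Kabsch rejects degenerate input", {
  expect_error(kabschSuperpose(matrix(rnorm(6), 2, 3),
                               matrix(rnorm(6), 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(matrix(rnorm(15), 5, 3), line), "degenerate")
})

test_that("Fv RMSD matches the Monte-Carlo noise expectation", {
  fv <- testFamily()$fam$structures[[1]]
  expect_equal(fvRmsd(fv, fv)$rmsd, 0, tolerance = 1e-10)
  set.seed(3)
  noisy <- fv
  a <- fvAtoms(noisy)
  bb <- a$atom %in% c("N", "CA", "C", "O")
  a[bb, c("x", "y", "z")] <- a[bb, c("x", "y", "z")] +
    matrix(rnorm(3 * sum(bb), 0, 0.1), sum(bb), 3)
  noisy@atoms <- a
  rep <- fvRmsd(noisy, fv)
  expect_gt(rep$rmsd, sqrt(3) * 0.1 * 0.8)   # 3D iid noise, fit absorbs little
  expect_lt(rep$rmsd, sqrt(3) * 0.1 * 1.2)
  expect_equal(rep$nAtoms,
               4 * nrow(FvBuilder:::residueTable(fv)))
})

test_that("framework RMSD ignores CDR perturbations and composes with Kabsch", {
  fv <- testFamily()$fam$structures[[1]]
  pert <- fv
  a <- fvAtoms(pert)
  cdr <- !is.na(a$region) & a$region != "FW"
  a[cdr, c("x", "y", "z")] <- a[cdr, c("x", "y", "z")] + 5
  pert@atoms <- a
  expect_equal(frameworkRmsd(pert, fv, "H")$rmsd, 0, tolerance = 1e-10)
  # compositional oracle: direct Kabsch on the extracted FW backbone
  other <- testFamily()$fam$structures[[2]]
  p <- FvBuilder:::pairedBackbone(fv, other, chains = "H", regions = "FW")
  expect_equal(frameworkRmsd(fv, other, "H")$rmsd,
               kabschSuperpose(p$model, p$native)$rmsd, tolerance = 1e-10)
})

test_that("CDR RMSD uses a framework fit without refitting the loop", {
  fv <- testFamily()$fam$structures[[1]]
  expect_equal(cdrRmsd(fv, fv, "H", 3)$rmsd, 0, tolerance = 1e-10)
  # rigid 1 A offset of the loop alone -> RMSD exactly 1, FW unchanged
  pert <- fv
  a <- fvAtoms(pert)
  sel <- a$chain == "H" & !is.na(a$region) & a$region == "CDR3"
  a$x[sel] <- a$x[sel] + 1
  pert@atoms <- a
  expect_equal(cdrRmsd(pert, fv, "H", 3)$rmsd, 1, tolerance = 1e-9)
  expect_equal(frameworkRmsd(pert, fv, "H")$rmsd, 0, tolerance = 1e-10)
  # loop length mismatch is an error, not a partial RMSD
  short <- fv
  a <- fvAtoms(short)
  drop <- which(sel & a$pos == max(a$pos[sel]))
  short@atoms <- a[-drop, ]
  expect_error(cdrRmsd(short, fv, "H", 3), "mismatch")
})

test_that("one-chain and both-chain framework fits differ under domain reorientation", {
  fv <- idealFv()
  rot <- fv
  a <- fvAtoms(rot)
  l <- a$chain == "L"
  m <- as.matrix(a[l, c("x", "y", "z")])
  ctr <- colMeans(m)
  R <- FvBuilder:::rotationMatrix(c(0, 0, 1), 8)
  a[l, c("x", "y", "z")] <- sweep(sweep(m, 2, ctr) %*% t(R), 2, -ctr)
  rot@atoms <- a
  one <- cdrRmsd(rot, fv, "L", 3, bothChains = FALSE)$rmsd
  both <- cdrRmsd(rot, fv, "L", 3, bothChains = TRUE)$rmsd
  expect_equal(one, 0, tolerance = 1e-8)   # L-only fit absorbs the rotation
  expect_gt(both, 0.5)                     # both-chain fit cannot
})

test_that("dihedral angles follow the IUPAC convention", {
  p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.5); p1 <- c(1, 0, -0.5)
  expect_equal(dihedralAngle(p1, p2, p3, c(1, 0, 2)), 0)          # cis
  expect_equal(abs(dihedralAngle(p1, p2, p3, c(-1, 0, 2))), 180)  # trans
  # quarter twists agree with the bio3d torsion oracle in value and sign
  for (p4 in list(c(0, 1, 2), c(0, -1, 2), c(1, 1, 2))) {
    ref <- bio3d::torsion.xyz(c(p1, p2, p3, p4))
    expect_equal(dihedralAngle(p1, p2, p3, p4), as.numeric(ref),
                 tolerance = 1e-6)
  }
})

test_that("chi1 accuracy applies the 40-degree circular cutoff", {
  base <- miniChain(rep("S", 4), chis = rep(list(c(-65, NA, NA, NA)), 4))
  expect_equal(chi1Accuracy(base, base), 100)
  variant <- function(offsets) {
    miniChain(rep("S", 4),
              chis = lapply(offsets, function(o) c(-65 + o, NA, NA, NA)))
  }
  # 39 degrees counts as correct, 41 does not
  expect_equal(chi1Accuracy(variant(c(39, 0, 0, 0)), base), 100)
  expect_equal(chi1Accuracy(variant(c(41, 0, 0, 0)), base), 75)
  # circular wrap: +350 is a -10 offset
  expect_equal(chi1Accuracy(variant(c(350, 0, 0, 0)), base), 100)
  # error when nothing is comparable
  gly <- miniChain(rep("G", 3))
  expect_error(chi1Accuracy(gly, gly), "comparable")
})

test_that("chi1 accuracy decreases as angular noise grows", {
  set.seed(4)
  n <- 40
  base <- miniChain(rep("S", n), chis = rep(list(c(-65, NA, NA, NA)), n))
  acc <- vapply(c(10, 45, 120), function(s) {
    noisy <- miniChain(rep("S", n),
                       chis = lapply(rnorm(n, 0, s),
                                     function(o) c(-65 + o, NA, NA, NA)))
    chi1Accuracy(noisy, base)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_true(all(acc >= 0 & acc <= 100))
})

test_that("chi1+2 accuracy requires both angles within the cutoff", {
  n <- 3
  mk <- function(c1, c2) miniChain(rep("L", n),
                                   chis = rep(list(c(c1, c2, NA, NA)), n))
  base <- mk(-65, 175)
  expect_equal(chi12Accuracy(base, base), 100)
  expect_equal(chi12Accuracy(mk(-65, 175 + 60), base), 0)  # chi2 off
  expect_equal(chi12Accuracy(mk(-65 + 60, 175), base), 0)  # chi1 off
})
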