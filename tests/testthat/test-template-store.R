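test_that("template store applies the resolution filter", {
  fam <- makeTemplateFamily(
    fixtureSpec(nStructures = 10, resolutionRange = c(2.0, 3.0), seed = 401),
    sideChains = FALSE)
  res <- fam$resolutions
  keep <- sum(res <= 2.5)
  store <- buildTemplateStore(fam$structures, res, cutoff = 2.5)
  expect_equal(length(store@records), keep)
  expect_lt(keep, 10)
  # infinite cutoff keeps everything; all-filtered errors
  expect_equal(length(buildTemplateStore(fam$structures, res,
                                         cutoff = Inf)@records), 10)
  expect_error(buildTemplateStore(fam$structures, res, cutoff = 0.5),
               "empty")
})

test_that("nanobody structures index with the heavy chain only", {
  vhh <- makeIdealizedFv("vhh1", heavy = consensusH(), seed = 6,
                         sideChains = FALSE)
  store <- buildTemplateStore(list(vhh), 2.0)
  expect_identical(store@records[["vhh1"]]$chains, "H")
})

test_that("fragment stores hold one loop per CDR per structure", {
  tf <- testFamily()
  for (ty in c("L1", "L2", "L3", "H1", "H2", "H3")) {
    st <- tf$fragments[[ty]]
    expect_equal(length(st@fragments), length(tf$fam$structures))
    for (f in st@fragments) {
      expect_equal(f$length, nchar(f$sequence))
      expect_equal(nrow(f$loopBB), 4 * f$length)
      expect_equal(nrow(f$nBB), 4 * st@nAnchor)
      expect_equal(nrow(f$cBB), 4 * st@nAnchor)
    }
  }
  # rebuilding the stores conserves their sizes (idempotence)
  again <- buildFragmentStores(tf$fam$structures, tf$fam$resolutions)
  for (ty in names(tf$fragments))
    expect_equal(length(again[[ty]]@fragments),
                 length(tf$fragments[[ty]]@fragments))
  # loop length equals the source CDR interval content
  defs <- cdrDefinitions("north")
  d <- defs[defs$chain == "L" & defs$cdr == 2, ]
  f1 <- tf$fragments$L2@fragments[[1]]
  src <- tf$fam$structures[[f1$sourceId]]
  r <- FvBuilder:::residueTable(src)
  expect_equal(f1$length,
               sum(r$chain == "L" & r$pos >= d$start & r$pos <= d$end))
})

test_that("sequence-identical loops are retained (redundant-set rule)", {
  a <- makeIdealizedFv("dupA", seed = 7, sideChains = FALSE)
  b <- makeIdealizedFv("dupB", seed = 8, noiseSigma = 0.3,
                       sideChains = FALSE)
  stores <- buildFragmentStores(list(a, b), c(1.8, 1.9))
  expect_equal(length(stores$H3@fragments), 2)
  expect_equal(stores$H3@fragments[[1]]$sequence,
               stores$H3@fragments[[2]]$sequence)
})

test_that("global template selection requires 80% on both chains", {
  mk <- function(id, hRate, lRate, res, seed) {
    set.seed(seed)
    h <- FvBuilder:::mutateSeq(consensusH(), seq_len(nchar(consensusH())),
                               hRate)
    l <- FvBuilder:::mutateSeq(consensusL(), seq_len(nchar(consensusL())),
                               lRate)
    makeIdealizedFv(id, heavy = h, light = l, seed = seed,
                    sideChains = FALSE)
  }
  target <- numberTarget(consensusH(), consensusL())
  # one record above threshold on both chains -> global
  good <- mk("good", 0.1, 0.1, 1.9, 11)
  far <- mk("far", 0.35, 0.35, 1.5, 12)
  store <- buildTemplateStore(list(good, far), c(1.9, 1.5))
  sel <- selectFrameworkTemplate(target, store)
  expect_equal(sel@mode, "global")
  expect_equal(unname(sel@vh), "good")
  expect_equal(unname(sel@orientationSource), "good")
  # complementary specialists -> hybrid with per-chain donors
  hOnlyGood <- mk("hdon", 0.02, 0.35, 1.8, 13)
  lOnlyGood <- mk("ldon", 0.35, 0.02, 1.7, 14)
  store2 <- buildTemplateStore(list(hOnlyGood, lOnlyGood), c(1.8, 1.7))
  sel2 <- selectFrameworkTemplate(target, store2)
  expect_equal(sel2@mode, "hybrid")
  expect_equal(unname(sel2@vh), "hdon")
  expect_equal(unname(sel2@vl), "ldon")
  # the orientation source is the best global candidate below threshold
  expect_true(sel2@orientationSource %in% c("hdon", "ldon"))
})

test_that("selection is deterministic and exclude-identical drops self", {
  tf <- testFamily()
  native <- tf$fam$structures[[1]]
  target <- numberTarget(fvSequence(native, "H"), fvSequence(native, "L"),
                         id = fvId(native))
  s1 <- selectFrameworkTemplate(target, tf$templates)
  s2 <- selectFrameworkTemplate(target, tf$templates)
  expect_equal(s1@vh, s2@vh)
  expect_equal(s1@mode, s2@mode)
  # the target itself is in the store: selected at 100% identity
  expect_equal(unname(s1@vh), fvId(native))
  expect_equal(s1@vhIdentity, 100)
  sx <- selectFrameworkTemplate(target, tf$templates,
                                excludeIdentical = TRUE)
  expect_false(unname(sx@vh) == fvId(native))
})

test_that("nanobody targets select a single-chain global template", {
  tf <- testFamily()
  target <- numberTarget(consensusH(), NULL)
  sel <- selectFrameworkTemplate(target, tf$templates)
  expect_equal(sel@mode, "global")
  expect_true(is.na(sel@vl))
  expect_equal(unname(sel@orientationSource), unname(sel@vh))
})

test_that("pairwise superimposition table matches the direct protocols", {
  tf <- testFamily()
  st <- tf$fam$structures
  tab <- pairwiseSuperimpositionTable(st, "vh")
  n <- length(st)
  expect_equal(nrow(tab), n * (n - 1) / 2)
  expect_true(all(tab$identity >= 0 & tab$identity <= 100))
  expect_true(all(tab$rmsd >= 0))
  expect_false(any(tab$a == tab$b))
  i <- 3
  expect_equal(tab$rmsd[i],
               frameworkRmsd(st[[tab$a[i]]], st[[tab$b[i]]], "H")$rmsd,
               tolerance = 1e-10)
  expect_equal(tab$identity[i],
               frameworkIdentity(st[[tab$a[i]]], st[[tab$b[i]]], "H"))
  # a structure against a coordinate-identical copy: identity 100, RMSD 0
  dup <- st[[1]]; dup@id <- "copy"
  tab2 <- pairwiseSuperimpositionTable(list(st[[1]], dup), "fv")
  expect_equal(tab2$identity, 100)
  expect_equal(tab2$rmsd, 0, tolerance = 1e-10)
})
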