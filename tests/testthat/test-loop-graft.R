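test_that("substitution score is the position-wise BLOSUM62 sum", {
  expect_equal(substitutionScore(strrep("A", 10), strrep("A", 10)), 40L)
  expect_equal(substitutionScore("NG", "NG"), 12L)
  expect_error(substitutionScore("AA", "AAA"), "equal length")
  # brute-force oracle on random pairs
  set.seed(11)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- get("BLOSUM62")
  aas <- rownames(m)[1:20]
  for (i in 1:10) {
    n <- sample(5:14, 1)
    a <- sample(aas, n, replace = TRUE)
    b <- sample(aas, n, replace = TRUE)
    brute <- 0L
    for (k in seq_len(n)) brute <- brute + m[a[k], b[k]]
    expect_equal(substitutionScore(paste(a, collapse = ""),
                                   paste(b, collapse = "")), brute)
  }
})

test_that("decoys rank by anchor RMSD, not substitution score", {
  frag <- function(id, res = 2.0) list(id = id, resolution = res)
  d1 <- list(fragment = frag("a"), score = 26, anchorRmsd = 0.188,
             spanMismatch = 0, stage = "cdr-db")
  d2 <- list(fragment = frag("b"), score = 47, anchorRmsd = 0.223,
             spanMismatch = 0, stage = "cdr-db")
  ranked <- rankDecoys(list(d2, d1))
  expect_equal(ranked[[1]]$anchorRmsd, 0.188)
  expect_equal(ranked[[1]]$score, 26)
  # ties in anchor RMSD break by higher score, then resolution, then id
  t1 <- list(fragment = frag("x", 2.2), score = 30, anchorRmsd = 0.1)
  t2 <- list(fragment = frag("y", 2.2), score = 45, anchorRmsd = 0.1)
  t3 <- list(fragment = frag("z", 1.5), score = 45, anchorRmsd = 0.1)
  ranked <- rankDecoys(list(t1, t2, t3))
  expect_equal(ranked[[1]]$fragment$id, "z")
  expect_equal(ranked[[2]]$fragment$id, "y")
})

test_that("candidate search filters by span and score and ranks self first", {
  tf <- testFamily()
  native <- tf$fam$structures[[1]]
  anchors <- FvBuilder:::anchorsForCdr(native, "H", 3, 5L)
  defs <- cdrDefinitions("north")
  d <- defs[defs$chain == "H" & defs$cdr == 3, ]
  r <- FvBuilder:::residueTable(native)
  targetSeq <- paste(r$aa[r$chain == "H" & r$pos >= d$start &
                            r$pos <= d$end], collapse = "")
  dec <- candidateDecoys(targetSeq, anchors, tf$fragments$H3)
  expect_gt(length(dec), 0)
  expect_equal(dec[[1]]$fragment$sourceId, fvId(native))  # self-fragment
  expect_lt(dec[[1]]$anchorRmsd, 1e-9)
  expect_true(all(diff(vapply(dec, `[[`, numeric(1), "anchorRmsd")) >= 0))
  # brute-force filter oracle over the store
  manual <- 0L
  for (f in tf$fragments$H3@fragments) {
    if (f$length != nchar(targetSeq)) next
    if (abs(f$span - anchors$span) > 0.8) next
    if (substitutionScore(targetSeq, f$sequence) < 25) next
    manual <- manual + 1L
  }
  expect_equal(length(dec), manual)
  # a passing decoy is excluded when the score threshold rises above it,
  # regardless of its anchor RMSD
  hi <- candidateDecoys(targetSeq, anchors, tf$fragments$H3,
                        scoreThreshold = max(vapply(dec, `[[`, numeric(1),
                                                    "score")) + 1)
  expect_lt(length(hi), length(dec))
  expect_false(fvId(native) %in%
                 vapply(hi, function(x) x$fragment$sourceId, character(1)) &&
                 length(hi) == length(dec))
  # empty store is an empty result, not an error
  empty <- new("FragmentStore", cdrType = "H3", nAnchor = 5L,
               fragments = list())
  expect_equal(length(candidateDecoys(targetSeq, anchors, empty)), 0)
})

test_that("grafting a self-fragment leaves coordinates unchanged", {
  tf <- testFamily()
  native <- tf$fam$structures[[1]]
  anchors <- FvBuilder:::anchorsForCdr(native, "L", 1, 5L)
  defs <- cdrDefinitions("north")
  d <- defs[defs$chain == "L" & defs$cdr == 1, ]
  r <- FvBuilder:::residueTable(native)
  tl <- r[r$chain == "L" & r$pos >= d$start & r$pos <= d$end,
          c("pos", "ins", "aa")]
  dec <- candidateDecoys(paste(tl$aa, collapse = ""), anchors,
                         tf$fragments$L1)
  self <- dec[[1]]
  expect_equal(self$fragment$sourceId, fvId(native))
  grafted <- graftLoop(native, self, "L", 1, tl)
  p <- FvBuilder:::pairedBackbone(grafted, native)
  expect_lt(max(abs(p$model - p$native)), 1e-6)
  expect_equal(nrow(FvBuilder:::residueTable(grafted)),
               nrow(FvBuilder:::residueTable(native)))
})

test_that("graft junction geometry stays within peptide range", {
  tf <- testFamily()
  native <- tf$fam$structures[[2]]
  target <- numberTarget(fvSequence(native, "H"), fvSequence(native, "L"),
                         id = "jt")
  sel <- selectFrameworkTemplate(target, tf$templates,
                                 excludeIdentical = TRUE)
  model <- assembleFramework(target, sel, tf$templates)
  out <- modelAllCdrs(model, target, tf$fragments,
                      excludeSources = fvId(native))
  # grafted loop length equals the target CDR length everywhere
  r <- FvBuilder:::residueTable(out$model)
  tr <- target
  for (ch in c("H", "L")) for (k in 1:3) {
    reg <- paste0("CDR", k)
    expect_equal(sum(r$chain == ch & r$region == reg),
                 sum(tr$chain == ch & tr$region == reg))
  }
  a <- fvAtoms(out$model)
  ca <- a[a$atom == "CA", ]
  for (ch in c("H", "L")) {
    m <- as.matrix(ca[ca$chain == ch, c("x", "y", "z")])
    d <- sqrt(rowSums((m[-1, ] - m[-nrow(m), ])^2))
    expect_true(all(d > 2.0 & d < 4.5))
  }
})

test_that("the cascade falls back through fv-db, seq-similar and ab initio", {
  tf <- testFamily()
  native <- tf$fam$structures[[1]]
  target <- numberTarget(fvSequence(native, "H"), fvSequence(native, "L"),
                         id = fvId(native))
  sel <- selectFrameworkTemplate(target, tf$templates)
  model <- assembleFramework(target, sel, tf$templates)
  stores <- tf$fragments
  res <- modelCdr(model, target, "H", 2, stores)
  expect_equal(res$provenance$stage, "cdr-db")
  # empty CDR-specific store: the Fv-wide database serves the loop
  s2 <- stores
  s2$H2 <- new("FragmentStore", cdrType = "H2", nAnchor = 5L,
               fragments = list())
  res2 <- modelCdr(model, target, "H", 2, s2)
  expect_equal(res2$provenance$stage, "fv-db")
  # every fragment fails the score filter: the most sequence-similar
  # length-matched loop is grafted, chosen by maximum substitution score
  res3 <- modelCdr(model, target, "H", 2, stores, scoreThreshold = 1e6)
  expect_equal(res3$provenance$stage, "seq-similar")
  tH2 <- paste(target$aa[target$chain == "H" & target$region == "CDR2"],
               collapse = "")
  h2len <- nchar(tH2)
  pool <- Filter(function(f) f$length == h2len && f$resolution <= 2.5,
                 c(stores$H2@fragments, stores$fv@fragments))
  poolScores <- vapply(pool, function(f)
    substitutionScore(tH2, f$sequence), numeric(1))
  expect_equal(res3$provenance$score, max(poolScores))
  # no length-matched fragment anywhere: structured ab initio signal
  s3 <- stores
  s3$H2 <- new("FragmentStore", cdrType = "H2", nAnchor = 5L,
               fragments = list())
  s3$fv@fragments <- Filter(function(f) f$length != h2len,
                            s3$fv@fragments)
  cond <- tryCatch(modelCdr(model, target, "H", 2, s3),
                   abInitioRequired = function(e) e)
  expect_s3_class(cond, "abInitioRequired")
  expect_equal(cond$chain, "H")
  expect_equal(cond$cdr, 2)
  expect_false(is.null(cond$nearestFragment))
})

test_that("loops are modelled in the fixed order for each chain layout", {
  tf <- testFamily()
  native <- tf$fam$structures[[1]]
  target <- numberTarget(fvSequence(native, "H"), fvSequence(native, "L"),
                         id = fvId(native))
  sel <- selectFrameworkTemplate(target, tf$templates)
  model <- assembleFramework(target, sel, tf$templates)
  out <- modelAllCdrs(model, target, tf$fragments)
  expect_equal(out$provenance$cdr, c("L2", "H2", "L1", "H1", "L3", "H3"))
  # VHH: heavy-only order conserved
  tH <- numberTarget(fvSequence(native, "H"), NULL, id = "vhh")
  selH <- selectFrameworkTemplate(tH, tf$templates)
  mH <- assembleFramework(tH, selH, tf$templates)
  outH <- modelAllCdrs(mH, tH, tf$fragments)
  expect_equal(outH$provenance$cdr, c("H2", "H1", "H3"))
  # light-only domain
  tL <- numberTarget(NULL, fvSequence(native, "L"), id = "vl")
  selL <- selectFrameworkTemplate(tL, tf$templates)
  mL <- assembleFramework(tL, selL, tf$templates)
  outL <- modelAllCdrs(mL, tL, tf$fragments)
  expect_equal(outL$provenance$cdr, c("L2", "L1", "L3"))
})
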