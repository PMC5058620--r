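## End-to-end orchestration: configuration, framework assembly with
## orientation transplant, the full build (template -> orientation -> loops
## -> side chains -> confidence + liabilities), calibration construction,
## and the benchmarking harness.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with its default:
#' global-template identity threshold 80%, template resolution cutoff
#' 2.5 A, confidence level 0.75, exposure threshold 10%, 5 anchor residues
#' per side, anchor-span tolerance 0.8 A, substitution-score threshold 25,
#' clash factor 0.65.
#'
#' @param identityThreshold global-mode framework identity threshold (%).
#' @param resolutionCutoff template resolution cutoff (A).
#' @param confidence confidence level for expected-RMSD annotation.
#' @param exposureThreshold liability exposure gate (% relative ASA).
#' @param nAnchor anchor residues per side for loop grafting.
#' @param spanTolerance anchor Calpha-separation tolerance (A).
#' @param scoreThreshold substitution-score filter threshold.
#' @param clashFactor van der Waals clash factor.
#' @param cdrSet CDR definition set name.
#' @param sideChains run side-chain completion and clash resolution.
#' @param liabilities scan sequence liabilities.
#' @param seed seed for any optional stochastic fixture generation; the
#'   modelling path itself is deterministic.
#' @return named list of settings.
#' @export
fvConfig <- function(identityThreshold = 80, resolutionCutoff = 2.5,
                     confidence = 0.75, exposureThreshold = 10,
                     nAnchor = 5L, spanTolerance = 0.8, scoreThreshold = 25,
                     clashFactor = 0.65, cdrSet = "north",
                     sideChains = TRUE, liabilities = TRUE, seed = 1L) {
  stopifnot(identityThreshold >= 0, identityThreshold <= 100,
            resolutionCutoff > 0, confidence >= 0, confidence <= 1,
            exposureThreshold >= 0, nAnchor >= 1, spanTolerance >= 0,
            clashFactor > 0, clashFactor < 1)
  list(identityThreshold = identityThreshold,
       resolutionCutoff = resolutionCutoff, confidence = confidence,
       exposureThreshold = exposureThreshold, nAnchor = as.integer(nAnchor),
       spanTolerance = spanTolerance, scoreThreshold = scoreThreshold,
       clashFactor = clashFactor, cdrSet = cdrSet,
       sideChains = sideChains, liabilities = liabilities,
       seed = as.integer(seed))
}

#' Assemble the framework model from a template selection
#'
#' Global mode copies both domains (and hence their relative orientation)
#' from the single template. Hybrid mode superimposes each donor chain's
#' framework backbone onto the corresponding chain of the orientation
#' source, so the assembled model inherits the source's VH-VL orientation
#' while keeping each donor's local framework geometry. Target residue
#' identities overwrite the template's at shared positions; side chains of
#' non-identical residues are stripped (completed later); template
#' positions absent from the target are dropped, and target positions
#' absent from the donor are reported with a warning.
#'
#' @param target residue table from [numberTarget()].
#' @param selection a [TemplateSelection-class].
#' @param store the [TemplateStore-class] the selection came from.
#' @return the assembled [FvStructure-class].
#' @export
assembleFramework <- function(target, selection, store) {
  chains <- unique(target$chain)
  src <- if (!is.na(selection@orientationSource))
    store@records[[selection@orientationSource]]$structure else NULL
  parts <- list()
  for (ch in chains) {
    donorId <- if (ch == "H") selection@vh else selection@vl
    if (is.na(donorId)) stop("no donor template for chain ", ch)
    rec <- store@records[[donorId]]
    if (is.null(rec) || !(ch %in% rec$chains))
      stop("donor template ", donorId, " lacks chain ", ch)
    donor <- rec$structure
    a <- donor@atoms[donor@atoms$chain == ch, ]
    if (selection@mode == "hybrid" && !is.null(src) &&
        fvId(donor) != fvId(src)) {
      p <- pairedBackbone(donor, src, chains = ch, regions = "FW")
      fit <- kabschSuperpose(p$model, p$native)
      a[, c("x", "y", "z")] <- applyTransform(coordMatrix(a), fit)
    }
    # overwrite residue identities with the target's
    tch <- target[target$chain == ch, ]
    tAa <- setNames(tch$aa, paste(tch$pos, tch$ins))
    dKey <- paste(a$pos, a$ins)
    keep <- dKey %in% names(tAa) |
      (!is.na(a$region) & a$region != "FW")       # CDR placeholders stay
    a <- a[keep, ]
    dKey <- dKey[keep]
    inT <- dKey %in% names(tAa)
    newAa <- ifelse(inT, tAa[dKey], a$aa)
    changed <- inT & newAa != a$aa
    a$aa <- newAa
    drop <- changed & !(a$atom %in% BACKBONE_ATOMS)
    a <- a[!drop, ]
    fwT <- paste(tch$pos, tch$ins)[tch$region == "FW"]
    missing <- setdiff(fwT, dKey)   # CDR positions are rebuilt by grafting
    if (length(missing))
      warning("target framework position(s) absent from donor ", donorId,
              " chain ", ch, ": ", paste(missing, collapse = ", "))
    parts[[ch]] <- a
  }
  fv <- fvStructure(do.call(rbind, parts), id = attr(target, "id") %||% "model",
                    cdrDefinition = "")
  assignRegions(fv, attr(target, "set") %||% "north")
}

regionLoopLength <- function(target, chain, cdr, set) {
  defs <- cdrDefinitions(set)
  d <- defs[defs$chain == chain & defs$cdr == cdr, ]
  sum(target$chain == chain & target$pos >= d$start & target$pos <= d$end)
}

#' Build a complete Fv model
#'
#' Runs the full pipeline: template selection, framework assembly with
#' orientation transplant, CDR loop grafting in the fixed order, partial
#' side-chain completion, staged clash resolution, per-region confidence
#' annotation and liability scanning. Deterministic for fixed inputs and
#' configuration.
#'
#' @param heavy,light target domain sequences (NULL to omit a chain;
#'   heavy-only models a VHH nanobody).
#' @param templates a [TemplateStore-class].
#' @param fragments fragment store list from [buildFragmentStores()].
#' @param calibration optional named list of [CalibrationTable-class]
#'   objects (`vh`, `vl`, `H1`..`L3`) for expected-RMSD annotation.
#' @param config a [fvConfig()] list.
#' @param excludeIdentical leave sequence-identical templates out.
#' @param excludeSources structure ids excluded from fragment searches.
#' @param id model id.
#' @return list with `model` (an [FvStructure-class]) and `report` (named
#'   list: `selection`, `regions` data.frame, `liabilities`, `clashStage`,
#'   `timings`).
#' @export
buildModel <- function(heavy = NULL, light = NULL, templates, fragments,
                       calibration = NULL, config = fvConfig(),
                       excludeIdentical = FALSE,
                       excludeSources = character(0), id = "target") {
  t0 <- Sys.time()
  target <- numberTarget(heavy, light, set = config$cdrSet, id = id)
  selection <- selectFrameworkTemplate(target, templates,
                                       threshold = config$identityThreshold,
                                       excludeIdentical = excludeIdentical)
  model <- assembleFramework(target, selection, templates)
  t1 <- Sys.time()
  loops <- modelAllCdrs(model, target, fragments,
                        spanTolerance = config$spanTolerance,
                        scoreThreshold = config$scoreThreshold,
                        excludeSources = excludeSources)
  model <- loops$model
  t2 <- Sys.time()
  clashStage <- NA_character_
  if (config$sideChains) {
    model <- partialSideChainPrediction(model, target,
                                        factor = config$clashFactor)
    relaxed <- resolveClashes(model, factor = config$clashFactor)
    model <- relaxed$structure
    clashStage <- relaxed$stage
  }
  t3 <- Sys.time()
  # region report: one row per modelled region (8 for an Fv, 4 for a VHH)
  chains <- unique(target$chain)
  rows <- list()
  for (ch in chains) {
    ident <- if (ch == "H") selection@vhIdentity else selection@vlIdentity
    tab <- if (!is.null(calibration))
      calibration[[if (ch == "H") "vh" else "vl"]] else NULL
    exp <- if (!is.null(tab))
      suppressWarnings(expectedRmsdAtConfidence(tab, ident,
                                                p = config$confidence))
    else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      region = paste0("FW-", ch),
      template = if (ch == "H") selection@vh else selection@vl,
      conditioning = ident, expectedRmsd = exp, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(loops$provenance))) {
    p <- loops$provenance[i, ]
    ch <- substr(p$cdr, 1, 1); k <- as.integer(substr(p$cdr, 2, 2))
    len <- regionLoopLength(target, ch, k, config$cdrSet)
    tab <- if (!is.null(calibration)) calibration[[p$cdr]] else NULL
    exp <- if (!is.null(tab))
      suppressWarnings(expectedRmsdAtConfidence(tab, len,
                                                p = config$confidence))
    else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      region = paste0("CDR", p$cdr), template = p$fragment,
      conditioning = len, expectedRmsd = exp, stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, rows)
  liab <- NULL
  if (config$liabilities) {
    liab <- scanMotifs(target)
    if (config$sideChains && nrow(liab))
      liab <- flagExposure(liab, relativeAsa(model),
                           threshold = config$exposureThreshold)
  }
  report <- list(
    id = id, selection = selection, regions = regions,
    provenance = loops$provenance, liabilities = liab,
    clashStage = clashStage,
    timings = c(framework = as.numeric(t1 - t0, units = "secs"),
                loops = as.numeric(t2 - t1, units = "secs"),
                sideChains = as.numeric(t3 - t2, units = "secs")))
  list(model = model, report = report)
}

#' Build framework and loop calibration tables from a structure library
#'
#' Framework tables come from the all-vs-all framework superimpositions
#' (VH-VH and VL-VL, identity-conditioned). CDR tables come from
#' leave-one-out loop prediction over the library: each member's loops are
#' re-modelled with its own fragments excluded and scored against the
#' member (RMSD after the respective chain's framework fit),
#' length-conditioned.
#'
#' @param structures named list of region-assigned [FvStructure-class].
#' @param resolutions parallel named numeric vector.
#' @param config a [fvConfig()].
#' @return named list of [CalibrationTable-class] objects (`vh`, `vl`,
#'   `H1`..`L3` as available).
#' @export
buildCalibration <- function(structures, resolutions, config = fvConfig()) {
  out <- list()
  hasH <- vapply(structures, function(s) "H" %in% fvChains(s), logical(1))
  hasL <- vapply(structures, function(s) "L" %in% fvChains(s), logical(1))
  if (sum(hasH) >= 2)
    out$vh <- frameworkCalibration(
      pairwiseSuperimpositionTable(structures[hasH], "vh"), "VH-fw")
  if (sum(hasL) >= 2)
    out$vl <- frameworkCalibration(
      pairwiseSuperimpositionTable(structures[hasL], "vl"), "VL-fw")
  templates <- buildTemplateStore(structures, resolutions,
                                  cutoff = config$resolutionCutoff)
  fragments <- buildFragmentStores(structures, resolutions,
                                   nAnchor = config$nAnchor)
  obs <- list()
  cfg <- config; cfg$sideChains <- FALSE; cfg$liabilities <- FALSE
  for (id in names(structures)) {
    native <- structures[[id]]
    ch <- fvChains(native)
    fit <- tryCatch(
      buildModel(heavy = if ("H" %in% ch) fvSequence(native, "H") else NULL,
                 light = if ("L" %in% ch) fvSequence(native, "L") else NULL,
                 templates = templates, fragments = fragments,
                 config = cfg, excludeIdentical = TRUE,
                 excludeSources = id, id = id),
      error = function(e) NULL)
    if (is.null(fit)) next
    for (cch in ch) for (k in 1:3) {
      rep <- tryCatch(cdrRmsd(fit$model, native, cch, k),
                      error = function(e) NULL)
      if (is.null(rep)) next
      len <- sum(residueTable(native)$chain == cch &
                   residueTable(native)$region == paste0("CDR", k))
      obs[[length(obs) + 1L]] <- data.frame(
        cdr = paste0(cch, k), len = len, rmsd = rep$rmsd)
    }
  }
  if (length(obs)) {
    obs <- do.call(rbind, obs)
    for (ty in unique(obs$cdr)) {
      d <- obs[obs$cdr == ty, ]
      out[[ty]] <- calibrationTable(d$len, d$rmsd, paste0("CDR", ty),
                                    "length")
    }
  }
  out
}

#' Benchmark models against native structures
#'
#' Applies the accuracy protocols to each model/native pair: Fv RMSD (both
#' chains' backbone fit), per-chain framework RMSD, and per-CDR RMSD after
#' the respective chain's framework fit. `mode` selects the CDR interval
#' set used for region boundaries ("north" default, "chothia" for the
#' narrower alternate definitions).
#'
#' @param models,natives parallel lists of [FvStructure-class] objects.
#' @param mode CDR definition set for the protocol.
#' @return data.frame, one row per target and region, with an aggregate
#'   mean attached as attribute `"means"`.
#' @export
benchmarkModels <- function(models, natives, mode = c("north", "chothia")) {
  mode <- match.arg(mode)
  stopifnot(length(models) == length(natives))
  rows <- list()
  for (i in seq_along(models)) {
    m <- assignRegions(models[[i]], mode)
    n <- assignRegions(natives[[i]], mode)
    id <- fvId(n)
    ch <- intersect(fvChains(m), fvChains(n))
    add <- function(region, rmsd)
      rows[[length(rows) + 1L]] <<- data.frame(
        target = id, region = region, rmsd = rmsd, stringsAsFactors = FALSE)
    if (length(ch) == 2) add("Fv", fvRmsd(m, n)$rmsd)
    for (c0 in ch) {
      add(paste0("FW-", c0), frameworkRmsd(m, n, c0)$rmsd)
      for (k in 1:3) {
        r <- tryCatch(cdrRmsd(m, n, c0, k)$rmsd, error = function(e) NA_real_)
        add(paste0("CDR", c0, k), r)
      }
    }
  }
  out <- do.call(rbind, rows)
  means <- aggregate(rmsd ~ region, data = out, FUN = mean, na.rm = TRUE)
  attr(out, "means") <- means
  out
}
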