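## Data-driven model confidence.
##
## The probability that a region is modelled within x Angstrom is estimated
## as a conditional probability P(x | s) = P(x AND s) / P(s), where the
## conditioning value s is the framework sequence identity (windowed at
## s +/- 2.5 on a 1-unit grid, so each grid bin is 1% wide) or the CDR loop
## length (exact match, since lengths are discrete). Inverting the curve at
## a chosen confidence level (default 75%) yields the expected RMSD.

#' Construct a calibration table
#'
#' @param cond conditioning values (identity % or loop length).
#' @param rmsd outcome backbone RMSDs (Angstrom).
#' @param kind label, e.g. "VH-fw" or "CDRH3".
#' @param condType `"identity"` or `"length"`.
#' @return a [CalibrationTable-class].
#' @export
calibrationTable <- function(cond, rmsd, kind = "VH-fw",
                             condType = c("identity", "length")) {
  condType <- match.arg(condType)
  if (length(cond) == 0L) stop("empty calibration table")
  new("CalibrationTable",
      data = data.frame(cond = cond, rmsd = rmsd), kind = kind,
      condType = condType)
}

setMethod("show", "CalibrationTable", function(object) {
  d <- object@data
  cat(sprintf("CalibrationTable[%s]: %d observations, %s-conditioned\n",
              object@kind, nrow(d), object@condType))
  cat(sprintf("  cond range %.4g-%.4g; median RMSD %.3g A\n",
              min(d$cond), max(d$cond), stats::median(d$rmsd)))
})

inWindow <- function(tab, s) {
  if (tab@condType == "identity")
    tab@data$cond >= s - 2.5 & tab@data$cond <= s + 2.5
  else tab@data$cond == s
}

#' Marginal, joint and conditional probabilities from a calibration table
#'
#' `marginalProbability` is the fraction of observations whose conditioning
#' value falls in the bin around `s`; `jointProbability` additionally
#' requires RMSD <= x; `conditionalProbability` is their ratio, the
#' probability that a region with conditioning value `s` is modelled within
#' `x` Angstrom. When the bin holds no observations the conditional
#' probability is undefined and `NA` is returned (distinct from 0); no
#' confidence is then available, as happens for unseen long CDRH3 loops.
#'
#' Tables may store each unordered pair once: the ordered-pair double count
#' cancels in every ratio.
#'
#' @param table a [CalibrationTable-class].
#' @param s conditioning value (identity % or loop length).
#' @param x RMSD threshold (Angstrom).
#' @return probability in \[0, 1\] (or `NA` when undefined).
#' @export
marginalProbability <- function(table, s) mean(inWindow(table, s))

#' @rdname marginalProbability
#' @export
jointProbability <- function(table, s, x)
  mean(inWindow(table, s) & table@data$rmsd <= x)

#' @rdname marginalProbability
#' @export
conditionalProbability <- function(table, s, x) {
  m <- marginalProbability(table, s)
  if (m == 0) return(NA_real_)
  jointProbability(table, s, x) / m
}

#' Loop-length-conditioned confidence
#'
#' Conditional probability for a CDR loop, conditioning on exact loop
#' length (no window).
#'
#' @param table a length-conditioned [CalibrationTable-class].
#' @param length CDR loop length (residues).
#' @param x RMSD threshold (Angstrom).
#' @return probability, or `NA` if the length was never observed.
#' @export
loopConfidence <- function(table, length, x) {
  if (table@condType != "length")
    stop("loopConfidence requires a length-conditioned table")
  conditionalProbability(table, length, x)
}

#' Expected RMSD at a confidence level
#'
#' Inverts the conditional-probability curve: the smallest RMSD grid value
#' x with P(x | s) >= p. The default confidence level is 75%; the grid step
#' is 0.1 Angstrom. Returns `NA` (with a warning) when no data exist in the
#' conditioning bin or the curve never reaches `p` within the grid - no
#' confidence estimate is then available.
#'
#' @param table a [CalibrationTable-class].
#' @param s conditioning value.
#' @param p confidence level in \[0, 1\] (default 0.75).
#' @param step RMSD grid step (default 0.1 A).
#' @param maxX upper grid bound (default: max observed RMSD, rounded up to
#'   the grid).
#' @return RMSD threshold in Angstrom, or `NA`.
#' @export
expectedRmsdAtConfidence <- function(table, s, p = 0.75, step = 0.1,
                                     maxX = NULL) {
  if (marginalProbability(table, s) == 0) {
    warning("insufficient data: no observations in the conditioning bin at ", s)
    return(NA_real_)
  }
  if (is.null(maxX)) maxX <- ceiling(max(table@data$rmsd) / step) * step
  grid <- seq(0, maxX, by = step)
  for (x in grid) {
    px <- conditionalProbability(table, s, x)
    if ((p > 0 && px >= p) || (p == 0 && px > 0)) return(x)
  }
  warning("insufficient data: confidence never reaches ", p,
          " within the RMSD grid")
  NA_real_
}

#' Framework calibration from a superimposition table
#'
#' Wraps the (identity, RMSD) columns of a [pairwiseSuperimpositionTable()]
#' result as a calibration table.
#'
#' @param pairs data.frame from [pairwiseSuperimpositionTable()].
#' @param kind label.
#' @return a [CalibrationTable-class].
#' @export
frameworkCalibration <- function(pairs, kind = "VH-fw") {
  ok <- !is.na(pairs$rmsd)
  calibrationTable(pairs$identity[ok], pairs$rmsd[ok], kind, "identity")
}

#' Export a confidence curve
#'
#' Tabulates P(x | s) on an RMSD grid for plotting or serialisation.
#'
#' @inheritParams expectedRmsdAtConfidence
#' @param xGrid RMSD thresholds (default 0 to max observed, step 0.1).
#' @return data.frame with columns `x` and `p`.
#' @export
confidenceCurve <- function(table, s, xGrid = NULL, step = 0.1) {
  if (is.null(xGrid))
    xGrid <- seq(0, ceiling(max(table@data$rmsd) / step) * step, by = step)
  data.frame(x = xGrid,
             p = vapply(xGrid, function(x) conditionalProbability(table, s, x),
                        numeric(1)))
}
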