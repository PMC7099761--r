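#' Nutrient-limitation statistics of a run
#'
#' Re-evaluates the limitation factors from the saved surface-layer nutrient
#' fields at every post-spin-up snapshot and summarizes (a) the percent of
#' time phosphorus limits production and (b) the climatological monthly
#' limiting nutrient, per functional type and aggregated.
#'
#' Two aggregate definitions are provided, since either could be meant by a
#' map of "percent of time with phosphate limitation": `"biomass_weighted"`
#' weights each type's limitation outcome by its surface biomass at that
#' snapshot; `"any_pft"` counts a snapshot as phosphorus-limited when any
#' type is. With a shared uptake ratio the identity of the limiting nutrient
#' reduces to `po4 < iRfr * (no3 + nh4)` and is the same for every type, so
#' the two definitions usually coincide; both are kept for generality.
#' Monthly modes break ties toward the nutrient with the smaller mean
#' limitation factor (the more severely limiting one).
#'
#' @param run an [NpzdRun-class] covering at least one full year after
#'   spin-up.
#' @param definition aggregate definition (see above).
#' @param surfaceDepth surface definition (m), default 0-10 m.
#' @return List: `percentPLimited` (scalar, 0-100), `perPft` (named vector of
#'   per-type percents), `monthly` (data.frame of modal limiting nutrient per
#'   calendar month, per type and aggregate), `definition`.
#' @export
limitationStats <- function(run,
                            definition = c("biomass_weighted", "any_pft"),
                            surfaceDepth = 10) {
  definition <- match.arg(definition)
  keep <- !isSpinup(run)
  if (sum(keep) < 365)
    stop("run must cover at least one full year after spin-up", call. = FALSE)
  no3 <- surfaceMean(run, "no3", surfaceDepth)[keep]
  nh4 <- surfaceMean(run, "nh4", surfaceDepth)[keep]
  po4 <- surfaceMean(run, "po4", surfaceDepth)[keep]
  month <- SummarizedExperiment::colData(run)$month[keep]
  policy <- runPolicy(run)
  pfts <- runParams(run)$pfts

  lim <- lapply(pfts, function(p)
    limitation(no3, nh4, po4, p@alphaNutrient, policy))
  pInd <- vapply(lim, function(l) l$plim < l$nlim, logical(length(no3)))
  nInd <- vapply(lim, function(l) l$nlim < l$plim, logical(length(no3)))
  perPft <- 100 * colMeans(pInd)
  names(perPft) <- names(pfts)

  w <- vapply(seq_along(pfts), function(i)
    surfaceMean(run, paste0("phyN", i), surfaceDepth)[keep],
    numeric(length(no3)))
  wt <- rowSums(w)
  wfrac <- rowSums(w * pInd) / ifelse(wt > 0, wt, 1)
  percent <- switch(definition,
    biomass_weighted = 100 * mean(wfrac),
    any_pft = 100 * mean(apply(pInd, 1, any)))

  modal <- function(pi, ni, fac) {
    vapply(1:12, function(m) {
      s <- month == m
      np <- sum(pi[s]); nn <- sum(ni[s])
      if (np > nn) "phosphorus"
      else if (nn > np) "nitrogen"
      else if (mean(fac$plim[s]) <= mean(fac$nlim[s])) "phosphorus"
      else "nitrogen"
    }, "")
  }
  monthly <- data.frame(month = 1:12)
  for (i in seq_along(pfts))
    monthly[[names(pfts)[i]]] <- modal(pInd[, i], nInd[, i], lim[[i]])
  aggInd <- if (definition == "any_pft") apply(pInd, 1, any) else wfrac > 0.5
  aggN <- if (definition == "any_pft") apply(nInd, 1, all) else !(wfrac > 0.5)
  monthly$aggregate <- modal(aggInd, aggN & !aggInd, lim[[1]])

  list(percentPLimited = percent, perPft = perPft, monthly = monthly,
       definition = definition)
}

#' Nutrient-ratio fields of a run
#'
#' `npWater`: dissolved nitrate:phosphate per layer and snapshot (sentinel
#' `NA` where phosphate is zero). `npOM`: N:P of the bulk organic matter,
#' summed over all organic ledgers (phytoplankton, zooplankton, detritus),
#' `NA` where total organic phosphorus is zero. Under a redfield run `npOM`
#' is identically 16; under a line-of-frugality run it lies in the attainable
#' uptake-ratio range.
#'
#' @param run an [NpzdRun-class].
#' @return List of two layers x snapshots matrices, `npWater` and `npOM`.
#' @export
npFields <- function(run) {
  orgN <- fieldMatrix(run, "phyN1") + fieldMatrix(run, "phyN2") +
    fieldMatrix(run, "phyN3") + fieldMatrix(run, "zooN") +
    fieldMatrix(run, "detN")
  orgP <- fieldMatrix(run, "phyP1") + fieldMatrix(run, "phyP2") +
    fieldMatrix(run, "phyP3") + fieldMatrix(run, "zooP") +
    fieldMatrix(run, "detP")
  npw <- fieldMatrix(run, "no3") / fieldMatrix(run, "po4")
  npw[fieldMatrix(run, "po4") <= 0] <- NA_real_
  npo <- orgN / orgP
  npo[orgP <= 0] <- NA_real_
  list(npWater = npw, npOM = npo)
}

#' Twin-run anomaly of a field
#'
#' Difference statistics `runB - runA` for a pair of twin runs (identical
#' grid and forcing, different stoichiometry policy). The twin contract is
#' verified from the stored forcing hash and grid before any arithmetic.
#' The anomaly convention is second minus first; called as
#' `chlAnomaly(rfr, lof)` it is the line-of-frugality excess.
#'
#' @param runA,runB [NpzdRun-class] twins.
#' @param name assay name (default `"chl"`).
#' @param postSpinupOnly restrict statistics to post-spin-up snapshots.
#' @return List: `meanSurface` (mean surface anomaly), `surfaceSeries`,
#'   `profile` (per-layer time-mean anomaly), `depth`.
#' @export
chlAnomaly <- function(runA, runB, name = "chl", postSpinupOnly = TRUE) {
  ha <- S4Vectors::metadata(runA)$forcingHash
  hb <- S4Vectors::metadata(runB)$forcingHash
  if (!identical(ha, hb))
    stop("twin contract violated: runs were made with different forcing",
         call. = FALSE)
  if (!isTRUE(all.equal(depths(runA), depths(runB))) ||
      ncol(runA) != ncol(runB))
    stop("twin contract violated: runs use different grids or sampling",
         call. = FALSE)
  keep <- if (postSpinupOnly) !isSpinup(runA) else rep(TRUE, ncol(runA))
  dif <- fieldMatrix(runB, name)[, keep, drop = FALSE] -
    fieldMatrix(runA, name)[, keep, drop = FALSE]
  sa <- surfaceMean(runB, name)[keep] - surfaceMean(runA, name)[keep]
  list(meanSurface = mean(sa), surfaceSeries = sa,
       profile = rowMeans(dif), depth = depths(runA))
}

#' Model-vs-reference skill statistics
#'
#' Computes mean bias, Pearson correlation, standard-deviation ratio,
#' centered RMS difference and the relative error
#' `mean(|reference - model|) / mean(reference)` over pairwise-complete
#' observations (NaN/NA masked). Standard deviations and the centered RMS
#' use the population (1/n) convention so the Taylor identity holds exactly;
#' the [SkillReport-class] validity method asserts it to 1e-12.
#'
#' @param model,reference numeric vectors or matrices of equal length.
#' @return A [SkillReport-class].
#' @examples
#' x <- sin(1:100 / 10)
#' skillStats(x + 0.1, x)  # bias 0.1, correlation 1
#' @export
skillStats <- function(model, reference) {
  m <- as.numeric(model); r <- as.numeric(reference)
  stopifnot(length(m) == length(r))
  ok <- is.finite(m) & is.finite(r)
  m <- m[ok]; r <- r[ok]
  n <- length(m)
  if (n < 2) stop("need at least 2 pairwise-complete observations",
                  call. = FALSE)
  sdp <- function(x) sqrt(mean((x - mean(x))^2))
  sm <- sdp(m); sr <- sdp(r)
  corr <- if (sm > 0 && sr > 0)
    mean((m - mean(m)) * (r - mean(r))) / (sm * sr) else NA_real_
  crmsd <- sqrt(mean(((m - mean(m)) - (r - mean(r)))^2))
  new("SkillReport",
      bias = mean(m) - mean(r),
      correlation = corr,
      sdModel = sm, sdReference = sr,
      sdRatio = if (sr > 0) sm / sr else NA_real_,
      crmsd = crmsd,
      relError = if (mean(r) != 0) mean(abs(r - m)) / mean(r) else NA_real_,
      n = n)
}

setMethod("show", "SkillReport", function(object) {
  cat(sprintf(
    "SkillReport (n = %d)\n  bias %.4g, corr %.4f, sd ratio %.4f, cRMSD %.4g, rel. error %.4g\n",
    object@n, object@bias, object@correlation, object@sdRatio,
    object@crmsd, object@relError))
})

#' SkillReport accessors
#' @param x a [SkillReport-class].
#' @return The named statistic.
#' @name skill-accessors
NULL

#' @rdname skill-accessors
#' @export
skillBias <- function(x) x@bias
#' @rdname skill-accessors
#' @export
skillCorrelation <- function(x) x@correlation
#' @rdname skill-accessors
#' @export
skillSdRatio <- function(x) x@sdRatio
#' @rdname skill-accessors
#' @export
skillCrmsd <- function(x) x@crmsd
#' @rdname skill-accessors
#' @export
skillRelError <- function(x) x@relError

#' Deep-chlorophyll-maximum detector on a single profile
#'
#' Finds the chlorophyll maximum below the mixed layer on a mean profile.
#' The maximum is searched among layers deeper than `mld`; ties report the
#' shallower depth. A profile whose sub-mixed-layer maximum does not reach
#' the surface value is surface-intensified and reported as having no DCM.
#'
#' @param depth layer-center depths (m), increasing.
#' @param chl mean chlorophyll profile (mg m^-3).
#' @param mld mixed-layer depth (m) delimiting the search.
#' @return List: `present`, `depth` (m, `NA` if absent), `intensity`
#'   (mg m^-3, `NA` if absent), `surface` (surface chlorophyll).
#' @export
dcmFromProfile <- function(depth, chl, mld) {
  stopifnot(length(depth) == length(chl), !is.unsorted(depth))
  surface <- chl[1]
  below <- which(depth > mld)
  if (length(below) == 0)
    return(list(present = FALSE, depth = NA_real_, intensity = NA_real_,
                surface = surface))
  k <- below[which.max(chl[below])]   # which.max: shallower wins ties
  present <- chl[k] >= surface && chl[k] > 0
  list(present = present,
       depth = if (present) depth[k] else NA_real_,
       intensity = if (present) chl[k] else NA_real_,
       surface = surface)
}

#' Deep-chlorophyll-maximum metrics of a run
#'
#' Averages the chlorophyll field over the post-spin-up snapshots of the
#' stratified-season months and applies [dcmFromProfile()] with the mean
#' mixed-layer depth of the same window.
#'
#' @param run an [NpzdRun-class].
#' @param months calendar months of the stratified window (default
#'   June-August).
#' @return As [dcmFromProfile()], plus `mldMean` (m).
#' @export
dcmMetrics <- function(run, months = 6:8) {
  cd <- SummarizedExperiment::colData(run)
  keep <- !cd$spinup & cd$month %in% months
  if (!any(keep)) stop("no post-spin-up snapshots in the requested months",
                       call. = FALSE)
  prof <- rowMeans(fieldMatrix(run, "chl")[, keep, drop = FALSE])
  f <- runForcing(run)
  mld <- mean(stats::approx(f@time, f@mld, xout = cd$time[keep],
                            rule = 2)$y)
  c(dcmFromProfile(depths(run), prof, mld), list(mldMean = mld))
}
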