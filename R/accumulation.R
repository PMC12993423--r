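#' Evaluation configuration
#'
#' Defaults follow the workflow's stated choices: structures body, bladder,
#' rectum and prostate; a 2\% relevance threshold on metric deviations; a
#' 1 cm margin target regenerated from the daily prostate; 0.1 Gy DVH bins;
#' geometry metrics on a 1 mm isotropic resampling of the dose grid.
#'
#' @param structures organ names to evaluate.
#' @param binWidthGy DVH bin width, Gy.
#' @param supersample in-plane rasterization refinement.
#' @param thresholdPct relevance threshold on |deviation|, percent.
#' @param marginMm margin of the target surrogate, mm (set to 0 to disable).
#' @param marginSource structure the margin target is grown from.
#' @param geometrySpacingMm grid spacing for masks and geometry metrics.
#' @param maxOutsideFrac tolerated fraction of structure voxels outside the
#'   dose grid.
#' @param strict if TRUE, a failing fraction aborts \code{\link{runCourse}};
#'   otherwise it is recorded and skipped.
#' @return a list of class \code{CourseConfig}.
#' @export
courseConfig <- function(structures = c("body", "bladder", "rectum",
                                        "prostate"),
                         binWidthGy = 0.1, supersample = 2L,
                         thresholdPct = 2, marginMm = 10,
                         marginSource = "prostate",
                         geometrySpacingMm = c(1, 1, 1),
                         maxOutsideFrac = 0.05, strict = FALSE) {
  stopifnot(binWidthGy > 0, thresholdPct > 0, marginMm >= 0)
  cfg <- list(structures = structures, binWidthGy = binWidthGy,
              supersample = as.integer(supersample),
              thresholdPct = thresholdPct, marginMm = marginMm,
              marginSource = marginSource,
              geometrySpacingMm = geometrySpacingMm,
              maxOutsideFrac = maxOutsideFrac, strict = isTRUE(strict))
  class(cfg) <- "CourseConfig"
  cfg
}

.margin_name <- function(source, marginMm)
  if (marginMm == 10) paste0(source, "+1cm") else
    sprintf("%s+%gmm", source, marginMm)

.metric_deviation <- function(m, m0) {
  dev <- ifelse(abs(m0) > 0, (m - m0) / m0 * 100, NA_real_)
  names(dev) <- names(m0)
  dev
}

.geom_summary <- function(mask, baseMask, baseVolume) {
  v <- maskVolume(mask)
  list(volume_cm3 = v,
       volume_dev_pct = if (baseVolume > 0)
         (v - baseVolume) / baseVolume * 100 else NA_real_,
       com = centerOfMass(mask),
       cmd_mm = centerOfMassDistance(mask, baseMask),
       dsc = diceCoefficient(mask, baseMask))
}

#' Evaluate the planning baseline
#'
#' Rasterizes the planning structures on the geometry grid, grows the margin
#' target from the planning prostate, samples the plan dose and computes the
#' baseline DVH curves and metrics. Deterministic: repeated calls give
#' identical results.
#'
#' @param course a \linkS4class{TreatmentCourse}.
#' @param config a \code{\link{courseConfig}}.
#' @return a \linkS4class{Baseline}.
#' @export
evaluateBaseline <- function(course, config = courseConfig()) {
  geom <- resampleGeometry(course@planDose@geometry,
                           config$geometrySpacingMm)
  masks <- list()
  for (nm in config$structures)
    masks[[nm]] <- rasterizeRoi(getRoi(course@planningStructures, nm), geom,
                                config$supersample)
  if (config$marginMm > 0) {
    tgt <- .margin_name(config$marginSource, config$marginMm)
    masks[[tgt]] <- expandMargin(masks[[config$marginSource]],
                                 config$marginMm)
    masks[[tgt]]@label <- tgt
  }
  metrics <- list(); curveMetrics <- list(); curves <- list()
  volumes <- numeric()
  for (nm in names(masks)) {
    smp <- sampleDose(masks[[nm]], course@planDose,
                      maxOutsideFrac = config$maxOutsideFrac)
    metrics[[nm]] <- doseMetrics(smp)
    curves[[nm]] <- cumulativeDvh(smp, config$binWidthGy)
    curveMetrics[[nm]] <- doseMetrics(curves[[nm]])
    volumes[nm] <- maskVolume(masks[[nm]])
  }
  new("Baseline", structures = names(masks), metrics = metrics,
      curveMetrics = curveMetrics, curves = curves, masks = masks,
      volumes = volumes)
}

#' Evaluate one fraction against the baseline
#'
#' Transforms the daily contours into the planning frame with the fraction's
#' registration (honouring the course's matrix direction convention),
#' rasterizes them on the baseline grid, computes the geometric change
#' metrics against the baseline masks, samples the plan dose and derives the
#' session DVH and metrics in plan-total dose units. The margin target is
#' regenerated from the daily prostate, not transformed from planning.
#'
#' @param course a \linkS4class{TreatmentCourse}.
#' @param fraction a \linkS4class{FractionRecord} of that course.
#' @param baseline the course \linkS4class{Baseline}.
#' @param config a \code{\link{courseConfig}}.
#' @return a \linkS4class{FractionResult}.
#' @export
evaluateFraction <- function(course, fraction, baseline,
                             config = courseConfig()) {
  direction <- if (identical(course@matrixMaps, "moving_to_fixed"))
    "moving_to_fixed" else "fixed_to_moving"
  geom <- baseline@masks[[1]]@geometry
  masks <- list()
  for (nm in config$structures) {
    troi <- transformRoi(getRoi(fraction@structures, nm),
                         fraction@registration, direction)
    masks[[nm]] <- rasterizeRoi(troi, geom, config$supersample)
  }
  if (config$marginMm > 0) {
    tgt <- .margin_name(config$marginSource, config$marginMm)
    masks[[tgt]] <- expandMargin(masks[[config$marginSource]],
                                 config$marginMm)
    masks[[tgt]]@label <- tgt
  }
  geomSummary <- list(); metrics <- list(); deviations <- list()
  curves <- list()
  for (nm in names(masks)) {
    geomSummary[[nm]] <- .geom_summary(masks[[nm]], baseline@masks[[nm]],
                                       baseline@volumes[[nm]])
    smp <- sampleDose(masks[[nm]], course@planDose,
                      maxOutsideFrac = config$maxOutsideFrac)
    metrics[[nm]] <- doseMetrics(smp)
    deviations[[nm]] <- .metric_deviation(metrics[[nm]],
                                          baseline@metrics[[nm]])
    curves[[nm]] <- cumulativeDvh(smp, config$binWidthGy)
  }
  new("FractionResult", index = fraction@index, geometry = geomSummary,
      metrics = metrics, deviations = deviations, curves = curves)
}

.mean_of_curves <- function(curves) {
  w <- vapply(curves, function(c) c@binWidthGy, numeric(1))
  if (max(w) - min(w) > 1e-12)
    stop("mixed DVH bin widths: ", paste(unique(w), collapse = ", "))
  K <- max(vapply(curves, function(c) length(c@doseAxis), integer(1)))
  S <- vapply(curves, function(c) {
    s <- c@cumVolumePct
    c(s, rep(0, K - length(s)))
  }, numeric(K))
  new("DvhCurve", doseAxis = (seq_len(K) - 1) * w[1],
      cumVolumePct = rowMeans(S), structure = curves[[1]]@structure,
      totalVolumeCm3 = mean(vapply(curves, function(c) c@totalVolumeCm3,
                                   numeric(1))),
      binWidthGy = w[1])
}

#' Accumulate fraction results over the course
#'
#' The accumulated cumulative DVH per structure is the equal-weight mean of
#' the daily cumulative (relative-volume) curves on a common dose axis in
#' plan-total Gy: with each fraction assumed to deliver 1/n of the plan and
#' organ sub-volumes treated as exchangeable across fractions, averaging the
#' daily curves is the accumulated-dose estimate. Partial courses use the
#' mean over the available fractions (\code{nAvailable} is recorded).
#' Accumulated metrics are read off the accumulated curve; deviations are
#' taken against the baseline metrics computed from the baseline curve with
#' the same estimator, and flagged where |deviation| exceeds the threshold.
#'
#' @param fractionResults nonempty list of \linkS4class{FractionResult}.
#' @param baseline the course \linkS4class{Baseline}.
#' @param nPlanned planned number of fractions (bookkeeping only; the
#'   relative-volume average is invariant to it).
#' @param config a \code{\link{courseConfig}}.
#' @return an \linkS4class{AccumulatedResult}.
#' @export
accumulateFractions <- function(fractionResults, baseline,
                                nPlanned = length(fractionResults),
                                config = courseConfig()) {
  if (!length(fractionResults)) stop("no fraction results to accumulate")
  curves <- list(); metrics <- list(); devs <- list(); flags <- list()
  for (nm in baseline@structures) {
    curves[[nm]] <- .mean_of_curves(lapply(fractionResults, function(f)
      f@curves[[nm]]))
    metrics[[nm]] <- doseMetrics(curves[[nm]])
    devs[[nm]] <- .metric_deviation(metrics[[nm]],
                                    baseline@curveMetrics[[nm]])
    flags[[nm]] <- !is.na(devs[[nm]]) &
      abs(devs[[nm]]) > config$thresholdPct
  }
  new("AccumulatedResult", curves = curves, metrics = metrics,
      deviationPct = devs, flags = flags,
      nAvailable = length(fractionResults),
      thresholdPct = config$thresholdPct)
}

#' Rate of threshold exceedance across results
#'
#' Percentage of the supplied results whose |deviation| of one metric for one
#' structure exceeds a threshold.
#'
#' @param results list of \linkS4class{FractionResult} or
#'   \linkS4class{AccumulatedResult}.
#' @param metric metric name (e.g. \code{"V20Gy_pct"}).
#' @param structure structure name.
#' @param thresholdPct threshold on |deviation|, percent.
#' @return exceedance rate in percent.
#' @export
thresholdExceedanceRate <- function(results, metric, structure,
                                    thresholdPct = 2) {
  devs <- vapply(results, function(r) {
    d <- if (is(r, "FractionResult")) r@deviations else r@deviationPct
    if (is.null(d[[structure]]))
      stop("structure '", structure, "' not present in results")
    if (!metric %in% names(d[[structure]]))
      stop("unknown metric '", metric, "'; available: ",
           paste(names(d[[structure]]), collapse = ", "))
    d[[structure]][[metric]]
  }, numeric(1))
  100 * mean(!is.na(devs) & abs(devs) > thresholdPct)
}

#' Run the full course workflow
#'
#' Baseline evaluation, per-fraction evaluation, accumulation, deviation
#' flagging and summary statistics, with per-stage timings. In lenient mode
#' (default) a failing fraction is recorded under \code{failures} and the
#' course continues; \code{config$strict = TRUE} re-raises the first failure.
#'
#' @param course a \linkS4class{TreatmentCourse}.
#' @param config a \code{\link{courseConfig}}.
#' @param verbose log one line per fraction to stderr.
#' @return a \linkS4class{CourseReport}.
#' @export
runCourse <- function(course, config = courseConfig(), verbose = FALSE) {
  timings <- numeric()
  t0 <- proc.time()[["elapsed"]]
  baseline <- evaluateBaseline(course, config)
  timings["baseline_s"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  results <- list(); failures <- list()
  for (f in course@fractions) {
    r <- tryCatch(evaluateFraction(course, f, baseline, config),
                  error = function(e) e)
    if (inherits(r, "error")) {
      if (config$strict)
        stop(sprintf("fraction %d: %s", f@index, conditionMessage(r)))
      failures[[sprintf("fraction_%d", f@index)]] <- conditionMessage(r)
    } else {
      results[[length(results) + 1L]] <- r
      if (verbose)
        message(sprintf("fraction %d: evaluated %d structure(s)", f@index,
                        length(r@metrics)))
    }
  }
  timings["fractions_s"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  if (!length(results)) stop("all fractions failed")
  acc <- accumulateFractions(results, baseline, course@nFractionsPlanned,
                             config)
  timings["accumulate_s"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  stats <- .course_stats(results, baseline, config)
  timings["stats_s"] <- proc.time()[["elapsed"]] - t0

  new("CourseReport", baseline = baseline, fractionResults = results,
      accumulated = acc, failures = failures, stats = stats,
      timings = timings, config = unclass(config))
}
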