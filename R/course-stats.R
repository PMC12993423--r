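#' Coefficient of variation of a series
#'
#' CV = sigma / mu x 100\%, with the sample (n - 1) standard deviation; used
#' to quantify interfractional variability of a structure's volume series.
#'
#' @param values numeric series, n >= 2, positive mean.
#' @return CV in percent.
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("insufficient data: need at least 2 values")
  mu <- mean(values)
  if (!is.finite(mu) || mu <= 0) stop("CV undefined: mean must be positive")
  stats::sd(values) / mu * 100
}

#' Cohen strength band of a correlation
#'
#' |r| below 0.3 is weak, above 0.5 strong, in between (boundaries included)
#' moderate.
#'
#' @param r correlation coefficient in [-1, 1].
#' @return \code{"weak"}, \code{"moderate"} or \code{"strong"}.
#' @export
cohenStrength <- function(r) {
  a <- abs(r)
  stopifnot(a <= 1 + 1e-12)
  if (a < 0.3) "weak" else if (a > 0.5) "strong" else "moderate"
}

#' Pearson correlation with Cohen banding
#'
#' @param x,y numeric series of equal length >= 3 with nonzero variance.
#' @return list of class \code{CorrelationResult}: \code{r}, \code{n},
#'   \code{strength} (Cohen band of |r|) and \code{sign}.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("insufficient data: need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  r <- stats::cor(x, y)
  structure(list(r = r, n = length(x), strength = cohenStrength(r),
                 sign = if (r > 0) "positive" else if (r < 0) "negative"
                        else "zero"),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d): %s %s correlation\n", x$r, x$n,
              x$strength, x$sign))
  invisible(x)
}

#' Distribution summary
#'
#' Always computes mean, SD (sample), median and quartiles (linear
#' interpolation between order statistics). \code{style = "auto"} flags
#' median/IQR presentation when |skewness| exceeds 1, else mean +- SD.
#'
#' @param values numeric series, n >= 1.
#' @param style \code{"auto"}, \code{"mean_sd"} or \code{"median_iqr"}.
#' @return list with mean, sd, median, q25, q75, n, skewness, presentation.
#' @export
summarizeDistribution <- function(values, style = c("auto", "mean_sd",
                                                    "median_iqr")) {
  style <- match.arg(style)
  stopifnot(length(values) >= 1L)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  s <- stats::sd(values)
  m <- mean(values)
  skew <- if (length(values) >= 3L && isTRUE(s > 0))
    mean((values - m)^3) / (sqrt(mean((values - m)^2)))^3 else 0
  pres <- switch(style, mean_sd = "mean_sd", median_iqr = "median_iqr",
                 auto = if (abs(skew) > 1) "median_iqr" else "mean_sd")
  list(mean = m, sd = if (is.na(s)) 0 else s, median = q[2], q25 = q[1],
       q75 = q[3], n = length(values), skewness = skew,
       presentation = pres)
}

#' One row per fraction and structure
#'
#' Flattens a course report into a table of the per-fraction geometry and
#' dose results: volumes, volume deviations, CMD, DSC, the metric block and
#' the metric deviations (columns \code{dev_*}).
#'
#' @param report a \linkS4class{CourseReport} (or list of them, pooled with a
#'   \code{course} column).
#' @return a data.frame.
#' @export
fractionTable <- function(report) {
  if (is.list(report) && !is(report, "CourseReport")) {
    tabs <- lapply(seq_along(report), function(i) {
      t <- fractionTable(report[[i]])
      t$course <- i
      t
    })
    return(do.call(rbind, tabs))
  }
  rows <- list()
  for (fr in report@fractionResults) {
    for (nm in names(fr@metrics)) {
      g <- fr@geometry[[nm]]
      row <- data.frame(fraction = fr@index, structure = nm,
                        volume_cm3 = g$volume_cm3,
                        volume_dev_pct = g$volume_dev_pct %||% NA_real_,
                        cmd_mm = g$cmd_mm, dsc = g$dsc)
      m <- fr@metrics[[nm]]; d <- fr@deviations[[nm]]
      for (k in names(m)) row[[k]] <- m[[k]]
      for (k in names(d)) row[[paste0("dev_", k)]] <- d[[k]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Pooled volume-dose correlation for one organ
#'
#' Pearson correlation between daily relative volume change and daily mean
#' dose deviation (both percent vs planning), pooled across all fractions of
#' all supplied reports. No per-course clustering correction is applied; the
#' pooled n is recorded in the result.
#'
#' @param x a \linkS4class{CourseReport}, list of reports, or a
#'   \code{\link{fractionTable}} data.frame.
#' @param organ structure name, e.g. \code{"bladder"}.
#' @return a \code{CorrelationResult}.
#' @export
volumeDoseCorrelation <- function(x, organ) {
  tab <- if (is.data.frame(x)) x else fractionTable(x)
  tab <- tab[tab$structure == organ, , drop = FALSE]
  if (!nrow(tab)) stop("structure '", organ, "' not present")
  ok <- stats::complete.cases(tab$volume_dev_pct, tab$dev_Dmean_Gy)
  pearsonCorrelation(tab$volume_dev_pct[ok], tab$dev_Dmean_Gy[ok])
}

# summary statistics block of runCourse
.course_stats <- function(results, baseline, config) {
  organs <- config$structures
  volumes <- lapply(organs, function(nm)
    vapply(results, function(f) f@geometry[[nm]]$volume_cm3, numeric(1)))
  names(volumes) <- organs
  cv <- vapply(volumes, function(v)
    if (length(v) >= 2 && mean(v) > 0) coefficientOfVariation(v)
    else NA_real_, numeric(1))
  volume_dev <- lapply(organs, function(nm)
    summarizeDistribution(vapply(results, function(f)
      f@geometry[[nm]]$volume_dev_pct, numeric(1))))
  names(volume_dev) <- organs
  has_prostate <- "prostate" %in% organs
  cmd <- if (has_prostate) vapply(results, function(f)
    f@geometry$prostate$cmd_mm, numeric(1)) else numeric(0)
  dsc <- if (has_prostate) vapply(results, function(f)
    f@geometry$prostate$dsc, numeric(1)) else numeric(0)
  correlations <- list()
  if (length(results) >= 3) {
    for (nm in intersect(c("bladder", "rectum"), organs)) {
      res <- tryCatch({
        vdev <- vapply(results, function(f)
          f@geometry[[nm]]$volume_dev_pct, numeric(1))
        ddev <- vapply(results, function(f)
          f@deviations[[nm]][["Dmean_Gy"]], numeric(1))
        ok <- stats::complete.cases(vdev, ddev)
        pearsonCorrelation(vdev[ok], ddev[ok])
      }, error = function(e) list(error = conditionMessage(e)))
      correlations[[nm]] <- res
    }
  }
  out <- list(volume_cv_pct = cv, volume_dev = volume_dev,
              correlations = correlations)
  if (length(cmd)) {
    out$prostate_cmd <- summarizeDistribution(cmd)
    out$prostate_dsc <- summarizeDistribution(dsc)
  }
  out
}
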