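.metrics_block <- function(m) as.list(m)

#' Serialize a course report
#'
#' Writes \code{report.json} (baseline, per-fraction and accumulated metrics,
#' deviations, flags, summary statistics, timings, failures),
#' \code{fractions.csv} (the \code{\link{fractionTable}}), and one DVH CSV
#' per structure for the baseline and accumulated curves.
#'
#' @param report a \linkS4class{CourseReport}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCourseReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- report@accumulated
  doc <- list(
    type = "doseacc.report",
    structures = report@baseline@structures,
    baseline = list(metrics = lapply(report@baseline@metrics,
                                     .metrics_block),
                    volumes_cm3 = as.list(report@baseline@volumes)),
    fractions = lapply(report@fractionResults, function(f) list(
      index = f@index,
      geometry = lapply(f@geometry, function(g)
        list(volume_cm3 = g$volume_cm3, volume_dev_pct = g$volume_dev_pct,
             com = g$com, cmd_mm = g$cmd_mm, dsc = g$dsc)),
      metrics = lapply(f@metrics, .metrics_block),
      deviation_pct = lapply(f@deviations, .metrics_block))),
    accumulated = list(n_available = acc@nAvailable,
                       threshold_pct = acc@thresholdPct,
                       metrics = lapply(acc@metrics, .metrics_block),
                       deviation_pct = lapply(acc@deviationPct,
                                              .metrics_block),
                       relevant_flags = lapply(acc@flags, as.list)),
    stats = report@stats,
    timings_s = as.list(report@timings),
    failures = report@failures,
    config = report@config)
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  utils::write.csv(fractionTable(report), file.path(dir, "fractions.csv"),
                   row.names = FALSE)
  for (nm in report@baseline@structures) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    writeDvhCsv(report@baseline@curves[[nm]],
                file.path(dir, sprintf("dvh_baseline_%s.csv", safe)))
    writeDvhCsv(acc@curves[[nm]],
                file.path(dir, sprintf("dvh_accumulated_%s.csv", safe)))
  }
  invisible(dir)
}
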