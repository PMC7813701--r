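# Reader-study statistics: fourfold tables, positivity/sensitivity,
# specificity, McNemar's paired comparison.

#' Construct a fourfold table
#'
#' @param a both methods positive; `b` method 1 (map) positive only;
#'   `c` method 2 (visual scale) positive only; `d` both negative.
#' @param b,c,d see `a`.
#' @param cohort,hemisphere stratum labels.
#' @return A [FourfoldTable-class].
#' @examples
#' t <- fourfoldTable(100, 42, 6, 51, cohort = "AD", hemisphere = "left")
#' positivityRate(t, "map")   # 142/199
#' mcnemarTest(t)$p.value
#' @export
fourfoldTable <- function(a, b, c, d, cohort = "", hemisphere = "") {
  new("FourfoldTable", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d), cohort = cohort,
      hemisphere = hemisphere)
}

#' @noRd
tableN <- function(t) t@a + t@b + t@c + t@d

setMethod("show", "FourfoldTable", function(object) {
  cat(sprintf("FourfoldTable %s %s (n = %d)\n",
              object@cohort, object@hemisphere, tableN(object)))
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(map = c("atrophy", "no atrophy"),
                              scale = c("MTA >= 2", "MTA < 2")))
  print(m)
})

#' Cross-tabulate paired readings into a fourfold table
#'
#' Records carry one row per subject and hemisphere with the binary map
#' reading (blue in the medial temporal region) and the ordinal MTA score;
#' the scale reading is positive when `mta_score >= 2` (the conventional
#' pathological cut). Incomplete records are excluded with a warning.
#'
#' @param records data.frame with columns `subject_id`, `diagnosis`,
#'   `hemisphere`, `map_reading` (0/1 or logical), `mta_score` (0-4).
#' @param cohort diagnosis stratum to tabulate (e.g. `"AD"`).
#' @param hemisphere hemisphere stratum (e.g. `"left"`).
#' @param mtaCut pathological MTA threshold (default 2).
#' @return A [FourfoldTable-class].
#' @export
crosstabReadings <- function(records, cohort, hemisphere, mtaCut = 2) {
  need <- c("subject_id", "diagnosis", "hemisphere", "map_reading", "mta_score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    dataError("records are missing column(s): %s", paste(miss, collapse = ", "))
  r <- records[records$diagnosis == cohort & records$hemisphere == hemisphere, ]
  if (nrow(r) == 0)
    dataError("no records for stratum (%s, %s)", cohort, hemisphere)
  bad <- is.na(r$map_reading) | is.na(r$mta_score) |
    r$mta_score < 0 | r$mta_score > 4
  if (any(bad)) {
    warning(sprintf("excluding %d incomplete/invalid record(s): %s",
                    sum(bad), paste(head(r$subject_id[bad], 5), collapse = ", ")))
    r <- r[!bad, ]
    if (nrow(r) == 0) dataError("no complete records for stratum (%s, %s)",
                                cohort, hemisphere)
  }
  r <- r[order(r$subject_id), ]  # order invariance
  mapPos <- as.logical(r$map_reading)
  mtaPos <- r$mta_score >= mtaCut
  fourfoldTable(sum(mapPos & mtaPos), sum(mapPos & !mtaPos),
                sum(!mapPos & mtaPos), sum(!mapPos & !mtaPos),
                cohort = cohort, hemisphere = hemisphere)
}

#' Positivity rate of one method in a fourfold table
#'
#' The fraction of subjects read positive: `(a + b) / n` for the map,
#' `(a + c) / n` for the visual scale. In a patient stratum this is the
#' method's sensitivity; in healthy controls it is 1 - specificity.
#'
#' @param t a [FourfoldTable-class].
#' @param method `"map"` or `"mta"`.
#' @return The proportion; attribute `"percent"` carries the value in
#'   percent rounded half-up to 1 decimal.
#' @export
positivityRate <- function(t, method = c("map", "mta")) {
  method <- match.arg(method)
  n <- tableN(t)
  if (n == 0) argumentError("empty table")
  p <- if (method == "map") (t@a + t@b) / n else (t@a + t@c) / n
  structure(p, percent = roundHalfUp(100 * p, 1))
}

#' Specificity of one method in a healthy-control fourfold table
#'
#' `(c + d) / n` for the map, `(b + d) / n` for the visual scale — the
#' complement of the positivity rate.
#'
#' @inheritParams positivityRate
#' @return The proportion, with a `"percent"` attribute as in
#'   [positivityRate()].
#' @export
specificity <- function(t, method = c("map", "mta")) {
  method <- match.arg(method)
  p <- 1 - as.numeric(positivityRate(t, method))
  structure(p, percent = roundHalfUp(100 * p, 1))
}

#' McNemar's test for paired binary readings
#'
#' Tests marginal homogeneity of the two readings from the discordant
#' cells `b` and `c`. `"chi2_cc"` is the continuity-corrected chi-squared
#' `(|b - c| - 1)^2 / (b + c)` on 1 df; `"exact"` is the two-sided
#' binomial test of `b` successes in `b + c` trials at p = 1/2; `"auto"`
#' (default) uses the exact test when `b + c < 25`. With no discordant
#' pairs the result is flagged and p = 1.
#'
#' @param t a [FourfoldTable-class].
#' @param mode `"auto"`, `"exact"` or `"chi2_cc"`.
#' @return list: `statistic` (chi-squared value or `NA` for exact),
#'   `p.value`, `method`, `flagged` (no-discordance degenerate case).
#' @export
mcnemarTest <- function(t, mode = c("auto", "exact", "chi2_cc")) {
  mode <- match.arg(mode)
  b <- t@b; c <- t@c
  if (b + c == 0)
    return(list(statistic = NA_real_, p.value = 1,
                method = "no discordant pairs", flagged = TRUE))
  if (mode == "auto") mode <- if (b + c < 25) "exact" else "chi2_cc"
  if (mode == "exact") {
    ht <- binom.test(b, b + c, p = 0.5)
    list(statistic = NA_real_, p.value = ht$p.value,
         method = "exact (binomial)", flagged = FALSE)
  } else {
    m <- matrix(c(t@a, t@c, t@b, t@d), 2, 2)
    ht <- mcnemar.test(m, correct = TRUE)
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "chi-squared with continuity correction", flagged = FALSE)
  }
}

#' The bundled reader-study fourfold tables
#'
#' Six 2x2 tables (AD, MCI and healthy-control strata, left and right
#' hemispheres) cross-classifying map-based medial temporal atrophy
#' readings against the MTA visual rating scale (pathological at >= 2),
#' from a published feasibility reader study on ADNI subjects. They ship
#' with the package as
#' `system.file("extdata", "reader_study_fourfold.csv", package = "voxnorm")`
#' and serve as the reference input for [evaluateStudy()].
#'
#' @return A named list of six [FourfoldTable-class] objects.
#' @export
readerStudyTables <- function() {
  path <- system.file("extdata", "reader_study_fourfold.csv",
                      package = "voxnorm", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    fourfoldTable(df$a[i], df$b[i], df$c[i], df$d[i],
                  cohort = df$cohort[i], hemisphere = df$hemisphere[i]))
  names(out) <- paste(df$cohort, df$hemisphere, sep = "_")
  out
}

#' Evaluate a reader study
#'
#' Computes, per stratum and hemisphere, the fourfold table, positivity
#' rates of both methods (in percent, half-up to 1 decimal), the implied
#' specificities, and McNemar's test.
#'
#' @param x either a data.frame of reading records (see
#'   [crosstabReadings()]) or a list of [FourfoldTable-class] objects.
#' @param mcnemarMode passed to [mcnemarTest()]; the default `"chi2_cc"`
#'   suits the large discordance counts of typical strata.
#' @return A data.frame with one row per (cohort, hemisphere): counts
#'   `a, b, c, d, n`, `map_rate_pct`, `mta_rate_pct`, `map_spec_pct`,
#'   `mta_spec_pct`, `mcnemar_chi2`, `mcnemar_p`.
#' @export
evaluateStudy <- function(x, mcnemarMode = "chi2_cc") {
  tabs <- if (is.data.frame(x)) {
    strata <- unique(x[, c("diagnosis", "hemisphere")])
    strata <- strata[order(strata$diagnosis, strata$hemisphere), ]
    lapply(seq_len(nrow(strata)), function(i)
      crosstabReadings(x, strata$diagnosis[i], strata$hemisphere[i]))
  } else x
  rows <- lapply(tabs, function(t) {
    mc <- mcnemarTest(t, mcnemarMode)
    data.frame(cohort = t@cohort, hemisphere = t@hemisphere,
               a = t@a, b = t@b, c = t@c, d = t@d, n = tableN(t),
               map_rate_pct = attr(positivityRate(t, "map"), "percent"),
               mta_rate_pct = attr(positivityRate(t, "mta"), "percent"),
               map_spec_pct = attr(specificity(t, "map"), "percent"),
               mta_spec_pct = attr(specificity(t, "mta"), "percent"),
               mcnemar_chi2 = mc$statistic, mcnemar_p = mc$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a study report as Markdown + JSON
#'
#' @param report output of [evaluateStudy()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  lines <- c("# Reader-study report", "",
             "| Cohort | Hemisphere | n | Map rate % | Scale rate % | McNemar chi2 | p |",
             "|---|---|---|---|---|---|---|",
             sprintf("| %s | %s | %d | %.1f | %.1f | %s | %.3g |",
                     report$cohort, report$hemisphere, report$n,
                     report$map_rate_pct, report$mta_rate_pct,
                     ifelse(is.na(report$mcnemar_chi2), "-",
                            sprintf("%.2f", report$mcnemar_chi2)),
                     report$mcnemar_p))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
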