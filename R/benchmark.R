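# Slide-quality benchmarking: per-institute ranking, paired scanner
# comparison and temporal monitoring of artifact burden.

# column holding a metric in a records data frame
metric_column <- function(metric) {
  if (metric %in% c("any_artifact", "any_artifact_pct")) return("any_artifact_pct")
  cls <- setdiff(artifact_scheme()$names, c("background", "tissue_no_artifact"))
  stop_if_not(metric %in% cls, "unknown metric: ", metric)
  paste0(metric, "_pct")
}

#' Build a slide-records table from QC summaries
#'
#' @param summaries List of `qc_slide_summary`.
#' @param institute_id,scanner_id,date Per-slide metadata vectors (recycled).
#' @return A records data frame: `slide_id`, `institute_id`, `scanner_id`,
#'   `date` (ISO-8601), one `<class>_pct` column per artifact class,
#'   `artifact_free_pct`, `any_artifact_pct`, `tissue_area_mm2`.
#' @export
records_from_summaries <- function(summaries, institute_id, scanner_id, date) {
  stop_if_not(length(summaries) >= 1, "no summaries", class = "slideqc_data_error")
  n <- length(summaries)
  base <- data.frame(slide_id = vapply(summaries, `[[`, "", "slide_id"),
                     institute_id = rep_len(institute_id, n),
                     scanner_id = rep_len(scanner_id, n),
                     date = rep_len(as.character(date), n))
  pct <- do.call(rbind, lapply(summaries, function(s) s$class_pct))
  colnames(pct) <- paste0(colnames(pct), "_pct")
  cbind(base, as.data.frame(pct),
        artifact_free_pct = vapply(summaries, `[[`, 0, "artifact_free_pct"),
        any_artifact_pct = vapply(summaries, `[[`, 0, "any_artifact_pct"),
        tissue_area_mm2 = vapply(summaries, `[[`, 0, "tissue_area_mm2"))
}

#' @rdname records_from_summaries
#' @param records A records data frame.
#' @param path CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname records_from_summaries
#' @export
read_records <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

# five-number + whisker/outlier stats of one numeric vector (type-7 quartiles;
# whiskers reach the furthest datum within 1.5*IQR of the quartiles)
group_stats <- function(x, group = NA_character_) {
  x <- x[is.finite(x)]
  stop_if_not(length(x) >= 1, "empty group", class = "slideqc_data_error")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(group = group, n = length(x), mean = mean(x), median = q[2],
       q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]))
}

stats_to_df <- function(stat_list) {
  df <- do.call(rbind, lapply(stat_list, function(s)
    data.frame(group = s$group, n = s$n, mean = s$mean, median = s$median,
               q1 = s$q1, q3 = s$q3, iqr = s$iqr,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               n_outliers = length(s$outliers))))
  df$outliers <- I(lapply(stat_list, `[[`, "outliers"))
  df
}

#' Rank institutes by mean artifact burden
#'
#' Groups slide records by institute and returns box-plot statistics of the
#' chosen metric per institute, sorted ascending by mean (the mean over the
#' whole slide set is the benchline a new institute compares against).
#'
#' @param records Records data frame (see [records_from_summaries]).
#' @param metric `"any_artifact"` or an artifact class name.
#' @return Data frame of per-institute stats (`group`, `n`, `mean`, `median`,
#'   `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`, `n_outliers`,
#'   `outliers` list column), ranked by mean; attribute `benchline` holds the
#'   overall mean.
#' @export
institute_stats <- function(records, metric = "any_artifact") {
  stop_if_not(is.data.frame(records) && nrow(records) >= 1,
              "no records", class = "slideqc_data_error")
  col <- metric_column(metric)
  groups <- split(records[[col]], records$institute_id)
  st <- Map(group_stats, groups, names(groups))
  df <- stats_to_df(st[order(vapply(st, `[[`, 0, "mean"))])
  attr(df, "benchline") <- mean(records[[col]], na.rm = TRUE)
  attr(df, "metric") <- metric
  df
}

#' Paired comparison of two scanners
#'
#' Slides scanned on both systems are paired by `slide_id`; the estimate is
#' the mean within-slide difference (scanner B minus scanner A) with a 95
#' percent paired Student-t confidence interval (or a bootstrap percentile
#' interval). Swapping the scanners negates the estimate and mirrors the
#' interval.
#'
#' @param records Records data frame containing exactly the two scanners'
#'   rows (every slide present for both).
#' @param metric `"any_artifact"` or an artifact class name.
#' @param scanners Length-2 character vector naming scanners A and B;
#'   defaults to the sorted unique scanner ids.
#' @param ci `"t"` (default) or `"bootstrap"`.
#' @param conf Confidence level (default 0.95).
#' @param nboot,seed Bootstrap resamples and seed (bootstrap only).
#' @return List: `points` (data frame `slide_id`, `a`, `b`), `mean_diff`,
#'   `ci` (length 2), `scanners`, `n`.
#' @export
scanner_compare <- function(records, metric = "any_artifact", scanners = NULL,
                            ci = c("t", "bootstrap"), conf = 0.95,
                            nboot = 2000, seed = 1L) {
  ci <- match.arg(ci)
  col <- metric_column(metric)
  if (is.null(scanners)) scanners <- sort(unique(records$scanner_id))
  stop_if_not(length(scanners) == 2, "need exactly two scanners")
  a <- records[records$scanner_id == scanners[1], ]
  b <- records[records$scanner_id == scanners[2], ]
  stop_if_not(nrow(a) == nrow(b) && setequal(a$slide_id, b$slide_id) &&
              !anyDuplicated(a$slide_id) && !anyDuplicated(b$slide_id),
              "every slide must be present for both scanners exactly once",
              class = "slideqc_pairing_error")
  b <- b[match(a$slide_id, b$slide_id), ]
  d <- b[[col]] - a[[col]]
  n <- length(d)
  m <- mean(d)
  interval <- if (ci == "t") {
    if (n < 2 || stats::sd(d) == 0) c(m, m)
    else m + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(d) / sqrt(n)
  } else {
    bm <- with_seed(seed, vapply(seq_len(nboot), function(i)
      mean(d[sample.int(n, n, replace = TRUE)]), numeric(1)))
    stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  list(points = data.frame(slide_id = a$slide_id, a = a[[col]], b = b[[col]]),
       mean_diff = m, ci = interval, scanners = scanners, n = n)
}

#' Box-plot statistics of artifact burden over time
#'
#' Partitions records into calendar periods and computes the same statistics
#' as [institute_stats] per period, in chronological order. Records whose
#' date does not parse as ISO-8601 are dropped with a message.
#'
#' @param records Records data frame.
#' @param granularity `"year"`, `"month"`, `"week"` (ISO week) or `"day"`.
#' @param metric `"any_artifact"` or an artifact class name.
#' @return Data frame of per-period stats, chronologically ordered.
#' @export
temporal_stats <- function(records, granularity = c("year", "month", "week", "day"),
                           metric = "any_artifact") {
  granularity <- match.arg(granularity)
  col <- metric_column(metric)
  dates <- as.Date(records$date, format = "%Y-%m-%d")
  bad <- is.na(dates)
  if (any(bad)) {
    message(sum(bad), " record(s) with unparseable dates dropped: ",
            paste(utils::head(records$slide_id[bad], 5), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
    dates <- dates[!bad]
  }
  stop_if_not(nrow(records) >= 1, "no records with valid dates",
              class = "slideqc_data_error")
  key <- switch(granularity,
                year = format(dates, "%Y"),
                month = format(dates, "%Y-%m"),
                week = format(dates, "%G-W%V"),
                day = format(dates, "%Y-%m-%d"))
  groups <- split(records[[col]], key)
  st <- Map(group_stats, groups, names(groups))
  df <- stats_to_df(st[order(names(groups))])
  attr(df, "metric") <- metric
  df
}

# open a raster graphics device, falling back to pdf when png is unavailable
open_figure <- function(path, width = 7, height = 5) {
  ok <- tryCatch({
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) grDevices::pdf(sub("\\.png$", ".pdf", path), width = width, height = height)
  invisible(ok)
}

#' Write a benchmark report
#'
#' For each stats table: a CSV, a machine-readable JSON twin (including
#' outliers) and a box-plot figure.
#'
#' @param stats A stats data frame from [institute_stats] or
#'   [temporal_stats], or a named list of them.
#' @param out_dir Output directory.
#' @return Character vector of written files, invisibly.
#' @export
write_report <- function(stats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(stats)) stats <- list(stats = stats)
  written <- character(0)
  for (nm in names(stats)) {
    df <- stats[[nm]]
    flat <- df[setdiff(names(df), "outliers")]
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(flat, csv, row.names = FALSE)
    js <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(lapply(seq_len(nrow(df)), function(i)
      c(as.list(flat[i, ]), list(outliers = df$outliers[[i]]))), js,
      auto_unbox = TRUE, digits = NA)
    fig <- file.path(out_dir, paste0(nm, ".png"))
    open_figure(fig)
    graphics::bxp(list(
      stats = t(as.matrix(df[, c("whisker_low", "q1", "median", "q3", "whisker_high")])),
      n = df$n, names = df$group,
      out = unlist(df$outliers),
      group = rep(seq_len(nrow(df)), lengths(df$outliers))),
      main = attr(df, "metric") %||% nm, ylab = "% area", las = 2)
    graphics::points(seq_len(nrow(df)), df$mean, pch = 19, col = "black")
    grDevices::dev.off()
    written <- c(written, csv, js, fig)
  }
  invisible(written)
}
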