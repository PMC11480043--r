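#' Absolute percent error of a measurement
#'
#' `|actual - measured| / actual * 100`, the per-model error statistic used in
#' all validation tables. Scale invariant: multiplying both arguments by a
#' common factor leaves the result unchanged.
#'
#' @param actual true value(s), strictly positive.
#' @param measured measured value(s), non-negative. Recycled against `actual`.
#' @return Percent error(s) on the 0-100 scale (can exceed 100).
#' @examples
#' percent_error(7.1, 6.60) # 7.04
#' @export
percent_error <- function(actual, measured) {
  if (anyNA(actual) || any(actual <= 0))
    stop("percent_error: 'actual' must be strictly positive")
  if (anyNA(measured) || any(measured < 0))
    stop("percent_error: 'measured' must be non-negative")
  abs(actual - measured) / actual * 100
}

#' Root-mean-square average of percent errors
#'
#' Aggregates a set of per-subject percent errors as `sqrt(mean(e^2))`. This
#' quadratic mean is the aggregation used for the headline error rates (5.16%
#' waistline, 4.58% hip on the sixteen prototype models); it always dominates
#' the arithmetic mean, with equality only when all errors are equal.
#'
#' @param errors numeric vector of non-negative percent errors, length >= 1.
#' @return The RMS average, same scale as the inputs.
#' @examples
#' rms_average(c(3, 4)) # 3.536
#' @export
rms_average <- function(errors) {
  if (length(errors) < 1L) stop("rms_average: 'errors' must be non-empty")
  if (anyNA(errors) || any(errors < 0))
    stop("rms_average: errors must be non-negative and non-missing")
  sqrt(mean(errors^2))
}

#' Summarise actual-vs-measured records
#'
#' Builds the per-record percent errors and both aggregates (RMS and plain
#' mean; the RMS is the headline statistic, the mean is reported for
#' transparency).
#'
#' @param actual,measured vectors of positive actual and non-negative measured
#'   values (cm).
#' @param labels optional record labels; defaults to `"S1"`, `"S2"`, ...
#' @return An object of class `error_summary`: list with `n`, `rms_percent`,
#'   `mean_percent` and a `records` data frame
#'   (`label`, `actual_cm`, `measured_cm`, `percent_error`).
#' @examples
#' error_summary(c(10, 8), c(9.5, 8.4))
#' @export
error_summary <- function(actual, measured, labels = NULL) {
  if (length(actual) != length(measured))
    stop("error_summary: 'actual' and 'measured' must have the same length")
  if (is.null(labels)) labels <- paste0("S", seq_along(actual))
  pe <- percent_error(actual, measured)
  structure(list(
    n = length(pe),
    rms_percent = rms_average(pe),
    mean_percent = mean(pe),
    records = data.frame(label = as.character(labels), actual_cm = actual,
                         measured_cm = measured, percent_error = pe,
                         stringsAsFactors = FALSE)
  ), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d, RMS error = %.2f%%, mean error = %.2f%%\n",
              x$n, x$rms_percent, x$mean_percent))
  print(transform(x$records, percent_error = round(percent_error, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Compare the cosine and ellipse girth methods against known truth
#'
#' Builds the actual / cosine / ellipse comparison for the waist and hip
#' landmarks, reports the percent error of each method and flags the closer
#' method per landmark ("tie" when equal).
#'
#' @param measurements a `body_measurements` object (see [measure_subject()]),
#'   or a list with numeric entries `waist_cm` and `hip_cm`, each itself a
#'   list with `cosine` and `ellipse` values.
#' @param truth list or named numeric with positive entries `waist` and `hip`
#'   (cm).
#' @return A data frame with one row per landmark: `landmark`, `actual_cm`,
#'   `cosine_cm`, `ellipse_cm`, `cosine_error_pct`, `ellipse_error_pct`,
#'   `closer`.
#' @examples
#' m <- list(waist_cm = list(cosine = 7.29, ellipse = 7.22),
#'           hip_cm = list(cosine = 10.11, ellipse = 9.34))
#' compare_methods(m, list(waist = 7.60, hip = 10.10))
#' @export
compare_methods <- function(measurements, truth) {
  truth <- as.list(truth)
  if (is.null(truth$waist) || is.null(truth$hip) ||
      truth$waist <= 0 || truth$hip <= 0)
    stop("compare_methods: 'truth' must contain positive 'waist' and 'hip'")
  get2 <- function(lm) {
    v <- measurements[[lm]]
    if (is.null(v$cosine) || is.null(v$ellipse))
      stop(sprintf("compare_methods: measurements$%s must have 'cosine' and 'ellipse'", lm))
    c(cosine = v$cosine, ellipse = v$ellipse)
  }
  rows <- lapply(c(waist = "waist_cm", hip = "hip_cm"), get2)
  actual <- c(waist = truth$waist, hip = truth$hip)
  out <- do.call(rbind, lapply(names(rows), function(lm) {
    v <- rows[[lm]]
    ec <- percent_error(actual[lm], v["cosine"])
    ee <- percent_error(actual[lm], v["ellipse"])
    closer <- if (abs(ec - ee) < 1e-12) "tie" else if (ec < ee) "cosine" else "ellipse"
    data.frame(landmark = lm, actual_cm = unname(actual[lm]),
               cosine_cm = unname(v["cosine"]), ellipse_cm = unname(v["ellipse"]),
               cosine_error_pct = unname(ec), ellipse_error_pct = unname(ee),
               closer = closer, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Longitudinal change report between two measurement sessions
#'
#' Differences the waist and hip circumferences of two `body_measurements`
#' taken with the same configuration (landmark bands and row count must
#' match, otherwise the landmarks are not comparable). Sign convention:
#' negative deltas mean slimming.
#'
#' @param old,new `body_measurements` objects from [measure_subject()], or
#'   lists with the same `waist_cm` / `hip_cm` structure plus a `config`
#'   entry.
#' @return An object of class `change_report`: per-landmark, per-method deltas
#'   in cm (`new - old`, exact) and in percent of the old value.
#' @export
monitor_change <- function(old, new) {
  key <- function(m) {
    cfg <- m$config
    if (is.null(cfg)) return(NULL)
    list(n_rows = cfg$n_rows, waist_band = cfg$waist_band, hip_band = cfg$hip_band)
  }
  ko <- key(old); kn <- key(new)
  if (!is.null(ko) && !is.null(kn) && !isTRUE(all.equal(ko, kn)))
    stop("monitor_change: configuration mismatch between 'old' and 'new' ",
         "(landmark bands / n_rows differ)")
  one <- function(lm, method) {
    o <- old[[lm]][[method]]; n <- new[[lm]][[method]]
    if (is.null(o) || is.null(n))
      stop(sprintf("monitor_change: missing %s/%s value", lm, method))
    data.frame(landmark = sub("_cm$", "", lm), method = method,
               old_cm = o, new_cm = n, delta_cm = n - o,
               delta_pct = (n - o) / o * 100, stringsAsFactors = FALSE)
  }
  grid <- expand.grid(lm = c("waist_cm", "hip_cm"),
                      method = c("cosine", "ellipse"),
                      stringsAsFactors = FALSE)
  deltas <- do.call(rbind, Map(one, grid$lm, grid$method))
  rownames(deltas) <- NULL
  structure(list(old = old, new = new, deltas = deltas),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat("<change_report> (negative delta = slimming)\n")
  d <- x$deltas
  d$old_cm <- round(d$old_cm, 2); d$new_cm <- round(d$new_cm, 2)
  d$delta_cm <- round(d$delta_cm, 2); d$delta_pct <- round(d$delta_pct, 2)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write an error summary to JSON and CSV
#'
#' @param summary an `error_summary`.
#' @param path_prefix output path without extension; writes
#'   `<prefix>.json` and `<prefix>.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_summary <- function(summary, path_prefix) {
  jp <- paste0(path_prefix, ".json")
  cp <- paste0(path_prefix, ".csv")
  jsonlite::write_json(list(n = summary$n,
                            rms_percent = summary$rms_percent,
                            mean_percent = summary$mean_percent),
                       jp, auto_unbox = TRUE, digits = NA)
  utils::write.csv(summary$records, cp, row.names = FALSE)
  invisible(c(jp, cp))
}

#' Render an error summary or method comparison as a Markdown table
#'
#' Values are rounded to 2 decimals for display (full precision is kept in
#' the underlying objects).
#'
#' @param x an `error_summary` or the data frame from [compare_methods()].
#' @return A character vector of Markdown lines.
#' @export
report_markdown <- function(x) {
  df <- if (inherits(x, "error_summary")) x$records else x
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  lines <- c(header, sep, unname(body))
  if (inherits(x, "error_summary"))
    lines <- c(lines, "",
               sprintf("RMS error: %.2f%%; mean error: %.2f%% (n = %d)",
                       x$rms_percent, x$mean_percent, x$n))
  lines
}
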