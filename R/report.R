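#' Write a stage result to CSV or JSON
#'
#' Flat tables go to CSV with a deterministic column order and numeric
#' columns at a fixed precision (6 significant digits by default); nested
#' records go to JSON at full precision, so they round-trip losslessly.
#'
#' @param results a data.frame (CSV or JSON) or list (JSON).
#' @param path output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @param digits significant digits for CSV numeric columns.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = NULL, digits = 6L) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "json"))
      stop_ib("cannot infer format from extension; pass format=")
  }
  format <- match.arg(format, c("csv", "json"))
  ok <- tryCatch({
    if (format == "csv") {
      if (!is.data.frame(results)) results <- as.data.frame(results)
      listcols <- vapply(results, is.list, logical(1L))
      for (cl in names(results)[listcols])
        results[[cl]] <- vapply(results[[cl]], function(v)
          paste(v, collapse = ";"), character(1L))
      num <- vapply(results, is.numeric, logical(1L))
      for (cl in names(results)[num]) results[[cl]] <- signif(results[[cl]], digits)
      utils::write.csv(results, path, row.names = FALSE)
    } else {
      jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_ib("cannot write report to ", path, ": ",
                           conditionMessage(ok))
  invisible(path)
}

#' Render the binding-time summary in the published table layout
#'
#' Formats per-condition binding-event counts as "count (percentage)" cells
#' per duration threshold, with per-site rows and an aggregate row per
#' condition (percentages of that condition's grand total).
#'
#' @param counts data.frame like [clcry4_binding_counts()]: columns
#'   `condition`, `site`, `total` and `ge_<t>ns` counts.
#' @param thresholds duration thresholds (ns) matching the count columns.
#' @return data.frame with formatted character columns, one row per
#'   condition-site plus aggregate rows.
#' @export
make_table2_report <- function(counts, thresholds = c(1, 10, 100)) {
  counts <- as.data.frame(counts)
  if (!"condition" %in% names(counts)) counts$condition <- "I"
  cols <- paste0("ge_", thresholds, "ns")
  out <- list()
  for (cond in unique(counts$condition)) {
    cc <- counts[counts$condition == cond, , drop = FALSE]
    summ <- binding_count_summary(cc[, c("site", "total", cols)],
                                  thresholds = thresholds)
    block <- data.frame(condition = cond, site = as.character(summ$site),
                        total = summ$total, stringsAsFactors = FALSE)
    for (th in thresholds) {
      cl <- paste0("ge_", th, "ns")
      block[[cl]] <- sprintf("%d (%.1f%%)", summ[[cl]],
                             summ[[paste0("pct_", cl)]])
    }
    out[[cond]] <- block
  }
  if (!length(out)) {
    res <- data.frame(condition = character(), site = character(),
                      total = integer(), stringsAsFactors = FALSE)
    for (th in thresholds) res[[paste0("ge_", th, "ns")]] <- character()
    return(res)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
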