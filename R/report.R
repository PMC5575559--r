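## numeric -> text that survives a round trip exactly
fmt_num <- function(v) {
  out <- vapply(v, function(x) {
    if (is.na(x)) "" else sprintf("%.17g", x)
  }, character(1L))
  out
}

flatten_records <- function(records) {
  rows <- lapply(records, function(rec) {
    base <- data.frame(image_id = rec$image_id,
                       culture_day = rec$culture_day,
                       is_aggregate = rec$is_aggregate,
                       carrier_object_count = rec$carrier_object_count,
                       stringsAsFactors = FALSE)
    if (nrow(rec$carriers) == 0L) {
      cbind(base, carrier_index = NA_integer_,
            center_row = NA_real_, center_col = NA_real_,
            radius_px = NA_real_, score = NA_real_,
            confluence_pct = NA_real_, cells_visible = NA_integer_,
            cells_corrected = NA_integer_)
    } else {
      cbind(base[rep(1L, nrow(rec$carriers)), , drop = FALSE],
            carrier_index = seq_len(nrow(rec$carriers)),
            rec$carriers)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write analysis records to CSV or JSON
#'
#' Writes one row per (image, carrier) pair — images without carriers get
#' a single image-level row with empty carrier fields — preserving record
#' order. Numbers are written at full precision so that
#' [read_report()] reproduces the records exactly.
#'
#' @param records non-empty list of [report_record()] objects.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(records, "report_record")) records <- list(records)
  if (length(records) == 0L) stop("records must be non-empty")
  if (!all(vapply(records, inherits, logical(1L), "report_record")))
    stop("records must all be report_record objects")
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    stop(sprintf("cannot write to '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE),
                  warning = function(w)
                    stop(sprintf("cannot write to '%s'", path), call. = FALSE))
  on.exit(close(con))

  if (format == "csv") {
    flat <- flatten_records(records)
    for (nm in names(flat))
      if (is.double(flat[[nm]])) flat[[nm]] <- fmt_num(flat[[nm]])
    utils::write.csv(flat, con, row.names = FALSE, na = "")
  } else {
    payload <- lapply(records, function(rec) {
      list(image_id = rec$image_id,
           culture_day = rec$culture_day,
           is_aggregate = rec$is_aggregate,
           carrier_object_count = rec$carrier_object_count,
           carriers = rec$carriers)
    })
    writeLines(jsonlite::toJSON(payload, dataframe = "columns",
                                digits = NA, auto_unbox = TRUE,
                                na = "null", null = "null"), con)
  }
  invisible(path)
}

#' Read analysis records written by write_report
#'
#' @param path file written by [write_report()].
#' @param format `"csv"` or `"json"`; `NULL` infers from the extension.
#' @return list of [report_record()] objects.
#' @export
read_report <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("report file not found: '%s'", path))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "json"))
      stop("cannot infer report format; pass format = 'csv' or 'json'")
  }
  if (format == "csv") {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(image_id = "character"))
    ids <- unique(flat$image_id)
    lapply(ids, function(id) {
      sub <- flat[flat$image_id == id, , drop = FALSE]
      has_carriers <- !all(is.na(sub$carrier_index))
      carriers <- if (has_carriers) {
        data.frame(center_row = as.numeric(sub$center_row),
                   center_col = as.numeric(sub$center_col),
                   radius_px = as.numeric(sub$radius_px),
                   score = as.numeric(sub$score),
                   confluence_pct = as.numeric(sub$confluence_pct),
                   cells_visible = as.integer(sub$cells_visible),
                   cells_corrected = as.integer(sub$cells_corrected))
      } else empty_carrier_rows()
      report_record(id, carriers,
                    culture_day = sub$culture_day[1L],
                    is_aggregate = sub$is_aggregate[1L],
                    carrier_object_count = sub$carrier_object_count[1L])
    })
  } else {
    payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    lapply(payload, function(rec) {
      carriers <- if (length(rec$carriers$center_row) == 0L)
        empty_carrier_rows()
      else
        data.frame(center_row = as.numeric(rec$carriers$center_row),
                   center_col = as.numeric(rec$carriers$center_col),
                   radius_px = as.numeric(rec$carriers$radius_px),
                   score = as.numeric(rec$carriers$score),
                   confluence_pct = as.numeric(rec$carriers$confluence_pct),
                   cells_visible = as.integer(rec$carriers$cells_visible),
                   cells_corrected = as.integer(rec$carriers$cells_corrected))
      report_record(rec$image_id, carriers,
                    culture_day = if (is.null(rec$culture_day)) NA_integer_
                      else rec$culture_day,
                    is_aggregate = if (is.null(rec$is_aggregate)) NA
                      else rec$is_aggregate,
                    carrier_object_count =
                      if (is.null(rec$carrier_object_count)) NA_integer_
                      else rec$carrier_object_count)
    })
  }
}
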