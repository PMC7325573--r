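#' Write / read a batch record CSV
#'
#' The on-disk schema is fixed: header exactly
#' `time_h, T_C, pH, u1_rpm, DO_pct, u2_vvm, u3_mlh, P_gL`.
#'
#' @param batch batch data frame with the standard columns.
#' @param path CSV path.
#' @return `read_batch_csv()` returns a `batch_record` data frame.
#' @export
write_batch_csv <- function(batch, path) {
  b <- as.data.frame(batch)
  missing <- setdiff(BATCH_COLUMNS, names(b))
  if (length(missing)) {
    stop(sprintf("batch is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(b[, BATCH_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  missing <- setdiff(BATCH_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, BATCH_COLUMNS]
  class(df) <- c("batch_record", "data.frame")
  attr(df, "batch_id") <- sub("\\.csv$", "", basename(path))
  df
}
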