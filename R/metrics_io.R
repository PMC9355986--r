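# Fixed column orders for the tabular pipeline outputs. Re-reading a written
# table must reproduce values to 1e-9 relative, so everything is written with
# full double precision and "." as the decimal separator regardless of locale.

metrics_columns <- c(
  "bee_id", "interval_index", "start_sample", "qc_pass", "qc_reasons",
  "dominant_frequency_hz", "peak_fx_mn", "peak_fy_mn", "peak_fz_mn",
  "peak_displacement_um", "peak_velocity_mm_s", "peak_acceleration_m_s2"
)

validate_metrics <- function(table) {
  missing <- setdiff(metrics_columns, names(table))
  if (length(missing)) {
    stop("metrics table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  peaks <- grep("^peak_", metrics_columns, value = TRUE)
  for (p in peaks) {
    if (any(table[[p]] < 0, na.rm = TRUE)) {
      stop("peak quantities must be >= 0 (", p, ")", call. = FALSE)
    }
  }
  if (nrow(table) > 1) {
    for (b in unique(table$bee_id)) {
      idx <- table$interval_index[table$bee_id == b]
      if (any(diff(idx) <= 0)) {
        stop("interval_index must be strictly increasing within bee ", b,
             call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' Write or read a per-interval metrics table
#'
#' One row per 1024-sample analysis interval: QC outcome, dominant buzz
#' frequency and peak force/kinematic amplitudes in reporting units
#' (mN, µm, mm/s, m/s², Hz). Column order is fixed; values round-trip
#' through disk to better than 1e-9 relative.
#'
#' @param table Data frame with the columns documented in
#'   [analyze_recording()].
#' @param path Output (input) CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the data frame.
#' @export
write_metrics <- function(table, path) {
  validate_metrics(table)
  out <- table[metrics_columns]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
  })
  utils::write.table(out, path, sep = ",", dec = ".", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", dec = ".",
                          stringsAsFactors = FALSE,
                          colClasses = c(bee_id = "character",
                                         qc_reasons = "character"))
  df$qc_pass <- as.logical(df$qc_pass)
  df$qc_reasons[is.na(df$qc_reasons)] <- ""
  validate_metrics(df)
  df
}

#' Convert between newtons and millinewtons
#'
#' Involutive unit helpers used at I/O boundaries; the package's canonical
#' force unit is mN.
#' @param x Numeric vector.
#' @return Converted vector.
#' @export
mn_to_n <- function(x) x / 1000

#' @rdname mn_to_n
#' @export
n_to_mn <- function(x) x * 1000
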