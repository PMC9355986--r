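#' Construct a multichannel buzz recording
#'
#' A recording bundles the three force channels and the vibrometer velocity
#' channel of one trial, sampled synchronously. Canonical internal units are
#' fixed by contract: forces in millinewtons (mN), thorax velocity in mm/s.
#' Unit conversions happen only at I/O boundaries (see [read_recording()]).
#'
#' @param force_x,force_y,force_z Numeric vectors, per-sample force in mN.
#'   The x and z axes align with the bee's dorsal-ventral and
#'   dorsal-longitudinal flight muscle groups respectively.
#' @param velocity Numeric vector, thorax (scutum) velocity in mm/s.
#' @param sample_rate Sampling rate in Hz (positive scalar; recordings are
#'   assumed uniformly sampled).
#' @param t0 Time offset of the first sample in seconds.
#' @param bee_id Label for the individual.
#' @param post_material `"plastic"` or `"carbon"` mounting post.
#' @param source Free-text provenance.
#'
#' @return An object of class `buzz_recording`.
#' @export
buzz_recording <- function(force_x, force_y, force_z, velocity,
                           sample_rate, t0 = 0, bee_id = "bee1",
                           post_material = c("plastic", "carbon"),
                           source = "") {
  post_material <- match.arg(post_material)
  rec <- structure(
    list(
      force_x = as.numeric(force_x),
      force_y = as.numeric(force_y),
      force_z = as.numeric(force_z),
      velocity = as.numeric(velocity),
      sample_rate = as.numeric(sample_rate)[1],
      t0 = as.numeric(t0)[1],
      bee_id = as.character(bee_id)[1],
      post_material = post_material,
      source = as.character(source)[1]
    ),
    class = "buzz_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  chans <- c("force_x", "force_y", "force_z", "velocity")
  lens <- vapply(rec[chans], length, integer(1))
  if (any(lens < 1L)) stop("all channels must have length >= 1", call. = FALSE)
  if (length(unique(lens)) != 1L) {
    stop("channel lengths differ: ",
         paste(sprintf("%s=%d", chans, lens), collapse = ", "), call. = FALSE)
  }
  for (ch in chans) {
    bad <- which(!is.finite(rec[[ch]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in channel '%s' at sample %d", ch, bad[1]),
           call. = FALSE)
    }
  }
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0) {
    stop("sample_rate must be a positive finite scalar", call. = FALSE)
  }
  invisible(rec)
}

#' @export
length.buzz_recording <- function(x) length(x$velocity)

#' @export
print.buzz_recording <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<buzz_recording> %s (%s post)\n", x$bee_id, x$post_material))
  cat(sprintf("  %d samples at %g Hz (%.3f s)\n", n, x$sample_rate,
              n / x$sample_rate))
  cat(sprintf("  peak |Fx| %.1f mN, |Fy| %.1f mN, |Fz| %.1f mN, |v| %.1f mm/s\n",
              max(abs(x$force_x)), max(abs(x$force_y)), max(abs(x$force_z)),
              max(abs(x$velocity))))
  invisible(x)
}

#' @export
as.data.frame.buzz_recording <- function(x, ...) {
  n <- length(x)
  data.frame(
    t = x$t0 + (seq_len(n) - 1) / x$sample_rate,
    fx = x$force_x, fy = x$force_y, fz = x$force_z, v = x$velocity
  )
}

# Scale factors into canonical units (mN, mm/s)
.force_unit_scale <- c(mN = 1, N = 1000)
.velocity_unit_scale <- c(`mm/s` = 1, `m/s` = 1000)

#' Read a multichannel recording from delimited text
#'
#' Reads a CSV/TSV file with one column per channel plus either a time column
#' (from which the sample rate is inferred) or a sample-index column (in which
#' case `sample_rate` must be supplied). Column names are resolved through
#' `schema`, so archives with arbitrary headers can be ingested without
#' renaming. Lines starting with `#` are treated as `key=value` metadata
#' (as written by [write_recording()]) and may supply `sample_rate`, `t0`,
#' `bee_id` and `post_material`.
#'
#' The inferred sample interval must be uniform to within 1 ppm; irregular
#' time bases are rejected rather than resampled.
#'
#' @param path Path to a delimited text file (`.tsv`/`.txt` are read as
#'   tab-separated, anything else as comma-separated).
#' @param schema Named list mapping roles `time` (or `sample`), `fx`, `fy`,
#'   `fz`, `v` to column names in the file.
#' @param units Named list with elements `force` (`"mN"` or `"N"`) and
#'   `velocity` (`"mm/s"` or `"m/s"`); values are converted to the canonical
#'   mN and mm/s on read.
#' @param sample_rate Sampling rate in Hz; required when the schema uses a
#'   sample-index column, otherwise inferred from the time column.
#' @param bee_id,post_material Metadata overrides; defaults come from file
#'   header metadata when present.
#'
#' @return A [buzz_recording].
#' @export
read_recording <- function(path,
                           schema = list(time = "t", fx = "fx", fy = "fy",
                                         fz = "fz", v = "v"),
                           units = list(force = "mN", velocity = "mm/s"),
                           sample_rate = NULL,
                           bee_id = NULL, post_material = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!units$force %in% names(.force_unit_scale)) {
    stop("unit error: force unit must be one of ",
         paste(names(.force_unit_scale), collapse = ", "), call. = FALSE)
  }
  if (!units$velocity %in% names(.velocity_unit_scale)) {
    stop("unit error: velocity unit must be one of ",
         paste(names(.velocity_unit_scale), collapse = ", "), call. = FALSE)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  meta <- read_header_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)

  for (role in c("fx", "fy", "fz", "v")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(df)) {
      stop(sprintf("schema error: no column '%s' for channel '%s' in %s",
                   if (is.null(col)) "<unset>" else col, role, path),
           call. = FALSE)
    }
  }
  chan <- function(role) {
    x <- df[[schema[[role]]]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(x))
    if (length(bad)) {
      stop(sprintf("format error: non-finite value in column '%s' (row %d)",
                   schema[[role]], bad[1]), call. = FALSE)
    }
    x
  }
  fx <- chan("fx"); fy <- chan("fy"); fz <- chan("fz"); v <- chan("v")

  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else 0
  if (!is.null(schema$time) && schema$time %in% names(df)) {
    tt <- as.numeric(df[[schema$time]])
    if (length(tt) >= 2) {
      dt <- diff(tt)
      if (any(dt <= 0)) {
        stop("format error: time column is not strictly increasing",
             call. = FALSE)
      }
      if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
        stop("format error: time column is not uniform within 1 ppm",
             call. = FALSE)
      }
      sample_rate <- 1 / stats::median(dt)
    } else if (is.null(sample_rate)) {
      stop("sample_rate required for single-row input", call. = FALSE)
    }
    t0 <- tt[1]
  } else {
    if (is.null(sample_rate) && !is.null(meta$sample_rate)) {
      sample_rate <- as.numeric(meta$sample_rate)
    }
    if (is.null(sample_rate)) {
      stop("schema error: no time column and no sample_rate given",
           call. = FALSE)
    }
  }

  buzz_recording(
    force_x = fx * .force_unit_scale[[units$force]],
    force_y = fy * .force_unit_scale[[units$force]],
    force_z = fz * .force_unit_scale[[units$force]],
    velocity = v * .velocity_unit_scale[[units$velocity]],
    sample_rate = sample_rate, t0 = t0,
    bee_id = bee_id %||% meta$bee_id %||% "bee1",
    post_material = post_material %||% meta$post_material %||% "plastic",
    source = path
  )
}

read_header_meta <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as annotated CSV
#'
#' Writes the four channels in canonical units (mN, mm/s) with a `t` column
#' in seconds, preceded by `# key=value` metadata lines so that
#' [read_recording()] round-trips sample rate and trial metadata.
#'
#' @param rec A [buzz_recording].
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  hdr <- c(
    sprintf("# sample_rate=%.10g", rec$sample_rate),
    sprintf("# t0=%.10g", rec$t0),
    sprintf("# bee_id=%s", rec$bee_id),
    sprintf("# post_material=%s", rec$post_material),
    "# units: fx,fy,fz in mN; v in mm/s; t in s"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    format(as.data.frame(rec), digits = 17, scientific = FALSE, trim = TRUE),
    con, sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
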