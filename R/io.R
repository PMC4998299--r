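#' Build a paired-series object from long-format records
#'
#' Validates and normalises a long table of serial paired measurements
#' (one row per subject, device and time point, with a reference-method
#' and a test-method value) and applies the record-exclusion rules:
#'
#' * rows with a missing reference or test value are dropped (both changes
#'   touching a dropped row are later excluded — a gap is never bridged);
#' * when `drop_first = TRUE`, the first pair of every subject–device
#'   series is dropped, mirroring designs in which the first simultaneous
#'   measurement is consumed to calibrate the test device.
#'
#' Every exclusion is logged with its reason in the `exclusions` attribute.
#'
#' @param data a data frame in long format.
#' @param cols named character vector mapping the standard roles
#'   `subject`, `device`, `time`, `rm`, `tm` to column names in `data`.
#'   `device` may be omitted when there is a single test method.
#' @param drop_first drop the first pair of each subject–device series
#'   (calibration exclusion). Defaults to `FALSE` for in-memory data;
#'   [read_series()] defaults it to `TRUE`.
#' @return a data frame of class `"paired_series"` with standardised
#'   columns `subject`, `device`, `time`, `rm`, `tm`, ordered by subject,
#'   device and time; attributes `exclusions` (data frame with a `reason`
#'   per dropped row) and `n_input` (rows read in).
#' @examples
#' d <- data.frame(subject = 1, time = 1:3, rm = c(3, 4, 5), tm = c(3.1, 4.2, 5.1))
#' as_paired_series(d)
#' @export
as_paired_series <- function(data,
                             cols = c(subject = "subject", device = "device",
                                      time = "time", rm = "rm", tm = "tm"),
                             drop_first = FALSE) {
  stopifnot(is.data.frame(data))
  defaults <- c(subject = "subject", device = "device", time = "time",
                rm = "rm", tm = "tm")
  defaults[names(cols)] <- cols
  cols <- defaults

  need <- c("subject", "time", "rm", "tm")
  missing_cols <- setdiff(cols[need], names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    subject = as.character(data[[cols["subject"]]]),
    device = if (cols["device"] %in% names(data)) {
      as.character(data[[cols["device"]]])
    } else "TM",
    time = data[[cols["time"]]],
    rm = data[[cols["rm"]]],
    tm = data[[cols["tm"]]],
    stringsAsFactors = FALSE
  )
  for (v in c("time", "rm", "tm")) {
    if (!is.numeric(df[[v]])) {
      suppressWarnings(num <- as.numeric(df[[v]]))
      bad <- which(!is.na(df[[v]]) & df[[v]] != "" & is.na(num))
      if (length(bad)) {
        stop("non-numeric value in column '", cols[v], "' at row ",
             bad[1], call. = FALSE)
      }
      df[[v]] <- num
    }
  }
  key <- paste(df$subject, df$device, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (subject, device, time) key: (%s, %s, %s)",
                 dup$subject, dup$device, format(dup$time)), call. = FALSE)
  }
  if (any(is.na(df$time))) {
    stop("missing time index", call. = FALSE)
  }
  df <- df[order(df$subject, df$device, df$time), , drop = FALSE]
  n_input <- nrow(df)

  reason <- rep(NA_character_, n_input)
  reason[is.na(df$rm) | is.na(df$tm)] <- "missing_value"
  if (drop_first) {
    first <- !duplicated(paste(df$subject, df$device, sep = "\r"))
    reason[first & is.na(reason)] <- "calibration_first_pair"
  }
  exclusions <- df[!is.na(reason), c("subject", "device", "time"), drop = FALSE]
  exclusions$reason <- reason[!is.na(reason)]
  kept <- df[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rownames(exclusions) <- NULL
  structure(kept,
            exclusions = exclusions,
            n_input = n_input,
            class = c("paired_series", "data.frame"))
}

#' Read paired serial measurements from a delimited text file
#'
#' Reads a long-format delimited file (one row per subject, device and
#' time point) and applies the exclusion rules of [as_paired_series()].
#' The calibration exclusion (`drop_first`) defaults to `TRUE` here: in
#' monitor-validation studies the first simultaneous measurement typically
#' calibrates the test device and must not contribute a change.
#'
#' @param path path to the file.
#' @param cols column mapping, see [as_paired_series()].
#' @param sep field delimiter (default comma); a header row is required.
#' @param drop_first drop each subject–device series' first pair.
#' @return a `"paired_series"` object; see [as_paired_series()].
#' @seealso [write_series()] for the inverse operation.
#' @export
read_series <- function(path,
                        cols = c(subject = "subject", device = "device",
                                 time = "time", rm = "rm", tm = "tm"),
                        sep = ",",
                        drop_first = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = c("NA", ""))
  if (nrow(raw) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  as_paired_series(raw, cols = cols, drop_first = drop_first)
}

#' Write a paired series (or any long table) as CSV
#'
#' Writes the standardised long format that [read_series()] reads back, so
#' simulated and real data flow through one pipeline.
#'
#' @param x a `"paired_series"` object or compatible data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x)[, c("subject", "device", "time", "rm", "tm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.paired_series <- function(x, ...) {
  ex <- attr(x, "exclusions")
  cat(sprintf("Paired series: %d pairs, %d subject(s), %d device(s)\n",
              nrow(x), length(unique(x$subject)), length(unique(x$device))))
  if (!is.null(ex) && nrow(ex)) {
    cat(sprintf("Excluded %d row(s): %s\n", nrow(ex),
                paste(sprintf("%s (%d)", names(table(ex$reason)),
                              as.integer(table(ex$reason))), collapse = ", ")))
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Extract consecutive changes from a paired series
#'
#' Builds one change observation from each pair of consecutive retained
#' measurements within a subject–device series. A change is never built
#' across an excluded row: if a middle measurement was dropped (missing
#' value), both changes that touched it are lost, not merged into one.
#'
#' @param series a `"paired_series"` object (or a data frame with the
#'   standardised columns, in which case no exclusions are assumed).
#' @return a data frame with one row per change: `subject`, `device`,
#'   `time_from`, `time_to`, `rm1`, `tm1`, `rm2`, `tm2`, `delta_rm`,
#'   `delta_tm`.
#' @examples
#' d <- data.frame(subject = 1, time = 1:3, rm = c(3, 4, 5), tm = c(3, 4, 5))
#' extract_changes(as_paired_series(d))
#' @export
extract_changes <- function(series) {
  stopifnot(is.data.frame(series))
  df <- as.data.frame(series)
  df <- df[order(df$subject, df$device, df$time), , drop = FALSE]
  ex <- attr(series, "exclusions")

  out <- lapply(split(df, paste(df$subject, df$device, sep = "\r")), function(g) {
    if (nrow(g) < 2L) return(NULL)
    i <- seq_len(nrow(g) - 1L)
    ch <- data.frame(
      subject = g$subject[i], device = g$device[i],
      time_from = g$time[i], time_to = g$time[i + 1L],
      rm1 = g$rm[i], tm1 = g$tm[i],
      rm2 = g$rm[i + 1L], tm2 = g$tm[i + 1L],
      stringsAsFactors = FALSE
    )
    if (!is.null(ex) && nrow(ex)) {
      exg <- ex[ex$subject == g$subject[1] & ex$device == g$device[1] &
                  ex$reason == "missing_value", , drop = FALSE]
      if (nrow(exg)) {
        bridged <- vapply(seq_len(nrow(ch)), function(k) {
          any(exg$time > ch$time_from[k] & exg$time < ch$time_to[k])
        }, logical(1))
        ch <- ch[!bridged, , drop = FALSE]
      }
    }
    ch
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject = character(), device = character(),
                      time_from = numeric(), time_to = numeric(),
                      rm1 = numeric(), tm1 = numeric(),
                      rm2 = numeric(), tm2 = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out$delta_rm <- out$rm2 - out$rm1
  out$delta_tm <- out$tm2 - out$tm1
  out
}
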