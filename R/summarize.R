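#' Summarise a set of change classifications
#'
#' Counts the four categories and computes the trend interchangeability
#' rate: interchangeable changes divided by interpretable changes
#' (total minus uninterpretable). Gray-zone changes are interpretable, so
#' they enter the denominator but not the numerator. `NA` classifications
#' (excluded records) are dropped before counting.
#'
#' @param categories a factor or character vector of categories as produced
#'   by [classify_change()].
#' @return a one-row data frame with columns `n_total`,
#'   `n_uninterpretable`, `n_noninterchangeable`, `n_gray`,
#'   `n_interchangeable`, `n_interpretable`, `tim_rate` and
#'   `rate_category`. When no change is interpretable the rate (and its
#'   category) is `NA`, flagged undefined rather than zero.
#' @examples
#' cls <- classify_change(c(3, 4), c(3, 3), c(5, 8), c(5, 5), rc = 0.05)
#' summarize_changes(cls)
#' @export
summarize_changes <- function(categories) {
  categories <- .as_category(as.character(categories))
  categories <- categories[!is.na(categories)]
  counts <- table(categories)
  n_total <- length(categories)
  n_unint <- as.integer(counts[["uninterpretable"]])
  n_inter <- as.integer(counts[["interchangeable"]])
  denom <- n_total - n_unint
  rate <- if (denom > 0) n_inter / denom else NA_real_
  data.frame(
    n_total = n_total,
    n_uninterpretable = n_unint,
    n_noninterchangeable = as.integer(counts[["noninterchangeable"]]),
    n_gray = as.integer(counts[["gray_zone"]]),
    n_interchangeable = n_inter,
    n_interpretable = denom,
    tim_rate = rate,
    rate_category = rate_category(rate),
    stringsAsFactors = FALSE
  )
}

#' Clinical quality category of a trend interchangeability rate
#'
#' Maps a rate to the reporting categories: excellent (>= 95%),
#' good (>= 90%), poor (75%–90%) and not clinically relevant (< 75%).
#'
#' @param tim_rate rate(s) in \[0, 1\]; `NA` maps to `NA`.
#' @return character vector of category labels.
#' @examples
#' rate_category(c(0.95, 0.9, 0.8, 0.67))
#' @export
rate_category <- function(tim_rate) {
  stopifnot(is.numeric(tim_rate) | all(is.na(tim_rate)))
  if (any(tim_rate < 0 | tim_rate > 1, na.rm = TRUE)) {
    stop("`tim_rate` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(is.na(tim_rate), NA_character_,
    ifelse(tim_rate >= 0.95, "excellent",
      ifelse(tim_rate >= 0.90, "good",
        ifelse(tim_rate >= 0.75, "poor", "not_clinically_relevant"))))
}

#' Compare interchangeability rates across devices
#'
#' Pearson chi-square test of homogeneity of the interchangeability rate
#' across devices, on the devices x (interchangeable, interpretable but not
#' interchangeable) contingency table. Devices with no interpretable
#' change are excluded with a warning.
#'
#' @param summaries a data frame of per-device summaries with columns
#'   `n_interchangeable` and `n_interpretable` and (optionally) `device`
#'   row labels, as produced by [summary.tim()]; or a `tim` fit, whose
#'   per-device summary is used.
#' @return an object of class `"htest"` from [stats::chisq.test()]
#'   (continuity correction disabled), with the contingency table attached.
#' @examples
#' s <- data.frame(device = c("A", "B"),
#'                 n_interchangeable = c(30, 18),
#'                 n_interpretable = c(84, 84))
#' compare_devices(s)
#' @export
compare_devices <- function(summaries) {
  if (inherits(summaries, "tim")) {
    summaries <- summary(summaries)$devices
  }
  stopifnot(is.data.frame(summaries),
            all(c("n_interchangeable", "n_interpretable") %in% names(summaries)))
  labels <- if ("device" %in% names(summaries)) {
    as.character(summaries$device)
  } else {
    paste0("device", seq_len(nrow(summaries)))
  }
  keep <- summaries$n_interpretable > 0
  if (any(!keep)) {
    warning("excluding device(s) with no interpretable change: ",
            paste(labels[!keep], collapse = ", "), call. = FALSE)
  }
  summaries <- summaries[keep, , drop = FALSE]
  labels <- labels[keep]
  if (nrow(summaries) < 2L) {
    stop("need at least 2 devices with interpretable changes", call. = FALSE)
  }
  tab <- cbind(
    interchangeable = summaries$n_interchangeable,
    not_interchangeable = summaries$n_interpretable - summaries$n_interchangeable
  )
  rownames(tab) <- labels
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res$data.name <- "device x interchangeability table"
  res$observed <- tab
  res
}
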