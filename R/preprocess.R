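#' Read raw paired phospho/total measurements
#'
#' Long-format CSV with header `analyte,condition,time_h,channel,value`,
#' where `channel` is `"phospho"` or `"total"` and `value` a non-negative
#' fluorescence intensity.
#'
#' @param path path to the CSV file.
#' @return a data.frame of raw measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_f("measurements file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("analyte", "condition", "time_h", "channel", "value"), "data")
  bad <- setdiff(unique(df$channel), c("phospho", "total"))
  if (length(bad)) stop_f("unknown channel value(s): %s", paste(bad, collapse = ", "))
  df
}

#' Write scaled measurements
#'
#' @param data data.frame with columns `analyte`, `condition`, `time_h`,
#'   `value`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  check_columns(data, c("analyte", "condition", "time_h", "value"), "data")
  write.csv(data[, c("analyte", "condition", "time_h", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize phosphorylated protein levels to total protein
#'
#' Divides each phospho measurement by the total measurement of the same
#' (analyte, condition, time point), removing the apparent loss of activation
#' caused by loss of total protein over multi-day time courses.
#'
#' @param raw data.frame with columns `analyte`, `condition`, `time_h`,
#'   `channel` (`"phospho"`/`"total"`) and `value`.
#' @return data.frame `analyte`, `condition`, `time_h`, `value` with the
#'   phospho/total ratio; same index set as the phospho channel. A phospho
#'   record without a matching total, or a total of 0, is an error naming the
#'   offending analyte, condition and time.
#' @export
normalize_to_total <- function(raw) {
  check_columns(raw, c("analyte", "condition", "time_h", "channel", "value"), "raw")
  if (any(!is.finite(raw$value))) stop_f("raw values must be finite")
  if (any(raw$value < 0)) stop_f("raw intensities must be non-negative")
  ph <- raw[raw$channel == "phospho", , drop = FALSE]
  tot <- raw[raw$channel == "total", , drop = FALSE]
  if (!nrow(ph)) stop_f("no phospho channel records found")
  key <- function(d) paste(d$analyte, d$condition, d$time_h, sep = "\r")
  kt <- key(tot)
  if (anyDuplicated(kt)) stop_f("duplicated total records")
  if (anyDuplicated(key(ph))) stop_f("duplicated phospho records")
  idx <- match(key(ph), kt)
  if (anyNA(idx)) {
    miss <- ph[which(is.na(idx))[1L], ]
    stop_f("missing total measurement for %s / %s / t = %s h",
           miss$analyte, miss$condition, format(miss$time_h))
  }
  denom <- tot$value[idx]
  if (any(denom == 0)) {
    z <- ph[which(denom == 0)[1L], ]
    stop_f("zero total for %s / %s / t = %s h: cannot normalize",
           z$analyte, z$condition, format(z$time_h))
  }
  data.frame(analyte = ph$analyte, condition = ph$condition,
             time_h = ph$time_h, value = ph$value / denom,
             stringsAsFactors = FALSE)
}

#' Scale each series to its maximum
#'
#' Divides every (analyte, condition) series by its own maximum, so values
#' are dimensionless in [0, 1] and every non-degenerate series attains 1
#' exactly. Scaling per analyte (not pooled across analytes within a
#' condition) prevents one analyte's intensity range from dominating the
#' others during model fitting. An all-zero series is returned unchanged with
#' a warning; negative input is an error.
#'
#' @param ratios data.frame with columns `analyte`, `condition`, `time_h`,
#'   `value` (non-negative), typically from [normalize_to_total()].
#' @return data.frame of the same shape with scaled values. Idempotent:
#'   applying twice equals applying once.
#' @export
scale_to_max <- function(ratios) {
  check_columns(ratios, c("analyte", "condition", "time_h", "value"), "ratios")
  if (any(!is.finite(ratios$value))) stop_f("values must be finite")
  if (any(ratios$value < 0)) stop_f("negative values cannot be max-scaled")
  key <- interaction(ratios$analyte, ratios$condition, drop = TRUE)
  mx <- ave(ratios$value, key, FUN = max)
  zero <- mx == 0
  if (any(zero)) {
    warn_f("all-zero series left unchanged: %s",
           paste(unique(paste(ratios$analyte[zero], ratios$condition[zero],
                              sep = "/")), collapse = ", "))
    mx[zero] <- 1
  }
  out <- ratios
  out$value <- ratios$value / mx
  out
}

#' Full preprocessing pipeline
#'
#' [normalize_to_total()] followed by [scale_to_max()]: raw paired
#' phospho/total intensities become normalized, max-scaled signals in [0, 1]
#' per analyte and condition, the scale every model in the package operates
#' on.
#'
#' @inheritParams normalize_to_total
#' @return scaled data.frame (`analyte`, `condition`, `time_h`, `value`).
#' @export
preprocess_dataset <- function(raw) {
  scale_to_max(normalize_to_total(raw))
}
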