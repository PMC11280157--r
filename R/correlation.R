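.PFT_PARAMS <- c("FVC", "IC", "VC", "FEV1", "TLC", "FEV6", "DLCO")

#' Pair CT-derived metrics with pulmonary function tests
#'
#' For every subject, selects the PFT record whose test date is nearest the
#' CT acquisition date and within `window_days` (default 90, the "within
#' three months" pairing rule). Subjects without a qualifying PFT are
#' dropped with a message. Duplicate subject ids on either side, or a
#' subject with more than one CT date, are an error.
#'
#' @param metrics a [metrics_table] data frame (or list of
#'   `muscle_metrics`) that additionally carries a `ct_date` column/field.
#' @param pfts data frame with columns `subject_id`, `test_date` and the
#'   PFT parameters (`FVC`, `IC`, `VC`, `FEV1`, `TLC`, `FEV6`, `DLCO`);
#'   several rows per subject are allowed.
#' @param window_days maximum |CT date - PFT date| in days.
#' @return data frame of paired records: the metric columns joined to the
#'   selected PFT row, plus `pairing_gap_days`.
#' @export
pair_ct_with_pft <- function(metrics, pfts, window_days = 90L) {
  df <- if (is.data.frame(metrics)) metrics else metrics_table(metrics)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids in the CT metrics")
  if (is.null(df$ct_date)) stop("metrics need a `ct_date` column for pairing")
  if (!all(c("subject_id", "test_date") %in% names(pfts)))
    stop("pfts need `subject_id` and `test_date` columns")
  df$ct_date <- as.Date(df$ct_date)
  pfts$test_date <- as.Date(pfts$test_date)
  if (anyDuplicated(paste(pfts$subject_id, pfts$test_date)))
    stop("duplicate subject/date rows in the PFT table")
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(df))) {
    cand <- pfts[pfts$subject_id == df$subject_id[i], , drop = FALSE]
    if (nrow(cand)) {
      gap <- abs(as.integer(cand$test_date - df$ct_date[i]))
      ok <- gap <= window_days
      if (any(ok)) {
        j <- which(ok)[which.min(gap[ok])]
        row <- cbind(df[i, , drop = FALSE],
                     cand[j, setdiff(names(cand), "subject_id"),
                          drop = FALSE],
                     pairing_gap_days = gap[j])
        rows[[length(rows) + 1L]] <- row
        next
      }
    }
    dropped <- dropped + 1L
  }
  if (dropped)
    message(dropped, " subject(s) had no PFT within ", window_days,
            " days and were dropped")
  if (!length(rows))
    return(df[0, , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties). Pairs with a
#' missing value in either vector are removed listwise. A constant vector
#' has no defined rank correlation: `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @return rho in \[-1, 1\], or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Spearman correlation table of muscle metrics against PFT parameters
#'
#' One rho per (PFT parameter x muscle metric) cell over the paired
#' cohort, with the per-cell n after listwise removal of missing values.
#' Cells with fewer than 3 complete pairs are reported as `NA`.
#'
#' @param paired data frame from [pair_ct_with_pft].
#' @param metric_cols metric columns to correlate; defaults to volume and
#'   density of the three muscle classes.
#' @return a `correlation_table`: data frame with `pft` rows and one
#'   column per metric, plus an `n` attribute of per-cell counts.
#' @export
build_correlation_table <- function(paired, metric_cols = NULL) {
  if (!nrow(paired)) stop("no paired subjects: cannot correlate")
  if (is.null(metric_cols))
    metric_cols <- as.vector(outer(.MUSCLE_CLASSES,
                                   c("_volume_cc", "_density_hu"), paste0))
  metric_cols <- intersect(metric_cols, names(paired))
  pft_cols <- intersect(.PFT_PARAMS, names(paired))
  tab <- data.frame(pft = pft_cols)
  ns <- data.frame(pft = pft_cols)
  for (mc in metric_cols) {
    rho <- rep(NA_real_, length(pft_cols))
    nn <- integer(length(pft_cols))
    for (i in seq_along(pft_cols)) {
      ok <- complete.cases(paired[[mc]], paired[[pft_cols[i]]])
      nn[i] <- sum(ok)
      if (nn[i] >= 3L)
        rho[i] <- suppressWarnings(
          spearman_rho(paired[[mc]][ok], paired[[pft_cols[i]]][ok]))
    }
    tab[[mc]] <- rho
    ns[[mc]] <- nn
  }
  attr(tab, "n") <- ns
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("Spearman rank correlations (rows: PFT parameters):\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Read a PFT CSV
#'
#' Expected columns: `subject_id`, `test_date`, `FVC`, `IC`, `VC`, `FEV1`,
#' `TLC`, `FEV6`, `DLCO`.
#'
#' @param path CSV file.
#' @return data frame with parsed dates.
#' @export
read_pft <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "test_date")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("PFT file lacks column(s): ", paste(missing, collapse = ", "))
  df$test_date <- as.Date(df$test_date)
  df
}
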