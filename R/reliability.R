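#' @title Inter-rater and tool reliability
#'
#' @description
#' Agreement between raters (or between the tool and a human rater) on a
#' subjects-by-raters score matrix is summarised with single-rater
#' intraclass correlation coefficients from the mean-squares decomposition
#' of the two-way layout, with percent agreement for ordinal rubric scores,
#' and with conventional reliability bands: poor below 0.50, moderate 0.50
#' to below 0.70, good 0.70 to 0.90, excellent above 0.90.
#'
#' @name reliability
NULL

#' Construct a ratings table
#'
#' @param scores Numeric matrix or data frame, one row per subject, one
#'   column per rater. Missing cells are allowed; analyses apply listwise
#'   deletion.
#' @param subjects,raters Optional row/column labels.
#' @return A `ratings_table` (a numeric matrix with dimnames).
#' @export
ratings_table <- function(scores, subjects = NULL, raters = NULL) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("ratings table needs at least 2 raters")
  if (nrow(m) < 2L) stop("ratings table needs at least 2 subjects")
  rownames(m) <- if (!is.null(subjects)) subjects else
    if (!is.null(rownames(m))) rownames(m) else paste0("s", seq_len(nrow(m)))
  colnames(m) <- if (!is.null(raters)) raters else
    if (!is.null(colnames(m))) colnames(m) else paste0("r", seq_len(ncol(m)))
  structure(m, class = c("ratings_table", "matrix", "array"))
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("<ratings table: %d subjects x %d raters, %d missing cells>\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

complete_rows <- function(rt) {
  m <- unclass(rt)
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Intraclass correlation coefficient
#'
#' Single-rater ICC from the mean-squares decomposition of the
#' subjects-by-raters layout (Shrout-Fleiss forms):
#' `ICC_1_1` one-way random, `ICC_2_1` two-way random with absolute
#' agreement, `ICC_3_1` two-way mixed consistency. `ICC_2_1` is the
#' default: absolute agreement is the stricter, conventional choice when
#' raters (or tool and human) are meant to be interchangeable. The form is
#' always recorded on the result because it materially changes the value.
#'
#' Rows with missing cells are dropped (listwise deletion); the number
#' retained is recorded in `attr(, "n")`.
#'
#' @param rt A `ratings_table` (or coercible matrix).
#' @param form `"ICC_2_1"` (default), `"ICC_1_1"` or `"ICC_3_1"`.
#' @return The ICC value with attributes `form` and `n`.
#' @examples
#' rt <- ratings_table(cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)))
#' icc(rt, "ICC_2_1")
#' @export
icc <- function(rt, form = c("ICC_2_1", "ICC_1_1", "ICC_3_1")) {
  form <- match.arg(form)
  m <- complete_rows(rt)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L)
    stop("insufficient data: fewer than 2 complete subjects after listwise deletion")
  ms <- mean_squares(m)
  if (ms$SST == 0)
    stop("undefined ICC: all cells are identical (zero variance)")
  val <- switch(form,
    ICC_1_1 = (ms$BMS - ms$WMS) / (ms$BMS + (k - 1) * ms$WMS),
    ICC_2_1 = (ms$BMS - ms$EMS) /
      (ms$BMS + (k - 1) * ms$EMS + k * (ms$JMS - ms$EMS) / n),
    ICC_3_1 = (ms$BMS - ms$EMS) / (ms$BMS + (k - 1) * ms$EMS)
  )
  structure(val, form = form, n = n)
}

# Mean squares of the two-way subjects x raters layout.
mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  mu <- mean(m)
  rmeans <- rowMeans(m); cmeans <- colMeans(m)
  SSB <- k * sum((rmeans - mu)^2)
  SSC <- n * sum((cmeans - mu)^2)
  SST <- sum((m - mu)^2)
  SSW <- sum((m - rmeans)^2)
  SSE <- SST - SSB - SSC
  list(BMS = SSB / (n - 1), JMS = SSC / (k - 1),
       WMS = SSW / (n * (k - 1)), EMS = SSE / ((n - 1) * (k - 1)),
       SST = SST)
}

#' Percent agreement between two raters
#'
#' Share of subjects on which the two raters' scores differ by at most
#' `tolerance` (default 0: exact agreement), as a percentage.
#'
#' @param rt A `ratings_table` with exactly 2 raters.
#' @param tolerance Maximum absolute difference still counted as agreement.
#' @return Percentage in \[0, 100\].
#' @export
percent_agreement <- function(rt, tolerance = 0) {
  m <- complete_rows(rt)
  if (ncol(m) != 2L) stop("percent agreement requires exactly 2 raters")
  if (nrow(m) < 1L) stop("no complete subjects")
  100 * mean(abs(m[, 1] - m[, 2]) <= tolerance)
}

#' Reliability band of an ICC value
#'
#' Conventional bands: poor below 0.50; moderate 0.50 to below 0.70; good
#' 0.70 to 0.90 (inclusive at both edges); excellent above 0.90. The bands
#' partition \[-1, 1\]; values outside that range are an error.
#'
#' @param icc_value Numeric vector of ICC values.
#' @return Character vector of `"POOR"`, `"MODERATE"`, `"GOOD"`,
#'   `"EXCELLENT"`.
#' @examples
#' band(c(0.213, 0.616, 0.850, 0.939))
#' @export
band <- function(icc_value) {
  if (any(is.na(icc_value)) || any(icc_value < -1) || any(icc_value > 1))
    stop("ICC values must lie in [-1, 1]")
  out <- rep("POOR", length(icc_value))
  out[icc_value >= 0.50] <- "MODERATE"
  out[icc_value >= 0.70] <- "GOOD"
  out[icc_value > 0.90] <- "EXCELLENT"
  out
}

#' Summarise reliability bands over a set of ICC values
#'
#' @param values Non-empty numeric vector of ICC values.
#' @return List with `counts` (named count per band) and `good_or_better`
#'   (number of values in the good or excellent band).
#' @examples
#' band_summary(validation_icc_values("micro")$icc)$good_or_better
#' @export
band_summary <- function(values) {
  if (!length(values)) stop("band_summary: empty value list")
  b <- factor(band(values), levels = c("POOR", "MODERATE", "GOOD",
                                       "EXCELLENT"))
  counts <- table(b)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       good_or_better = sum(b %in% c("GOOD", "EXCELLENT")))
}

#' Read or write a ratings table as CSV
#'
#' Subjects-by-raters CSV: first column subject labels, remaining columns
#' one per rater with rater IDs in the header.
#'
#' @param path CSV path.
#' @param rt A `ratings_table`.
#' @return `read_ratings_csv()` returns a `ratings_table`.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ratings_table(df[, -1, drop = FALSE], subjects = df[[1]])
}

#' @rdname read_ratings_csv
#' @export
write_ratings_csv <- function(rt, path) {
  df <- cbind(data.frame(subject = rownames(rt)), as.data.frame(unclass(rt)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
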