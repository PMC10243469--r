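#' Age bands of the stratified sampling frame
#'
#' Six age bands spanning 4;0 to 7;11 (48 to 95 months). Band boundaries are
#' inclusive, in months.
#'
#' @return Data frame with columns `band` (label), `min_months`,
#'   `max_months`.
#' @export
age_bands <- function() {
  data.frame(
    band = c("4:0-4:5", "4:6-4:11", "5:0-5:5", "5:6-5:11",
             "6:0-6:11", "7:0-7:11"),
    min_months = c(48L, 54L, 60L, 66L, 72L, 84L),
    max_months = c(53L, 59L, 65L, 71L, 83L, 95L),
    stringsAsFactors = FALSE
  )
}

# Band label for an age in months, or NA when outside the frame.
age_band_for <- function(age_months) {
  b <- age_bands()
  i <- findInterval(age_months, b$min_months)
  out <- rep(NA_character_, length(age_months))
  ok <- i >= 1L & !is.na(age_months)
  ok[ok] <- age_months[ok] <= b$max_months[i[ok]]
  out[ok] <- b$band[i[ok]]
  out
}

#' Normative retell profile by age band
#'
#' Per-band means and standard deviations of retell duration (seconds),
#' total child word count, and number of secondary-speaker utterances,
#' as observed in the validation sample. The synthetic-data generator uses
#' these as its age-graded defaults; secondary-speaker input (parental
#' scaffolding) declines steeply with age.
#'
#' @return Data frame with one row per age band.
#' @export
retell_norms <- function() {
  cbind(age_bands()["band"], data.frame(
    duration_mean = c(109.48, 106.13, 108.62, 108.53, 109.38, 107.47),
    duration_sd = c(37.1, 35.7, 33.7, 34.3, 34.2, 32.1),
    words_mean = c(136.18, 132.58, 145.71, 146.19, 162.67, 167.54),
    words_sd = c(48.9, 45.6, 43.9, 42.9, 54.4, 40.8),
    secondary_mean = c(11.36, 8.75, 7.26, 4.54, 2.81, 2.42),
    secondary_sd = c(15.1, 10.4, 10.4, 7.1, 4.3, 4.2)
  ))
}

#' Validation-study reliability values
#'
#' The tool-versus-manual intraclass correlations reported by the
#' validation study: 44 micro-structure metrics (`set = "micro"`) or the
#' seven story-grammar elements plus the composite (`set = "macro"`).
#' Useful as input to [band_summary()] and as worked-example data.
#'
#' @param set `"micro"` or `"macro"`.
#' @return Data frame with columns `metric`/`element`, `label`, `icc`.
#' @export
validation_icc_values <- function(set = c("micro", "macro")) {
  set <- match.arg(set)
  f <- system.file("extdata", paste0(set, "_icc_validation.csv"),
                   package = "storysampler", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Geographical representation of the validation sample
#'
#' Participant counts by United Kingdom region for the 599-child
#' micro-structure test sample, with the population share of each region.
#' `representation_pct` is computed as `100 * participants / total`.
#'
#' @return Data frame with columns `region`, `participants`,
#'   `population_pct`, `representation_pct`, `difference_pct`.
#' @export
region_distribution <- function() {
  f <- system.file("extdata", "region_distribution.csv",
                   package = "storysampler", mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  df$representation_pct <- round(100 * df$participants /
                                   sum(df$participants), 1)
  df$difference_pct <- round(df$representation_pct - df$population_pct, 1)
  df
}
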