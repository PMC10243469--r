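#' @title Stratified sampling frame and participant flow
#'
#' @description
#' The study sample is assembled against a stratified frame crossing six
#' age bands (4;0 to 7;11), five national deprivation quintiles and sex,
#' with 10 children per cell (20 per band-by-quintile cell, 100 per band,
#' 600 in total). Socio-economic position is derived from the partial
#' postcode: the deprivation ranks of all full postcode areas within the
#' partial area are averaged and the mean rank is binned into national
#' quintiles (quintile 1 = most deprived; rank 1 = most deprived, a
#' convention recorded here). Candidate participants pass through an
#' ordered exclusion pipeline (country, task completion,
#' language/disability, audibility, analysis suitability) with per-stage
#' accounting.
#'
#' @name sampling_frame
NULL

UK_NATIONS <- c("England", "Wales", "Scotland", "NorthernIreland")

#' Construct a deprivation-rank table
#'
#' @param df Data frame with columns `nation`, `partial` (partial postcode
#'   area), `postcode` (full postcode area) and `rank` (deprivation rank,
#'   1 = most deprived).
#' @param N Named integer vector: total ranked areas per nation. Defaults
#'   to the number of rows per nation in `df`.
#' @return An `imd_table`.
#' @export
imd_table <- function(df, N = NULL) {
  stopifnot(all(c("nation", "partial", "postcode", "rank") %in% names(df)))
  if (is.null(N)) N <- vapply(split(df, df$nation), nrow, 0L)
  for (nat in unique(df$nation)) {
    r <- df$rank[df$nation == nat]
    if (any(r < 1L) || any(r > N[[nat]]))
      stop(sprintf("imd table: ranks for %s must lie in 1..%d", nat, N[[nat]]))
  }
  structure(df, class = c("imd_table", "data.frame"), N = N)
}

#' @export
print.imd_table <- function(x, ...) {
  cat(sprintf("<deprivation rank table: %d areas, %d partial areas, %s>\n",
              nrow(x), length(unique(x$partial)),
              paste(unique(x$nation), collapse = "/")))
  invisible(x)
}

#' Map a partial postcode to a deprivation quintile
#'
#' Averages the deprivation ranks of every full postcode area within the
#' partial postcode area, then bins the mean rank into national quintiles:
#' quintile q covers mean ranks in ((q-1)N/5, qN/5], N being the nation's
#' total ranked areas.
#'
#' @param pp Partial postcode area.
#' @param imd An `imd_table`.
#' @return Integer quintile 1 (most deprived) to 5.
#' @export
quintile_for_partial_postcode <- function(pp, imd) {
  stopifnot(inherits(imd, "imd_table"))
  hit <- imd$partial == pp | startsWith(imd$postcode, paste0(pp, " "))
  if (!any(hit))
    stop(sprintf("unmapped partial postcode '%s'", pp))
  nations <- unique(imd$nation[hit])
  if (length(nations) > 1L)
    stop(sprintf("partial postcode '%s' spans more than one nation", pp))
  N <- attr(imd, "N")[[nations]]
  mean_rank <- mean(imd$rank[hit])
  q <- as.integer(ceiling(mean_rank * 5 / N))
  max(1L, min(5L, q))
}

#' Build the stratified sampling frame
#'
#' @param bands Age-band table as from [age_bands()].
#' @param n_quintiles Number of deprivation quintiles (default 5).
#' @param sexes Sex strata (default `c("M", "F")`).
#' @param per_cell Target per (band, quintile, sex) cell (default 10).
#' @param expected_total Optional declared grand total; a mismatch with the
#'   constructed frame is a validation error.
#' @return A `sampling_frame`: data frame of cells with columns `band`,
#'   `quintile`, `sex`, `target`, `filled`, plus an assignment registry.
#' @export
build_frame <- function(bands = age_bands(), n_quintiles = 5,
                        sexes = c("M", "F"), per_cell = 10,
                        expected_total = NULL) {
  if (is.null(bands) || nrow(bands) == 0L)
    stop("frame validation error: no age bands supplied")
  if (n_quintiles < 1L || per_cell < 1L)
    stop("frame validation error: quintiles and per-cell target must be positive")
  cells <- expand.grid(sex = sexes, quintile = seq_len(n_quintiles),
                       band = bands$band, stringsAsFactors = FALSE)
  cells <- cells[, c("band", "quintile", "sex")]
  cells$target <- per_cell
  cells$filled <- 0L
  total <- sum(cells$target)
  if (!is.null(expected_total) && total != expected_total)
    stop(sprintf(
      "frame validation error: declared total %d but frame totals %d",
      expected_total, total))
  structure(cells, class = c("sampling_frame", "data.frame"),
            assigned = stats::setNames(
              vector("list", nrow(cells)),
              paste(cells$band, cells$quintile, cells$sex, sep = "|")))
}

#' @export
print.sampling_frame <- function(x, ...) {
  cat(sprintf(
    "<sampling frame: %d cells (%d bands x %d quintiles x %d sexes), target %d, filled %d>\n",
    nrow(x), length(unique(x$band)), length(unique(x$quintile)),
    length(unique(x$sex)), sum(x$target), sum(x$filled)))
  invisible(x)
}

FLOW_FILTERS <- list(
  country = function(r) r$nation %in% UK_NATIONS,
  completion = function(r) r$completed_tasks,
  language_disability = function(r) r$english_first_language &
    !r$disability_flag,
  monolingual = function(r) r$monolingual,
  audibility = function(r) r$audible,
  analysis_suitability = function(r) is.na(r$analysis_suitable) |
    r$analysis_suitable
)

#' Run the participant-flow exclusion pipeline
#'
#' Applies the named filters in order, recording the number excluded and
#' remaining at every stage. Stage names: `country` (Great Britain or
#' Northern Ireland), `completion` (completed all app tasks),
#' `language_disability` (English first language, no recorded disability),
#' `monolingual`, `audibility` (recording screened as audible),
#' `analysis_suitability` (not flagged unsuitable by a rater).
#'
#' @param roster Participant data frame (see [gen_roster()] for columns).
#' @param filters Character vector of stage names, applied in order.
#' @return List of class `flow_result`: `flow` (data frame `stage`,
#'   `excluded`, `remaining`) and `roster` (the survivors).
#' @export
apply_flow_filters <- function(roster,
                               filters = c("country", "completion",
                                           "language_disability",
                                           "audibility")) {
  stopifnot(is.data.frame(roster), nrow(roster) > 0L)
  unknown <- setdiff(filters, names(FLOW_FILTERS))
  if (length(unknown))
    stop("unknown flow filter(s): ", paste(unknown, collapse = ", "))
  stages <- list()
  cur <- roster
  for (f in filters) {
    keep <- FLOW_FILTERS[[f]](cur)
    keep[is.na(keep)] <- FALSE
    stages[[f]] <- data.frame(stage = f, excluded = sum(!keep),
                              remaining = sum(keep))
    cur <- cur[keep, , drop = FALSE]
  }
  flow <- do.call(rbind, stages)
  rownames(flow) <- NULL
  structure(list(flow = flow, roster = cur), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat("<participant flow>\n")
  print(x$flow, row.names = FALSE)
  invisible(x)
}

#' Assign a participant to their frame cell
#'
#' Routes a participant who survived the flow filters into their (age
#' band, deprivation quintile, sex) cell if it is below target.
#'
#' @param frame A `sampling_frame`.
#' @param p One-row data frame or list with `id`, `age_months`, `sex`,
#'   `partial_postcode`.
#' @param imd An `imd_table` for quintile lookup.
#' @return List with the updated `frame`, `status` (`"ASSIGNED"`,
#'   `"FULL"`, `"OUT_OF_FRAME"`) and `cell` (cell id or `NA`).
#' @export
assign_participant <- function(frame, p, imd) {
  stopifnot(inherits(frame, "sampling_frame"))
  b <- age_band_for(p$age_months)
  if (is.na(b))
    return(list(frame = frame, status = "OUT_OF_FRAME", cell = NA_character_))
  q <- quintile_for_partial_postcode(p$partial_postcode, imd)
  i <- which(frame$band == b & frame$quintile == q & frame$sex == p$sex)
  if (length(i) != 1L)
    return(list(frame = frame, status = "OUT_OF_FRAME", cell = NA_character_))
  cell <- paste(b, q, p$sex, sep = "|")
  if (frame$filled[i] >= frame$target[i])
    return(list(frame = frame, status = "FULL", cell = cell))
  frame$filled[i] <- frame$filled[i] + 1L
  reg <- attr(frame, "assigned")
  reg[[cell]] <- c(reg[[cell]], as.character(p$id))
  attr(frame, "assigned") <- reg
  list(frame = frame, status = "ASSIGNED", cell = cell)
}

#' Assign a whole roster to the frame
#'
#' @param frame A `sampling_frame`.
#' @param roster Participant data frame.
#' @param imd An `imd_table`.
#' @return List with the final `frame` and `assignments` (data frame `id`,
#'   `status`, `cell`). Unmapped postcodes are recorded with status
#'   `"UNMAPPED"` rather than aborting the run.
#' @export
assign_roster <- function(frame, roster, imd) {
  out <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    p <- roster[i, ]
    res <- tryCatch(assign_participant(frame, p, imd), error = function(e) {
      list(frame = frame, status = "UNMAPPED", cell = NA_character_)
    })
    frame <- res$frame
    out[[i]] <- data.frame(id = as.character(p$id), status = res$status,
                           cell = res$cell, stringsAsFactors = FALSE)
  }
  list(frame = frame, assignments = do.call(rbind, out))
}

#' Frame fill status and oversampling factor
#'
#' @param frame A `sampling_frame`.
#' @param completed,audible Optional participant-flow counts used to report
#'   the oversampling factor: completed sign-ups per usable (audible)
#'   recording, to 1 decimal place. Zero usable recordings flags the factor
#'   undefined (`NA`).
#' @return List of class `frame_status`: `cells` (frame with `shortfall`),
#'   `total_target`, `total_filled`, `shortfall` (unfilled cells),
#'   `oversampling_factor`.
#' @export
frame_status <- function(frame, completed = NULL, audible = NULL) {
  stopifnot(inherits(frame, "sampling_frame"))
  cells <- as.data.frame(frame)
  cells$shortfall <- cells$target - cells$filled
  factor <- NA_real_
  if (!is.null(completed) && !is.null(audible))
    factor <- if (audible > 0) round(completed / audible, 1) else NA_real_
  structure(list(cells = cells, total_target = sum(cells$target),
                 total_filled = sum(cells$filled),
                 shortfall = cells[cells$shortfall > 0L, , drop = FALSE],
                 oversampling_factor = factor),
            class = "frame_status")
}

#' @export
print.frame_status <- function(x, ...) {
  cat(sprintf("<frame status: %d of %d filled, %d cells short>\n",
              x$total_filled, x$total_target, nrow(x$shortfall)))
  if (!is.na(x$oversampling_factor))
    cat(sprintf("  oversampling factor: %.1f\n", x$oversampling_factor))
  invisible(x)
}

#' Read or write a participant roster CSV
#'
#' One participant per row with columns `id`, `age_months`, `sex`,
#' `partial_postcode`, `country`, `nation`, `english_first_language`,
#' `monolingual`, `disability_flag`, `completed_tasks`, `audible`,
#' `analysis_suitable`.
#'
#' @param path CSV path.
#' @param roster Participant data frame.
#' @return `read_roster_csv()` returns the roster data frame.
#' @export
read_roster_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("english_first_language", "monolingual", "disability_flag",
                "completed_tasks", "audible", "analysis_suitable"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname read_roster_csv
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}
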