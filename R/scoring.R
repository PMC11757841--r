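#' @keywords internal
instrument_info <- function(instrument) {
  switch(instrument,
    GAD7 = list(n_items = 7L, min = 0L, max = 3L),
    PHQ9 = list(n_items = 9L, min = 0L, max = 3L),
    IUS12 = list(n_items = 12L, min = 0L, max = 5L),
    stop("Unknown instrument: ", instrument)
  )
}

#' Score a questionnaire response as an item sum
#'
#' GAD-7 and PHQ-9 items are rated 0-3 (totals 0-21 and 0-27); IUS-12 items
#' are rated 0-5 (total 0-60). Higher totals mean more severe symptoms /
#' stronger intolerance of uncertainty.
#'
#' @param items Integer vector of item ratings, or a matrix (participants x
#'   items) for batch scoring.
#' @param instrument One of `"GAD7"`, `"PHQ9"`, `"IUS12"`.
#' @return The total score (vector of totals for a matrix input).
#' @export
score_instrument <- function(items, instrument = c("GAD7", "PHQ9", "IUS12")) {
  instrument <- match.arg(instrument)
  info <- instrument_info(instrument)
  m <- if (is.matrix(items)) items else matrix(items, nrow = 1L)
  if (ncol(m) != info$n_items) {
    stop(instrument, " requires ", info$n_items, " items; got ", ncol(m), ".")
  }
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))
    stop(instrument, ": missing item rating(s) in response ",
         paste(bad, collapse = ", "), "; incomplete responses are not scorable.")
  }
  out_of_range <- m < info$min | m > info$max | m != round(m)
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
    stop(instrument, ": item ", idx[["col"]], " of response ", idx[["row"]],
         " is out of range [", info$min, ", ", info$max, "].")
  }
  totals <- rowSums(m)
  if (is.matrix(items)) totals else totals[[1L]]
}

#' Psychological distress index
#'
#' GAD-7 and PHQ-9 totals are each standardized (sample mean and sd, n-1
#' denominator) and summed. The resulting index has sample mean 0 by
#' construction; its scale depends on the anxiety-depression correlation.
#'
#' @param gad7_totals,phq9_totals Equal-length numeric vectors of totals
#'   (n >= 2, each with nonzero variance).
#' @return Numeric vector: `z(gad7) + z(phq9)`.
#' @export
distress_index <- function(gad7_totals, phq9_totals) {
  if (length(gad7_totals) != length(phq9_totals)) {
    stop("GAD-7 and PHQ-9 total vectors must have equal length.")
  }
  if (length(gad7_totals) < 2L) stop("At least 2 participants are required.")
  if (stats::sd(gad7_totals) == 0 || stats::sd(phq9_totals) == 0) {
    stop("Zero variance in questionnaire totals; the distress index is undefined.")
  }
  as.numeric(scale(gad7_totals)) + as.numeric(scale(phq9_totals))
}

#' Attention-check pass flag
#'
#' An instructed-response item is passed when the given option equals the
#' instructed one; a participant passes when all their items do.
#'
#' @param expected,given Equal-length vectors of instructed and given options.
#' @return `TRUE` if every item matches.
#' @export
attention_pass <- function(expected, given) {
  if (length(expected) != length(given)) stop("`expected` and `given` lengths differ.")
  all(expected == given)
}

#' Code raw vaccination and booster responses
#'
#' Vaccination status is asked on a 1-5 scale: 1 = all necessary doses,
#' 2 = partially vaccinated, 3 = planning to vaccinate, 4 = not planning,
#' 5 = prefer not to say. Codes 1-2 count as vaccinated, 3-4 as unvaccinated,
#' 5 as missing. Booster willingness (asked of the vaccinated) is 0 = no,
#' 1 = yes, 2 = prefer not to say (missing).
#'
#' @param data Data frame with columns `vaccination_status` (1-5) and
#'   `booster_raw` (0/1/2, `NA` allowed for participants never asked).
#' @return `data` with logical `vaccinated` and numeric 0/1 `booster_willing`
#'   columns added (`NA` = missing).
#' @export
code_outcomes <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("vaccination_status", "booster_raw") %in% names(data)))
  v <- data$vaccination_status
  bad_v <- !is.na(v) & !(v %in% 1:5)
  if (any(bad_v)) {
    stop("Unknown vaccination status code(s): ",
         paste(unique(v[bad_v]), collapse = ", "))
  }
  data$vaccinated <- ifelse(is.na(v) | v == 5, NA, v %in% 1:2)
  b <- data$booster_raw
  bad_b <- !is.na(b) & !(b %in% 0:2)
  if (any(bad_b)) {
    stop("Unknown booster willingness code(s): ",
         paste(unique(b[bad_b]), collapse = ", "))
  }
  data$booster_willing <- ifelse(is.na(b) | b == 2, NA_real_, as.numeric(b == 1))
  data
}

#' Apply the analytic-sample exclusions
#'
#' Participants who were unvaccinated at follow-up are dropped first; then
#' participants with a missing booster response (including those who
#' preferred not to answer either question). Counts at each step always sum
#' to the input n.
#'
#' @param roster Data frame with `vaccinated` (logical, `NA` = missing) and
#'   `booster_willing` (0/1/`NA`) columns, e.g. from [code_outcomes()].
#' @return List with `kept` (the analytic sample) and `exclusions`, a data
#'   frame of step-wise counts (`unvaccinated`, `missing_booster`, `kept`).
#' @export
analytic_sample <- function(roster) {
  stopifnot(is.data.frame(roster),
            all(c("vaccinated", "booster_willing") %in% names(roster)))
  n0 <- nrow(roster)
  unvacc <- !is.na(roster$vaccinated) & !roster$vaccinated
  step1 <- roster[!unvacc, , drop = FALSE]
  missing_booster <- is.na(step1$vaccinated) | is.na(step1$booster_willing)
  kept <- step1[!missing_booster, , drop = FALSE]
  list(
    kept = kept,
    exclusions = data.frame(
      step = c("unvaccinated", "missing_booster", "kept"),
      n = c(sum(unvacc), sum(missing_booster), nrow(kept))
    )
  )
}

#' Percent agreement and Cohen's kappa for two raters
#'
#' @param table Square contingency matrix of category counts (rows: rater 1,
#'   columns: rater 2, identical category sets).
#' @return List with `percent_agreement` (observed agreement, trace / total)
#'   and `kappa` (chance-corrected agreement, in `[-1, 1]`).
#' @export
rater_agreement <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("Agreement table must be square.")
  if (any(m < 0) || any(m != round(m))) stop("Cells must be nonnegative counts.")
  n <- sum(m)
  if (n == 0) stop("Agreement table is empty.")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) stop("Degenerate marginals (expected agreement 1): kappa undefined.")
  list(percent_agreement = p_o, kappa = (p_o - p_e) / (1 - p_e))
}
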