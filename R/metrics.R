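#' Construct a discounting profile
#'
#' A participant's indifference points across the delay conditions, together
#' with the derived area-under-the-curve (AuC) discounting statistic.
#'
#' @param points Data frame with columns `days` and `subjective_value`
#'   (optionally `label`), one row per delay, strictly increasing in days.
#' @param delayed_amount The fixed larger-later reward the points refer to.
#' @param trials Optional per-trial log to retain.
#' @return A `discount_profile` with elements `points`, `delayed_amount`,
#'   `auc`, and `trials`.
#' @export
discount_profile <- function(points, delayed_amount, trials = NULL) {
  stopifnot(is.data.frame(points),
            all(c("days", "subjective_value") %in% names(points)),
            nrow(points) >= 1L)
  if (delayed_amount <= 0) stop("`delayed_amount` must be positive.")
  points <- points[order(points$days), , drop = FALSE]
  if (is.unsorted(points$days, strictly = TRUE)) {
    stop("Delays must be strictly increasing (no duplicate day-values).")
  }
  structure(
    list(points = points, delayed_amount = delayed_amount,
         auc = auc_trapezoid(points$days, points$subjective_value, delayed_amount),
         trials = trials),
    class = "discount_profile"
  )
}

#' @export
print.discount_profile <- function(x, ...) {
  cat("Discounting profile:", nrow(x$points), "indifference points,",
      "delayed amount", x$delayed_amount, "\n")
  print(x$points, row.names = FALSE)
  cat(sprintf("AuC = %.4f\n", x$auc))
  invisible(x)
}

#' Normalize a discounting curve
#'
#' Delays are expressed as fractions of the maximum delay and subjective
#' values as fractions of the delayed amount; an anchor point (0, 1) — the
#' undelayed reward at full value — is prepended.
#'
#' @param profile A [discount_profile()], or a data frame of points (then
#'   `delayed_amount` is required).
#' @param delayed_amount The delayed reward amount (ignored when `profile`
#'   is a `discount_profile`).
#' @return Data frame with columns `x`, `y`, all in `[0, 1]`.
#' @export
dd_normalize <- function(profile, delayed_amount = NULL) {
  if (inherits(profile, "discount_profile")) {
    points <- profile$points
    delayed_amount <- profile$delayed_amount
  } else {
    points <- profile
    if (is.null(delayed_amount)) stop("`delayed_amount` is required.")
  }
  if (delayed_amount <= 0) stop("`delayed_amount` must be positive.")
  data.frame(
    x = c(0, points$days / max(points$days)),
    y = c(1, points$subjective_value / delayed_amount)
  )
}

auc_trapezoid <- function(days, values, delayed_amount) {
  if (is.unsorted(days, strictly = TRUE)) stop("Delays must be strictly increasing.")
  x <- c(0, days / max(days))
  y <- c(1, values / delayed_amount)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Area under the normalized discounting curve
#'
#' Trapezoidal area under the normalized (delay fraction, value fraction)
#' curve, including the (0, 1) anchor segment. 1 means no discounting; values
#' near 0 mean extreme discounting.
#'
#' @param profile A [discount_profile()], or a data frame of points with a
#'   `delayed_amount` argument.
#' @inheritParams dd_normalize
#' @return A number in (0, 1] for any titration-produced profile.
#' @export
dd_auc <- function(profile, delayed_amount = NULL) {
  if (inherits(profile, "discount_profile")) {
    return(auc_trapezoid(profile$points$days, profile$points$subjective_value,
                         profile$delayed_amount))
  }
  if (is.null(delayed_amount)) stop("`delayed_amount` is required.")
  auc_trapezoid(profile$days, profile$subjective_value, delayed_amount)
}

#' AuC for a matrix of indifference points
#'
#' Row-wise trapezoidal AuC for many participants at the same delays; used by
#' the cohort generator where profiles are produced in bulk.
#'
#' @param iv Matrix (participants x delays) of indifference points.
#' @param days Day-values of the delay conditions (columns of `iv`).
#' @param delayed_amount The delayed reward amount.
#' @return Numeric vector of AuC values, one per row.
#' @export
dd_auc_matrix <- function(iv, days, delayed_amount) {
  stopifnot(is.matrix(iv), ncol(iv) == length(days))
  x <- c(0, days / max(days))
  w <- diff(x)
  y <- cbind(1, iv / delayed_amount)
  k <- length(x)
  as.numeric((y[, -k, drop = FALSE] + y[, -1, drop = FALSE]) %*% w / 2)
}

#' Fit a hyperbolic discount rate to a profile
#'
#' Least-squares estimate of the per-day rate `k` in `V = A / (1 + k D)` over
#' the profile's indifference points. Supports parameter-recovery checks; the
#' primary discounting statistic remains the AuC.
#'
#' @param profile A [discount_profile()] with at least 2 points.
#' @param k_max Upper search bound for `k` (per day).
#' @return List with `k`, `sse`, and `fitted` values.
#' @export
fit_hyperbolic <- function(profile, k_max = 10) {
  stopifnot(inherits(profile, "discount_profile"), nrow(profile$points) >= 2L)
  d <- profile$points$days
  v <- profile$points$subjective_value
  a <- profile$delayed_amount
  sse <- function(k) sum((v - a / (1 + k * d))^2)
  # coarse log-spaced bracket (plus the k = 0 boundary), then refine
  grid <- c(0, 10^seq(-8, log10(k_max), length.out = 120))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  k <- if (hi > lo) {
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
    if (sse(0) <= opt$objective) 0 else opt$minimum
  } else 0
  if (!is.finite(sse(k))) stop("Hyperbolic fit failed: non-finite objective at k = ", k)
  list(k = k, sse = sse(k), fitted = a / (1 + k * d))
}
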