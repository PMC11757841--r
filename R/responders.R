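#' Simulated choice agents for the titration task
#'
#' A responder maps an (offer, amount, delay) triple to a choice. The
#' deterministic rule takes the immediate offer whenever it is at least the
#' agent's subjective value of the delayed reward (ties go to the certain
#' immediate reward). With `temperature > 0` choices become probabilistic via
#' a logistic rule on the offer-minus-value difference, which nests the
#' deterministic agent continuously as temperature tends to 0.
#'
#' @param model Discounting model: `"hyperbolic"` (`V = A/(1 + kD)`),
#'   `"exponential"` (`V = A exp(-kD)`), `"fixed_threshold"` (constant `V`),
#'   `"always_immediate"`, or `"always_delayed"`.
#' @param k Per-day discount rate (hyperbolic/exponential), `>= 0`.
#' @param threshold Constant subjective value (fixed_threshold model).
#' @param temperature Logistic choice noise scale, `>= 0`; 0 = deterministic.
#' @return A `dd_responder` object.
#' @export
responder <- function(model = c("hyperbolic", "exponential", "fixed_threshold",
                                "always_immediate", "always_delayed"),
                      k = NULL, threshold = NULL, temperature = 0) {
  model <- match.arg(model)
  if (model %in% c("hyperbolic", "exponential")) {
    if (is.null(k) || !is.numeric(k) || length(k) != 1L || k < 0) {
      stop("`k` must be a single nonnegative number for the ", model, " model.")
    }
  }
  if (model == "fixed_threshold") {
    if (is.null(threshold) || !is.numeric(threshold) || threshold < 0) {
      stop("`threshold` must be a nonnegative amount for the fixed_threshold model.")
    }
  }
  if (!is.numeric(temperature) || temperature < 0) {
    stop("`temperature` must be >= 0.")
  }
  structure(list(model = model, k = k, threshold = threshold,
                 temperature = temperature),
            class = "dd_responder")
}

#' Subjective value of a delayed reward for a responder
#'
#' @param resp A [responder()].
#' @param amount Delayed reward amount (> 0).
#' @param days Delay in days (>= 0); zero delay means no discounting.
#' @return The subjective (present) value, in the same units as `amount`.
#' @export
responder_value <- function(resp, amount, days) {
  stopifnot(inherits(resp, "dd_responder"), amount > 0)
  if (any(days < 0)) stop("`days` must be nonnegative.")
  switch(resp$model,
    hyperbolic = amount / (1 + resp$k * days),
    exponential = amount * exp(-resp$k * days),
    fixed_threshold = rep(resp$threshold, length(days)),
    always_immediate = rep(0, length(days)),   # any offer beats the delay
    always_delayed = rep(Inf, length(days))    # no offer is ever enough
  )
}

#' One choice between an immediate offer and the delayed reward
#'
#' @param resp A [responder()].
#' @param offer Immediate amount on offer.
#' @param amount Delayed reward amount.
#' @param days Delay in days.
#' @return `"immediate"` or `"delayed"`. With `temperature > 0` the choice is
#'   random (immediate with probability `plogis((offer - V)/temperature)`);
#'   seed the RNG for reproducibility. The RNG is untouched in the
#'   deterministic branch.
#' @export
responder_choose <- function(resp, offer, amount, days) {
  stopifnot(inherits(resp, "dd_responder"))
  if (resp$model == "always_immediate") return("immediate")
  if (resp$model == "always_delayed") return("delayed")
  v <- responder_value(resp, amount, days)
  if (resp$temperature == 0) {
    if (offer >= v) "immediate" else "delayed"
  } else {
    p_imm <- stats::plogis((offer - v) / resp$temperature)
    if (stats::runif(1) < p_imm) "immediate" else "delayed"
  }
}
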