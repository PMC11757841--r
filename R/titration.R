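#' Default delay conditions of the discounting task
#'
#' The seven delays at which the larger-later reward is offered, with their
#' conventional day-values (1 week = 7, 1 month = 30, 3 months = 90,
#' 6 months = 180, 1 year = 365, 3 years = 1095, 10 years = 3650).
#'
#' @return A data frame with columns `label` and `days`, ascending in days.
#' @export
delay_conditions <- function() {
  data.frame(
    label = c("1 week", "1 month", "3 months", "6 months",
              "1 year", "3 years", "10 years"),
    days = c(7, 30, 90, 180, 365, 1095, 3650),
    stringsAsFactors = FALSE
  )
}

#' Configure the adjusting-amount titration task
#'
#' The task pits an adjustable immediate reward against a fixed larger-later
#' reward. The first adjustment is half the initial difference between the
#' two amounts; each subsequent adjustment halves again.
#'
#' @param delayed_amount Fixed larger-later reward (default $2000).
#' @param initial_immediate Immediate offer on the first trial (default $1000).
#' @param n_trials Choices per delay condition (default 6).
#' @param delays Data frame of delay conditions (`label`, `days`), strictly
#'   increasing in days; defaults to [delay_conditions()].
#' @param currency_precision Decimal places to keep on offers, or `NULL`
#'   (default) for full numeric precision. Rounding breaks the exact halving
#'   identities, so the default is no rounding.
#' @return A `dd_task_config` object.
#' @export
task_config <- function(delayed_amount = 2000, initial_immediate = 1000,
                        n_trials = 6L, delays = delay_conditions(),
                        currency_precision = NULL) {
  stopifnot(is.numeric(delayed_amount), length(delayed_amount) == 1L,
            is.numeric(initial_immediate), length(initial_immediate) == 1L)
  if (!(initial_immediate > 0 && initial_immediate < delayed_amount)) {
    stop("`initial_immediate` must lie strictly between 0 and `delayed_amount`.")
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("`n_trials` must be >= 1.")
  if (!is.data.frame(delays) || !all(c("label", "days") %in% names(delays)) ||
      nrow(delays) < 1L) {
    stop("`delays` must be a data frame with columns `label` and `days`.")
  }
  if (any(delays$days <= 0)) stop("Delay day-values must be positive.")
  if (is.unsorted(delays$days, strictly = TRUE)) {
    stop("Delays must be strictly increasing in days.")
  }
  if (anyDuplicated(delays$label)) stop("Delay labels must be unique.")
  if (!is.null(currency_precision)) {
    stopifnot(is.numeric(currency_precision), currency_precision >= 0)
  }
  structure(
    list(delayed_amount = delayed_amount,
         initial_immediate = initial_immediate,
         n_trials = n_trials,
         delays = delays,
         currency_precision = currency_precision),
    class = "dd_task_config"
  )
}

resolve_delay <- function(config, delay) {
  if (is.character(delay)) {
    i <- match(delay, config$delays$label)
    if (is.na(i)) stop("Unknown delay label: ", delay)
    return(list(label = config$delays$label[i], days = config$delays$days[i]))
  }
  if (is.list(delay) && all(c("label", "days") %in% names(delay))) {
    return(list(label = as.character(delay$label)[1],
                days = as.numeric(delay$days)[1]))
  }
  stop("`delay` must be a delay label or a list with `label` and `days`.")
}

round_offer <- function(offer, config) {
  if (is.null(config$currency_precision)) offer
  else round(offer, config$currency_precision)
}

#' Start a titration run for one delay condition
#'
#' @param config A [task_config()].
#' @param delay A delay label from `config$delays`, or a list with `label`
#'   and `days`.
#' @return A `titration_state`: the offer and pending adjustment step for
#'   the next trial, plus the trial history so far.
#' @export
titration_start <- function(config, delay) {
  if (!inherits(config, "dd_task_config")) stop("`config` must be a task_config.")
  delay <- resolve_delay(config, delay)
  structure(
    list(config = config,
         delay = delay,
         offer = config$initial_immediate,
         step = (config$delayed_amount - config$initial_immediate) / 2,
         trials_done = 0L,
         history = data.frame(trial_index = integer(), immediate_offer = numeric(),
                              choice = character(), stringsAsFactors = FALSE)),
    class = "titration_state"
  )
}

#' Apply one choice to a titration state
#'
#' Choosing the delayed reward raises the next immediate offer by the current
#' step; choosing the immediate reward lowers it. The step then halves.
#'
#' @param state A `titration_state`.
#' @param choice `"immediate"` or `"delayed"` (abbreviations and the one-letter
#'   log codes `"I"`/`"D"` accepted).
#' @return The updated `titration_state`.
#' @export
titration_choose <- function(state, choice) {
  if (!inherits(state, "titration_state")) stop("`state` must be a titration_state.")
  choice <- normalize_choice(choice)
  if (state$trials_done >= state$config$n_trials) {
    stop("All ", state$config$n_trials, " trials already completed for this condition.")
  }
  rec <- data.frame(trial_index = state$trials_done + 1L,
                    immediate_offer = state$offer,
                    choice = choice, stringsAsFactors = FALSE)
  sgn <- if (choice == "delayed") 1 else -1
  state$offer <- round_offer(state$offer + sgn * state$step, state$config)
  state$step <- state$step / 2
  state$trials_done <- state$trials_done + 1L
  state$history <- rbind(state$history, rec)
  state
}

normalize_choice <- function(choice) {
  if (length(choice) != 1L || is.na(choice)) stop("`choice` must be a single value.")
  ch <- as.character(choice)
  if (ch %in% c("I", "i")) return("immediate")
  if (ch %in% c("D", "d")) return("delayed")
  match.arg(ch, c("immediate", "delayed"))
}

#' Estimated indifference point after a completed condition
#'
#' After the final trial the subjective value of the delayed reward is the
#' immediate amount that would have been presented on a hypothetical next
#' trial, i.e. the final offer moved once more by half the last applied step
#' in the direction of the final choice.
#'
#' @param state A completed `titration_state` (all trials answered).
#' @return A one-row data frame with `label`, `days`, `subjective_value`.
#' @export
indifference_point <- function(state) {
  if (!inherits(state, "titration_state")) stop("`state` must be a titration_state.")
  if (state$trials_done < state$config$n_trials) {
    stop("Condition incomplete: ", state$trials_done, " of ",
         state$config$n_trials, " trials answered.")
  }
  data.frame(label = state$delay$label, days = state$delay$days,
             subjective_value = state$offer, stringsAsFactors = FALSE)
}

#' Run one delay condition with a responder
#'
#' @param resp A [responder()].
#' @param config A [task_config()].
#' @param delay A delay label or `list(label, days)`.
#' @return A list with `point` (one-row indifference data frame) and
#'   `trials` (the per-trial log).
#' @export
run_condition <- function(resp, config, delay) {
  state <- titration_start(config, delay)
  for (t in seq_len(config$n_trials)) {
    ch <- responder_choose(resp, offer = state$offer,
                           amount = config$delayed_amount,
                           days = state$delay$days)
    if (!identical(ch, "immediate") && !identical(ch, "delayed")) {
      stop("Responder returned an invalid choice: ", deparse(ch))
    }
    state <- titration_choose(state, ch)
  }
  trials <- state$history
  trials$delay_label <- state$delay$label
  trials$delay_days <- state$delay$days
  list(point = indifference_point(state),
       trials = trials[, c("delay_label", "delay_days", "trial_index",
                           "immediate_offer", "choice")])
}

#' Run the full task (all delays) with a responder
#'
#' @param resp A [responder()].
#' @param config A [task_config()].
#' @param shuffle_delays If `TRUE`, administer the delay conditions in a
#'   random order (seed the RNG beforehand); the recorded profile is always
#'   in ascending delay order, and the AuC is order-invariant.
#' @return A [discount_profile()] carrying the indifference points, the AuC,
#'   and the full trial log.
#' @export
run_task <- function(resp, config = task_config(), shuffle_delays = FALSE) {
  idx <- seq_len(nrow(config$delays))
  if (shuffle_delays) idx <- sample(idx)
  out <- lapply(idx, function(i) {
    run_condition(resp, config, config$delays$label[i])
  })
  points <- do.call(rbind, lapply(out, `[[`, "point"))
  trials <- do.call(rbind, lapply(out, `[[`, "trials"))
  points <- points[order(points$days), , drop = FALSE]
  rownames(points) <- NULL
  discount_profile(points, config$delayed_amount, trials = trials)
}

#' Vectorized titration for deterministic threshold agents
#'
#' Runs the adjusting-amount rule simultaneously for many agents, each
#' characterised by a subjective value `sv` for the delayed reward at one
#' delay: the agent takes the immediate offer whenever `offer >= sv` (ties
#' go to the certain immediate reward). Identical, trial for trial, to
#' driving [titration_choose()] with a threshold responder, but a vector op
#' per trial.
#'
#' @param sv Numeric vector of subjective values, one per agent.
#' @param config A [task_config()].
#' @param keep_trials If `TRUE` also return presented offers and choices.
#' @return If `keep_trials` is `FALSE`, the vector of indifference points.
#'   Otherwise a list with `indifference`, and `offers`/`choices` matrices
#'   (agents x trials; choices coded `"I"`/`"D"`).
#' @export
titrate_threshold <- function(sv, config = task_config(), keep_trials = FALSE) {
  n <- length(sv)
  offer <- rep(config$initial_immediate, n)
  step <- (config$delayed_amount - config$initial_immediate) / 2
  offers <- if (keep_trials) matrix(NA_real_, n, config$n_trials) else NULL
  choices <- if (keep_trials) matrix(NA_character_, n, config$n_trials) else NULL
  for (t in seq_len(config$n_trials)) {
    imm <- offer >= sv
    if (keep_trials) {
      offers[, t] <- offer
      choices[, t] <- ifelse(imm, "I", "D")
    }
    offer <- round_offer(offer + ifelse(imm, -step, step), config)
    step <- step / 2
  }
  if (keep_trials) list(indifference = offer, offers = offers, choices = choices)
  else offer
}
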