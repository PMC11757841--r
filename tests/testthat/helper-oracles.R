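# Independent oracles, kept deliberately naive and separate from package code.

# Sequential replay of the adjusting-amount halving rule for one condition:
# returns the immediate amount of the hypothetical next trial.
oracle_replay <- function(choices, delayed = 2000, initial = 1000) {
  offer <- initial
  adj <- (delayed - initial) / 2
  for (ch in choices) {
    offer <- offer + (if (ch %in% c("D", "delayed")) 1 else -1) * adj
    adj <- adj / 2
  }
  offer
}

# Replay driven by a deterministic threshold rule (immediate iff offer >= v).
oracle_titrate_threshold <- function(v, delayed = 2000, initial = 1000,
                                     n_trials = 6) {
  offer <- initial
  adj <- (delayed - initial) / 2
  for (t in seq_len(n_trials)) {
    offer <- offer + (if (offer >= v) -1 else 1) * adj
    adj <- adj / 2
  }
  offer
}

# Trapezoid AuC over already-normalized points via pracma (independent code path).
oracle_auc <- function(days, sv, delayed) {
  pracma::trapz(c(0, days / max(days)), c(1, sv / delayed))
}

# Roster emulating the study's exclusion counts: completers, of whom some are
# unvaccinated and some (vaccinated) gave no booster answer.
roster_fixture <- function(n_total = 3185, n_unvacc = 270, n_missing = 368) {
  n_kept <- n_total - n_unvacc - n_missing
  data.frame(
    participant_id = seq_len(n_total),
    vaccination_status = c(rep(3L, n_unvacc),            # unvaccinated
                           rep(1L, n_missing),           # vaccinated, no answer
                           rep(c(1L, 2L), length.out = n_kept)),
    booster_raw = c(rep(NA_integer_, n_unvacc),
                    rep(2L, n_missing),                  # prefer not to say
                    rep(c(1L, 0L, 1L), length.out = n_kept))
  )
}

# Cheap profile builder for metrics tests.
make_profile <- function(sv, days = delay_conditions()$days, delayed = 2000) {
  discount_profile(data.frame(days = days, subjective_value = sv), delayed)
}
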