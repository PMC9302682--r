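# Independent oracles and shared fixtures for the test suite.

# Brute-force reimplementation of inverse-variance pooling with the
# DerSimonian-Laird moment estimator, written with explicit loops and
# kept deliberately independent of the package's vectorized code path.
dl_pool_oracle <- function(y, se) {
  k <- length(y)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / se[i]^2
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    sw <- sw + w[i]; swy <- swy + w[i] * y[i]; sw2 <- sw2 + w[i]^2
  }
  mu_f <- swy / sw
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (y[i] - mu_f)^2
  tau2 <- max(0, (Q - (k - 1)) / (sw - sw2 / sw))
  wr <- numeric(k)
  for (i in seq_len(k)) wr[i] <- 1 / (se[i]^2 + tau2)
  mu_r <- sum(wr * y) / sum(wr)
  list(fixed = mu_f, Q = Q, tau2 = tau2, random = mu_r,
       se_random = 1 / sqrt(sum(wr)),
       I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# Minimal hand-built trial: 2 x 2 arms of participants with chosen
# per-arm eczema outcomes (resolved through the UKWP field).
make_trial <- function(trial_id, events_treat, n_treat, events_ctrl, n_ctrl,
                       ...) {
  n <- n_treat + n_ctrl
  participant_table(
    trial_id = trial_id,
    participant_id = sprintf("%s-%03d", trial_id, seq_len(n)),
    arm = rep(c(1, 0), c(n_treat, n_ctrl)),
    sex = rep_len(c(0, 1), n),
    eczema_ukwp = c(rep(c(1, 0), c(events_treat, n_treat - events_treat)),
                    rep(c(1, 0), c(events_ctrl, n_ctrl - events_ctrl))),
    visit_ages_days = list(c(90L, 180L, 365L)),
    ...
  )
}

# The published perfect-prediction configuration: in the standard-care
# arm 5/22 infants without FLG mutations and 1/1 with mutations had
# eczema; in the intervention arm 3/21 and 1/3.
flg_perfect_prediction_trial <- function() {
  cells <- data.frame(
    arm = c(0, 0, 1, 1), flg = c(0, 1, 0, 1),
    events = c(5, 1, 3, 1), n = c(22, 1, 21, 3)
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(
      arm = rep(arm, n), flg = rep(flg, n),
      y = rep(c(1, 0), c(events, n - events))
    ))
  }))
  participant_table(
    trial_id = "FLG", participant_id = sprintf("f%02d", seq_len(nrow(rows))),
    arm = rows$arm, sex = rep_len(c(0, 1), nrow(rows)),
    flg_mutations = rows$flg, eczema_ukwp = rows$y,
    visit_ages_days = list(c(365L))
  )
}
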