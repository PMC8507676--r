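# Shared helpers for the test suite.

# a dice script assigning one face to every rolling area for n rounds;
# per-round overrides given as list(round = list(station = faces))
script_uniform <- function(n_rounds, face = 3L, overrides = list()) {
  rows <- expand.grid(round = seq_len(n_rounds), station = rolling_areas(),
                      stringsAsFactors = FALSE)
  rows$face1 <- face
  rows$face2 <- NA_integer_
  for (r in names(overrides)) {
    for (st in names(overrides[[r]])) {
      faces <- overrides[[r]][[st]]
      i <- rows$round == as.integer(r) & rows$station == st
      rows$face1[i] <- faces[1L]
      rows$face2[i] <- if (length(faces) > 1L) faces[2L] else NA_integer_
    }
  }
  dice_script(rows)
}

# independent brute-force reference for the allocation invariants:
# feasible split maximising total served (work conservation), given bounds
max_served_oracle <- function(capacity, treat_len, disch_len) {
  as.integer(min(capacity, treat_len + disch_len))
}

# fully scripted 3-round scenario with a complete hand trace:
# 6 initial patients (2 registration, 1 assessment-treat, 2 suture,
# 1 discharge-wait), every plan the suture room, strategy II rules
hand_trace_shift <- function() {
  cfg <- shift_config("II", n_rounds = 3,
                      initial_patients = 6,
                      initial_allocation = c(registration = 2,
                                             med_assess.treat = 1,
                                             suture = 2,
                                             med_assess.discharge_wait = 1),
                      path_probs = c(1, 0, 0, 0),
                      initial_plans = "suture")
  sc <- script_uniform(3, face = 1, overrides = list(
    `1` = list(walk_in = 1, registration = 2, triage = 3, med_assess = 4,
               suture = 5, imaging = 1, lab = 1, medication = 1),
    `2` = list(walk_in = 2, registration = 1, triage = 2, med_assess = 6,
               suture = 4, imaging = 1, lab = 1, medication = 1),
    `3` = list(walk_in = 1, registration = 3, triage = 1, med_assess = 3,
               suture = 2, imaging = 2, lab = 2, medication = 2)))
  play_shift(cfg, seed = 1, script = sc)
}

# the paper-and-pencil trace of that scenario, derived by hand
hand_trace_expected <- list(
  walk_ins = c(1, 2, 1), registration = c(2, 1, 2), triage = c(0, 2, 1),
  ma_treat = c(1, 0, 2), discharges = c(1, 0, 1), suture = c(0, 3, 0),
  lwot = c(0, 0, 0), wip_after = c(6, 8, 8), tokens_suture = c(1, 0, 0))

# play a shift and check the conservation identity after every round
conservation_trace_ok <- function(cfg, seed) {
  res <- play_shift(cfg, seed = seed)
  r <- res$rounds
  exits <- cumsum(r[, "discharges"] + r[, "referrals"] + r[, "lwot"])
  arrivals <- cumsum(r[, "walk_ins"])
  all(res$initial_patients + arrivals == exits + r[, "wip_after"])
}
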