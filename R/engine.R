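# Round, shift and Monte Carlo execution with reproducible or scripted dice.

.REC_COLS <- c("round", "walk_ins", "registration", "triage", "referrals",
               "ma_treat", "discharges",
               "suture", "imaging", "lab", "medication",
               "lwot", "wip_after",
               "tokens_suture", "tokens_imaging", "tokens_lab", "tokens_medication",
               "cap_walk_in", "cap_registration", "cap_triage", "cap_med_assess",
               "cap_suture", "cap_imaging", "cap_lab", "cap_medication")

#' Scripted dice for deterministic replay
#'
#' A dice script fixes the underlying die face(s) of every rolling area in
#' every round, replacing the RNG for tests and replay. Scripted faces are
#' underlying faces 1-6; remaps (the 4-6 die) are applied on top.
#'
#' @param x `data.frame` with columns `round`, `station` and `face1`
#'   (plus `face2`, ... for multi-die areas; `NA` for unused face columns).
#'   Stations are the eight rolling areas, see [rolling_areas()].
#' @return Object of class `dice_script`.
#' @examples
#' sc <- dice_script(data.frame(round = 1, station = rolling_areas(),
#'                              face1 = 3))
#' @export
dice_script <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("round", "station", "face1") %in% names(x)))
    stop("a dice script needs columns round, station, face1", call. = FALSE)
  bad <- setdiff(unique(x$station), .ROLLING)
  if (length(bad))
    stop(sprintf("unknown rolling area(s) in dice script: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  rounds <- as.integer(x$round)
  if (anyNA(rounds) || any(rounds < 1L))
    stop("dice script rounds must be positive integers", call. = FALSE)
  face_cols <- grep("^face[0-9]+$", names(x), value = TRUE)
  script <- rep(list(stats::setNames(vector("list", length(.ROLLING)), .ROLLING)),
                max(rounds))
  for (i in seq_len(nrow(x))) {
    faces <- as.integer(unlist(x[i, face_cols], use.names = FALSE))
    faces <- faces[!is.na(faces)]
    if (!length(faces) || any(faces < 1L | faces > 6L))
      stop(sprintf("invalid scripted faces for %s in round %d (must be 1-6)",
                   x$station[i], rounds[i]), call. = FALSE)
    script[[rounds[i]]][[x$station[i]]] <- faces
  }
  structure(script, class = "dice_script")
}

script_faces <- function(script, r, station) {
  faces <- if (r <= length(script)) script[[r]][[station]] else NULL
  if (is.null(faces))
    stop(sprintf("dice script has no entry for %s in round %d", station, r),
         call. = FALSE)
  faces
}

#' Play one round
#'
#' Executes one 48-minute round as a synchronous update against the
#' start-of-round queue contents: every rolling area's die is drawn first,
#' and a patient moved into a queue during the round is not eligible for
#' service there until the next round. In board terms the round is:
#' walk-ins arrive (one D6), registration and triage each move
#' `min(die, queue)` forward (triage applying the GP-referral rule when
#' active), medical assessment splits its dice between its treat and
#' discharge-wait queues, and each specialized resource passes the
#' minimum-batch gate before moving served patients back to the
#' discharge-wait queue. Under the synchronous contract the processing
#' order of the areas does not affect the outcome.
#'
#' @param state Board state from [make_initial_board()] or a previous round.
#' @param cfg An [shift_config()].
#' @param script Optional [dice_script()]; when given every rolling area of
#'   this round must be covered.
#' @param order Processing order of the rolling areas (testing hook; any
#'   permutation of [rolling_areas()] yields the same result).
#' @return List with the updated `state` and `record`, a named numeric
#'   vector of the round's counts (walk-ins, per-station served counts,
#'   referrals, discharges, LWOT, end-of-round WIP, tokens, capacities).
#' @export
play_round <- function(state, cfg, script = NULL, order = .ROLLING) {
  r <- state$round + 1L
  if (r > cfg$n_rounds)
    stop(sprintf("shift already complete (%d rounds played)", cfg$n_rounds),
         call. = FALSE)
  if (length(order) != length(.ROLLING) || !setequal(order, .ROLLING))
    stop("order must be a permutation of rolling_areas()", call. = FALSE)

  # --- pre-phase: draw all randomness in canonical order -------------------
  caps <- stats::setNames(integer(length(.ROLLING)), .ROLLING)
  for (st in .ROLLING) {
    spec <- if (st == "med_assess") cfg$ma_dice else dice_d6()
    caps[[st]] <- if (is.null(script)) roll_n(spec, 1L)
                  else roll(spec, faces = script_faces(script, r, st))
  }
  n_in <- caps[["walk_in"]]
  new_plan_codes <- sample_path_codes(n_in, cfg$path_probs)

  q <- state$queues
  # last round's walk-ins join the registration line; eligible this round
  if (length(q$walk_in)) {
    q$registration <- c(q$registration, q$walk_in)
    q$walk_in <- integer(0L)
  }
  elig <- lengths(q)   # start-of-round snapshot

  n_reg <- 0L; n_tri <- 0L; n_ref <- 0L
  n_treat <- 0L; n_disch <- 0L
  served_spec <- stats::setNames(integer(4L), .STATIONS[.SPECIALIZED])
  lwot_n <- 0L

  for (st in order) {
    if (st == "walk_in") {
      # --- arrivals -------------------------------------------------------
      if (n_in > 0L) {
        if (state$n_patients + n_in > state$capacity)
          state <- grow_board(state, state$n_patients + n_in)
        ids <- state$n_patients + seq_len(n_in)
        state$n_patients <- state$n_patients + n_in
        state$plans[ids] <- as.list(new_plan_codes)
        state$plan_pos[ids] <- 1L
        state$entry_round[ids] <- r
        q$walk_in <- ids
        state$counts[["arrivals"]] <- state$counts[["arrivals"]] + n_in
      }
    } else if (st == "registration") {
      n_reg <- min(caps[["registration"]], elig[["registration"]])
      if (n_reg > 0L) {
        moved <- q$registration[seq_len(n_reg)]
        q$registration <- q$registration[-seq_len(n_reg)]
        q$triage <- c(q$triage, moved)
      }
    } else if (st == "triage") {
      ts <- triage_split(caps[["triage"]], elig[["triage"]], cfg$refer_gp)
      n_ref <- ts[["referred"]]
      n_tri <- n_ref + ts[["to_assessment"]]
      if (n_tri > 0L) {
        moved <- q$triage[seq_len(n_tri)]
        q$triage <- q$triage[-seq_len(n_tri)]
        if (n_ref > 0L) {
          ref_ids <- moved[seq_len(n_ref)]
          state$exit_round[ref_ids] <- r
          state$exit_kind[ref_ids] <- 2L
          state$counts[["referrals"]] <- state$counts[["referrals"]] + n_ref
          moved <- moved[-seq_len(n_ref)]
        }
        if (length(moved))
          q$med_assess.treat <- c(q$med_assess.treat, moved)
      }
    } else if (st == "med_assess") {
      al <- allocate_assessment(caps[["med_assess"]],
                                elig[["med_assess.treat"]],
                                elig[["med_assess.discharge_wait"]],
                                rule = cfg$allocation,
                                tie_break = cfg$bm_tie_break,
                                random_split = cfg$random_split)
      n_treat <- al[["treat"]]; n_disch <- al[["discharge"]]
      if (n_treat > 0L) {
        moved <- q$med_assess.treat[seq_len(n_treat)]
        q$med_assess.treat <- q$med_assess.treat[-seq_len(n_treat)]
        for (id in moved) {
          plan <- state$plans[[id]]
          pos <- state$plan_pos[id]
          dest <- if (pos <= length(plan)) plan[pos] else .DISCH_WAIT
          q[[dest]] <- c(q[[dest]], id)
        }
      }
      if (n_disch > 0L) {
        out <- q$med_assess.discharge_wait[seq_len(n_disch)]
        q$med_assess.discharge_wait <- q$med_assess.discharge_wait[-seq_len(n_disch)]
        state$exit_round[out] <- r
        state$exit_kind[out] <- 1L
        state$counts[["discharges"]] <- state$counts[["discharges"]] + n_disch
      }
    } else {
      # --- specialized resource under the batching gate -------------------
      g <- batching_gate(elig[[st]], state$tokens[[st]], cfg$min_batch)
      state$tokens[[st]] <- g$tokens_after
      if (g$may_roll) {
        n_s <- min(caps[[st]], elig[[st]])
        if (n_s > 0L) {
          moved <- q[[st]][seq_len(n_s)]
          q[[st]] <- q[[st]][-seq_len(n_s)]
          for (id in moved) {
            pos <- state$plan_pos[id] + 1L
            state$plan_pos[id] <- pos
            plan <- state$plans[[id]]
            dest <- if (pos <= length(plan)) plan[pos] else .DISCH_WAIT
            q[[dest]] <- c(q[[dest]], id)
          }
        }
        served_spec[[st]] <- n_s
      } else if (g$lwot_emitted) {
        out <- q[[st]][1L]   # FIFO: the longest-waiting patient leaves
        q[[st]] <- q[[st]][-1L]
        state$exit_round[out] <- r
        state$exit_kind[out] <- 3L
        state$counts[["lwot"]] <- state$counts[["lwot"]] + 1L
        lwot_n <- lwot_n + 1L
      }
    }
  }

  wip_after <- sum(lengths(q))
  state$queues <- q
  state$round <- r
  state$wip_trace <- c(state$wip_trace, wip_after)

  record <- stats::setNames(
    c(r, n_in, n_reg, n_tri, n_ref, n_treat, n_disch,
      served_spec, lwot_n, wip_after, state$tokens, caps),
    .REC_COLS)
  list(state = state, record = record)
}

#' Play a full shift
#'
#' Builds the initial board and plays `cfg$n_rounds` rounds. The same seed
#' and configuration yield an identical result.
#'
#' @param cfg An [shift_config()].
#' @param seed Optional integer seed applied via [set.seed()] before board
#'   construction.
#' @param script Optional [dice_script()] covering every rolling area in
#'   every round.
#' @param order See [play_round()].
#' @return Object of class `ed_shift`: `config`, `seed`, `rounds` (matrix,
#'   one row per round), `totals` (arrivals, discharges, referrals, lwot),
#'   `initial_patients`, `wip_trace` and `final_state` (which carries the
#'   per-patient exit ledger, see [patient_ledger()]).
#' @examples
#' res <- play_shift(shift_config("IV"), seed = 1)
#' res$totals
#' @export
play_shift <- function(cfg, seed = NULL, script = NULL, order = .ROLLING) {
  stopifnot(inherits(cfg, "ed_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- make_initial_board(cfg)
  recs <- matrix(0, nrow = cfg$n_rounds, ncol = length(.REC_COLS),
                 dimnames = list(NULL, .REC_COLS))
  for (i in seq_len(cfg$n_rounds)) {
    out <- play_round(state, cfg, script = script, order = order)
    state <- out$state
    recs[i, ] <- out$record
  }
  structure(list(config = cfg,
                 seed = seed,
                 rounds = recs,
                 totals = state$counts,
                 initial_patients = state$initial_patients,
                 wip_trace = state$wip_trace,
                 final_state = state),
            class = "ed_shift")
}

#' @export
print.ed_shift <- function(x, ...) {
  t <- x$totals
  cat(sprintf("ED game shift: strategy %s, %d rounds, %d initial patients\n",
              x$config$strategy, x$config$n_rounds, x$initial_patients))
  cat(sprintf("  arrivals %d | discharges %d | referrals %d | LWOT %d | end WIP %d\n",
              t[["arrivals"]], t[["discharges"]], t[["referrals"]],
              t[["lwot"]], board_wip(x$final_state)))
  invisible(x)
}

# stable per-run seed derivation: distinct for runs 1..n, < 2^31
run_seed <- function(master_seed, i) {
  as.integer(((as.numeric(master_seed) %% 2147483647) * 10007 + i) %% 2147483647)
}

#' Monte Carlo batch of shifts
#'
#' `run_monte_carlo()` plays `n_runs` independent shifts, seeding run `i`
#' with a stable derivation from `master_seed` (so any subset of runs is
#' reproducible on its own) and returns the full shift results.
#' `mc_measures()` is the memory-light variant that keeps only the
#' per-shift measures of [shift_measures()], one row per run.
#'
#' @param cfg An [shift_config()].
#' @param n_runs Number of complete shifts (the published analysis
#'   uses 10,000).
#' @param master_seed Integer master seed.
#' @return `run_monte_carlo()`: list of `ed_shift` objects (class `ed_mc`).
#'   `mc_measures()`: `data.frame` of per-run measures with attributes
#'   `strategy`, `n_rounds`, `n_runs`, `master_seed`.
#' @examples
#' m <- mc_measures(shift_config("IV"), n_runs = 50, master_seed = 1)
#' mean(m$discharges_incl_referrals)
#' @export
run_monte_carlo <- function(cfg, n_runs = 10000L, master_seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L)
    stop("n_runs must be a positive integer", call. = FALSE)
  res <- lapply(seq_len(n_runs), function(i)
    play_shift(cfg, seed = run_seed(master_seed, i)))
  structure(res, class = "ed_mc", strategy = cfg$strategy,
            master_seed = master_seed)
}

#' @rdname run_monte_carlo
#' @export
mc_measures <- function(cfg, n_runs = 10000L, master_seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L)
    stop("n_runs must be a positive integer", call. = FALSE)
  first <- shift_measures(play_shift(cfg, seed = run_seed(master_seed, 1L)))
  out <- matrix(NA_real_, nrow = n_runs, ncol = length(first),
                dimnames = list(NULL, names(first)))
  out[1L, ] <- first
  for (i in seq_len(n_runs)[-1L])
    out[i, ] <- shift_measures(play_shift(cfg, seed = run_seed(master_seed, i)))
  df <- as.data.frame(out)
  attr(df, "strategy") <- cfg$strategy
  attr(df, "n_rounds") <- cfg$n_rounds
  attr(df, "n_runs") <- n_runs
  attr(df, "master_seed") <- master_seed
  df
}
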