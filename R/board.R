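# Domain state for the ED board: stations, queues, patients and initial setup.
#
# Queue indices (order fixed; specialized resources are 6:9):
#   1 walk_in, 2 registration, 3 triage, 4 med_assess.treat,
#   5 med_assess.discharge_wait, 6 suture, 7 imaging, 8 lab, 9 medication
.STATIONS <- c("walk_in", "registration", "triage",
               "med_assess.treat", "med_assess.discharge_wait",
               "suture", "imaging", "lab", "medication")
.SPECIALIZED <- 6L:9L
.DISCH_WAIT <- 5L
# one die per rolling area; med_assess serves both of its queues
.ROLLING <- c("walk_in", "registration", "triage", "med_assess",
              "suture", "imaging", "lab", "medication")
.EXIT_KINDS <- c("discharged", "referred", "lwot")

#' Stations of the ED board
#'
#' `ed_stations()` lists every queue on the board (medical assessment has
#' two: `med_assess.treat` for patients awaiting first assessment and
#' `med_assess.discharge_wait` for patients returning from a specialized
#' resource). `specialized_stations()` lists the four resources subject to
#' the minimum-batch policy. `rolling_areas()` lists the eight areas that
#' roll a die each round.
#'
#' @return Character vector of station names.
#' @export
ed_stations <- function() .STATIONS

#' @rdname ed_stations
#' @export
specialized_stations <- function() .STATIONS[.SPECIALIZED]

#' @rdname ed_stations
#' @export
rolling_areas <- function() .ROLLING

station_index <- function(name) {
  i <- match(name, .STATIONS)
  if (anyNA(i))
    stop(sprintf("unknown station(s): %s",
                 paste(name[is.na(i)], collapse = ", ")), call. = FALSE)
  i
}

check_path_probs <- function(path_probs) {
  p <- as.numeric(path_probs)
  if (length(p) != 4L || anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("path_probs must be 4 non-negative probabilities summing to 1 ",
         "(suture, imaging, lab, medication)", call. = FALSE)
  p
}

# specialized-station codes (6..9) for n new treatment plans
sample_path_codes <- function(n, path_probs) {
  if (n == 0L) return(integer(0L))
  .SPECIALIZED[sample.int(4L, n, replace = TRUE, prob = path_probs)]
}

#' Draw treatment plans
#'
#' Assigns each patient a treatment plan: the specialized resource(s) the
#' patient must visit between first assessment and discharge. Default plans
#' visit exactly one resource, drawn uniformly from suture, imaging, lab
#' and medication.
#'
#' @param n Number of plans to draw.
#' @param path_probs Probabilities for (suture, imaging, lab, medication);
#'   must be non-negative and sum to 1.
#' @return Character vector of specialized station names, length `n`.
#' @examples
#' set.seed(1)
#' assign_plan(5)
#' assign_plan(3, c(1, 0, 0, 0)) # everyone to the suture room
#' @export
assign_plan <- function(n = 1L, path_probs = c(0.25, 0.25, 0.25, 0.25)) {
  p <- check_path_probs(path_probs)
  .STATIONS[sample_path_codes(as.integer(n), p)]
}

#' Default start-of-shift patient placement
#'
#' Every shift starts with 28 patients on the board, the mean D6 roll (3.5)
#' times the eight rolling areas. The published board photo fixes only that
#' total; this default spreads the 28 over the stations in approximately
#' that proportion and is fully configurable through
#' [shift_config()]`$initial_allocation`.
#'
#' @return Named integer vector over stations, summing to 28.
#' @export
default_initial_allocation <- function() {
  c(walk_in = 3L, registration = 4L, triage = 3L,
    med_assess.treat = 4L, med_assess.discharge_wait = 2L,
    suture = 3L, imaging = 3L, lab = 3L, medication = 3L)
}

#' Configure one simulated shift
#'
#' Bundles one strategy's full rule set. Leaving `min_batch`, `refer_gp`,
#' `ma_dice` and `allocation` as `NULL` takes the strategy's canonical
#' binding from [strategy_defaults()]; each can be overridden individually.
#'
#' @param strategy Strategy id, `"I"`..`"VI"`.
#' @param n_rounds Rounds per shift (default 10; each round represents
#'   48 minutes, ten make an 8-hour shift).
#' @param initial_patients Patients on the board at round 0 (default 28).
#' @param initial_allocation Named integer vector placing the initial
#'   patients on stations; must sum to `initial_patients`.
#' @param path_probs Treatment-plan probabilities, see [assign_plan()].
#' @param min_batch Minimum queue length for a specialized resource to roll
#'   (1 disables the batching policy).
#' @param refer_gp Logical: triage refers one patient per round to a GP on
#'   a die of 2+.
#' @param ma_dice [dice_spec()] rolled by medical assessment.
#' @param allocation Assessment allocation rule, see [allocate_assessment()].
#' @param bm_tie_break Buffer-management tie-break queue.
#' @param random_split Point distribution for the `random` rule.
#' @param initial_plans Optional character vector of specialized station
#'   names, recycled over the pre-seeded patients that have not yet passed
#'   first assessment (those at walk-in, registration, triage and the
#'   assessment treat queue, in that order). When given, board construction
#'   consumes no randomness.
#' @return Object of class `ed_config`.
#' @examples
#' cfg <- shift_config("IV")
#' cfg$min_batch   # 1: the TOC shifts drop the batching policy
#' @export
shift_config <- function(strategy = c("I", "II", "III", "IV", "V", "VI"),
                         n_rounds = 10L,
                         initial_patients = 28L,
                         initial_allocation = NULL,
                         path_probs = c(0.25, 0.25, 0.25, 0.25),
                         min_batch = NULL,
                         refer_gp = NULL,
                         ma_dice = NULL,
                         allocation = NULL,
                         bm_tie_break = c("treat", "discharge"),
                         random_split = c("bernoulli", "uniform"),
                         initial_plans = NULL) {
  strategy <- match.arg(as.character(strategy), c("I", "II", "III", "IV", "V", "VI"))
  defaults <- strategy_defaults(strategy)
  if (is.null(min_batch)) min_batch <- defaults$min_batch
  if (is.null(refer_gp)) refer_gp <- defaults$refer_gp
  if (is.null(ma_dice)) ma_dice <- defaults$ma_dice
  if (is.null(allocation)) allocation <- defaults$allocation
  allocation <- match.arg(allocation, .ALLOC_RULES)
  bm_tie_break <- match.arg(bm_tie_break)
  random_split <- match.arg(random_split)

  n_rounds <- as.integer(n_rounds)
  if (is.na(n_rounds) || n_rounds < 0L)
    stop("n_rounds must be a non-negative integer", call. = FALSE)
  min_batch <- as.integer(min_batch)
  if (is.na(min_batch) || min_batch < 1L)
    stop("min_batch must be a positive integer (1 disables the batching policy)",
         call. = FALSE)
  if (!inherits(ma_dice, "dice_spec"))
    stop("ma_dice must be a dice_spec object", call. = FALSE)
  path_probs <- check_path_probs(path_probs)

  initial_patients <- as.integer(initial_patients)
  if (is.na(initial_patients) || initial_patients < 0L)
    stop("initial_patients must be a non-negative integer", call. = FALSE)
  if (is.null(initial_allocation)) {
    initial_allocation <- if (initial_patients == 28L) {
      default_initial_allocation()
    } else if (initial_patients == 0L) {
      stats::setNames(integer(length(.STATIONS)), .STATIONS)
    } else {
      stop("initial_allocation must be given explicitly when initial_patients ",
           "is neither 28 nor 0", call. = FALSE)
    }
  }
  alloc <- stats::setNames(integer(length(.STATIONS)), .STATIONS)
  idx <- station_index(names(initial_allocation))
  alloc[idx] <- as.integer(initial_allocation)
  if (anyNA(alloc) || any(alloc < 0L))
    stop("initial_allocation must contain non-negative integers", call. = FALSE)
  if (sum(alloc) != initial_patients)
    stop(sprintf("initial_allocation places %d patients but initial_patients is %d",
                 sum(alloc), initial_patients), call. = FALSE)
  if (!is.null(initial_plans)) {
    if (!all(initial_plans %in% .STATIONS[.SPECIALIZED]))
      stop("initial_plans must name specialized stations", call. = FALSE)
  }

  structure(list(strategy = strategy,
                 n_rounds = n_rounds,
                 initial_patients = initial_patients,
                 initial_allocation = alloc,
                 path_probs = path_probs,
                 min_batch = min_batch,
                 refer_gp = isTRUE(refer_gp),
                 ma_dice = ma_dice,
                 allocation = allocation,
                 bm_tie_break = bm_tie_break,
                 random_split = random_split,
                 initial_plans = initial_plans),
            class = "ed_config")
}

#' @export
print.ed_config <- function(x, ...) {
  cat("ED game shift configuration\n")
  cat(sprintf("  strategy:          %s (%s)\n", x$strategy, x$allocation))
  cat(sprintf("  rounds per shift:  %d\n", x$n_rounds))
  cat(sprintf("  initial patients:  %d\n", x$initial_patients))
  cat(sprintf("  min batch:         %d%s\n", x$min_batch,
              if (x$min_batch == 1L) " (batching policy off)" else ""))
  cat(sprintf("  refer to GP:       %s\n", if (x$refer_gp) "yes" else "no"))
  cat(sprintf("  assessment dice:   %s\n", dice_label(x$ma_dice)))
  if (x$allocation == "buffer_management")
    cat(sprintf("  BM tie-break:      %s\n", x$bm_tie_break))
  if (!is.null(x$n_runs))
    cat(sprintf("  Monte Carlo runs:  %d (master seed %s)\n",
                x$n_runs, format(x$master_seed)))
  invisible(x)
}

# grow patient attribute vectors when walk-ins exceed the preallocation
grow_board <- function(state, need) {
  newcap <- max(state$capacity * 2L, need + 16L)
  extra <- newcap - state$capacity
  state$plans <- c(state$plans, vector("list", extra))
  state$plan_pos <- c(state$plan_pos, integer(extra))
  state$entry_round <- c(state$entry_round, integer(extra))
  state$exit_round <- c(state$exit_round, rep(NA_integer_, extra))
  state$exit_kind <- c(state$exit_kind, rep(NA_integer_, extra))
  state$capacity <- newcap
  state
}

#' Set up the board for round 0
#'
#' Places the configured initial patients on the board with zero tokens and
#' zero cumulative counts. Patients that have not yet passed first
#' assessment get a sampled (or configured) treatment plan; patients
#' pre-seeded at a specialized resource have that resource as their plan;
#' patients pre-seeded in the discharge-wait queue have completed their plan
#' and only await discharge processing.
#'
#' @param cfg An [shift_config()] object.
#' @return Board state: a list with `queues` (patient ids per station),
#'   `tokens` (delayed-care tokens per specialized resource), `round`,
#'   cumulative `counts`, per-patient attribute vectors and `wip_trace`.
#' @export
make_initial_board <- function(cfg) {
  stopifnot(inherits(cfg, "ed_config"))
  alloc <- cfg$initial_allocation
  n0 <- sum(alloc)
  cap <- n0 + 8L * cfg$n_rounds + 16L

  state <- list(
    queues = stats::setNames(rep(list(integer(0L)), length(.STATIONS)), .STATIONS),
    tokens = stats::setNames(integer(4L), .STATIONS[.SPECIALIZED]),
    round = 0L,
    counts = c(arrivals = 0L, discharges = 0L, referrals = 0L, lwot = 0L),
    plans = vector("list", cap),
    plan_pos = integer(cap),
    entry_round = integer(cap),
    exit_round = rep(NA_integer_, cap),
    exit_kind = rep(NA_integer_, cap),
    n_patients = n0,
    capacity = cap,
    initial_patients = n0,
    wip_trace = integer(0L)
  )
  if (n0 == 0L) return(state)

  # patients ahead of first assessment need a plan draw (stations 1:4)
  pre_flow_n <- sum(alloc[1:4])
  pre_plans <- if (pre_flow_n == 0L) {
    integer(0L)
  } else if (!is.null(cfg$initial_plans)) {
    station_index(rep_len(cfg$initial_plans, pre_flow_n))
  } else {
    sample_path_codes(pre_flow_n, cfg$path_probs)
  }

  id <- 0L
  flow_i <- 0L
  for (s in seq_along(.STATIONS)) {
    k <- alloc[[s]]
    if (k == 0L) next
    ids <- id + seq_len(k)
    id <- id + k
    state$queues[[s]] <- ids
    if (s <= 4L) {                      # awaiting first assessment
      state$plans[ids] <- as.list(pre_plans[flow_i + seq_len(k)])
      flow_i <- flow_i + k
      state$plan_pos[ids] <- 1L
    } else if (s == .DISCH_WAIT) {      # plan complete, awaiting discharge
      state$plans[ids] <- list(integer(0L))
      state$plan_pos[ids] <- 1L
    } else {                            # waiting at their own plan stop
      state$plans[ids] <- list(s)
      state$plan_pos[ids] <- 1L
    }
  }
  state$entry_round[seq_len(n0)] <- 0L
  state
}

#' Per-patient ledger of a board state or shift result
#'
#' @param x A board state from [make_initial_board()]/[play_round()] or an
#'   `ed_shift` result from [play_shift()].
#' @return `data.frame` with one row per patient: `id`, `plan` (specialized
#'   stations, collapsed with `+`), `entry_round`, `exit_round`, `exit_kind`
#'   (`discharged`, `referred`, `lwot`, or `NA` while still on the board).
#' @export
patient_ledger <- function(x) {
  state <- if (inherits(x, "ed_shift")) x$final_state else x
  n <- state$n_patients
  ids <- seq_len(n)
  plan_chr <- vapply(state$plans[ids], function(p) {
    if (!length(p)) "" else paste(.STATIONS[p], collapse = "+")
  }, character(1L))
  data.frame(id = ids,
             plan = plan_chr,
             entry_round = state$entry_round[ids],
             exit_round = state$exit_round[ids],
             exit_kind = .EXIT_KINDS[state$exit_kind[ids]],
             stringsAsFactors = FALSE)
}

# total patients currently on the board
board_wip <- function(state) sum(lengths(state$queues))

# conservation identity: initial + arrivals = exits + on-board
conservation_ok <- function(state) {
  exits <- sum(state$counts[c("discharges", "referrals", "lwot")])
  state$initial_patients + state$counts[["arrivals"]] ==
    exits + board_wip(state)
}
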