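# Config files, score sheets, summary tables and run manifests.

.SIM_KEYS <- c("strategy", "n_rounds", "initial_patients", "initial_allocation",
               "path_probs", "min_batch", "refer_gp", "ma_dice", "allocation",
               "bm_tie_break", "random_split", "initial_plans",
               "n_runs", "master_seed", "out_dir")

parse_dice <- function(x) {
  if (inherits(x, "dice_spec")) return(x)
  key <- tolower(as.character(x))
  switch(key,
    d6 = , standard_d6 = dice_d6(),
    four_to_six = , "4-6" = , "4to6" = dice_four_to_six(),
    "2d6" = , "2xd6" = , two_d6 = dice_sum(dice_d6(), dice_d6()),
    stop(sprintf("unknown dice specification '%s' (use d6, four_to_six or 2d6)", x),
         call. = FALSE))
}

#' Full simulation configuration
#'
#' An [shift_config()] extended with the Monte Carlo settings. The defaults
#' reproduce the standard mode of the published analysis: 10 rounds,
#' 28 initial patients, 10,000 runs.
#'
#' @param strategy Strategy id, `"I"`..`"VI"`.
#' @param n_runs Monte Carlo runs.
#' @param master_seed Master seed for the run-seed derivation.
#' @param out_dir Optional output directory recorded for writers.
#' @param ... Further arguments to [shift_config()] (`ma_dice` may also be
#'   the string `"d6"`, `"four_to_six"` or `"2d6"`).
#' @return Object of class `ed_config` with `n_runs`, `master_seed`,
#'   `out_dir` fields.
#' @export
sim_config <- function(strategy = "I", n_runs = 10000L, master_seed = 1L,
                       out_dir = NULL, ...) {
  dots <- list(...)
  if (!is.null(dots$ma_dice)) dots$ma_dice <- parse_dice(dots$ma_dice)
  cfg <- do.call(shift_config, c(list(strategy = strategy), dots))
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L)
    stop("n_runs must be a positive integer", call. = FALSE)
  cfg$n_runs <- n_runs
  cfg$master_seed <- as.integer(master_seed)
  cfg$out_dir <- out_dir
  cfg
}

#' Load a simulation configuration from YAML and/or overrides
#'
#' Reads a flat YAML file of [sim_config()] keys, applies any overrides
#' given as named arguments (CLI-flag equivalents), validates the result
#' jointly and echoes the resolved configuration via `message()` for
#' auditability. Unknown keys are an error naming the offending key.
#'
#' @param path Optional path to a YAML config file.
#' @param ... Named overrides of config keys.
#' @param quiet Suppress the config echo.
#' @return An `ed_config` from [sim_config()].
#' @examples
#' cfg <- load_config(strategy = "IV", quiet = TRUE)
#' c(cfg$min_batch, cfg$refer_gp)  # 1, TRUE
#' @export
load_config <- function(path = NULL, ..., quiet = FALSE) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), .SIM_KEYS)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(vals$initial_allocation))
    vals$initial_allocation <- unlist(vals$initial_allocation)
  if (!is.null(vals$path_probs)) vals$path_probs <- unlist(vals$path_probs)
  cfg <- do.call(sim_config, vals)
  if (!quiet) {
    echo <- utils::capture.output(print(cfg))
    message(paste(echo, collapse = "\n"))
  }
  cfg
}

#' Write and re-read a per-round score sheet
#'
#' The score sheet mirrors the game's paper sheets: one CSV row per round
#' with walk-ins, per-station processed counts, referrals, discharges,
#' LWOT, end-of-round WIP, token and capacity snapshots, plus a totals row.
#' `read_score_sheet()` reproduces the round records exactly.
#'
#' @param result An `ed_shift` from [play_shift()].
#' @param path Output CSV path.
#' @return `write_score_sheet()` the path, invisibly; `read_score_sheet()`
#'   the round-record matrix.
#' @export
write_score_sheet <- function(result, path) {
  stopifnot(inherits(result, "ed_shift"))
  df <- as.data.frame(result$rounds)
  sum_cols <- c("walk_ins", "registration", "triage", "referrals", "ma_treat",
                "discharges", "suture", "imaging", "lab", "medication", "lwot")
  totals <- df[1L, ]
  totals[] <- NA
  totals[sum_cols] <- colSums(df[sum_cols])
  totals$round <- NA
  totals$wip_after <- if (nrow(df)) df$wip_after[nrow(df)] else NA
  out <- rbind(cbind(row = as.character(df$round), df[-1L]),
               cbind(row = "total", totals[-1L]))
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, na = ""),
    error = function(e) stop(sprintf("failed to write score sheet to %s: %s",
                                     path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' @rdname write_score_sheet
#' @export
read_score_sheet <- function(path) {
  if (!file.exists(path))
    stop(sprintf("score sheet not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  rounds <- df[df$row != "total", , drop = FALSE]
  m <- cbind(round = as.numeric(rounds$row),
             as.matrix(rounds[setdiff(names(rounds), "row")]))
  rownames(m) <- NULL
  m
}

#' Write the strategy summary table
#'
#' Renders [strategy_table()] to CSV with numbers rounded to one decimal
#' for display; the full-precision table goes to a sibling file with
#' suffix `_full`.
#'
#' @param summaries List of [mc_summary()] objects (or a ready-made
#'   [strategy_table()] data frame).
#' @param path Output CSV path.
#' @return Invisibly, `c(display = path, full = <sibling path>)`.
#' @export
write_summary <- function(summaries, path) {
  tab <- if (is.data.frame(summaries)) summaries else strategy_table(summaries)
  full_path <- sub("(\\.[^.]+)?$", "_full\\1", path)
  disp <- tab
  num <- vapply(disp, is.numeric, logical(1L))
  disp[num] <- lapply(disp[num], round, digits = 1L)
  tryCatch({
    utils::write.csv(disp, path, row.names = FALSE)
    utils::write.csv(tab, full_path, row.names = FALSE)
  }, error = function(e) stop(sprintf("failed to write summary to %s: %s",
                                      path, conditionMessage(e)), call. = FALSE))
  invisible(c(display = path, full = full_path))
}

#' Write a JSON run manifest
#'
#' Records the fully resolved configuration, seed and package version so a
#' run can be reproduced byte for byte.
#'
#' @param cfg An `ed_config`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(cfg, path) {
  stopifnot(inherits(cfg, "ed_config"))
  manifest <- list(
    package = "edgame",
    version = as.character(utils::packageVersion("edgame")),
    strategy = cfg$strategy,
    n_rounds = cfg$n_rounds,
    initial_patients = cfg$initial_patients,
    initial_allocation = as.list(cfg$initial_allocation),
    path_probs = cfg$path_probs,
    min_batch = cfg$min_batch,
    refer_gp = cfg$refer_gp,
    ma_dice = dice_label(cfg$ma_dice),
    allocation = cfg$allocation,
    bm_tie_break = cfg$bm_tie_break,
    random_split = cfg$random_split,
    n_runs = cfg$n_runs,
    master_seed = cfg$master_seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dice script from CSV
#'
#' The CSV has columns `round`, `station`, `face1` (and `face2`, ... for
#' multi-die areas); see [dice_script()].
#'
#' @param path CSV path.
#' @return A `dice_script` object.
#' @export
read_dice_script <- function(path) {
  if (!file.exists(path))
    stop(sprintf("dice script not found: %s", path), call. = FALSE)
  dice_script(utils::read.csv(path, stringsAsFactors = FALSE))
}
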