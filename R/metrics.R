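# Per-shift measures and cross-run aggregation.

#' Performance measures of one shift
#'
#' Extracts the shift's primary measurements: throughput (discharges, GP
#' referrals and their sum), LWOT count, arrivals, end-of-shift WIP, the
#' time-averaged WIP (mean of end-of-round WIP over the rounds), per-round
#' rates, and per-patient tracked length-of-stay means (rounds from entry
#' to exit; pre-seeded patients enter at round 0). Rates of a zero-round
#' shift are defined as 0.
#'
#' @param result An `ed_shift` from [play_shift()].
#' @return Named numeric vector: `discharges`, `referrals`,
#'   `discharges_incl_referrals`, `lwot`, `arrivals`, `end_wip`,
#'   `time_avg_wip`, `discharges_per_round`, `discharges_incl_referrals_per_round`,
#'   `total_output_per_round`, `tracked_discharge_los`, `tracked_total_los`
#'   (tracked LOS entries are `NA` when no patient of that kind exited).
#' @export
shift_measures <- function(result) {
  stopifnot(inherits(result, "ed_shift"))
  t <- result$totals
  n_rounds <- result$config$n_rounds
  disch <- t[["discharges"]]; ref <- t[["referrals"]]; lwot <- t[["lwot"]]
  di <- disch + ref
  end_wip <- board_wip(result$final_state)
  time_avg_wip <- if (n_rounds > 0L) mean(result$wip_trace) else end_wip
  rate <- function(x) if (n_rounds > 0L) x / n_rounds else 0

  st <- result$final_state
  ids <- seq_len(st$n_patients)
  kind <- st$exit_kind[ids]
  stay <- st$exit_round[ids] - st$entry_round[ids]
  proper <- !is.na(kind) & kind != 3L
  gone <- !is.na(kind)
  c(discharges = disch,
    referrals = ref,
    discharges_incl_referrals = di,
    lwot = lwot,
    arrivals = t[["arrivals"]],
    end_wip = end_wip,
    time_avg_wip = time_avg_wip,
    discharges_per_round = rate(disch),
    discharges_incl_referrals_per_round = rate(di),
    total_output_per_round = rate(di + lwot),
    tracked_discharge_los = if (any(proper)) mean(stay[proper]) else NA_real_,
    tracked_total_los = if (any(gone)) mean(stay[gone]) else NA_real_)
}

#' Length of stay by Little's Law
#'
#' Little's Law relates time-averaged work in progress, output rate and
#' time in system: `LOS = WIP / output_rate`. Discharge LOS uses proper
#' exits (discharges plus GP referrals) per round as the rate; total LOS
#' additionally counts LWOT exits. Returns `NA` (LOS undefined) when the
#' output rate is not positive, except that zero WIP with positive output
#' is a legitimate zero.
#'
#' @param avg_wip Time-averaged number of patients in the ED.
#' @param output_per_round Output rate, patients per round.
#' @return Length of stay in rounds (48 minutes each).
#' @examples
#' littles_law_los(28.5, 3.41) # ~ 8.4 rounds
#' @export
littles_law_los <- function(avg_wip, output_per_round) {
  out <- avg_wip / output_per_round
  out[!is.finite(out) | output_per_round <= 0] <- NA_real_
  out
}

#' Aggregate Monte Carlo runs for one strategy
#'
#' Computes, per measure, the mean, median, variance and sample (n-1)
#' standard deviation across runs, and for total proper discharges
#' (discharges plus referrals) two 95%-level interval estimates: the normal
#' approximation `mean +/- z * sd` (the reported default) and the empirical
#' 2.5/97.5 percentiles. Strategy-level length of stay is derived by
#' Little's Law from the mean time-averaged WIP and the mean per-round
#' output rates.
#'
#' @param measures Per-run measures from [mc_measures()] (or a data frame
#'   of [shift_measures()] rows).
#' @param conf Confidence level for the interval bounds (default 0.95).
#' @param strategy Strategy label; defaults to the attribute carried by
#'   `measures`.
#' @return Object of class `ed_mc_summary`: `stats` (per-measure summary
#'   table), `discharge_bounds` (normal and empirical), `mean_wip`,
#'   `mean_lwot`, `discharge_los`, `total_los`, tracked-LOS means, `n_runs`.
#' @export
mc_summary <- function(measures, conf = 0.95, strategy = NULL) {
  measures <- as.data.frame(measures)
  if (!nrow(measures))
    stop("measures must contain at least one run", call. = FALSE)
  if (is.null(strategy)) strategy <- attr(measures, "strategy")
  n_rounds <- attr(measures, "n_rounds")

  num <- measures[vapply(measures, is.numeric, logical(1L))]
  stats_tab <- data.frame(
    measure = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1L)),
    median = vapply(num, function(x) stats::median(x, na.rm = TRUE), numeric(1L)),
    var = vapply(num, function(x) stats::var(x, na.rm = TRUE), numeric(1L)),
    sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  one_run <- nrow(measures) == 1L
  if (one_run) stats_tab$var <- stats_tab$sd <- 0
  stats_tab$pct_sd <- ifelse(stats_tab$mean != 0, stats_tab$sd / stats_tab$mean, NA_real_)

  di <- measures$discharges_incl_referrals
  mu <- mean(di); sd_di <- if (one_run) 0 else stats::sd(di)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  normal_bounds <- c(lower = mu - z * sd_di, upper = mu + z * sd_di)
  emp_bounds <- stats::quantile(di, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                names = FALSE)
  mean_wip <- mean(measures$time_avg_wip)
  mean_di_rate <- mean(measures$discharges_incl_referrals_per_round)
  mean_out_rate <- mean(measures$total_output_per_round)

  structure(list(
    strategy = strategy,
    n_runs = nrow(measures),
    n_rounds = n_rounds,
    conf = conf,
    stats = stats_tab,
    discharge_mean = mu,
    discharge_sd = sd_di,
    discharge_bounds = normal_bounds,
    discharge_bounds_empirical = c(lower = emp_bounds[1L], upper = emp_bounds[2L]),
    mean_wip = mean_wip,
    mean_lwot = mean(measures$lwot),
    discharge_los = littles_law_los(mean_wip, mean_di_rate),
    total_los = littles_law_los(mean_wip, mean_out_rate),
    tracked_discharge_los = mean(measures$tracked_discharge_los, na.rm = TRUE),
    tracked_total_los = mean(measures$tracked_total_los, na.rm = TRUE)),
    class = "ed_mc_summary")
}

#' @export
print.ed_mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary%s: %d run(s)\n",
              if (!is.null(x$strategy)) paste0(" (strategy ", x$strategy, ")") else "",
              x$n_runs))
  cat(sprintf("  discharges incl. referrals: mean %.1f, sd %.2f, %d%% bounds [%.1f, %.1f]\n",
              x$discharge_mean, x$discharge_sd, round(100 * x$conf),
              x$discharge_bounds[["lower"]], x$discharge_bounds[["upper"]]))
  cat(sprintf("  mean WIP %.1f | mean LWOT %.1f | discharge LOS %.1f | total LOS %.1f rounds\n",
              x$mean_wip, x$mean_lwot, x$discharge_los, x$total_los))
  invisible(x)
}

.STRATEGY_META <- data.frame(
  strategy = c("I", "II", "III", "IV", "V", "VI"),
  shift = c(1L, 1L, 1L, 2L, 3L, 1L),
  type = c("Trad", "Trad", "Trad", "TOC", "TOC", "Trad"),
  assessment = c("Random", "50%", "Discharge", "BM", "BM", "50%"),
  stringsAsFactors = FALSE)

#' Summary table across strategies
#'
#' One row per strategy with the columns of the published comparison:
#' Strategy, Shift, Type, Assessment Strategy, Discharges (Mean), Std Dev,
#' %Std Dev, 95% Percentile (Min), 95% Percentile (Max), WIP (Mean),
#' LWOT (Mean), Total LOS (Mean), Discharge LOS (Mean).
#'
#' @param summaries List of [mc_summary()] objects.
#' @return `data.frame` at full precision (use [write_summary()] for the
#'   one-decimal display rendering).
#' @export
strategy_table <- function(summaries) {
  if (inherits(summaries, "ed_mc_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1L), "ed_mc_summary")))
  rows <- lapply(summaries, function(s) {
    st <- s$strategy %||% NA_character_
    meta <- .STRATEGY_META[match(st, .STRATEGY_META$strategy), ]
    data.frame(
      `Strategy` = st,
      `Shift` = meta$shift,
      `Type` = meta$type,
      `Assessment Strategy` = meta$assessment,
      `Discharges (Mean)` = s$discharge_mean,
      `Std Dev` = s$discharge_sd,
      `%Std Dev` = if (s$discharge_mean != 0) s$discharge_sd / s$discharge_mean else NA_real_,
      `95% Percentile (Min)` = s$discharge_bounds[["lower"]],
      `95% Percentile (Max)` = s$discharge_bounds[["upper"]],
      `WIP (Mean)` = s$mean_wip,
      `LWOT (Mean)` = s$mean_lwot,
      `Total LOS (Mean)` = s$total_los,
      `Discharge LOS (Mean)` = s$discharge_los,
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confidence-interval overlap between strategies
#'
#' Pairwise comparison of total proper discharges: do the 95%-level
#' intervals of two strategies overlap, and what is the mean difference?
#' Non-overlap is the improvement criterion used for the strategy ranking.
#'
#' @param summaries List of at least two [mc_summary()] objects.
#' @param empirical Use the empirical percentile bounds instead of the
#'   normal-approximation bounds.
#' @return Object of class `ed_comparison` with logical `overlap` and
#'   numeric `mean_diff` matrices (row minus column) plus the interval
#'   table; has print and plot methods.
#' @export
compare_strategies <- function(summaries, empirical = FALSE) {
  stopifnot(length(summaries) >= 2L,
            all(vapply(summaries, inherits, logical(1L), "ed_mc_summary")))
  labs <- vapply(seq_along(summaries), function(i)
    summaries[[i]]$strategy %||% as.character(i), character(1L))
  bounds <- t(vapply(summaries, function(s)
    if (empirical) s$discharge_bounds_empirical else s$discharge_bounds,
    numeric(2L)))
  means <- vapply(summaries, function(s) s$discharge_mean, numeric(1L))
  k <- length(summaries)
  overlap <- matrix(NA, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k))
    overlap[i, j] <- bounds[i, 1L] <= bounds[j, 2L] && bounds[j, 1L] <= bounds[i, 2L]
  mean_diff <- outer(means, means, `-`)
  dimnames(mean_diff) <- list(labs, labs)
  structure(list(strategies = labs, means = means,
                 intervals = data.frame(strategy = labs, mean = means,
                                        lower = bounds[, 1L], upper = bounds[, 2L],
                                        row.names = NULL),
                 overlap = overlap, mean_diff = mean_diff,
                 empirical = empirical),
            class = "ed_comparison")
}

#' @export
print.ed_comparison <- function(x, digits = 1, ...) {
  cat("Strategy comparison: discharges incl. referrals,",
      if (x$empirical) "empirical" else "normal-approximation",
      "95% bounds\n")
  print(round(x$intervals[-1L] * 1, digits + 1),
        row.names = x$intervals$strategy)
  cat("interval overlap:\n")
  print(x$overlap)
  invisible(x)
}

#' @param x An `ed_comparison` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @describeIn compare_strategies Interval chart of mean discharges with
#'   their 95%-level bounds per strategy.
#' @export
plot.ed_comparison <- function(x, ...) {
  k <- nrow(x$intervals)
  ylim <- range(x$intervals$lower, x$intervals$upper)
  graphics::plot(seq_len(k), x$intervals$mean, xaxt = "n",
                 xlab = "Strategy", ylab = "Discharges incl. referrals",
                 ylim = ylim, pch = 19,
                 main = "Mean discharges with 95% bounds", ...)
  graphics::axis(1, at = seq_len(k), labels = x$intervals$strategy)
  graphics::arrows(seq_len(k), x$intervals$lower, seq_len(k), x$intervals$upper,
                   angle = 90, code = 3, length = 0.06)
  invisible(x)
}
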