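# Rule logic modulating raw dice capacity: the minimum-batch gate with
# delayed-care tokens and LWOT emission, triage GP referral, buffer-zone
# classification, and the medical-assessment capacity allocation rules.

.ZONES <- c("green", "yellow", "red", "black")

# integer zone code (1..4); vectorised, no validation (hot path)
zone_int <- function(q) 1L + (q > 6L) + (q > 9L) + (q > 12L)

#' Buffer-zone classification of a queue
#'
#' Buffer management grades how far a queue has penetrated its buffer:
#' six or fewer waiting patients is green (no action), 7-9 yellow (plan),
#' 10-12 red (act) and 13 or more black (the problem has materialised).
#' Six is the largest number the assessment resource can process in one
#' round with a single die, hence the green boundary.
#'
#' @param queue_len Non-negative integer queue length(s).
#' @return Ordered factor with levels green < yellow < red < black.
#' @examples
#' buffer_zone(c(0, 6, 7, 9, 10, 12, 13))
#' @export
buffer_zone <- function(queue_len) {
  q <- as.integer(queue_len)
  if (anyNA(q) || any(q < 0L))
    stop("queue length must be a non-negative integer", call. = FALSE)
  factor(.ZONES[zone_int(q)], levels = .ZONES, ordered = TRUE)
}

#' Minimum-batch gate with delayed-care tokens
#'
#' Under traditional management the four specialized resources may only
#' roll their die when at least `min_batch` (default 3) patients wait.
#' A round in which a non-empty queue stays blocked earns the resource one
#' delayed-care token; at two tokens, each further blocked round with a
#' non-empty queue makes one patient leave without treatment (LWOT).
#' Tokens are cleared whenever the die may be rolled or the queue is empty.
#' `min_batch = 1` disables the policy entirely (the TOC shifts).
#'
#' @param queue_len Patients waiting at the specialized resource.
#' @param tokens Current delayed-care tokens (0, 1 or 2).
#' @param min_batch Minimum queue length required to roll.
#' @return List with `may_roll` (logical), `tokens_after` (0-2) and
#'   `lwot_emitted` (0 or 1: one patient leaves the queue untreated).
#' @examples
#' batching_gate(2, 0, 3) # blocked, gains a token
#' batching_gate(2, 2, 3) # blocked, one LWOT
#' batching_gate(3, 2, 3) # may roll, tokens cleared
#' @export
batching_gate <- function(queue_len, tokens, min_batch = 3L) {
  queue_len <- as.integer(queue_len)
  tokens <- as.integer(tokens)
  min_batch <- as.integer(min_batch)
  if (length(tokens) != 1L || is.na(tokens) || tokens < 0L || tokens > 2L)
    stop("delayed-care tokens must be 0, 1 or 2", call. = FALSE)
  if (length(min_batch) != 1L || is.na(min_batch) || min_batch < 1L)
    stop("min_batch must be a positive integer", call. = FALSE)
  if (length(queue_len) != 1L || is.na(queue_len) || queue_len < 0L)
    stop("queue length must be a non-negative integer", call. = FALSE)

  if (queue_len >= min_batch) {
    list(may_roll = TRUE, tokens_after = 0L, lwot_emitted = 0L)
  } else if (queue_len == 0L) {
    list(may_roll = FALSE, tokens_after = 0L, lwot_emitted = 0L)
  } else if (tokens < 2L) {
    list(may_roll = FALSE, tokens_after = tokens + 1L, lwot_emitted = 0L)
  } else {
    list(may_roll = FALSE, tokens_after = 2L, lwot_emitted = 1L)
  }
}

#' Triage service with optional GP referral
#'
#' Triage serves `min(capacity, queue_len)` patients. When referral is
#' enabled (the TOC shifts), triage first refers exactly one patient to an
#' external general practitioner whenever its die shows 2 or more and at
#' least one patient was served; the remainder go on to medical assessment.
#' A referral is a proper exit, distinct from LWOT.
#'
#' @param capacity Triage die value for the round.
#' @param queue_len Patients waiting at triage.
#' @param refer_enabled Logical: is the refer-to-GP rule active?
#' @return Named integer vector `c(referred, to_assessment)`.
#' @examples
#' triage_split(5, 10, TRUE)  # c(referred = 1, to_assessment = 4)
#' triage_split(1, 10, TRUE)  # a roll of 1 refers nobody
#' @export
triage_split <- function(capacity, queue_len, refer_enabled = FALSE) {
  capacity <- as.integer(capacity)
  queue_len <- as.integer(queue_len)
  served <- min(capacity, queue_len)
  if (isTRUE(refer_enabled) && capacity >= 2L && served >= 1L) {
    c(referred = 1L, to_assessment = served - 1L)
  } else {
    c(referred = 0L, to_assessment = served)
  }
}

.ALLOC_RULES <- c("random", "fifty_fifty", "discharge_priority", "buffer_management")

#' Split medical-assessment capacity between its two queues
#'
#' Medical assessment both treats newly assessed patients (sending them to
#' their specialized resource) and discharges returning ones. Each round its
#' die value is split between the treat queue and the discharge-wait queue
#' according to one of four rules:
#'
#' * `random`: each capacity point goes to either queue with probability
#'   1/2 (points aimed at an exhausted queue spill to the other). A
#'   `random_split = "uniform"` variant instead draws the treat share
#'   uniformly on `0..capacity`.
#' * `fifty_fifty`: half the points to each side, the odd point to treat;
#'   shortfall in one queue spills to the other.
#' * `discharge_priority`: discharge first, remainder to treat.
#' * `buffer_management`: serve the queue in the worse buffer zone point by
#'   point, re-evaluating zones after every point; on equal zones serve the
#'   tie-break queue first (`treat` by default).
#'
#' All rules are work-conserving: capacity is left unused only when both
#' queues are exhausted, and no queue is ever over-served.
#'
#' @param capacity Assessment die value (>= 0).
#' @param treat_len,disch_len Start-of-round lengths of the treat and
#'   discharge-wait queues.
#' @param rule Allocation rule, see above. Strategy ids map to rules via
#'   [strategy_defaults()].
#' @param tie_break Queue served first when buffer zones are equal
#'   (`buffer_management` only).
#' @param random_split Point distribution for the `random` rule.
#' @return Named integer vector `c(treat, discharge)`.
#' @examples
#' allocate_assessment(5, 10, 10, "fifty_fifty")        # c(3, 2)
#' allocate_assessment(5, 10, 3, "discharge_priority")  # c(2, 3)
#' @export
allocate_assessment <- function(capacity, treat_len, disch_len,
                                rule = .ALLOC_RULES,
                                tie_break = c("treat", "discharge"),
                                random_split = c("bernoulli", "uniform")) {
  rule <- match.arg(rule)
  tie_break <- match.arg(tie_break)
  random_split <- match.arg(random_split)
  cp <- as.integer(capacity)
  tl <- as.integer(treat_len)
  dl <- as.integer(disch_len)
  if (is.na(cp) || cp < 0L || is.na(tl) || tl < 0L || is.na(dl) || dl < 0L)
    stop("capacity and queue lengths must be non-negative integers", call. = FALSE)

  if (rule == "discharge_priority") {
    nd <- min(cp, dl)
    nt <- min(cp - nd, tl)
  } else if (rule == "buffer_management") {
    nt <- 0L; nd <- 0L
    t <- tl; d <- dl; rem <- cp
    while (rem > 0L && (t > 0L || d > 0L)) {
      take_treat <- if (t > 0L && d > 0L) {
        zt <- zone_int(t); zd <- zone_int(d)
        if (tie_break == "treat") zt >= zd else zt > zd
      } else t > 0L
      if (take_treat) { nt <- nt + 1L; t <- t - 1L }
      else            { nd <- nd + 1L; d <- d - 1L }
      rem <- rem - 1L
    }
  } else {
    t0 <- if (rule == "random") {
      if (random_split == "bernoulli") stats::rbinom(1L, cp, 0.5)
      else sample.int(cp + 1L, 1L) - 1L
    } else {
      as.integer(ceiling(cp / 2))    # odd point to treat
    }
    nt <- min(t0, tl)
    nd <- min(cp - t0, dl)
    rem <- cp - nt - nd
    add <- min(rem, tl - nt); nt <- nt + add; rem <- rem - add
    nd <- nd + min(rem, dl - nd)
  }
  c(treat = as.integer(nt), discharge = as.integer(nd))
}

#' Parameter bundle of the six assessment strategies
#'
#' Strategies I-III are the traditional shift-1 variants (minimum batch 3,
#' no GP referral, a single D6 at medical assessment) differing only in how
#' assessment capacity is split. Strategy IV is the TOC shift-2 rule set
#' (batch of one, GP referral, the 4-6 die, buffer management); V elevates
#' the constraint with two D6 while keeping the TOC rules; VI keeps the
#' traditional rules but adds the second die (50/50 split).
#'
#' @param strategy One of `"I"`..`"VI"`.
#' @return List with `min_batch`, `refer_gp`, `ma_dice`, `allocation`.
#' @export
strategy_defaults <- function(strategy) {
  strategy <- as.character(strategy)
  switch(strategy,
    I   = list(min_batch = 3L, refer_gp = FALSE, ma_dice = dice_d6(),
               allocation = "random"),
    II  = list(min_batch = 3L, refer_gp = FALSE, ma_dice = dice_d6(),
               allocation = "fifty_fifty"),
    III = list(min_batch = 3L, refer_gp = FALSE, ma_dice = dice_d6(),
               allocation = "discharge_priority"),
    IV  = list(min_batch = 1L, refer_gp = TRUE, ma_dice = dice_four_to_six(),
               allocation = "buffer_management"),
    V   = list(min_batch = 1L, refer_gp = TRUE,
               ma_dice = dice_sum(dice_d6(), dice_d6()),
               allocation = "buffer_management"),
    VI  = list(min_batch = 3L, refer_gp = FALSE,
               ma_dice = dice_sum(dice_d6(), dice_d6()),
               allocation = "fifty_fifty"),
    stop(sprintf("unknown strategy '%s' (use I, II, III, IV, V or VI)", strategy),
         call. = FALSE)
  )
}
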