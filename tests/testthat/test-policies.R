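test_that("the minimum-batch gate follows the token and LWOT rules", {
  g <- batching_gate(2, 0, 3)
  expect_false(g$may_roll); expect_identical(g$tokens_after, 1L)
  expect_identical(g$lwot_emitted, 0L)

  g <- batching_gate(2, 2, 3)
  expect_false(g$may_roll); expect_identical(g$tokens_after, 2L)
  expect_identical(g$lwot_emitted, 1L)

  g <- batching_gate(3, 2, 3)
  expect_true(g$may_roll); expect_identical(g$tokens_after, 0L)
  expect_identical(g$lwot_emitted, 0L)

  g <- batching_gate(0, 1, 3)
  expect_false(g$may_roll); expect_identical(g$tokens_after, 0L)
  expect_identical(g$lwot_emitted, 0L)

  g <- batching_gate(1, 2, 1)   # batch of one disables the policy
  expect_true(g$may_roll); expect_identical(g$tokens_after, 0L)
  expect_identical(g$lwot_emitted, 0L)

  expect_error(batching_gate(2, 3, 3), "tokens")
  expect_error(batching_gate(-1, 0, 3), "non-negative")
  expect_error(batching_gate(2, 0, 0), "positive")
})

test_that("a batch of one never accrues tokens nor emits LWOT", {
  for (q in 0:15) for (tok in 0:2) {
    g <- batching_gate(q, tok, 1)
    expect_identical(g$lwot_emitted, 0L)
    expect_identical(g$tokens_after, 0L)
  }
})

test_that("triage referral takes one patient on a die of 2+", {
  expect_identical(triage_split(5, 10, TRUE),
                   c(referred = 1L, to_assessment = 4L))
  expect_identical(triage_split(1, 10, TRUE),
                   c(referred = 0L, to_assessment = 1L))
  expect_identical(triage_split(4, 0, TRUE),
                   c(referred = 0L, to_assessment = 0L))
  expect_identical(triage_split(5, 10, FALSE),
                   c(referred = 0L, to_assessment = 5L))
  # referral has first claim on a single served patient
  expect_identical(triage_split(2, 1, TRUE),
                   c(referred = 1L, to_assessment = 0L))
})

test_that("triage conserves served patients for all inputs", {
  for (cap in 1:6) for (q in 0:8) for (ref in c(TRUE, FALSE)) {
    s <- triage_split(cap, q, ref)
    expect_identical(sum(s), min(cap, q))
  }
})

test_that("buffer zones switch at 6/7, 9/10 and 12/13 and are monotone", {
  z <- buffer_zone(c(0, 6, 7, 9, 10, 12, 13, 40))
  expect_equal(as.character(z),
               c("green", "green", "yellow", "yellow", "red", "red",
                 "black", "black"))
  zz <- buffer_zone(0:30)
  expect_true(all(diff(as.integer(zz)) >= 0))
  expect_error(buffer_zone(-1), "non-negative")
})

test_that("assessment allocation reproduces the documented splits", {
  expect_identical(allocate_assessment(5, 10, 10, "fifty_fifty"),
                   c(treat = 3L, discharge = 2L))
  expect_identical(allocate_assessment(6, 2, 10, "fifty_fifty"),
                   c(treat = 2L, discharge = 4L))
  expect_identical(allocate_assessment(5, 10, 3, "discharge_priority"),
                   c(treat = 2L, discharge = 3L))
  expect_identical(allocate_assessment(4, 0, 0, "random"),
                   c(treat = 0L, discharge = 0L))
  # buffer management: treat queue in the black zone drains first
  expect_identical(allocate_assessment(6, 13, 5, "buffer_management"),
                   c(treat = 6L, discharge = 0L))
  # once zones equalise, the tie-break queue is served first
  expect_identical(allocate_assessment(8, 13, 5, "buffer_management"),
                   c(treat = 8L, discharge = 0L))
  expect_identical(allocate_assessment(8, 13, 5, "buffer_management",
                                       tie_break = "discharge"),
                   c(treat = 7L, discharge = 1L))
  expect_error(allocate_assessment(5, 3, 3, "nonsense"))
})

test_that("all allocation rules are work-conserving and never over-serve", {
  set.seed(7)
  grid <- expand.grid(cap = 0:12, t = 0:15, d = c(0:6, 10L, 15L))
  for (rule in c("random", "fifty_fifty", "discharge_priority",
                 "buffer_management")) {
    ok <- vapply(seq_len(nrow(grid)), function(i) {
      a <- allocate_assessment(grid$cap[i], grid$t[i], grid$d[i], rule)
      a[["treat"]] <= grid$t[i] && a[["discharge"]] <= grid$d[i] &&
        sum(a) == max_served_oracle(grid$cap[i], grid$t[i], grid$d[i])
    }, logical(1L))
    expect_true(all(ok), label = paste("work conservation under", rule))
  }
})

test_that("discharge priority maximises discharges over all rules", {
  set.seed(11)
  grid <- expand.grid(cap = 0:12, t = 0:15, d = 0:15)
  best <- vapply(seq_len(nrow(grid)), function(i)
    allocate_assessment(grid$cap[i], grid$t[i], grid$d[i],
                        "discharge_priority")[["discharge"]], integer(1L))
  for (rule in c("random", "fifty_fifty", "buffer_management")) {
    other <- vapply(seq_len(nrow(grid)), function(i)
      allocate_assessment(grid$cap[i], grid$t[i], grid$d[i], rule)[["discharge"]],
      integer(1L))
    expect_true(all(best >= other),
                label = paste("discharge priority dominates", rule))
  }
})

test_that("strategy bindings match the shift structure of the game", {
  s4 <- strategy_defaults("IV")
  expect_identical(s4$min_batch, 1L)
  expect_true(s4$refer_gp)
  expect_identical(s4$ma_dice$kind, "four_to_six")
  expect_identical(s4$allocation, "buffer_management")

  s6 <- strategy_defaults("VI")
  expect_identical(s6$min_batch, 3L)
  expect_false(s6$refer_gp)
  expect_identical(s6$ma_dice$kind, "sum")
  expect_identical(s6$allocation, "fifty_fifty")

  expect_error(strategy_defaults("VII"), "unknown strategy")
})
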