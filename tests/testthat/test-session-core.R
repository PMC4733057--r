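test_that("round payoff follows l*b - g*c and rejects bad input", {
  expect_identical(round_payoff(g = 2, l = 4, b = 2, c_ = 1), 6)
  expect_identical(round_payoff(0, 0), 0)
  expect_identical(round_payoff(5, 0), -5)
  expect_identical(round_payoff(c(2, 0), c(4, 0)), c(6, 0))
  expect_error(round_payoff(-1, 0), "non-negative")
  expect_error(round_payoff(1, 1, b = 0), "positive")
})

test_that("token accumulation adds round payoffs to the endowment", {
  expect_equal(accumulate_tokens(1000, 6), 1006)
  expect_equal(accumulate_tokens(1000), 1000)
  expect_equal(accumulate_tokens(1000, c(6, -3, 2)), 1005)
})

test_that("behavioural type is (g-l)/(g+l), undefined for isolated nodes", {
  expect_equal(behavioural_type(3, 1), 0.5)
  for (k in c(1, 4, 9)) expect_equal(behavioural_type(k, k), 0)
  expect_true(is.na(behavioural_type(0, 0)))
  expect_equal(behavioural_type(c(3, 0), c(1, 0)), c(0.5, NA))
  expect_error(behavioural_type(-1, 2), "non-negative")
})

test_that("type classification cuts at +/- 1/3 with closed fair interval", {
  expect_identical(classify_type(0.5), "altruist")
  expect_identical(classify_type(0), "fair")
  expect_identical(classify_type(-1), "egoist")
  expect_identical(classify_type(1 / 3), "fair")
  expect_identical(classify_type(-1 / 3), "fair")
  expect_identical(classify_type(c(1, -0.4, NA)),
                   c("altruist", "egoist", NA))
  expect_error(classify_type(1.2), "\\[-1, 1\\]")
})

test_that("empty update set advances the round unchanged", {
  cfg <- session_config(4)
  st <- initial_round_state(cfg)
  nxt <- validate_and_apply_round(st, NULL, cfg)
  expect_identical(nxt$round_index, 1L)
  expect_identical(nrow(nxt$edges), 0L)
  expect_equal(nxt$cumulative_tokens, rep(1000, 4))
})

test_that("first-round scenario: 2 added links and 4 incoming give g=2, l=4", {
  cfg <- session_config(7)
  st <- initial_round_state(cfg)
  upd <- data.frame(actor = c(1, 1, 4, 5, 6, 7),
                    target = c(2, 3, 1, 1, 1, 1),
                    action = "add")
  nxt <- validate_and_apply_round(st, upd, cfg)
  expect_identical(nxt$g[1], 2L)
  expect_identical(nxt$l[1], 4L)
  expect_equal(nxt$round_payoff[1], 6)
  expect_equal(nxt$cumulative_tokens[1], 1006)
})

test_that("invalid updates are rejected with reasons; strict mode raises", {
  cfg <- session_config(5)
  st <- initial_round_state(cfg)
  st <- validate_and_apply_round(
    st, data.frame(actor = 1, target = 2, action = "add"), cfg)
  upd <- data.frame(
    actor = c(1, 1, 1, 3, 4, 4, 4),
    target = c(2, 3, 2, 3, 5, 3, 2),
    action = c("add", "remove", "remove", "add", "add", "add", "add"))
  # 1->2 add targets an existing recipient; 1->3 remove a non-recipient;
  # 1->2 remove is valid (rejected rows consume no slots); 3->3 is a
  # self-link; actor 4's third submission exceeds the cap of 2.
  nxt <- validate_and_apply_round(st, upd, cfg)
  rej <- attr(nxt, "rejected_updates")
  expect_setequal(rej$reason,
                  c("add targets an existing recipient",
                    "remove targets a non-recipient",
                    "self-link", "update cap exceeded"))
  acc <- attr(nxt, "accepted_updates")
  expect_identical(nrow(acc), 3L)  # 1->2 remove, 4->5 add, 4->3 add
  expect_identical(nrow(nxt$edges), 2L)
  expect_error(
    validate_and_apply_round(st, upd, cfg, strict = TRUE),
    "invalid update")
})

test_that("per-actor cap rejects the third submission only", {
  cfg <- session_config(6)
  st <- initial_round_state(cfg)
  upd <- data.frame(actor = 1, target = c(2, 3, 4), action = "add")
  nxt <- validate_and_apply_round(st, upd, cfg)
  expect_identical(attr(nxt, "accepted_updates")$target, c(2L, 3L))
  expect_identical(attr(nxt, "rejected_updates")$reason, "update cap exceeded")
})

test_that("duplicate submissions of the same update are rejected", {
  cfg <- session_config(4)
  st <- initial_round_state(cfg)
  upd <- data.frame(actor = 1, target = c(2, 2), action = "add")
  nxt <- validate_and_apply_round(st, upd, cfg)
  expect_identical(nrow(attr(nxt, "accepted_updates")), 1L)
  expect_identical(attr(nxt, "rejected_updates")$reason, "duplicate update")
})

test_that("visibility respects the treatment: providers hidden unless reciprocal", {
  cfg <- session_config(5, treatment = "reciprocal")
  st <- initial_round_state(cfg)
  upd <- data.frame(actor = c(1, 2, 3), target = c(2, 1, 1), action = "add")
  st <- validate_and_apply_round(st, upd, cfg)
  # focal 1: recipients {2}, providers {2, 3}; 2 is reciprocal
  ro <- visible_sets(st, 1, "recipient_only", candidate_sample = c(4, 5))
  expect_named(ro, c("recipients", "candidates"))
  expect_identical(ro$recipients, 2L)
  re <- visible_sets(st, 1, "reciprocal", candidate_sample = c(4, 5))
  expect_identical(re$reciprocals, 2L)
  expect_identical(re$providers, 3L)
  expect_identical(re$recipients, integer(0))
  # disjointness
  all_ids <- c(re$recipients, re$candidates, re$providers, re$reciprocals)
  expect_identical(anyDuplicated(all_ids), 0L)
})

test_that("overlapping candidate samples are filtered with a warning", {
  cfg <- session_config(5)
  st <- initial_round_state(cfg)
  st <- validate_and_apply_round(
    st, data.frame(actor = 1, target = 2, action = "add"), cfg)
  expect_warning(v <- visible_sets(st, 1, "recipient_only",
                                   candidate_sample = c(1, 2, 3)),
                 "filtered")
  expect_identical(v$candidates, 3L)
})

test_that("empty network shows only candidates", {
  cfg <- session_config(4)
  st <- initial_round_state(cfg)
  v <- visible_sets(st, 1, "recipient_only", candidate_sample = c(2, 3))
  expect_identical(v$recipients, integer(0))
  expect_identical(v$candidates, c(2L, 3L))
})

test_that("conservation laws hold on every round of simulated sessions", {
  for (seed in 1:3) {
    s <- sim_small(seed = seed)
    b <- s$config$benefit_b; c_ <- s$config$cost_c
    for (st in s$rounds) {
      m <- nrow(st$edges)
      expect_identical(sum(st$g), m)
      expect_identical(sum(st$l), m)
      expect_equal(sum(st$round_payoff), m * (b - c_))
      expect_equal(sum(st$g - st$l), 0L)
    }
    expect_true(validate_session(s))
  }
})

test_that("token audit: cumulative tokens equal endowment plus payoff history", {
  s <- sim_small(treatment = "reciprocal", seed = 7)
  pay <- vapply(s$rounds, function(st) st$round_payoff,
                numeric(s$config$n_participants))
  for (k in seq_along(s$rounds)) {
    expect_equal(s$rounds[[k]]$cumulative_tokens,
                 s$config$endowment + rowSums(pay[, seq_len(k), drop = FALSE]))
  }
})
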