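test_that("event annotation uses the preceding round's displayed state", {
  f <- make_fixture_session()
  ev <- annotate_events(f)
  expect_identical(nrow(ev), nrow(f$events))
  # round-1 additions happen on the empty network: all deltas zero
  r1 <- ev[ev$round == 1, ]
  expect_true(all(r1$delta_g == 0) && all(r1$delta_pi == 0))
  expect_true(all(r1$target_category == "candidate"))
  # round 3: 3 removes 4; state after round 2 has g=(2,2,1,1,1), pi=2l-g
  st2 <- f$rounds[[3]]
  i <- which(ev$round == 3 & ev$actor == 3 & ev$action == "remove")
  expect_identical(ev$target[i], 4L)
  expect_identical(ev$delta_g[i], st2$g[4] - st2$g[3])
  expect_identical(ev$delta_pi[i], st2$round_payoff[4] - st2$round_payoff[3])
  # reciprocator categories: a removal of a mutual partner
  rm6 <- ev[ev$round == 6, ]
  st5 <- f$rounds[[6]]
  for (j in seq_len(nrow(rm6))) {
    mutual <- rm6$actor[j] %in% recipients(st5, rm6$target[j])
    expect_identical(rm6$target_category[j],
                     if (mutual) "reciprocal" else "recipient")
  }
})

test_that("deltas are plain target-minus-actor differences", {
  sp <- make_spread_state()
  cfg <- sp$config
  st2 <- validate_and_apply_round(
    sp$state, data.frame(actor = 5, target = 3, action = "add"), cfg)
  ev <- data.frame(round = c(1, 1, 1, 1, 2),
                   actor = c(2, 3, 3, 1, 5), target = c(1, 1, 4, 4, 3),
                   action = c("add", "add", "add", "add", "add"))
  s <- new_session(cfg,
                   c(list(initial_round_state(cfg)), list(sp$state, st2),
                     replicate(2, st2, simplify = FALSE)), ev)
  # only the annotation of round-2 events is of interest here
  ann <- annotate_events(s)
  i <- which(ann$round == 2)
  # actor 5: g=0, pi=0; target 3: g=2, pi=-2
  expect_identical(ann$delta_g[i], 2L)
  expect_identical(ann$delta_pi[i], -2L)
})

test_that("round filtering drops the first ten rounds, boundary inclusive", {
  ev <- data.frame(round = c(1, 10, 11, 60), actor = 1, target = 2,
                   action = "add", delta_g = 0, delta_pi = 0)
  kept <- filter_rounds(ev)
  expect_identical(kept$round, c(11, 60))
  expect_identical(nrow(filter_rounds(ev[0, ])), 0L)
})

test_that("histogram counts, marginals and means are conserved", {
  ev <- data.frame(delta_g = c(0, 2, -1, -1, 2), delta_pi = c(1, -1, -2, -2, -1))
  h <- build_histogram(ev)
  expect_identical(sum(h$joint$count), 5L)
  expect_identical(sum(h$marginal_g$count), 5L)
  expect_identical(sum(h$marginal_pi$count), 5L)
  expect_equal(h$mean_delta_g, mean(ev$delta_g))
  expect_equal(h$mean_delta_pi, mean(ev$delta_pi))
  # marginals are the row/column sums of the joint table
  for (d in h$marginal_g$delta)
    expect_identical(h$marginal_g$count[h$marginal_g$delta == d],
                     sum(h$joint$count[h$joint$delta_g == d]))
  one <- build_histogram(data.frame(delta_g = -1, delta_pi = -2))
  expect_equal(c(one$mean_delta_g, one$mean_delta_pi), c(-1, -2))
  expect_error(build_histogram(ev[0, ]), "no events")
  # histograms and raw events give identical preference proportions
  expect_identical(preference_proportion(h, "payoff"),
                   preference_proportion(ev, "payoff"))
})

test_that("exact binomial p-values match direct tail summation for n <= 25", {
  for (n in 1:25) for (k in 0:n) {
    expect_equal(exact_binom_p(k, n), binom_tail_oracle(k, n),
                 tolerance = 1e-12, label = sprintf("k=%d, n=%d", k, n))
    expect_equal(exact_binom_p(k, n),
                 stats::binom.test(k, n, 0.5)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("preference proportions handle the documented reference cases", {
  ev <- data.frame(delta_g = 0, delta_pi = c(rep(-1, 7), 1))
  p <- preference_proportion(ev, "payoff")
  expect_equal(p$proportion, 0.875)
  expect_equal(p$p_value, 18 / 256)
  tie <- preference_proportion(
    data.frame(delta_pi = c(rep(-1, 5), rep(1, 5))), "payoff")
  expect_equal(tie$p_value, 1)
  onesided <- preference_proportion(
    data.frame(delta_pi = rep(1, 10)), "payoff")
  expect_equal(onesided$proportion, 0)
  expect_equal(onesided$p_value, 2 / 1024)
  expect_warning(
    z <- preference_proportion(data.frame(delta_pi = c(0, 0)), "payoff"),
    "undefined")
  expect_true(is.na(z$proportion))
  expect_identical(z$n_zero, 2L)
})

test_that("reciprocation split partitions removals by reverse-link presence", {
  s <- sim_small(treatment = "reciprocal", seed = 17)
  ev <- annotate_events(s)
  sp <- split_by_reciprocation(ev, s)
  rem <- ev[ev$action == "remove", ]
  expect_identical(nrow(sp$reciprocator) + nrow(sp$non_reciprocator),
                   nrow(rem))
  expect_identical(intersect(rownames(sp$reciprocator),
                             rownames(sp$non_reciprocator)), character(0))
  # the split agrees with the annotated target category
  expect_true(all(sp$reciprocator$target_category == "reciprocal"))
  expect_true(all(sp$non_reciprocator$target_category == "recipient"))
  ro <- sim_small(seed = 18)
  expect_error(split_by_reciprocation(annotate_events(ro), ro),
               "reciprocal-treatment")
  expect_silent(split_by_reciprocation(annotate_events(ro), ro,
                                       diagnostic = TRUE))
})

test_that("quadrant fractions match brute-force sign counting", {
  set.seed(9)
  ev <- data.frame(delta_g = sample(-3:3, 200, replace = TRUE),
                   delta_pi = sample(-3:3, 200, replace = TRUE))
  q <- quadrant_fractions(ev)
  signed <- ev[ev$delta_g != 0 & ev$delta_pi != 0, ]
  for (sg in c(-1, 1)) for (sp_ in c(-1, 1)) {
    expect_equal(
      q$fractions[if (sg > 0) "pos" else "neg", if (sp_ > 0) "pos" else "neg"],
      mean(sign(signed$delta_g) == sg & sign(signed$delta_pi) == sp_))
  }
  expect_equal(sum(q$fractions), 1)
  expect_identical(q$n_signed + sum(q$zero_counts), 200L)
  allpp <- quadrant_fractions(data.frame(delta_g = 1:3, delta_pi = 1))
  expect_equal(allpp$fractions["pos", "pos"], 1)
})

test_that("per-participant preferences use strict majorities of nonzero deltas", {
  ev <- data.frame(
    actor = c(rep(1, 4), rep(2, 4), 3),
    action = "add",
    delta_pi = c(-1, -2, -3, 1,   -1, -1, 1, 1,   0),
    delta_g = 0)
  pref <- per_participant_preference(ev)
  get <- function(a, act, ax)
    pref$label[pref$actor == a & pref$action == act & pref$axis == ax]
  expect_identical(get(1, "add", "payoff"), "prefers_less")
  expect_identical(get(2, "add", "payoff"), "no_preference")  # exact tie
  expect_identical(get(3, "add", "payoff"), "no_preference")  # only zeros
  expect_identical(get(1, "remove", "payoff"), "no_preference")  # no events
})

test_that("update slots are conserved across adds, removes and renounced", {
  f <- make_fixture_session()
  act <- update_activity_series(f)
  expect_identical(act$adds, c(5L, 3L, 2L, 1L, 0L, 0L, 1L, 0L))
  expect_identical(act$removes, c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 0L))
  expect_true(all(act$adds + act$removes + act$renounced == 10L))
  # a round with no events renounces every slot
  expect_identical(act$renounced[8], 10L)
})
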