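#' Behaviour parameters for synthetic agents
#'
#' The simulator's agents follow a two-stage policy each round: for each of
#' the update slots they first decide whether to act at all, then whether
#' the action is an addition or a removal, and finally which target to
#' pick. Target choice is sign-stratified: a sign decision selects whether
#' the target should be strictly worse or strictly better off than the
#' focal agent (by previous-round payoff, and for removals also by
#' generosity), and the target is drawn uniformly within the selected
#' stratum, falling back to equal-valued targets and then the opposite
#' stratum when it is empty. Inside [simulate_session()] the sign
#' decisions come from a session-level quota controller that keeps the
#' recorded sign frequencies at the configured probabilities even when
#' preferred strata are unavailable (see the methods vignette); used
#' stand-alone, [choose_updates()] draws signs as independent Bernoulli
#' trials.
#'
#' @param p_use_slot probability each update slot is used in a round.
#' @param p_add_given_both propensity to add (vs remove) when both are
#'   feasible; the effective add probability declines with the agent's
#'   current normalized generosity so that additions and removals balance
#'   at a stationary density equal to `p_add_given_both` (see the methods
#'   vignette).
#' @param q_add_lower_payoff probability an addition targets a strictly
#'   lower-payoff node (previous-round payoff) among visible targets.
#' @param q_remove_higher_payoff probability a removal targets a strictly
#'   higher-payoff recipient.
#' @param q_remove_less_generous probability a removal targets a strictly
#'   less generous recipient, applied to the non-reciprocator pool.
#' @param q_remove_more_generous_reciprocal probability a removal from the
#'   reciprocator pool targets a strictly more generous reciprocator
#'   (reciprocal treatment only).
#' @param q_secure_provider probability an addition targets a visible
#'   provider rather than a candidate (reciprocal treatment only).
#' @return An object of class `behaviour_params`.
#' @seealso [behaviour_preset()] for the calibrated defaults.
#' @export
behaviour_params <- function(p_use_slot = 0.7,
                             p_add_given_both = 0.62,
                             q_add_lower_payoff = 0.60,
                             q_remove_higher_payoff = 0.67,
                             q_remove_less_generous = 0.56,
                             q_remove_more_generous_reciprocal = 0.73,
                             q_secure_provider = 0.45) {
  p <- list(p_use_slot = p_use_slot,
            p_add_given_both = p_add_given_both,
            q_add_lower_payoff = q_add_lower_payoff,
            q_remove_higher_payoff = q_remove_higher_payoff,
            q_remove_less_generous = q_remove_less_generous,
            q_remove_more_generous_reciprocal = q_remove_more_generous_reciprocal,
            q_secure_provider = q_secure_provider)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  is.na(x) || x < 0 || x > 1, logical(1))
  if (any(bad))
    stop("all behaviour parameters must be probabilities in [0, 1]: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "behaviour_params")
}

#' Named behaviour-parameter presets
#'
#' Calibrated defaults for the two treatments, with the target-choice
#' probabilities set to the observed event proportions (additions to less
#' successful targets, removals from more successful / less generous
#' targets, removals from more generous reciprocators) and the add/remove
#' balance set so the stationary network density matches the observed
#' stationary generosity (62% recipient-only, 69% reciprocal).
#' `"random_neutral"` sets every choice probability to 0.5.
#'
#' @param name one of `"recipient_only_default"`, `"reciprocal_default"`,
#'   `"random_neutral"`.
#' @return A [behaviour_params()] object.
#' @export
behaviour_preset <- function(name = c("recipient_only_default",
                                      "reciprocal_default",
                                      "random_neutral")) {
  switch(match.arg(name),
    recipient_only_default = behaviour_params(
      p_use_slot = 0.7, p_add_given_both = 0.62,
      q_add_lower_payoff = 0.60, q_remove_higher_payoff = 0.67,
      q_remove_less_generous = 0.56,
      q_remove_more_generous_reciprocal = 0.5, q_secure_provider = 0),
    reciprocal_default = behaviour_params(
      p_use_slot = 0.7, p_add_given_both = 0.69,
      q_add_lower_payoff = 0.61, q_remove_higher_payoff = 0.59,
      q_remove_less_generous = 0.71,
      q_remove_more_generous_reciprocal = 0.73, q_secure_provider = 0.45),
    random_neutral = behaviour_params(
      p_use_slot = 0.7, p_add_given_both = 0.5,
      q_add_lower_payoff = 0.5, q_remove_higher_payoff = 0.5,
      q_remove_less_generous = 0.5,
      q_remove_more_generous_reciprocal = 0.5, q_secure_provider = 0.5))
}

#' Sample the candidate set shown to a participant
#'
#' A new uniform sample, without replacement, from the nodes that are
#' neither the focal participant nor one of its current recipients. Uses
#' the current R random-number stream.
#'
#' @param state the start-of-round `round_state`.
#' @param focal participant index.
#' @param k requested sample size; all of the pool is returned when the
#'   pool is smaller.
#' @return Integer vector of at most `k` node indices (possibly empty).
#' @export
sample_candidates <- function(state, focal, k) {
  stopifnot(k >= 1)
  pool <- setdiff(seq_len(n_participants(state)),
                  c(focal, recipients(state, focal)))
  if (length(pool) == 0L) return(integer(0))
  pool[sample.int(length(pool), min(k, length(pool)))]
}

# -- sign-quota controller ----------------------------------------------
# The simulator steers the sign frequencies of the session's recorded
# (nonzero-delta) events toward the configured probabilities. A decision
# consults the session's running counts for the relevant contract (add
# payoff sign, removal payoff sign, removal generosity sign per target
# pool) and picks the sign that brings the empirical fraction closest to
# q; ties are broken by a Bernoulli(q) draw. After the target is chosen
# the *actual* recorded sign is fed back, so events forced onto the wrong
# side by stratum unavailability (an agent at a payoff extreme may have no
# better-off recipient at all) are compensated by later decisions — by any
# agent — and the session-level marginals the event analysis measures
# converge to the configured q's. Without a controller (quota = NULL)
# decisions are independent Bernoulli(q) draws.

quota_contracts <- c("add_pi", "add_g", "rem_pi", "rem_g_recip",
                     "rem_g_nonrecip")

new_quota <- function() {
  e <- new.env(parent = emptyenv())
  e$match <- stats::setNames(integer(length(quota_contracts)), quota_contracts)
  e$total <- e$match
  e
}

quota_want <- function(quota, contract, q) {
  if (is.null(quota)) return(stats::runif(1) < q)
  n <- quota$total[[contract]]
  k <- quota$match[[contract]]
  err_match <- abs((k + 1) / (n + 1) - q)
  err_other <- abs(k / (n + 1) - q)
  if (err_match < err_other) TRUE
  else if (err_match > err_other) FALSE
  else stats::runif(1) < q
}

quota_feed <- function(quota, contract, delta, match_positive) {
  if (is.null(quota) || delta == 0) return(invisible())
  quota$total[[contract]] <- quota$total[[contract]] + 1L
  if ((delta > 0) == match_positive)
    quota$match[[contract]] <- quota$match[[contract]] + 1L
  invisible()
}

# joint payoff x generosity stratification for removals: the signs of both
# deltas are drawn independently and the target comes from the
# intersection, which keeps both recorded marginals at their configured
# probabilities. When the intersection is empty the pick degrades to a
# single-axis stratified draw on the priority axis ("balanced" flips a
# fair coin for the axis), preferring targets that are *equal* to the
# focal on the other axis — such events carry a zero delta there and drop
# out of the other marginal instead of contaminating it.
pick_stratified2 <- function(ids, pay, gen, focal_pay, focal_gen,
                             want_hi, want_more,
                             priority = c("payoff", "generosity",
                                          "balanced")) {
  priority <- match.arg(priority)
  pi_match <- if (want_hi) ids[pay > focal_pay] else ids[pay < focal_pay]
  g_match <- if (want_more) ids[gen > focal_gen] else ids[gen < focal_gen]
  both <- intersect(pi_match, g_match)
  if (length(both)) return(both[sample.int(length(both), 1L)])
  if (priority == "balanced")
    priority <- if (stats::runif(1) < 0.5) "payoff" else "generosity"
  if (priority == "payoff") {
    prim <- pi_match
    absorb <- intersect(pi_match, ids[gen == focal_gen])
    eq <- ids[pay == focal_pay]
    sec <- if (want_hi) ids[pay < focal_pay] else ids[pay > focal_pay]
  } else {
    prim <- g_match
    absorb <- intersect(g_match, ids[pay == focal_pay])
    eq <- ids[gen == focal_gen]
    sec <- if (want_more) ids[gen < focal_gen] else ids[gen > focal_gen]
  }
  for (s in list(absorb, prim, eq, sec))
    if (length(s)) return(s[sample.int(length(s), 1L)])
  ids[sample.int(length(ids), 1L)]
}

#' Choose a participant's link updates for one round
#'
#' Implements the agents' two-stage decision rule against what the
#' interface displays: the previous round's per-round payoff and
#' generosity (out-degree) of every visible node, never cumulative tokens
#' and never, in the recipient-only treatment, provider identities.
#'
#' @param state the start-of-round `round_state` (the previous round's
#'   outcome, which is what participants see).
#' @param focal participant index.
#' @param candidates candidate sample for this round, from
#'   [sample_candidates()].
#' @param params a [behaviour_params()].
#' @param config the [session_config()].
#' @param quota optional sign-quota controller created by the simulator;
#'   when supplied, the agent steers the sign frequencies of its recorded
#'   events toward the configured probabilities (self-correcting for
#'   rounds where the preferred stratum is unavailable). `NULL` (the
#'   default) gives independent Bernoulli draws.
#' @return Data frame of 0 to `max_updates_per_round` rows with columns
#'   `actor`, `target`, `action`; an empty frame means the agent renounced
#'   its updates.
#' @export
choose_updates <- function(state, focal, candidates, params, config,
                           quota = NULL) {
  n <- config$n_participants
  view <- visible_sets(state, focal, config$treatment, candidates)
  reciprocal <- config$treatment == "reciprocal"
  recips_all <- if (reciprocal) c(view$recipients, view$reciprocals)
                else view$recipients
  pay <- state$round_payoff
  gen <- state$g
  pending_add <- integer(0)
  pending_rm <- integer(0)
  out <- list()

  for (slot in seq_len(config$max_updates_per_round)) {
    if (stats::runif(1) >= params$p_use_slot) next
    add_pool <- setdiff(c(view$candidates,
                          if (reciprocal) view$providers else integer(0)),
                        pending_add)
    rm_pool <- setdiff(recips_all, pending_rm)
    can_add <- length(add_pool) > 0L
    can_rm <- length(rm_pool) > 0L
    if (!can_add && !can_rm) next
    do_add <- if (can_add && can_rm) {
      gnorm <- state$g[focal] / (n - 1L)   # the displayed generosity
      p <- params$p_add_given_both
      num <- p * (1 - gnorm)
      den <- num + (1 - p) * gnorm
      stats::runif(1) < (if (den == 0) 1 else num / den)
    } else can_add

    if (do_add) {
      pool <- add_pool
      if (reciprocal) {
        prov_avail <- intersect(pool, view$providers)
        cand_avail <- setdiff(pool, prov_avail)
        if (length(prov_avail) && length(cand_avail))
          pool <- if (stats::runif(1) < params$q_secure_provider)
            prov_avail else cand_avail
      }
      prefer_low <- quota_want(quota, "add_pi",
                               params$q_add_lower_payoff)
      # generosity plays no role in additions: its marginal is held
      # neutral (0.5) while the payoff axis carries the configured bias
      want_more_g <- quota_want(quota, "add_g", 0.5)
      tgt <- pick_stratified2(pool, pay[pool], gen[pool],
                              pay[focal], gen[focal],
                              want_hi = !prefer_low,
                              want_more = want_more_g,
                              priority = "payoff")
      quota_feed(quota, "add_pi", pay[tgt] - pay[focal],
                 match_positive = FALSE)
      quota_feed(quota, "add_g", gen[tgt] - gen[focal],
                 match_positive = TRUE)
      pending_add <- c(pending_add, tgt)
      out[[length(out) + 1L]] <- data.frame(actor = focal, target = tgt,
                                            action = "add")
    } else {
      pool <- rm_pool
      if (reciprocal) {
        rec_avail <- intersect(pool, view$reciprocals)
        nrec_avail <- setdiff(pool, rec_avail)
        # pool chosen in proportion to its size: no extra parameter
        use_rec <- length(rec_avail) &&
          stats::runif(1) < length(rec_avail) / length(pool)
        pool <- if (use_rec) rec_avail else
          if (length(nrec_avail)) nrec_avail else rec_avail
        q_g_more <- if (use_rec) params$q_remove_more_generous_reciprocal
                    else 1 - params$q_remove_less_generous
        g_contract <- if (use_rec) "rem_g_recip" else "rem_g_nonrecip"
        priority <- if (use_rec) "generosity" else "payoff"
      } else {
        q_g_more <- 1 - params$q_remove_less_generous
        g_contract <- "rem_g_nonrecip"
        priority <- "payoff"
      }
      want_hi <- quota_want(quota, "rem_pi",
                            params$q_remove_higher_payoff)
      want_more <- quota_want(quota, g_contract, q_g_more)
      tgt <- pick_stratified2(pool, pay[pool], gen[pool],
                              pay[focal], gen[focal],
                              want_hi, want_more, priority)
      quota_feed(quota, "rem_pi", pay[tgt] - pay[focal],
                 match_positive = TRUE)
      quota_feed(quota, g_contract, gen[tgt] - gen[focal],
                 match_positive = TRUE)
      pending_rm <- c(pending_rm, tgt)
      out[[length(out) + 1L]] <- data.frame(actor = focal, target = tgt,
                                            action = "remove")
    }
  }
  if (!length(out))
    return(data.frame(actor = integer(0), target = integer(0),
                      action = character(0)))
  do.call(rbind, out)
}

#' Simulate a complete donation-game session
#'
#' Generates a session round by round: each round every agent receives a
#' fresh candidate sample, chooses up to `max_updates_per_round` updates
#' through [choose_updates()], and the whole network is updated
#' simultaneously through [validate_and_apply_round()] (strict mode — the
#' policy only emits valid updates). Round 0 is the empty network, so the
#' first round consists of additions only. The result is fully reproducible
#' from `(config, params, seed)`: agents are visited in a fixed order on a
#' single seeded RNG stream.
#'
#' @param config a [session_config()].
#' @param params a [behaviour_params()]; defaults to the treatment's
#'   calibrated preset.
#' @param seed integer RNG seed.
#' @return A `coopnet_session`; `metadata` records seed, params and
#'   generator provenance.
#' @examples
#' s <- simulate_session(session_config(10, n_rounds = 5), seed = 1)
#' validate_session(s)
#' @export
simulate_session <- function(config,
                             params = behaviour_preset(
                               if (config$treatment == "reciprocal")
                                 "reciprocal_default"
                               else "recipient_only_default"),
                             seed = 1L) {
  stopifnot(inherits(config, "session_config"),
            inherits(params, "behaviour_params"))
  set.seed(as.integer(seed))
  state <- initial_round_state(config)
  rounds <- vector("list", config$n_rounds + 1L)
  rounds[[1L]] <- state
  events <- vector("list", config$n_rounds)
  quota <- new_quota()
  for (r in seq_len(config$n_rounds)) {
    per_agent <- lapply(seq_len(config$n_participants), function(f) {
      cand <- sample_candidates(state, f, config$candidate_sample_size)
      choose_updates(state, f, cand, params, config, quota)
    })
    upd <- do.call(rbind, per_agent)
    state <- validate_and_apply_round(state, upd, config, strict = TRUE)
    rounds[[r + 1L]] <- state
    acc <- attr(state, "accepted_updates")
    if (nrow(acc))
      events[[r]] <- cbind(round = r, acc)
  }
  ev <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  new_session(config, rounds, ev,
              metadata = list(generator = "coopnet::simulate_session",
                              seed = as.integer(seed),
                              params = unclass(params)))
}
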