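#' Annotate link-update events with target category and deltas
#'
#' Every validated update is annotated against the state of the round
#' *preceding* the decision — exactly what the interface displayed: the
#' target's and actor's generosity (out-degree) and previous-round payoff
#' `l*b - g*c`. Cumulative tokens are never used (participants could not
#' see them). `delta_g = g_target - g_actor` and
#' `delta_pi = pi_target - pi_actor`.
#'
#' Target categories follow the treatment's visibility: additions target
#' `"candidate"`s (or, in the reciprocal treatment, `"provider"`s);
#' removals target `"recipient"`s (or `"reciprocal"`s when the target was
#' also a provider of the actor in the preceding round — observable only
#' in the reciprocal treatment).
#'
#' @param session a `coopnet_session`.
#' @return Data frame with one row per event: `round`, `actor`, `target`,
#'   `action`, `target_category`, `delta_g`, `delta_pi`, `treatment`.
#' @export
annotate_events <- function(session) {
  ev <- session$events
  n <- session$config$n_participants
  reciprocal <- session$config$treatment == "reciprocal"
  if (nrow(ev) == 0L)
    return(cbind(ev, target_category = character(0),
                 delta_g = integer(0), delta_pi = integer(0),
                 treatment = character(0)))
  if (any(ev$actor < 1L | ev$actor > n | ev$target < 1L | ev$target > n))
    stop("event references an unknown participant id", call. = FALSE)
  parts <- lapply(split(seq_len(nrow(ev)), ev$round), function(ix) {
    r <- ev$round[ix[1L]]
    st <- session$rounds[[r]]  # state at end of round r - 1
    a <- ev$actor[ix]; t <- ev$target[ix]
    # target is a provider of the actor iff the reverse link t -> a exists
    is_prov <- reciprocal &
      ((t - 1L) * n + a) %in% edge_codes(st$edges, n)
    add <- ev$action[ix] == "add"
    data.frame(idx = ix, round = r, actor = a, target = t,
               action = ev$action[ix],
               target_category = ifelse(add,
                 ifelse(is_prov, "provider", "candidate"),
                 ifelse(is_prov, "reciprocal", "recipient")),
               delta_g = st$g[t] - st$g[a],
               delta_pi = st$round_payoff[t] - st$round_payoff[a],
               treatment = session$config$treatment)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$idx), setdiff(names(out), "idx"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop the transient opening rounds from an event list
#'
#' The first rounds are dominated by the build-up from the empty network,
#' so event statistics exclude them; by default only events from round 11
#' onward are kept.
#'
#' @param events annotated event data frame.
#' @param min_round first round to keep (default 11).
#' @return The filtered data frame.
#' @export
filter_rounds <- function(events, min_round = 11L) {
  events[events$round >= min_round, , drop = FALSE]
}

#' Joint histogram of link-update events
#'
#' Counts events over the integer grid of (`delta_g`, `delta_pi`), plus
#' the two marginal count tables and the mean of each delta. The marginals
#' are the row/column sums of the joint table by construction.
#'
#' @param events non-empty annotated event data frame.
#' @return An object of class `event_histogram`: list with `joint` (data
#'   frame `delta_g`, `delta_pi`, `count`), `marginal_g`, `marginal_pi`
#'   (data frames `delta`, `count`), `mean_delta_g`, `mean_delta_pi`, `n`.
#' @export
build_histogram <- function(events) {
  if (NROW(events) == 0L) stop("no events to histogram", call. = FALSE)
  joint <- as.data.frame(table(delta_g = events$delta_g,
                               delta_pi = events$delta_pi),
                         stringsAsFactors = FALSE)
  joint <- joint[joint$Freq > 0L, ]
  joint <- data.frame(delta_g = as.integer(joint$delta_g),
                      delta_pi = as.integer(joint$delta_pi),
                      count = joint$Freq)
  marg <- function(delta) {
    tab <- table(delta)
    data.frame(delta = as.integer(names(tab)), count = as.integer(tab))
  }
  structure(list(joint = joint,
                 marginal_g = marg(events$delta_g),
                 marginal_pi = marg(events$delta_pi),
                 mean_delta_g = mean(events$delta_g),
                 mean_delta_pi = mean(events$delta_pi),
                 n = nrow(events)),
            class = "event_histogram")
}

#' @export
print.event_histogram <- function(x, ...) {
  cat(sprintf(
    "<event_histogram> %d events; mean (delta_g, delta_pi) = (%.2f, %.2f)\n",
    x$n, x$mean_delta_g, x$mean_delta_pi))
  invisible(x)
}

#' Exact two-sided binomial p-value against 0.5
#'
#' The doubled smaller tail, capped at 1: `min(1, 2 * min(P(X <= k),
#' P(X >= k)))` for `X ~ Binomial(n, 1/2)`. For the symmetric null this
#' coincides with the convention of [stats::binom.test()].
#'
#' @param k observed count of one category.
#' @param n total number of trials.
#' @return p-value in `(0, 1]`.
#' @export
exact_binom_p <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Preference proportion on one delta axis
#'
#' Among events with a nonzero delta on the chosen axis, the proportion
#' targeting a strictly worse-off node (`delta < 0`), with the exact
#' two-sided binomial test against the no-preference null of 0.5.
#' Zero-delta events are excluded from the test but counted.
#'
#' @param events annotated event data frame (typically pre-filtered to one
#'   action and to rounds past the transient), or an `event_histogram`.
#' @param axis `"payoff"` (`delta_pi`) or `"generosity"` (`delta_g`).
#' @return List with `n_minus`, `n_plus`, `n_zero`, `proportion`
#'   (= `n_minus / (n_minus + n_plus)`) and `p_value`; `proportion` and
#'   `p_value` are `NA` when every delta is zero.
#' @export
preference_proportion <- function(events, axis = c("payoff", "generosity")) {
  axis <- match.arg(axis)
  if (inherits(events, "event_histogram")) {
    marg <- if (axis == "payoff") events$marginal_pi else events$marginal_g
    delta <- rep(marg$delta, marg$count)
  } else {
    delta <- if (axis == "payoff") events$delta_pi else events$delta_g
  }
  n_minus <- sum(delta < 0)
  n_plus <- sum(delta > 0)
  n_zero <- sum(delta == 0)
  if (n_minus + n_plus == 0L) {
    warning("all deltas are zero; proportion undefined", call. = FALSE)
    return(list(n_minus = n_minus, n_plus = n_plus, n_zero = n_zero,
                proportion = NA_real_, p_value = NA_real_))
  }
  list(n_minus = n_minus, n_plus = n_plus, n_zero = n_zero,
       proportion = n_minus / (n_minus + n_plus),
       p_value = exact_binom_p(n_minus, n_minus + n_plus))
}

#' Split removal events by reciprocation status of the target
#'
#' A removal counts as a reciprocator event when the target was also a
#' provider of the actor in the round preceding the decision. The split is
#' only meaningful in the reciprocal treatment, where subjects could see
#' who reciprocates; calling it on a recipient-only session is an error
#' unless `diagnostic = TRUE` (the quantity is still computable from the
#' recorded network, just unobservable to subjects).
#'
#' @param events annotated event data frame.
#' @param session the `coopnet_session` the events came from.
#' @param diagnostic allow the split on recipient-only sessions?
#' @return List with `reciprocator` and `non_reciprocator` event data
#'   frames; together they partition the removal events.
#' @export
split_by_reciprocation <- function(events, session, diagnostic = FALSE) {
  if (session$config$treatment != "reciprocal" && !diagnostic)
    stop("reciprocator split requires a reciprocal-treatment session ",
         "(set diagnostic = TRUE to force)", call. = FALSE)
  rem <- events[events$action == "remove", , drop = FALSE]
  is_rec <- vapply(seq_len(nrow(rem)), function(i) {
    st <- session$rounds[[rem$round[i]]]
    rem$target[i] %in% providers(st, rem$actor[i])
  }, logical(1))
  list(reciprocator = rem[is_rec, , drop = FALSE],
       non_reciprocator = rem[!is_rec, , drop = FALSE])
}

#' Quadrant fractions of the (delta_g, delta_pi) plane
#'
#' Fractions of events in each sign quadrant, computed over events with
#' both deltas nonzero; events on an axis are excluded from the fractions
#' but reported as zero counts.
#'
#' @param events annotated event data frame.
#' @return List with `fractions` (2x2 matrix, rows `delta_g` neg/pos,
#'   columns `delta_pi` neg/pos, summing to 1 when any off-axis event
#'   exists), `n_signed`, and `zero_counts` (`zero_g`, `zero_pi`,
#'   `zero_both`).
#' @export
quadrant_fractions <- function(events) {
  if (NROW(events) == 0L) stop("no events", call. = FALSE)
  zg <- events$delta_g == 0
  zp <- events$delta_pi == 0
  signed <- events[!zg & !zp, , drop = FALSE]
  frac <- matrix(0, 2, 2, dimnames = list(delta_g = c("neg", "pos"),
                                          delta_pi = c("neg", "pos")))
  if (nrow(signed)) {
    gi <- ifelse(signed$delta_g > 0, "pos", "neg")
    pi_ <- ifelse(signed$delta_pi > 0, "pos", "neg")
    tab <- table(factor(gi, c("neg", "pos")), factor(pi_, c("neg", "pos")))
    frac[] <- tab / nrow(signed)
  }
  list(fractions = frac, n_signed = nrow(signed),
       zero_counts = c(zero_g = sum(zg & !zp), zero_pi = sum(zp & !zg),
                       zero_both = sum(zg & zp)))
}

#' Per-participant update preferences
#'
#' Labels each actor's preference for every (action, axis) combination
#' from the strict majority of its nonzero-delta events: a participant
#' "prefers_more" when more than half of its targeted nodes are better
#' off on that axis, "prefers_less" when more than half are worse off, and
#' "no_preference" on an exact tie or with no nonzero-delta events.
#'
#' @param events annotated event data frame.
#' @return Data frame with columns `actor`, `action`, `axis`, `n_less`,
#'   `n_more`, `label`.
#' @export
per_participant_preference <- function(events) {
  grid <- expand.grid(actor = sort(unique(events$actor)),
                      action = c("add", "remove"),
                      axis = c("payoff", "generosity"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- events[events$actor == grid$actor[i] &
                  events$action == grid$action[i], , drop = FALSE]
    delta <- if (grid$axis[i] == "payoff") sel$delta_pi else sel$delta_g
    n_less <- sum(delta < 0); n_more <- sum(delta > 0)
    label <- if (n_more > n_less) "prefers_more"
             else if (n_less > n_more) "prefers_less"
             else "no_preference"
    cbind(grid[i, , drop = FALSE],
          data.frame(n_less = n_less, n_more = n_more, label = label))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-round add / remove / renounced-slot counts
#'
#' Every participant holds `max_updates_per_round` update slots per round;
#' slots not spent on an addition or removal are renounced, so per round
#' `adds + removes + renounced = max_updates_per_round * n`.
#'
#' @param session a `coopnet_session`.
#' @return Data frame with columns `round`, `adds`, `removes`,
#'   `renounced`.
#' @export
update_activity_series <- function(session) {
  cfg <- session$config
  total <- cfg$max_updates_per_round * cfg$n_participants
  rounds <- seq_len(cfg$n_rounds)
  ev <- session$events
  adds <- vapply(rounds, function(r)
    sum(ev$round == r & ev$action == "add"), integer(1))
  removes <- vapply(rounds, function(r)
    sum(ev$round == r & ev$action == "remove"), integer(1))
  data.frame(round = rounds, adds = adds, removes = removes,
             renounced = total - adds - removes)
}
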