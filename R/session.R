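#' Session objects
#'
#' A `coopnet_session` bundles a [session_config()], the ordered list of
#' round states (element 1 is the empty round-0 state) and the validated
#' link-update event log. Both the simulator and the file readers produce
#' this container.
#'
#' @param config a [session_config()].
#' @param rounds list of `round_state` objects, rounds 0..n_rounds.
#' @param events data frame with columns `round`, `actor`, `target`,
#'   `action` holding every validated update, in application order.
#' @param metadata named list (label, seed, generator provenance, ...).
#' @return An object of class `coopnet_session`.
#' @export
new_session <- function(config, rounds, events, metadata = list()) {
  structure(list(config = config, rounds = rounds,
                 events = as_events(events), metadata = metadata),
            class = "coopnet_session")
}

as_events <- function(events) {
  if (is.null(events) || NROW(events) == 0L)
    return(data.frame(round = integer(0), actor = integer(0),
                      target = integer(0), action = character(0)))
  stopifnot(all(c("round", "actor", "target", "action") %in% names(events)))
  data.frame(round = as.integer(events$round),
             actor = as.integer(events$actor),
             target = as.integer(events$target),
             action = as.character(events$action))
}

#' @export
print.coopnet_session <- function(x, ...) {
  cat(sprintf(
    "<coopnet_session> %s: n=%d, %d rounds, %d link-update events%s\n",
    x$config$treatment, x$config$n_participants, x$config$n_rounds,
    nrow(x$events),
    if (!is.null(x$metadata$label)) paste0(" [", x$metadata$label, "]") else ""))
  invisible(x)
}

#' Validate the internal consistency of a session
#'
#' Checks every structural invariant of the donation game on every round:
#' degree conservation (`sum(g) == sum(l) == |E|`), the payoff identity
#' (`round_payoff == l*b - g*c` and its population sum `|E|*(b - c)`), the
#' token audit (cumulative tokens equal endowment plus all past round
#' payoffs), no self or duplicate edges, the per-actor update cap, and the
#' replay property: applying the event log from the empty round-0 network
#' through [validate_and_apply_round()] must reproduce every stored edge
#' set exactly.
#'
#' @param session a `coopnet_session`.
#' @return Invisibly `TRUE`; otherwise an error naming the offending round
#'   (and actor where applicable).
#' @export
validate_session <- function(session) {
  cfg <- session$config
  n <- cfg$n_participants
  rounds <- session$rounds
  if (length(rounds) != cfg$n_rounds + 1L)
    stop("session must contain n_rounds + 1 round states", call. = FALSE)
  if (nrow(rounds[[1L]]$edges) != 0L)
    stop("round 0 must be the empty network", call. = FALSE)

  for (k in seq_along(rounds)) {
    st <- rounds[[k]]
    m <- nrow(st$edges)
    if (st$round_index != k - 1L)
      stop(sprintf("round index mismatch at position %d", k), call. = FALSE)
    if (m > 0L) {
      if (any(st$edges[, 1L] == st$edges[, 2L]))
        stop(sprintf("self-edge in round %d", st$round_index), call. = FALSE)
      if (anyDuplicated(edge_codes(st$edges, n)))
        stop(sprintf("duplicate edge in round %d", st$round_index), call. = FALSE)
    }
    if (sum(st$g) != m || sum(st$l) != m)
      stop(sprintf("degree conservation violated in round %d", st$round_index),
           call. = FALSE)
    if (!all(st$round_payoff == st$l * cfg$benefit_b - st$g * cfg$cost_c))
      stop(sprintf("payoff identity violated in round %d", st$round_index),
           call. = FALSE)
    if (sum(st$round_payoff) != m * (cfg$benefit_b - cfg$cost_c))
      stop(sprintf("payoff conservation violated in round %d", st$round_index),
           call. = FALSE)
  }

  # token audit against cumulative sums of round payoffs
  pay <- vapply(rounds, function(s) s$round_payoff, numeric(n))
  cum <- cfg$endowment + apply(pay, 1L, cumsum)     # (round+1) x n
  for (k in seq_along(rounds)) {
    if (!all(rounds[[k]]$cumulative_tokens == cum[k, ]))
      stop(sprintf("token audit failed in round %d", k - 1L), call. = FALSE)
  }

  ev <- session$events
  if (nrow(ev) > 0L) {
    slots <- table(paste(ev$round, ev$actor))
    if (any(slots > cfg$max_updates_per_round))
      stop("per-actor update cap exceeded in event log", call. = FALSE)
  }

  replay <- replay_events(cfg, ev)
  for (k in seq_along(rounds)) {
    stored <- sort(edge_codes(rounds[[k]]$edges, n))
    got <- sort(edge_codes(replay[[k]]$edges, n))
    if (!identical(stored, got))
      stop(sprintf("event replay does not reproduce round %d", k - 1L),
           call. = FALSE)
  }
  invisible(TRUE)
}

# Rebuild all round states from the event log alone.
replay_events <- function(config, events) {
  state <- initial_round_state(config)
  out <- vector("list", config$n_rounds + 1L)
  out[[1L]] <- state
  events <- as_events(events)
  for (r in seq_len(config$n_rounds)) {
    upd <- events[events$round == r, c("actor", "target", "action")]
    state <- validate_and_apply_round(state, upd, config, strict = TRUE)
    out[[r + 1L]] <- state
  }
  out
}
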