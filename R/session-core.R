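#' Session configuration
#'
#' Immutable parameters of one session of the directed donation game.
#' A directed link (donor -> recipient) represents the act of providing
#' `benefit_b` tokens per round at a personal cost of `cost_c` tokens,
#' for as long as the donor maintains the link. Each round every
#' participant may add and/or remove up to `max_updates_per_round`
#' outgoing links; nobody controls their incoming links.
#'
#' @param n_participants number of participants, at least 3.
#' @param n_rounds number of rounds played (default 60).
#' @param benefit_b tokens a recipient gains per incoming link per round
#'   (default 2). Must exceed `cost_c`.
#' @param cost_c tokens a donor pays per outgoing link per round (default 1).
#' @param endowment initial token balance of every participant (default 1000).
#' @param max_updates_per_round link-update slots per participant per round
#'   (default 2).
#' @param treatment `"recipient_only"` (provider identities hidden, so
#'   intentional direct reciprocation is impossible) or `"reciprocal"`
#'   (providers visible, reciprocators grouped separately).
#' @param candidate_sample_size number of currently unlinked nodes shown
#'   to each participant as candidates every round (default 8).
#'
#' @return An object of class `session_config`.
#' @examples
#' session_config(n_participants = 30)
#' @export
session_config <- function(n_participants,
                           n_rounds = 60L,
                           benefit_b = 2L,
                           cost_c = 1L,
                           endowment = 1000L,
                           max_updates_per_round = 2L,
                           treatment = c("recipient_only", "reciprocal"),
                           candidate_sample_size = 8L) {
  treatment <- match.arg(treatment)
  n_participants <- as.integer(n_participants)
  n_rounds <- as.integer(n_rounds)
  max_updates_per_round <- as.integer(max_updates_per_round)
  candidate_sample_size <- as.integer(candidate_sample_size)
  if (is.na(n_participants) || n_participants < 3L)
    stop("n_participants must be an integer >= 3", call. = FALSE)
  if (is.na(n_rounds) || n_rounds < 1L)
    stop("n_rounds must be a positive integer", call. = FALSE)
  if (!(benefit_b > cost_c && cost_c > 0))
    stop("benefit_b > cost_c > 0 is required", call. = FALSE)
  if (is.na(max_updates_per_round) || max_updates_per_round < 1L)
    stop("max_updates_per_round must be >= 1", call. = FALSE)
  if (is.na(candidate_sample_size) || candidate_sample_size < 1L)
    stop("candidate_sample_size must be >= 1", call. = FALSE)
  structure(
    list(n_participants = n_participants,
         n_rounds = n_rounds,
         benefit_b = benefit_b,
         cost_c = cost_c,
         endowment = endowment,
         max_updates_per_round = max_updates_per_round,
         treatment = treatment,
         candidate_sample_size = candidate_sample_size),
    class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "<session_config> n=%d, rounds=%d, b=%s, c=%s, endowment=%s, cap=%d, %s\n",
    x$n_participants, x$n_rounds, x$benefit_b, x$cost_c, x$endowment,
    x$max_updates_per_round, x$treatment))
  invisible(x)
}

# -- round states --------------------------------------------------------

#' Empty initial round state
#'
#' The network starts as a set of disconnected nodes: round 0 has no edges,
#' zero payoffs and the full endowment for everyone.
#'
#' @param config a [session_config()].
#' @return An object of class `round_state`.
#' @export
initial_round_state <- function(config) {
  n <- config$n_participants
  new_round_state(0L, empty_edges(), n, config$benefit_b, config$cost_c,
                  rep(config$endowment, n))
}

empty_edges <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("donor", "recipient")))
}

# edges: m x 2 integer matrix (donor, recipient); cumulative already includes
# this round's payoff.
new_round_state <- function(round_index, edges, n, b, c_, cumulative) {
  g <- tabulate(edges[, 1L], nbins = n)
  l <- tabulate(edges[, 2L], nbins = n)
  structure(
    list(round_index = as.integer(round_index),
         edges = edges,
         g = g,
         l = l,
         round_payoff = l * b - g * c_,
         cumulative_tokens = cumulative),
    class = "round_state")
}

#' @export
print.round_state <- function(x, ...) {
  cat(sprintf("<round_state> round %d: %d participants, %d links\n",
              x$round_index, length(x$g), nrow(x$edges)))
  invisible(x)
}

n_participants <- function(state) length(state$g)

edge_codes <- function(edges, n) (edges[, 1L] - 1L) * n + edges[, 2L]

code_to_edges <- function(codes, n) {
  codes <- sort(codes)
  cbind(donor = (codes - 1L) %/% n + 1L, recipient = (codes - 1L) %% n + 1L)
}

#' Recipients and providers of a participant
#'
#' `recipients()` returns the nodes the focal participant currently donates
#' to (its out-neighbours); `providers()` the nodes donating to it
#' (in-neighbours).
#'
#' @param state a `round_state`.
#' @param focal participant index.
#' @return Integer vector of participant indices.
#' @export
recipients <- function(state, focal) {
  sort(unname(state$edges[state$edges[, 1L] == focal, 2L]))
}

#' @rdname recipients
#' @export
providers <- function(state, focal) {
  sort(unname(state$edges[state$edges[, 2L] == focal, 1L]))
}

# -- elementary accounting ----------------------------------------------

#' Per-round payoff of a participant
#'
#' A participant with `g` recipients (outgoing links) and `l` providers
#' (incoming links) earns `l * b - g * c` tokens in a round; the value may
#' be negative for net donors.
#'
#' @param g number of recipients (out-degree), non-negative.
#' @param l number of providers (in-degree), non-negative.
#' @param b benefit per incoming link, positive.
#' @param c_ cost per outgoing link, positive.
#' @return Integer (or numeric) token payoff `l * b - g * c_`. Vectorised.
#' @examples
#' round_payoff(g = 2, l = 4, b = 2, c_ = 1)  # 6
#' @export
round_payoff <- function(g, l, b = 2, c_ = 1) {
  if (any(g < 0) || any(l < 0)) stop("g and l must be non-negative", call. = FALSE)
  if (any(b <= 0) || any(c_ <= 0)) stop("b and c_ must be positive", call. = FALSE)
  l * b - g * c_
}

#' Accumulate round payoffs onto the endowment
#'
#' Losses and earnings of every round are added to the initial endowment;
#' there is no other source or sink of tokens.
#'
#' @param endowment starting token balance.
#' @param round_payoffs numeric vector of per-round payoffs (possibly empty).
#' @return `endowment + sum(round_payoffs)`.
#' @examples
#' accumulate_tokens(1000, c(6))        # 1006
#' accumulate_tokens(1000, c(6, -3, 2)) # 1005
#' @export
accumulate_tokens <- function(endowment, round_payoffs = numeric(0)) {
  endowment + sum(round_payoffs)
}

#' Behavioural type L
#'
#' The behavioural type of a node is read off its local network structure:
#' `L = (g - l) / (g + l)`, where `g` counts recipients and `l` providers.
#' `L = 1` is a pure altruist (only gives), `L = -1` a pure egoist (only
#' receives), `L = 0` a fair player. Isolated nodes (`g + l = 0`) have no
#' defined type and return `NA`; they are excluded from any averaging.
#'
#' @param g number of recipients (out-degree).
#' @param l number of providers (in-degree). Vectorised over both.
#' @return Numeric in `[-1, 1]`, or `NA` where `g + l == 0`.
#' @examples
#' behavioural_type(3, 1)  # 0.5
#' behavioural_type(0, 0)  # NA: isolated node
#' @export
behavioural_type <- function(g, l) {
  if (any(g < 0) || any(l < 0)) stop("g and l must be non-negative", call. = FALSE)
  s <- g + l
  ifelse(s == 0, NA_real_, (g - l) / s)
}

#' Classify a behavioural type value
#'
#' Cuts the `[-1, 1]` range into altruists (`L > 1/3`), fair players
#' (`-1/3 <= L <= 1/3`) and egoists (`L < -1/3`).
#'
#' @param L numeric vector of behavioural types in `[-1, 1]`; `NA` allowed
#'   (isolated nodes) and propagated.
#' @return Character vector with levels `"altruist"`, `"fair"`, `"egoist"`.
#' @export
classify_type <- function(L) {
  if (any(L < -1 | L > 1, na.rm = TRUE))
    stop("L must lie in [-1, 1]", call. = FALSE)
  out <- rep(NA_character_, length(L))
  out[!is.na(L) & L > 1 / 3] <- "altruist"
  out[!is.na(L) & L >= -1 / 3 & L <= 1 / 3] <- "fair"
  out[!is.na(L) & L < -1 / 3] <- "egoist"
  out
}

# -- round update --------------------------------------------------------

as_updates <- function(updates) {
  if (is.null(updates) || NROW(updates) == 0L)
    return(data.frame(actor = integer(0), target = integer(0),
                      action = character(0)))
  stopifnot(all(c("actor", "target", "action") %in% names(updates)))
  data.frame(actor = as.integer(updates$actor),
             target = as.integer(updates$target),
             action = as.character(updates$action))
}

#' Validate and apply one round of link updates
#'
#' All decisions of a round are evaluated against the start-of-round state
#' and applied simultaneously; because each actor controls only its own
#' outgoing links, no collisions are possible. An addition must target a
#' node the actor does not currently donate to, a removal must target a
#' current recipient, self-links are forbidden, and each actor has at most
#' `max_updates_per_round` slots (extra submissions are rejected in
#' submission order).
#'
#' Invalid updates are dropped and reported via the `"rejected_updates"`
#' attribute of the returned state (a data frame with a `reason` column),
#' which makes replay of recorded data robust to artefacts. With
#' `strict = TRUE` any invalid update raises an error instead; the
#' simulator runs in strict mode.
#'
#' @param state the start-of-round `round_state`.
#' @param updates data frame with columns `actor`, `target`, `action`
#'   (`"add"` or `"remove"`); zero rows allowed.
#' @param config the [session_config()].
#' @param strict raise an error on any invalid update?
#' @return The next `round_state` (round index incremented, degrees,
#'   payoffs and cumulative tokens recomputed), with attributes
#'   `"accepted_updates"` and `"rejected_updates"`.
#' @export
validate_and_apply_round <- function(state, updates, config, strict = FALSE) {
  n <- n_participants(state)
  updates <- as_updates(updates)
  m <- nrow(updates)
  existing <- edge_codes(state$edges, n)
  accepted <- logical(m)
  reason <- character(m)
  used <- integer(n)           # accepted slots per actor so far
  seen <- character(0)         # accepted (actor,target,action) keys

  for (i in seq_len(m)) {
    a <- updates$actor[i]; t <- updates$target[i]; act <- updates$action[i]
    key <- paste(a, t, act, sep = ":")
    code <- (a - 1L) * n + t
    reason[i] <-
      if (is.na(a) || is.na(t) || a < 1L || a > n || t < 1L || t > n)
        "unknown participant id"
      else if (a == t) "self-link"
      else if (!act %in% c("add", "remove")) "unknown action"
      else if (used[a] >= config$max_updates_per_round)
        "update cap exceeded"
      else if (key %in% seen) "duplicate update"
      else if (act == "add" && code %in% existing)
        "add targets an existing recipient"
      else if (act == "remove" && !code %in% existing)
        "remove targets a non-recipient"
      else ""
    if (reason[i] == "") {
      accepted[i] <- TRUE
      used[a] <- used[a] + 1L
      seen <- c(seen, key)
    } else if (strict) {
      stop(sprintf("invalid update in round %d: actor %s -> %s (%s): %s",
                   state$round_index + 1L, a, t, act, reason[i]),
           call. = FALSE)
    }
  }

  ok <- updates[accepted, , drop = FALSE]
  add_codes <- with(ok[ok$action == "add", , drop = FALSE],
                    (actor - 1L) * n + target)
  rm_codes <- with(ok[ok$action == "remove", , drop = FALSE],
                   (actor - 1L) * n + target)
  new_codes <- c(setdiff(existing, rm_codes), add_codes)
  nxt <- new_round_state(state$round_index + 1L, code_to_edges(new_codes, n),
                         n, config$benefit_b, config$cost_c,
                         cumulative = state$cumulative_tokens)
  nxt$cumulative_tokens <- state$cumulative_tokens + nxt$round_payoff
  attr(nxt, "accepted_updates") <- ok
  attr(nxt, "rejected_updates") <-
    cbind(updates[!accepted, , drop = FALSE],
          reason = reason[!accepted])
  nxt
}

#' What a participant sees before updating links
#'
#' Returns the node categories displayed to the focal participant,
#' depending on the treatment. In the recipient-only treatment only the
#' focal's current recipients and a random candidate sample are visible;
#' provider identities are withheld, making direct reciprocation
#' impossible. In the reciprocal treatment providers are shown too, and
#' nodes that are simultaneously provider and recipient are grouped as
#' reciprocators (and removed from the plain provider/recipient lists, so
#' the categories are disjoint).
#'
#' @param state the start-of-round `round_state`.
#' @param focal participant index.
#' @param treatment `"recipient_only"` or `"reciprocal"`.
#' @param candidate_sample integer vector of candidate node indices; must
#'   exclude the focal and its current recipients (offending entries are
#'   filtered out with a warning).
#' @return A list with elements `recipients` and `candidates`, plus
#'   `providers` and `reciprocals` in the reciprocal treatment.
#' @export
visible_sets <- function(state, focal,
                         treatment = c("recipient_only", "reciprocal"),
                         candidate_sample = integer(0)) {
  treatment <- match.arg(treatment)
  rec <- recipients(state, focal)
  cand <- as.integer(candidate_sample)
  bad <- cand == focal | cand %in% rec
  if (any(bad)) {
    warning("candidate sample overlapped focal/recipients; filtered",
            call. = FALSE)
    cand <- cand[!bad]
  }
  if (treatment == "recipient_only")
    return(list(recipients = rec, candidates = cand))
  prov <- providers(state, focal)
  recip <- intersect(rec, prov)
  list(recipients = setdiff(rec, recip),
       candidates = cand,
       providers = setdiff(prov, recip),
       reciprocals = recip)
}
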