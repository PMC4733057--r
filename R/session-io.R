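#' Write a session to a self-describing JSON file
#'
#' One file per session: schema version, config, metadata, the per-round
#' edge lists and the validated event log. Sessions are small (tens of
#' nodes, 60 rounds), so a single text file round-trips losslessly and
#' stays diffable.
#'
#' @param session a `coopnet_session`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  cfg <- session$config
  obj <- list(
    schema_version = "1.0",
    config = unclass(cfg),
    metadata = session$metadata,
    rounds = lapply(session$rounds, function(st)
      list(donor = as.integer(st$edges[, 1L]),
           recipient = as.integer(st$edges[, 2L]))),
    events = list(round = session$events$round,
                  actor = session$events$actor,
                  target = session$events$target,
                  action = session$events$action))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a session file
#'
#' Reads a file written by [write_session()], rebuilds every round state
#' from the config and edge lists, and validates all structural
#' invariants including the event-replay property through
#' [validate_session()]. A corrupted file (duplicate edge, broken replay,
#' schema mismatch) raises a structured error naming the offending round.
#'
#' @param path path to a session JSON file.
#' @return A validated `coopnet_session`.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != "1.0")
    stop("unsupported session schema version: ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version,
         call. = FALSE)
  cfg <- do.call(session_config, obj$config[c(
    "n_participants", "n_rounds", "benefit_b", "cost_c", "endowment",
    "max_updates_per_round", "treatment", "candidate_sample_size")])
  rounds <- rebuild_rounds(cfg, obj$rounds)
  ev <- if (length(obj$events$round) == 0L) NULL else
    data.frame(round = unlist(obj$events$round),
               actor = unlist(obj$events$actor),
               target = unlist(obj$events$target),
               action = unlist(obj$events$action))
  session <- new_session(cfg, rounds, ev, metadata = as.list(obj$metadata))
  validate_session(session)
  session
}

# reconstruct round states (degrees, payoffs, token balances) from stored
# per-round edge lists
rebuild_rounds <- function(cfg, round_edges) {
  n <- cfg$n_participants
  cum <- rep(cfg$endowment, n)
  out <- vector("list", length(round_edges))
  for (k in seq_along(round_edges)) {
    re <- round_edges[[k]]
    edges <- if (length(re$donor) == 0L) empty_edges() else
      cbind(donor = as.integer(re$donor), recipient = as.integer(re$recipient))
    st <- new_round_state(k - 1L, edges, n, cfg$benefit_b, cfg$cost_c, cum)
    if (k > 1L) {
      cum <- cum + st$round_payoff
      st$cumulative_tokens <- cum
    }
    out[[k]] <- st
  }
  out
}

#' Deterministic hand-scripted fixture session
#'
#' A 5-participant, 8-round reciprocal-treatment session with scripted
#' updates covering additions, removals, renounced slots and reciprocated
#' pairs; its final round contains an altruist (node 5, g=1, l=0), an
#' egoist (node 4, g=0, l=1) and three fair players. Used throughout the
#' test suite as a fully hand-checkable oracle.
#'
#' @return A validated `coopnet_session`.
#' @export
make_fixture_session <- function() {
  cfg <- session_config(5L, n_rounds = 8L, treatment = "reciprocal",
                        candidate_sample_size = 4L)
  upd <- function(...) {
    m <- matrix(c(..., integer(0)), ncol = 3L, byrow = TRUE)
    data.frame(actor = as.integer(m[, 1L]), target = as.integer(m[, 2L]),
               action = c("add", "remove")[as.integer(m[, 3L])])
  }
  script <- list(
    upd(1, 2, 1,  1, 3, 1,  2, 1, 1,  3, 4, 1,  5, 1, 1),
    upd(2, 3, 1,  4, 5, 1,  5, 2, 1),
    upd(3, 4, 2,  3, 1, 1,  4, 1, 1),
    upd(1, 4, 1,  2, 3, 2),
    upd(4, 5, 2,  5, 2, 2),
    upd(4, 1, 2,  5, 1, 2),
    upd(5, 1, 1),
    upd())
  state <- initial_round_state(cfg)
  rounds <- list(state)
  events <- list()
  for (r in seq_along(script)) {
    state <- validate_and_apply_round(state, script[[r]], cfg, strict = TRUE)
    rounds[[r + 1L]] <- state
    acc <- attr(state, "accepted_updates")
    if (nrow(acc)) events[[length(events) + 1L]] <- cbind(round = r, acc)
  }
  s <- new_session(cfg, rounds, do.call(rbind, events),
                   metadata = list(label = "fixture", generator = "scripted"))
  validate_session(s)
  s
}

# -- deposited-dataset adapter ------------------------------------------

#' Read a directory of deposited session files
#'
#' Adapter for an unpacked archive of anonymized session data, one
#' sub-file per session named with a letter: sessions B-E belong to the
#' recipient-only treatment, F-J to the reciprocal treatment (sub-file A
#' is the format description and is skipped). Two layouts are accepted:
#'
#' * an event log with columns `round, actor, target, action`, replayed
#'   from the empty network; or
#' * per-round edge snapshots with columns `round, donor, recipient`
#'   (round 0 absent or empty), from which the event log is derived by
#'   diffing consecutive rounds.
#'
#' Any other column layout raises an unsupported-format error listing the
#' expected columns. Every adapted session is validated against all
#' structural invariants.
#'
#' @param directory directory containing files like `sessionB.csv` ...
#'   `sessionJ.csv` (the letter may appear anywhere in the name).
#' @param n_rounds number of rounds per session (default 60).
#' @return Named list of validated `coopnet_session` objects, tagged with
#'   treatment and source file in their metadata.
#' @export
read_deposited_dataset <- function(directory, n_rounds = 60L) {
  files <- list.files(directory, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  letters_found <- toupper(sub(".*([A-Ja-j])\\.(csv|tsv)$", "\\1", files))
  keep <- letters_found %in% LETTERS[2:10]
  files <- files[keep]; letters_found <- letters_found[keep]
  if (!length(files))
    stop("no session sub-files (B-J) found in ", directory, call. = FALSE)
  out <- list()
  for (i in seq_along(files)) {
    letter <- letters_found[i]
    treatment <- if (letter %in% c("B", "C", "D", "E")) "recipient_only"
                 else "reciprocal"
    out[[letter]] <- read_deposited_session(files[i], treatment, n_rounds)
  }
  out[order(names(out))]
}

read_deposited_session <- function(path, treatment, n_rounds) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  cols <- names(tab)
  if (all(c("round", "actor", "target", "action") %in% cols)) {
    ids <- sort(unique(c(tab$actor, tab$target)))
    n <- length(ids)
    ev <- data.frame(round = as.integer(tab$round),
                     actor = match(tab$actor, ids),
                     target = match(tab$target, ids),
                     action = as.character(tab$action))
  } else if (all(c("round", "donor", "recipient") %in% cols)) {
    ids <- sort(unique(c(tab$donor, tab$recipient)))
    n <- length(ids)
    ev <- events_from_snapshots(
      data.frame(round = as.integer(tab$round),
                 donor = match(tab$donor, ids),
                 recipient = match(tab$recipient, ids)), n, n_rounds)
  } else {
    stop("unsupported deposited-data layout in ", basename(path),
         ": expected columns (round, actor, target, action) or ",
         "(round, donor, recipient); got (", paste(cols, collapse = ", "),
         ")", call. = FALSE)
  }
  if (n < 3L)
    stop("fewer than 3 participants in ", basename(path), call. = FALSE)
  cfg <- session_config(n, n_rounds = n_rounds, treatment = treatment)
  rounds <- replay_events(cfg, ev)
  s <- new_session(cfg, rounds, ev,
                   metadata = list(label = basename(path),
                                   source = path, id_labels = ids,
                                   generator = "deposited-data adapter"))
  validate_session(s)
  s
}

# derive add/remove events by diffing consecutive per-round edge lists
events_from_snapshots <- function(snap, n, n_rounds) {
  prev <- integer(0)
  out <- list()
  for (r in seq_len(n_rounds)) {
    e <- snap[snap$round == r, , drop = FALSE]
    cur <- if (nrow(e)) (e$donor - 1L) * n + e$recipient else integer(0)
    added <- setdiff(cur, prev)
    removed <- setdiff(prev, cur)
    if (length(added) + length(removed)) {
      am <- code_to_edges(added, n); rm_ <- code_to_edges(removed, n)
      out[[length(out) + 1L]] <- data.frame(
        round = r,
        actor = c(am[, 1L], rm_[, 1L]),
        target = c(am[, 2L], rm_[, 2L]),
        action = rep(c("add", "remove"), c(length(added), length(removed))))
    }
    prev <- cur
  }
  if (!length(out))
    return(data.frame(round = integer(0), actor = integer(0),
                      target = integer(0), action = character(0)))
  do.call(rbind, out)
}

#' Export a session in the deposited event-log layout
#'
#' Writes the event log as a plain CSV with columns
#' `round, actor, target, action` — the layout [read_deposited_dataset()]
#' replays. Useful for building test corpora and for interchange.
#'
#' @param session a `coopnet_session`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_deposited_session <- function(session, path) {
  utils::write.csv(session$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export annotated events as CSV
#'
#' @param events annotated event data frame from [annotate_events()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export network snapshots of selected rounds
#'
#' Writes one edge-list file per requested round (TSV columns
#' `donor`, `recipient`), or GraphML when `format = "graphml"` and the
#' igraph package is available — mirroring the usual presentation of
#' session snapshots at rounds 0, 1, 2, 10 and 60.
#'
#' @param session a `coopnet_session`.
#' @param rounds integer vector of round indices to export.
#' @param dir output directory (created if missing).
#' @param format `"tsv"` or `"graphml"`.
#' @return Invisibly, the vector of files written.
#' @export
export_snapshots <- function(session, rounds = c(0, 1, 2, 10,
                                                 session$config$n_rounds),
                             dir = ".", format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rounds <- rounds[rounds >= 0 & rounds <= session$config$n_rounds]
  files <- character(0)
  for (r in rounds) {
    st <- session$rounds[[r + 1L]]
    path <- file.path(dir, sprintf("round_%03d.%s", r, format))
    if (format == "tsv") {
      utils::write.table(as.data.frame(st$edges), path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    } else {
      if (!requireNamespace("igraph", quietly = TRUE))
        stop("GraphML export requires the igraph package", call. = FALSE)
      gr <- igraph::graph_from_edgelist(
        matrix(as.character(st$edges), ncol = 2L), directed = TRUE)
      igraph::write_graph(gr, path, format = "graphml")
    }
    files <- c(files, path)
  }
  invisible(files)
}
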