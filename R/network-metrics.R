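#' Normalized generosity
#'
#' An individual's generosity is its number of recipients `g`; dividing by
#' the number of *other* participants, `n - 1`, makes sessions of
#' different size comparable (a value of 1 means the node donates to
#' everyone else).
#'
#' @param g out-degree (number of recipients), `0 <= g <= n - 1`.
#' @param n session size, at least 2. Vectorised over `g`.
#' @return `g / (n - 1)` in `[0, 1]`.
#' @export
normalized_generosity <- function(g, n) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (any(g < 0) || any(g > n - 1))
    stop("g must lie in [0, n - 1]", call. = FALSE)
  g / (n - 1)
}

#' Per-round mean normalized generosity of a session
#'
#' The average generosity of all participants is also the network density;
#' its rise and plateau describe the emergence of the cooperation network.
#'
#' @param session a `coopnet_session`.
#' @return Numeric vector with one value per stored round, starting at
#'   round 0 (always 0: the network starts disconnected).
#' @export
mean_generosity_series <- function(session) {
  n <- session$config$n_participants
  vapply(session$rounds,
         function(st) mean(normalized_generosity(st$g, n)), numeric(1))
}

#' Fraction of bidirectional links
#'
#' Direct reciprocation is measured as the fraction of directed links
#' whose reverse link is also present. With `mode = "dyad"` the statistic
#' is instead the fraction of connected dyads that are mutual (a
#' reciprocated pair counts once, not twice).
#'
#' @param edges two-column matrix of (donor, recipient) pairs.
#' @param n number of participants (needed to code edges; defaults to the
#'   largest index present).
#' @param mode `"link"` (default, fraction of links) or `"dyad"`.
#' @return Fraction in `[0, 1]`, or `NA` for an empty edge set (excluded
#'   from averages).
#' @examples
#' e <- rbind(c(1, 2), c(2, 1), c(1, 3))
#' bidirectional_fraction(e)  # 2/3
#' @export
bidirectional_fraction <- function(edges, n = NULL, mode = c("link", "dyad")) {
  mode <- match.arg(mode)
  m <- nrow(edges)
  if (is.null(m) || m == 0L) return(NA_real_)
  if (is.null(n)) n <- max(edges)
  codes <- edge_codes(edges, n)
  rev_codes <- (edges[, 2L] - 1L) * n + edges[, 1L]
  mutual <- sum(rev_codes %in% codes)
  if (mode == "link") mutual / m
  else (mutual / 2) / (m - mutual / 2)
}

#' Per-round bidirectional-link fraction of a session
#'
#' @inheritParams mean_generosity_series
#' @param mode see [bidirectional_fraction()].
#' @return Numeric vector, one value per stored round (`NA` for rounds
#'   with no links, notably round 0).
#' @export
bidirectional_series <- function(session, mode = c("link", "dyad")) {
  mode <- match.arg(mode)
  n <- session$config$n_participants
  vapply(session$rounds,
         function(st) bidirectional_fraction(st$edges, n, mode), numeric(1))
}

#' Random-graph null for the bidirectional fraction
#'
#' Under the null model, the `m` directed links are a uniform draw from
#' all `n * (n - 1)` ordered pairs without self-loops (out-degrees
#' unconstrained — the observed networks are compared against graphs with
#' "the same number of links" only). The expected bidirectional fraction
#' has the closed form `(m - 1) / (n * (n - 1) - 1)`: given a link, each
#' of the remaining `m - 1` links is its reverse with equal probability
#' over the remaining `N - 1` slots.
#'
#' @param n number of nodes.
#' @param m number of directed links, `1 <= m <= n * (n - 1)`.
#' @param reps Monte Carlo replicates.
#' @param seed optional RNG seed for reproducible draws.
#' @return List with `mean`, `sd`, `samples` (length `reps`) and
#'   `expected` (the closed form).
#' @export
reciprocity_null <- function(n, m, reps = 1000L, seed = NULL) {
  N <- n * (n - 1L)
  if (m < 1L || m > N) stop("m must lie in [1, n*(n-1)]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  # enumerate ordered non-self pairs and the index of each pair's reverse
  d <- rep(seq_len(n), each = n - 1L)
  r <- unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i)))
  code <- (d - 1L) * n + r
  rev_idx <- match((r - 1L) * n + d, code)
  samples <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(N, m)
    mean(rev_idx[idx] %in% idx)
  }, numeric(1))
  list(mean = mean(samples), sd = stats::sd(samples), samples = samples,
       expected = (m - 1) / (N - 1))
}

#' Stationary rounds of a series
#'
#' A round belongs to the stationary regime when the absolute value of the
#' numerical derivative of the series is below 10% of the maximum absolute
#' derivative. Derivatives are central differences, with one-sided
#' differences at the two endpoints. If the series is constant (maximum
#' derivative 0) every round is stationary.
#'
#' @param series per-round numeric values, length at least 3.
#' @param threshold fraction of the maximum absolute derivative below
#'   which a round counts as stationary (default 0.1).
#' @return Integer vector of stationary positions (1-based indices into
#'   `series`).
#' @export
stationary_rounds <- function(series, threshold = 0.1) {
  k <- length(series)
  if (k < 3L) stop("series must have length >= 3", call. = FALSE)
  d <- numeric(k)
  d[1L] <- series[2L] - series[1L]
  d[k] <- series[k] - series[k - 1L]
  if (k > 2L) d[2:(k - 1L)] <- (series[3:k] - series[1:(k - 2L)]) / 2
  dmax <- max(abs(d))
  if (dmax == 0) return(seq_len(k))
  which(abs(d) < threshold * dmax)
}

#' Stationary average of a series
#'
#' The arithmetic mean of the final `window` values (5 rounds by default).
#' A warning is raised when any of those rounds falls outside the
#' stationary regime detected by [stationary_rounds()].
#'
#' @param series per-round numeric values.
#' @param window number of trailing rounds to average (default 5).
#' @return The mean of the last `window` values.
#' @export
stationary_average <- function(series, window = 5L) {
  k <- length(series)
  if (k < window) stop("series shorter than the averaging window", call. = FALSE)
  idx <- (k - window + 1L):k
  if (k >= 3L && !all(idx %in% stationary_rounds(series)))
    warning("averaging window extends outside the stationary regime",
            call. = FALSE)
  mean(series[idx])
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation, used to measure how closely a
#' participant's per-round recipient and provider counts track each other.
#' Count series are heavily tied, hence the tau-b variant.
#'
#' @param x,y numeric vectors of equal length, at least 2.
#' @return tau-b in `[-1, 1]`, or `NA` when either input has zero
#'   variance (excluded from session averages).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

#' Recipient-provider coupling per participant
#'
#' For every participant, the Kendall tau-b correlation between its
#' per-round number of recipients (g) and providers (l) across rounds
#' 1..n_rounds. Strong positive values mean the two counts move together:
#' generosity is compensated by incoming donations.
#'
#' @param session a `coopnet_session`.
#' @return Data frame with columns `participant` and `tau` (`NA` where a
#'   count series is constant); the session mean ignores `NA`s.
#' @export
recipient_provider_tau <- function(session) {
  n <- session$config$n_participants
  gs <- vapply(session$rounds[-1L], function(st) st$g, numeric(n))
  ls <- vapply(session$rounds[-1L], function(st) st$l, numeric(n))
  tau <- vapply(seq_len(n), function(i) {
    if (stats::var(gs[i, ]) == 0 || stats::var(ls[i, ]) == 0) NA_real_
    else kendall_tau(gs[i, ], ls[i, ])
  }, numeric(1))
  data.frame(participant = seq_len(n), tau = tau)
}

#' Behavioural-type series of a session
#'
#' The per-round mean of `L = (g - l) / (g + l)` over connected
#' participants (isolated nodes are excluded; a round where everyone is
#' isolated yields `NA`), plus the per-round, per-participant values and
#' class labels.
#'
#' @param session a `coopnet_session`.
#' @return List with `mean_L` (numeric, one entry per stored round) and
#'   `types` (long data frame: `round`, `participant`, `L`, `type`).
#' @export
behavioural_type_series <- function(session) {
  rows <- lapply(session$rounds, function(st) {
    L <- behavioural_type(st$g, st$l)
    data.frame(round = st$round_index,
               participant = seq_along(L),
               L = L,
               type = classify_type(L))
  })
  types <- do.call(rbind, rows)
  mean_L <- vapply(session$rounds, function(st) {
    L <- behavioural_type(st$g, st$l)
    if (all(is.na(L))) NA_real_ else mean(L, na.rm = TRUE)
  }, numeric(1))
  list(mean_L = mean_L, types = types)
}

#' Flat metrics report for one session
#'
#' A long key-value table of the session-level statistics: the
#' per-round mean generosity, bidirectional fraction and mean behavioural
#' type, their stationary (last-5-round) averages, and the mean
#' recipient-provider Kendall tau.
#'
#' @param session a `coopnet_session`.
#' @param label session label; defaults to the metadata label.
#' @param window trailing window for stationary averages (default 5).
#' @return Data frame with columns `session`, `treatment`, `metric`,
#'   `round` (`NA` for stationary/aggregate values) and `value`.
#' @export
metrics_report <- function(session, label = NULL, window = 5L) {
  if (is.null(label))
    label <- if (!is.null(session$metadata$label)) session$metadata$label else ""
  tr <- session$config$treatment
  gen <- mean_generosity_series(session)
  bid <- bidirectional_series(session)
  bts <- behavioural_type_series(session)$mean_L
  rounds <- vapply(session$rounds, function(s) s$round_index, integer(1))
  long <- function(metric, value, round = NA_integer_)
    data.frame(session = label, treatment = tr, metric = metric,
               round = round, value = value)
  tau <- recipient_provider_tau(session)$tau
  rbind(
    long("mean_generosity", gen, rounds),
    long("bidirectional_fraction", bid, rounds),
    long("mean_L", bts, rounds),
    long("stationary_generosity", stationary_average(gen, window)),
    long("stationary_bidirectional",
         stationary_average(bid[-1L], window)),
    long("stationary_mean_L", stationary_average(bts[-1L], window)),
    long("mean_recipient_provider_tau", mean(tau, na.rm = TRUE)))
}
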