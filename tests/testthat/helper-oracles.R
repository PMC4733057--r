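# Independent oracles used across the suite. These deliberately use the
# slowest, most transparent formulation of each quantity.

# Kendall tau-b by explicit O(n^2) pair counting with tie correction.
kendall_pair_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      if (a == 0) tie_x <- tie_x + 1
      if (b == 0) tie_y <- tie_y + 1
      if (a * b > 0) conc <- conc + 1
      if (a * b < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Exact two-sided binomial p-value against 1/2 by direct tail summation.
binom_tail_oracle <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  lower <- sum(pmf[1:(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# Expected bidirectional fraction of a uniform random directed graph with
# exactly m edges, by exhaustive enumeration of all edge sets.
null_enumeration_oracle <- function(n, m) {
  d <- rep(seq_len(n), each = n - 1L)
  r <- unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i)))
  code <- (d - 1L) * n + r
  rev_code <- (r - 1L) * n + d
  sets <- utils::combn(length(code), m)
  mean(apply(sets, 2L, function(idx)
    mean(rev_code[idx] %in% code[idx])))
}

# A small session with a non-trivial payoff spread, built by hand.
make_spread_state <- function() {
  cfg <- session_config(5L, n_rounds = 4L, candidate_sample_size = 4L)
  st <- initial_round_state(cfg)
  upd <- data.frame(actor = c(2L, 3L, 3L, 1L),
                    target = c(1L, 1L, 4L, 4L),
                    action = "add")
  list(config = cfg, state = validate_and_apply_round(st, upd, cfg))
}

sim_small <- function(treatment = "recipient_only",
                      preset = paste0(treatment, "_default"),
                      n = 12L, rounds = 12L, seed = 42L) {
  if (treatment == "reciprocal" && preset == "reciprocal_default")
    preset <- "reciprocal_default"
  simulate_session(session_config(n, n_rounds = rounds, treatment = treatment),
                   behaviour_preset(preset), seed = seed)
}
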