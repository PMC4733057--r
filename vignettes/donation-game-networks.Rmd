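---
title: "Cooperative actions as directed links: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative actions as directed links: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopnet)
```

## The model

coopnet studies social networks that are *built from* cooperative acts
rather than overlaid on them. A single act — paying a cost $c$ to provide
a benefit $b > c$ — is a directed link from donor to recipient, and the
link keeps paying every round until the donor removes it. The network
therefore *is* the record of who currently helps whom; there is no
separate strategy variable.

Per round, a participant with $g$ recipients (outgoing links, its
**generosity**) and $l$ providers (incoming links) earns

$$\pi = l\,b - g\,c,$$

with $b = 2$, $c = 1$ by default, on top of a starting endowment of
1000 tokens. Each participant may add and/or remove up to two outgoing
links per round; all decisions of a round are evaluated against the
start-of-round network and applied simultaneously. Because every actor
controls only its own outgoing links, simultaneous updates cannot
collide.

The local structure encodes a behavioural type,

$$L = \frac{g - l}{g + l} \in [-1, 1],$$

with altruists ($L > 1/3$), fair players ($|L| \le 1/3$) and egoists
($L < -1/3$). $L$ is undefined for isolated nodes ($g + l = 0$) and such
nodes are excluded from all averages.

Two information treatments are modelled. In the **recipient-only**
treatment a participant sees its recipients and a fresh random sample of
*candidates* (nodes it does not currently support); provider identities
are hidden, so intentional direct reciprocation is impossible. In the
**reciprocal** treatment providers are visible as well, and nodes that
are simultaneously provider and recipient are grouped as *reciprocators*.

## Session-level statistics

* **Density / mean generosity.** Individual generosity is normalized by
  the number of *other* participants, $g/(n-1)$, so that sessions of
  different size are comparable; the per-round mean is the network
  density (`mean_generosity_series()`).
* **Stationarity.** A round is stationary when the absolute numerical
  derivative of the density series is below 10% of the maximum absolute
  derivative (`stationary_rounds()`). Central differences are used, with
  one-sided differences at the endpoints; this choice is reported so
  alternative schemes can be compared. For a constant series the rule is
  degenerate and every round counts as stationary. Summary values are
  averaged over the final five rounds (`stationary_average()`), which
  warns if that window leaves the detected stationary regime — on noisy
  session-level series single rounds can exceed the 10% cut even deep in
  the plateau, which is why the warning is advisory rather than an error.
* **Direct reciprocation.** The fraction of directed links whose reverse
  link exists (`bidirectional_fraction()`). The quoted definition is a
  fraction *of links*; a dyad-based variant (a mutual pair counted once)
  is available behind `mode = "dyad"`. The random baseline
  (`reciprocity_null()`) draws edge sets of exactly $m$ ordered non-self
  pairs uniformly — the null constrains only the *number* of links, not
  degrees (a degree-preserving null would answer a different question).
  Its expectation has the closed form $(m-1)/(n(n-1)-1)$, which the
  Monte Carlo sampler is tested against.
* **Recipient–provider coupling.** Per participant, the Kendall
  correlation between its per-round $g$ and $l$ series
  (`recipient_provider_tau()`). Count series are heavily tied, so the
  tie-corrected $\tau_b$ variant is used.

## Link-update event analysis

Every validated add/remove event is annotated with the target category
and the differences $\Delta g = g_\text{target} - g_\text{actor}$ and
$\Delta\pi = \pi_\text{target} - \pi_\text{actor}$, computed from the
state of the round *preceding* the decision — exactly what the interface
displayed. Previous-round payoff is used, never cumulative tokens, which
participants could not see. The first ten rounds are excluded from event
statistics (`filter_rounds()`): they are dominated by the build-up from
the empty network.

From the joint histogram $p(\Delta g, \Delta\pi)$ and its marginals,
preference proportions are computed over events with a *nonzero* delta;
zero-delta events are counted and reported but excluded from tests, as
they carry no directional information. The proportion is tested against
the no-preference null of 0.5 with an exact binomial test; the two-sided
p-value is defined as the doubled smaller tail capped at 1, which for a
symmetric null coincides with `binom.test()`. Removal events in the
reciprocal treatment are split by whether the target was also a provider
of the actor in the preceding round (`split_by_reciprocation()`); the
split is an error on recipient-only sessions, where subjects could not
observe it, unless explicitly forced for diagnostics. Pooled proportions
pool raw events across sessions within a treatment (per-session values
are also available); per-participant preference labels use the strict
majority of an actor's nonzero-delta events, with ties and empty sets
labelled `no_preference`.

## The synthetic-session generator

`simulate_session()` produces sessions with the statistical structure the
analysis pipeline assumes. Each agent, per round and per update slot:

1. acts with probability `p_use_slot` (otherwise the slot is renounced);
2. chooses addition vs removal; when both are feasible the effective add
   probability is the relative-propensity mix
   $p_\text{add}(\hat g) = \frac{p(1-\hat g)}{p(1-\hat g) + (1-p)\hat g}$,
   where $\hat g$ is the agent's displayed normalized generosity and
   $p$ = `p_add_given_both`. Additions and removals balance exactly where
   $p_\text{add} = 1/2$, i.e. at density $\hat g = p$, so
   `p_add_given_both` *is* the stationary density of the session. (A
   linearly decreasing form was considered but cannot reach a stationary
   density above 0.5 with a probability-valued parameter.) At full
   saturation the add branch falls through to remove-or-renounce.
3. picks a target by sign-stratification: the desired sign of
   $\Delta\pi$ (and, for removals, of $\Delta g$) is decided first, then
   the target is drawn uniformly inside that stratum, falling back to
   equal-valued targets and then the opposite stratum when it is empty.
   For removals both signs are drawn and the target comes from the
   intersection when possible. Additions carry no generosity preference:
   their $\Delta g$ marginal is held neutral at 0.5, matching the absence
   of a generosity effect on additions.

Uniform choice over the whole pool would *not* be neutral: conditioning
on link existence shifts the deltas (a recipient has, by construction,
one extra provider and hence a higher expected payoff than an otherwise
identical node), and agents below their equilibrium generosity add more
often, so add events oversample less generous actors. Sign-stratification
makes the recorded sign an explicit decision rather than a by-product of
pool composition.

Within `simulate_session()` the sign decisions come from a session-level
quota controller: for each contract (addition payoff sign, removal payoff
sign, removal generosity sign per reciprocator/non-reciprocator pool, and
the neutral addition generosity sign) it tracks the running frequency of
recorded nonzero-delta signs and picks the sign that keeps that frequency
closest to the configured probability, breaking ties with a Bernoulli
draw. This matters because preferred strata are not always available —
an agent at the top of the payoff ranking has no better-off recipient to
drop, and with a homogeneous agent population payoff and generosity are
negatively associated among reciprocators, so the "more generous and
better off" corner is empty in roughly half of the decisions. Events
forced onto the other side by such unavailability are compensated by
later decisions, and the session-level sign frequencies converge to the
configured parameters — which is precisely the parameter-recovery
contract the event-analysis tests exercise. Used stand-alone,
`choose_updates()` draws independent Bernoulli signs instead.

### Parameter presets

| parameter | recipient_only_default | reciprocal_default | random_neutral |
|---|---|---|---|
| `p_use_slot` | 0.7 | 0.7 | 0.7 |
| `p_add_given_both` (stationary density) | 0.62 | 0.69 | 0.5 |
| `q_add_lower_payoff` | 0.60 | 0.61 | 0.5 |
| `q_remove_higher_payoff` | 0.67 | 0.59 | 0.5 |
| `q_remove_less_generous` | 0.56 | 0.71 | 0.5 |
| `q_remove_more_generous_reciprocal` | — | 0.73 | 0.5 |
| `q_secure_provider` | 0 | 0.45 | 0.5 |

The `q` values and stationary densities are the observed session
statistics of the two treatments; `q_secure_provider = 0.45` reflects
that additions go to candidates slightly more often than to providers.
`p_use_slot = 0.7` is a free choice (round-level activity is not pinned
down by a single published number) giving roughly 30% renounced slots
and late-round add/remove counts of similar size. The number of
candidates displayed per round is likewise not fixed by the experimental
record; `candidate_sample_size = 8` is the package default and is
reported with results.

### What the generator does and does not emulate

Simulated sessions reproduce: the rise of density from an empty network
to a treatment-dependent plateau, approximate fairness ($\bar L \approx
0$), conserved token accounting, and event-level sign statistics at the
configured rates; neutral agents sit inside the random-graph reciprocity
band. They do *not* emulate: heterogeneous participants (a single
parameter set drives all agents, so the between-individual variance of
generosity — and with it the strong empirical recipient–provider
coupling — is understated), learning or adaptation across rounds,
within-round timing, or end-game effects. One visible consequence:
because payoff-biased removals preferentially hit better-off targets and
mutual partnerships make both sides better off, biased presets can push
direct reciprocation *below* the random baseline, whereas human sessions
sit clearly above it — reproducing that surplus would require retaliation
or partner-loyalty mechanisms the parameter set deliberately omits.
Passing tests on synthetic sessions therefore validate the pipeline's
arithmetic and the generator's contracts, not behavioural claims about
human play.

## Numerical and design notes

* Degenerate inputs: empty edge sets yield `NA` reciprocity (excluded
  from averages); all-isolated rounds yield `NA` mean $L$; constant
  series are wholly stationary; zero-variance count series yield `NA`
  Kendall correlation, excluded from session means.
* Invalid recorded updates (cap violations, duplicate links, self-links,
  removals of absent links) are dropped with a reason attached, so
  recorded data replays robustly; the simulator runs in strict mode and
  treats any such event as a bug.
* Reproducibility: a session is a pure function of (config, parameters,
  seed); sessions are replayed from their event log on every read, and
  the replay must reproduce each stored edge list exactly.
* Test problem sizes: the suite simulates sessions of 10–30 participants
  over 6–60 rounds, uses 10,000 Monte Carlo replicates for the
  reciprocity null at (n = 30, m = 500), enumerates all two-colour edge
  sets exhaustively up to n = 4, and checks the exact binomial p-value
  against direct tail summation for all n ≤ 25.

## A worked round

```{r}
cfg <- session_config(7, benefit_b = 2, cost_c = 1, endowment = 1000)
state <- initial_round_state(cfg)
updates <- data.frame(actor  = c(1, 1, 4, 5, 6, 7),
                      target = c(2, 3, 1, 1, 1, 1),
                      action = "add")
state1 <- validate_and_apply_round(state, updates, cfg)
c(g = state1$g[1], l = state1$l[1],
  payoff = state1$round_payoff[1], tokens = state1$cumulative_tokens[1])
```

Participant 1 supports two others (cost 2), is supported by four
(benefit 8), earns 6 tokens in the round and starts the next one with
1006 tokens.

## A full pipeline run

```{r}
s <- simulate_session(session_config(30, treatment = "reciprocal"),
                      behaviour_preset("reciprocal_default"), seed = 1)
gen <- mean_generosity_series(s)
suppressWarnings(stationary_average(gen))

ev <- filter_rounds(annotate_events(s))
preference_proportion(ev[ev$action == "add", ], "payoff")[c("proportion", "p_value")]

m <- nrow(s$rounds[[61]]$edges)
obs <- bidirectional_fraction(s$rounds[[61]]$edges, n = 30)
null <- reciprocity_null(30, m, reps = 2000, seed = 2)
c(observed = obs, null_expected = null$expected)
```
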