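---
title: "Cleavage entropy: quantifying protease substrate specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleavage entropy: quantifying protease substrate specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavent)
```

## The model

A protease reads its substrate through binding subpockets that contact the
eight residues flanking the scissile bond; following the Schechter-Berger
convention these substrate positions are P4, P3, P2, P1 on the N-terminal
(non-prime) side and P1', P2', P3', P4' on the C-terminal side, with
cleavage between P1 and P1'. A specific protease tolerates few residues at
a subpocket; a promiscuous one tolerates many. cleavent turns a table of
experimentally observed cleavage windows into a quantitative specificity
score per subpocket.

For each subpocket $i$, raw occurrence counts $c_{a,i}$ of the 20 canonical
amino acids are normalized in two stages: first by the background abundance
$f_a$ of each amino acid, then each column is rescaled to sum to one,

$$p_{a,i} = \frac{c_{a,i}/f_a}{\sum_b c_{b,i}/f_b}.$$

The subpocket cleavage entropy is the normalized Shannon entropy

$$S_i = -\sum_{a} p_{a,i}\,\ln p_{a,i} \,/\, \ln 20,$$

with $0\ln 0 := 0$ by continuity. $S_i = 0$ means a perfectly conserved
residue; $S_i = 1$ means the observed distribution is indistinguishable
from background. The abundance division is what shifts the "unspecific"
endpoint from *uniform* to *background-like*: a subpocket whose counts are
exactly proportional to $f_a$ normalizes to the uniform column and scores
exactly 1. The total cleavage entropy

$$S_\mathrm{cleavage} = \sum_{i \in \{P4 \ldots P4'\}} S_i \in [0, 8]$$

ranks whole proteases, from highly specific signaling enzymes to
promiscuous digestive ones.

Cooperative readout between two subpockets $i, j$ is scored on the joint
20 x 20 residue-pair distribution, normalized against the independence
product $f_a f_b$ of the background,

$$S_{i,j} = -\sum_{a,b} q_{ab}\,\ln q_{ab} \,/\, \ln 400, \qquad
q_{ab} \propto c_{ab} / (f_a f_b),$$

so that 0 marks a conserved residue pair and 1 a pair distribution expected
by chance. A perfectly coupled pair with uniform marginals (20 equiprobable
pairs out of 400) scores $\ln 20 / \ln 400 = 0.5$ even though both marginal
entropies are 1 — that gap is the cooperativity signal. Because the joint
table has 400 cells rather than 20, pairs are gated by a much stricter
substrate cutoff (default 10 000 effective observations vs 100 records for
the one-dimensional analysis); gated pairs carry no value rather than a
noisy one.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_substrates` | 100 | inclusive per-protease record cutoff; fewer records make the 20-bin distribution too noisy to score |
| `min_pair_substrates` | 10000 | inclusive cutoff on *effective* pair totals (records canonical at both positions), matching the 1-D statistics scaled to 400 cells |
| `yellow_cutoff` | 0.85 | subpocket label boundary, inclusive: `S_i <= 0.85` is "specific" |
| `red_cutoff` | 0.5 | strict: `S_i < 0.5` is "highly specific" |
| `specific_cutoff` | 6.8 | strict protease-level boundary (average subpocket entropy 0.85 over 8 subpockets) |
| `highly_cutoff` | 4.0 | strict protease-level boundary (average subpocket entropy 0.5) |
| abundance source | `"mccaldon"` | background frequencies; `"uniform"` makes normalization a no-op |

The asymmetric boundary semantics (0.85 inclusive, all others strict) follow
the conventional definitions of the thresholds literally; both are
configurable. All units are dimensionless (entropies are normalized).

Group summaries use the sample (n−1) standard deviation by default — the
choice is recorded in the output and switchable to population — and a group
of one member reports sd 0 alongside `n = 1` rather than `NA`, so downstream
tabulation never mixes types. Ranking ties are broken lexicographically by
protease identifier for reproducibility.

## Handling of real-data imperfections

Experimental windows near a substrate terminus have fewer than eight
residues; the missing slots are marked with a gap symbol. Ambiguity codes
(X, B, Z, J, U, O) are treated as unresolved. Both are excluded *per
position* rather than discarding the whole record: every subpocket (and
every subpocket pair) has its own effective total, which is what the count
cutoffs are applied to. A subpocket with zero effective counts is flagged
unavailable, and totals over fewer than eight subpockets are refused unless
explicitly requested as partial (then annotated with the number of summed
subpockets), because a silent partial sum would corrupt rankings.
Duplicate windows are counted as often as they appear; no deduplication
rule is imposed. Proteases that systematically leave subpockets unoccupied
(methionyl aminopeptidases) are removed by an explicit identifier list, not
auto-detection — the package has no enzyme-class ontology.

## What the synthetic generators emulate

The generators produce cleavage tables with controlled statistical
structure so every scoring stage is testable without any external
database:

* `generate_conserved()` — fixed residues at chosen subpockets (the
  $S_i = 0$ endpoint; with all eight slots mapped, the
  $S_\mathrm{cleavage} = 0$ endpoint).
* `generate_background()` — every position follows the background (the
  $S_i = 1$, $S_\mathrm{cleavage} = 8$ endpoint).
* `generate_motif_mixture()` — fraction $q$ of records carry a conserved
  motif, the rest are background; motif-position entropy decreases
  monotonically in $q$, emulating a trypsin-like conserved-P1 preference.
* `generate_coupled_pair()` — a bijective coupling between two subpockets
  with uniform marginals ($S_{i,j} = 0.5$, $S_i = S_j = 1$).
* `generate_independent_pair()` — one pair's joint counts exactly
  proportional to $f_a f_b$ ($S_{i,j} = 1$).

Each generator has two modes. `"sampled"` draws i.i.d. records and shows
realistic sampling noise; `"expected_counts"` allocates the target
distribution deterministically by largest-remainder rounding (ties broken
in alphabet order, per-cell error strictly below 1), which makes the
analytic endpoints exact rather than stochastic and the endpoint tests
non-flaky. Every generator is deterministic given its seed, restores the
caller's RNG state, and emits the same TSV dialect the reader parses, with
the generating spec echoed in `#` provenance header lines.

What the generators do **not** emulate: affinity- or turnover-weighted
substrate sampling, correlated position structure beyond a single coupled
pair, database biases (over-representation of well-studied substrates),
or secondary-structure context. A green endpoint test therefore
establishes the scoring arithmetic, not the biological fidelity of any
particular database snapshot.

## Numerical choices

* Probability columns are validated to sum to 1 within 1e-9; entropy
  identities are asserted at 1e-12 (double-precision headroom).
* The log base is configurable and provably irrelevant — computing with
  base 2, e, or 10 with a matching normalizer yields identical scores —
  which the suite checks.
* A subtlety of exactness: integer counts can be *exactly* proportional to
  the background only when every $n f_a$ is an integer. The exact-endpoint
  fixtures therefore use the uniform background at $n$ divisible by 20
  (400 for pairs); with the packaged natural-abundance table the
  largest-remainder allocation attains $|S_i - 1| \lesssim 10^{-6}$ at
  $n = 2000$, a bound the tests assert rather than gloss over.
* Conserved columns produce IEEE `-0` from the negated empty sum; the
  entropy functions normalize it to `+0`.

## Design choices where the design was open

* The background reference cites but does not print its values; the
  packaged table is transcribed from the cited abundance survey
  (McCaldon & Argos 1988) and renormalized over the 20 canonical residues
  on load. No test depends on the transcription; analytic tests use the
  uniform background.
* The "equal distribution scores 1" endpoint is interpreted on the
  *normalized* probabilities — in raw-count terms the maximum is attained
  by abundance-proportional counts — which reconciles the one-dimensional
  endpoint with the pairwise "expected by random chance from natural
  abundance" endpoint.
* The pairwise diagonal ($i = j$) is excluded rather than defined: the
  joint of a position with itself is degenerate, and the report layout
  carries the single-subpocket entropies as a separate row instead.
* The expected-by-chance pair background is the independence product
  $f_a f_b$; no joint background table exists to do better.
* The pair cutoff applies to effective pair totals, not raw record counts,
  so gaps weaken a pair's evidence exactly as they weaken a column's.

## Known limitations

Entropies are estimated by plug-in from finite counts and are biased
downward at small n — the count cutoffs bound but do not remove this.
Substrates contribute equally regardless of cleavage efficiency;
affinity-weighted scoring would need data the method does not assume.
Higher-order (3+ subpocket) cooperativity and significance testing of
pairwise effects are out of scope, as are phylogenetic analysis and
3-D structure mapping.

## A worked run

```{r example}
bg <- load_abundance("uniform")

# a trypsin-like synthetic protease: conserved K at P1, 60% motif fraction
rec <- generate_motif_mixture(c(P1 = "K"), q = 0.6, n = 5000, bg = bg,
                              mode = "expected_counts", seed = 42)
prof <- compute_profile(rec, bg = bg)
prof
classify_subpocket(prof$S_i[["P1"]])
classify_protease(prof$S_cleavage)
```

The P1 entropy reflects the 60/40 motif mixture exactly (closed form:
entropy of $0.6\,e_K + 0.4/20$, i.e. 0.595), while the unconstrained
subpockets sit at or just below 1 — the background block is allocated
exactly, but the motif records' unconstrained positions are sampled, so a
trace of sampling noise remains.
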