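---
title: "Connectivity scoring of transcriptome signatures: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity scoring of transcriptome signatures: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconnect)
```

## The problem

Drug-repurposing by signature matching asks: given a disease state
summarized as a transcriptome signature — a set of up-regulated and a set
of down-regulated genes — which compounds in a reference database of
drug-perturbation experiments induce transcriptional changes that *oppose*
that state? A compound that pushes the disease's up genes down and its
down genes up is a repurposing candidate; a compound whose changes overlap
the disease profile is a candidate model of the disease. The same
machinery, run with a drug's own signature as the query, finds the drug's
transcriptional neighbours, and over-represented pharmacological classes
among those neighbours suggest a mechanism of action.

`sigconnect` implements this pipeline end to end: signature construction,
a ranked-profile instance database, the bidirectional Kolmogorov–Smirnov
(KS) connectivity score, compound-level aggregation with empirical
permutation p-values, mechanism-of-action tallies, and a synthetic
database generator with planted ground truth that makes every stage
testable offline.

## The scoring model

**Instances and ranks.** One *instance* is one treatment experiment
(compound, cell line, arrays), represented as a permutation of the probe
universe: rank 1 is the probe most up-regulated by the treatment, rank
$n$ the most down-regulated. Ranking makes scoring free of normalization
details — any strictly increasing transform of the underlying amplitudes
yields the same profile, a property the test suite checks directly. The
rank direction is a convention the sign of every downstream score depends
on; `sigconnect` fixes 1 = most up-regulated.

**KS tag-set statistic.** For a tag set occupying ascending ranks
$V_1 < \dots < V_t$ of a list of length $n$:

$$a = \max_{j=1..t}\left(\tfrac{j}{t} - \tfrac{V_j}{n}\right),\qquad
  b = \max_{j=1..t}\left(\tfrac{V_j}{n} - \tfrac{j-1}{t}\right),\qquad
  es = \begin{cases} a & a \ge b\\ -b & a < b\end{cases}$$

$es \in [-1, 1]$; $+1$ means the tags sit at the very top. This is the
signed sup-deviation between the tag empirical step function and the
uniform reference; the suite verifies the closed form against a
brute-force evaluation of that sup at every rank, exactly, on 1000 random
cases.

**Raw score and null instances.** Per instance, $s = es_{up} - es_{down}$
when the two sides deviate in opposite directions, and $s = 0$ when they
share a strict sign — a contradictory pattern carries no directional
evidence ("null instance"). Two boundary rules are deliberate: a side
statistic of exactly 0 does *not* null the score (nulling a measure-zero
case would discard the other side's information), and a one-sided query
scores as the $es$ of its only side. Because the one-sided rule returns
the raw $es$ rather than a sign-adjusted version, the up/down-swap
antisymmetry property ($s \mapsto -s$) holds for two-sided signatures,
which is how it is tested.

**Connectivity score.** Raw scores are scaled database-wide:
$c = s/p_{max}$ for $s > 0$ and $c = -s/q_{min}$ for $s < 0$, with
$p_{max}$ / $q_{min}$ the extreme raw scores over *all* instances for this
query. Scaling per database, not per compound, keeps $c$ comparable
across compounds, and guarantees the extreme instances attain $\pm 1$.

**Aggregation.** Groups are compound × cell line by default (published
result tables name groups that way; plain-compound grouping is an
option). The *similarity mean* is the arithmetic mean of member $c$
values, including null instances by default — the reported $N$ ("number
of arrays") counts all member instances — with a toggle to exclude them
(the non-null count is always reported). If exclusion leaves a group with
no non-null members its similarity mean is defined as 0.

**Enrichment and permutation p.** All $N$ instances are ordered by $c$
descending, ties broken deterministically by instance identifier, and a
group's *enrichment* is the KS statistic of its member positions in that
ordering. Its p-value is empirical: draw `n_perm` uniform random
same-size position sets (100 000 by default) and report the fraction at
least as extreme as observed. When $\binom{N}{t}$ does not exceed the
enumeration cap (100 000), all subsets are enumerated and the p-value is
exact at the same cost. p = 0 is reported verbatim; a pseudo-count mode
`(count+1)/(n_perm+1)` is available but off by default.

Two tail conventions are implemented because the choice is genuinely
open. The default `signed` rule counts draws with the same sign and at
least the observed magnitude; under a fully null database this makes
p-values approximately uniform on $[0, \Pr(\text{sign match})] \approx
[0, 0.5]$, i.e. conservative two-sided behaviour compressed into a
half-range. The `absolute` rule counts magnitude regardless of sign and
is the calibrated choice: under the null its p-values are approximately
uniform on $[0,1]$, which is what the calibration checks in the test
suite assert. Neither rule is claimed to reproduce any particular
historical service's convention.

**Ranking.** Final order: p-value ascending, then $|enrichment|$
descending, then $|similarity\ mean|$ descending, then group key
lexicographically. All floating ties everywhere in the engine resolve
deterministically (the $a = b$ KS tie takes the positive branch, and both
deviations are exposed in the result so tie cases are auditable).

## Signature construction

*Disease signatures* select genes at `qvalue <= q_threshold`, split by
fold-change sign, ordered by effect size, optionally truncated to the
`top_k` strongest per side. *Drug signatures* rank probes by the
difference of treated and control row means (matrices assumed log-scale;
a log-ratio of linear intensities is behind a switch) and select by rank
counts (default top/bottom 50) or absolute cutoffs. The defaults are
configuration, not a claim about any specific published threshold scheme,
which is why the selection rule is recorded in the signature's
provenance.

*Probe mapping* is a pure offline table join with optional case folding
(mouse→human symbol convention): one-to-many expansion, unmapped genes
dropped and counted, and any probe reachable from both sides removed from
both with a conflict count — the conservative way to preserve the
disjointness invariant. A mapping can legitimately produce an empty
signature; it is the one constructor path allowed to, and it attaches the
full drop/conflict report instead of failing.

## The synthetic database

The generator emulates exactly the structure the engine consumes. Per
probe a shared baseline $b_g \sim N(\mu_0, \sigma_0^2)$; per instance a
control value $b_g + \varepsilon$ and a treated value
$b_g + \textit{effect}_{kg} + \varepsilon'$ with independent
$N(0, \sigma^2)$ noise; the amplitude is their difference (the baseline
cancels — it is kept for realism of the written matrices), and the effect
is $+\delta$ on a planted compound's up set, $-\delta$ on its down set,
and 0 elsewhere. Planted compounds are `concordant`, `oppositional`, or
`null`; `make_planted_query()` returns the signature that should retrieve
them with positive (sets copied) or negative (sets swapped) similarity.

Defaults are the reference regime used across the suite: $G = 1000$
probes, $K = 50$ compounds × $m = 4$ instances, tag sets of $t = 100$
(50 up + 50 down), $\delta = 2$ against per-value $\sigma = 1$ — an
amplitude shift of 2 against paired-noise sd $\sqrt 2$, strong but not
deterministic. The baseline ($\mu_0 = 7$, $\sigma_0 = 1.5$) is a
realistic log2-intensity scale chosen once; it does not influence ranks.

Instance identifiers are accession-style and assigned in shuffled
(seeded) order. This matters: the connectivity ordering breaks ties by
instance identifier, and under a null query roughly half of all instances
tie at $c = 0$. Identifiers that sorted by compound would cluster a
compound's members inside that tie block and bias the group enrichment;
accession-style ids, as real databases use, keep tie resolution unrelated
to group structure.

What the simulator does *not* model — and hence what passing tests do not
show about real data: probe-level affinity effects, correlated gene
modules, batch and cell-line covariance, dose structure, and raw-array or
RNA-seq count noise. It validates the *scoring machinery* (recovery,
calibration, symmetries, determinism), not biological generalization.

## Problem sizes and numerical choices

The suite and the acceptance script run, as the package's reference
checks: 1000-case KS oracle equivalence; the $N = 5$ exact-enumeration
permutation example against its 100 000-draw sampling estimate; 100
seeded planted-recovery runs at the default regime with `n_perm` 10 000;
one no-effect database of $K = 200$ groups ($m = 4$, $G = 500$) with
`n_perm` 20 000 for calibration (fraction of p < 0.05 within the 99%
binomial region around 0.05, and a uniformity goodness-of-fit at
$\alpha = 0.01$ under the absolute tail); and a byte-identity rerun for
determinism. `run_query()` computes the permutation null once per
distinct group size from one seeded stream and shares it across groups of
that size — marginal p-values are unchanged and a 200-group query costs
one null distribution, not 200.

## Limitations

- The raw-score rule for one-sided queries follows the simple convention
  above; one-sided down-only queries report the down-side $es$ with its
  native sign, so their interpretation differs from the two-sided score.
- Group p-values are raw empirical values, deliberately without
  multiple-testing adjustment; specificity-style statistics beyond the
  non-null count and weighted (L1000-style) connectivity variants are out
  of scope.
- The mechanism-of-action tally is descriptive; the hypergeometric
  over-representation tail is an optional extension, computed over
  distinct compound names against a user-supplied background.
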