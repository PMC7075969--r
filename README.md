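# sigconnect

Transcriptome-signature connectivity scoring for in-silico drug
repurposing and mechanism-of-action inference.

## What problem this solves

A disease state (for instance the transcriptome of *Fmr1*-knockout
neurons in a fragile X syndrome model) can be summarized as a
**gene signature**: the set of up-regulated and the set of down-regulated
genes versus control. A reference database holds thousands of
**instances** — drug-perturbation experiments, each stored as a ranked
list of probes ordered by treatment-induced expression change. Compounds
whose instances *reverse* the disease signature (up genes driven down and
vice versa) are repurposing candidates; querying with a drug's own
signature instead retrieves its transcriptional neighbours, whose shared
pharmacological classes hint at the drug's mechanism of action.

`sigconnect` is for computational biologists who want this analysis as a
tested, scriptable package rather than a web form: it builds signatures
from differential-expression tables or treated/control matrices, maps
them across identifier namespaces, reads and writes the rank-matrix and
GRP file dialects, scores queries, and ships a synthetic database
generator with planted ground truth so the whole pipeline is verifiable
offline.

## The statistic

For a tag set at ascending ranks $V_1<\dots<V_t$ in a list of length $n$,
the signed Kolmogorov–Smirnov enrichment is

$$a=\max_j\left(\frac{j}{t}-\frac{V_j}{n}\right),\quad
 b=\max_j\left(\frac{V_j}{n}-\frac{j-1}{t}\right),\quad
 es=\begin{cases}a& a\ge b\\-b&\text{otherwise,}\end{cases}$$

so $es=+1$ when the tags sit at the very top. Per instance the raw score
is $s = es_{up}-es_{down}$ when the sides deviate in opposite directions
and $0$ when they agree in sign (a "null instance"); raw scores are
scaled database-wide into connectivity scores $c\in[-1,1]$. Per compound
(× cell line) the package reports the **similarity mean** (mean member
$c$), **N** (member instances), the **enrichment** of the members'
positions in the $c$-ordering, and an **empirical permutation p-value**
(100 000 random same-size instance sets by default, exact enumeration
when affordable), ranked by p, then |enrichment|, then |similarity mean|.
A negative similarity mean marks a compound *oppositional* to the query —
the repurposing signal.

## Worked example

Simulate a 50-compound database in which compound 7 was planted
*oppositional* to a 100-tag query signature, then run the query:

```r
library(sigconnect)

cfg <- simulation_config(
  planted = data.frame(compound = c(7L, 20L),
                       mode = c("oppositional", "concordant")),
  seed = 101L)
sim <- simulate_database(cfg)
sim$db
#> instance_db: 1000 probes x 200 instances (50 compounds, 1 cell lines)

query <- make_planted_query(sim$truth, 7L)
query
#> gene_signature: 50 up / 50 down tags (namespace: SIM)

res <- run_query(sim$db, query, query_config(n_perm = 10000L, seed = 2L))
print(res, n = 5)
#> connectivity query: 50 groups over 200 instances (50 up / 50 down tags used)
#>  rank  group_key compound cell_line n_instances similarity_mean enrichment
#>     1  cpd_7:SIM    cpd_7       SIM           4      -0.9683463     -0.985
#>     2  cpd_9:SIM    cpd_9       SIM           4      -0.1363049     -0.730
#>     3 cpd_12:SIM   cpd_12       SIM           4       0.6060393      0.680
#>     4 cpd_18:SIM   cpd_18       SIM           4       0.3764045      0.675
#>     5 cpd_19:SIM   cpd_19       SIM           4       0.3174157      0.635
#>  p_value n_nonnull
#>   0.0000         4
#>   0.0055         3
#>   0.0092         3
#>   0.0102         2
#>   0.0187         2
```

The planted compound is retrieved at rank 1 with a strongly negative
similarity mean (−0.97: its four instances reverse the query almost
perfectly), enrichment −0.985 (its instances occupy the very bottom of
the connectivity ordering), and an empirical p of 0 at 10 000 draws.
`write_results(res, "results.tsv", "instances.tsv")` persists both
tables; `second_order_query()` plus `class_tally()` run the
mechanism-of-action analysis on top of a ranked result.

The same pipeline is available from a shell via the installed script
(`inst/scripts/sigconnect`): subcommands `signature`, `drug-signature`,
`build-db`, `query`, `moa`, `simulate`, each writing a YAML run manifest
alongside its outputs.

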