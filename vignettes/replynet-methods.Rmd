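---
title: "Methods: reply networks, word-category profiles, and their integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reply networks, word-category profiles, and their integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replynet)
```

`replynet` analyzes threaded forum conversations from two sides — the
directed reply network the messages induce, and the psycholinguistic
word-category profile of each member's text — and then joins the two at the
member level. This vignette is the package's account of the methods: the
constructions and their assumptions, the tunable parameters and why their
defaults are what they are, the numerical conventions adopted where
several defensible choices exist, and what the synthetic data generator
does and does not establish about real forums.

## The conversational record

A corpus is a set of threads, each opened by an initiator, each message
carrying an ordinal timestamp and, optionally, a pointer to the specific
earlier message it replies to. Three modelling commitments are baked into
the data model:

* **Timestamps are ordinals.** Only within-thread order matters for the
  reply rules; calendar arithmetic is out of scope, so real datetimes are
  reduced to integers at the reader boundary.
* **Text is pre-tokenized.** Tokenization (for Chinese forums,
  segmentation) is a plug-in concern at import time; the pipeline consumes
  token lists and is language-agnostic.
* **Deleted accounts keep their edges.** A member who deleted their account
  leaves messages whose text is unavailable (`NA` token slot) but whose
  reply structure is intact; network operations keep them, linguistic
  operations skip them. In the motivating study group 37 of 5,050 members
  were in this state, which is why linguistic denominators there are 5,013.

## Reply-edge construction

Every message produces exactly one directed edge: opening post → self-loop
at the initiator; untargeted message → edge to the thread initiator;
targeted reply → edge to the replied message's author (self-loop on
self-reply). This is the only reading under which the motivating group's
published counts balance (36,657 non-loop edges plus the self-loops equal
the 40,357 messages), so the edge count always equals the message count —
an invariant asserted in tests. Self-loops are removed before structural
analysis; the removal records opening-post loops separately from
self-replies and untargeted initiator follow-ups, because the published
account distinguishes the two provenances (3,565 vs 135) without
reconciling them against the thread count, and the package deliberately
reports both rather than adjudicating.

## Topological measures: conventions

Where a measure has several common variants, the package fixes one
headline convention and documents the alternative:

* **Density** uses the carried multi-edge count `m` over `n(n-1)`
  (self-loops excluded). The published density of the motivating network
  (143.8×10⁻⁵ at n = 5,050) is only consistent with multi-edges counting.
* **Reciprocity** is the share of directed edges in the simple projection
  whose reverse edge exists — the "if I replied to you, did you ever reply
  to me" reading. The Garlaschelli–Loffredo density-corrected coefficient
  rides along as an attribute, not the headline.
* **Clustering** is node-averaged local clustering on the undirected
  simple projection, zero for degree < 2. This projection convention is
  the one under which a directed G(5050, 36657) random graph lands near
  0.29×10⁻², matching the published random-graph baseline; a fully
  directed clustering definition would not.
* **Average shortest path** is the mean over ordered pairs with a
  connecting directed path; unreachable pairs are excluded, never imputed
  with a large constant. **Diameter** is the maximum over reachable pairs
  (the standard reading of "largest shortest path").
* **Betweenness** is standard shortest-path betweenness on the simple
  projection, endpoints excluded, normalized by `(n-1)(n-2)`.

All of these are exercised against brute-force oracles (Floyd–Warshall,
exhaustive path enumeration, adjacency-matrix counting) on random digraphs
of up to 6 nodes, where exhaustive computation is cheap and unambiguous.

### Power-law fitting

Degree tails are fitted by discrete maximum likelihood with the lower
cutoff `x_min` selected by minimizing the Kolmogorov–Smirnov distance
between the empirical tail and the fitted model — the modern standard; the
likelihood uses a Hurwitz-zeta normalizer evaluated by Euler–Maclaurin
summation (100 explicit terms plus correction, accurate to well below the
estimation noise). The scan requires at least 10 tail observations behind
any candidate cutoff and caps the number of candidates at 60 quantiles for
large samples. Degenerate inputs (constant samples, fewer than 10 positive
values) are errors, not silent zeros. A continuous-MLE closed form is
available for cross-checks, and an independent implementation (igraph's
`plfit`) is used in the test suite as a cross-check only. The package also
ships an exact inverse-CDF sampler for the discrete power law (tabulated to
10⁵ with a continuous tail beyond), because validating an estimator with an
approximate sampler confounds sampler bias with estimator bias.

### Bow-Tie decomposition

The six classes follow reachability semantics around the largest strongly
connected component: IN reaches the SCC, OUT is reached from it, TUBES lie
on IN→OUT paths avoiding the SCC, TENDRILS are otherwise reachable from IN
or reaching OUT, and DISC is everything else. Two decisions deserve note.
First, equally large strongly connected components are tied-broken by the
smallest contained node index, making the decomposition deterministic.
Second, smaller strongly connected components that meet no other criterion
fall into DISC; the class of non-largest SCCs is genuinely underdetermined
in the usual informal definitions, and DISC is the assignment consistent
with "disconnected from the bow-tie core". The implementation computes
reachability with two auxiliary-source BFS traversals; for the remaining
nodes, reachability from IN on the full graph already avoids the SCC
(a path through the SCC would re-classify the endpoint), an equivalence
the test suite verifies against a brute-force classifier that explicitly
removes the SCC before computing closures, over a thousand random digraphs.

## Null models

* **Erdős–Rényi G(n, m)**: exactly `m` distinct edges, uniform.
* **Barabási–Albert variant**: the growth process mirrors forum
  accumulation — a complete directed 5-clique seed, then each arriving
  node posts 7 out-edges (new → existing, replier → earlier poster) to
  degree-proportional targets, distinct within a step. The first two
  arrivals face fewer existing nodes than edges requested; the default
  *exact-count mode* draws those targets with multiplicity so the edge
  contract `20 + 7(n − 5)` holds exactly (35,335 at n = 5,050, density
  138.6×10⁻⁵). The new→existing direction is the only one that reproduces
  the published bow-tie profile of this model (largest SCC exactly the
  seed clique, ≈0.10% at n = 5,050, with a huge IN), since no edge ever
  points from an older node to a newer one. The published edge count for
  this model (36,657) contradicts its own published density; the package
  follows the density-consistent construction.
* **Watts–Strogatz**: ring lattice with `k` neighbours, independent edge
  rewiring. The published comparison names *seven* neighbours, which no
  even-degree ring realizes and which contradicts the published edge count
  (17,401 ≠ 5050·7/2); the default is `k = 6` with the published rewiring
  probability 0.45, and `k` stays a parameter. At `p = 0` the closed-form
  lattice clustering `3(k−2)/(4(k−1))` is asserted exactly.

## Word-category counting

Categories form a hierarchy (seven mains; affect → positive/negative;
negative → anxious/angry/sad; pronouns → first/second/third person) and
membership is transitive upward. Counting uses set semantics: each token
increments every category in the closure of its labels once, and counts
once toward the tagged total regardless of how many categories it hits. So
category rates can jointly exceed 100% (a word can be both a pronoun and,
say, an affect term) while no single rate can, and the tag rate keeps its
"share of tokens matching anything" meaning. Occurrence rates use **total
tokens** as the denominator (the standard convention), not
dictionary-eligible tokens; with the alternative denominator every rate
would scale by the tag rate, changing nothing rank-based downstream but
shifting the printed percentages.

The shipped lexicon is a ~130-word English stand-in covering the full
hierarchy; the 7,444-word dictionary used in the motivating study is
proprietary and cannot be redistributed. Every linguistic number the
package prints on synthetic data therefore reflects the toy lexicon's
coverage, not any real dictionary's.

## The synthetic forum generator

The generator is first-class, tested code; its defaults are the study
conditions it emulates, chosen once:

| parameter | default | rationale |
|---|---|---|
| members, threads (mdd-scale preset) | 5,050 / 3,700 | the motivating group's scale |
| participant count per thread | 1 + heavy-tailed draw (exponent 2.2), cap 276 | participation peaks at 2 and tails to a 276 maximum; the true law is unpublished, so a capped power form matches the qualitative shape |
| single-participant share | 0.08 | keeps the mode at 2 while allowing self-conversations |
| member activity | Pareto propensity, exponent 2.4 | heavy-tailed posting activity |
| messages per replier | 1 + Geom(0.234) | calibrated so the preset centers on ≈40,357 messages |
| message length | lognormal, meanlog 3.58, sdlog 1.0 | ≈56 tokens/message, matching ≈2.28M words over ≈40k messages; heavy-tailed word counts |
| targeted-reply share | 0.3 | most forum replies address the thread at large |
| token mixture | function ≈45%, cognitive ≈12%, negative > positive affect, first-person-dominant pronouns, 25% out-of-dictionary | reproduces the published qualitative signature: tag rate ≈75%, function words near half, negative dominance, self-focus |
| deleted accounts | 37/5050 | the motivating group's deleted-member share |

Calibration was done once, over 20 seed replicates of the preset, before
any test band was frozen; the preset's message count stays within ±11% of
the 40,357 target across those replicates and the test asserts a ±12% band.
A `length_coupling` knob (default 0) amplifies a member's message length
with their realized message volume, implanting a tunable monotone
association between out-degree and word count used to validate the
correlation machinery; note that even at 0 the association is strongly
positive simply because more messages mean more words.

What the generator does **not** emulate: calendar time and membership
churn, topical structure, message semantics beyond category mixtures,
degree–reciprocity dependence of real conversations (the motivating
group's reciprocity of 34% is far above anything these mechanisms
produce), and any real dictionary's coverage. Tests passing on generated
corpora therefore establish the *correctness of the computations* under
realistic scale and shape — not that the generator reproduces any real
community's joint distribution.

## Integration layer

The member feature table joins six topological columns (in-degree,
out-degree, threads created, per-node average shortest path over the
member's reachable set, normalized betweenness, local clustering) with
thirteen linguistic columns (word count, seven mains, positive, negative,
three pronoun persons) for every member with available text. Members who
reach no other node get a *missing* path length, and the Spearman matrix
uses pairwise-complete observations, so such members drop out of
path-length pairs only — listwise deletion would discard their perfectly
well-defined degree and language columns. Rank correlations use average
ranks on ties; constant columns are flagged `NA` rather than zeroed. No
multiple-testing correction is applied to the 19×19 matrix, matching the
descriptive use of these correlations; treat individual cells accordingly.

The affect comparison reports **both** two-sample conventions (Welch and
pooled variance): the degrees of freedom printed in the motivating study
match neither the paired nor the pooled layout exactly, so the package
refuses to force a match and emits both, with Welch as the headline.

Convergence curves use equal-occupancy (quantile) bins — 20 by default —
because heavy-tailed topological columns make equal-width bins degenerate
(one bin takes nearly everything). Heavy-tailed columns can be
log-transformed before binning; this moves bin boundaries only, since
rank-based statistics are invariant under strictly monotone transforms (a
property the tests assert). The rise-then-fall "two-phase" shape is
operationalized as the split of the bin-mean sequence minimizing
monotonicity violations, with the turning bin reported.

## Problem sizes and runtime choices

The test suite validates metric implementations by exhaustive oracles at
≤6 nodes, bow-tie equivalence on 1,300 random digraphs of ≤10 nodes,
estimator recovery at samples up to 10⁵, ER ensemble behaviour at
n = 1,200 for the branching-process concentration check and at the full
n = 5,050 for the published-value reproductions (10 seeds for SCC share
and clustering, 5 for average path length). These sizes keep the whole
suite under a minute on one core while leaving every assertion at the
scale its claim refers to; the full-scale ensembles are the ones compared
against published values, and their tolerances (±0.10 percentage points on
the SCC share, ±0.15 on path length, ±0.05×10⁻² on clustering) come from
the documented comparison bands, not from observed spread.

## Known limitations

* The Bow-Tie DISC assignment for non-largest strongly connected
  components is a documented convention, not a community standard.
* The discrete power-law fit reports one global exponent; no comparison
  against alternative tail families (lognormal, truncated power law) is
  implemented.
* The generator's reply-target choice is uniform over earlier messages;
  real forums concentrate replies on recent and popular messages.
* Published values for the motivating group itself (reciprocity 34%, SCC
  54.53%, the 19-property correlation matrix, all category means) depend
  on the non-deposited corpus; the package carries them as reference
  constants (`mdd_reference()`) and never claims to reproduce them.
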