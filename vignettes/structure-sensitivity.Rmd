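---
title: "Measuring the sensitivity of Bayesian network classifiers to structural errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the sensitivity of Bayesian network classifiers to structural errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Practitioners who elicit Bayesian network structures from experts, or learn
them from small datasets, inevitably get some of the structure wrong: an arc
is missing, points the wrong way, or an entire variable was never measured.
`bnsens` quantifies how much such structural errors cost when the network is
used as a classifier. The experimental idea is *progressive mutilation*:
start from a gold-standard network, repeatedly apply one class of structural
edit (node removal, edge removal, or edge reversal), refit the parameters
from data after every edit, and trace classification accuracy (ACC) and the
area under the ROC curve (AUC) as functions of the fraction of the structure
destroyed. Comparing edit orders — most-important-first versus
least-important-first versus random — separates the cost of losing structure
per se from the cost of losing the *right* structure.

## The model and the measures

Networks are discrete Bayesian networks: a DAG over categorical variables
with one conditional probability table (CPT) per node. CPT rows are indexed
row-major over parent configurations with the **last parent cycling
fastest**, which is also the order used by the XMLBIF 0.3 serialization the
package reads and writes.

Two importance measures drive the edit orders:

* **Node importance** is the value of information (VOI) of a variable $Y$
  for the class $C$, computed model-based by exact inference:
  $\mathrm{VOI}(Y) = H(C) - \sum_y P(y)\, H(C \mid y)$, with all entropies in
  base-2 logarithms (bits). For distributions read consistently off one
  joint this equals the mutual information $I(C; Y)$ and is therefore
  nonnegative; the implementation treats it as such (a tiny negative value
  can only be numerical noise and is clamped by construction of the
  formula, not by post-hoc clipping).
* **Edge importance** is a Euclidean arc strength: for an arc $Z \to X$ with
  co-parents $\mathbf{W}$, the expected mean Euclidean distance between the
  CPT rows of $X$ under different states of $Z$,
  $\sum_{\mathbf{w}} P(\mathbf{w}) \cdot \mathrm{mean}_{z \ne z'}
  \lVert P(X \mid z, \mathbf{w}) - P(X \mid z', \mathbf{w}) \rVert_2$,
  with the co-parent distribution $P(\mathbf{w})$ obtained by exact
  inference. An arc whose rows are identical has strength exactly zero.

Exact inference is variable elimination with a min-degree elimination
heuristic (lexicographic tie-breaking), with barren-node pruning.
Zero-probability evidence raises a typed condition rather than returning
`NaN`s.

## The mutilation procedures

* **Node removal** deletes a node and its incident edges (no bridging of
  paths through the removed node — the information the node carried is meant
  to be lost). The ranking is **dynamic**: VOI is recomputed on the current,
  already-mutilated model before every removal, because removals change
  every remaining node's information value. The class node is never removed.
* **Edge removal** deletes one arc at a time following a **static** ranking
  computed once on the gold network; removing an arc does not change what
  the gold-standard strengths were.
* **Edge reversal** flips arcs one at a time. Reversing an arc in a DAG can
  create a cycle, so the requested order is realized with a *postponement
  queue*: walk the ranked list, reverse the first arc whose reversal keeps
  the graph acyclic, postpone the rest, and rescan from the front after
  every accepted reversal. Reversing every edge of a DAG always yields a
  DAG, so the schedule provably completes.

After **every** edit the parameters are refit on the original dataset
(restricted to the surviving columns) and the model is evaluated by
**resubstitution** on that same dataset. Resubstitution is deliberate: the
object of study is how well each mutilated structure can still represent the
data it is fit to, not out-of-sample generalization; it also keeps every
point on a trajectory comparable, since all models see identical records.

## Evaluation

Classification uses the posterior of the class given all remaining feature
columns. The **designated positive class** is the most prevalent class in
the gold data, fixed once and reused along the whole trajectory, so that ACC
and AUC remain comparable as the model degrades. ROC/AUC is one-vs-rest on
the posterior score of that class, with the midrank (Mann–Whitney) treatment
of ties — equivalently, the trapezoidal area over the tie-grouped ROC curve.
This makes two endpoint identities exact rather than approximate:

* a model in which the class is disconnected from all features produces the
  same score for every record, and midrank AUC of a constant scorer is
  exactly 0.5;
* the accuracy of such a model equals the prevalence of the most frequent
  class (the "prevalence floor"), which is why raw accuracy is a misleading
  sensitivity measure — a useless classifier on a 99.9999%-prevalence
  problem is 99.9999% accurate.

Getting the first identity *bitwise* exact requires care: per-record
normalization of log-joints must not leave floating-point dust that breaks
score ties. The scorer therefore computes the class-dependent part of the
log-joint only from CPTs that actually depend on the class state; factors of
class-independent nodes cancel structurally instead of numerically. Records
whose evidence has probability zero under a model fall back to the class
prior (and are counted, so the fallback rate is observable).

## Fitting and structure learning

CPTs are fit by Dirichlet-smoothed maximum likelihood:
$\hat{P}(x \mid \mathbf{pa}) = (N(x,\mathbf{pa}) + s/r)\,/\,(N(\mathbf{pa}) + s)$
with $r$ the child's cardinality and equivalent sample size $s = 1$ by
default — enough to keep every row a proper distribution even for parent
configurations never observed (with $s = 0$, unseen rows are set uniform,
a documented extension since pure ML leaves them undefined). `fit_report()`
exposes how many rows were effectively smoothed, which is the mechanism
behind the most instructive failure mode: reversing the arcs of a naive
Bayes turns the class CPT into one row per *feature configuration*, a table
that can dwarf the dataset by orders of magnitude.

For gold standards learned from data the package provides an augmented
naive Bayes (ANB): a naive Bayes skeleton plus a maximum-spanning tree over
the features weighted by empirical class-conditional mutual information,
rooted at the lexicographically first feature, with an optional CMI
threshold that prunes weak augmenting arcs (threshold high enough and the
ANB collapses to a plain naive Bayes).

## The synthetic benchmark generator

Real clinical datasets cannot ship inside a package, so experiments run on
synthetic scenarios whose *shapes* — node counts, class counts, class
prevalences, record counts, mean in-degrees, missingness — emulate a
familiar family of small medical classification benchmarks. The emulation is
of summary statistics only; the CPTs, dependence patterns, and any clinical
semantics are not modeled. `scenario_presets()` ships eight such shapes
(e.g. a 10-node / 286-record / 70.3%-prevalence binary problem, a 22-node /
2126-record 3-class problem, a 20-class tumor-like problem).

The generator makes the class a root with the specified prevalence, layers
the features so the graph is a DAG by construction, and draws
$\lfloor \text{edge\_density} \times n \rceil$ edges with class-to-feature
candidates upweighted 3:1 and at most 4 parents per node. Feature CPT rows
are mixtures $(1 - w)\,\mathbf{b} + w\,\mathbf{s}_k$ of one shared base
distribution $\mathbf{b}$ and per-configuration sharp draws
$\mathbf{s}_k \sim \mathrm{Dirichlet}(1/(1{+}s))$, with
$w = s/(1{+}s)$ controlled by `effect_strength` $s$ (default 2). At $s = 0$
all rows collapse to the base distribution — an exact null model in which no
feature carries information — and increasing $s$ monotonically increases
learnable signal; this gives the test suite an analytic handle on "how much
structure is there to destroy". Missing values are masked completely at
random (never in the class column) and replaced by an explicit
`absent_or_normal` state before fitting, which extends the domain only of
columns that actually had missing cells. One preset caps its missing rate at
the generator's 5% ceiling, slightly below the dataset it emulates.

All stochastic steps are seeded through a save/restore wrapper so that
generation never perturbs, and is never perturbed by, the caller's RNG
state.

## Design decisions worth knowing

* Problem sizes in the presets and tests are the package's own choices,
  selected to keep exact inference and brute-force enumeration oracles
  feasible at desk scale.
* Deterministic orders (descending/ascending) are run once per experiment;
  only random orders are replicated over seeds.
* `remove_node()` supports an optional parent-to-child bridging mode, but
  the trajectories never use it: the studied error is *losing* a variable.
* Reversal trajectories refit after every single reversal, so intermediate
  models along the postponement schedule are all valid classifiers.
* The AUC implementation is cross-checked in the test suite against an
  independent implementation (pROC) and against direct concordant-pair
  counting, and exact inference is cross-checked against brute-force joint
  enumeration.

## Limitations

Resubstitution evaluation cannot detect overfitting; the saturated models
produced by extreme reversals can look *better* on training data than the
gold standard even when their CPTs are mostly prior. The generator emulates
marginal shapes, not real dependence structure, so absolute ACC/AUC values
are not comparable to results on the real benchmark datasets — only the
qualitative degradation patterns are. And all conclusions are about
classification performance with a fixed class variable; other uses of a
network (diagnosis of multiple targets, decision support) may weight
structural errors differently.
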