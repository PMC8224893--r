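---
title: "Simulating phenotypes on signed pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phenotypes on signed pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbsim)
```

## The model

`perturbsim` treats a cell's regulatory wiring as one large signed directed
graph: nodes are biological elements (genes, miRNAs, metabolites) and each
edge carries a weight of $+1$ (activation) or $-1$ (inhibition). Such a
*meta-pathway* typically arises by merging many curated pathway maps on
their shared nodes; `merge_graphs()` performs that union and refuses to
silently resolve sign conflicts, because a flipped edge sign inverts every
prediction downstream of it.

The question the package answers is: *given that some nodes are forced up
or down, what happens to everything else?* Each node $V_i$ is modelled as a
three-state random variable — activated, inhibited, unchanged — whose
distribution is estimated by Monte Carlo:

1. Every input node draws a synthetic log2 fold change from a rectified
   Gaussian ($\max(0, \sigma Z + \mu)$ for up-regulation, $\min(0, \sigma Z
   - \mu)$ for down; $\mu = 5$, $\sigma = 2$). These parameters describe the
   magnitude distribution of strong deregulation events in tumour
   expression compendia and are deliberately taken as fixed constants —
   the package does not refit them — though `logfc_mean` / `logfc_sd` are
   exposed for sensitivity analyses.
2. The draws propagate to the steady state of a linear balance: a node's
   perturbation is its own imposed change plus the sum over upstream
   neighbours of their perturbation, divided by the upstream node's total
   absolute out-weight and signed by the connecting edge. The denominator
   belongs to the *sender*: a regulator with many targets spreads its
   influence thin. (Normalising by the receiver's own downstream edges,
   a reading the bare formula would also admit, has no propagation
   semantics — nothing the receiver sends out can rescale what it takes
   in — so the package follows the sender-normalised convention of the
   pathway-impact-analysis lineage it extends.)
3. The sign of the propagated perturbation classifies the node's state in
   that repetition; `T` repetitions give state probabilities
   $\Pr(V_i = v \mid I)$, the average perturbation, and the log-odds
   activity score.

The linearity of step 2 is an explicit modelling assumption: saturation,
cooperativity and dose thresholds are outside this model, which is why the
output is read as a *direction-and-confidence* prediction rather than a
quantitative expression forecast.

## Activity scores

The activity score condenses the state distribution into one signed number:
$+\log_2(p/(1-p))$ if activation has majority probability $p > 1/2$, the
negated analogue for inhibition, and $0$ when the unchanged state dominates
or no state reaches one half (the score is only defined for a majority, so
ties report 0 while the full probability triple remains available). A
unanimous tally would give an infinite score; the package applies a
continuity correction, entering the count $T$ into the odds as $T - 1/2$,
which caps the magnitude at $\log_2((T - 1/2)/(1/2))$ — about $10.97$ at
$T = 1000$ — and keeps scores finite, ranked, and $T$-dependent.

Zero is treated exactly: a node tallies "unchanged" only when its
perturbation is exactly zero (it received no signal, or every input draw
rectified to zero). No epsilon is applied — the propagation arithmetic is
exact on the inputs it is given, and an epsilon would silently reclassify
small but genuine effects.

## Significance

A strong activity score is not automatically interesting: hub-adjacent
nodes light up for *any* input. The package therefore re-simulates `R`
random inputs with the same number of nodes and the same multiset of
directions, drawn uniformly from the (non-virtual) network nodes, keeping
the non-expressed constraints; the p-value of a node is the fraction of
random inputs whose activity score exceeds the observed one.

Two choices deserve note:

* **Magnitudes, not raw scores.** The comparison uses $|A|$ by default. A
  one-sided comparison on raw scores would assign $p \approx 1$ to every
  strongly *inhibited* node — the opposite of the intended semantics, under
  which strong inhibition is as extreme as strong activation.
  `pvalue_mode = "raw"` restores the literal one-sided rule for users who
  want it.
* **No smoothing.** $p = r/R$ exactly, so $p = 0$ is possible; the q-value
  stage tolerates zeros. Storey q-values use the single-point
  $\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m))$ at
  $\lambda = 0.5$, which is stable at the small family sizes of desk-scale
  networks (a spline over $\lambda$ needs far more p-values than a toy
  graph provides); $\pi_0$ is floored at $1/m$ so that an all-small p-value
  family does not collapse every q-value to zero. Node and pathway families
  are adjusted separately.

## Numerical choices

* **Solver.** Jacobi iteration (simultaneous update) from $P = \Delta E$,
  tolerance $10^{-6}$ in max-norm, at most 2000 sweeps. Jacobi rather than
  Gauss–Seidel because the result must not depend on node order. On
  acyclic graphs the iteration terminates exactly; on cyclic graphs the
  operator can fail to contract (a two-node feedback loop with unit weights
  makes the steady state non-unique), in which case the minimum-norm
  least-squares solution of $(I - M)P = \Delta E$ is reported and flagged
  `converged = FALSE`. A run aborts when more than 10% of its repetitions
  diverge. `propagate_exact()` implements the direct solve and doubles as
  the independent oracle in the tests.
* **Random numbers.** All normal variates come from one hand-written
  Marsaglia polar generator seeded through R's RNG; draws are consumed in a
  documented order (input nodes sorted by id within each repetition), so a
  seeded run is bit-reproducible end to end, including the output file.
* **Dependent inputs.** A dependency group is replaced by a virtual
  regulator with one signed edge per member and the input $\{V^* = +1\}$;
  a single magnitude draw then drives the whole group coherently. With a
  single member and a unit out-degree virtual node this construction is
  provably equivalent to perturbing the member directly (the test suite
  checks tally-level identity under a shared seed); the exported operation
  nonetheless requires two or more members, since a singleton "dependency"
  is just a direct input.
* **Non-expressed genes** are deleted, not clamped to zero: deletion also
  shrinks the out-degree denominator of their upstream regulators, so the
  remaining targets receive proportionally more signal — clamping would
  leak influence into a gene the cell does not express. Removed nodes are
  still reported, as permanently unchanged.
* **Pathway aggregation.** Pathway-level analysis needs a per-repetition
  scalar per pathway; the package sums member-node perturbations (a linear,
  superposition-respecting choice) and then applies the identical tally →
  probability → score → p-value pipeline. `pathway_aggregation = "mean"`
  rescales by pathway size; tallies and scores are unaffected, only the
  average perturbation changes.

## Benchmarking

`classify_logfc()` thresholds observed log fold changes at 0.6 in absolute
value; the boundary value counts as altered (only strictly smaller
magnitudes are "non-altered"). Predictions are classified by activity-score
sign. `evaluate_predictions()` builds two class-specific tables: among
observed-altered genes, sign agreement defines TP/TN/FP/FN and hence PPV,
Sensitivity, Specificity; among observed-non-altered genes an "unaltered"
prediction is a true positive and an "altered" one a false negative,
giving the FNR. A gene predicted unaltered but observed altered is a false
positive *of the unaltered class* — the four altered-class cells are
defined purely by sign combinations and cannot absorb it. Rates with empty
denominators are `NA`, never 0, so averaging reports across datasets is not
biased by degenerate tables. The microarray non-expressed rule uses the
linear-interpolation (type 7) percentile; the convention matters at toy
sizes and is recorded here because several are in common use.

## Synthetic data, and what the tests do (and do not) show

`random_network()` (Erdős–Rényi-style signed digraphs, optional acyclicity,
BFS-grown overlapping pathways), `toy_cascade()` (a branching tree with the
closed-form steady state $x/b^d$), and `synth_observed_logfc()` (one
propagated draw plus additive Gaussian noise) generate every input the test
suite uses; nothing is downloaded. These generators emulate the *formal*
structure of a meta-pathway — signed edges, cycles, overlapping pathway
membership — but not the degree distribution, motif content, or edge
density of curated biological maps, nor correlated measurement noise. A
green suite therefore validates the algorithmic contracts (propagation
arithmetic, tally bookkeeping, calibration of the empirical null), not
predictive accuracy on real cell lines, which depends on pathway curation
quality.

The null-calibration check deserves a note on its fixture. With the inner
tally fixed at $T = 20$, activity scores take at most 21 magnitudes, and
p-values from strict exceedance counting are only approximately uniform
when the null score distribution is well spread: a fixture whose nodes are
perturbed with an essentially deterministic sign piles scores onto the
continuity cap and produces p-value atoms instead. The test therefore uses
a hub fed by two leaf classes with steady-state contribution weights 1 and
1/2 (the latter diluted through a negative parallel path, so *every* node
still contributes positively) and a direction-balanced 10-node input: the
hub's per-repetition sign stays genuinely stochastic for any random input,
which is precisely the regime in which an empirical null is meaningful.
Problem sizes throughout the suite (graphs of 15–50 nodes, $T$ of 20–1000,
$R$ of 50–200, $10^6$ generator draws) were chosen as the smallest at which
each property is statistically decidable — moment checks at Monte-Carlo
error, KS tests at $\alpha = 0.01$ — and are stated in the tests
themselves.

## Defaults

| Parameter | Default | Meaning |
|---|---|---|
| `T` | 1000 | Monte-Carlo repetitions of the observed input |
| `R` | 1000 | input randomizations for the empirical null |
| `T_inner` | 100 | repetitions per randomization |
| `logfc_mean`, `logfc_sd` | 5, 2 | rectified-Gaussian magnitude (log2 units) |
| `tol`, `max_iter` | 1e-6, 2000 | Jacobi stopping rule |
| `pvalue_mode` | `"abs"` | two-sided magnitude comparison |
| `pathway_aggregation` | `"sum"` | per-step pathway summary |
| `threshold` | 0.6 | observed-LFC alteration cutoff |
| `lambda` | 0.5 | Storey $\pi_0$ tuning point |

## Known limitations

* Linear propagation: no saturation, no logic gates, no dose response.
* Edge weights are restricted to $\pm 1$; quantitative interaction
  strengths are out of scope.
* Cyclic subgraphs whose operator does not contract are answered with a
  least-squares compromise and flagged, not resolved dynamically.
* The pathway score aggregation (sum of member perturbations) is a
  declared convention, not a claim of bit-compatibility with any other
  implementation; `"mean"` is provided as the alternative.
* Identifier namespaces are opaque strings; no cross-species or
  cross-database mapping is attempted.
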