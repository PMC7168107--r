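---
title: "Model-based diagnosis and troubleshooting of neuromuscular complaints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based diagnosis and troubleshooting of neuromuscular complaints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physdx)
```

## The diagnostic problem

A clinician examining a patient with weakened movements or defected skin
sensations faces an attribution problem: the observable signal (a muscle
test, a sensation over a dermatome) is downstream of a chain of anatomical
components — nerve roots innervating nerves, nerves serving muscles and
dermatomes — and any upstream fault can mask the true state of the tested
component. A failed shoulder-extension test implicates the deltoid, but
equally the radial nerve or the C6 root above it.

`physdx` casts this as consistency-based diagnosis over a typed influence
DAG. Components are one of four kinds: `nerve_root` (sources), `nerve`,
`muscle` and `dermatome` (sinks). An edge `a -> b` states that the output
of `a` is an input of `b`, so a healthy test of `b` requires `b` *and its
entire ancestor closure* to function. Dermatomes are special: a defected
sensation is a signal, but the skin itself is assumed healthy, so
dermatomes are never candidate faults — they are pure test surfaces for
their ancestors.

## The weak fault model and its consequences

Only healthy behaviour is modelled (a *weak fault model*). Two asymmetric
consequences drive everything downstream:

* a **failed** test of component $c$ proves that some member of
  $\{c\} \cup \mathrm{anc}(c)$ is faulty — this set (minus dermatomes) is a
  *conflict*;
* a **passed** test proves nothing: a faulty component may still pass, so
  passes never exonerate and never filter the candidate set.

Given observations, each failed test contributes one conflict, and the
subset-minimal *hitting sets* of the conflicts are exactly the
subset-minimal diagnoses. Because conflicts here are ancestor closures on
a modestly sized DAG, conflicts are computed directly by reachability
(no truth-maintenance machinery is needed — the closures *are* the
conflicts under this semantics), and hitting sets are enumerated by a
branching tree over the first unhit conflict followed by an exact
minimality filter: a hitting set is minimal iff every element hits some
conflict that no other element of the set hits.

Each diagnosis $\Delta$ receives probability $\propto p^{|\Delta|}$, where
$p$ is a uniform per-component prior fault probability (default
$p = 0.1$, configurable; any $p < 0.5$ ranks smaller diagnoses higher,
consistent with the minimality preference). Probabilities are normalized
over the returned minimal set — entropy and the health state below require
a proper distribution. The per-component *health state*
$H(c) = \sum_{\Delta \ni c} P(\Delta)$ summarizes the set.

```{r}
m <- fragment_model()
d <- diagnose(m, observation_set("DC6", FALSE))
d
round(health_state(d), 3)
```

## Sequential troubleshooting

With several candidates, the next test is chosen by expected information
gain. The entropy of the set is
$\mathrm{Ent}(D) = -\sum_{\Delta} P(\Delta)\log_2 P(\Delta)$.
For a probe of $c$, a pass leaves $D$ unchanged (weak fault model), so only
the fail branch is informative:

$$\mathrm{IG}(D \mid c) = P_{\mathrm{fail}}(c)\,
  \bigl(\mathrm{Ent}(D) - \mathrm{Ent}(D \mid c\ \text{failed})\bigr),
  \qquad
  P_{\mathrm{fail}}(c) = \sum_{\Delta \cap (\{c\}\cup\mathrm{anc}(c)) \neq \emptyset} P(\Delta).$$

The gain definition leaves open which outcome defines the posterior; we
weight the fail-branch reduction by the probability that the probe can
fail at all, which equals the expected posterior-entropy reduction because
the pass branch is an identity update. An `optimistic` variant (raw
fail-branch reduction, no weighting) is available via the `ig_mode`
argument of `run_probing()` for comparison.

"One of its inputs" in the update rule is read as *transitive* ancestors:
a failed probe keeps exactly the diagnoses intersecting the probe's
self-inclusive ancestor closure, then renormalizes. Direct-parents-only
would be strictly weaker and can discard the true diagnosis. Filtering and
renormalization preserve relative weights, so repeated updates commute
with the prior.

The loop (`run_probing()`) stops when the set cannot shrink further: at
most one candidate left, no untested candidates (candidates are the union
of diagnosis members), or every candidate has zero expected gain — a
zero-gain probe either intersects every diagnosis (fail update is the
identity) or none (it cannot fail under the current candidates). Ties
among maximal-gain probes are broken uniformly at random under the
session seed, so sessions are exactly reproducible. An answer that
eliminates every candidate (possible when the true fault set is
non-minimal) aborts the session with a dedicated condition carrying the
partial log; re-diagnosis with the augmented observation set is the
documented follow-up. A uniform-random probe policy is built in as the
baseline for the policy comparison.

## The scenario simulator

`generate_scenario()` emulates a clinical examination with known ground
truth: (1) draw $k$ distinct faultable components uniformly; (2) label
every component in the faults' self-inclusive descendant closure as
failing with probability `fail_prob` (default 0.5; `fail_prob = 1` is the
*relaxed mode* in which every affected component fails — closer to
clinical reality, where a genuinely faulty pathway rarely passes a
directed test); all other components pass; (3) force at least one
explaining symptom per fault (uniformly chosen within its closure) so the
true diagnosis is never unexplained; (4) reveal an initial observation
subset of failing components, sized uniformly between 1 and $k$.

Fault sets in which two faults share an *affecting component*
(overlapping self-inclusive ancestor closures — covering both a common
ancestor and one fault masking another) cannot be recovered jointly as a
minimal diagnosis; `generate_batch()` either redraws them (default,
bounded retries, counts reported) or discards them post hoc
(`discard_mode = "discard"`), mirroring a generate-then-filter design.
The default batch design is exhaustive single faults over every faultable
component plus 150 instances per cardinality 2–6; on a 75-faultable model
this is 825 configured instances.

### What the generator emulates, and what it does not

The bundled `fragment_model()` preserves anatomical fidelity for a small
neighbourhood of C6. The synthetic generator instead emulates the
*statistics* of a full clinical model: layered connectivity, overlapping
closures, about 75 components. Layer sizes default to 12 roots / 24
nerves / 28 muscles / 11 dermatomes with a mean non-root in-degree of 1.5.
The root count and connectivity were fixed once, at design time, so that
multi-fault scenarios with pairwise disjoint closures remain reasonably
common up to six faults (a few percent of draws at $k = 6$): with fewer
lineages or denser fan-in, closure collisions make high-cardinality
ancestor-disjoint fault sets vanishingly rare, and the multi-fault study
design collapses. `edges_per_node` is implemented as target mean
*in-degree* of non-root components: every non-root draws one mandatory
parent plus a Poisson number of extras, which keeps "every non-root has a
parent" and the connectivity target compatible on all shapes.

Synthetic scenarios do not emulate graded symptom severity, pain
descriptors, correlated failures along a pathway, or patient-language
complaints; passing tests on synthetic batches therefore demonstrates the
algorithmic contracts (soundness, completeness, retention, policy
ordering), not clinical accuracy of any bundled anatomy.

## Evaluation metrics

Computed over *faultable* components only — dermatomes can never be true
or predicted positives, and including them would deflate false positive
rates artificially.

* **Diagnosis-set size**, before vs after troubleshooting.
* **Weighted FPR**: per diagnosis, $\mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$
  against the injected faults, weighted by diagnosis probability. A
  degenerate diagnosis with $\mathrm{FP}+\mathrm{TN}=0$ contributes 0 and
  is flagged.
* **Health-state ROC AUC**: the health state is thresholded at
  $0, 0.1, \ldots, 1$ (strictly greater than the threshold predicts
  faulty), corner points $(0,0)$ and $(1,1)$ are appended, and the curve
  is integrated by the trapezoid rule after sorting by FPR (TPR as
  tie-break). The thresholds are fixed by the design; the integration
  rule is our choice.
* **Top-K**: exact set equality between the true fault set and one of the
  K most probable diagnoses (ties broken by cardinality, then
  lexicographic order, for determinism).
* **Wasted effort**: expected number of healthy components inspected when
  examining components in decreasing health-state order until every true
  fault is reached. Ties at the critical level are handled analytically:
  $m$ tied healthy and $r$ tied faulty components contribute
  $m\,r/(r+1)$ expected wasted inspections under a uniform tie order.
  The metric is defined here in these terms because only its name, not a
  formula, is fixed by the surrounding literature.

`evaluate_batch()` reports per-cardinality means and an improvement table
oriented so that a positive entry always means troubleshooting helped:
before $-$ after for set size, weighted FPR and wasted effort; after $-$
before for AUC and top-K hit rates.

## Numerical choices and degenerate inputs

* Probabilities are renormalized after every filter; equal-cardinality
  diagnosis sets are exactly uniform, and sums are kept within $10^{-9}$
  of 1.
* Entropy terms with $P(\Delta) = 0$ contribute 0; expected gains are
  clipped at 0 against floating-point jitter, and gain ties use a
  $10^{-12}$ tolerance.
* The empty diagnosis (no failed observations) is a first-class value:
  `diagnose()` returns $\{\emptyset\}$ with probability 1, candidate
  probes are empty, and the loop terminates immediately.
* Health-state AUC is undefined without faulty components and raises a
  typed error rather than returning a number.
* Problem sizes used in the shipped tests and acceptance script — 50
  oracle-equivalence models ($\le 12$ faultable components, exhaustive
  subset enumeration), 200 soundness pairs, 520 retention sessions, 300
  paired policy scenarios, and one full 825-instance relaxed batch — were
  chosen as the smallest sizes at which the corresponding claims are
  statistically meaningful.

## Known limitations

* Single-fault-mode reasoning only: no abductive or strong-fault-model
  extensions, no graded or probabilistic test outcomes.
* The bundled anatomy is a teaching/testing fixture, not a clinically
  complete model; the model file is the single source of truth and no
  anatomy is hard-coded in the algorithms.
* Non-minimal true diagnoses (a fault set whose symptoms are fully
  explainable by a proper subset) are invisible by design: the engine
  searches minimal diagnoses only, and an inconsistent probing answer is
  surfaced rather than silently repaired.
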