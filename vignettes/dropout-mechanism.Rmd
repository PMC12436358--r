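---
title: "Attribute drop-out for active learning with heuristic annotators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribute drop-out for active learning with heuristic annotators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldropout)
library(dplyr)
```

## The problem

Pool-based active learning assumes an oracle that labels whatever query it is
shown. When the oracle is a human annotator — a clinician triaging patients, a
loan officer screening applications — behavioral research says the label often
comes from a *fast-and-frugal heuristic*: a decision made on one attribute, or
a short lexicographic scan of a few. Such an annotator is systematically
error-prone on a specific subset of queries, and an active learner that seeks
out uncertain points tends to land exactly there. `aldropout` implements a
remedy that acts on the query itself: estimate, per query, which attributes
would make a one-attribute decision risky, and *hide those attributes* so the
annotator's heuristic is forced onto safer cues.

## The mislabeling model

Work in the two-dimensional space of a pair of attributes A and B, centered at
their population medians. A one-attribute annotator implements an axis-aligned
decision boundary (label by the sign of one attribute's deviation from its
median). The unknown true boundary is assumed linear, through the median
point, at an angle $\theta_{TDB}$ to an attribute axis distributed uniformly
on $[45^\circ, 90^\circ]$ — i.e. the class structure genuinely involves both
attributes, with neither axis-aligned nor unrelated to the cues.

For a query with absolute deviations $(a, b)$ from the two medians, the
worst-case probability that a one-attribute decision lands on the wrong side
of the true boundary is modeled in closed form as

$$
P(a,b) \;=\; 0.5 \;-\; \frac{1}{90}\,\arctan^\circ\!\frac{\min(a,b)}{\max(a,b)},
$$

with a degree-valued arctangent (equivalently $0.5 - \tfrac{2}{\pi}\arctan(\cdot)$
in radians). Its geometry is what matters for the mechanism:

* $P = 0.5$ when either deviation is 0: a value sitting exactly at its median
  gives the heuristic a coin flip;
* $P = 0$ exactly on the 45° line $a = b$: balanced deviations are
  unambiguous under every admissible boundary;
* $P > 0.3$ exactly when the point is inclined within 18° of an axis, because
  $0.5 - 18/90 = 0.3$ — this is where the default drop threshold comes from.

```{r formula}
p_mislabel_worst(deviation_pair(value_a = 7, median_a = 4,
                                value_b = 1, median_b = 6))
```

When the attribute the annotator uses is *known*, the directed variants apply
(`p_mislabel_directed()`): using A is safe whenever $b > a$, and the maximum
of the two directed probabilities recovers the worst case. The drop-out
mechanism always uses the worst case, since the learner cannot observe the
annotator's choice.

Two internal wrinkles of this derivation were genuinely open and are resolved
here as follows. First, the underlying wedge geometry (which boundary draws
flip a given point) and the closed form disagree by a normalization constant:
integrating the uniform boundary angle over its $45^\circ$ range but
normalizing by $90^\circ$ halves the probability. We treat the closed form as
normative — it is what the threshold calibration (0.3 ↔ 18°) is stated in —
and `simulate_mislabel_frequency()` validates its *ordering*: the Monte-Carlo
wedge frequency, with each heuristic facing a boundary drawn uniformly
$[45^\circ,90^\circ]$ from its own axis, is exactly a monotone transform
(2×) of the formula, zero on the 45° line, symmetric in $(a,b)$ and
scale-invariant. Second, the prose and the equations disagree about which
axis the heuristic boundary lies along when attribute A is used; we follow
the equations' validity condition (using A is error-free for $b > a$), which
is also the reading consistent with the empirical observation that decisions
on near-median values are the risky ones.

A degenerate case the derivation never treats: both deviations exactly zero.
We define $P(0,0) = 0.5$, the supremum — a point exactly at both medians is
maximally ambiguous. Probabilities are clipped to their range after
evaluation, and the 0.3 threshold is compared strictly (`>`).

## The drop-out mechanism

For a queried instance with $d \ge 2$ attributes, every unordered attribute
pair is scored by $P$ on its deviation pair. If a pair exceeds the threshold
(default 0.3), its *smaller-deviation* member — the attribute closest to its
median, hence the dangerous cue — becomes a drop candidate. Candidates are
sorted by probability (descending), deduplicated keeping each attribute's
best-supported occurrence, and at most `max_drop = 2` attributes are hidden:

```{r dropout}
rank_drop_candidates(c(0.1, 0.2, 5), medians = c(0, 0, 0))
mask_query(c(0.1, 0.2, 5), medians = c(0, 0, 0))
```

Two boundary decisions are ours. The drop list is capped at $d - 1$ so a
query always keeps at least one visible attribute — an all-masked query is
unanswerable. And deviations are compared on the raw attribute scales, as the
model is stated; because cross-attribute deviation ratios are unit-sensitive,
`rank_drop_candidates(rescale = TRUE)` optionally divides deviations by a
per-attribute robust scale, but this is off by default.

## Synthetic annotators

Two heuristic oracles label (possibly masked) queries:

* **Take-the-Best** (`fit_ttb()`): each attribute is scored by the accuracy
  of the one-cue median-split classifier; directions are flipped when
  accuracy falls below one half; cues are ranked by adjusted accuracy. At
  prediction time the best *visible* cue decides; a masked or exactly-at-median
  cue falls through to the next; if nothing can decide, the majority class is
  returned (an annotator always answers). "Exceeds the median" is strict.
* **Fast-and-frugal tree** (`fit_fft()`): the annotator model fixes only how
  such a tree is *used* (median-binarized nodes, skip masked nodes); its
  construction is a design choice, and we adopt the standard recipe from the
  fast-and-frugal literature: the top-`depth` accuracy-ranked cues become nodes; each
  non-terminal node exits on its higher-purity side with that side's majority
  class; the terminal node exits both sides. `new_fft_oracle()` builds a tree
  from an explicit node table (e.g. a published clinical tree) without
  fitting.

Both oracles are deterministic functions of (model, query), which is what
makes the whole pipeline seed-reproducible.

## The active-learning loop

`run_al_cycle()` runs the full protocol: an initial labeled set (default 5,
drawn uniformly — the protocol says only "small") is labeled by the oracle
unmasked; then until the pool is exhausted, a logistic-regression learner is
retrained on the labeled set (with *all* attributes — masking applies only to
what the annotator sees), the strategy picks a query, drop-out optionally
masks it, the oracle labels it, and the full attribute vector with the
oracle's label joins the labeled set. Accuracy is recorded on the entire
dataset against ground truth after every retraining, *including* the
pre-query model (curve index 0), so a pool of size $n$ yields a curve of
length $n + 1$.

Strategies: `entropy` picks the pool point maximizing
$-\sum_i p_i \log p_i$ (natural log; the argmax is base-invariant);
`density` weights entropy by mean similarity to the pool,
$\mathrm{sim}(x, x') = 1/(1 + \lVert x - x'\rVert)$ — any bounded decreasing
transform of Euclidean distance would do as a similarity; the reciprocal form
is bounded in $(0,1]$ and monotone in distance (a Gaussian kernel is available);
`random` is the baseline. Ties go to the smallest dataset index. Features
are z-scored on the full dataset for learner fitting and distances, while
medians and deviations stay raw. While the labeled set contains one class,
the learner predicts that class and exposes uniform probabilities, so
uncertainty scoring stays defined.

## Evaluation

The area under a learning curve (`aulc()`) is the unit-step sum of
post-query accuracies — not a trapezoid — so AULC over $n$ queries divided
by $n$ is the mean accuracy maintained during learning, keeping the statistic
interpretable across pools of different sizes. The drop-out
effect is summarized by the effectiveness increase

$$
\frac{\mathrm{AULC}_{with} - \mathrm{AULC}_{without}}
     {\mathrm{AULC}_{without} - \mathrm{AULC}_{random}},
$$

undefined when the strategy is no better than random (returned `NA`,
flagged), and by a one-sided paired t-test of "with > without" across
experiment cells (`paired_t_test()`, df = n−1; one-sided because the hypothesis under test is
directional — the mechanism is meant to help, not merely to change things).
Zero-variance
differences are reported as undefined rather than inventing a statistic,
except the all-zero case, which is t = 0, p = 0.5. `run_experiment()` wires
the grid together, with iteration $i$ in every cell using seed
`base_seed + i − 1` so conditions are matched pair-wise.

## What the synthetic data does and does not show

`generate_linear_dataset()` realizes the model's assumptions exactly:
independent uniform attributes on symmetric intervals (the simplest marginal
with median = center; the geometric argument fixes only the boundary-angle
distribution, so the marginal is our choice, configurable to Gaussian in
spirit via `weights`/`centers`), labels from a linear boundary through the
medians, the $d=2$ boundary angle uniform on $[45^\circ, 90^\circ]$.

`generate_bias_fixture()` builds the demonstration scenario the mechanism
targets: $n$ rows, four attributes, labels from a linear boundary on
attributes 2–4 (weights 1, 0.45, 0.45; uniform deviations on $[-10,10]$).
The salient attribute 1 has deviation magnitude uniform on $[0,10]$; beyond
magnitude 3 its sign agrees with the label, inside that band the sign is a
coin flip. Its single-cue accuracy is therefore $0.7 + 0.3/2 = 0.85$ —
highest of all cues, so Take-the-Best trusts it first — while being
worthless exactly where the mislabeling model flags it. About half of all
points have worst-case probability above 0.3 on the (1, 2) pair, so drop-out
engages often and pushes the annotator onto the genuinely informative second
cue.

Passing tests on these generators show the mechanism behaves as derived
*under the model's own assumptions*: linear separability, boundary through
the medians, annotators that truly are one-attribute heuristics. Real data
violate all three to varying degrees — attributes are correlated and
heterogeneous in units (the raw-scale deviation ratios then mix units),
boundaries are nonlinear, and human annotators mix strategies — so synthetic
results bound what to expect, they do not guarantee it. The CSV loader
(`load_csv_dataset()`) exists precisely so the pipeline can be pointed at
real tabular benchmarks.

## Problem sizes and numerical choices

The directional evaluation in this package's test suite uses three bias
fixtures of $n = 400$ rows, two heuristics, entropy sampling, and 10
iterations per cell with fixed seeds — large enough that the drop-out effect
dominates iteration noise for a one-sided paired test across the six cells,
and small enough to be a routine test-suite run. Learner fits go through
`stats::glm.fit` on the standardized design; perfect-separation warnings are
expected on separable synthetic data and suppressed; aliased coefficients
are treated as zero. Degenerate single-class generator draws are resampled
with an incremented seed and a message.

## Limitations

The model is pairwise and two-class by construction; it estimates nothing
about which attribute a *particular* annotator uses, and the worst case can
be pessimistic when annotators favor informative cues. Masking more than
`max_drop` attributes, multi-class geometry, probabilistic annotators, and
learning the threshold from interaction are all out of scope.
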