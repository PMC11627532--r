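---
title: "Models and methods in catwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in catwarp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catwarp)
```

`catwarp` studies how category structure warps memory for the features of
novel objects, in two coupled ways: a behavioral paradigm in which the colors
of *shared* object parts are misremembered as closer to the category's
average color than the colors of *unique* parts, and a two-pathway
hippocampal network model (C-HORSE) in which the same asymmetry appears in
the similarity structure of learned feature representations. This vignette
explains the models, the conventions the package fixes where the design was
genuinely open, the numerical choices, and what the synthetic data can and
cannot show.

## Stimulus structure

Two categories (Alpha, Gamma) of four satellite objects each. Every satellite
has one part of each type (head, tail, back, leg); three of its parts are
shared with other category members and one is unique to it. The bookkeeping
identity that makes this work: per category, each part type contributes
exactly one shared part (owned by the three satellites whose unique part is
of a *different* type) and one unique part, giving 4 shared + 4 unique parts
per category and 16 parts in total. `satellite_set()` randomizes part
identities, codenames, and which type is unique on which satellite, under
these structural constraints.

Novel satellites for the post-learning test (`build_novel_set()`) keep a
category's shared parts but replace one rotating part type with a never-seen
part, so each novel object overlaps its category in at least three parts and
carries a class name but no codename.

## Color geometry

Part colors live in the L\* = 60 plane of CIELAB. Each category's eight parts
sit equally spaced on a circle of radius 14 (centers (22, −25) and (22, 25);
which category gets which circle is randomized). The adjacent chord is
2·14·sin(π/8) ≈ 10.715, printed as 10.71 at the conventional precision.
Two conventions are package choices, documented here because the design
leaves them open:

- **Circle phase.** The angular position of slot 0 is fixed at phase 0. All
  geometric invariants (circle membership, chord lengths, centroid identity)
  are phase-independent.
- **Shared-eligible positions.** Same-category same-type part pairs (always
  one shared + one unique part) must sit exactly two positions apart, which
  forces the shared- and unique-eligible position sets to agree in parity
  blockwise. Arrangement 1 uses positions {0, 1, 4, 5} for shared parts,
  pairing (0, 2), (1, 3), (4, 6), (5, 7); arrangement 2 swaps the two sets
  (and the swap applied twice is the identity). An alternating assignment
  such as {0, 2, 4, 6} cannot satisfy the two-apart constraint, because a
  pair spanning the two sets would sit an odd number of positions apart.

Foils (`make_foils()`) are placed exactly half an adjacent chord
(14·sin(π/8) ≈ 5.358, printed 5.35) from the target along the line to the
category circle center (attract toward, repel away) and along its
perpendicular (the two orthogonal foils, mirror-symmetric about the
attract–repel line). The category's "average color" is the circle center,
which equals the mean of its eight part coordinates.

## Trial scheduling

Schedules are built by seeded randomized-greedy construction with bounded
restarts (default 10,000) and verified by a separate pure checker
(`validate_schedule()`); every emitted sequence passes with zero violations.

- **Exposure.** Variant 1 reveals every part of every satellite once per
  occurrence, so shared colors are seen three times and unique colors once.
  Variant 2 reveals one unique and one shared color per satellite, with the
  shared choices forming an exact cover so all 16 colors appear exactly once;
  the cover is found by rejection-sampling a perfect matching between
  satellites and the shared parts they own.
- **Learning blocks.** 16 part trials alternate with 16 color trials; each of
  the 16 parts is queried once per trial type per block. Part trials never
  repeat a satellite or a part type back to back. The constraint on which
  part a color trial may test is stated ambiguously in ordinary prose
  ("not the part tested on the preceding color trial, or the two part trials
  before that"); the package implements the reading *not among the parts of
  the three most recent part trials*, which also subsumes most cases of the
  alternative reading, and records the alternative here. Shared parts are
  queried on the satellite given by `build_shared_query_plan()`, which cycles
  each shared part's three owners so that each is used exactly twice over six
  blocks; the Experiment-2 variant (`exp2_decoupling`) lets the color trial
  use a different owner than the part trial within a block.
- **Post-learning test.** 72 part + 72 color trials with no feedback. The
  printed totals do not fix the allocation across feature types; the package
  balances them exactly: 24 unique-trained (each unique part three times),
  24 shared-trained (each shared part once per owner), and 24 shared-novel
  (each novel satellite's three shared parts once), under the same adjacency
  constraints as learning.

## The network model

C-HORSE is a rate-coded autoencoder of the hippocampus. Input, EC_in, and
EC_out have 26 units — one per satellite feature (2 class + 8 codename + 16
part units, the two categories on disjoint subsets); every satellite pattern
activates 6 units. Hidden layers are DG (400), CA3 (80), and CA1 (100) —
sizes are package defaults, as the source design fixes only their ordering.
The trisynaptic pathway (TSP) runs EC_in → DG → CA3 → CA1 with sparse fixed
fan-in connectivity (0.25, 0.25 from EC_in; 0.05 for DG → CA3); the
monosynaptic pathway (MSP) is the full EC_in → CA1 projection; CA1 → EC_out
is the shared readout. Input → EC_in and the big-loop EC_out → EC_in are
one-to-one and fixed.

**Unit dynamics.** Each unit's activation is bounded in [0, 1] and follows
`a ← a + dt · (f(net) − a)` with dt = 0.5 for 100 cycles per phase. The
transfer function is a logistic of `gain · (net − θ)` where the threshold θ
is the layer's k-winners-take-all threshold: the midpoint between the k-th
and (k + 1)-th largest net input, floored at a fixed minimum (0.5). At
uniform drive the adaptive part cancels and no unit is favoured. Active
fractions are DG 4%, CA3 12%, CA1 15% (DG sparsest, CA1 least sparse), and
the free EC_out layer competes at k = 8 of 26 — slightly above the six active
units of a pattern, so a marginal winner is not displaced by a single false
alarm. The DG knob is exposed as a conductance-style parameter Gi with
`k_fraction = k_base / Gi` (defaults k_base = 0.24, Gi = 6). Projection drive
is normalized by expected active fan-in; the relative CA3 → CA1 strength
(`ca3_ca1_scale = 2`) lets the pattern-separated CA3 code tip CA1 winners
toward item-specific units in the intact model.

**Learning.** Each trial runs a *plus* phase (input and target pattern
clamped, both surviving pathways, big loop on) and one *minus* phase per
surviving pathway (input clamped, that pathway alone). Weight changes follow
soft-bounded Contrastive Hebbian Learning,
`Δw ∝ pre⁺post⁺ − pre⁻post⁻`, each projection using the minus phase in which
it was active; CA1 → EC_out, active in every phase, splits its learning rate
across the minus phases run. Because the input layer is clamped to the same
full pattern in both phases, the pure CHL contrast reaching the
representation-forming projections is weak; the package therefore mixes in
the conditional-PCA Hebbian term of this model family,
`Δw ∝ post⁺ (pre⁺ − w)`, at proportions `k_hebb_msp = 0.4` and
`k_hebb_tsp = 0.3` (the readout stays purely error-driven, and setting the
mix to zero recovers pure CHL). The defaults — learning rates 0.1 (TSP),
0.05 (MSP), 0.3 (readout), and the inhibition parameters above — are the
package's calibrated operating point: at these values the intact model
reconstructs the satellites at ≈ 96% after six epochs, and the lesioned
models show the intended representational asymmetry (next section).

**Training and testing.** Six epochs of 16 trials (each satellite twice, in
seeded random order), tested before training (epoch 0) and after every
epoch. Reconstruction accuracy is the fraction of a pattern's *active* units
whose EC_out activation exceeds 0.5 after settling with the input clamped;
a switch (`score_all_units`) scores all 26 units on the correct side of 0.5
instead, and both are reported in the package's own checks. Lesions zero and
freeze the MSP projection (EC_in → CA1; the "TSP only" model) or the four
TSP projections ("MSP only"), and are present during both training and
testing. Feature probes clamp a single one-hot input with the big loop
lesioned and read CA1 after 100 cycles — the *initial response*, before CA1
can influence DG and CA3 through the loop.

## Representational analysis

For each model initialization, each feature's CA1 initial-response vector is
correlated (Pearson) with every other same-category feature; the mean of
those correlations is Fisher-Z transformed (atanh, with |r| clipped at
1 − 10⁻⁷ so the degenerate identical vectors of untrained networks stay
finite). Whether codename and class units count as "features" is
underdetermined; the package includes all 13 per-category features by
default and offers a parts-only switch, and the shared-vs-unique contrast is
always computed on the 16 part features' role means. The contrast runs a
paired t test per lesion condition (df = n_inits − 1) and a two-way ANOVA
(condition × role) with the initialization as the observational unit — for
50 initializations and two conditions the interaction has df (1, 196). Both
are computed directly from their sum-of-squares definitions and are
cross-checked against `stats::t.test()` and `stats::aov()` in the test
suite.

For visualization, per-initialization feature × feature correlation
matrices are aligned on canonical feature slots, averaged across
initializations *and* the two categories, converted to distances (1 − r),
and embedded in 2D with classical metric MDS (`stats::cmdscale`). Each
feature's distance to the category centroid (the mean embedded coordinate)
summarizes integration; in MSP-only models shared features sit closer to the
centroid than unique features.

At the defaults, with 50 initializations per condition, the shared-unique
Fisher-Z gap is large under MSP-only (≈ 0.14) and small but reliable under
TSP-only (≈ 0.05), with a strongly significant condition × role interaction
— the qualitative pattern the model family predicts: the monosynaptic
pathway integrates features by their category role; the trisynaptic pathway
keeps representations separated and is much less sensitive to role.

## Synthetic participants

The generator (`simulate_cohort()`) exists to exercise the behavioral
pipeline, not to model cognition. Its memory-warping rule: the remembered
color is the target displaced `bias` CIELAB units toward the category center
plus isotropic Gaussian noise (SD `memory_noise_sd`); the subject picks the
nearest of the five options, with a `lapse` probability of guessing
uniformly and ties broken in seeded random order. A nearest-option rule was
chosen over a softmax for having the fewest free parameters while still
producing graded foil-choice profiles. Biases may vary over blocks
(length-2 inputs are interpolated linearly); defaults emulate the headline
behavioral pattern — a stable shared-feature attraction (2.5 units) and a
declining unique-feature attraction (2.5 → 0.5), memory noise 4 CIELAB
units, lapse 0.1, a per-subject bias offset with SD 0.5, and part accuracy
rising from near chance toward but not reaching ceiling (shared starting
higher, matching early inference advantage for shared parts). Cohort sizes
default to 85 and 109, the two experiments' post-exclusion sample sizes.

The generator does not model reaction times, timeouts, exclusions, color
perception, or any learning dynamics beyond the parameter trajectories. A
passing recovery test therefore shows that the *pipeline* — coding, scoring,
tests — faithfully recovers a known generative ordering (shared > unique >
0 in ≥ 95% of replicate cohorts at the test's generating values); it says
nothing about whether human data would show that ordering.

## Behavioral measures

Color responses are coded +1 (attract foil), −1 (repel foil), 0 (target or
orthogonal foil); the attraction-bias score is the group mean of these
codes, and satisfies the algebraic identity
`score = P(attract) − P(repel)` against the foil-choice profile (asserted on
every table the tests build). Records flagged as timed out are dropped by
default. Classical tests (one-sample and paired t, Cohen's d) are computed
from their direct formulas, with zero-variance score vectors flagged as
degenerate (t = ±∞ for a constant nonzero score, 0 for identically null
scores); Benjamini–Hochberg FDR goes through `stats::p.adjust`. The power
computation iterates n against the noncentral t distribution; it is
**one-tailed by default** because only the one-tailed reading reproduces the
documented sample size of 109 at d = 0.24 and 80% power — an inference the
package makes explicit rather than a stated fact of the design.

## Orchestration and reproducibility

`run_model_experiment()` and `run_behavior_experiment()` chain the stages;
every stochastic stage derives its seed deterministically from the master
seed and the stage name, manifests carry a configuration hash, and a rerun
with the same configuration yields an identical manifest hash. Problem sizes
in the shipped checks are the study scale: 50 initializations per lesion
condition, six epochs of 16 trials, 100 settling cycles per phase, and 100
replicate synthetic cohorts of 100 subjects for the recovery check. The
per-seed results are not checkpointed to disk; a failed run is simply re-run
from its master seed, which reproduces it exactly.

## Known limitations

- The network is a feed-forward rate approximation with a one-to-one big
  loop; it has no CA3 recurrent collaterals, no within-trial weight decay,
  and no spiking or oscillatory dynamics, and its printed t and F magnitudes
  are implementation-sensitive (the directional and significance structure,
  not the magnitudes, is the contract).
- Single-feature pattern completion through the sparse trisynaptic masks is
  intrinsically partial; the TSP-only integration effect is small (by
  design it should be), and its size depends on the inhibition defaults
  documented above.
- CIELAB Euclidean distance is treated as the perceptual metric; no
  conversion to display color spaces is attempted.
- The scheduler's bounded-restart strategy is simple and reproducible but
  not guaranteed to find a sequence if constraints were tightened
  substantially; it errors with a diagnostic rather than looping forever.
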