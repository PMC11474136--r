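---
title: "Evaluating automated triage appraisers with range-method gage R&R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating automated triage appraisers with range-method gage R&R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triageRR)
```

## The problem

When an automated appraiser — for example a large-language-model prompt —
assigns Simple Triage and Rapid Treatment (START) codes to mass-casualty
patients, two questions precede any accuracy claim: does the same prompt
give the same answer when asked again (repeatability), and do different
prompts give the same answer for the same patient (reproducibility)?
Industrial measurement-systems analysis answers exactly these questions, and
because START codes are ordinal (red = 1, yellow = 2, green = 3, black = 4,
in priority order) the *range method* of gage repeatability & reproducibility
(gage R&R) is the right variant: it relies on subgroup ranges rather than on
normality or linearity assumptions.

triageRR packages the full evaluation loop: a deterministic START engine, a
seeded synthetic vignette generator, stochastic appraiser models behind a
pluggable interface, a crossed study runner, the range-method decomposition,
and accuracy/overtriage/undertriage reporting.

## The START engine

The engine applies the canonical published flowchart gates in order:

1. ambulatory → green;
2. not breathing, including after airway repositioning → black; breathing
   only after repositioning → red;
3. respiratory rate strictly over 30/min → red (a rate of exactly 30
   passes, matching the conventional wording "respirations over 30");
4. failed perfusion — absent radial pulse, or capillary refill strictly
   over 2 s — → red; when both indicators are present, either failing
   triggers red (the conservative reading);
5. not obeying simple commands → red;
6. otherwise yellow.

Pediatric patients are triaged with the same adult gates rather than
JumpSTART, because the evaluation this package emulates applied START to
all vignettes regardless of age.  The engine requires consistent structured
input: a vignette that reaches the perfusion gate with neither perfusion
indicator recorded is a configuration error that names the vignette, and
contradictory narratives (e.g. "ambulatory and unconscious") cannot arise
because narratives are rendered *from* the structured fields, never parsed
back.

```{r engine}
p <- physiology(ambulatory = FALSE, spontaneous_breathing = TRUE,
                respiratory_rate = 32, radial_pulse_present = TRUE)
decision_trace(p)
```

## What the synthetic cohort emulates

`generate_cohort()` reproduces the composition of the 391-vignette training
cohort that the reference evaluation used: 25 black, 35 red, 130 yellow and
201 green vignettes; ages from a normal(29.9, 18.2) truncated to 0–80 years
and rounded to whole years, with the pediatric share (≤ 16 y) pinned at
27.9% by sampling the age mixture conditionally on the cut; 71% male.
Physiology is sampled within class-conditional clinically plausible ranges
(e.g. a yellow vignette has a respiratory rate of 10–30, a palpable radial
pulse, refill ≤ 2 s and obeys commands) and every draw is verified against
the engine at generation time, so the labelled class and the engine's class
agree by construction.  Red vignettes mix four failure modes (airway
recovery, tachypnea, failed perfusion, altered mental status) with weights
chosen once for heterogeneity (0.15/0.3/0.3/0.25); the evaluation's source
database does not publish its mode mix.

Narratives come from a small library of templates (three surface forms, with
the body varying by which observations are present), selected
deterministically from the vignette id; they vary in wording the way real
training vignettes do, but they carry no semantics beyond the structured
fields.  What passing tests on this cohort therefore show is that the
*pipeline and statistics* behave correctly — they do not show that any
particular LLM behaves like the stochastic stand-ins, and no claim about
real prompt wording effects can be read off the simulation.

## Appraiser models

A synthetic appraiser is a 4×4 row-stochastic confusion matrix conditioned
on the vignette's reference code, plus an invalid-response rate (default
0.3%, the rate the reference evaluation observed) and a template library for
embedding the colour word in text.  Replicate-to-replicate variation is
modelled as i.i.d. draws per query — the simplest mechanism that reproduces
the central observation that the same prompt does not always return the
same answer.  This is a deliberate simplification: real LLM responses are
exchangeable only approximately, and per-vignette determinism (about half
of all prompt × vignette cells in the reference evaluation had zero range
over ten replicates) is *not* reproduced by i.i.d. draws.  Consequently the
simulated repeatability is substantially larger than the published 0.17 —
see "Known limitations" below.

The nine-appraiser demonstration preset anchors each per-class diagonal at
the published per-class agreement rates (red 80.9%, yellow 50.8%, green
69.4%, black 64.6%) and shifts it per prompt so the expected per-prompt
accuracies equal the nine published values (71.8 … 46.7%); error mass is
split to make overtriage dominate (expected pooled overtriage 32.9%,
undertriage 3.1%).  Red-reference errors can only be undertriage and
black-reference errors only overtriage, a direct consequence of the ordinal
encoding.  These matrices are presets for demonstration, not estimates —
the reference evaluation published no per-prompt confusion matrices to fit.

## The crossed study and parsing

`run_crossed_study()` executes the crossed layout appraiser-outermost, then
vignette, then replicate, exactly one record per planned trial regardless of
invalid responses.  Queries are prompt + narrative + the fixed instruction
"Answer only with the color code and no other text".  Responses are parsed
by case-insensitive word-boundary token matching: a response is valid iff
exactly one *distinct* colour word occurs (any number of times), so "RED."
parses, "hundred" does not, and "red or yellow" is invalid.  External
appraisers plug in as callbacks taking the built query string; a callback
that still fails after 2 retries yields an invalid record and the run
continues.

## The range-method decomposition

With k appraisers, n parts and r replicates:

* d2 constants are the expected range of m independent standard normal
  deviates, computed by numerical integration of
  `E[range] = ∫ 1 − Φ(x)^m − (1 − Φ(x))^m dx` (absolute tolerance 1e−6,
  cached).  This matches published control-chart tables where they exist
  (d2(2) = 1.128, d2(10) = 3.078) and extends to the 391-part subgroup the
  part-variation step needs.  Using the integrated constant rather than the
  3-digit table value moves third-decimal results (e.g. a two-part worked
  example gives 1.7725 where table arithmetic gives 1.773).
* Repeatability: EV = R̄/d2(r), R̄ the mean per-cell (appraiser × part)
  range of valid ordinals.  Cells with fewer than two valid responses
  cannot contribute a range; they are excluded and tallied.
* Reproducibility: AV = sqrt(max(0, (R_A/d2(k))² − EV²/(n·r))) with R_A the
  spread of appraiser mean ordinals — the standard bias correction for
  repeatability leaking into appraiser means, clipped at zero.  No d2*
  small-sample correction is applied beyond this term; the simpler
  convention is declared and verified against a brute-force oracle instead.
* GRR = sqrt(EV² + AV²); PV = (spread of part means)/d2(n); TV² = GRR² + PV².
* Percent figures are **variance** contributions (component²/TV² × 100),
  not SD ratios: only under this convention do the published shares
  14% + 4.2% + 81% sum to ~100 given EV = 0.17 and AV = 0.091.
* Usability bands on %GRR: < 10 adequate for general use, 10–30 adequate
  for low-risk use (30 itself inclusive), > 30 inadequate.

Degenerate inputs are signalled, not silently absorbed: no usable cells, a
single appraiser, a single part, or an all-zero decomposition each raise an
error; a perfectly consistent system returns EV = AV = GRR = 0 exactly with
pct_PV = 100.

## Accuracy metrics

Accuracy is the share of *valid* responses matching the adjudicated
reference standard; invalid responses leave the denominator.  Overtriage is
assigning a lower ordinal (higher acuity) than the reference, undertriage a
higher ordinal — so any live code assigned to a black-reference patient
counts as overtriage, following the ordinal definition even though it is
clinically debatable.  Per-appraiser SDs are computed over the replicate-
level accuracy proportions (the grouping is otherwise underdetermined).
The reference standard itself comes from two raters plus a tiebreaker;
three-way disagreements are marked unresolved and excluded downstream with
a warning rather than guessed.  Cohen's κ is unweighted with the asymptotic
normal CI on Cohen's standard error.

## Problem sizes and reproducibility

The defaults run the full crossed design — 9 appraisers × 391 vignettes ×
10 replicates = 35,190 trials — in a few seconds; unit tests use smaller
layouts (2–3 appraisers, ≤ 20 vignettes, ≤ 10 replicates) and the oracle
equivalence checks use randomized 3 × 5 × 4 designs over 20 seeds.  Every
stochastic stage takes an explicit integer seed, restores the caller's RNG
state, and is byte-reproducible: the pipeline manifest records md5 digests
that are identical across reruns of the same config and seed.

## Known limitations

* i.i.d. per-query draws overstate within-cell variation relative to a real
  LLM whose answers are strongly vignette-conditioned.  The preset run's
  EV (~0.5) is therefore far above the published 0.17 even though its
  accuracy structure matches; treat simulated EV/AV as properties of the
  stand-in, not predictions.  Relatedly, the published EV = 0.17 is not
  derivable from the published range frequencies themselves (their mean
  range ≈ 0.63 gives 0.63/d2(10) ≈ 0.20); this package documents its
  convention (EV = R̄/d2(r)) and does not attempt to reverse-engineer the
  difference.
* The appraiser interface is offline by design; no network client ships
  with the package.
* Only plain Cohen's κ is provided; weighted variants and ANOVA-method
  gage R&R are out of scope, as are JumpSTART/SALT and any treatment
  recommendations.
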