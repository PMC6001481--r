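---
title: "Modeling sensitive-period effects in second-language learning with the dual-path network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sensitive-period effects in second-language learning with the dual-path network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`dualpathL2` implements a connectionist account of why age of acquisition
(AoA) limits second-language (L2) morphosyntax learning while length of
exposure (LoE) helps, and why L2 learners can be *worse* at frequent rules
(determiners, plurals) than at rare ones (third-person -s, past tense).
The package contains four coupled pieces:

1. **Miniature languages.** Two artificial grammars — an English-like SVO
   language with determiners, plural *-z*, particle verbs, third-person
   *-ss* and past *-ed*, and a Korean-like SOV case-marked language with
   verb-final morphology (*ka/ul/eykey*, *-da/-eoss/-iss*) — that share
   one meaning system (concepts, roles X/Y/Z, kind/number features,
   event semantics).
2. **Corpus statistics.** Forward conditional probabilities (CPs) of five
   morphosyntactic rules, e.g. DET CP = P(determiner | verb), computed
   over "units" in which suffix morphemes are absorbed into their head
   word, plus transcriptions of published child-directed-speech counts
   against which the arithmetic is checked.
3. **The dual-path network.** A simple recurrent sequencing pathway
   (previous word → ccompress → hidden → compress → produced word, with a
   context copy of the hidden layer) coupled to a meaning pathway in
   which per-sentence *fast weights* of strength 6 bind roles to concepts
   in both directions.
4. **Simulations and measures.** Korean L1 training with 3-year weight
   checkpoints, English (or bilingual) L2 continuation from each
   checkpoint, and three outcome measures: word-prediction accuracy,
   SSE-based rule proportion from matched grammatical/ungrammatical
   items, and the code-switching rate of greedy production.

## The grammars

Messages are sampled structure-first (intransitive / transitive /
dative), with animate agents (X) and goals (Z), an unrestricted
patient/theme (Y), kind features (DEF/INDEF/PROX/DIST) and number
features (SING/TWO/THREE/PLUR) per argument, and optional PAST and PROG
event features (present/simple are defaults with no feature).  Mass nouns
(*sugar, milk, water, coffee*) surface bare when non-singular in both
languages.  Realization is deterministic, so a corpus record can always
be regenerated from its message — a property the tests exploit.

A quarter of training records have their message withheld (the exact
count is enforced), which pushes the sequencing system to carry purely
syntactic knowledge.

### Calibrating the grammar ("table7-tuned")

The published grammar was built so that the five rule CPs in its training
corpora come out near DET 0.47, PL 0.40, PAR 0.22, 3PS 0.16, PST 0.11.
The distributional parameters behind that profile are not stated, so the
packaged `table7-tuned` preset derives them in closed form.  Writing
$p_i, p_t, p_d$ for the structure mix, $\varphi$ for the phrasal-verb
probability, $g$ for P(PROG), $p$ for P(PAST) and $s$ for P(SING):

* **PAR** counts exactly the phrasal verbs: $(p_i + p_t)\,\varphi = 0.22$.
* **DET** counts verbs whose object NP opens with a determiner:
  $[\,p_t(1-\varphi) + p_d\,]\; d = 0.47$, where $d$ is the probability
  that an object NP is determiner-initial (it is not when the object is
  INDEF+PLUR, or a non-singular mass noun).
* **PL** is the fraction of noun units carrying *-z*:
  $(1-s)(1-m) = 0.40$ with $m$ the mass fraction of noun slots.
* **3PS** $= (1-g)(1-p)\,s = 0.16$ and **PST** $= (1-g)\,p = 0.11$.

Solving with uniform kind weights (kind features are stated to be equally
frequent) gives the preset: structure mix (0.4067, 0.1433, 0.45), number
weights (0.5442, 0.2029, 0.2029, 0.05), P(PAST) = 0.2723, P(PROG) =
0.596, phrasal 0.4.  A 20,000-pair corpus generated from this preset
reproduces the target profile within sampling noise (≈ ±0.01); the
acceptance tolerance is ±0.05.  Note that this preset necessarily drops
the 8:1 singular bias of the naive defaults: an 8:1 bias caps the plural
CP at about 0.27 and cannot reach 0.40.  The naive preset keeps the 8:1
bias for users who want the stated bias rather than the stated CP
profile.

## The network

Defaults: hidden 160, compress 60, ccompress 20, four role units
(A, X, Y, Z), one concept unit per concept plus one per kind/number
feature (46 in total), seven event-semantics units (PAST, PROG, XX, YY,
ZZ, LANG_EN, LANG_KO), and a word layer over the full bilingual
inventory plus boundary tokens (106).  A message binds each noun role to
its concept *and* to its kind and number feature units (the message
notation of the grammar tables prints these explicitly, e.g.
"X = DOG, DEF, SING"); tense and aspect remain absence-coded in the
event semantics.  Without role-bound noun features the network provably
cannot choose among determiners or decide plural marking, and the
determiner rule never rises above chance.  All learned weights (biases
included) start uniform on [−0.25, 0.25], i.e. a total range of 0.5.
The layer sizes are a desk-scale calibration: large enough that the
Korean grammar is learned to high accuracy within a handful of model
years and that a frozen-syntax late learner can still reach the
published mid-60% English accuracy through its lexical route (both
checked in the tests), small enough that full scaled simulations run in
minutes.

Per step, activation flows previous-word → cconcept → (fast transpose) →
crole → hidden and previous-word → ccompress → hidden, alongside context,
event semantics and an accumulated crole trace; and hidden → role →
(fast) → concept → word together with hidden → compress → word.  The
crole trace accumulates by elementwise maximum — a reconstruction of
"keeps track of the roles that have been processed"; sum or decaying
traces would also be defensible, but the maximum keeps the trace bounded
and order-free.  Context resets to 0.5 at sentence start.

Training is per-step backpropagation with the context treated as fixed
input (the standard Elman regime — no unrolling through time).  The
output layer is either **softmax**, trained under multinomial
cross-entropy (output delta `o − t`), or per-unit **logistic**, trained
under summed squared error, whose delta `(o − t)·o(1 − o)` carries the
activation-function derivative — the classic entrenchment factor: as
units commit toward 0 or 1, the same error moves the weights less, so
early knowledge becomes progressively harder to overwrite.  Plain
gradient descent under that loss is an order of magnitude too slow to
meet the behavioral calibration that a rate of 0.1 brings the first
language to adult level within about five model years, so the logistic
regime uses classical momentum (0.9), the standard accelerator in this
simulator family; the softmax regime needs none and uses plain descent.
With momentum the squared-error model shows exactly the intended
life-course: fast first-language acquisition, then gradual decade-scale
second-language curves on which later starters are slower but
eventually converge.

The lexical/syntactic partition used by the dual-rate schedule is exact:
lexical = {concept→word, hidden→compress, compress→word, output bias};
syntactic = every other learned group (interior biases included).  The
fast binding matrices are installed per sentence and never persist.

The reported error measure is always the summed squared difference
between output activations and the one-hot target, independent of the
training loss.

## Schedules and simulations

Rates are a function of total model age (1 model year = 1,000 training
trials), never of time since L2 onset:

* constant — 0.1 for life (Simulation 1, logistic output);
* stretched-Z — 0.1 through year 10, linear decline to 0.025 at year 16,
  flat after (Simulation 2);
* dual-rate — syntactic rate declines 0.1 → 0 over years 10–16, lexical
  rate constant 0.1 (Simulations 3 and 4).

The decline is linear because only its endpoints are described.  L1
training runs on a fresh 20,000-pair Korean corpus (cycled when needed)
up to the largest AoA, with snapshots every 3 years; each snapshot seeds
an L2 run on a fresh English corpus (Simulations 1–3) or a 50/50
randomly interleaved bilingual corpus whose messages carry exactly one
language feature (Simulation 4).  The L1 phase carries no language
feature; the feature is introduced together with the bilingual input.

Judgment items use the canonical printed frames ("a boy touch -ed the
apple", "two boy -z touch -ed the apple", "a boy break -ss down the
apple"), varying only the content words, and are evaluated
production-style: the generating message is installed, and the
prediction error at the divergence point is scored against the omitted
token and against the token that replaces it.  Evaluation draws are
fresh at every checkpoint (with recorded seeds)
rather than reusing one fixed test set; both readings of the published
procedure are defensible and fresh draws avoid overfitting the metric to
one sample.

The effect analysis regresses rule proportion on AoA × LoE × rule CP
(centered) with a per-subject random intercept.  With few subjects the
random-intercept variance often estimates to zero; the fixed effects
remain valid and the summary records the singular fit.  The rule-CP
predictor is measured on each subject's own English training input with
the same unit-absorption convention as the corpus statistics.

### Problem sizes

The package's own checks use a scaled design: AoA {3, 12, 21} × 3
subjects, 1,000 trials per year, evaluations every 2 years with 100
judgment items per rule and 200 test sentences per language; the
dual-rate and bilingual simulations keep the full 20 years of L2
exposure (their late-learner claims concern asymptotic behavior), while
the constant-rate simulation uses 10.  These sizes were chosen so a
full scaled simulation completes in minutes on one core while the
qualitative effect signs are stable across seeds; the full design (AoA
3–21 by 3, 10 subjects, 20 years) is available through
`simulation_spec(sim, "full")`.

## What the generator does and does not emulate

The synthetic languages capture the rule-bearing structure the analyses
need — determiner/plural marking tied to kind and number features,
particle verbs, agreement-like -ss, tense morphology, case marking and
verb-final order in the L1 — under fully known distributional statistics.
They do not contain relative clauses, questions, passives, case-marker
omission, lexical ambiguity across languages, or any pragmatics, and all
sentences are short.  Passing simulations therefore demonstrate that the
*mechanism* (shared network, age-dependent rates, lexical/syntactic
split) produces the published qualitative pattern under these idealized
conditions — not that it quantitatively fits human learners.

## Numerical notes and limitations

* Generation, initialization and training are exactly reproducible given
  a seed; the compiled core is deterministic and single-threaded.
* Weight matrices update in place in compiled code; snapshots must go
  through `copy_network()` / checkpoints (both deep-copy).
* Greedy production breaks activation ties toward the lowest word index
  and never emits the sentence-start token.
* `rule_proportion` errors on degenerate all-zero SSEs instead of
  silently returning 0.5; `rule_cp` errors on zero denominators.
* Softmax is computed with max-shifting; logistic cross-entropy is used
  with activations strictly inside (0, 1), so no clipping is needed at
  these scales.
* The mixed-model analysis fits the raw proportion (no transform); with
  proportions near 0.5 and modest variance this is innocuous, but it is
  not a logistic item-level model of judgments, and no such model is
  attempted for the simulated data.
* In this grammar, rule frequency (CP) is negatively confounded with
  per-instance difficulty: the low-CP rules (third-person `-ss`, past
  `-ed`) are near-deterministic once the message fixes tense and number
  — and an L1 habit of post-verbal suffixes reinforces them — while the
  high-CP rules demand harder choices (eleven determiners; particle
  versus object onset).  Under full syntactic plasticity the model
  therefore tends to show a *negative* main effect of rule CP on rule
  proportion even in the constant-rate regime, where a frequency-driven
  positive effect might be expected; the age-related interactions are
  unaffected.  Users comparing frequency accounts should keep this
  confound in mind.
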