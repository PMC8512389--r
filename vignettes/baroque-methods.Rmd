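---
title: "Hybrid bee-swarm / deep-Q feature selection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid bee-swarm / deep-Q feature selection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter, the places where the
design was genuinely open and what we chose, and what the synthetic-data
tests do and do not establish about real wearable-sensor data.

## The task and the objective

Human activity recognition from body-worn inertial sensors is a supervised
multi-class problem over windows of accelerometer/gyroscope signal. After
windowing and feature extraction, each window is a vector of `N` named
features; wrapper feature selection searches binary masks `s` over those
features, scoring each candidate by training a classifier on the selected
columns and measuring held-out accuracy. Two results are compared by
accuracy first and, on exact ties, by the number of selected features —
smaller subsets win because every extracted feature costs computation on
the device. `better()` implements exactly this strict partial order, and
every search engine in the package uses it.

The objective is built once per run (`mask_objective()`): a single
stratified holdout split (default 70/30) drawn from the run seed, then
frozen. Freezing the split makes the fitness landscape a deterministic
function of the mask, which in turn makes memoization sound: metaheuristics
revisit masks constantly, so results are cached by the exact bit pattern
and repeated queries are free. Each distinct mask is additionally evaluated
under its own deterministic RNG substream derived from the mask, so a
mask's value does not depend on evaluation order or on whether the cache is
enabled — a property the test suite checks directly. Published experiments
in this line of work mix 70/30, 90/10 and 10-fold protocols across
datasets; we default to the single stratified holdout (fast, stationary
landscape) and provide `kfold_protocol()` for the rest.

An all-zero mask is invalid rather than scored zero: accuracy is undefined
with no input columns, so region generation and every engine repair empty
masks by setting one bit instead of ever submitting them.

## The outer search: bee swarm optimization

BSO keeps a reference solution and spawns a search region of `nb` masks by
three strategies controlled by `flip`: masks that flip every `flip`-th bit
starting at offsets `0..flip-1`; masks that flip contiguous blocks of
`ceiling(N/flip)` bits; and, if more bees remain, masks flipping
`ceiling(N/flip)` random positions. The first two strategies are exact to
the published worked example (for `N = 16, flip = 4`: flip sets
`(0,4,8,12) … (3,7,11,15)` then `(0,1,2,3) … (12,13,14,15)`); the third is
described in the literature only as "random according to Pareto's law",
which names no distribution — we read it as a seeded uniform choice of
distinct positions and note the Pareto reading as unresolved.

After every bee reports its best local solution to the dance table, the
reference advances. The published pseudocode resets the chance counter at
the top of every iteration, which would make diversification unreachable;
the accompanying prose instead describes a persistent record of remaining
chances. We follow the prose: the counter persists across iterations,
resets on global improvement (and after diversification), and each
non-improving iteration spends one chance, with the escape firing on the
iteration that spends the last — so `max_chances = 3` diversifies on the
third consecutive non-improving iteration, matching the hand-traced
example. Two further ambiguities we resolved:

* *Intensification target.* The prose triggers intensification only when
  the best local solution beats the current reference; we set the reference
  to the iteration's best dance entry in the non-improving case too,
  keeping the search moving rather than stalling on a stale reference.
* *"Furthest solution" for diversification.* Furthest from what is not
  stated, and re-using tabu-listed masks would defeat the tabu list. We
  diversify to the freshly generated candidate with maximal Hamming
  distance from the best global solution among candidates not in the tabu
  list, preserving the stated intent (jump far away) without revisiting.

The tabu list guarantees no reference solution repeats within a run; when
every natural choice is tabu the engine falls back to the best non-tabu
dance entry, then to diversification, then to a fresh random mask. The
dance table is cleared each iteration (whether it persists is unstated; a
cleared table keeps iterations independent given the reference).

## The local search: multi-agent deep Q-learning

Each of the `N` features is an agent. Agent `u` observes a binary vector of
length `2N`: a one-hot block whose entry `u` equals the mask's bit `u`,
followed by the full mask. The published worked example
(`N = 5`, mask `10110`, agent 3 → `0010010110`) places the one-hot block
first even though the surrounding prose describes the opposite order; the
worked example wins here since it is the only operational definition given.
One consequence we keep as specified: an agent whose feature is unselected
has an all-zero block, making its observation agent-anonymous.

Actions are binary — keep or flip your own bit — with two restrictions: a
flip must lie in the XOR neighborhood of the best global solution (only
bits where the current mask and the best global mask differ may flip, so
every accepted flip moves the trajectory toward the best known solution),
and a flip that would empty the mask is unavailable. When the mask equals
the best global solution the XOR set is empty and the restriction
degenerates; we fall back to allowing every position, otherwise all agents
would be frozen exactly when a bee starts at the incumbent.

The reward after a step from accuracy `acc_prev` to `acc_curr` with
selected counts `k_prev`, `k_curr`:

* accuracy up: `r = acc_curr`;
* accuracy down: `r = 0.5 (acc_curr − acc_prev)` (negative);
* unchanged: `r = ± δ · acc_curr`, positive exactly when `k_prev > k_curr`.

The penalty coefficient 0.5 is fixed by the reference design; the design
factor δ is never given a magnitude there, so we default to `δ = 0.1` —
small enough that subset shrinkage never outweighs a real accuracy change
(any accuracy step in a holdout of `m` test rows changes accuracy by at
least `1/m`, and `δ · acc ≤ 0.1` is comparable only when accuracy is flat).

Agents step sequentially round-robin in index order within a search. The
source material describes the per-feature Markov chains as mutually
independent, yet the reward depends on the joint mask, which only one agent
at a time may change; sequential stepping is the interpretation that makes
the environment well-defined, and we flag it as such. Learning state — the
value network, its target copy, the replay buffer and the exploration rate
(tabular mode: the Q-table) — persists across bees and across outer
iterations, so the swarm accumulates experience; the alternative (fresh
learner per bee) would discard almost all training signal at the budgets
used here.

The value network is a single hidden layer (`2N → hid_num → 2`, rectifier,
linear outputs), trained by Adam on the squared temporal-difference error
with uniformly sampled replay mini-batches and a target network copied at a
fixed period. Unstated hyperparameters were fixed once at field-standard
values and are all configurable: `hid_num = 64`, `γ = 0.9`, tabular
`α = 0.1`, network learning rate `1e-3`, ε from 1.0 to 0.05 with ×0.995
decay per step, buffer capacity 10 000, batch 32, target copy every 100
training steps, training every step after a 200-experience warm-up. An
episode terminates only at budget exhaustion, so only the last transition
of a local search is marked terminal.

Both the value network and the convolutional evaluator below are
implemented directly in base-R matrix code (forward pass, backprop, Adam);
at these layer sizes matrix multiplication dominates and R's BLAS handles
it comfortably.

## Evaluators

`knn_evaluator()` (default `k = 2`, the common wearable-sensor setting) and
`svm_evaluator()` (default `gamma = 0.001`) wrap `class::knn` and
`e1071::svm`. `cnn_evaluator()` is a compact 1-D convolutional network —
conv(5)×32 / pool / conv(3)×64 / pool, then fully connected layers sized to
the flattened output, 256 and 64, softmax output — that treats the selected
feature vector as a one-dimensional sequence. That reading deserves a note:
the architecture is motivated by inertial data being a time series, yet the
selector feeds it a feature vector, not a raw series; we implement the
vector-as-sequence interpretation because it is the only one consistent
with the selector's data flow. Two pooling stages need at least 12 inputs;
fewer is an error.

## Comparators

The GA, binary PSO and ACO comparators are deliberately minimal textbook
variants around the published hyperparameters (GA: threshold 0.5, crossover
0.8, mutation 0.01; BPSO: threshold 0.5, inertia 0.9, acceleration 2 and 2;
ACO: 10 ants, initial pheromone 1, deposit 0.1, evaporation parameter
0.95). Choices the sources leave open, fixed here: tournament selection of
size 2 with elitism of one and uniform crossover (GA); global-best topology
with a deterministic sigmoid-threshold transfer, velocity clamp ±4, and the
boundary `sigmoid(0) = 0.5` resolving as "select" (BPSO); inclusion
probability `τ_j / (τ_j + mean τ)`, iteration-best deposit, and
"evaporation rate 0.95" read as the retention factor, since retaining 5 %
per iteration would erase the colony's memory within a few iterations
(ACO). Population sizes and iteration counts are not published; defaults
are 20 individuals/particles and 50 iterations.

## The feature chain

Preprocessing follows the standard inertial recipe: mean imputation of
missing samples, a running median (width 3 by default; the width is not
specified in the source literature and is configurable), a zero-phase
3rd-order Butterworth low-pass at 20 Hz (forward–backward application
avoids phase lag distorting window statistics; the application mode is
unstated upstream), and 2.56 s windows with 50 % overlap (128 samples at
50 Hz, stride 64). The median filter replicates edge values so filtering
preserves length without biasing boundaries toward zero; the Butterworth
filter uses odd-reflection padding to suppress start-up transients. Window
labels are the majority of per-sample labels with ties resolved toward the
label occurring earliest in the window (how per-sample labels become window
labels is never stated upstream).

The default catalogue extracts 26 single-channel features per channel,
matching the published per-channel count for 12-channel smartphone data.
The published material counts 26 but enumerates only 19 (11 time-domain:
mean, variance, SD, mode, median, max, min, zero-crossing rate, IQR,
skewness, kurtosis; 8 frequency-domain: DC, top three frequencies, and
spectral mean/SD/skewness/kurtosis); we complete the set with seven
staples from the accompanying feature table — absolute mean, square-root
amplitude, RMS, peak-to-peak, signal energy, spectral entropy and crest
factor — and expose the full 31-feature menu for custom catalogues.
Channel pairs within each tri-axial sensor group get Pearson correlation
and cosine distance.

Several printed formulas in that feature table are garbled and were
replaced by the standard definitions they evidently intend: the grouped-data
median form (which requires binning never defined) by the ordinary sample
median; SRA by `((1/N) Σ √|x|)²`; frequency center by the power-weighted
mean frequency `Σ f P / Σ P`; RMS frequency by `√(Σ f² P / Σ P)`; the
entropy's unspecified probabilities by normalized squared spectral
magnitudes; and a cross-correlation printed without its square root by the
Pearson correlation. The IQR uses the `(n+1)`-interpolation rule (R
quantile type 6) that the printed formula implies. Degenerate windows
return 0 for skewness, kurtosis and any factor with a vanishing denominator,
so feature matrices are finite for all finite inputs — the selector's
evaluation must stay well-defined on constant windows.

## Synthetic data: what it emulates and what it does not

`sim_feature_table()` plants ground truth directly in feature space:
informative columns with class means on an equally spaced grid of step
`effect_size` (in within-class SD units, class-to-level assignment permuted
per column), redundant columns built as `ρ z + √(1−ρ²) e` with the noise
orthogonalized in-sample so the correlation to the standardized source is
exactly `redundancy_corr`, and label-independent noise columns. Labels are
assigned block-wise then shuffled, so classes are balanced within one
sample and splits stratify cleanly. `sim_recording()` emulates the
signal-level structure the feature chain exploits: dynamic activities as a
band-limited sinusoid plus noise, stationary activities distinguished only
by the gravity component projected through the class's orientation vector.

These generators reproduce the statistical structure the selector uses —
class-conditional mean shifts, controllable redundancy, oscillation bands,
gravity orientation — and none of the rest of real HAR data: no
within-class multimodality from subject differences, no label noise, no
autocorrelation between neighboring windows (which makes random holdout
splits optimistic on real overlapping windows), no sensor drift or
saturation. A selector that passes the planted-recovery tests has
demonstrated that it finds known-relevant columns under clean conditions;
transfer to a specific device and activity set still requires evaluation
on that data.

## Problem sizes and study conditions in the tests

The planted-recovery conditions are fixed: 600 windows, 4 classes, 10
informative + 5 redundant + 85 noise features at effect size 1.5, a
2-nearest-neighbour evaluator, the default swarm settings
(`nb = 10, flip = 5, max_chances = 3`) for 50 iterations, seeds 1–5. The
per-bee local budget defaults to 30 agent steps — enough for each agent of
a differing bit to act a few times at these dimensionalities while keeping
a 50-iteration run in the low thousands of classifier trainings, which the
memoized kNN objective evaluates in about two minutes per seed on one core.
Budget-matched algorithm comparisons use 600 classifier evaluations per
method over three seeds and compare medians; exhaustive-oracle tests run at
`N = 8`, where all 255 nonzero masks can be enumerated. Toy-landscape
optimality is checked in 4 of 5 seeds rather than 5 of 5 because these are
stochastic searches at small budgets, not exact solvers.

## Known limitations

* The DQN observation is agent-anonymous for unselected features (see
  above); richer observations would break the published encoding.
* The sequential round-robin agent schedule is an interpretation; a
  simultaneous-move formalization would need a different reward attribution.
* Fitness memoization assumes a frozen split; resampling splits per
  evaluation would turn the landscape stochastic and invalidate the cache.
* The CNN evaluator is practical for small feature counts (its first dense
  layer is quadratic in the flattened width); kNN or SVM evaluators are the
  realistic choice inside the search loop, with the CNN reserved for final
  models.
* Run reports record wall-clock fields for convenience; they are
  hardware-dependent and excluded from determinism guarantees.
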