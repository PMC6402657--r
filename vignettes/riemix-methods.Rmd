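---
title: "Adaptive Riemannian mixtures of relevance vector machines for multi-class EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Riemannian mixtures of relevance vector machines for multi-class EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemix)
```

## The problem

In a co-adaptive online brain-computer interface, a user performs four
mental tasks (two motor imageries, two speech imageries) while a classifier
decodes 2-second EEG windows every 0.25 s and drives visual feedback. Both
sides learn at once: the machine re-trains between runs, and the user
explores and exploits mental strategies in response to the feedback. Because
the user's EEG distribution drifts — and can drift *back* toward earlier
states — a single model trained on the most recent run is not necessarily
the best predictor; this package instead maintains a mixture of per-run
models whose weights adapt online.

The session protocol assumed throughout: runs of 40 ten-second trials (10
per class, randomly ordered), segmented into 2 s windows advancing by
0.25 s, so each trial yields 33 overlapping segments and each run 1320
labeled segments (330 per class). The first run is a calibration run with
sham feedback (correct with probability 0.8); subsequent runs give
constrained and then unconstrained feedback.

## Features: covariance descriptors on the SPD manifold

The feature of a segment $X \in \mathbb{R}^{D\times T}$ is its spatial
covariance $C = XX^\top/(T-1)$, a symmetric positive-definite (SPD) matrix.
SPD matrices are treated as points of a Riemannian manifold with the
affine-invariant distance

$$d_R^2(S_1, S_2) = \sum_i \log^2 \lambda_i\big(S_1^{-1}S_2\big),$$

which is invariant to any invertible linear mixing of the channels and to
inversion. Linearization at a reference point $C$ uses the matrix logarithm
$T = \log(C^{-1/2} S C^{-1/2})$; Euclidean distances between such tangent
vectors approximate $d_R$ near the reference. The Karcher (Fréchet) mean of
a set is computed by iterated tangent averaging: initialize at the
arithmetic mean, average the tangent vectors at the current estimate, map
the average back through the exponential map, and stop when the mean
tangent norm falls below a tolerance (default `1e-6`, 50 iterations); at
that point the defining first-order condition — zero mean tangent vector —
holds to the same tolerance.

Tangent matrices are vectorized by stacking the diagonal and the
$\sqrt{2}$-weighted upper triangle. The $\sqrt 2$ weight makes the map an
isometry (vector norm = Frobenius norm), which is what makes the tangent
Euclidean distance agree with $d_R$ in the commuting case; a plain factor 2
would not. The weight is an argument (`offDiagWeight`) should anyone want
the alternative.

## Representative-sample selection

Users are asked to repeat one mental pattern throughout a trial, so a
trial's 33 segment covariances should scatter around a central pattern,
contaminated by distraction. For each trial the Karcher mean of its segment
covariances is computed and only the $k$ segments nearest the mean (under
$d_R$, ties to the lower segment index) are kept for training. $k$ trades
diversity against noise and is cross-validated over $k = 8,\dots,12$ on the
next run's data, ranked by confusion-matrix quality; exact ties resolve to
the smaller $k$. A pre-filter may first discard segments whose true-class
probability under the previous mixture falls below $\epsilon_f = 0.1$ —
deliberately *below* the 0.25 chance level, so only certainly-noisy
segments are dropped and the new run's selection stays as independent of
older models as possible. A trial that loses every segment to the
pre-filter keeps its single highest-probability segment (with a warning).

## Spatial filtering

Multi-class common spatial patterns: whiten with the pooled (balanced)
class-mean covariance, approximately jointly diagonalize the whitened
class means with a Jacobi-angle rotation scheme, then rank every component
by the mutual information between its per-segment log-variance and the
class label. The MI is estimated under a Gaussian model of the
log-variance per class (closed form), which is stable at the 330
samples/class the protocol provides; histogram estimators are noisier at
this size. The top `d = 12` components are retained by default. The
contract is deliberately behavioural — "rank components by
class-discriminative information" — and is verified by subspace-recovery
tests rather than by matching one reference implementation, since joint
diagonalization is unique only up to permutation and sign.

## Classifier: sparse multinomial-probit RVM

Each run's selected segments, filtered and mapped to tangent features at
their own Karcher mean, train a multi-class relevance vector machine with
Gaussian kernel $k(x,y) = \exp(-\|x-y\|^2/2\sigma^2)$, $\sigma$ set by the
median pairwise distance of the training features (recorded in the model).
The latent multinomial-probit expectations are one-dimensional integrals
over a standard normal; they are evaluated by fixed 32-node Gauss-Hermite
quadrature, so training is deterministic. Weights get MAP updates with
per-sample precision hyper-parameters shared across classes; the MacKay
update $\alpha_n \leftarrow C\gamma_n / \sum_c w_{nc}^2$ with
well-determinedness $\gamma_n = 1-\alpha_n\Sigma_{nn}$ lets the precisions
of uninformative samples diverge, and samples with $\alpha_n > 10^5$ are
pruned from the basis (the pruning flavour of the multi-class RVM).
Convergence: change of all log-precisions below `1e-4`, at most 500
iterations; the kernel matrix carries a `1e-8` diagonal jitter.

One caveat worth knowing: MAP pruning is not exactly invariant to
duplicating the training set — duplicates compete for the same basis role
and probabilities can shift a few percent even though decisions agree. The
test suite asserts decision-level idempotence and bounds the probability
shift.

## The adaptive mixture

After run $r$, two updates happen. First, the previous run's sub-model is
re-selected: candidates trained on run $r-1$ at $k=8..12$ are scored on the
new data $D_r$ by the confusion-matrix quality
$p(Q) = \min(q)/\mathrm{mean}(q)$ ($q$ = diagonal of the row-normalized
confusion matrix) and the best replaces it. Second, the new run's sub-model
is appended at the inferred $k^\ast$ — the $k$ that just won the
cross-validation, since $D_{r+1}$ does not exist yet. At the very first
update there is no earlier cross-validation; the calibration model keeps
the heuristic $k = 9$ and the run-1 model is appended with the same
$k^\ast = 9$. Priors: every older sub-model $i$ gets $a_i = p(Q_i)$ from
its confusion on $D_r$, re-evaluated at every run; the newest gets the
maximum of those (so it is never suppressed); any $a_i$ below the
suppression threshold $\epsilon = 0.25$ is zeroed.

Online, a segment covariance $C$ is pushed through every sub-model's filter
and compared with its reference mean; with $\bar d_i(t)$ the running mean
of $d_R(C_i, \mu_i)$, the weights are

$$w_i(t) = \frac{a_i/\bar d_i(t)}{\sum_j a_j/\bar d_j(t)}$$

over the active sub-models, and the output is the weighted sum of the
sub-models' class probabilities. The index set of the running mean is not
fully pinned down by its defining description; this package takes the mean
over the *segments of the current trial*, reset at each trial onset and
initialized with the first segment's distance. That keeps weights
responsive to the user's current state while stable within a trial; the
division is guarded by $\max(\bar d_i, 10^{-6})$. Argmax ties resolve to
the lowest class index. The selection/refit pass runs once per run (its
procedure lists its steps once), and all non-suppressed sub-models are
retained — the mixture has no size cap by default.

## Evaluation metrics

*Accuracy* is computed over all 1320 segments of a run, with no
confidence-based discarding. *Confusion-matrix quality* $p(Q)$ penalizes
class bias: a constant predictor scores 25% accuracy but quality 0; the
quality is 1 exactly when all class-wise accuracies are equal. Note the
flip side: an *unbiased* chance-level classifier is balanced and can score
high quality — quality measures balance, accuracy measures correctness,
and they are reported together. *Separability* of two classes is
$d_R(\mu_A,\mu_B)/(\sigma_A\sigma_B)$ with $\mu$ the class Karcher means
and $\sigma$ the standard deviation of member-to-own-mean distances.
*Instability* of a class is the number of principal components needed to
reach 95% (inclusive) of the tangent-space variance at the class mean — a
proxy for exploration (high) versus exploitation (low); a class with zero
variance has instability 0 by convention. Separability and instability are
computed after a 12-component spatial filter, either the previous run's
filter (reconstructing what the online system saw) or one fitted on the
run's own data (preferred for judging the user independently of the
classifier).

Paired run-to-run comparisons use the exact left-tail Wilcoxon signed-rank
test: zero differences dropped, mid-ranks on ties, and the tail probability
taken over all $2^n$ sign assignments (computed by dynamic programming,
identical to enumeration). Published p-values from the original study
reproduce at printed precision for the large majority of entries; the
handful that differ are off by one enumeration step, consistent with a
different zero/tie convention in the original analysis tool. Per-subject
improvement is summarized by the OLS slope of quality over the four
constrained-feedback runs.

## The synthetic session generator

The generator emulates exactly what the covariance feature can see — and
nothing else. A base AR(1)-structured covariance (channel correlation
decaying with index distance, variances in the tens of µV², typical of
band-passed EEG) anchors four class prototypes placed along fixed
orthonormal tangent directions at geodesic magnitude `separation`. Each
trial draws a mean covariance at tangent dispersion `tau` from its class
prototype and emits a zero-mean Gaussian series around it that is *not*
stationary: the block-wise covariance carries (i) a demeaned AR(1) power
fluctuation along the identity tangent direction — the low-rank,
always-present amplitude waxing and waning of real band-passed EEG — and
(ii) AR(1)-correlated tangent excursions in random high-rank directions
whose amplitude scales with `tau`, the within-trial face of exploration.
This anisotropy matters: with a strictly stationary series, within-class
tangent scatter at low dispersion would be pure covariance-estimation
noise, which is isotropic (maximum-rank) and would push the instability
metric *up* as the user exploits — the opposite of what exploration
semantics require. Trials may also receive an implanted 2 s span from a
far-off covariance (probability `pOut`) to model distraction, and the
ground truth records the span so selection tests can verify outlier
rejection. Between runs the
prototypes drift by `drift` along fixed directions and the dispersion
contracts by the exploitation factor `gamma`. A small feedback-driven user
model (dispersion contracts after majority-correct trials, inflates after
majority-incorrect, prototypes step at feedback-regime changes) supports
closed-loop tests. Everything derives deterministically from one integer
seed.

Protocol constants default to the study conditions (60 channels, 256 Hz,
7 runs, 10 trials/class, 10 s trials, 2 s / 0.25 s segmentation). The free
magnitudes default to a mid-performing user — separation 0.8, dispersion
0.4, drift 0.15, gamma 0.9, pOut 0.1, baseline power-fluctuation
magnitude 0.5 (about ±15% channel power swings), within-trial exploration
factor 2 — chosen once as plausible for band-limited EEG covariance
structure and kept fixed. The baseline magnitude is deliberately modest:
the pooled covariance of a long dispersion-free trial must still converge
to its prototype (the Jensen bias of averaging scaled covariances grows
with the square of the fluctuation magnitude).

What the generator does *not* emulate: evoked temporal structure, 1/f
spectra beyond the AR(1) channel structure, volume-conduction forward
models, artifacts other than the implanted spans, or any physiology of
motor/speech imagery. Passing end-to-end tests therefore demonstrates that
the pipeline recovers class structure *placed in the spatial covariance* —
the feature's own modeling assumption — not that it handles every property
of real EEG.

## Numerical choices

- Eigendecompositions are taken on the symmetrized matrix $(S+S^\top)/2$;
  eigenvalues are clipped below at `1e-12` before logarithms, with a
  warning on active clipping.
- Covariance descriptors accept a shrinkage weight toward the scaled
  identity for rank-deficient segments; the default is 0 (the literal
  definition), and a degenerate segment with shrinkage 0 is an error
  rather than a silent repair.
- Band-pass (8–70 Hz, order 5) and notch (60 Hz) Butterworth filters run
  zero-phase (forward–backward) for offline analysis and single-pass for
  causal replay — which the online experiment used is not recorded, so
  both are exposed.
- Resampling (1000→256 Hz as 32/125) is done in the Fourier domain with
  reflection padding; exact for band-limited signals and
  transient-free at the edges.
- The Jacobi joint-diagonalization sweeps until the largest rotation sine
  falls below `1e-10` (at most 100 sweeps). MI ties break to the lower
  component index.
- Gauss-Hermite nodes come from the Golub–Welsch eigenproblem; 32 nodes
  throughout.

## Problem sizes in the test suite

The suite exercises the full pipeline at reduced problem sizes chosen to
keep the geometry honest while staying light: 6–12 channels at 64 Hz,
3–4 runs, 5–10 trials per class, CSP dimension 4–6. Segmentation counts
(33 per trial, 330 per class per run) are asserted at the protocol's own
arithmetic. The end-to-end checks adapt over three runs and evaluate on a
held-out fourth: a high-separation session must exceed 80% held-out
segment accuracy, and a zero-separation session must stay within 7 points
of the 25% chance level. The derived statistics of the published study
tables are recomputed from the shipped plain-text tables at full size.

## Known limitations

- The readers cover the common continuous-EEG subset of EDF and
  BrainVision (equal-rate channels; binary INT_16/IEEE_FLOAT_32 and ASCII
  vectorized layouts); annotation-channel parsing is out of scope.
- Ocular-artifact removal is a pass-through hook; plug in a method via
  `removeEOGArtifacts(method = ...)`.
- The mixture adapts per run (batch), not per sample; that is the design,
  matching the co-adaptation argument that the machine should hold still
  while the user adapts.
- Separability requires at least two samples per class and positive
  spread; degenerate classes raise diagnostics rather than returning
  infinities.
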