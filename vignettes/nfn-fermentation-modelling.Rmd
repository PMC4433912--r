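---
title: "Neuro-fuzzy modelling of batch fermentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy modelling of batch fermentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfnferm)
```

## The model

`nfnferm` models a batch fermentation as a discrete-time system: the state
at the next sampling instant — cell mass $X$ (g/L), lactose $S$ (g/L),
dissolved oxygen $C$ (mg/L) — is a static nonlinear function of the current
state and the elapsed time,

$$\begin{aligned}
X_{k+1} &= f_X(t_k, X_k, S_k, C_k),\\
S_{k+1} &= f_S(t_k, X_k, S_k, C_k),\\
C_{k+1} &= f_C(t_k, X_k, S_k, C_k),
\end{aligned} \qquad k = 1,\dots,K-1,$$

and the three $f$'s are approximated jointly by one three-layer network:

1. **Normalization.** Every input slot and every output variable is divided
   by its maximum over the training set, mapping the data into $[0, 1]$.
   This is a hard assumption: states encountered at prediction time that
   exceed a training maximum by more than 10% trigger a warning and are
   clipped (recursive simulation can drift slightly beyond the maxima; the
   ramp output keeps predictions bounded by them, so the drift cannot
   compound).
2. **Hidden layer.** $J_m$ neurons with logistic sigmoid transfer
   $x_j = (1+e^{-a_j\cdot u})^{-1}$ and weights $a_{ji}$ drawn i.i.d. from
   $\mathrm{Uniform}(0,1)$, then frozen. The network is therefore a
   random-feature expansion; all learning happens downstream.
3. **Output layer.** A piece-wise linear unit ramp
   $\mathrm{ramp}(v)=\min(\max(v,0),1)$ applied to $w_j \cdot x$. On the
   training data the targets are normalized into $[0,1]$, where the ramp is
   the identity, so fitting the output weights is a *linear* problem.

A constant unit signal enters twice when `include_bias = TRUE` (default): as
a bias input to every hidden sigmoid and as an intercept signal for every
output neuron. The architecture diagrams this family of networks is drawn
from place a single constant source ambiguously; feeding it to both layers
is the choice that costs nothing and measurably conditions the linear solve,
so it is the default and a single flag controls it.

### The fourth input

Only three state variables exist, but the network uses four inputs. The
default recipe is `c("t", "X", "S", "C")`: normalized elapsed time plus the
three states. Time is the natural fourth signal for a batch process, whose
dynamics are strongly phase-dependent (lag, exponential growth, substrate
exhaustion). The recipe is configurable — `c("X", "S", "C", "one")`
expresses a duplicated-bias variant — so the choice is a default, not a
constraint.

## Training: fuzzy least squares in one solve

For each batch $r$ the fit quality is the time-weighted least-squares
criterion over its one-step transitions (normalized scale),

$$J_r = \sum_{k=1}^{K-1} \gamma_k\, \lVert y_{k+1} - \hat y_{k+1}\rVert^2 ,$$

with $\gamma_k \ge 0$ (default: uniform 1 — nothing in the method requires
non-uniform weights, and uniform is the only choice that treats all phases
of the cultivation symmetrically a priori). Stacking every transition of
every batch gives the design matrix $Z$ (hidden signals, one row per
transition) and target matrix $Y$; the weighted normal system is

$$M = Z^\top \Gamma Z, \qquad B = Z^\top \Gamma Y, \qquad M w \cong B .$$

`solve_weights()` computes the minimum-norm least-squares solution by SVD,
zeroing singular values below `rank_tolerance` (default $10^{-10}$,
relative to the largest). The tolerance matters because Uniform(0,1) hidden
weights produce strongly collinear features — all are increasing in every
input — so $M$ is routinely ill-conditioned and occasionally numerically
rank-deficient; the SVD route makes that a reported property (`rank` in the
training report) instead of a failure.

The fuzzy element enters as *grading*, not as fuzzy arithmetic: the
equality $M w \cong B$ is required to hold only to the degree given by the
membership of the criterion,

$$\mu_r = \exp(-J_r/\sigma) \quad\text{(default)}, \qquad
  \alpha = \min_r \mu_r ,$$

the Bellman–Zadeh minimum across the $R$ experiments. A linear membership
$\max(0, 1 - J_r/\sigma)$ is available; the exponential is the default
because it never collapses to exactly zero and thus always ranks candidate
models. The scale $\sigma$ (default 1, on the scale of summed squared
normalized residuals) sets how quickly satisfaction decays; with $K-1=12$
transitions and 3 outputs, $J_r \approx 0.01$–$0.1$ for good fits, so the
default keeps $\alpha$ usefully inside $(0.9, 1)$ rather than saturating.

Because training reduces to one linear solve, the ramp's saturation is
ignored while fitting. The assumption is checked after the fact: if more
than 1% of fitted pre-activations fall outside $[0, 1]$ (beyond a $10^{-6}$
numerical margin — targets can sit exactly on the knee), training warns
that the linear solution is not the true least-squares optimum of the
saturated network.

### Hidden-size selection

`select_hidden_size()` trains each candidate $J_m$ in `j_range` and applies
the acceptance rule: the smallest $J_m$ with $\alpha \ge$
`acceptance_alpha` (default 0.8), falling back to the argmax of $\alpha$ if
none qualifies. Candidates use seed `config$seed + J_m`, so the random
hidden draws are independent across candidates yet reproducible. $\alpha$
is *monitored, not assumed monotone* in $J_m$: a larger random feature set
usually fits better but need not, and the per-candidate table is returned
so the user sees the whole profile.

## The synthetic-data generator

No cultivation dataset for this process is publicly deposited, so the
package generates its own study material with a Monod-type mechanistic
surrogate:

$$\frac{dX}{dt} = \mu X,\quad
  \mu = \mu_{max}\frac{S}{K_s+S}\frac{C}{K_c+C};\qquad
  \frac{dS}{dt} = -\frac{\mu X}{Y_{xs}};\qquad
  \frac{dC}{dt} = k_La(C^\ast - C) - \frac{\mu X}{Y_{xc}} .$$

Defaults (all configuration, not constants): $\mu_{max}=0.45$ 1/h,
$K_s=1.2$ g/L, $K_c=0.3$ mg/L, $Y_{xs}=0.5$ g/g, $Y_{xc}=0.05$ g/mg,
$k_La=60$ 1/h, $C^\ast=7$ mg/L, with $X_0=0.2$ g/L, $S_0=44$ g/L,
$C_0=7$ mg/L over 12 h. These values give near-complete lactose depletion
within the 12-hour window, a realistic oxygen sag to roughly 5 mg/L during
peak uptake, and biomass accounting consistent with the yield — the
qualitative shape of an aerobic whey-lactose batch. Six batches sampled at
13 hourly points is the default layout. Per-batch initial conditions are
jittered uniformly by ±5% (ordinary inoculum and medium variability), and
measurements carry 2% multiplicative Gaussian noise clipped at zero —
relative noise because Kjeldahl, enzymatic-UV and oxygen-probe errors scale
with the signal. The dissolved-oxygen unit (mg/L) is a convention of the
generator, carried in column names, not hard-coded logic.

The same mechanistic model provides the "conventional model" arm of the
comparison methodology (`conventional_predict()`): from each measured state
it integrates one sampling interval forward, so both arms predict from
identical information.

What the generator does *not* emulate: pH and temperature excursions (held
constant in the emulated protocol), product formation, sensor drift or
autocorrelated noise, irregular sampling, and model mismatch between the
data-generating process and the conventional baseline (the baseline *is*
the generator unless deliberately perturbed). Tests passing on this
material therefore demonstrate correctness of the algorithms, not that the
network rivals mechanistic models on real cultivations.

## Numerical choices

* **Integration**: classical fixed-step RK4 (`deSolve`, `method = "rk4"`),
  default `dt = 0.01` h. The fastest time scale is oxygen transfer
  ($1/k_La \approx 1$ min); `simulate_batch()` warns when
  `dt * kLa > 2`, approaching the explicit-RK stability bound. Stiff
  solvers are unnecessary at these scales and fixed steps make runs
  bit-reproducible.
* **Degenerate inputs**: an all-zero normalization column is an error (the
  variable carries no scale); a constant-in-time dataset is legal and is
  fitted exactly through the intercept signal, with the documented caveat
  that its targets sit on the ramp knee.
* **Ties**: hidden-size selection prefers the *smallest* qualifying
  candidate; in model comparisons the Fisher ratio is judged by
  $|F_E - 1|$, since the ideal variance ratio of a perfect fit is unity
  and both directions of departure are misfit.
* **Serialization**: model JSON stores weights with 17 significant digits,
  which round-trips IEEE doubles bit-exactly.
* **Reproducibility**: every stochastic step (hidden weights, jitter,
  noise) flows from an explicit integer seed through `withr::with_seed()`,
  leaving the caller's RNG state untouched.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the method at the study scale
it is designed for — $R = 6$ batches, $K = 13$ samples, $J_m = 5$ hidden
neurons — plus smaller parameter-recovery layouts (12 batches × 4 points)
where exactness is the point; the solver is cross-checked on random systems
up to dimension 20. These sizes exercise every code path in seconds.

## Known limitations

* With $J_m = 5$ and all-positive Uniform(0,1) hidden weights, the feature
  map is nearly affine over the unit box. One-step prediction of $X$ and
  $S$ is strong, but low-variance, sharply nonlinear channels — dissolved
  oxygen around substrate exhaustion — are systematically the hardest, and
  measurement noise bounds the attainable correlation for any predictor on
  such channels. The comparison tests in `test-acceptance.R` document this
  honestly rather than relaxing their thresholds.
* Training data must cover the state region visited at prediction time;
  extrapolation beyond the training maxima is clipped, which biases rather
  than extrapolates.
* The network is a surrogate for *this sampling grid*: it learns
  $t_k \mapsto t_{k+1}$ maps at the training spacing and has no notion of
  continuous time between samples.
* Fuzziness enters only through the criterion's membership; weights are
  crisp reals, and no linguistic variables are implemented.
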