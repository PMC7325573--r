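---
title: "Methods: soft sensing and predictive control of a fed-batch lysine fermenter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft sensing and predictive control of a fed-batch lysine fermenter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermpc)
```

## The problem

Product concentration $P$ in fed-batch l-Lysine fermentation cannot be
measured on-line: the assay is an off-line laboratory procedure with a
two-hour cadence, while the auxiliary process channels — temperature $T$,
pH, agitation rate $u_1$, dissolved oxygen $DO$, airflow rate $u_2$ and
ammonia flow rate $u_3$ — are available every 15 minutes. `fermpc`
implements the full chain that turns this into a control problem:

1. a **soft sensor**: an LSSVM regression from the six auxiliary channels
   to $P$, with its two hyperparameters tuned by Grey-Wolf Optimization
   against a cross-validation RMSE;
2. a **non-linear MPC** that, at each 15-minute instant, asks a
   population optimizer for the input increments minimizing a
   receding-horizon tracking cost evaluated through the soft sensor;
3. a **synthetic fed-batch plant** standing in for real fermenter
   campaigns, so the whole chain is reproducible at desk scale.

## LSSVM regression

Given training pairs $(x_i, y_i)_{i=1}^l$, the least-squares SVM replaces
the SVM's inequality constraints by equalities with squared slack, so
training reduces to one dense linear system via the KKT conditions:

$$
\begin{pmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} & K + g^{-1} I \end{pmatrix}
\begin{pmatrix} b \\ \alpha \end{pmatrix} =
\begin{pmatrix} 0 \\ y \end{pmatrix},
\qquad
K_{ij} = \exp\!\left(-\frac{\lVert x_i - x_j\rVert^2}{2\sigma^2}\right),
$$

with predictor $y(x) = \sum_i \alpha_i K(x, x_i) + b$. The penalty $g > 0$
is an inverse ridge strength; the width $\sigma$ sets the kernel's length
scale on the normalized feature space. We solve the $(l{+}1)\times(l{+}1)$
system as one unsymmetric dense solve with partial pivoting (the block
matrix is symmetric but indefinite, so Cholesky is not applicable), verify
the residual, and report the condition estimate if it exceeds $10^{12}$.
The distance in the kernel is the squared Euclidean norm over the full
feature vector.

## Hyperparameter search

All channels, target included, are min–max normalized to $[-1, 1]$ with
statistics fitted **on the training batches only**. Batches are split
6 train / 2 cross-validation / 2 test. The tuner minimizes the
cross-validation RMSE (normalized scale) over the box
$g \in [1, 10^4]$, $\sigma \in [0.001, 0.1]$, in raw coordinates; the
first coordinate is read as $g$ and the second as $\sigma$, matching the
magnitudes of typical penalty and width values. Test metrics are reported
on both the normalized and the physical scale, because conventions differ
between studies. The fractional MAPE (no $\times 100$) is reported only
on the physical scale: the normalized target crosses zero.

## Grey-Wolf Optimization

GWO moves a population of candidates toward the three best solutions seen
so far (alpha, beta, delta). Per wolf and per leader, with fresh uniform
draws per component,

$$A = 2 a r_1 - a, \quad C = 2 r_2, \quad
D_L = |C X_L - X|, \quad X_L' = X_L - A D_L,$$

and the new position is the average of the three $X_L'$; the control
parameter $a$ ramps linearly from 2 to 0 over the run. Design choices the
original formulation leaves open, fixed here:

* **Bound handling** — positions are clipped into the box after the
  update, preserving the update law inside the box.
* **Leaders are elitist best-so-far** (not the best of the current
  generation), which guarantees a monotone convergence trace; ties break
  toward the earlier-evaluated solution.
* **Non-finite objective values** map to a worst-possible sentinel so the
  optimizer stays total — the MPC cost can be evaluated at degenerate
  candidates.
* The prey of the encircling metaphor is never materialized; the three
  leaders replace it.

The PSO baseline is canonical global-best PSO: inertia decaying linearly
$0.9 \to 0.4$, $c_1 = c_2 = 2$, velocity clamped at 20 % of the box
width. All of these are exposed in `optimizer_config()`.

## Receding-horizon control

At each 15-minute step the controller minimizes

$$J = \sum_{j=1}^{N_{pred}} Q_{out} (y_{pred}(t{+}j) - y_{ref}(t{+}j))^2
    + \sum_{j=1}^{N_{con}} R_{in} \lVert \Delta u(t{+}j{-}1)\rVert^2$$

over the $3 N_{con}$-dimensional increment box ($\Delta u_1 \in [-15,15]$
rpm, $\Delta u_2 \in [-1,1]$ vvm, $\Delta u_3 \in [-30,30]$ mL/h), with
defaults $N_{pred} = N_{con} = 1$, $Q_{out} = 1$, $R_{in} = 0.001$,
initial inputs $(326, 0.1, 88)$, input boxes $u_1 \in [316,345]$,
$u_2 \in [0.1,1.65]$, $u_3 \in [51,110]$ and output constraint
$0 \le y \le 45$ g/L. Only the first increment is ever applied.
Choices where the blueprint was open:

* **Output feedback is an additive bias** (DMC style):
  $e(t) = y_{meas}(t) - y_{pred}(t|t-1)$ is added to all horizon
  predictions.
* **Output and input box violations are penalized** quadratically
  (weight $10^6$) rather than rejected, keeping the objective total over
  the increment box.
* If $u(t) + \Delta u$ would leave the input box, the result is clamped
  onto the box and the event logged — enforcing simultaneous feasibility
  of both boxes.
* The reference trajectory is previewed (both built-in scenarios use
  pre-specified references); temperature and substrate are held fixed.
* During optimization the measured $T$, pH, $DO$ are frozen at their
  latest values while the candidate $u$ varies. A static six-feature
  sensor therefore gives the controller only the *correlational* response
  of $P$ to the actuators, not a causal process model — tracking on the
  mechanistic plant is consequently loose, which is a documented
  limitation of the static-map design. The optional lagged-product
  regressor (`include_lag = TRUE` in `tune_soft_sensor()`) is the
  recommended configuration for closed loop; the constraint-satisfaction
  guarantees hold for either regressor.

## The synthetic plant

No kinetic model or batch data accompany the original study, so the
simulator is the package's own stand-in, labelled synthetic throughout.
It is the standard minimal fed-batch amino-acid model:

* Monod × logistic growth,
  $\mu = \mu_{max} \frac{S}{K_s + S} f_{DO}(DO) f_{pH}(pH) (1 - X/X_{max})$;
* Luedeking–Piret production, $\dot P = (\alpha_{lp}\mu + \beta_{lp}) X$;
* oxygen balance
  $\dot{DO} = k_La(u_1, u_2)(100 - DO) - (c_\mu \mu X + c_m X f_{DO})$
  with $k_La$ linear in agitation and airflow. The **maintenance term**
  $c_m X$ dominates once growth slows, so the dissolved-oxygen signal
  tracks biomass — the physiological reason a static map from
  instantaneous measurements to $P$ can work at all;
* pH driven by ammonia feed against acid production,
  $\dot{pH} = g_{alk} u_3 - g_{acid} \mu X$;
* temperature controlled at 32 °C with a small **metabolic heat
  signature** ($\le$ ~0.4 °C, proportional to the oxygen transfer rate)
  plus sensor noise. A perfectly constant channel would be degenerate
  under min–max normalization — its scaled values would be pure noise
  spanning the full $[-1,1]$ range, which destroys the locality of any
  narrow RBF kernel — and a slight metabolic warm-up under imperfect
  cooling is also what a real broth shows.

Integration is fixed-step RK4 at 0.025 h internally, observed every
0.25 h; halving the internal step moves the final product by well under
0.1 %. The product channel the sensor trains on is the 2-h-assay series
spline-reconstructed to 15 min (end conditions reproduce cubics exactly);
the raw 15-min product is kept in the record's metadata for honest error
accounting.

### What a campaign emulates — and what it does not

`generate_batches()` emulates a ten-batch identification campaign running
**one recipe**: each actuator follows the same nominal ramp, discretized
into 6 constant feed phases; batch-to-batch variability enters as segment
switch-time jitter (±3 % of the batch length per boundary), small DCS
level execution error (±0.45 % of the actuator box), and initial-condition
spread (inoculum ±4.5 %, substrate ±3 %, inoculation pH ±0.009). These
scales were calibrated once, jointly, against two stated requirements: the
product plateaus in 30–45 g/L over 72 h, and a sensor tuned on 6 batches
with $\sigma \le 0.1$ predicts 2 held-out batches at normalized RMSE
< 0.15 — an RBF interpolant collapses toward its bias within a distance
$\sigma$ of the training manifold, so identifiability at narrow widths
*requires* a recipe-following campaign. The defaults were verified on
eight master seeds before being frozen.

Consequently, a green identifiability test establishes that the pipeline
recovers learnable structure under recipe-scale variability; it does
**not** establish that a static six-channel sensor generalizes across
exploratory campaigns that roam the actuator boxes freely — under such
excursions the narrow-kernel sensor degrades to its bias, which is a
faithful property of the method, not of the implementation. Other real
features not emulated: assay delay and irregular assay timing, sensor
drift and recalibration, feed composition changes, strain variation, and
oxygen-transfer fidelity beyond a linear $k_La$.

## Numerical choices

* KKT solves use LAPACK LU; residuals are checked against
  $10^{-8}\max(1,\lVert y\rVert_\infty)$ and failures name the condition
  estimate.
* Kernel distance matrices clamp tiny negative squared distances (from
  floating cancellation) to zero.
* The assay spline falls back to linear interpolation below 4 knots.
* All randomness flows from a single master seed through named
  sub-streams (`plant`, `tuner`, `controller`, per-batch, per-step)
  derived by a 31-bit string hash, so every stage is independently
  bit-reproducible and derived seeds stay below $2^{31}$.
* One ambiguity in the printed operating envelope (the lower bound of the
  ammonia-flow box) is resolved as $u_3 \in [51, 110]$ mL/h; the bounds
  are constructor arguments, so either reading is available.

## Known limitations

* The static-map controller limitation described above; use the lagged
  regressor for closed loop.
* Sharp step references are physically untrackable on a monotone batch
  process; the step scenario exercises robustness of the machinery, and
  tracking guarantees are asserted only where they are well-posed
  (perfect-model and offset-rejection settings).
* The fractional MAPE is reported as defined; on near-zero actual values
  it is undefined and the evaluator returns `NA` for batches containing
  zeros rather than silently rescaling.
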