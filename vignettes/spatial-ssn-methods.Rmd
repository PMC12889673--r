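---
title: "Spatially extended SSN models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially extended SSN models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ssnspace` implements a spatially extended stabilized supralinear network
(SSN) of mouse V1 layer 2/3 with four recurrent cell types — excitatory (E)
and the PV, SST and VIP interneuron classes — discretized on a regular
two-dimensional retinotopic grid. A unit of type $A$ at grid position $x$
responding to a stimulus of size $s$ follows

$$\tau_A \frac{dr_A(x;s)}{dt} = -r_A(x;s) +
\Big[\sum_B \sum_y W_{AB}(x-y)\, r_B(y;s)\, \Delta^2 + T_A\Big]_+^2,$$

where $B$ ranges over the recurrent types and three external sources:
feedforward drive from layer 4 (L4), feedback from area LM, and a residual
input R standing for unmeasured sources. $[\cdot]_+^2$ is the rectified
quadratic transfer function that gives the SSN its expansive,
activity-dependent gain; a rectified-linear variant is available for
ablation studies. $\Delta^2$ is the grid area element, so the sum
approximates the continuous spatial integral.

Connectivity kernels are isotropic 2D Gaussians,
$W_{AB}(x-y) = \frac{w_{AB}}{2\pi\sigma_{AB}^2}
e^{-|x-y|^2/2\sigma_{AB}^2}$, so each projection is described by a signed
amplitude $w_{AB}$ (non-negative for presynaptic E/L4/LM/R, non-positive
for PV/SST/VIP) and a spatial scale $\sigma_{AB}$. The residual input is a
center Gaussian whose peak grows with the square root of stimulus size,
$r_R(x;s) = \tfrac18\sqrt{s}\, e^{-|x|^2/2\sigma_R^2}$; under a linear
dependence on $s$ the 85°/5° amplitude ratio would be 17, and the square
root scaling exists precisely to temper that growth to $\sqrt{17}$.

The 28 amplitudes and 4 biases are the fitted parameters; spatial scales,
time constants, and the residual profile are fixed inputs.

## Parameters, units, defaults

* **Grid**: the reference configuration in the literature is 30 × 30 nodes
  at 6° spacing. The package's default *fixture* uses 12 × 12 at 6°
  (±33°), chosen so that the full fit–classify–perturb cycle runs in
  seconds to minutes; all functions take an arbitrary
  `retinotopic_grid()`. Node coordinates are centered,
  $x_i = (i-(n-1)/2)\Delta$; for even $n$ the stimulus center falls
  between nodes and "the centered unit" is the nearest node.
* **Stimulus sizes**: 5° to 85° in 10° steps, matching the size-tuning
  protocol the synthetic data emulate.
* **Time constants**: $\tau_E = 20$ ms, $\tau_{PV,SST,VIP} = 10$ ms. The
  source literature does not print $\tau$; the E-slower-than-I convention
  of rate models is used. Every sign-based stability statement is
  invariant to positive rescaling of $\tau$ within a type (tested), but
  the stability report records the $\tau$ used because eigenvalue
  magnitudes scale with $1/\tau$.
* **Kernel scales** $\sigma_{AB}$: inputs, not estimates. The package
  default is a uniform 10°; no projection-specific anisotropy is assumed.
  Pass a 4 × 7 table to override.
* **$\sigma_R$**: default 30°, configurable; the residual gain defaults to
  1/8.
* **Boundaries**: open (truncated); retinotopic space is not periodic, and
  the reference grid at ±87° comfortably contains the largest stimulus.
  Kernel row sums therefore undershoot the amplitude near the rim; tests
  assert convergence to the amplitude with growing extent.

## Numerical choices

* **Trajectory integration** (`integrate_dynamics`): explicit Euler with
  `dt = min(tau)/10`, guarded by `dt <= min(tau)/5`. Rates remain
  non-negative because the update is a convex combination of the current
  state and a non-negative target.
* **Fixed points** (`steady_state`, `solve_fixed_point`): Euler at
  `dt = min(tau)/2` until the relative residual
  $\max|f(u)-r| / (\max r + \varepsilon)$ falls below `tol`
  (default 1e-6), then a damped Newton polish on $f(Wr+h) - r = 0$ once
  the residual is below 1e-2. The Euler phase selects the attractor of
  the actual dynamics; Newton only sharpens the final digits, removing
  the slow tail contributed by near-critical eigenmodes. A Newton step
  that fails to reduce the residual falls back to Euler.
* **Divergence**: any rate above 1e6 aborts with a `diverged` flag —
  supralinear networks need not possess a stable fixed point, and the
  fitter treats such parameter points as high-loss, never as errors.
  Solves whose residual has stopped decreasing far from a fixed point
  (oscillatory non-convergence) are likewise reported early as
  non-converged rather than exhausting the step budget; because such a
  failure can also mean the Euler *step* — not the fixed point — is
  unstable (strongly oscillatory Jacobian modes), a failed solve is
  retried once at one fifth of the step before being reported.
* **Derivative conventions**: $f'(u) = 2[u]_+$ for the quadratic and the
  0/1 step for the linear variant, both defined as 0 at $u \le 0$. Silent
  units therefore have zero gain and decouple from the Jacobian and the
  response matrix — which modes exist depends on which units are active.
* **Eigenvalues**: dense `eigen()` up to 2000 rows, ARPACK
  (largest-real-part) above; the two paths are tested against each other.
  Leading means maximal real part, ties broken by smallest |imaginary
  part|, with the non-negative-imaginary member representing a conjugate
  pair.
* **Eigenvectors** of $R_{XX}$ are unit-norm with the largest-magnitude
  entry made real and positive, so projections are deterministic across
  LAPACK builds. The uniform-pattern coefficients $c = V^{-1}\mathbf 1$
  come from a linear solve; a condition number above 1e10 marks the basis
  defective and predictions fall back to direct matrix action.

## Fitting

The loss is
$L = \big[\sum_s\sum_A\sum_x c_A (r - \tilde r)^2 \,/\,
\sum_s\sum_A\sum_x c_A \tilde r^2\big]^{1/2}$ with per-type weights
$c_A$ (default equal). The denominator is a pure normalization (zero
prediction ⇒ $L = 1$). The printed form of this expression is ambiguous
about whether the normalization is global or per size; the global reading
is the default here because a single normalizing constant is exactly what
"merely a normalization factor" describes, and the per-size alternative is
exposed as `normalization = "per_size"`.

Optimization is L-BFGS-B within sign-respecting boxes (|w| ≤ 5, |T| ≤ 5).
Gradients are computed by implicit differentiation at the converged fixed
point: with $u = Wr + h$ and $A = I - F W$ at the solution,
$dL/d\theta = (F A^{-T} \partial L/\partial r) \cdot \partial u/\partial
\theta$, one adjoint solve per stimulus size. This is the
infinite-unrolling limit of backpropagation through the time-stepped
dynamics, and it matches central finite differences of the objective to
better than 1e-3 relative (tested at random parameter points). Parameter
points with non-convergent dynamics contribute a fixed penalty (10× the
zero-prediction loss) with zero gradient, so line searches back away from
unstable regions without crashing.

Inside the objective, every steady-state solve starts from the observed
rates of that stimulus size (with a fixed cold-start fallback), never from
the previous parameter point's solution. A quasi-Newton optimizer needs
the objective to be a *deterministic function of the parameters*;
warm-starting across parameter points makes the returned fixed point — and
hence the loss — depend on evaluation history, which degrades the line
search. Starting from the data also biases basin selection toward fixed
points resembling the observations, which is the branch a fit should be
scored on when attractors coexist.

Restarts draw amplitudes uniformly in sign-respecting boxes of half-width
`init_scale` (default 2.5, covering the magnitude range a circuit of this
rate scale can support) and biases uniformly in [−1, 1]; initializations
whose dynamics fail to converge at every size are redrawn, up to 20 times.
Ranking returns the `top_k` fits by loss and is bit-reproducible given the
config seed.

Variants for the ablation analyses: `no_recurrent` pins all 16 recurrent
amplitudes at zero (the prediction then reduces to a pointwise function of
the external currents), `no_E_projections` pins the four $w_{A,E}$, and
`linear_nl` swaps in the rectified-linear transfer function.

## Stability and perturbation analysis

At a steady state the Jacobian is $J = T^{-1}(-I + FW)$ with
$F = \mathrm{diag}\, f'(u^*)$. Cell-type-specific stabilization is read
off subnetwork Jacobians with the rows and columns of excluded inhibitory
populations removed: a leading eigenvalue with positive real part means
the excluded population is required for stability. The four standard
subnetworks (E alone; PV, SST or VIP removed) plus the full network are
evaluated per stimulus size.

Linear response about a stable fixed point gives
$\delta r = (I - FW)^{-1} F\, \delta h \equiv R\,\delta h$. A uniform
perturbation $\gamma\mathbf 1_X$ of type $X$ produces
$\delta r_X = \gamma\sum_i c_i\lambda_i v_i$ in the eigenbasis of
$R_{XX}$; its mean can stay positive even when $\lambda_1 < 0$, because
the cross terms of the expansion can outweigh the
$\lambda_1 c_1^2\langle v_1^2\rangle$ term. The patterned perturbation
$\gamma v_1$ isolates that mode: its projection is $\gamma\lambda_1$, so
the response is paradoxical along the pattern exactly when
$\lambda_1 < 0$. When $\lambda_1$ belongs to a complex pair the physical
pattern is the normalized real part of $v_1$ and the projection is
computed by direct matrix action (flagged in the output); physical
perturbations are real-valued.

The determinant identity $\mathrm{sign}\det(-J_{-X}) =
\mathrm{sign}\det(R_{XX})$ at a stable fixed point forces the number of
unstable modes of the subnetwork without $X$ and the number of
paradoxically responding modes of $X$ to share parity; the counts need
not be equal, and the test suite records cases where they differ.
Near-singular determinants (reciprocal condition below 1e-12) are
reported as indeterminate rather than classified.

Perturbation simulations start from the steady state, switch the current
$\gamma\cdot$pattern on at 1 s, and integrate to 3 s or until the readout
settles (relative change per time constant below 1e-6). Readouts follow
the two conventions in use for mean-activity changes — the dot product
with the all-ones vector and the per-neuron mean, which differ by
$N_X$ — and both are returned, labelled.

## What the synthetic data emulate — and what they do not

The generator reproduces the *structure* of the size-tuning experiments:
nine sizes from 5° to 85°, 2D rate fields peaked at the stimulus center,
and surround-suppressed size tuning for the E/PV/SST-like populations.
The measured L4 and LM input profiles are not public, so the drive is an
explicit stand-in: radially symmetric plateau-with-Gaussian-edge fields
whose plateau tracks the stimulus radius ($s/2$) and whose size-tuned
peaks (rising quickly then declining mildly for L4; rising slowly and
sustained for LM) emulate feedforward and feedback drives that are
themselves size-tuned. No claim is made that these match the measured
fields, and observation noise (additive Gaussian, default 5% of each
population's peak, clipped at zero) does not model calcium-imaging
statistics or deconvolution artifacts. Passing tests therefore
demonstrate correctness of the machinery and recoverability under the
synthetic conditions — not fidelity to the unreleased recordings.

The ground-truth generator jitters a fixed baseline amplitude table (all
entries ±10%) and, in the `isn` regime, enforces the operating point the
downstream analyses assume: at the 55° steady state the E subnetwork is
unstable while the full network is stable, retrying with rescaled
recurrent amplitudes when a draw fails. The baseline table was chosen
once so that the resulting circuits are inhibition-stabilized at every
size with PV and SST (but not VIP) required for stabilization, all four
populations active, and surround-suppressed E/PV tuning — the regime the
analyses are about. The `weak` regime (recurrent amplitudes × 0.01) is
the stable non-ISN control.

## Problem sizes used by the shipped analyses

The default fixture (12 × 12 grid, 9 sizes) keeps every stage fast: the
fixture builds in ~1 s, a single fit evaluation costs ~0.3 s, the
10-restart recovery fit minutes, and the perturbation and parity suites
seconds each. The uniform/patterned SST dissociation search runs on a
20 × 20 grid (±57°): the dissociation requires spatially heterogeneous
activity, i.e. a stimulus that does *not* fill the grid, so the wider
grid — not a larger stimulus — is the operative condition. These sizes
are the package's own choices for a desk-scale reproduction; everything
accepts larger grids.

## Known limitations

* Space and cell type only: no orientation or feature dimensions, no
  conductances, spikes, or synaptic delays.
* The fitter returns point estimates; no uncertainty quantification over
  parameters.
* Kernel scales and time constants are inputs, not inferred.
* The E subnetwork is never removable in the stabilization analysis (by
  construction of the question, not a technical limit).
* With many silent units the response-matrix blocks become singular and
  parity diagnostics are reported indeterminate instead of forced.
* Ablation fits reproduce the qualitative failure of interest — removing
  recurrence or E projections leaves a fit an order of magnitude worse,
  with distorted mid-size tuning — but fine-grained directional signatures
  of the ablated optimum (for example, whether its centered-E response at
  the smallest size under- or overshoots the full fit's) are not forced by
  the synthetic drive family: at a grossly misfit optimum that value is
  within the noise of the loss, and the ablated model can reach the small
  observed 5° response through the residual input or steep L4/LM mixtures.
  Conclusions of that grain require the measured input fields.
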