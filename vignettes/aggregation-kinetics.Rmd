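---
title: "Coagulation-fragmentation kinetics of silicified cell aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coagulation-fragmentation kinetics of silicified cell aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicoag)
```

## The model

Bacteria engineered to display a silica-nucleating peptide on their surface
become sticky once a silica precursor (TMOS) is added: silica deposited on
one cell binds the peptide displayed on its neighbors, and the culture
collapses into aggregates that settle out of suspension. `silicoag`
implements the kinetic model of this process as a mass-action reaction
network over three kinds of species: unsilicified cells $C$, precursor $S$,
and aggregates $A_j$ containing $j$ cells ($j = 1, \dots, N$, with $A_1$
the silicified, aggregation-prone monomer):

$$C + S \underset{k_{n1}}{\overset{k_{p1}}{\rightleftharpoons}} A_1,
\qquad
A_i + A_j
\underset{k_n(i,j)}{\overset{k_p(i,j)}{\rightleftharpoons}} A_{i+j}
\quad (i + j \le N).$$

The deterministic dynamics are the standard truncated
coagulation--fragmentation (Smoluchowski-type) ODE system. Formation of
$A_j$ sums over unordered pairs $(i, j-i)$ up to $\lfloor j/2 \rfloor$;
loss of $A_j$ sums over partners $m \le N - j$; and the self channel
$A_j + A_j \to A_{2j}$ is gated by the truncation logic function
$\phi(j) = \mathbf{1}[2j \le N]$ and carries the conventional factor 2 in
the loss of $A_j$. The terminal size $N$ only forms and fragments, never
coagulates further.

Two conventions deserve comment because the piecewise definition of
$\phi$ is ambiguous at its boundary:

* **$\phi(N/2) = 1$.** The channel $A_{N/2} + A_{N/2} \to A_N$ must exist
  — the formation sum for $A_N$ runs to $i = N/2$ — and setting the gate
  open at $N/2$ is the only choice under which total cell mass
  $C + \sum_j j A_j$ is conserved exactly. The package treats mass
  conservation as the ground truth for every such tie-break, and the test
  suite verifies $\dot C + \sum_j j \dot A_j = 0$ to $10^{-12}$ relative
  for random states under every kernel family.
* **$N$ must be even.** The terminal-size reaction block sums to $N/2$;
  rather than silently flooring an odd $N$, validation rejects it.
* **Odd $j$ formation limits** are read as $\lfloor j/2 \rfloor$, which
  counts each unordered pair exactly once.

The precursor has no printed rate equation. The default holds $S$ constant
(`s_mode = "constant"`), the excess-precursor reading consistent with bulk
TMOS addition; `s_mode = "dynamic"` adds $\dot S = -k_{p1} C S + k_{n1}
A_1$ for completeness. The mode is explicit in every interface and recorded
in trajectory metadata.

## Kernels

How $k_p(i,j)$ varies with aggregate size is not constrained by the
available information, so the kernel is a modeling choice exposed as
`kernel_spec()`:

* `constant` (default): $k_p(i,j) = k_p$. Fewest assumptions; all packaged
  defaults use it.
* `brownian`: $k_p \, (i^{1/3} + j^{1/3})(i^{-1/3} + j^{-1/3})/4$, the
  diffusion-limited rate for spherical clusters, normalized to $k_p$ at
  equal sizes. Size-dependence is weak (bounded by a factor of a few).
* `product`: $k_p \, i j / N$, a strongly size-favoring kernel for
  sensitivity analysis.

Fragmentation uses the same family shape with scale $k_n$, interpreted per
unordered break-up channel. Rate tables are materialized as symmetric
$N \times N$ matrices; entries with $i + j > N$ are populated but unused —
the right-hand side, not the table, enforces the truncation.

## Units and the observable

The model is dimensionless in concentration ("model units") with time in
minutes. The experimental observable is the OD600 of the supernatant,
normalized to its reading at time zero. Two constants map model to
measurement:

* **`od_per_unit` (default 350)**: OD600 per model density unit. The value
  is chosen so the experimental densities and the simulated density sweep
  describe the same cultures: the base culture (OD600 $\approx$ 2.8) sits
  at model density 0.008, the middle of the simulated 0.002--0.016 sweep,
  and the settlement-assay culture (OD600 $\approx$ 5.5) lands at 0.0157,
  the top of that range. This constant is a calibration parameter, not a
  physical claim — and as shown below it is identifiable only jointly with
  the rate scale.
* **`settle_threshold` (default 2)**: the aggregate size at and above which
  cells leave the supernatant. The data do not pin this down; 2 is the
  minimal assumption consistent with silicified cells being
  aggregation-prone, and the threshold can be fitted over an integer grid
  as a calibration hyperparameter.

The suspended fraction at time $t$ is
$(C + \sum_{j < \text{thr}} j A_j) / M(0)$ with $M(0)$ the initial cell
mass, mirroring the time-zero normalization of the experiments; the settled
percentage is $100(1 - \text{suspended})$, linearly interpolated between
output grid points (exact on the grid).

## Packaged defaults

`default_params()` ships a parameter set reproduced by
`analysis/01_calibrate_defaults.R`. Structure is fixed a priori:
silicification fast and effectively irreversible on the 90-minute assay
($k_{p1} = 1$ per concentration per minute, $k_{n1} = 0$, $S_0 = 1$ held
constant), slow fragmentation ($k_n = 0.02$ per minute — silica bonds do
not noticeably dissolve on this timescale, but a small reverse rate leaves
the late-time plateau finite and the rate identifiable), truncation
$N = 50$. The single remaining constant $k_p$ is solved by 1-D root
finding so the model settles 97% of cells by 15 minutes for a culture at
OD600 5.5 — the headline settlement anchor ("approximately 95% within 15
min"), with margin for the "approximately" — giving $k_p = 52.554$. The
density-ordering prediction (faster settlement at higher initial density,
both in the 0.002--0.016 sweep and in the 1x/2x/4x/6x endpoint assay) is
verified as a constraint, not fitted.

```{r defaults}
default_params()
default_mapping()
```

## Numerical choices

* **Integration**: `deSolve::lsoda` (adaptive, stiff-capable), default
  `rtol = 1e-8`, `atol = 1e-12`, with the right-hand side compiled and
  called directly by the solver. Failed solves raise; they never return
  silently truncated trajectories.
* **Integrity checks**: every trajectory must conserve total cell mass to
  $10^{-6}$ relative (the observed drift, typically $10^{-11}$, is
  recorded in `solver_meta`); concentrations in $(-10^{-10}, 0)$ are
  clipped to zero on output, anything more negative is an error rather
  than a silent repair.
* **Tolerance stability**: halving the solver tolerances changes the
  suspended fraction by less than $10^{-6}$ everywhere (tested).
* **Closed-form check**: for $N = 2$ the system reduces to
  $\dot A_1 = -2 k_p A_1^2$ with solution
  $A_1(t) = a_0 / (1 + 2 k_p a_0 t)$; the integrator reproduces it to
  better than $10^{-6}$.

## The stochastic oracle

The same network is simulated exactly (direct-method Gillespie) at integer
copy number in a volume $\Omega$, as an independent check that the ODE
right-hand side is the true mean-field limit of the reaction scheme —
including its factor-of-2 dimerization bookkeeping. Propensities are chosen
so the large-$\Omega$ means match the deterministic equations: for $i < j$,
$(k_p(i,j)/\Omega)\, n_i n_j$; for $i = j$,
$(k_p(j,j)/\Omega)\, n_j(n_j - 1)$, whose mean loss of $A_j$ is
$2 k_p A_j^2$; fragmentation $k_n(i,j)\, n_{i+j}$ per unordered channel.
Cell mass in counts is conserved exactly (integer arithmetic, no
tolerance), runs are reproducible from `(seed, run_index)`, and the
ensemble suspended fraction is compared to the ODE per grid time as
z-scores with standard errors taken across runs. The validation
configuration ($N = 8$, $\Omega = 10^4$, 500 runs) keeps the mean-field
bias, of order $1/\Omega$, well below the ensemble standard error; the
oracle is intended for $N \le 16$ and $\Omega \le 10^5$ and warns (not
errors) beyond that.

## Calibration and identifiability

Fitting minimizes the sum of squared residuals (optionally weighted by
inverse replicate variance; the default is unweighted, as the experiments
report simple replicate means) between observed normalized OD and the model
suspended fraction. Rates span orders of magnitude and must stay positive,
so continuous parameters are optimized in log space by Levenberg-Marquardt
(`minpack.lm::nls.lm`) within bounds, from multiple reproducibly drawn
starts; an integer `settle_threshold`, if free, is optimized by exhaustive
grid. Fitting data generated at known parameters with zero noise returns
them to $10^{-4}$ relative with numerically zero loss, and the full
generate-then-fit recovery study (5 densities $\times$ 19 time points
$\times$ 3 replicates, 3% noise, 20 repeats) recovers both rate scales
with relative RMSE near 2%.

One structural fact matters when choosing free parameters: because the
fitted observable is *normalized* OD, `od_per_unit` enters only through
the model densities $d_i = \mathrm{OD}_i / \texttt{od\_per\_unit}$, and
the normalized dynamics depend on densities only through the products
$k_p d_i$. Jointly rescaling $k_p \to c\,k_p$ and
$\texttt{od\_per\_unit} \to c\,\texttt{od\_per\_unit}$ therefore leaves
every residual exactly unchanged, for any density design: the pair is
structurally non-identifiable from settlement curves alone. The test suite
asserts this invariance rather than hiding it. Consequently the packaged
`od_per_unit` is a convention anchored to the printed density scale, and
calibration should fix it (or fix one rate) rather than fit both.

## The synthetic-data generator

`generate_settlement_curves()` emulates the measurement design of the
settlement experiments: supernatant OD sampled every 5 minutes over 1.5 h
(19 readings per curve), 3 replicates per density, density sweeps as
multiples (1x, 2x, 4x, 6x) of a base culture at OD600 2.8, and endpoint
summaries normalized to the *measured* (noisy) time-zero reading, so
realistic normalization error propagates into endpoint percentages exactly
as it would for an experimenter. Noise is multiplicative Gaussian
(default CV 3%, a typical plate-reader scale; the experiments report only
replicate means, so no noise law could be estimated from them), truncated
at zero so no negative OD is ever produced.

What the generator does *not* emulate — and hence what passing recovery
tests do and do not show about real data: sedimentation physics (settling
velocity does not depend on aggregate size or geometry; "settled" is a
sharp size threshold), silica chemistry (precursor hydrolysis and
condensation are folded into one effective silicification rate), surface
display expression dynamics, cell growth or death over the assay,
correlated or heteroscedastic instrument error, and evaporation or
meniscus artifacts. Recovery results certify the fitting machinery under
the stated noise model, not the realism of that model.

## Problem sizes

The packaged analyses and tests use: truncation $N = 50$ for all
default-parameter work (large enough that the terminal bin holds under 1%
of cell mass by 90 minutes even at the highest endpoint-assay density,
0.048, under the defaults);
$N \le 8$ and $\Omega \le 10^4$ with 100--500 runs for stochastic
validation; and 20 generate-fit repeats for the recovery study. These
choices are the package's own balance of resolution against runtime; all
are arguments, not constants.

## Known limitations

* The kernel families are phenomenological; nothing here selects among
  them from data of this design (they predict similar normalized settlement
  curves at these densities).
* `od_per_unit` and the rate scale are jointly unidentifiable from
  normalized settlement data (see above); absolute calibration requires an
  independent measurement of cell density in model units.
* The truncation $N$ is a numerical device: mass accumulating in $A_N$
  represents "all aggregates of size $\ge N$", and size-resolved
  conclusions near $N$ are truncation-shaped.
* The stochastic oracle is exact but unoptimized by design (full
  propensity recomputation per event); it is a validation tool, not a
  production simulator.
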