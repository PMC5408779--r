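---
title: "Models and methods: lateral inhibition, Notch positive feedback, and crypt-niche patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchcrypt)
```

## The question

The intestinal crypt base maintains a mosaic of Notch-high stem cells (CBCs)
and Notch-low, Dll-presenting Paneth cells. Classical lateral inhibition
(LI) — ligand on one cell activates Notch on its neighbor, whose signaling
then represses the neighbor's own ligand — is in principle sufficient to
produce such alternating patterns. The circuit studied here adds a direct
positive feedback (PF): cleaved NICD activates transcription of the Notch
receptor itself. This package implements the computational case for what
that feedback buys: single-cell input–output analysis, pair-cell
bistability, multicell linear stability (maximum Lyapunov exponent, MLE),
deterministic patterning dynamics, and a stochastic cellular Potts model of
the crypt base in which signaling competes with cell growth, division,
migration, and anoikis.

## The circuit models

Per cell $i$, with $\langle X_j\rangle_i$ the (weighted) average of $X$
over the neighbors of $i$, transcriptional activation and repression are
Hill functions
$\sigma(x,k,p) = x^p/(k^p + x^p)$ and $\delta(x,k,h) = k^h/(k^h + x^h)$,
and the trans-activation flux is bilinear in receptor and neighbor ligand,
$x_i = N_i \langle D_j \rangle_i$. The five-species dimensionless model
(`rhs_model2`) tracks Notch mRNA, NOTCH, Dll mRNA, DLL, and NICD:

$$
\begin{aligned}
\dot{Nm}_i &= \beta_{nm}\left[(1-S_{PF}) + S_{PF}\,\sigma(x_i,k_p,p)\right] - \alpha_n Nm_i\\
\dot N_i &= \beta_N Nm_i - \alpha_N N_i - x_i\\
\dot{Dm}_i &= \beta_{dm}\left[(1-S_{LI}) + S_{LI}\,\delta(x_i,k_d,h)\right] - \alpha_d Dm_i\\
\dot D_i &= \beta_D Dm_i - \alpha_D D_i - \langle N_j\rangle_i D_i\\
\dot R_i &= x_i - \alpha_R R_i
\end{aligned}
$$

The regulatory strengths $S_{PF}, S_{LI} \in [0,1]$ are the regulated
fractions of the maximum transcription rates: $S_{PF}=0$ is the pure LI
circuit, and increasing $S_{PF}$ trades basal Notch transcription for
NICD-activated transcription at a fixed maximum. Assuming fast mRNA
turnover, the quasi-steady-state reduction (`qssa_reduce`) eliminates both
mRNAs and yields the three-species protein model (`rhs_model3`) used by all
analyses, with effective rates $\beta_N' = \beta_N\beta_{nm}/\alpha_n$ and
$\beta_D' = \beta_D\beta_{dm}/\alpha_d$. The dimensional model is related
to these by the reference scales in `scaling_constants()` (time $t_0$,
protein references $N_0 = D_0 = R_0 = t_0 k_t$) and is not integrated
directly. In the reduced model the NOTCH decay slot carries the protein
degradation rate; the package stores it in both `alpha_n` and `alpha_N` so
either naming convention reads correctly.

## Reference parameters (fixtures)

The model family fixes no canonical numeric parameter set, so the
package ships its own reference set, `fixture_params()`:

```{r}
fixture_params("pfli_default")
```

The set was chosen once, before any result was frozen, to satisfy all the
qualitative regime constraints simultaneously:

* the LI-only circuit (`li_default`, the same set with $S_{PF}=0$) is
  pair-bistable from $h = 2$ but not at $h = 1$;
* the PFLI circuit is pair-bistable already at $h = 1$ with $p = 2$;
* the PFLI single-cell response has a finite hysteresis window bounded by
  two folds ($S_{PF} = 0.98$ rather than 1: with zero basal transcription
  the off branch exists at every input and the window never closes from
  above);
* both circuits have a positive MLE on the periodic hexagonal lattice at
  the fixture's own cooperativity $h = 4$. The hexagonal packing is
  6-regular, so the most inhibitory eigenvalue of the row-normalized
  averaging matrix is $-1/2$ (against $-1$ for an isolated pair); a
  2-by-2 block calculation at the uniform state shows the LI gain at
  $h = 2$ is marginal at best there, which is why lattice patterning
  requires sharper repression than pair bistability does.

The asymmetric ligand scales ($\beta_D = 32$, $\alpha_D = 2$) keep the
ligand turnover fast relative to the receptor, which makes the transition
dynamics along the $S_{PF}$ ramp well ordered at small tissue sizes.
`pfli_matched_li` is the LI comparator with $\beta_N$ rescaled by
`match_notch_levels()` (bisection on the pair-census Notch-high NICD,
matched within 2\%), so amplitude differences cannot masquerade as
architectural ones.

## Analysis layers

**Single cell** (`single_cell_response`, `detect_hysteresis`): the cell is
driven by a fixed external ligand level $D_{ext}$ with $\langle N_j\rangle
= 0$ (the source presents ligand only; whether the source also depletes the
cell's own ligand is not specified by the protocol, and we take the
depletion-free reading). Fixed points come from dense sign-bracketing of
the scalar receptor balance; stability follows from the triangular
structure of the driven system. LI yields one monotone branch; PF folds it.

**Pair** (`pair_fixed_points`, `pair_bistability_map`, `nullclines`): the
six-dimensional two-cell system is solved by damped Newton iteration from
64 Halton low-discrepancy starts spanning $[0, 2\beta/\alpha]$ per species
(reproducible without seeds), plus warm starts; roots merging within
$10^{-6}$ relative distance are deduplicated and classified with the
analytic Jacobian. Nullclines project onto the $(N_i, N_j)$ plane with the
non-projected species eliminated by their own steady-state relations
(damped Picard for the coupled ligand balance).

**Lattice** (`build_lattice`, `homogeneous_fixed_point`, `compute_mle`,
`mle_sweep`): the uniform state solves a one-dimensional reduction exactly
(the uniform ligand balance is strictly decreasing in $D$, so $D(N)$ is
unique); with strong PF several uniform branches can coexist and the
analyses linearize around the active (largest-$N$) branch. The full
Jacobian at a uniform state is $I \otimes A + W \otimes B$, so its spectrum
is the union over averaging-matrix eigenvalues $\mu$ of the 3-by-3 spectra
$A + \mu B$; the MLE is its largest real part. The sweep applies the
cooperativity label $H$ to the LI Hill coefficient $h$ while the PF keeps
its configured $p$ — the natural reading, since the LI arm is the one whose
cooperativity requirement is under test.

**Dynamics** (`simulate_patterning`, `pattern_time`): seeded multiplicative
uniform noise of relative amplitude $10^{-2}$ around the uniform state,
integrated with a stiff-capable solver (`deSolve::lsoda`, rtol $10^{-8}$,
atol $10^{-10}$; tight tolerances keep basin assignment near saddle points
reproducible). Species within $-$atol of zero are clamped; larger
negativity is treated as solver failure. The transition period ends when
the maximum DLL rate $|\dot D|$ over cells last drops below $10^{-4}$
(configurable; a transition band needs a definite endpoint, so a
threshold must be fixed). Final cells split into NICD-high/low sets by a
2-means partition seeded at the extremes, which avoids hard-coding a
threshold for the deterministic layer.

## The stochastic crypt model

`run_crypt` couples a cellular Potts (GGH) model to the per-cell circuit: a
frozen support layer (basement membrane) along the bottom of a bounded 2-D
lattice carries a monolayer of epithelial cells. Pixel-copy attempts are
accepted with probability $\min(1, e^{-\Delta E/T})$ against an energy of
heterotypic contact terms (order-2 neighborhood) plus quadratic volume
constraints. Each Monte Carlo sweep is followed by one joint RK4 step of
the circuit over all cells inside the niche window, with neighborhood means
weighted by shared contact length (juxtacrine flux is contact-
proportional); cells pushed outside the window stop being integrated but
still present ligand. Fates follow a NICD threshold calibrated once per
circuit as the midpoint of the two stable pair-census NICD levels
(threshold-inclusive = stem). Stem cells grow by `growth_rate *
turnover_multiplier` target volume per sweep and divide along a random
centroid axis at twice the resting volume, daughters inheriting the
mother's signaling state; cells that lose support contact are removed
(anoikis), and cells whose centroid crowding pushes into the absorbing
lateral margins are removed as niche exits. The turnover multiplier scales
only the growth rate; divisions, exits, and anoikis all accelerate with it
downstream, which is the observable the turnover experiment varies.

Potts energies, temperature, lattice size, and cell counts have no
canonical values for this model; the defaults here (60 cells, 320-by-26 lattice,
$T = 4$, $\lambda = 8$, adhesion favoring support > cell–cell > medium)
were fixed by the requirements that an isolated cell hold its target volume
within 5\%, the monolayer stay confluent, and a standard 800–1000-sweep run
at the slowest turnover still contain divisions. The signaling step
`ode_dt = 0.02` makes pattern re-equilibration (a few hundred sweeps)
comparable to the division interval at high turnover — the regime the
turnover experiment is about.

The graded feedback-suppression experiment (`pf_strength_sweep`) titrates
the regulated arm of Notch transcription down while holding the basal arm
fixed — the in-silico analog of knocking out the NICD-bound enhancer while
leaving the basal promoter intact, which is the corresponding genetic
perturbation. A sweep at fixed maximum rate (shifting $S_{PF}$ alone)
would *raise* basal production as the feedback is removed and leaves the
Notch-high fraction flat or increasing; the knockout titration is the
reading under which the stem-cell depletion phenotype is reproduced.

## What the generator does and does not emulate

The crypt model is the package's synthetic-data generator: it produces
NICD distributions, event logs, and spatial patterns under controlled
turnover. It emulates contact-mediated signaling on a fluctuating cell
packing, fate-dependent growth, and proliferation-driven displacement. It
does not emulate the three-dimensional crypt geometry (the monolayer is a
flattened section, so its contact graph is nearly a chain), lineage-specific
differentiation beyond the binary stem/Paneth rule, Wnt or other gradients,
or cis-inhibition. Passing tests therefore certify the circuit logic and
the simulator's bookkeeping, not quantitative agreement with organoid
measurements.

## Known limitations

Two of the headline robustness comparisons do not reproduce under this
implementation's conditions, and the package reports them as measured
rather than asserting them:

* **Patterning speed at 144 cells.** At small tissue sizes (6-by-6 and
  below) the feedback shortens the transition period monotonically in
  $S_{PF}$ and beats the matched LI comparator. On the 12-by-12 periodic
  hexagonal lattice the mosaic admits packing defects, and their resolution
  — not the initial divergence — dominates the transition time; the PF
  latch slows defect resolution, inverting the comparison. The speed claim
  is a small-tissue statement in this model family.

* **Crypt robustness under turnover.** In the $S$-rescaled
  parameterization both circuits share the same maximum Notch production,
  so the LI comparator produces receptor at that maximum constitutively;
  the feedback cannot make the Notch-high state more robust than that, and
  its suppression of Notch-low cells slows their re-activation after
  division-driven rearrangements. Across ligand amplitudes, hysteresis
  widths, cooperativities, timescale ratios, and temperatures we find LI's
  bimodality at high turnover equal to or slightly above PFLI's. The
  feedback's unambiguous crypt-level signatures in this implementation are
  the ones that do reproduce: the binary switch response, the reduced
  cooperativity requirement, the wider patterning region, and the collapse
  of the stem compartment when the feedback arm is knocked down.

## Problem sizes

The shipped analyses use a 481-point input grid (single cell), Hill grids
$h \in \{1,\dots,4\}$, $p \in \{2,3\}$ (pair), a 20-by-20 production-rate
grid at $H \in \{1,2,4\}$ linearized on a 4-by-4 periodic hex lattice
(sweep), 20-seed ensembles on the 12-by-12 lattice (dynamics), and 60-cell,
800-sweep crypt runs with 10 seeds per condition; these sizes were chosen
so every figure's statistic stabilizes (medians move by less than the
seed-to-seed spread when doubled).
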