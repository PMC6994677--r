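---
title: "Models and methods: folding-state structure and dynamics from SANS and NSE"
author: "nsedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: folding-state structure and dynamics from SANS and NSE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsedyn)
```

# Scope and scientific background

Apomyoglobin-like systems can be trapped in qualitatively different
folding states — native-like, molten globule, acid unfolded, chemically
denatured — and the transition between *protein-like* and *polymer-like*
dynamics across these states is measurable by combining small-angle
neutron scattering (SANS, equilibrium dimensions) with neutron spin-echo
spectroscopy (NSE, the normalized intermediate scattering function
$S(q,t)/S(q,0)$ on 0.1–250 ns and $q = 0.03$–$0.15\,\mathrm{\AA^{-1}}$).
This package implements the full analysis chain for such experiments,
together with seeded synthetic-data generators that emulate every input,
so the chain is testable end to end without instrument data.

Internally all lengths are in ångström, times in ns, diffusion
coefficients in $\mathrm{\AA^2/ns}$, viscosities in mPa·s, temperatures
in K; `nm` input is converted once at the interface.

# Structural models

## Generalized Guinier and excluded-volume form factors

Compact states are described by
$I(q) = A \exp[-R_g^2 q^2/(3-\alpha)]$, valid for $qR_g < 1.3$; the
shape parameter $\alpha$ (0 for a spheroid) is fixed at 0 by default and
can be freed. The fit iterates its own window: starting from the
supplied range, the upper bound shrinks until
$q_\mathrm{max} R_g \le 1.3$ (at most 10 iterations). The validity bound
is standard; the iteration procedure is this package's choice, since only
the bound itself is prescribed by Guinier analysis.

Unfolded states use the excluded-volume chain form factor in its
standard two-term lower-incomplete-gamma representation with
$U = q^2 R_g^2 (2\nu+1)(2\nu+2)/6$:
$$P(q) = \frac{1}{\nu U^{1/2\nu}}\gamma(1/2\nu, U)
       - \frac{1}{\nu U^{1/\nu}}\gamma(1/\nu, U).$$
The formula is evaluated through `pgamma`, with a series expansion below
$U = 10^{-8}$ to avoid cancellation, and is validated against the
closed-form Debye function at $\nu = 1/2$ (relative agreement $10^{-6}$
over $qR_g \in [0.01, 10]$). Derived chain quantities follow the printed
closed forms exactly: $\nu = 1/m$, $l = R_g\sqrt{(2\nu+1)(2\nu+2)}/N^\nu$,
$R_E = \sqrt{(2\nu+1)(2\nu+2)}\,R_g$,
$c^* = M/(N_A \tfrac{4}{3}\pi R_g^3)$. The default bead count is
$N = 20$ (about 7 amino acids per bead for a 153-residue chain); the
choice is a discretization, not a physical claim, and the test suite
carries an $N = 30$ regression confirming the dynamical conclusions are
unchanged under a finer discretization.

Weighted fits use $1/\sigma^2$ weights throughout; points with
$\sigma = 0$ receive the median positive $\sigma$ of the curve, which
avoids infinite weights on placeholder errors. Parameter covariances are
reported in the fixed convention $(J^\top W J)^{-1}$ — no rescaling by
the reduced $\chi^2$ — so that doubling all input uncertainties doubles
every parameter standard error, a property the suite asserts.

## Infinite-dilution extrapolation

The form factor per unit mass is the per-$q$ intercept of a weighted
linear fit of $I(q,c)/c$ versus $c$. Curves are interpolated linearly in
$(q, I)$ onto the first curve's grid over the common range (smooth 1-D
curves; no model bias). The intercept's uncertainty is propagated
analytically from the input $\sigma$, which keeps the two-concentration
case well-defined. In the closure tests the three lowest concentrations
(3, 6, 15 mg/mL) feed the extrapolation: at 30 mg/mL the
interaction structure factor is strong enough that its curvature in $c$
biases a linear extrapolation, which mirrors the experimental practice
of measuring the form on dilute samples.

## Structure factor and the MSA

The experimental structure factor is the pointwise ratio of the
concentrated curve (per unit mass) to the form factor, smoothed with a
centered moving average (default 5 points; the edges keep partial
windows), uncertainties propagated in quadrature and reduced by the
effective window.

The model structure factor for charged macro-ions is the mean spherical
approximation for a hard core with screened-Coulomb (Yukawa) tail, with
contact potential
$\beta u(\sigma^+) = Z^2 \lambda_B / [\sigma (1+\kappa a)^2]$
($\lambda_B$ the Bjerrum length, $\kappa$ the inverse screening length,
$a$ the radius, $\sigma = 2a$). It is computed by solving the
Ornstein–Zernike equation under the MSA closure numerically: Picard
iteration on $\gamma = h - c$ with fast sine transforms, the hard-core
grid aligned so a node falls exactly on $\sigma$ and the contact bin
carrying the mean of the inside/outside limits. That makes the scheme
$O(\Delta r^2)$; at the default resolution (1024 points per diameter)
the zero-charge solution agrees with the closed-form Percus–Yevick
structure factor to better than $10^{-6}$ for volume fractions up to
0.2, which is the package's accuracy statement for the charged case as
well. When the MSA returns an unphysical negative contact value of
$g(r)$ — common for weakly concentrated, strongly charged solutions —
the standard rescaling inflates the effective hard core at fixed number
density and potential until $g(\sigma^{*+}) = 0$; the rescale factor and
contact value are returned as attributes. A numerical solution was
preferred over the classical closed-form algebra because it is
self-validating against the Percus–Yevick limit and grid-refinement
checks, whereas the closed form offers no independent check against
transcription error; the model content is identical.

## Hydrodynamic functions

Two scalar estimators bracket the solvent-mediated correction:
$H_{c,q0} = D_c S_{q0}/D_0$ at low $q$ and
$H_{c,qL} = \eta_{c=0}/\eta_\mathrm{conc}$ at high $q$. The viscosity
ratio is implemented dilute-over-concentrated; that direction is fixed by
the published working values themselves (0.344 = 1.72/5.01), which
resolves the ambiguity of calling it "the ratio of concentrated and
diluted viscosities". $H$ is treated as $q$-independent between the two
anchors, and the pipeline applies $H_{c,q0}$ in the $D_\mathrm{eff}$
correction.

# Dynamical models

## Cumulant and stretched-exponential analysis

The initial slope is fitted as
$S(q,t)/S(q,0) = A\exp(-D_1 t - D_2 t^2)$ on the times where the signal
retains at least 40% of its amplitude (configurable; the cut is this
package's choice as no canonical window exists). $D_1$ has units of 1/ns
in this parameterization; the reported diffusion coefficient is
$D_1/q^2$ in $\mathrm{\AA^2/ns}$, applied *before* the interaction
correction $D_\mathrm{eff}(q) = (D_1/q^2)\,S(c,q)/H_{c,q0}$ — this is
the convention that makes the result comparable with DLS. Amplitudes are
bounded to $[0.8, 1.2]$ as normalized NSE data cannot stray far from 1.

The stretched-exponential form is implemented exactly as
$A\exp(-D' q^2 t^\beta)$, i.e. with the exponent acting on $t$ alone, so
the unit of $D'$ depends on the fitted $\beta$
($\mathrm{\AA^2/ns^\beta}$); this is noted rather than "corrected".
$\beta$ is bounded to $[0.3, 1.2]$ and initialized at 0.85, covering
simple diffusion and Zimm-like stretching without degeneracy; $D'$ is
optimized on a log scale with a start from the first decade of decay,
which removed every spurious bound-pinned solution observed with naive
starts. The across-$q$ summary is the unweighted arithmetic mean of
$\beta$.

## Zimm and ZIF dynamic structure factor

The central model is the finite bead–spring chain with hydrodynamic
interactions and excluded volume:
$$I(q,t) = \frac{e^{-q^2 D (H/S) t}}{N}\sum_{n,m=0}^{N-1}
  \exp\!\left[-\frac{q^2 B(n,m,t)}{6}\right],$$
$$B(n,m,t) = |n-m|^{2\nu} l^2 + \frac{4R_E^2}{\pi^2}
  \sum_{p=1}^{p_\mathrm{max}} \frac{A(p)}{p^{2\nu+1}}
  \cos\frac{\pi p n}{N}\cos\frac{\pi p m}{N}
  \left[1-e^{-t/\tau_p}\right],$$
always evaluated as $I(q,t)/I(q,0)$ since NSE measures normalized ISFs.
Bead indices run $0..N-1$ and $(n-m)^{2\nu}$ is implemented as
$|n-m|^{2\nu}$, required for non-integer $2\nu$. $p_\mathrm{max}$
defaults to $N$ (all modes contribute) and $A(p) = 1$ for the Zimm and
ZIF models; $A(p)$ is exposed as a hook for damped-amplitude variants
but those models are out of scope. The implementation diagonalizes the
mode sum into a cosine-matrix product and is checked to $10^{-10}$
against an independent brute-force double/mode sum on chains of up to 5
beads.

Mode relaxation times use the standard Zimm-with-excluded-volume
spectrum
$$\tau_p = \frac{\eta R_E^3}{\sqrt{3\pi}\, k_B T}\, p^{-3\nu},
  \qquad R_E = l N^\nu .$$
The dimensionless prefactor is exposed (`tau_prefactor`) because
published absolute first-mode times depend on convention; with the
$1/\sqrt{3\pi}$ default, a GdmCl-denatured-like chain
($\eta = 1.9$ mPa·s, $l = 13.4$ Å, $\nu = 0.64$, $N = 20$, $T = 283.15$ K)
has $\tau_1 \approx 120$ ns. Because no single convention reproduces all
published absolute $t_\mathrm{Zimm}$ values jointly, the first Zimm time
is reported under this documented convention and compared only at the
order-of-magnitude level, never as an absolute target. Internal friction
enters as a mode-independent additive time,
$\tau_p^\mathrm{ZIF} = \tau_p + \tau_\mathrm{intern}$, which
preferentially damps the high-$p$ modes; $\tau_\mathrm{intern} = 0$
recovers Zimm bit-for-bit.

The center-of-mass diffusion coefficient defaults to the Zimm relation
$D = 0.196\,k_B T/(\eta R_E)$ so that a chain spec is one
self-consistent Zimm object; measured (DLS) values override it. The
correction factor $H/S$ multiplies the center-of-mass exponent exactly
as written in the model, including during fitting.

The global ZIF fit runs one weighted least squares over all $(q,t)$
points simultaneously with only $(D, \tau_\mathrm{intern})$ free,
$\tau_\mathrm{intern}$ bounded below by zero (a Zimm-consistent sample
is recognized by the bound being active), and reports the reduced
$\chi^2 = \sum[(\mathrm{model}-\mathrm{data})/\sigma]^2/(n-2)$ over all
jointly fitted points — the convention is stated here because reduced
and total $\chi^2$ differ by the large joint $n$.

## Stretching exponent of the Zimm model

Fitting stretched exponentials to noiseless Zimm ISFs of a Gaussian
chain ($\nu = 1/2$, $N = 20$, $l = 14$ Å, $\eta = 1.7$ mPa·s,
$T = 283.15$ K, Zimm-relation $D$) over $q = 0.08$–$0.15\,\mathrm{\AA^{-1}}$
and $t = 1$–100 ns gives a mean $\beta$ of 0.83 (per-$q$ values fall
from 0.89 at $q = 0.08$ to 0.79 at $q = 0.15$), consistent with the
$\approx 0.85$ figure quoted as the Zimm prediction for Gaussian chains;
the exact number depends mildly on the fit window because the KWW form
is only an approximation to the Zimm ISF. This is the computation
`scripts/acceptance.R` performs.

# Rigid-body branch

The first-cumulant diffusion coefficient of a rigid scatterer couples
translation and rotation through the 6×6 generalized diffusion matrix
$\mathbf{D}$ (translation $\mathrm{\AA^2/ns}$, rotation
$\mathrm{rad^2/ns}$, origin at the center of diffusion):
$$D_0(q) = \frac{1}{q^2 F(q)}\left\langle
  w(\hat u)^\dagger\, \mathbf{D}\, w(\hat u)\right\rangle_{\hat u},
  \qquad
  w(\hat u) = \sum_j b_j e^{i \vec q\cdot\vec r_j}
  \begin{pmatrix}\vec q\\ \vec q\times\vec r_j\end{pmatrix}.$$
The phase factors are conjugate on the two indices — the only reading
under which the orientational average is real and the isotropic limit
$D_0 = D$ holds exactly — and the bilinear form is non-negative because
$\mathbf{D}$ is positive semidefinite. A 9×9 layout mentioned in parts
of the literature is not used; external bead-shell outputs must be
supplied in the standard 6×6 text layout documented in
`read_diffusion_matrix`. Computing the matrix from structure (bead-shell
hydrodynamics) is out of scope: the matrix is an input.

Orientational averages use a deterministic Fibonacci-lattice quadrature
(default 500 directions) rather than random sampling, for bit
reproducibility; every call re-evaluates at doubled resolution and warns
above 1% relative change. The form factor in the denominator uses the
same point set, so analytic limits hold exactly per point set; the
standalone `form_factor` uses the exact Debye double sum
$F(q) = \sum_{jk} b_j b_k \,\mathrm{sinc}(q r_{jk})$. Agreement between
the quadrature and an independent Monte-Carlo average (fixed seed,
$10^5$ directions) is asserted at 0.5% on toy systems.

Coordinates come from standard PDB files via the bio3d reader; per-atom
coherent scattering lengths come from the bundled standard table, and
with the deuteration flag the labile hydrogens — nearest heavy atom
within 1.3 Å being N, O or S — take the deuterium value, emulating H/D
exchange in heavy-water buffers. Residue-level coarse-graining sums $b$
per residue at the $b$-weighted centroid.

Internal modes are supplied by an anisotropic elastic network (uniform
springs between centers within a 13 Å cutoff, uniform masses): a
connected network yields exactly six near-zero modes, and the first
internal mode is numbered 7. Amplitudes follow equipartition,
$k_\alpha = k_B T/(\bar m \omega_\alpha^2)$, in $\mathrm{\AA^2}$ when
the spring constant is expressed in $k_BT/\mathrm{\AA^2}$. The harmonic
model does not predict relaxation *rates*: $\lambda_\alpha$ is an input
(default 1/ns), so mode-specific effective-diffusion curves
$$D^{\alpha}_\mathrm{eff}(q) = \frac{\lambda_\alpha k_\alpha}{q^2 F(q)}
 \left\langle\Big|\sum_j b_j e^{i\vec q\cdot \vec r_j}
 (\vec q\cdot \vec e_j^{\,\alpha})\Big|^2\right\rangle$$
carry shape information; their absolute scale is in units of
$\lambda_\alpha$. The mixed-index notation found in some statements of
this sum is resolved as the symmetric double sum over center pairs,
which is manifestly non-negative and invariant under a global sign flip
of the eigenvector — both asserted in the tests. The elastic network
replaces all-atom force-field normal modes deliberately: at the
resolution of a coarse scattering calculation the network's low modes
carry the same collective-motion content, and the package stays free of
force-field machinery.

# Synthetic data: what it emulates and what it does not

`sample_state_spec` fixes the four study conditions (native-like "pd6",
molten globule "pd4", acid unfolded "pd2", chemically denatured
"gdmcl") at their published working parameters: structural
($R_g$ = 14.8/25.4/26.7/70.2 Å, $\nu$ = –/0.46/0.55/0.64,
$R_H$ = 19.6/30.0/18.0/56.7 Å), dynamical ($D$ = 6.1/1.7/3.0/1.2
$\mathrm{\AA^2/ns}$, $\tau_\mathrm{intern}$ = –/49.63/50.89/0 ns,
$\eta$ = 1.7/1.7/1.7/1.9 mPa·s) and the scalar side measurements
(structure-factor values at the DLS $q$, concentrated/dilute
viscosities, DLS diffusion coefficients). A seed is mandatory for any
stochastic output and all randomness flows through it.

SANS curves are built as $I(q,c) = c\,P(q)\,S(q,c) + \varepsilon$ with
2% relative Gaussian noise: excluded-volume $P$ with a repulsive MSA
$S$ whose volume fraction scales with concentration (effective charge 8,
screening 30 Å — chosen so the 30 mg/mL structure factor suppression is
comparable to the measured low-$q$ values) for the denatured states, and
Guinier $P$ with a weak low-$q$ attractive enhancement for the
native-like state near its isoelectric point. NSE spectra for unfolded
states come from the package's own Zimm/ZIF simulator on
$q = 0.03$–$0.15\,\mathrm{\AA^{-1}}$ (step 0.01) and 40 log-spaced
Fourier times 0.5–250 ns — the coverage of the spin-echo instruments
such experiments run on — with absolute Gaussian noise
$\sigma(t) = 0.02\,(1 + t/t_\mathrm{max})$, emulating echo-amplitude
loss at long Fourier times. These grid sizes are deliberate: at this
data volume the global ZIF fit determines $\tau_\mathrm{intern}$ to a
few percent, so the suite's 10% recovery checks test accuracy rather
than luck; sparser grids left the estimator spread comparable to the
tolerance. The native-like spectra decay as
$\exp[-q^2(D_0(q) + \Delta D(q))t]$ from a compact 20-center fixture,
with $\Delta D$ a single scaled elastic-network mode contributing 20% of
the total — enough signal for the decomposition stage to recover.

What the generators do **not** emulate: instrument resolution and
wavelength smearing, detector geometry, background/buffer subtraction,
multiple scattering, aggregation kinetics, and any non-Gaussian noise.
Passing the closure tests therefore demonstrates the correctness and
statistical calibration of the analysis chain, not robustness to those
instrument-level systematics.

# Numerical choices and degenerate inputs

* All fits are deterministic: fixed, data-driven initializations
  (log-slope starts for decay rates, log–log slope for $\nu$), no random
  restarts. Nonlinear least squares uses Levenberg–Marquardt
  (`minpack.lm`) with explicit bounds.
* Degenerate inputs are flagged rather than silently fitted: flat SANS
  curves yield an invalid Guinier fit (or an error), a flat structure
  factor drives the MSA charge to its zero bound with a degeneracy flag,
  $\beta$ or $\tau_\mathrm{intern}$ pinned at bounds are reported.
* The OZ/MSA solver refuses to continue when $1 - \rho\hat c$ touches
  zero (diverging compressibility) and errors when no physical rescaling
  exists.
* Interpolation between grids is linear and never extrapolates; curve
  division errors out on non-positive form factors.
* Fit windows: Guinier window iteration (above); the cumulant window
  keeps $S/S_0 \ge 0.4$; the ZIF fit uses all points jointly.

# Problem sizes in the shipped tests

The suite runs the full closure at the study conditions: 13 $q$ × 41 $t$
NSE sets for three states, three-concentration SANS series of 122 $q$
points, Monte-Carlo oracles at $10^5$–$3\times10^5$ directions, and OZ
grids of 1024 points per diameter. These sizes were chosen so the entire
suite completes in a few minutes on a single core while keeping every
statistical tolerance at least two estimated standard errors wide.

# Known limitations

* The MSA solver's Picard iteration slows beyond volume fractions of
  about 0.3 and is not intended for dense colloidal regimes.
* $t_\mathrm{Zimm}$ absolute values are convention-dependent (see
  above); only ratios and orders of magnitude are meaningful across
  conventions.
* The ZIF model's $\tau_\mathrm{intern}$ is mode-independent by
  construction; mode-dependent internal friction, damped mode
  amplitudes beyond the $A(p)$ hook, compacted-chain variants and
  semidilute/reptation dynamics are out of scope.
* The rigid-body branch consumes diffusion matrices; it does not compute
  them from structure.
* DLS inversion (CONTIN) and CD spectroscopy deconvolution are upstream
  of this package; their outputs enter only as scalars.
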