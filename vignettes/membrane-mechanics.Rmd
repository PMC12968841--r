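---
title: "Membrane bending moduli from fluctuations: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane bending moduli from fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

memflex estimates the bilayer bending modulus $\kappa_b$ from thermal
fluctuations of coarse-grained membrane trajectories by three independent
routes, and ships a synthetic equilibrium-ensemble generator with known
mechanics so that each route is validated by parameter recovery rather
than by comparison to another implementation. This vignette documents the
underlying models, every tunable that matters, the numerical choices, and
what a green test does and does not establish.

Internal units are nm, ps, K. Moduli are handled in units of $k_BT$
($k_B T \equiv 1$ internally) and converted to joules with
`kbt_to_joule()` using $k_B = 1.380649\times10^{-23}$ J/K.

## The fluctuation models

**Undulation spectrum.** The bilayer mid-surface is a height field
$h(x,y)$ over the periodic $L\times L$ cell, expanded on the discrete
lattice $q = 2\pi(n_x,n_y)/L$. For a tensionless-to-weakly-tense membrane
the Helfrich energy plus equipartition gives, in the package's Fourier
convention ($h(x) = \sum_q h_q e^{iq\cdot x}$, modes estimated per bead as
$(1/N)\sum_j z_j e^{-iq\cdot x_j}$),

$$\langle |h_q|^2 \rangle = \frac{k_BT}{A(\tau q^2 + \kappa_b q^4)},
\qquad A = L^2 .$$

Any prefactor convention for the continuum Fourier pair is defensible in
isolation; what is testable is self-consistency, so the generator and the
estimator share this one convention and the round trip (sample with known
$\kappa$, fit $\hat\kappa$) is the module's master test.

**Coupled-undulation density correlations (BW-DCF).** Each leaflet's head
density along $z$ is modeled as a Gaussian of 2D density $\rho_0$
(nm$^{-2}$), center $\pm d/2$ and mean-square width $a$ (nm$^2$). Because
only the shared undulation correlates the two leaflets (interface jitter
is per-bead and independent), the cross-leaflet pair correlation admits
the Mehler expansion on density derivatives

$$G_{+-}(z_1,z_2,q) = \sum_{k\ge 1} \frac{\hat S_k(q)}{k!}\,
\partial^k\rho_+(z_1)\,\partial^k\rho_-(z_2),$$

exact for jointly Gaussian heights, with $\hat S_k$ the transform of the
$k$-th power of the height covariance. Sandwiching the measured
cross-leaflet matrix $B_{nm}(q)$ between inverses of the overlap matrix
$A_{nm}=\int \partial^n\rho\,\partial^m\rho\,dz$ isolates
$\hat S_1(q) = [A^{-1}B(q)A^{-1}]_{11}$, and

$$\gamma_{cu}(q) = \frac{k_BT}{q^2 \hat S_1(q)} = \gamma_0 + \kappa_b q^2$$

gives $\kappa_b$ as the quadratic coefficient ($\gamma_0$ plays the role
of a tension). The flattened typography of the defining identity is read
as $k_BT/(q^2\gamma_{cu})$ on the left side, the only reading consistent
with capillary-wave scaling $\langle|h_q|^2\rangle \propto k_BT/(\gamma q^2)$.

**Real-space splay (RSF).** Each lipid carries a tilt director $n$ (unit
vector from the terminal-tail centroid to the head bead, oriented away
from the midplane) and a local interface normal $N$ (least-squares plane
through same-leaflet heads within a patch). For a neighbor pair at lateral
separation $h\,e_1$ the two-point splay is

$$S_t = \frac{(n_B-n_A)\cdot e_1 - (N_B-N_A)\cdot e_1}{h},$$

Boltzmann-distributed with $P(S_t)\propto\exp(-K_cA_lS_t^2/2k_BT)$, so
quadratic fitting of $-(2k_BT/A_l)\ln P$ returns the monolayer splay
modulus $K_c$; the bilayer modulus is exactly $2K_c$. The printed
finite-difference assembly sums the director and normal increments; the
free energy is a function of $\nabla n - \nabla N$, so the difference form
is the default and the literal sum form is available via
`convention = "sum"`. Per-species-pair moduli combine as
$1/K_c = \phi_{total}^{-1}\sum \phi_{ij}/\chi_{ij}$.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `n_max` | 5 | — | mode cutoff $|n|\le n_{max}$; the default fit window is the lowest 5 shells, where $q^4$ dominates |
| `q_window` (q⁻⁴) | 5 shells | — | the paper-scale band; configurable as a $[q_{min},q_{max}]$ range |
| `n_bw` | 5 in `estimate_bwdcf()` (3 at the low level) | — | Mehler truncation order; see *Truncation* below |
| γ fit window | 3 shells | — | only the lowest shells are truncation-bias-free |
| `cutoff` (RSF) | 1.2 | nm | neighbor search between head beads |
| `patch_radius` | 1.5 | nm | plane-fit patch; widen to several lipid spacings when interface jitter is large (see *Findings*) |
| splay histogram | 101 bins over mean ± 4 SD, fit where counts ≥ 10 | — | intercept and linear term of the energy fit absorb normalization and asymmetry |
| `bin_width` (density) | 0.05 | nm | leaflet profiles; integral always equals $n_{leaflet}/A_o$ |
| MSD fit window | 10–50% of max lag | — | slope/4 is $D$; standard error from 8 independent lipid groups |

## The synthetic world

`generate_trajectory()` draws **independent equilibrium frames**: a fresh
Helfrich height field per frame, head beads at
$z = \pm d/2 + h(x,y) + \mathcal N(0,a)$, one terminal tail bead per lipid
placed along the director, lipids on jittered square lattices whose
lateral positions follow a wrapped Gaussian walk of step variance $2D\,dt$
per axis. Defaults describe a 40 × 40 nm patch: 1024 lipids per leaflet,
$\kappa = 30\,k_BT$, $\tau = 0$, $d = 4$ nm, $a = 0.09$ nm², $T = 310$ K,
$dt = 1$ ns, $D = 5\times10^{-6}$ nm²/ps — the magnitudes a
coarse-grained phosphatidylcholine patch exhibits.

Two deliberate design choices:

* **Tilt is a smooth field, not per-lipid noise.** Independent per-lipid
  director noise makes the pairwise splay variance scale as $1/h^2$, i.e.
  a scale mixture over pair distances that is *not* Boltzmann-Gaussian.
  The stated world requires Gaussian pairwise splay, so tilt components
  are band-limited Gaussian fields (wavelengths 4–8 nm) with pointwise
  per-axis sd `tilt_sd`; the implied splay variance
  $V_t = \tfrac12\,tilt\_sd^2\langle q^2\rangle_{band}$ is recorded as
  ground truth. By default `tilt_sd` is derived from $\kappa$ so that
  $K_c = \kappa/2$, making all three estimators target the same modulus —
  the elastic consistency a real membrane would show.
* **Direct splay mode** places lipids in isolated dimers on a flat
  membrane and tilts each pair so its splay is drawn exactly from
  $\mathcal N(0, k_BT/(K_cA_l))$ — the distribution-shape-sensitive test
  of the Boltzmann inversion with zero geometric confounders.

What the generator does **not** emulate: time correlation between frames
(real MD frames are strongly correlated; effective sample sizes there are
far smaller than the frame count), protrusion and peristaltic modes,
area/volume fluctuations of the box, tilt–splay coupling to curvature
beyond the shared surface, multi-species mixing physics (species tags
exist only for the pair-combination bookkeeping). A green recovery test
therefore establishes estimator correctness *given equilibrium sampling of
the stated model*, not robustness to MD artifacts.

## Numerical choices

**Spectral estimator.** The plain nonuniform Fourier sum over $N$ beads
carries an incoherent sampling floor of order $(a + \mathrm{Var}\,h)/N$
whose exact size depends on the lateral point statistics (Poisson vs
lattice vs partially diffused), visibly biasing the upper fit shells.
`average_spectrum()` therefore fits the per-frame heights by linear least
squares on the band-limited cos/sin design: inter-mode leakage is removed
exactly, and the white-noise power bias is subtracted using the regression
residual variance — unbiased irrespective of the point statistics. The
direct sum remains available (`estimator = "direct"`, and `height_modes()`
for raw modes).

**BW truncation and its tail.** Truncating the Mehler series at $n_{bw}$
leaves a parity-allowed contamination
$\epsilon(q)=\sum_{k>n_{bw}}\hat S_k(q)/k!\,([A^{-1}\tilde A]_{1k})^2$
that grows with $q$ and with the effective interface width ($a$ plus the
undulation variance); at $n_{bw}=3$ it reaches tens of percent over the
usual fit shells at the defaults' effective width, at $n_{bw}=5$ a few
percent (even orders cannot contaminate the $(1,1)$ element by parity, so
5 is the useful maximum below the conditioning limit). `estimate_bwdcf()`
uses $n_{bw}=5$, fits the lowest 3 shells, and by default subtracts the
remaining tail, rebuilt from measurable quantities only: the height
covariance from the per-mode $\hat S_1$ estimates and the overlap
coefficients from the fitted density model.

**Uncertainties.** The BW standard error comes from contiguous frame-block
resampling (16 blocks) — a 3-point regression error is not a statistical
statement. The diffusion standard error comes from 8 independent lipid
groups, because MSD points share time origins and the OLS slope error
underestimates. The q⁻⁴ error is the per-mode scatter of
$k_BT/(ASq^4)$ across the window.

**Periodic-boundary hygiene.** All pair geometry uses the minimum-image
convention in $x$–$y$. Center-of-mass motion removal accumulates per-frame
mean minimum-image displacements rather than subtracting the wrapped
centroid — the naive mean jumps by $L/N$ whenever a bead crosses the
boundary, which measurably inflates recovered diffusion constants. MSD
unwrapping assumes per-frame steps below $L/2$.

**Leaflet assignment.** The midplane rule (head above/below the mean head
$z$) is refined by a local pass comparing each head to the mean $z$ of
laterally nearby heads: at $\kappa \sim 25$–$30\,k_BT$ on a 40 nm box the
undulation amplitude tail reaches $d/2$ and the global rule mislabels a
fraction of a percent of lipids riding extreme bumps — enough to pollute
leaflet-relative observables with thickness-sized outliers. Assignment is
computed once on the first frame; the flip-flop warning fires only for
lipids beyond the midplane in a majority of frames, since transient bump
crossings are not flips.

**Degenerate inputs.** Classed errors distinguish configuration errors
(unknown species tag, empty fit windows, non-commensurate q-vectors,
non-square boxes), degenerate physics (single-sided bilayers, coincident
pairs, zero-length directors) and fit failures (non-convergent density
fits, non-positive splay curvature). Gaussian density fits use an `nls`
scale offset so exact (zero-residual) histograms converge. The area per
lipid is the per-leaflet $l_{cell}^2/n_{leaflet}$ averaged over leaflets,
which reconciles the halved textbook form written with the bilayer total.

## Findings worth knowing

* **Local-normal patches must span several lipid spacings.** With
  interface jitter $a \approx 0.09$ nm² and ~1.25 nm lipid spacing, a
  1.5 nm patch holds ~5 heads and the plane-fit slope noise leaks
  $\sim 0.15$ nm$^{-2}$ into the splay variance — more than the splay
  signal itself. At 2.8 nm patches the leakage drops to a few percent.
  The spec-conventional 1.5 nm default is kept for compatibility; use
  wider patches on noisy interfaces.
* **Neglecting tension biases the plain q⁻⁴ inversion upward**, since
  $k_BT/(ASq^4) = \kappa + \tau/q^2$ term by term; the tension-inclusive
  fit (weighted by inverse squared relative error) separates the two.
* **In-plane invariance only.** Splay and spectra are invariant under
  lateral translations and in-plane rotations; the implementation assumes
  the membrane normal is the $z$ axis, as does every leaflet-resolved
  observable.

## Limitations

Frames are treated as independent; applying the reported standard errors
to time-correlated MD output overstates precision unless frames are
decimated to the correlation time. The BW-DCF route assumes symmetric
leaflets and Gaussian leaflet densities; strongly non-Gaussian interfacial
profiles (gel phases) violate the model. RSF values depend on the normal
estimation scale (patch radius) on noisy interfaces. No XTC/TRR reader is
included — convert binary trajectories to multi-frame GRO or the CSV
dialect first.
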