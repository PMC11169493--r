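---
title: "Methods: structure-based Förster and generalized-Förster EET analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based Förster and generalized-Förster EET analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonet)
```

## Scope and model

`excitonet` estimates excitation energy transfer (EET) between chlorophyll
pigments of a photosynthetic supercomplex directly from an atomic
structure. It works in the weak-coupling (Förster) limit, appropriate for
pigments with small electronic interactions, and treats strongly coupled
pigment groups at the aggregate level with generalized Förster theory.

**Pairwise rates.** The rate from donor pigment $m$ to acceptor $n$ is

$$k_{mn} = \frac{2\pi}{\hbar}\,|V_{mn}|^2 \int d\omega\,
  F_m(\omega)\,A_n(\omega),$$

with the coupling $V_{mn}$ in cm$^{-1}$, the donor emission and acceptor
absorption lineshapes unit-normalized in $\omega$ (cm$^{-1}$), and
$\hbar = 5.3088$ cm$^{-1}$ ps, so rates come out in ps$^{-1}$ and time
constants $\tau = 1/k$ in ps.

**Couplings.** $V_{mn}$ is the screened TrEsp (transition charges from
electrostatic potentials) Coulomb sum

$$V_{mn} = f(R_{mn}) \sum_{l \in m}\sum_{l' \in n}
  \frac{q^T_l\,q^T_{l'}}{|R_{l,l'}|},$$

with atom-centered transition charges $q^T$ in units of $e$, interatomic
distances in Å, and the conversion constant
$e^2/4\pi\varepsilon_0 = 1.1614\times 10^5$ cm$^{-1}$ Å. The environmental
screening factor is the piecewise model

$$f(R) = \begin{cases} 1 & R \le 6.6\ \text{Å} \\
  A e^{-\beta R} + 0.54 & 6.6 < R < 20\ \text{Å} \\
  0.54 & R \ge 20\ \text{Å},\end{cases}$$

evaluated at the center-to-center distance (Mg–Mg for chlorins). The
exponential constants default to $A = 2.68$, $\beta = 0.27$ Å$^{-1}$, which
make the model near-continuous at both breakpoints
($f(6.6^+) \approx 0.991$, $f(20^-) \approx 0.552$); both are
configuration-exposed, as is the choice of distance convention. A classical
point-dipole coupling ($\kappa$-factor form, $5.034\times 10^3$
cm$^{-1}$ D$^{-2}$ Å$^3$) is provided as the far-field oracle; the TrEsp sum
must agree with it to better than 1% beyond 60 Å, which the test suite
asserts.

**Lineshapes.** Emission and absorption are pure Gaussians,

$$F_m(\omega) = \frac{1}{\sigma\sqrt{2\pi}}
  \exp\!\Big[-\frac{(\omega_m - S - \omega)^2}{2\sigma^2}\Big], \qquad
  A_n(\omega) = \frac{1}{\sigma\sqrt{2\pi}}
  \exp\!\Big[-\frac{(\omega_n - \omega)^2}{2\sigma^2}\Big],$$

and the overlap integral has the closed form
$J = \exp[-\Delta^2/2(\sigma_F^2+\sigma_A^2)] /
\sqrt{2\pi(\sigma_F^2+\sigma_A^2)}$, cross-checked against adaptive
quadrature to $10^{-10}$ relative.

**Aggregate rates.** For donor aggregate $D$ and acceptor aggregate $A$,

$$k_{DA} = \frac{2\pi}{\hbar} \sum_{\alpha\in D}\sum_{\beta\in A}
  \frac{e^{-\varepsilon_\alpha^D/k_BT}}{Z}\,
  |V_{\alpha\beta}^{DA}|^2 \int d\omega\,
  S_\alpha^D(\omega)\,S_\beta^A(\omega),$$

where $\varepsilon$ are eigenvalues of the aggregate's Frenkel exciton
Hamiltonian (site energies on the diagonal, intra-aggregate couplings off
it), $Z$ the Boltzmann partition function over donor exciton states, and
$V_{\alpha\beta} = \sum_{m,n} c_{\alpha m} c_{\beta n} V_{mn}$ the site
couplings rotated into the exciton bases. For two single-pigment aggregates
this reduces *exactly* to the pairwise rate — a reduction the acceptance
tests assert at machine precision.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| $\hbar$, $k_B$ | 5.3088, 0.69504 | cm$^{-1}$ ps, cm$^{-1}$ K$^{-1}$ | fixes the cm$^{-1}$/Å/ps unit system |
| Temperature | 300 | K | ambient; Boltzmann weighting of donor exciton states |
| Chl *a* $\omega_0$ | 14 925 | cm$^{-1}$ | Qy band near 670 nm |
| Chl *c* $\omega_0$ | 15 800 | cm$^{-1}$ | blue-shifted Qy near 633 nm |
| Stokes shift $S$ | 160 | cm$^{-1}$ | Chl *a* in protein |
| FWHM | 240 | cm$^{-1}$ | Chl *a* absorption bandwidth |
| `width_mode` | `fwhm_converted` | — | see *Width convention* below |
| Screening $A$, $\beta$, $f_\infty$ | 2.68, 0.27, 0.54 | —, Å$^{-1}$, — | near-continuity at 6.6 and 20 Å |
| Effective dipole | 4.0 (Chl *a*), 3.5 (Chl *c*) | D | in-protein Qy transition dipoles; charges rescaled on assignment |
| `screen_intra` | `TRUE` | — | screening applied inside aggregates too |
| `tau_cutoff` | 20 | ps | map edges slower than this are omitted |
| Bins | [0,1), [1,10), [10,20) | ps | fast / medium / slow map categories, half-open at the upper edge |

**Width convention.** The literature this model family comes from labels
$\sigma$ a "full width at half maximum" while using it in the Gaussian
standard-deviation slot. We default to treating the quoted 240 cm$^{-1}$ as
a true FWHM and converting ($\sigma = \mathrm{FWHM}/2.3548$), because that
matches observed Chl *a* bandwidths; `width_mode = "raw_sigma"` is exposed
for sensitivity runs.

**Chlorophyll *c*.** Site energies for Chl *c* and the Chl *c* → Chl *a*
spectral overlap are poorly constrained by structure alone; the overlap
table mechanism (`overlap_table()`) lets a measured value replace the
Gaussian closed form for any class pair, taking precedence whenever an
entry exists. Chl *c* Stokes shift and width default to the Chl *a* values.

**Pheophytin** uses the Chl *a* charge table and spectrum (same macrocycle
topology); `include_pheo = FALSE` removes it from the pigment set.
Carotenoids never carry transition charges and are excluded from all
couplings; they participate only in the census.

## The transition-charge library

The paper-grade workflow derives TrEsp charges from TDDFT calculations.
Such charge sets are rarely redistributable, so the bundled library
(`inst/extdata/tresp_charges_synthetic.json`) is an explicitly *synthetic*
dipole-faithful pseudo-chlorin set: macrocycle charges that are
mirror-symmetric in x and antisymmetric in y, so the monopole and all
quadrupole moments vanish identically and the far field converges to the
point dipole as $(a/R)^3$. Charges are uniformly rescaled on assignment so
the transition dipole magnitude equals the configured effective dipole.
Any JSON library in the documented format can be dropped in; couplings are
linear in each pigment's charge scale, so only dipole magnitudes and charge
*patterns* matter.

## Synthetic study structures

The generators stand in for a deposited structure so that every physics
stage is testable offline, with ground truth recorded as attributes:

- `make_dimer()` — two pseudo-chlorins at a set separation/orientation,
  with the analytic point-dipole coupling recorded (far-field and
  screening-branch checks).
- `make_supercomplex()` — per monomer, two belts of `n_per_belt` antenna
  sites arranged on an arc that wraps a linear pseudo-core (the arc ends
  contact the core; peripheral sites do not), duplicated by an exact C2
  rotation about the membrane normal. Defaults place adjacent sites 15 Å
  apart and the two layer planes 16 Å apart — typical closest Mg–Mg
  distances between neighbouring antenna subunits. Chain ids encode
  aggregate membership (A..F + core X, lower case for the second monomer),
  so one mapping table drives the aggregate stage. Recorded ground truth:
  the C2 chain/pigment pairing, layer labels, and the aggregate mapping.
- `make_slab()` — two z-planes of pigments for layer-classification tests.
- `make_inventory_supercomplex()` — a census-only stand-in carrying the
  published pigment inventory of the cryptophyte PSII–ACPII supercomplex
  (209 Chl *a* total; 133 Chl *a*, 14 Chl *c*, 48 alloxanthin,
  8 crocoxanthin, 4 α-carotene across twelve antenna chains) as single-atom
  placeholder pigments. It exercises parsing, classification, selection and
  ratio arithmetic end-to-end; it carries no usable geometry.

What the generators deliberately do **not** emulate: protein scaffolds,
realistic site-energy disorder, vibronic structure, carotenoid geometry,
and the full ~300-pigment density of a real supercomplex. Passing tests
therefore validate the *machinery* (couplings, overlaps, rate formulas,
symmetry, network logic) and the qualitative antenna topology — not the
absolute picosecond values of any particular deposited structure, which
additionally depend on quantum-chemistry charges and measured spectra.

## Numerical choices

- Boltzmann energies are shifted by the lowest donor eigenvalue before
  exponentiation; the weight ratio is exactly invariant and the shift
  prevents underflow at low temperature.
- Eigenvalues are reported ascending; exciton coefficients are rows of the
  (orthonormal) eigenvector transpose. Degenerate states may mix freely —
  every rate is invariant under such mixing, and tests only pin magnitudes.
- Exciton lineshape widths and Stokes shifts are participation-weighted
  ($|c_{\alpha m}|^2$) means of the site values: the generalized rate
  expression needs *some* exciton lineshape and this is the simplest choice
  consistent with the site-level treatment; it is exact whenever an
  aggregate is homogeneous.
- Layer assignment: sign of the center's projection on the membrane normal
  relative to the median chlorin projection; a projection exactly at the
  origin counts as stromal (documented tie rule). Carotenoids stay
  unassigned.
- Pathway ranking: path cost is the sum of edge time constants (series
  approximation, matching the additive route framing of antenna relay
  descriptions); a max-bottleneck cost is exposed as an alternative. Ties
  within $10^{-9}$ relative are ordered lexicographically by node id for
  determinism.
- Pair couplings closer than 0.5 Å at any atom pair are rejected as
  clashes; empty aggregates, uncharged pigments, non-bijective
  permutations, degenerate membrane axes and conflicting chain mappings
  are errors, not silent fallbacks.
- Multi-model structure files: first model only.

## Problem sizes

The shipped tests run the full pipeline on supercomplexes of 20–40
pigments (14 aggregates), dimers out to 120 Å, and 100-draw randomized
property checks; the whole suite completes in well under a minute on one
CPU. The same code path scales to full supercomplex models (hundreds of
chlorins); the pairwise stage is $O(N^2)$ in pigments with a configurable
distance cutoff for larger systems.

## Known limitations

- No Redfield/modified-Redfield rates, no master-equation population
  dynamics, no charge-separation modelling at the reaction center.
- Single-realization Hamiltonians: no disorder averaging over site
  energies.
- Pure Gaussian lineshapes; no vibronic sidebands, no temperature-dependent
  broadening.
- The bundled charge library is dipole-faithful but synthetic; quantitative
  work on real structures should substitute a quantum-chemistry-derived
  TrEsp set and measured site energies via the configuration.
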