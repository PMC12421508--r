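---
title: "Quantifying acetylation effects in secondary cell wall models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acetylation effects in secondary cell wall models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylwall)
```

# The scientific problem

Chemical acetylation protects wood against fungal decay, and two molecular
mechanisms have been proposed: acetyl groups could bind diffusing ions
directly, or acetylation could displace cell-wall water and slow transport
by dehydration. Molecular-dynamics models of a lignin/hemicellulose/cellulose
secondary cell wall let both effects be measured separately — one model
series keeps all water and lets the box expand on acetylation, the other
holds the volume fixed so acetyl groups displace water and the moisture
content drops. `acetylwall` implements the complete quantitative analysis
such a study needs:

* **acetylation bookkeeping** — exposure-based hydroxyl selection,
  weight-percent gain (WPG), constant-volume water removal, and the inverse
  atom-count arithmetic;
* **diffusion estimation** — trajectory unwrapping, drift removal,
  mean-squared displacement (MSD), and two Einstein-relation estimators with
  block-averaged uncertainties;
* **interaction analysis** — switching-function atom-pair contacts, radial
  distribution functions (RDF), relative ion-binding free energies with
  propagated errors, and ion dwell-time distributions;
* **solvent structure** — the bulk-water-pocket fraction over time.

Because microsecond all-atom trajectories are not reproducible at desk
scale, the package ships seeded synthetic generators that emulate exactly
the statistical structure each estimator assumes, with machine-readable
ground truth. Every estimator is validated against those known answers.

# Acetylation bookkeeping

Acetylation replaces a hydroxyl group's hydrogen with an acetyl group
(–C(=O)CH~3~): +6 atoms and +43.045 g/mol added, −1 atom and −1.008 g/mol
removed, so each site contributes net +5 atoms and +42.037 g/mol. The
degree of modification is the weight-percent gain

$$\mathrm{WPG} = 100\,\frac{m_\mathrm{post} - m_\mathrm{pre}}{m_\mathrm{pre}},$$

computed from dry masses only, so it is invariant to any water-removal
policy (a tested property). Only hemicellulose and lignin hydroxyls are
candidates — densely packed cellulose is not acetylated — and a site is
"exposed" when its hydroxyl oxygen lies within a cutoff (3, 6, or 12 Å, or
∞ for full acetylation) of the nearest water oxygen under minimum-image
distances. The oxygen–oxygen convention is used because it does not depend
on hydrogen placement.

For constant-volume models the number of waters displaced by acetylation
follows from the expanded model's volume change $\Delta V$:

$$N_\mathrm{removed} = \mathrm{round}\!\left(\frac{\rho_{\mathrm{H_2O}}\,N_A\,\Delta V}{MW_{\mathrm{H_2O}}}\right),$$

with $MW_{\mathrm{H_2O}} = 18.02$ g/mol and a configurable density
defaulting to 0.997 g/cm³ (300 K liquid water; the protocol leaves the
value unstated). The inverse arithmetic
`sites = (post − pre + 3·waters_removed)/5` recovers the site count from
total atom counts and errors on non-integer results, which signal
inconsistent inputs. Applied to the published constant-volume system sizes
it yields 4098 sites at full acetylation and 1193 at the 3 Å cutoff
(29% of all sites); the 10% WPG column of the published table is *not*
consistent with this arithmetic (it implies 52.9% rather than the printed
54%), so it is excluded from validation.

Two water-removal policies are offered: `"displace"` (default) removes the
waters nearest the new acetyl sites, matching the physical picture of
acetyl bulk displacing adjacent water, and `"random"` removes a seeded bulk
sample. Whether ions count toward total mass in the moisture percentage is
configurable (`include_ions`, default off); the convention is not fixed by
the protocol.

`apply_plan()` performs the replacement at the bookkeeping level: labels,
counts, masses, and pseudo-coordinates near the site. Downstream analyses
need group identities and abundances, not strain-minimised geometry, so no
force-field relaxation is attempted (and none is in scope).

# Diffusion estimation

Coordinates are unwrapped by the displacement scheme
$u(t) = u(t-1) + \mathrm{mi}(w(t)-w(t-1))$ using each frame's own box, which
tolerates the slow box fluctuations of semi-isotropic pressure coupling,
and is exact while no particle crosses half a box length per frame (a
warning fires otherwise). Drift is removed by subtracting the
centre-of-mass displacement of a reference group (the central cellulose
fibril in the real systems). Alignment is translation-only: rotational
superposition would corrupt the MSDs of every atom outside the reference
group, and the reference barely rotates.

Two estimators implement the 3-D Einstein relation $D = \mathrm{MSD}/6t$:

* `diffusion_linear()` — least-squares slope of an MSD series versus lag,
  divided by 6. Default fit window: 10–90% of the available lag span (the
  protocol does not state its window; the default avoids the short-lag
  regime and the poorly averaged tail).
* `diffusion_sliding()` — displacement over a fixed lag $\Delta t$ averaged
  over maximally overlapping window starts, for tightly coupled components
  whose limited independent sampling makes the long-time MSD nonlinear.
  Standard errors come from block means over *non-overlapping*
  window-length segments, so overlap cannot understate the error.

Uncertainties elsewhere follow the same block convention (19 × 50 ns
segments for diffusion in the source protocol, 20 equal blocks for contact
and RDF statistics); both counts are arguments, since the two conventions
coexist.

Two MSD variants are provided. `msd_fixed_origin()` references every
displacement to the first post-equilibration frame, exactly as the water
protocol describes. `msd_time_averaged()` additionally averages over all
available time origins at each lag. The distinction matters for
validation: the fixed-origin MSD's uncertainty is set entirely by the group
size at one origin (relative spread ≈ $\sqrt{24}/6/\sqrt{N}$ per lag point,
about 4% of the fitted slope at 500 tracers regardless of trajectory
length), while time-origin averaging brings the fitted slope within ~1–2%
at the same size. Recovery tests therefore use the time-averaged variant
with lags up to a tenth of the window (longer lags have too few independent
segments); the fixed-origin variant remains the default for the
water-protocol path. Internally everything is in Å²/ns; the conversion
1 Å²/ns = 10⁻⁷ cm²/s is exact and applied once.

# Contacts, free energies, and dwell times

Atom-pair contacts use the logistic switching weight
$w(d) = [1 + e^{5(d - 5\,\text{Å})}]^{-1}$ summed over heavy-atom pairs at
minimum-image distances. The weight falls below 10⁻¹⁵ past 12 Å, where the
sum is hard-truncated — declared so scores are bit-stable regardless of any
neighbour-search radius. Functional-group heavy atoms are hydroxyl {O},
carboxyl {C, O, O}, and acetyl {carbonyl C, carbonyl O, ester O, methyl C}.

Mean contact scores are normalised by functional-group *abundance* (number
of chemical instances, counted via per-instance head atoms) into per-site
interaction probabilities, and relative binding free energies follow from
the probability ratio against the carboxyl reference (the strongest
ion-binding group):

$$\Delta G = -RT\,\ln(P_s / P_c), \qquad
\sigma_{\Delta G} = RT\sqrt{(\sigma_s/P_s)^2 + (\sigma_c/P_c)^2},$$

with $R = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 300$ K by
default, and $\sigma$ from 20 trajectory blocks. The exact normalisation
constant cancels in the ratio; the per-site convention is used (the
protocol states only "normalized by a functional group abundance") and the
equal-per-site alternative differs only by that cancelling constant. The
carboxyl reference row is exactly 0 ± 0 by construction. Zero
probabilities raise a "not estimable" error rather than returning
infinities.

The independent RDF route computes a number-density-normalised $g(r)$ to
10 Å, retains raw per-centre pair counts, and integrates them to the first
minimum of the smoothed profile (5-bin running mean; first strict local
minimum after the global peak). Multi-peaked profiles — the acetyl RDF has
internal structure from its four heavy atoms — may need the manual
`r_min` override, which is why detection failure is an explicit error
rather than a guess. The resulting coordination numbers per site enter the
same $\Delta G$ formula, giving a second estimate with its own 20-block
error.

Dwell times are maximal runs of consecutive frames with an ion–site
minimum-image distance ≤ 6 Å. Runs touching either end of the analysed
window are flagged censored — their true length is unknown, and trivalent
ions routinely stay bound longer than an entire trajectory — and are
excluded from mean-recovery statistics. Because most events are short while
long events dominate the bound time, distributions are summarised by the
time-weighted CDF: each event weighted by its share of total bound time.

# The synthetic generators

Each generator emulates one statistical structure and records its ground
truth in the return value, never in file names:

* `gen_brownian()` — independent Gaussian walks with per-dimension step
  variance $2D\Delta t$, wrapped into the box. Validates unwrapping and both
  diffusion estimators; defaults (500 particles, 1000 frames at 0.1 ns)
  match the validation conditions, and the planted coefficients 0.05, 0.62,
  and 6.1 Å²/ns span the trivalent-ion, reduced-moisture-ion, and
  monovalent-ion/water scales of the real systems.
* `gen_binding()` — a two-state Markov chain per ion (geometric run lengths,
  means specified in ns and converted by the frame interval, matching what
  a frame-based estimator can actually see) teleporting ions between a
  contact shell and a far position. Validates the dwell machinery,
  including censoring.
* `gen_boltzmann_sites()` — each frame, each ion independently occupies a
  site of type $s$ with probability ∝ count$_s \cdot e^{-E_s/RT}$, sitting
  2–3 Å from it on a 20 Å site grid (so cross-site contact weights are
  below truncation). Occupancy is resampled per frame with no kinetics:
  this fixture validates the thermodynamic estimators, `gen_binding()` the
  kinetic ones, keeping the two validation surfaces decoupled. On this
  idealised geometry the contact and RDF routes see essentially the same
  occupancy events, so their agreement check exercises the two
  normalisation paths rather than independent noise.
* `gen_toy_cellwall()` — polymer bead chains with labelled hydroxyl and
  carboxyl sites, a bound water shell (2.8–4.2 Å from beads) and a distant
  bulk cloud, optional ions, and optional isolated hydroxyl–water pairs at
  exact separations. Validates exposure selection, acetylation application,
  and water-pocket classification against constructed truth.

What these fixtures deliberately do **not** reproduce: excluded volume,
electrostatics, force-field energetics, correlated polymer motion, and the
multi-peaked RDF shapes of real acetyl groups. Passing tests therefore
demonstrate estimator correctness on data satisfying each estimator's own
assumptions — not the physical accuracy of any simulation.

# Water pockets

A water molecule is "bulk" when its oxygen is more than 5 Å (configurable)
from every biopolymer atom. The water side uses the oxygen only (hydrogen
placement is irrelevant at this scale); the polymer side includes
hydrogens, reading "any biopolymer atom" literally, with a heavy-atom-only
flag. Ions are not biopolymer atoms. The per-frame percentage is reported
as a series with equilibration frames flagged rather than dropped, so
plots can show them greyed out while summaries exclude them.

# Numerical conventions and degenerate inputs

* Å for length, ns for time, kcal/mol for energy; 1-based atom indexing
  throughout, as in every R container this package builds on.
* Orthorhombic boxes only; triclinic input is rejected with a clear error.
* Minimum-image components lie in $[-L/2, L/2)$; the neighbour search is an
  exact chunked all-pairs minimum-image computation (no cell approximation),
  checked against a 27-image enumeration oracle.
* Equilibration default: the first 50 ns of a loaded trajectory are
  excluded from all summary statistics.
* Empty selections are errors where a mean would be undefined (contacts,
  MSD, moisture with zero total mass) and empty results where a set is the
  natural answer (neighbour pairs of an empty group, a never-bound ion).
* The frame interval is taken from the file when available, otherwise it
  must be supplied; the stated saving interval of the source protocol is
  internally inconsistent with its own block analyses, so no default is
  guessed.

# Validation scale

The test suite and the acceptance script run at sizes chosen to make every
statistical check well-conditioned while completing in minutes on one CPU:
Brownian fixtures at 500 × 1000 frames, Boltzmann fixtures with 420 sites,
120 ions and 400 frames, binding fixtures yielding ≥ 5000 uncensored dwell
events, and ideal-gas RDF checks with ≥ 20,000 counts per bin so the
±0.02 flatness band sits several standard errors out.

# Known limitations

* Bookkeeping-level acetylation: no reaction chemistry, no differential
  lignin-versus-hemicellulose reactivity, no geometry relaxation.
* Relative free energies only — no absolute binding constants and no
  unbound-state reference (the unbound ion population in the real systems
  is too small to serve as one).
* No anomalous-diffusion exponents, glass-transition detection,
  hydrogen-bond analysis, or pocket-volume estimation.
* Censored dwell events are reported but not modelled; survival-style
  estimators would be needed for trajectories where most events are
  censored.
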