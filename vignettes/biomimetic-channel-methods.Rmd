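---
title: "Methods: building and analysing a biomimetic CNT potassium channel"
author: "cntkchan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and analysing a biomimetic CNT potassium channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntkchan)
```

## The system

Potassium channels separate K+ from Na+ with their selectivity filter: a
narrow pore lined by four rings of backbone carbonyl oxygens that form
the sequential binding sites S1--S4.  `cntkchan` implements a synthetic
mimic of that filter -- an armchair (7,7) carbon nanotube, 0.95 nm in
diameter, whose wall is decorated with 20 inward-pointing carbonyl
oxygens in four rings -- together with the trajectory analyses used to
characterise ion conduction through it: permeation-event counting and
knock-on mode classification, selectivity ratios, solvation-shell
statistics, spatial densities, an electrostatic-potential profile, and
umbrella-sampling/WHAM free-energy reconstruction.

Atomistic molecular dynamics of such a system is far outside a desk-scale
package, so a first-class synthetic-data module generates trajectories,
biased samples and snapshots with the *statistical structure* those
analyses assume, with known ground truth.  Every downstream operator is
therefore testable exactly; what the tests demonstrate is the
correctness of the operators, not the physics of any particular MD
force field (see "What the generators do and do not emulate").

## Channel construction

The builder follows a fixed recipe:

1. **Rolled lattice.**  Wall carbons are generated from the graphene
   lattice folded onto a cylinder; for chiral indices $(n,m)$ the
   diameter is $d = (a/\pi)\sqrt{n^2+nm+m^2}$ with $a = \sqrt3\,d_{CC}$.
   The default C--C bond length is 1.415 Å, which puts the armchair
   hexatomic-ring spacing $\sqrt3\,d_{CC}$ at 2.45 Å and the (7,7)
   diameter at 0.95 nm.  In an armchair tube each ring row spans two
   atomic z-levels, so the ring spacing is twice the adjacent
   level gap; `ring_spacing()` measures it that way from coordinates.
2. **Axial strain.**  The filter's carbonyl layers are ~2.9 Å apart,
   wider than the pristine ring spacing, so the tube is stretched by
   10%.  Strain is applied as an affine z-scaling about the centre
   (`apply_axial_strain()`), a deterministic surrogate for
   force-field relaxation that preserves the one quantity the recipe
   pins down: the strained ring spacing of ~2.7 Å.
3. **Mid-section.**  A 13.34 Å slab is excised and recentred.  Whether
   the section is cut before or after straining is ambiguous in
   principle; `cnt_spec(section_before_strain=)` exposes both
   orderings, defaulting to strain-then-cut so the retained section has
   the stated length.
4. **Carbonyl decoration.**  Four wall-carbon levels, one ring period
   apart and as central as possible, each donate five carbons at
   maximally even angular spacing; each is retagged and given an oxygen
   displaced radially inward by the C=O bond length (1.23 Å -- the
   standard backbone value; the geometry is otherwise unspecified, so
   radial-inward in the carbon's z-plane is our choice).  Per-layer
   azimuthal registry is configurable (`offset_deg`), default aligned.
5. **Charges.**  Partial charges are assigned per group tag from a
   table.  The default is the backbone-carbonyl convention
   $\pm 0.51\,e$ on C=O pairs with all other carbons neutral, which
   keeps the channel exactly neutral; any table (e.g. DFT-derived
   values) can be supplied instead.

`assemble_membrane_system()` completes the simulation cell: two pored
graphene sheets at the channel mouths, 3-site water on a jittered cubic
lattice at 0.0334 molecules/Å$^3$ in the two chambers (reproducible
without an external packing tool), and ion counts
$N = \mathrm{round}(c\,N_A V)$ per salt with Cl$^-$ balancing all
cations.  At the default 5.1 nm box and 0.5 M KCl + 0.5 M NaCl this
gives ~10,000 atoms and 28 ions of each cation.

## The synthetic permeation generator

`generate_permeation_trajectory()` emits a long-format trajectory plus a
ground-truth event log.  It runs a knock-on conveyor that mirrors the
conduction phenomenology of the four-site channel at low field:

* A resident cation occupies S2.  Each cycle, an incoming ion enters
  from the entrance-side reservoir, pauses at an inlet position, then
  commits to S4; the resident is displaced upward (knock-on) and
  completes its own traversal into the exit-side reservoir, while the
  incoming ion walks S4→S3→S2 and becomes the new resident.
* With probability `mode1_prob` an entry is **mode 1**: two water
  tracers sit between the incoming and resident cations (occupying the
  intervening sites, as a knock-on column does).  Otherwise it is
  **mode 2**: the incoming ion swaps with the S4 water so a single
  water spaces the two cations until exit.
* **Na+ events** enter directly to S3, ride ~2 Å off-axis
  (`na_radial_offset`), and are flushed out by an incoming K+ -- every
  Na+ exit is a knock-off, and the following K+ becomes the resident.
* An event is logged only when its ion completes the full crossing, so
  replaying the trajectory through `detect_events()` recovers the log
  count exactly.

Dwell times are exponential with base rate `hop_rate` (2/ns by
default); the underlying microscopic rates are not observable at this
level, so the distribution is an explicit assumption.  Two floors are
imposed -- two frame intervals inside the channel, four in the
reservoirs -- so that every configuration is resolvable at the output
cadence (0.1 ns frames) and event counts are invariant under
twofold subsampling.  If a `reference_pmf` is supplied, mean dwells
scale by $\exp(\Delta U^\ddagger/kT)$ of the forward barrier, emulating
landscape effects qualitatively.  Positions carry small Gaussian jitter
(0.1 Å transverse, 0.08 Å axial) so density and RDF estimators see
realistic scatter without moving anything across a detection threshold.

The packaged `kcl_mix_0p2V()` configuration fixes the study mixture:
`mode1_prob = 0.76`, `na_fraction = 0.02` (Na+ crossings are rare at
low field), K+ on-axis within 0.3 Å.

**What the generators do not emulate.**  Absolute permeation rates
(real channels conduct at $10^7$/s under these fields; the generator's
clock is arbitrary), field-dependent hydration changes, correlated
multi-ion queueing beyond one resident + one incomer, and bulk
RDF fine structure.  Tests that pass on this data certify the
estimators and the pipeline plumbing -- not force-field physics.

## Permeation analyses

`detect_events()` counts a traversal when a cation goes from below
`entrance_z - buffer` to above `exit_z + buffer` (buffer 2 Å -- the
crossing planes are otherwise arbitrary, and a committed-crossing margin
prevents double counting of mouth recrossings).  An ion must return
below the entrance threshold before it can start a new event.  Sites
are the carbonyl-layer planes with tolerance equal to half the layer
spacing; positions between sites are reported as `"inter-site"` rather
than invented extra sites (off-axis Na+ dwells show up there).

`classify_modes()` operationalises the two conduction modes: over
frames where the event ion is in-channel with another cation above it
(nearest-above if several), count water tracers strictly between them;
the label is the modal count (2 → mode 1, 1 → mode 2, anything else
unclassified) and fractions are reported over classified events.  The
modal-count rule is our resolution of transiently varying water counts.

Rates are least-squares slopes of the cumulative flux versus time
(resampled on a uniform grid), with the plain count/duration estimate
reported alongside; the selectivity ratio is their quotient.  When no
Na+ event is observed the ratio is reported as a *lower bound* using
one pseudo-event over the simulated time -- an honest reading of a
finite record that contains zero crossings.

`detect_knock_on()` annotates a site advance as knock-on when another
cation has just arrived within `approach_cutoff` (6 Å, roughly two
site spacings) behind it within a 5-frame window.

## Solvation and densities

RDFs are pair-distance histograms normalised by $4\pi r^2 dr$ and a
partner density measured in a user-defined bulk region; in confined
geometry no global normalisation exists, so in-channel curves are
shape-only by design.  Minimum-image distances are used when a box is
present.  The first minimum is the first local minimum after the global
peak of a 3-point-smoothed curve, ties toward smaller r.

Coordination profiles count ligand oxygens within the species'
first-shell radius -- 3.6 Å (K+) and 3.2 Å (Na+), the bulk RDF
first-minimum values -- split by partner group; the split is exactly
additive.  Orientation histograms use the water dipole (bisector from O
through the HH midpoint) against +z, the field direction, with the
isotropic $\sin\theta$ baseline returned alongside; the dipole (rather
than OH-vector) convention is configurable in principle and stated here
because either is defensible.

Densities: axial profiles are per-frame counts per z-bin width (a
linear density whose integral is the mean in-range count); radial
profiles divide by exact annulus areas times slab height, which makes a
radially uniform fixture exactly flat; planar maps are x--y histograms
over in-channel frames (|z| below the channel half-length).

## Electrostatics

The potential profile uses a Gaussian-smeared Coulomb sum,
$\phi(\mathbf r) = \sum_i q_i\,\mathrm{erf}(r_i/\sqrt2\sigma)/r_i$
(vacuum, non-periodic, $\sigma$ = 1 Å), optionally disc-averaged about
the axis with an equal-area polar quadrature.  This is a deliberate
replacement for periodic mesh-Ewald maps of the solvated system: the
desk-scale object of interest is the interior valley shape created by
the four negative rings, which the smeared sum reproduces; absolute
magnitudes include no solvent screening and should be read accordingly.
Output is kT/e at 300 K by default, volts optionally.

## Umbrella sampling and WHAM

The packaged reference landscapes `na_two_site` and `k_two_site`
encode the two-binding-site free-energy profiles: a flat bulk plateau,
an entrance barrier ΔE1 (6.2 kcal/mol Na+, 3.1 K+), an entrance well,
a first-site barrier ΔE2 above that well (6.6 Na+, 3.5 K+), then
site wells with a lower inter-site barrier for Na+ than K+ and similar
exit barriers.  Nodes are joined by a monotone cubic Hermite spline
(Steffen-type slopes, zero at extremum nodes) so that each labelled
extremum sits exactly at its node with exactly the stated energy; an
unconstrained cubic spline overshoots extrema and would corrupt the
encoded barrier heights.

`generate_umbrella_samples()` runs one Metropolis chain per window,
all windows advanced in lockstep, targeting
$\exp[-(U(z)+\tfrac12 k(z-z_i)^2)/kT]$.  The default protocol is the
standard ladder: centres −10 to 10 Å every 0.5 Å, $k = 20$
kcal/mol/Å$^2$, 300 K, $10^4$ retained samples per window with the
first half of each chain discarded (mirroring an
equilibration/production split).  The proposal width is
$2.4\sqrt{kT/k}$, the near-optimal random-walk scaling; the closed
forms $\mathrm{var} = kT/k$ (flat landscape) and $kT/(k+\kappa)$
(harmonic) are test anchors.  The production runs being mimicked
restrained a second, columnar ion as well; our 1-D surrogate folds that
ion's influence into the reference profile itself -- a stated deviation.

`wham()` iterates the standard self-consistent equations on a 0.1 Å
grid to $10^{-6}$ kcal/mol on the window free energies (the defaults a
citable WHAM implementation would use).  Three numerical guards
matter in practice:

* bins with fewer than `min_count` (25) total samples are unsupported
  (rare-excursion tails carry exploding reweighting factors);
* the reported PMF is trimmed to the window-centre range;
* windows must form one overlap-connected component, otherwise the
  relative offsets between groups are undetermined and the result is
  flagged.

The PMF is zeroed on the 2 Å nearest the entrance-side boundary.
`extract_barriers()` locates stationary points by sign changes of a
5-point-smoothed derivative (ties toward smaller z), enforces max/min
alternation, and iteratively removes the least prominent adjacent pair
below 0.5 kcal/mol -- statistical wiggles on a plateau are not
barriers.  ΔE1 is the first maximum over the bulk reference; ΔE2 is
the second maximum over the intervening well (the printed barriers
read most naturally from the preceding well; the convention is ours
and configurable by reading `barriers`/`extrema` directly).

Reconstruction accuracy at the default protocol is ~0.1--0.3 kcal/mol
RMSD over the window range, comfortably resolving the ~3 kcal/mol
Na+/K+ barrier differences that explain the channel's selectivity.

## Problem sizes

The shipped drivers and tests use: 150--2000 synthetic events
(binomial error on a 76% mode fraction at 2000 events: ~1%), $10^4$
samples per umbrella window across 41 windows, 4000--5000-point gas
fixtures for RDF checks, and a single 5.1 nm assembled system.  These
sizes make every statistical tolerance in the test suite a ≥3σ bound.

## Known limitations

* The affine strain model ignores Poisson contraction and bond
  relaxation; only the axial spacing is faithful.
* Default carbonyl charges are a convention, not the DFT values of the
  original parametrisation (which are not published in the main text);
  all charge-dependent results scale accordingly.
* The smeared-sum potential is unscreened vacuum electrostatics.
* The generator's dwell statistics, dwell floors, and single-file
  conveyor are modelling choices; they are documented above precisely
  because no observable constrains them.
* WHAM here is strictly 1-D; multi-ion (multi-dimensional) free-energy
  surfaces are out of scope.
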