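# cntkchan

Construction and trajectory analysis of a biomimetic carbon-nanotube
potassium channel, in R.

Biological potassium channels separate K⁺ from Na⁺ at near-diffusion
rates using a selectivity filter: four stacked rings of backbone
carbonyl oxygens forming the binding sites S1–S4.  A synthetic mimic —
an armchair (7,7) carbon nanotube (0.95 nm diameter) stretched by 10% so
its hexatomic-ring spacing grows from 2.45 Å to ~2.7 Å, cut to a
13.34 Å section, and decorated with 20 inward-pointing carbonyl oxygens
in four rings — reproduces the filter's geometry and, in simulation,
much of its selectivity.  `cntkchan` implements that construction and
the full analysis chain used to characterise conduction through such a
channel, for anyone studying ion transport in functionalised nanopores:

* **channel builder** — rolled-lattice CNT coordinates
  (d = (a/π)·√(n²+nm+m²)), affine axial strain, mid-section excision,
  carbonyl decoration, tag-driven partial charges, and full membrane
  assembly (pored graphene sheets, lattice water, ions at molar counts);
* **permeation analysis** — committed-crossing event detection,
  cumulative fluxes and least-squares rates, the K⁺/Na⁺ selectivity
  ratio SR = k_K/k_Na (with a principled lower bound when no Na⁺
  crossing is observed), S1–S4 occupancy, knock-on annotation, and
  classification of the two conduction modes by the number of water
  molecules spacing consecutive cations (mode 1: two waters; mode 2:
  one);
* **solvation structure** — ion–oxygen RDFs decomposed by partner group,
  coordination/hydration profiles with shell radii 3.6 Å (K⁺) and
  3.2 Å (Na⁺), water-dipole orientation histograms, and axial, radial
  and planar densities;
* **electrostatics** — the axial potential profile of the charged
  structure via a Gaussian-smeared Coulomb sum
  φ(r) = Σᵢ qᵢ·erf(rᵢ/√2σ)/rᵢ;
* **free energies** — umbrella-window generation over packaged
  two-binding-site reference landscapes and self-consistent WHAM,
  P(z) ∝ Σᵢ nᵢ(z) / Σⱼ Nⱼ·exp[(Fⱼ − wⱼ(z))/kT], with extraction of the
  entrance barrier ΔE₁ and first-site barrier ΔE₂;
* **synthetic data** — a first-class generator module (stochastic
  knock-on conveyor trajectories with ground-truth event logs,
  Metropolis umbrella samples, solvation snapshots, ideal-gas
  fixtures) so that every operator is testable without molecular
  dynamics.

Trajectories are exchanged as multi-frame extended XYZ or multi-model
PDB; umbrella windows use the de-facto WHAM metadata layout; results
are delimited tables.

## Worked example

```r
library(cntkchan)

channel <- build_channel()                      # (7,7), 10% strain, 4x5 carbonyls
cat(sprintf("channel: %d atoms, %d carbonyl oxygens, ring spacing %.2f A\n",
            nrow(channel), sum(channel$tag == "carbonyl_O"),
            ring_spacing(channel)))

sim    <- generate_permeation_trajectory(kcl_mix_0p2V(n_events = 500, seed = 1))
events <- detect_events(sim$trajectory, sim$geometry)
modes  <- classify_modes(events, sim$trajectory, sim$geometry)
flux   <- cumulative_flux(events, total_time = sim$trajectory$n_frames * sim$trajectory$dt)
rk  <- permeation_rate(flux, "K"); rna <- permeation_rate(flux, "Na")
sr  <- selectivity_ratio(rk$rate_per_s, rna$rate_per_s, rna$n, attr(flux, "total_time"))
cat(sprintf("events: %d (%d Na+); mode 1 %.1f%%, mode 2 %.1f%%; SR %.0f\n",
            nrow(events), sum(events$species == "Na"),
            100 * modes$fractions[["mode1"]], 100 * modes$fractions[["mode2"]],
            sr$sr))

pmf <- wham(generate_umbrella_samples(reference_pmf_profile("na_two_site"),
                                      umbrella_protocol(seed = 1)))
br <- extract_barriers(pmf)
cat(sprintf("Na+ barriers: dE1 %.2f, dE2 %.2f kcal/mol\n", br$dE1, br$dE2))
```

prints

```
channel: 160 atoms, 20 carbonyl oxygens, ring spacing 2.70 A
events: 500 (10 Na+); mode 1 72.9%, mode 2 27.1%; SR 53
Na+ barriers: dE1 6.22, dE2 6.58 kcal/mol
```

Reading: all 500 scripted crossings are recovered; ~3/4 of K⁺ entries
proceed by the two-water knock-on column (mode 1, 76% expected at this
mixture) and the rest by the one-water entry swap; the rare Na⁺
crossings make the channel strongly K⁺-selective over this record; and
the umbrella/WHAM round trip reconstructs the encoded Na⁺ entrance and
first-site barriers (6.2 and 6.6 kcal/mol) to within ~0.1 kcal/mol.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the study
end-to-end, each a thin narrative script over the package functions,
writing delimited tables under `results/`:

```
01_build_channel.R         channel + membrane system, PDB/XYZ/charge table
02_simulate_trajectories.R synthetic permeation trajectory + umbrella windows
03_permeation_analysis.R   events, fluxes, rates, SR, modes, knock-on
04_solvation_structure.R   RDFs, coordination, hydration, orientation, densities
05_electrostatics.R        axial potential profile of the charged channel
06_pmf_wham.R              WHAM reconstruction and barrier extraction
```

Run them in order with `Rscript analysis/01_build_channel.R`, etc.
`run_pipeline()` offers the same stages behind one call with a single
config list (or YAML file) and seed.

The methods vignette (`vignettes/biomimetic-channel-methods.Rmd`)
documents the model assumptions, parameter defaults, numerical choices
and what the synthetic generators do and do not emulate.

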