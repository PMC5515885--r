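# npcrowd

Ratiometric FRET quantification of protein crowding in the nuclear pore
complex (NPC).

## The problem

The central channel of the NPC is filled with intrinsically disordered,
FG-motif-rich nucleoporins (FG-Nups) that form a crowded, protein-rich
permeability barrier.  Crowding in this channel can be probed in living
cells with **GimRET**, a FRET pair of CFP (donor) and a glycine-inserted
YFP (YFP1G, acceptor) whose acceptor fluorescence is quenched by
macromolecular crowding while the donor is insensitive.  Fusing the probe
to individual Nups and imaging donor (460–500 nm) and acceptor
(520–570 nm) channels turns local crowding into a measurable intensity
ratio.

`npcrowd` implements the complete quantification pipeline for this kind
of experiment, for microscopists and image analysts who want a tested,
scriptable replacement for manual region-of-interest workflows:

* **Spectroscopy.**  The probe signal of an emission spectrum is the
  band-integrated acceptor/donor ratio
  `A/D = Σ I(λ), λ ∈ [520, 570] / Σ I(λ), λ ∈ [460, 500]`
  (inclusive grid sums).  Crowding calibration uses a linear quench
  model with saturation floor, `A/D(C) = r₀ · max(1 − sC, φ)` with
  defaults `s = 1/500 (mg/mL)⁻¹` and `φ = 0.2`, fitted by
  Levenberg–Marquardt least squares and invertible to a concentration
  estimate.
* **Interphase imaging.**  The nuclear-envelope rim is segmented from
  the donor channel (Otsu threshold, hole-filling, and a
  brightness-calibrated boundary band); the per-cell statistic is
  `[probe]_NE / [probe]_Cyto`, the ratio of background-subtracted A/D
  ratios at the rim and in the cytoplasm.  Group summaries (mean ± SD,
  quartiles, 1.5·IQR outliers) and two-tailed Welch t-tests compare
  treatments against intact cells.
* **Mitosis.**  In three-channel time-lapse stacks (donor, acceptor,
  chromosome marker), anaphase onset is detected as the persistent
  separation of the chromosome masses; localization
  (rim/cytoplasm donor excess) and probe signal (rim/cytoplasm A/D,
  normalized to onset) are traced on the chromosome surface, and the
  times of half-maximal assembly and half-minimal crowding are
  extracted by midpoint crossing with linear interpolation.
* **Synthetic data.**  Every stage has a phantom generator (emission
  spectra, two-channel interphase cells, intact/treated immunostain
  pairs, anaphase-to-G1 stacks) that emits exact ground truth, so the
  pipeline is validated end to end as a parameter-recovery experiment.

## Worked example

```r
library(npcrowd)

## spectra: crowding quenches the acceptor band
adRatio(simulateSpectrum("GimRET", C = 0))    # 1.2058
adRatio(simulateSpectrum("GimRET", C = 100))  # 0.9647  (= 0.8 x baseline)

## interphase cell: segment, measure, compare with ground truth
ph    <- simulateInterphaseCell(cellPhantomConfig("peripheral", seed = 1))
masks <- segmentCell(ph$donor)
measureCell(ph$donor, ph$acceptor, masks)
#> CellMeasurement 'cell': probeNE 0.7278, probeCyto 0.9601, relative 0.7581
expectedValues(ph$manifest)$relativeProbe
#> [1] 0.75

## mitotic reassembly: trace and half-times
tl <- simulateTimelapse(timelapsePhantomConfig("early_assembler", seed = 1))
quantifyTimelapse(tl$donor, tl$acceptor, tl$chromosome)
#> TimelapseTrace: 19 frames, t = -6.0..30.0 min (onset frame 4)
#>   localization half-time: 3.74 min
#>   probe half-time: 4.15 min
```

The `relative 0.7581` read-out means the probe signal at the nuclear
envelope is ~24% lower than in the cytoplasm of the same cell — the
crowding signature of a peripheral FG-Nup — and matches the phantom's
generating truth of 0.75.  The half-times recover the generating
kinetics (onset 1 min, rate ln2/3 min⁻¹, analytic half-max 4 min).

A thin command-line wrapper for batch work ships in
`inst/scripts/npcrowd-cli.R` (subcommands `simulate`, `quantify`,
`calibrate`).

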