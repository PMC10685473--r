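# footmodel

Multi-segment kinetic foot model for clinical gait analysis in R.

Traditional gait analysis treats the foot as a single rigid segment, which
hides clinically important motion — the rise and fall of the medial
longitudinal arch (MLA), hallux dorsiflexion at push-off — and overstates
ankle kinetics. `footmodel` implements a four-segment foot model (hindfoot,
midfoot, forefoot, hallux) built on an eleven-marker foot set plus shank
references, for laboratories using optical motion capture and a single
floor-mounted force plate. It is aimed at biomechanics researchers and
clinical gait analysts who want intersegmental foot kinematics *and*
kinetics without extra instrumentation.

## What it computes

* **Segment frames.** Each segment is defined by an Origin marker, a
  Long-Axis marker and a Plane marker: the z-axis runs origin to long-axis
  marker, the x-axis is the right-handed normal of the marker plane, y
  completes the triad, and fixed RX/RY/RZ offsets align all segments with
  the anatomical convention (z anterior, y up, x lateral). Virtual markers
  (ankle joint centre, navicular–cuboid midpoint, 1st–5th metatarsal
  midpoint) are inter-marker midpoints.
* **Intersegmental angles.** Distal-relative-to-proximal rotations are
  decomposed by the x–z–y Cardan sequence:
  `R = Rx(α) · Rz(β) · Ry(γ)`, with α dorsi(+)/plantarflexion(−), β
  inversion(+)/eversion(−), γ internal(+)/external(−) rotation (abduction
  for the hallux). Four joints are reported: ankle (hindfoot vs shank),
  Chopart (midfoot vs hindfoot), Lisfranc (forefoot vs midfoot) and 1st
  MTP (hallux vs forefoot).
* **MLA height/length ratio.** Arch length is |1MTH − BC|; arch height is
  the perpendicular distance from the navicular marker to that line.
* **Joint moments and powers** by Newton–Euler inverse dynamics over each
  joint's distal free body, with segment masses apportioned by assumed
  volumes (hindfoot half of the non-toe foot; midfoot and forefoot a
  quarter each; hallux the toe fraction), centres of mass halfway along
  each segment's long axis, and radii of gyration as fractions of segment
  length:

      F_J = Σ_i m_i (a_i − g) − F_grf
      M_J = Σ_i [I_i α_i + ω_i × I_i ω_i + (r_i − c_J) × m_i (a_i − g)]
            − (CoP − c_J) × F_grf − T_z

* **CPcross masking.** With one force plate the full ground reaction is
  attributed to every joint's distal free body; the CPcross convention
  reports each joint's kinetics only once the centre of pressure has
  crossed anterior to that joint's centre, which it does in anatomical
  order as it travels heel to toe.
* **CMC reliability.** Within-day coefficients of multiple correlation for
  repeated-trial waveforms, with the conventional strong (R ≥ 0.7) /
  moderate / poor labels.
* **Synthetic gait generator.** A rigid forward model with prescribed joint
  waveforms, a double-hump vertical GRF and a heel-to-toe CoP, providing
  exact ground truth for validation.

Marker data are read from TRC or long-format CSV, force-plate data from
CSV (pre-computed CoP or raw plate moments), configuration from YAML.

## Worked example

```r
library(footmodel)

trial <- generate_trial(healthy_default_spec(seed = 1))   # synthetic walk
cfg   <- trial_config(body_mass = 64)
kin   <- joint_angle_pipeline(trial$traj, trial$fp, cfg)
kin
#> <foot_kinematics> side: right
#>   ankle     ROM (deg): sagittal  26.0 frontal   6.5 transverse   2.7
#>   chopart   ROM (deg): sagittal   6.4 frontal   3.8 transverse   3.7
#>   lisfranc  ROM (deg): sagittal  14.0 frontal   0.2 transverse   7.4
#>   mtp1      ROM (deg): sagittal  36.8 frontal   0.1 transverse  11.7
#>   MLA ratio: 0.111 - 0.179

anthro <- build_anthropometrics(64)
kset <- inverse_dynamics(kin$poses, anthro, kin$fp, events = kin$events)
kset <- cpcross_mask(kset, kin$fp, kin$poses, kin$events,
                     progression_axis(kin$traj, kin$events))
kset
#> <joint_kinetics_set> convention: plantar  side: right
#>   ankle     peak |M| 1.541 N m/kg, peak |P| 2.927 W/kg, CoP crossing @ 14%
#>   chopart   peak |M| 1.546 N m/kg, peak |P| 0.475 W/kg, CoP crossing @ 14%
#>   lisfranc  peak |M| 0.909 N m/kg, peak |P| 0.470 W/kg, CoP crossing @ 25%
#>   mtp1      peak |M| 1.243 N m/kg, peak |P| 0.870 W/kg, CoP crossing @ 43%
```

The angle ROMs are the healthy-adult ranges the generator prescribes
(hindfoot sagittal ~26°, hallux sagittal ~37°); the MLA ratio falls
through stance to a minimum before toe off; the CoP crosses the ankle,
Chopart, Lisfranc and 1st MTP joint centres in anatomical order (the ankle
and Chopart share the inter-malleolar centre, hence the tie at 14%).

From a shell, the same pipeline runs as:

```sh
footmodel simulate --out trial/ --seed 1
footmodel run --markers trial/markers.csv --force trial/force.csv --out results/
footmodel reliability --curves 'curves/*.csv' --out report.csv
```

(`exec/footmodel` in the installed package; invoke with `Rscript` if it is
not on your PATH.)

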