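# cranioload

Finite-element analysis of masticatory loading on the infant cranium over
the first 48 months of life.

Infant skulls experience a rapidly changing mechanical environment as
feeding shifts from suckling to biting and chewing: the jaw-closing
muscles (temporalis, masseter, medial pterygoid) grow severalfold, cranial
bone stiffens by an order of magnitude, and sutures and fontanelles close.
`cranioload` is for biomechanists and craniofacial researchers who want a
fully synthetic, reproducible version of this analysis — every input
(skull geometry, muscle measurements) is generated by the package, so the
entire pipeline runs with no clinical data.

## The model

* **Muscle forces.** Peak per-side muscle force is estimated from the
  maximum anatomical cross-sectional area via a muscle stress factor
  σ<sub>m</sub> = 37 N cm⁻²: F = σ<sub>m</sub> · CSA<sub>max</sub>, where
  CSA<sub>max</sub> is the mean area in two sectioning planes 2 mm apart,
  perpendicular to the mean fibre direction.  Age trajectories of force
  come from a monotone spline regression over a synthetic 51-individual
  cohort (ages 0–48 months), with bootstrap 95 % bands.
* **Materials.** Isotropic linear elasticity with age-dependent moduli:
  E<sub>bone</sub>(t) = 421 + 125·(t − 3) MPa (ν = 0.22) and
  E<sub>joint</sub>(t) = 30 + 100·(min(t, 12) − 3) MPa (ν = 0.30), t in
  months; suture patency itself closes on an age schedule.
* **Elastostatics.** Small-strain FEM on a labelled tetrahedral skull
  surrogate (4-node constant-strain elements, sparse Cholesky, mm–N–MPa),
  with muscle loads applied as origin-to-insertion force vectors and bite
  points plus temporomandibular joints (TMJ) fixed in all translations.
* **Temporal fascia.** The minimum fascia force that prevents inferior
  deflection of the zygomatic arch is solved in closed form from the
  model's linearity (one baseline and one unit-fascia solve) and reported
  relative to the masseter and temporalis forces.
* **Bite modes.** Bilateral first molars (mode 1), bilateral central
  incisors (mode 2), unilateral left molar (mode 3); outputs are bite
  forces (reactions at the bite constraints), per-side TMJ reactions, and
  von Mises strain/stress fields probed at nine facial locations.

## Worked example

```r
library(cranioload)

# synthetic cohort -> per-side muscle force growth curves
cohort <- generate_csa_cohort(cohort_params())
gm <- fit_growth(cohort)
gm
#> <growth_model> 3 muscles; per-side force at target ages (N):
#>            muscle force_N.3 force_N.6 force_N.12 force_N.24 force_N.36 force_N.48
#>        temporalis  32.00236  36.56819   41.80303   52.56072   67.03467   80.87134
#>          masseter  25.25875  28.64737   35.15460   47.34533   58.59163   69.57081
#>  medial_pterygoid  23.94489  25.93469   30.09957   38.99103   48.51914   58.22610

# calibrated 48-month surrogate and its stiffness operator
mesh <- build_skull_mesh(skull_params(48))
mesh
#> <skull_mesh> age 48 months: 22520 nodes, 67870 tetrahedra
#>   regions: skull_base (17580), facial (15408), parietal (13956), frontal (11564),
#>            occipital (7882), zygomatic_arch_L (740), zygomatic_arch_R (740)
#>   patent sutures: none
fm <- fem_assemble(mesh)

# balance the temporal fascia against the masseter pull on the arch
forces <- setNames(as.list(predict(gm, 48)$force_N), predict(gm, 48)$muscle)
tff <- solve_tff(fm, forces)
tff
#> <fascia_result> age 48 months: TFF = 29.50 N/side (42.4% of masseter,
#>   36.5% of temporalis), residual 5.73e-17 mm

# bilateral molar bite with the balanced fascia applied
bite <- run_bite(fm, forces, mode = 1, with_fascia = TRUE, tff = tff$tff_N)
bite
#> <bite_result> age 48, mode 1, fascia 29.5 N: bite 236.8 N (z 218.8 N),
#>   TMJ L 37.5 / R 37.5 N
```

Reading the numbers: the fitted curves put the per-side temporalis force
at ~81 N by 48 months; balancing the arch needs a fascia force of ~42 % of
the masseter force; and the bilateral molar bite produces a total
constraint reaction of ~237 N with symmetric TMJ loading.  Because the
fascia's temporal-line counter-force is deliberately omitted, applying the
fascia lowers the bite force relative to the fascia-free run.
`run_series()` sweeps ages × modes × fascia and adds derived columns
(incisor/molar force ratio, fascia reduction); `probe_fields()` (also on
every `bite$probes`) tabulates the nine facial probe values.

A thin CLI wraps the same functions:

```sh
inst/scripts/cranioload run --config my.yaml --out results/
```

## Scope

The surrogate reproduces mechanical organisation (lever geometry, load
paths, material contrast, suture schedule), not anatomical shape; absolute
bite forces and strain magnitudes of real crania are outside its scope.
See the methods vignette (`vignettes/cranioload-methods.Rmd`) for the
model's assumptions, calibration and limitations.
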