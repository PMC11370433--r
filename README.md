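# slicekin

Kinetic analysis of single-turnover RNA-induced silencing complex (RISC)
slicing assays, for biochemists measuring how fast an Argonaute2-guide
complex cleaves a target RNA and how mutations or target mismatches change
that rate.

In a single-turnover assay, trace radiolabeled target (0.05 nM) is incubated
with excess RISC (2, 5, 10 nM) and the fraction sliced is quantified over
time from gel band intensities. Under enzyme excess, target dissociation and
product release are kinetically invisible, so the progress curves are
governed by two elementary rate constants — association (*k*<sub>on</sub>)
and slicing (*k*<sub>slice</sub>) — plus a defective enzyme sub-population
(fraction 1 − *F*<sub>a</sub>) that binds normally but slices slowly
(*k*<sub>phase2</sub>), producing a second kinetic phase. `slicekin` fits
the mass-action scheme

    E  + S  --kon-->  ES   --kslice-->   E  + P
    E' + S  --kon-->  E'S  --kphase2-->  E' + P

to the full concentration series at once, seeding a constrained
L1-objective ODE fit from a pseudo-steady-state closed form

*F*<sub>sliced</sub>(t) = *F*<sub>a</sub>·(1 − e^(−t / (1/(*k*<sub>on</sub>·*E*<sub>all</sub>) + 1/*k*<sub>slice</sub>))) + (1 − *F*<sub>a</sub>)·(1 − e^(−*k*<sub>phase2</sub>·t)),

with bootstrap confidence intervals and the standard fallback constraints
(diffusion-limited *k*<sub>on</sub> = 0.1 /nM/s; *k*<sub>phase2</sub> = 0
when the second phase is unresolved; *F*<sub>a</sub> = 0.85 when the plateau
is unreached). It also quantifies active RISC stocks from titration data via
the ligand-depletion (quadratic) binding isotherm, estimates dissociation
rate constants from cold-chase filter-binding traces
(*F*<sub>bound</sub> = A·e^(−*k*<sub>off</sub>·t) + B), and reports fold
changes between conditions with intervals. A synthetic-data generator with
known ground truth makes every stage testable end to end.

## Worked example

```r
library(slicekin)

truth <- kinetic_params(kon = 0.02, kslice = 5e-3, kphase2 = 1e-5, Fa = 0.9)
ds <- generate_slicing_dataset(truth, noise = noise_model(sd = 0.02, seed = 7))
fit <- fit_slicing(ds, n_boot = 200, seed = 7)
fit
```

```
Slicing ODE fit (l1 loss): converged
  kon     = 0.01777  [0.01414, 0.03038]
  kslice  = 0.004955  [0.004505, 0.005366]
  kphase2 = 0 (fixed)
  Fa      = 0.9096  [0.8901, 0.9329]
  objective (total |dev|) = 0.5964 over 36 points
  fallbacks applied: kphase2 fixed at 0 (second phase unresolved) 
```

The generating values were *k*<sub>on</sub> = 0.02 /nM/s,
*k*<sub>slice</sub> = 5e-3 /s, *F*<sub>a</sub> = 0.9: the fit recovers
*k*<sub>slice</sub> within ~1% here and brackets all three with its 95%
intervals. The 1000-s design cannot see the slow second phase
(1/*k*<sub>phase2</sub> = 1e5 s), so the *k*<sub>phase2</sub> = 0 fallback
fires and is logged — the same behavior the fallback exists for on real
truncated datasets.

Comparing a mutant against wildtype:

```r
mut <- generate_slicing_dataset(kinetic_params(0.02, 1e-3, 1e-5, 0.9),
                                noise = noise_model(sd = 0.02, seed = 8))
fit_mut <- fit_slicing(mut, n_boot = 200, seed = 8)
fold_change(fit, fit_mut, "kslice", label_a = "WT", label_b = "mutant")
```

```
Fold change in kslice (WT / mutant): 4.494  [3.66, 5.855] at 95%
```

i.e. the mutant slices ~5-fold slower (true ratio: 5), with an asymmetric
interval from pairing bootstrap draws in log space.

Titration and dissociation stages work the same way:

```r
cv <- generate_titration(noise = noise_model(sd = 0.03, seed = 1))
fit_titration(cv, preset = "miR-200b", n_boot = 0)   # active stock 47,296 pM (truth 50,000)

tc <- generate_dissociation(noise = noise_model(sd = 0.02, seed = 1))
fit_dissociation(tc, n_boot = 0)                     # koff 1.001e-3 /s (truth 1e-3)
```

File-based workflows use `read_slicing_table()` / `read_titration_table()` /
`read_dissociation_table()` (plain TSV; nM, pM, seconds) and
`fit_to_json()` for machine-readable results.

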