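# mtdynamics

Quantitative analysis of microtubule dynamic instability, GAP-stimulated
GTPase kinetics, and chaperone complex stoichiometry — with a seeded
synthetic-data generator that stands in for the microscope and the plate
reader, so every analysis stage can be validated by round-trip parameter
recovery.

The package is aimed at cytoskeleton and tubulin-biogenesis labs that
measure astral microtubule (aMT) length-vs-time traces in live cells,
titrate GTP hydrolysis of the TBC-DEG tubulin chaperone (the
TBCD–TBCE–Arl2 heterotrimer) against its TBCC GAP by the malachite-green
assay, and weigh the resulting complexes by SEC-MALS.

## What it computes

**Dynamic instability.** A length trace $\ell(t)$ sampled every 4–5 s for
10 min is segmented into assembly, disassembly, pause and undetermined
phases (net change $\geq 0.5$ µm with $|r| \geq 0.85$ for events; $\geq 4$
flat samples for pauses). Catastrophes are transitions from assembly or
pause into disassembly; rescues from disassembly or pause into assembly.
Per microtubule,

$$f_{cat} = \frac{n_{cat}}{t_{assembly} + t_{pause}}, \qquad
  f_{res} = \frac{n_{res}}{t_{disassembly} + t_{pause}}$$

in min⁻¹, then mean ± SEM per condition and Welch t-tests between
conditions. Traces are simulated from a three-state continuous-time Markov
chain (growth $+v_g$, shrink $-v_s$, pause 0) whose hazards are solved from
targeted statistics and calibrated against the classifier itself (see the
methods vignette).

**GTPase kinetics.** Phosphate standard-curve calibration, absorbance to
rate conversion, and a Michaelis–Menten fit
$v = V_{max} S / (K_m + S)$, profiled so that $V_{max}$ is closed-form and
$K_m$ is a deterministic 1-D search; $k_{cat} = V_{max}/[E]$, with standard
errors, plus percent-change comparison of $k_{cat}$ across conditions.

**Complex masses.** Exact Dalton sums for integer subunit compositions
(e.g. TBCD + TBCE + Arl2 = 197,972.0 Da → 198 kDa) and brute-force
inference of stoichiometry from a measured mass with ranked candidates.

## Worked example

```r
library(mtdynamics)

## dynamics: calibrate the generator to the wild-type reference row,
## simulate 200 traces, classify and summarize
wt  <- mt_reference_targets("wild_type")
cal <- calibrate_generator(wt$targets, v_g = wt$v_g, v_s = wt$v_s,
                           n = 250, seed = 11)
dyn <- summarize_cohort(simulate_cohort(200, cal$params, seed = 12))
summarize_condition(dyn, "wild_type")
#> Condition 'wild_type': 200 microtubules from 100 cells
#>             statistic         value   n
#>           mean_length 0.786 ± 0.025 200
#>         assembly_rate 1.36 ± 0.0092 200
#>     assembly_duration     48 ± 0.79 200
#>      disassembly_rate  3.03 ± 0.023 200
#>  disassembly_duration    24.2 ± 0.4 200
#>      catastrophe_freq 0.826 ± 0.016 200
#>           rescue_freq  1.38 ± 0.033 200
#>        pause_duration   18.5 ± 0.33 197
```

The recovered statistics sit within a few percent of the generating
targets (assembly 1.4 µm/min, disassembly 3.06 µm/min, rescue 1.5 min⁻¹,
pause 18 s; catastrophe frequency, the hardest statistic to recover through
classification censoring, lands within ~10% of 0.90 min⁻¹). `n = 197` for
pause duration means three microtubules had no detectable pause and were
dropped from that statistic only.

```r
## kinetics: synthetic titration at the fully assembled chaperone-GAP-
## tubulin parameters, fitted back
tt <- gtpase_reference_truth("TBC-DEG:TBCC:tubulin", seed = 42)
fit_mm(simulate_titration(tt))
#> Michaelis-Menten fit (n = 10, E = 1 uM):
#>   Km   = 101.1 +/- 5.9 uM
#>   Vmax = 1.897 +/- 0.033 uM/min
#>   kcat = 1.897 +/- 0.033 min^-1

## masses: which stoichiometry explains a 310 +/- 10 kDa SEC-MALS peak?
units <- data.frame(name = c("core", "tubulin", "TBCC"),
                    mass_da = c(197972.0, 110000, 34045.4))
infer_stoichiometry(310, 10, units)
#>   core tubulin TBCC predicted_da predicted_kda residual_kda
#> 1    1       1    0       307972           308       -2.028
```

One chaperone core binding one αβ-tubulin dimer (308 kDa predicted) is the
only composition within 2 sd of the measurement.

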