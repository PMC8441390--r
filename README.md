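# optomotif

Tools for quantifying and modelling transcriptional adaptation to
optogenetically controlled Notch signalling in early *Drosophila* embryos.

During cellularisation, nuclear entry of the Notch intracellular domain
(NICD) can be placed under blue-light control, while nascent transcription of
the Notch target *sim* is read out live through MS2 stem-loops bound by
fluorescent MCP. The striking observation this package is built around is
*near-perfect adaptation*: target transcription rises within minutes of
activation and then collapses back towards baseline even though nuclear NICD
stays high. `optomotif` implements the full quantitative chain needed to ask
which regulatory architecture can produce that behaviour:

1. **Image quantification** — multi-scale Laplacian-of-Gaussian detection,
   counting and median-intensity quantification of nascent-transcription
   spots in maximum-projected stacks (`quantify_spots()`), and nuclear
   segmentation (Gaussian smoothing + Otsu) with background subtraction,
   photobleaching correction and the nuclear/total reporter ratio
   (`quantify_nuclei()`, `fit_bleaching()`).
2. **Nucleocytoplasmic transport model** — a linear four-species ODE system
   for fluorescent (F) and photobleached (B) reporter in cytoplasm (C) and
   nucleus (N):

   ```
   dCF/dt = ke·NF − ki·CF − b·CF      dNF/dt = ki·CF − ke·NF − b·NF
   dCB/dt = ke·NB − ki·CB + b·CF      dNB/dt = ki·CB − ke·NB + b·NF
   ```

   integrated in closed form per light/dark segment of an activation
   protocol (`simulate_import_export()`), fitted to nuclear/total ratio data
   (`fit_import_export()`), and used to build the nuclear-input profile
   N(t) = NF + NB that drives transcription (`build_input_profile()`).
3. **Adaptation motifs** — negative feedback, incoherent feedforward and
   state-dependent inactivation, each in elementary mass-action and
   Hill-exponent form (`simulate_motif()`, equations in
   `?motif_rhs`), with the in-silico perturbations that discriminate among
   them: inhibitor knock-out (k4 = 0), attenuator knock-out (k1 → 10·k1) and
   stabilisation of the active state (k2 → 0.1·k2)
   (`apply_perturbation()`).
4. **Fitting** — bounded global optimisation of motif parameters against
   expression time series under the fixed rescaling convention (data × 1/300,
   model output × 100, MSE loss; rates in [1e-4, 100] optimised in log space,
   Hill exponents in [0.25, 4]) via `fit_motif()`, plus seeded
   parameter/trace recovery studies (`recovery_study()`).
5. **Synthetic data** — generators with full ground-truth annotation for
   spot frames, two-channel translocation time-lapses and per-nucleus
   expression cohorts (`render_spot_frames()`, `render_nuclear_timelapse()`,
   `simulate_expression_cohort()`), so every stage is testable end to end
   without any external data.

## Worked example

The demonstration pipeline simulates a ground-truth expression cohort from
the published state-dependent-inactivation parameters under continuous
activation, refits the motif to the pooled intensity, and simulates
perturbations:

```r
library(optomotif)
res <- run_pipeline(demo_config(seed = 1), out_dir = "demo_out")
res$fit
#> Motif fit: state_dependent_inactivation ( elementary )
#>       k1       k2       k3       k4
#> 0.110900 0.083940 0.023820 0.001132
#>   rescaled MSE: 0.006626  (3339 loss evaluations, seed 1)
res$perturbations
#>       perturbation      peak      final adaptation_index
#> 1             none 0.3340428 0.15491807        0.5362329
#> 2    attenuator_ko 0.7031061 0.06591352        0.9062538
#> 3 stabilize_active 0.6502919 0.63917230        0.0170994
res$activation_rate
#> [1] 42
```

The fitted output trace reproduces the generating cohort (rescaled MSE
0.0066 on noisy data); the `adaptation_index` column is 1 − final/peak, so
the hallmark of state-dependent inactivation is visible directly: knocking
out the attenuator *increases* adaptation (0.91 vs 0.54) instead of
abolishing it, while stabilising the active state converts the transient
into a sustained plateau (index 0.02). The activation rate is the maximal
slope of the expressing-nuclei count in the first 7 minutes (nuclei/min).
All outputs are written to `demo_out/` as CSV/JSON with a provenance line
(config hash + seed); reruns with the same config are byte-identical.

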