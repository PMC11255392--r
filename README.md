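# lumicell

Population calcium-imaging analysis of luminance coding in the larval
zebrafish cerebellum.

The cerebellum receives two input streams: granule cells (GCs), whose
parallel fibers are thought to carry contextual signals, and inferior
olive neurons (IONs), whose climbing fibers are thought to carry
error-like signals, both converging on Purkinje cells (PCs). When larval
zebrafish view whole-field luminance steps and flashes, GCs respond
mostly with sustained, luminance-graded activity — some ramping over many
seconds — while IONs respond mostly with transients at luminance
changes. `lumicell` implements the full analysis chain with which such
recordings are quantified, together with seeded synthetic-data generators
that plant known ground truth at every stage, so each step's recovery
performance is measurable.

The pipeline:

* **Stimuli** — piecewise-constant luminance protocols ("steps": 5 s at
  5/20/100% of maximal luminance with 7 s dark intervals, covering all 12
  ordered level transitions; "flashes": 3/7/21 s at full brightness), a
  calcium-indicator kernel model, and a regressor bank (gamma-corrected
  luminance profiles and ON/OFF transition trains, kernel-convolved).
* **Imaging** — plane-wise rigid motion correction with 10 µm artifact
  rejection, eight-neighbour correlation maps, seeded ROI growing, ROI
  merging across planes, trace extraction.
* **Responses** — trial-to-trial reliability (mean pairwise Pearson r
  across repetitions) with Otsu gating, Ward clustering of mean
  responses, best-regressor classification (luminance vs transition
  group), and cross-validated center-of-mass (COM) response timing.
* **Decoding** — ridge regression for time since stimulus onset, RBF
  support-vector regression for instantaneous luminance, with the
  10-train/2-test trial scheme and population subsampling.
* **PC model** — each PC trace as
  `offset + Σ GCcoeff·GCregressor + Σ IONcoeff·IONregressor` with offset
  in [-5, 5] and nonnegative coefficients in [0, 1000], L1-regularized
  (leave-one-out lambda cross-validation over 1e-7…1e-2, shared
  geometric-mean lambda), kernel matching between indicators, a
  regressor-wise shuffle null on test cost, and the GC/ION contribution
  index `(ΣGC − ΣION)/(ΣGC + ΣION)`.
* **Behavior** — swim-bout detection from velocity traces, stimulus-
  aligned bout histograms, and a bootstrap test for bout suppression in
  the 1.5 s after luminance-OFF transitions.

## Worked example

Generate a synthetic GC/ION population under the steps protocol, gate it
by reliability, and classify cells by their best regressor:

```r
library(lumicell)

stim   <- sample_protocol(build_steps_protocol(n_repetitions = 1), 0.5)
recipe <- default_population_recipe()
pop    <- gen_population(c(recipe$gc, recipe$ion), stim, n_cells = 400,
                         n_trials = 6, responsive_fraction = 0.5,
                         noise_sd = 0.3, seed = 103)

gate <- gate_responsive(pop$tensor)
cat(sprintf("threshold %.3f; %.1f%% responsive; accuracy %.1f%%\n",
            gate$threshold, 100 * mean(gate$responsive),
            100 * mean(gate$responsive == pop$truth$responsive)))
#> threshold 0.181; 50.0% responsive; accuracy 100.0%

bank <- build_regressor_bank(stim)
grp  <- classify_by_best_regressor(
  regressor_correlations(trial_average(pop$tensor), bank))
```

The reliability histogram of this population is bimodal; Otsu's method
puts the cut at 0.181, and every cell lands on the side its planted label
says it should (50% of cells carry a response template, 50% are noise).
The decoding contrast on the flashes protocol
(`analysis/04_decoding.R`) prints:

```
time decoding R2: 0.88 (ramping population) vs 0.19 (transient population)
luminance decoding (SVR) R2: 0.96
```

— a ramping population supports decoding of elapsed time where an
equally sized transient population does not, and a sustained, graded
population supports decoding of the displayed luminance level.

The numbered scripts under `analysis/` run the whole chain on synthetic
data and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_stimuli_and_regressors.R` | protocols, sampling, regressor bank |
| `02_segment_movie.R` | planted-movie motion correction + segmentation |
| `03_responses.R` | reliability gating, clustering, COM sorting |
| `04_decoding.R` | time/luminance decoding contrasts |
| `05_pc_model.R` | constrained PC fits, shuffle null, GC/ION index |
| `06_behavior.R` | bout detection and the OFF-suppression bootstrap |

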