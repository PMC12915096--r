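# probekit

Desk-scale discovery of small-molecule fluorescent probe candidates from
tabular SMILES libraries.

Target-specific fluorescent probes are usually found by iterating
synthesis and spectroscopy over a handful of scaffolds. A faster route is
to screen libraries of molecules that already have validated target
affinity and ask which of them happen to be usable fluorophores. probekit
implements the computational side of that strategy as a tested R package:

- **Curation** of heterogeneous photophysical tables: SMILES
  canonicalization, activity-score labeling (0–100 scale, threshold 20),
  duplicate merging, removal of conflicting annotations, physical range
  filters (quantum yield ≤ 1, wavelengths within 200–1500 nm, log10 ε ≤ 7),
  and replicate consolidation by a median ± tolerance rule (5 nm for
  wavelengths, 0.1 for quantum yield, 0.02 for log10 ε), with full audit
  accounting and 7:1:2 train/validation/test splits.
- **A conditioned directed message-passing neural network** (bond-centric
  D-MPNN, depth 3, hidden size 300): hidden states on directed edges,
  each edge aggregating its source atom's incoming edge states (reverse
  edge excluded),

  `h⁰_e = τ(W_in [x_src(e); f_e])`,
  `h^t_e = τ(W_h [h^{t−1}_e; Σ_{e′→src(e), e′≠rev(e)} h^{t−1}_{e′}])`,

  followed by atom readout and mean pooling. A fluorescence-activity
  classifier is conditioned on an absorption/emission wavelength pair
  (300–900 / 400–1200 nm, scaled to [0,1]²); seven property regressors
  (λ_abs, λ_em, both FWHMs, log10 ε, PLQY, lifetime) are conditioned on
  the solvent structure through a second message-passing branch. Training
  is Adam with BCE/MSE losses; a compiled single-precision core keeps
  desk-scale training in minutes on one CPU.
- **Two-step screening**: retrieval of experimentally known activity for
  cached (structure, condition) pairs, model prediction for the rest,
  threshold exclusion, then property prediction for survivors only —
  with deterministic, reproducibly sorted output.
- **Chemical-space analysis**: Bemis–Murcko scaffolds, ECFP4 fingerprints
  (radius 2, 2048 bits), exact t-SNE (perplexity 30, seed 42), and
  top-20 scaffold frequency tables.
- **Assay mathematics**: the Förster–Hoffmann viscosity fit
  (log I = C + x·log η), one-site and Hill saturation-binding fits for
  dissociation constants, inhibition-rate percentages, and bootstrap CIs.
- **A synthetic fluorophore generator** with planted, documented
  structure–property rules (donor–π–acceptor templates, solvatochromic
  shifts, noise and deliberate inconsistencies) so the entire pipeline is
  testable offline.

## Worked example

Fit a dissociation constant from a saturation titration (the probe
concentration grid runs 0–1000 nM), then screen a small synthetic
library:

```r
library(probekit)

# --- binding assay: planted Kd of 54.8 nM with 2% intensity noise
series <- generate_assay_curves("kd", list(F0 = 10, Bmax = 100, Kd = 54.8),
                                noise_sd = 2, seed = 7)
fit <- fit_saturation_kd(series)
tidy(fit)
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 F0        9.67
#> 2 Bmax    104.
#> 3 Kd       57.5
```

The fitted `Kd` of 57.5 nM recovers the planted 54.8 nM within the ~10%
accuracy expected at this noise level; `F0` and `Bmax` are the baseline
and amplitude in intensity units.

```r
# --- train a small activity classifier on synthetic fluorophores
lib <- generate_library(generator_spec(n = 800, seed = 1))
cf  <- classification_frame(lib)
l1  <- train_model(
  cf[1:700, ], cf[701:800, ],
  cfg = encoder_config("classification", hidden = 128, ffn_hidden = 128,
                       epochs = 15, init_lr = 1e-3, seed = 1)
)
glance(l1)
#> # A tibble: 1 × 7
#>   task           target_property epochs best_epoch best_val_metric final_train_loss n_train
#>   <chr>          <chr>            <int>      <int>           <dbl>            <dbl>   <int>
#> 1 classification NA                  15         14           0.994            0.191     700

# --- screen structures the model has never seen, 370/420 nm window
unseen <- setdiff(unique(cf$smiles[701:800]), cf$smiles[1:700])
hits <- two_step_screen(tibble::tibble(smiles = unseen), l1, list(),
                        wavelength_pair = c(370, 420), threshold = 0.5)
head(hits[, c("smiles", "provenance", "activity_score", "passed_l1")], 3)
#> # A tibble: 3 × 4
#>   smiles        provenance activity_score passed_l1
#>   <chr>         <chr>               <dbl> <lgl>
#> 1 CC=CC(=CC=O)C predicted           1.000 TRUE
#> 2 CC=CC(=CC#N)C predicted           1.000 TRUE
#> 3 COC=CC=CC#N   predicted           1.000 TRUE
```

A validation AUC of 0.994 after fifteen epochs means the classifier has
essentially recovered the generator's planted activity window. Screening
the 17 held-out structures passes 12 on to property prediction;
`provenance` records whether a score was retrieved from cached
experimental data (training structures under the same condition are never
re-predicted) or predicted by the model.

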