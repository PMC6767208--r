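# floorgait

Staff-versus-elderly activity recognition from piezoelectric floor sensors.

## The problem

Nursing homes increasingly monitor residents' physical activity because low
activity is an early marker of frailty. Piezoelectric floor sensors are an
unobtrusive way to do this — thin polymer bands under the flooring emit a
charge proportional to the applied pressure — but most of what such a floor
records is produced by the medical staff, not by the residents. Any
floor-based activity monitor therefore needs to decide, per recorded event,
whether the people on the floor are staff or elderly.

`floorgait` implements a staged learning pipeline for this decision on
multichannel 100 Hz floor recordings, together with a synthetic floor-signal
generator so that every stage can be trained and tested without access to
clinical recordings:

1. **Preprocessing** — each channel is low-pass filtered with a zero-lag
   Butterworth response (10 Hz cutoff, order 5), linearly detrended by least
   squares, quiet channels are zeroed, and the channels are summed into a
   mono signal `s`.
2. **Step dictionary** — m = 3 unit-norm atoms `d_m` of 0.7 s are learned
   from staff walks by convolutional basis pursuit denoising,

   `min_{x,d} Σ_signals [ ½‖Σ_m x_m ∗ d_m − s‖₂² + λ Σ_m ‖x_m‖₁ ]`, λ = 5,

   solved by interleaved consensus-ADMM steps in the frequency domain. The
   network input is the (non-sparse) embedding `S_d = (s ∗ d_m)_{m=1..3}`.
3. **Step-proposal network (SPN)** — a fully convolutional 1D network
   (conv 32×60 stride 10 + BatchNorm + tanh, then 1×1 convolutions to 16, 8
   and 3 sigmoid outputs) scores anchor boxes of 20/30/40 samples at every
   grid position for the probability of containing a footstep. Anchors with
   IoU > 0.7 against a labelled step box are positives, < 0.3 negatives,
   the rest neutral; the loss is the negated sum of anchor log-likelihoods.
4. **Activity classifier** — the SPN's three blocks are transferred and
   frozen; a conv(8→1, kernel 5) + ReLU, maxpool 5 and dense 18→64→16→1
   head is trained with binary cross-entropy to output `P(staff)`. A signal
   is classified staff when the score is ≥ τ.
5. **Evaluation** — ROC/AUC (Mann–Whitney concordance) with stratified
   bootstrap intervals, confusion tables at thresholds, average precision
   for step detection, and an ablation harness (`full`, `no_spn_pretrain`,
   `raw_cnn`, `rf_baseline`).

## Worked example

```r
library(floorgait)

# a 93-recording synthetic dataset mirroring the field composition
ds <- generate_dataset(synthetic_config(seed = 101))
split <- stratified_split(ds, test_fraction = 0.3, seed = 12)

# fit the staged pipeline on the training set
pipe <- fit_pipeline(split$train, pipeline_config(seed = 1))

# score the held-out recordings and evaluate
scores <- predict_pipeline(pipe, split$test)
status <- vapply(split$test$recordings,
                 function(r) r$annotation$person_status, "")
event  <- vapply(split$test$recordings,
                 function(r) r$annotation$event_class, "")
activity <- ifelse(event == "walk_single", "single",
                   ifelse(event == "walk_multi", "multi", "other"))
evaluate_scores(scores, status, activity, taus = c(0.2, 0.4), seed = 1)
```

```
<eval_report> n=28  AUC=0.968 (95% CI 0.872-1.000)
  single walks AUC=1.000
  multi walks AUC=1.000
  other walks AUC=1.000
```

The report's AUC is the probability that a randomly chosen staff recording
scores above a randomly chosen elderly one; the per-activity lines restrict
that comparison to single walks, multi-person walks and non-walk events (the
global value can sit below them because scores are also ranked across
activity types). The confusion tables in the returned object count
classified-staff / classified-elderly per true (status × activity) cell at
each threshold τ; when the pipeline errs it is typically on pushed
wheelchairs, whose signal contains genuine staff steps but carries an
elderly label.

The step detector can be inspected on its own:

```r
monos <- lapply(split$train$recordings[1:30], preprocess_recording)
fit <- learn_dictionary(monos, m = 3, atom_sec = 0.7, lam = 5,
                        iters = 150, seed = 1)
emb <- lapply(monos, embed_signal, dict = fit$dictionary)
W <- spn_forward(emb[[1]], pipe$spn)     # anchor scores, T_f x 3
decode_boxes(W, anchor_grid(ncol(emb[[1]]$channels)))
```

A thin command-line front end (`inst/scripts/floorgait.R`) exposes
`simulate`, `preprocess`, `learn-dict`, `train` and `evaluate` subcommands
over these functions.

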