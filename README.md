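# ttsdecode

Temporal attention-aware timestep selection for RNN-based neural decoders.

## The problem

Intracortical brain–computer interfaces decode movement from binned
population firing rates (here 64 ms bins, a `time bins × units` matrix per
session). Recurrent decoders — vanilla RNN, LSTM or GRU — predict the
current 2-D hand velocity from the window of the `T` most recent bins. The
window length `T` matters: short windows miss preparatory activity that
precedes execution, long windows add stochastic noise and per-prediction
cost, and the usual remedy is an expensive grid search over `T` with one
full training per candidate.

`ttsdecode` implements a one-pass alternative for scientists building or
calibrating such decoders:

1. **Train once, long.** A decoder is trained at a generous `T` together
   with a *temporal attention module* scoring every timestep:
   `u_τ = ReLU(W h_τ + b)`, `a_τ = softmax_τ(u_τᵀ v)`, prediction
   `ŷ = dᵀ Σ_τ a_τ h_τ`.
2. **Select.** The attention vectors are averaged over all training
   observations (`ā_τ = (1/N) Σ_t a_τᵗ`) and the essential length `T*` is
   the smallest recent window holding at least 95% (configurable) of the
   cumulative attention mass:
   `a*(k) = 100 · Σ_{τ=T−k+1}^T ā_τ / Σ_τ ā_τ ≥ threshold`.
3. **Retrain compact.** A fresh decoder without the attention module,
   predicting from the final hidden state (`ŷ = dᵀ h_T`), is retrained on
   windows of length `T*`.

The recurrent cells (with layer normalization), the attention module, and
the Adam-based training loop are implemented in the package in batched
matrix form with analytic gradients (verified against finite differences in
the test suite). A fully seeded synthetic-session generator with a known
encoding lag `L` makes the whole pipeline testable end to end: sessions
where the "true" essential timestep count is known by construction.

## Worked example

```r
library(ttsdecode)

# a synthetic session: 32 units, 3000 bins, velocity drives rates over the
# last 4 bins (the ground-truth essential window)
sess <- make_session(synthetic_config(n_bins = 3000, n_units = 32,
                                      lag_window = 4, seed = 101))

cfg <- recovery_config(seed = 1)      # scaled-down unidirectional LSTM
report <- run_tts(sess, T_len = 12, config = cfg,
                  split = split_spec(train_end = 2500), threshold = 95)
report
#> <tts_report> T=12 -> T*=3 (threshold 95%)
#>   full-T decoder:      test R2 = 0.812, CC = 0.906
#>   retrained T* decoder: test R2 = 0.886, CC = 0.943

round(report$selection$cumulative_pct, 1)
#>  [1]  69.5  91.6  98.1  99.5  99.7  99.8  99.8  99.8  99.9  99.9  99.9 100.0
```

Reading the output: from a 12-bin window the attention mass concentrates on
the most recent bins (69.5% on the last bin alone, 98.1% on the last
three, crossing the 95% threshold at `T* = 3`), and the compact 3-bin
decoder retrained without the attention module decodes the held-out suffix
of the session *better* than the full 12-bin decoder — the long window's
extra bins carry no information about the current velocity in this
session, only noise, at four times the per-prediction recurrence cost.
`report$attention` holds the per-observation attention matrix
(`plot_attention()` renders the heatmap with the most-highlighted-timestep
trace).

Decoding quality uses `R² = 1 − Var(y − ŷ)/Var(y)` and Pearson's `CC`
(`metric_report()`), and `compare_groups()` provides the
Shapiro–Wilk/Friedman/Wilcoxon workflow for comparing decoder conditions.

A command-line front end is installed with the package
(`exec/ttsdecode`): subcommands `run` (YAML config → artifacts + manifest),
`simulate`, `tts`, `evaluate`, `viz`.

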