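# molcrnn

Conditional recurrent generative modeling of molecules for
target-focused virtual library design, in R.

`molcrnn` is for computational and medicinal chemists who want to
generate candidate molecules around a small set of known actives — for
example, the published inhibitors of a kinase — and push them through a
reproducible standardization, diversity-analysis and drug-likeness
screening pipeline. It implements a *distribution-learning* conditional
RNN (cRNN): no scoring function is optimized; the model learns to
reproduce the chemical distribution of its training corpus and new
molecules are sampled from the learned latent neighborhood of the
actives.

## The model

Molecules are SMILES token sequences in one-hot representation. A
one-layer bidirectional LSTM feature extractor (2 × 512 units by
default) reads a molecule and is projected to the initial hidden state
*h*₀ of a one-layer LSTM generator (256 units) with a dense softmax
head. With input vectors *x*₁:ₙ the recurrence is *hᵢ = R(hᵢ₋₁, xᵢ)*,
*oᵢ = O(hᵢ)*, trained teacher-forced with cross-entropy

    L = (1/n) Σ_batch Σ_i ( − Σ_j y_ij log p_ij ),
    p_ij = exp(o_ij) / Σ_k exp(o_ik)

(summed over positions, averaged over the batch, padding masked),
updated with Adam (learning rate 1e-4) until convergence. Three
enhancements support working from few actives:

* **transfer learning** — pretrain on a large general corpus, fine-tune
  all parameters on the target actives;
* **regularization enhancement** — add zero-mean Gaussian noise to *h*₀
  during training (`h₀ + ξ`, `ξ ~ N(0, σ²)`);
* **sampling enhancement** — build new conditioning vectors by linear
  interpolation `(1−α)h₀ⁱ + αh₀ʲ` (default), spherical interpolation
  `sin[(1−β)θ]/sinθ·h₀ⁱ + sin(βθ)/sinθ·h₀ʲ`, or single-point Gaussian
  perturbation.

Around the model: Open-Babel-backed SMILES standardization (stereo,
salts, duplicates), ten drug-likeness descriptors (MW, logP, QED, SA,
BertzCT, TPSA, ESOL logS, rotatable bonds, HBD, HBA), Murcko scaffold
extraction (plain and generic), reconstruction/generation rates (R%,
G%), relative scaffold diversity with cumulative frequency curves,
scaffold-novelty comparison, and a screening funnel (scaffold /
substructure novelty against the known actives, then inclusive property
bounds 200 ≤ MW ≤ 700, −2 ≤ LogP ≤ 6, QED ≥ 0.15, SA ≤ 5) with exact
per-stage accounting. A fragment-grammar corpus generator makes every
part testable offline. See `vignettes/conditional-rnn-library-design.Rmd`
for the methods account.

## Worked example

```r
library(molcrnn)

pair <- make_pair_corpora(seed = 1, n_source = 30, n_target = 14)
cfg <- train_config(encoder_dim = 16, decoder_dim = 40,
                    learning_rate = 0.01, batch_size = 30,
                    max_epochs = 250, seed = 8, tol = 0, patience = 999)
pre  <- train_crnn(pair$source, cfg)          # pretraining
ft   <- cfg; ft$max_epochs <- 120L
ckpt <- finetune_crnn(pre, pair$target, ft)   # transfer learning

reconstruction_rate(ckpt, pair$target)
#> [1] 57.14286

gset <- build_library(ckpt, pair$target,
                      sampling_config(n_samples = 400, seed = 12,
                                      max_len = 70),
                      training_corpora = list(pair$source, pair$target))
gset
#> Generated library: 76 molecules from 400 attempts
#>   removed: invalid 144 | internal duplicates 159 | training duplicates 13 | structural alerts 8

scaffold_diversity(gset$molecules$smiles, generic = TRUE)
#> Scaffold diversity (generic Murcko): 22 distinct / 76 molecules = 28.9%

run_funnel(gset$molecules$smiles, pair$target)
#> Screening funnel
#>     stage n_in n_out n_removed
#>   novelty   76    38        38
#>  druglike   38    20        18
```

Reading the numbers: at this reduced training budget the fine-tuned
model reproduces 57% of its 14 target molecules exactly under greedy
decoding; of 400 stochastic sampling attempts, 76 distinct, valid, new,
alert-free molecules survive post-processing (every attempt is counted
in exactly one bucket); their generic-scaffold diversity (28.9%)
exceeds the target family's by construction of the interpolation
sampling; and the funnel removes scaffold repeats of the actives first,
then property outliers.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "molcrnn", package = "molcrnn")` with
subcommands `standardize`, `fixtures`, `train`, `finetune`, `sample`,
`evaluate`, `screen` and `diversity`, all seeded via `--seed`.

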