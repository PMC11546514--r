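# ddipair

Binary drug–drug interaction (DDI) prediction from pairs of SMILES
strings, for computational chemists and method developers who want a
fully self-contained, inspectable implementation of a sequence-based
pair classifier: no pretrained downloads, no GPU, every metric computed
from first principles.

## The model

A pair `(SMILES_A, SMILES_B)` is mapped to an interaction probability:

1. **Tokenizer** — atom-level segmentation (bracket atoms and `Cl`/`Br`
   kept whole) followed by byte-pair encoding: the most frequent
   adjacent symbol pair is merged greedily, ties broken
   lexicographically, pairs occurring once never merged. Sequences are
   wrapped in BOS/EOS and padded to a fixed length.
2. **BiLSTM encoder** — per direction and step `t`:

       f_t = σ(W_f [x_t, h_{t−1}] + b_f)      (forget gate)
       i_t = σ(W_i [x_t, h_{t−1}] + b_i)      (input gate)
       o_t = σ(W_o [x_t, h_{t−1}] + b_o)      (output gate)
       c̃_t = tanh(W_c [x_t, h_{t−1}] + b_c)   (candidate)
       c_t = f_t ⊙ c_{t−1} + i_t ⊙ c̃_t
       h_t = o_t ⊙ tanh(c_t)

   run over real tokens only; the final forward and backward states are
   concatenated.
3. **MLP** — `O = W_o ReLU(W_h h + b_h) + b_o` per drug.
4. **Predictor** — the two drug features are concatenated and passed
   through one affine map and a sigmoid: `p = σ(w·[O_A, O_B] + b)`.

Two branch topologies are supported: **parameter-sharing** (one branch
encodes both drugs) and **parameter-independent** (a branch per drug,
exactly twice the encoder parameters). Training is AdamW on binary
cross-entropy with a step learning-rate schedule, best-validation-AUC
checkpointing, and bit-reproducible seeding. Evaluation (confusion
analytics, precision/recall/F1, ROC-AUC via the trapezoid =
Mann–Whitney concordance, PR-AUC, Tanimoto similarity) is implemented
from scratch and cross-checked against independent oracles in the test
suite. A synthetic-data module plants a known substructure interaction
rule in balanced SMILES pairs so the whole pipeline is testable at desk
scale; see the methods vignette (`vignettes/ddipair-methods.Rmd`) for
the model, the design decisions and the generator's limits.

## Worked example

```r
library(ddipair)

dir <- tempfile()
cmd_simulate(file.path(dir, "sim"), n_pairs = 2000, seed = 1)   # balanced pairs, 5% label noise
fit <- cmd_train(file.path(dir, "sim", "pairs.csv"), file.path(dir, "run"),
                 mode = "sharing", seed = 1, epochs = 15, batch_size = 32,
                 learning_rate = 1e-3, embed_dim = 32, lstm_hidden = 16,
                 mlp_hidden = 16, mlp_out = 4, max_len = 128, n_merges = 60)
report <- cmd_evaluate(fit$checkpoint, file.path(dir, "sim", "pairs.csv"),
                       file.path(dir, "eval"), split = "test", seed = 1)
print(report)
#> <ddi_eval> n=400 threshold=0.5
#>   TP=186 FP=13 TN=192 FN=9
#>   precision=0.935 recall=0.954 F1=0.944
#>   AUC-ROC=0.931 PR-AUC=0.873
```

The test split has 400 pairs; with 5% of labels flipped at generation,
an AUC-ROC around 0.93 means the planted rule was essentially
recovered (the noise itself caps the measurable AUC near 0.95).
Prediction on unlabeled pairs writes probabilities to three decimals
and interaction calls at the strict 0.5 threshold:

```r
cmd_predict(fit$checkpoint, "unknown_pairs.csv", "predictions.csv")
```

A command-line front end wrapping these functions is installed at
`inst/cli/ddipair.R`:

```sh
Rscript inst/cli/ddipair.R simulate --out sim --n-pairs 2000 --seed 1
Rscript inst/cli/ddipair.R train --data sim/pairs.csv --out run --mode sharing --seed 1
```

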