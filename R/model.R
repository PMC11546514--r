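# Pair-classification network: embedding -> BiLSTM -> MLP per drug,
# concatenation, affine + sigmoid predictor. Two modes: "sharing" (both
# drugs encoded by one branch) and "independent" (a branch per drug).
#
# The functions here are the readable reference implementations; training
# and batched prediction go through the C++ fast path (src/ddi_net.cpp),
# which the tests hold to these references.

#' Model configuration
#'
#' Dimensions follow the published configuration: 512-unit token
#' embeddings, 128 hidden units per LSTM direction (so the concatenated
#' bidirectional state has 256 units), a 128-unit MLP hidden layer, 4 MLP
#' output units per drug (8 predictor inputs), and maximum sequence length
#' 512.
#'
#' @param vocab_size Number of tokens in the vocabulary.
#' @param embed_dim Token embedding dimension.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param mlp_hidden MLP hidden-layer units.
#' @param mlp_out MLP output units per drug.
#' @param mode `"sharing"` (one branch for both drugs) or `"independent"`.
#' @param max_len Token-sequence length fed to the encoder.
#' @return A `ddi_model_config` list.
#' @export
model_config <- function(vocab_size, embed_dim = 512L, lstm_hidden = 128L,
                         mlp_hidden = 128L, mlp_out = 4L,
                         mode = c("sharing", "independent"), max_len = 512L) {
  mode <- match.arg(mode)
  cfg <- list(vocab_size = as.integer(vocab_size),
              embed_dim = as.integer(embed_dim),
              lstm_hidden = as.integer(lstm_hidden),
              mlp_hidden = as.integer(mlp_hidden),
              mlp_out = as.integer(mlp_out),
              mode = mode,
              max_len = as.integer(max_len))
  bad <- vapply(cfg[c("vocab_size", "embed_dim", "lstm_hidden", "mlp_hidden",
                      "mlp_out", "max_len")],
                function(x) !is.finite(x) || x < 1L, logical(1L))
  if (any(bad)) {
    stop("all model dimensions must be positive integers", call. = FALSE)
  }
  structure(cfg, class = "ddi_model_config")
}

runif_mat <- function(nrow, ncol, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

init_lstm_params <- function(embed_dim, hidden) {
  fan_in <- embed_dim + hidden
  gates <- c("f", "i", "o", "c")
  p <- c(
    stats::setNames(lapply(gates, function(g) runif_mat(hidden, fan_in, fan_in)),
                    paste0("w_", gates)),
    stats::setNames(lapply(gates, function(g) numeric(hidden)),
                    paste0("b_", gates)))
  p
}

init_branch <- function(config) {
  list(
    emb = runif_mat(config$vocab_size, config$embed_dim, config$embed_dim),
    fwd = init_lstm_params(config$embed_dim, config$lstm_hidden),
    bwd = init_lstm_params(config$embed_dim, config$lstm_hidden),
    mlp = list(
      W_h = runif_mat(config$mlp_hidden, 2L * config$lstm_hidden,
                      2L * config$lstm_hidden),
      b_h = numeric(config$mlp_hidden),
      W_o = runif_mat(config$mlp_out, config$mlp_hidden, config$mlp_hidden),
      b_o = numeric(config$mlp_out)))
}

#' Initialize model parameters
#'
#' Weights are drawn uniformly in +/- 1/sqrt(fan_in) per matrix; biases
#' start at zero. In sharing mode one branch is stored and used for both
#' drugs; in independent mode each drug gets its own branch (drawn
#' separately).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `ddi_model`: list with `config`, `branch_a`, `branch_b`
#'   (`NULL` in sharing mode), and `predictor` (`w`, `b`).
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ddi_model_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  model <- list(
    config = config,
    branch_a = init_branch(config),
    branch_b = if (config$mode == "independent") init_branch(config),
    predictor = list(
      w = stats::runif(2L * config$mlp_out,
                       -1 / sqrt(2 * config$mlp_out),
                       1 / sqrt(2 * config$mlp_out)),
      b = 0))
  structure(model, class = "ddi_model")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Branch used for drug B: branch_a itself in sharing mode.
branch_b_of <- function(model) {
  if (is.null(model$branch_b)) model$branch_a else model$branch_b
}

#' @export
print.ddi_model <- function(x, ...) {
  n <- count_parameters(x$config)
  cat(sprintf("<ddi_model> mode=%s vocab=%d embed=%d hidden=%d/dir | %d parameters\n",
              x$config$mode, x$config$vocab_size, x$config$embed_dim,
              x$config$lstm_hidden, n$total))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Computes the gated recurrence on the concatenated input
#' `[x_t, h_{t-1}]`: sigmoid forget/input/output gates, tanh cell
#' candidate, `c_t = f * c_{t-1} + i * c_tilde`, `h_t = o * tanh(c_t)`
#' (elementwise products).
#'
#' @param x Embedded input vector (length `embed_dim`).
#' @param state List with `h` and `c` vectors (length `hidden`).
#' @param params LSTM parameter list: gate weights `w_f`, `w_i`, `w_o`,
#'   `w_c` of shape `hidden x (embed_dim + hidden)` and biases `b_f`,
#'   `b_i`, `b_o`, `b_c`.
#' @return List with the new `h` and `c`.
#' @export
lstm_cell_step <- function(x, state, params) {
  z <- c(x, state$h)
  if (ncol(params$w_f) != length(z)) {
    stop(sprintf("LSTM input size mismatch: weights expect %d, got %d",
                 ncol(params$w_f), length(z)), call. = FALSE)
  }
  f <- sigmoid(drop(params$w_f %*% z) + params$b_f)
  i <- sigmoid(drop(params$w_i %*% z) + params$b_i)
  o <- sigmoid(drop(params$w_o %*% z) + params$b_o)
  c_tilde <- tanh(drop(params$w_c %*% z) + params$b_c)
  c_new <- f * state$c + i * c_tilde
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new)
}

run_lstm <- function(X, params, hidden) {
  state <- list(h = numeric(hidden), c = numeric(hidden))
  for (t in seq_len(ncol(X))) {
    state <- lstm_cell_step(X[, t], state, params)
  }
  state$h
}

#' Encode one token sequence with a bidirectional LSTM
#'
#' Embeds the real (mask == 1) tokens, runs a forward LSTM left-to-right
#' and a backward LSTM right-to-left over those positions only, and
#' concatenates the two final hidden states. Padding never enters either
#' recurrence, so appending `<pad>` leaves the output unchanged.
#'
#' @param seq A `token_seq` from [encode()].
#' @param embedding Embedding matrix (`vocab_size x embed_dim`), row
#'   `id + 1` holds token `id`.
#' @param fwd,bwd LSTM parameter lists (see [lstm_cell_step()]).
#' @return Numeric vector of length `2 * hidden`:
#'   `c(h_forward, h_backward)`.
#' @export
bilstm_encode <- function(seq, embedding, fwd, bwd) {
  stopifnot(inherits(seq, "token_seq"))
  ids <- seq$ids[seq$mask == 1L]
  if (length(ids) == 0L) {
    stop("all-padding sequence cannot be encoded", call. = FALSE)
  }
  if (any(ids < 0L) || any(ids >= nrow(embedding))) {
    stop("token ID outside the embedding table", call. = FALSE)
  }
  X <- t(embedding[ids + 1L, , drop = FALSE])  # embed_dim x T
  hidden <- nrow(fwd$w_f)
  h_fwd <- run_lstm(X, fwd, hidden)
  h_bwd <- run_lstm(X[, rev(seq_len(ncol(X))), drop = FALSE], bwd, hidden)
  c(h_fwd, h_bwd)
}

#' MLP forward pass
#'
#' `O = W_o %*% ReLU(W_h %*% h + b_h) + b_o`; ReLU between the two affine
#' layers, no activation after the output layer.
#'
#' @param h Input vector.
#' @param params List with `W_h`, `b_h`, `W_o`, `b_o`.
#' @return Output feature vector.
#' @export
mlp_forward <- function(h, params) {
  if (ncol(params$W_h) != length(h)) {
    stop(sprintf("MLP input size mismatch: weights expect %d, got %d",
                 ncol(params$W_h), length(h)), call. = FALSE)
  }
  hidden <- pmax(drop(params$W_h %*% h) + params$b_h, 0)
  drop(params$W_o %*% hidden) + params$b_o
}

#' Predict the interaction probability for one pair of token sequences
#'
#' Each drug is encoded by [bilstm_encode()] and [mlp_forward()] through
#' its branch (the same branch for both drugs in sharing mode); the two
#' feature vectors are concatenated (drug A first) and passed through the
#' affine + sigmoid predictor.
#'
#' @param seqA,seqB `token_seq` objects encoded under the model's
#'   vocabulary.
#' @param model A `ddi_model`.
#' @return Probability in (0, 1).
#' @export
predict_pair <- function(seqA, seqB, model) {
  stopifnot(inherits(model, "ddi_model"))
  ba <- model$branch_a
  bb <- branch_b_of(model)
  featA <- mlp_forward(bilstm_encode(seqA, ba$emb, ba$fwd, ba$bwd), ba$mlp)
  featB <- mlp_forward(bilstm_encode(seqB, bb$emb, bb$fwd, bb$bwd), bb$mlp)
  v <- c(featA, featB)
  sigmoid(sum(model$predictor$w * v) + model$predictor$b)
}

#' Closed-form trainable-parameter counts
#'
#' Shared storage is counted once: the independent mode has exactly twice
#' the sharing mode's encoder parameters, while the predictor is common to
#' both.
#'
#' @param config A [model_config()].
#' @return List with `encoder_params`, `predictor_params`, `total`.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "ddi_model_config"))
  e <- config$embed_dim
  h <- config$lstm_hidden
  emb <- config$vocab_size * e
  lstm_dir <- 4L * (h * (e + h) + h)
  mlp <- (2L * h * config$mlp_hidden + config$mlp_hidden) +
    (config$mlp_hidden * config$mlp_out + config$mlp_out)
  branch <- emb + 2L * lstm_dir + mlp
  encoder <- branch * if (config$mode == "independent") 2L else 1L
  predictor <- 2L * config$mlp_out + 1L
  list(encoder_params = encoder, predictor_params = predictor,
       total = encoder + predictor)
}

#' Batched interaction probabilities for SMILES pairs
#'
#' Encodes both SMILES columns under `vocab` and runs the compiled forward
#' pass. Equivalent to [predict_pair()] per row.
#'
#' @param model A `ddi_model`.
#' @param smiles_a,smiles_b Character vectors of equal length.
#' @param vocab The `ddi_vocab` the model was trained with.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
model_predict <- function(model, smiles_a, smiles_b, vocab) {
  stopifnot(length(smiles_a) == length(smiles_b))
  A <- encode_batch(smiles_a, vocab, model$config$max_len)
  B <- encode_batch(smiles_b, vocab, model$config$max_len)
  net_forward_ids(model, A, B)
}

# Forward over pre-encoded id batches; checks IDs fit the embedding.
net_forward_ids <- function(model, A, B, labels = numeric(0),
                            want_grad = FALSE) {
  v <- model$config$vocab_size
  if (max(A$ids, B$ids) >= v || min(A$ids, B$ids) < 0L) {
    stop("token ID outside the model's vocabulary", call. = FALSE)
  }
  res <- cpp_net_batch(A$ids, A$n_real, B$ids, B$n_real,
                       model$branch_a, branch_b_of(model),
                       model$predictor$w, model$predictor$b,
                       is.null(model$branch_b), labels, want_grad)
  if (want_grad || length(labels) > 0L) res else res$probs
}
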