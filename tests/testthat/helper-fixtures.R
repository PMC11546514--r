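# Shared fixtures: everything is built in code at test time.

toy_corpus <- c("CCO", "CCN", "ClCCl", "c1ccccc1", "C(=O)O", "NCCS")

toy_vocab <- function(n_merges = 0L) train_bpe(toy_corpus, n_merges)

toy_model_config <- function(vocab, mode = "sharing", embed_dim = 5L,
                             lstm_hidden = 3L, mlp_hidden = 4L, mlp_out = 2L,
                             max_len = 16L) {
  model_config(vocab_size(vocab), embed_dim = embed_dim,
               lstm_hidden = lstm_hidden, mlp_hidden = mlp_hidden,
               mlp_out = mlp_out, mode = mode, max_len = max_len)
}

# Random LSTM parameters with small weights, independent of init_model.
rand_lstm_params <- function(embed_dim, hidden) {
  w <- function() matrix(stats::runif(hidden * (embed_dim + hidden), -0.5, 0.5),
                         nrow = hidden)
  b <- function() stats::runif(hidden, -0.1, 0.1)
  list(w_f = w(), w_i = w(), w_o = w(), w_c = w(),
       b_f = b(), b_i = b(), b_o = b(), b_c = b())
}

# Independent concordance oracle: exhaustive mean over (positive, negative)
# pairs of [s_pos > s_neg] + 0.5 * [s_pos == s_neg].
concordance_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# A small labeled dataset with splits, for training smoke tests.
tiny_split_dataset <- function(n_pairs = 60L, label_noise = 0, seed = 5L) {
  ds <- generate_dataset(generator_config(n_pairs = n_pairs,
                                          label_noise = label_noise,
                                          seed = seed))
  split_dataset(ds, seed = seed)
}

expect_same_numbers <- function(a, b, tol = 0) {
  expect_equal(a, b, tolerance = tol)
}
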