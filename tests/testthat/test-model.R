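test_that("lstm cell reproduces the gate equations", {
  # zero weights: every gate sits at sigmoid(0) = 0.5, candidate at tanh(0) = 0
  h <- 3L
  p <- list(w_f = matrix(0, h, 5), w_i = matrix(0, h, 5),
            w_o = matrix(0, h, 5), w_c = matrix(0, h, 5),
            b_f = numeric(h), b_i = numeric(h), b_o = numeric(h),
            b_c = numeric(h))
  c0 <- c(1, -2, 0.5)
  st <- lstm_cell_step(c(0.3, 0.7), list(h = numeric(h), c = c0), p)
  expect_equal(st$c, 0.5 * c0)
  expect_equal(st$h, 0.5 * tanh(0.5 * c0))

  # scalar case, all weights [1, 1]: hand evaluation of the recurrence
  ps <- list(w_f = matrix(c(1, 1), 1), w_i = matrix(c(1, 1), 1),
             w_o = matrix(c(1, 1), 1), w_c = matrix(c(1, 1), 1),
             b_f = 0, b_i = 0, b_o = 0, b_c = 0)
  st <- lstm_cell_step(1, list(h = 0, c = 0), ps)
  sig1 <- 1 / (1 + exp(-1))
  expect_equal(st$c, sig1 * tanh(1), tolerance = 1e-12)
  expect_equal(st$h, sig1 * tanh(sig1 * tanh(1)), tolerance = 1e-12)
  expect_equal(st$c, 0.5568, tolerance = 1e-4)
  expect_equal(st$h, 0.3696, tolerance = 1e-4)

  expect_error(lstm_cell_step(c(1, 2, 3), list(h = 0, c = 0), ps), "mismatch")
})

test_that("gate activations stay strictly inside (0, 1)", {
  set.seed(17)
  for (rep in 1:10) {
    p <- rand_lstm_params(4, 3)
    x <- rnorm(4, sd = 3)
    st0 <- list(h = rnorm(3), c = rnorm(3))
    z <- c(x, st0$h)
    for (g in c("f", "i", "o")) {
      act <- 1 / (1 + exp(-(drop(p[[paste0("w_", g)]] %*% z) +
                            p[[paste0("b_", g)]])))
      expect_true(all(act > 0 & act < 1))
    }
  }
})

test_that("bilstm equals two explicit unidirectional passes", {
  set.seed(23)
  v <- toy_vocab()
  emb <- matrix(rnorm(vocab_size(v) * 4, sd = 0.3), ncol = 4)
  fwd <- rand_lstm_params(4, 3)
  bwd <- rand_lstm_params(4, 3)
  s <- encode("CCO", v, 10)  # 5 real tokens with BOS/EOS

  out <- bilstm_encode(s, emb, fwd, bwd)

  # independent oracle: run the cell step by step in both orders
  ids <- s$ids[s$mask == 1]
  X <- t(emb[ids + 1, , drop = FALSE])
  step_through <- function(Xo, p) {
    st <- list(h = numeric(3), c = numeric(3))
    for (t in seq_len(ncol(Xo))) st <- lstm_cell_step(Xo[, t], st, p)
    st$h
  }
  expect_equal(out, c(step_through(X, fwd),
                      step_through(X[, rev(seq_len(ncol(X))), drop = FALSE], bwd)))
})

test_that("length-1 input runs one step per direction on the same token", {
  set.seed(8)
  emb <- matrix(rnorm(8), ncol = 2)
  fwd <- rand_lstm_params(2, 2)
  bwd <- rand_lstm_params(2, 2)
  s <- structure(list(ids = c(3L, 0L), mask = c(1L, 0L), n_real = 1L),
                 class = "token_seq")
  out <- bilstm_encode(s, emb, fwd, bwd)
  x <- emb[4, ]
  one <- function(p) lstm_cell_step(x, list(h = numeric(2), c = numeric(2)), p)$h
  expect_equal(out, c(one(fwd), one(bwd)))
})

test_that("padding never enters the recurrence", {
  set.seed(4)
  emb <- matrix(rnorm(12), ncol = 2)
  fwd <- rand_lstm_params(2, 2)
  bwd <- rand_lstm_params(2, 2)
  base <- structure(list(ids = c(1L, 4L, 2L, 0L), mask = c(1L, 1L, 1L, 0L),
                         n_real = 3L), class = "token_seq")
  padded <- structure(list(ids = c(1L, 4L, 2L, rep(0L, 7)),
                           mask = c(1L, 1L, 1L, rep(0L, 7)), n_real = 3L),
                      class = "token_seq")
  expect_identical(bilstm_encode(base, emb, fwd, bwd),
                   bilstm_encode(padded, emb, fwd, bwd))
  allpad <- structure(list(ids = rep(0L, 4), mask = rep(0L, 4), n_real = 0L),
                      class = "token_seq")
  expect_error(bilstm_encode(allpad, emb, fwd, bwd), "padding")
})

test_that("mlp applies ReLU between affine layers and nothing after", {
  p0 <- list(W_h = matrix(0, 3, 2), b_h = numeric(3),
             W_o = matrix(0, 2, 3), b_o = c(5, -1))
  expect_equal(mlp_forward(c(1, 2), p0), c(5, -1))

  p <- list(W_h = diag(2), b_h = numeric(2), W_o = diag(2), b_o = numeric(2))
  expect_equal(mlp_forward(c(1, -1), p), c(1, 0))
  expect_error(mlp_forward(c(1, 2, 3), p), "mismatch")
})

test_that("default dimensions follow the published configuration", {
  cfg <- model_config(vocab_size = 100)
  expect_equal(cfg$embed_dim, 512L)
  expect_equal(2L * cfg$lstm_hidden, 256L)   # MLP input
  expect_equal(cfg$mlp_hidden, 128L)
  expect_equal(cfg$mlp_out, 4L)              # predictor input 2 x 4 = 8
  expect_equal(cfg$max_len, 512L)
  m <- init_model(toy_model_config(toy_vocab()), seed = 1)
  expect_equal(dim(m$branch_a$mlp$W_h), c(4L, 6L))
  expect_equal(length(m$predictor$w), 4L)
})

test_that("predict_pair composes encoder, MLP and sigmoid predictor", {
  v <- toy_vocab()
  cfg <- toy_model_config(v)
  m <- init_model(cfg, seed = 3)
  sa <- encode("CCO", v, cfg$max_len)
  sb <- encode("ClCCl", v, cfg$max_len)

  # zero predictor weights: p = sigmoid(0) = 0.5 for any pair
  m0 <- m
  m0$predictor$w[] <- 0
  m0$predictor$b <- 0
  expect_equal(predict_pair(sa, sb, m0), 0.5)

  # chained hand computation through the three stage oracles
  ba <- m$branch_a
  featA <- mlp_forward(bilstm_encode(sa, ba$emb, ba$fwd, ba$bwd), ba$mlp)
  featB <- mlp_forward(bilstm_encode(sb, ba$emb, ba$fwd, ba$bwd), ba$mlp)
  s <- sum(m$predictor$w * c(featA, featB)) + m$predictor$b
  expect_equal(predict_pair(sa, sb, m), 1 / (1 + exp(-s)))

  # sharing mode encodes identical inputs identically
  expect_equal(mlp_forward(bilstm_encode(sa, ba$emb, ba$fwd, ba$bwd), ba$mlp),
               featA)
  p <- predict_pair(sa, sb, m)
  expect_true(p > 0 && p < 1)
})

test_that("compiled forward pass equals the pure-R composition", {
  v <- toy_vocab(2)
  for (mode in c("sharing", "independent")) {
    cfg <- toy_model_config(v, mode = mode)
    m <- init_model(cfg, seed = 11)
    pairs <- list(c("CCO", "ClCCl"), c("c1ccccc1", "CCN"), c("C(=O)O", "NCCS"))
    probs_cpp <- model_predict(m,
                               vapply(pairs, `[[`, "", 1),
                               vapply(pairs, `[[`, "", 2), v)
    probs_r <- vapply(pairs, function(pr) {
      predict_pair(encode(pr[1], v, cfg$max_len),
                   encode(pr[2], v, cfg$max_len), m)
    }, numeric(1))
    expect_equal(probs_cpp, probs_r, tolerance = 1e-12)
    # determinism: bit-identical on repeat
    expect_identical(probs_cpp,
                     model_predict(m, vapply(pairs, `[[`, "", 1),
                                   vapply(pairs, `[[`, "", 2), v))
  }
})

test_that("parameter counts: closed form, duplication, additivity", {
  cfg <- model_config(vocab_size = 10, embed_dim = 4, lstm_hidden = 3,
                      mlp_hidden = 5, mlp_out = 2, mode = "sharing",
                      max_len = 8)
  n <- count_parameters(cfg)
  expect_equal(n$encoder_params, 40 + 192 + 47)  # embedding + BiLSTM + MLP
  expect_equal(n$predictor_params, 5)
  expect_equal(n$total, n$encoder_params + n$predictor_params)

  cfg_ind <- model_config(vocab_size = 10, embed_dim = 4, lstm_hidden = 3,
                          mlp_hidden = 5, mlp_out = 2, mode = "independent",
                          max_len = 8)
  n_ind <- count_parameters(cfg_ind)
  expect_equal(n_ind$encoder_params, 2L * n$encoder_params)
  expect_equal(n_ind$predictor_params, n$predictor_params)
})

test_that("identically initialized independent branches match sharing mode", {
  v <- toy_vocab()
  m_sh <- init_model(toy_model_config(v, mode = "sharing"), seed = 21)
  m_ind <- init_model(toy_model_config(v, mode = "independent"), seed = 21)
  m_ind$branch_a <- m_sh$branch_a
  m_ind$branch_b <- m_sh$branch_a
  m_ind$predictor <- m_sh$predictor
  a <- c("CCO", "ClCCl", "NCCS")
  b <- c("c1ccccc1", "CCN", "C(=O)O")
  expect_identical(model_predict(m_sh, a, b, v), model_predict(m_ind, a, b, v))
})

test_that("analytic gradients match central finite differences", {
  v <- toy_vocab()
  set_leaf <- function(lst, path, idx, val) {
    if (length(path) == 1) {
      lst[[path]][idx] <- val
      return(lst)
    }
    lst[[path[1]]] <- set_leaf(lst[[path[1]]], path[-1], idx, val)
    lst
  }
  get_leaf <- function(lst, path, idx) {
    for (p in path) lst <- lst[[p]]
    lst[idx]
  }
  for (mode in c("sharing", "independent")) {
    cfg <- toy_model_config(v, mode = mode)
    m <- init_model(cfg, seed = 2)
    A <- ddipair:::encode_batch(c("CCO", "ClCCl"), v, cfg$max_len)
    B <- ddipair:::encode_batch(c("NCCS", "c1ccccc1"), v, cfg$max_len)
    labels <- c(1, 0)
    res <- ddipair:::net_forward_ids(m, A, B, labels, want_grad = TRUE)
    leaves <- list(
      list(c("branch_a", "fwd", "w_f"), 2L),
      list(c("branch_a", "fwd", "b_c"), 1L),
      list(c("branch_a", "bwd", "w_o"), 4L),
      list(c("branch_a", "emb"), 9L),
      list(c("branch_a", "mlp", "W_h"), 5L),
      list(c("branch_a", "mlp", "b_o"), 2L),
      list(c("predictor", "w"), 3L),
      list(c("predictor", "b"), 1L))
    if (mode == "independent") {
      leaves <- c(leaves, list(list(c("branch_b", "fwd", "w_i"), 7L),
                               list(c("branch_b", "mlp", "W_o"), 1L)))
    }
    eps <- 1e-6
    for (lf in leaves) {
      v0 <- get_leaf(m, lf[[1]], lf[[2]])
      lp <- ddipair:::net_forward_ids(set_leaf(m, lf[[1]], lf[[2]], v0 + eps),
                                      A, B, labels)$loss
      lm <- ddipair:::net_forward_ids(set_leaf(m, lf[[1]], lf[[2]], v0 - eps),
                                      A, B, labels)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- get_leaf(res$grads, lf[[1]], lf[[2]])
      expect_lt(abs(fd - an) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("out-of-range token IDs are rejected", {
  v <- toy_vocab()
  cfg <- toy_model_config(v)
  m <- init_model(cfg, seed = 1)
  A <- ddipair:::encode_batch("CCO", v, cfg$max_len)
  bad <- A
  bad$ids[2, 1] <- cfg$vocab_size + 5L
  expect_error(ddipair:::net_forward_ids(m, bad, A), "vocabulary")
})
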