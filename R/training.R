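# Loss, learning-rate schedule, AdamW optimization loop, checkpoint
# selection, and multi-run orchestration.

#' Training configuration
#'
#' Defaults follow the published BIOSNAP profile: AdamW with learning rate
#' 2e-5 and weight decay 2e-4, batch size 8, 30 epochs, and a step
#' schedule multiplying the rate by 0.8 every 10 epochs. The DrugBank
#' profile uses weight decay 1e-2 and batch size 16.
#'
#' @param learning_rate Base learning rate (> 0).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Number of training epochs (>= 0).
#' @param scheduler_gamma Multiplicative decay factor, in (0, 1].
#' @param scheduler_step Epochs between decays (>= 1).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param n_runs Replicate runs for [run_replicates()].
#' @return A `ddi_train_config` list.
#' @export
training_config <- function(learning_rate = 2e-5, weight_decay = 2e-4,
                            batch_size = 8L, epochs = 30L,
                            scheduler_gamma = 0.8, scheduler_step = 10L,
                            seed = 1L, n_runs = 3L) {
  stopifnot(learning_rate > 0, weight_decay >= 0,
            batch_size >= 1, epochs >= 0,
            scheduler_gamma > 0, scheduler_gamma <= 1, scheduler_step >= 1,
            n_runs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 scheduler_gamma = scheduler_gamma,
                 scheduler_step = as.integer(scheduler_step),
                 seed = as.integer(seed), n_runs = as.integer(n_runs)),
            class = "ddi_train_config")
}

#' Binary cross-entropy loss
#'
#' `-w * (t * log(p) + (1 - t) * log(1 - p))`, averaged over items.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithm,
#' which also realises the `0 * log(0) = 0` convention.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param t True labels in `{0, 1}` (same length as `p`).
#' @param w Rescaling weight (scalar or per item). The balanced datasets
#'   this framework targets use `w = 1`.
#' @return Mean loss (non-negative scalar).
#' @examples
#' bce_loss(0.5, 1)  # log(2)
#' @export
bce_loss <- function(p, t, w = 1) {
  if (!all(t %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  stopifnot(length(p) == length(t), all(p >= 0 & p <= 1))
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  mean(-w * (t * log(pc) + (1 - t) * log(1 - pc)))
}

#' Step learning-rate schedule
#'
#' `lr = base_lr * gamma^floor(epoch / step_size)` with `epoch` counted
#' from 0, stepped once per epoch.
#'
#' @param epoch Zero-based epoch index.
#' @param base_lr Base learning rate.
#' @param gamma Decay factor.
#' @param step_size Epochs between decays (>= 1).
#' @return The learning rate for that epoch.
#' @examples
#' step_lr(10, 2e-5, 0.8, 10)  # 1.6e-5
#' @export
step_lr <- function(epoch, base_lr, gamma = 0.8, step_size = 10L) {
  stopifnot(step_size >= 1, epoch >= 0)
  base_lr * gamma^(epoch %/% step_size)
}

# --- AdamW over the nested parameter list ------------------------------

# Recursively map f over matching numeric leaves of a params/grads pair.
map_leaves <- function(p, g, f) {
  if (is.list(p)) {
    for (nm in names(p)) {
      if (!is.null(g[[nm]])) p[[nm]] <- map_leaves(p[[nm]], g[[nm]], f)
    }
    return(p)
  }
  f(p, g)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

new_adamw_state <- function(trainable) {
  list(m = zero_like(trainable), v = zero_like(trainable), t = 0L)
}

# One AdamW update (decoupled weight decay scaled by lr, as in the
# reference optimizer): beta1 = 0.9, beta2 = 0.999, eps = 1e-8.
adamw_step <- function(trainable, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- map_leaves(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_leaves(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  trainable <- map_leaves(trainable, map_leaves(state$m, state$v, function(m, v) {
    list(m = m, v = v)
  }), function(p, mv) {
    p - lr * ((mv$m / bc1) / (sqrt(mv$v / bc2) + eps) + weight_decay * p)
  })
  list(trainable = trainable, state = state)
}

trainable_of <- function(model) {
  keep <- intersect(c("branch_a", "branch_b", "predictor"), names(model))
  model[keep][!vapply(model[keep], is.null, logical(1L))]
}

split_rows <- function(dataset, split) {
  if (is.null(dataset$split)) {
    stop("dataset has no split assignment; call split_dataset() first",
         call. = FALSE)
  }
  dataset[dataset$split == split, , drop = FALSE]
}

#' Train the pair classifier
#'
#' Mini-batch AdamW optimization of the binary cross-entropy, with
#' per-epoch step-schedule learning rates and per-epoch reshuffling of the
#' training split under the run seed. After each epoch the validation
#' split is scored; the returned model is the checkpoint of the epoch with
#' the best validation ROC-AUC. The whole run is deterministic given
#' (seed, configs, dataset).
#'
#' @param dataset A labeled pair dataset with a `split` column (see
#'   [split_dataset()]); `train` and `valid` splits must be non-empty.
#' @param vocab The `ddi_vocab` used to encode the SMILES columns.
#' @param model_config A [model_config()]; its `vocab_size` must equal
#'   `vocab_size(vocab)`.
#' @param train_config A [training_config()].
#' @return List with `model` (best checkpoint), `history` (data frame:
#'   epoch, lr, train_loss, valid_loss, valid_auc) and `best_epoch`.
#' @export
train <- function(dataset, vocab, model_config, train_config) {
  stopifnot(inherits(model_config, "ddi_model_config"),
            inherits(train_config, "ddi_train_config"))
  if (model_config$vocab_size != vocab_size(vocab)) {
    stop("model_config$vocab_size does not match the vocabulary",
         call. = FALSE)
  }
  tr <- split_rows(dataset, "train")
  va <- split_rows(dataset, "valid")
  if (nrow(tr) == 0L || nrow(va) == 0L) {
    stop("train and valid splits must be non-empty", call. = FALSE)
  }

  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(train_config$seed)

  model <- init_model(model_config, seed = train_config$seed)
  trainable <- trainable_of(model)
  opt <- new_adamw_state(trainable)

  max_len <- model_config$max_len
  trA <- encode_batch(tr$smiles_a, vocab, max_len)
  trB <- encode_batch(tr$smiles_b, vocab, max_len)
  vaA <- encode_batch(va$smiles_a, vocab, max_len)
  vaB <- encode_batch(va$smiles_b, vocab, max_len)

  n_epochs <- train_config$epochs
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), valid_loss = numeric(0),
                        valid_auc = numeric(0))
  best <- list(auc = -Inf, trainable = trainable, epoch = 0L)

  take_cols <- function(batch, idx) {
    list(ids = batch$ids[, idx, drop = FALSE], n_real = batch$n_real[idx])
  }

  for (epoch in seq_len(n_epochs)) {
    lr <- step_lr(epoch - 1L, train_config$learning_rate,
                  train_config$scheduler_gamma, train_config$scheduler_step)
    order_idx <- sample.int(nrow(tr))
    batch_starts <- seq(1L, nrow(tr), by = train_config$batch_size)
    epoch_loss <- 0
    for (s in batch_starts) {
      idx <- order_idx[s:min(s + train_config$batch_size - 1L, nrow(tr))]
      model[names(trainable)] <- trainable
      res <- net_forward_ids(model, take_cols(trA, idx), take_cols(trB, idx),
                             labels = tr$label[idx], want_grad = TRUE)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite training loss at epoch %d; aborting", epoch),
             call. = FALSE)
      }
      epoch_loss <- epoch_loss + res$loss * length(idx)
      upd <- adamw_step(trainable, res$grads, opt, lr,
                        train_config$weight_decay)
      trainable <- upd$trainable
      opt <- upd$state
    }
    model[names(trainable)] <- trainable
    vres <- net_forward_ids(model, vaA, vaB, labels = va$label)
    vauc <- roc_auc(vres$probs, va$label)$auc
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      train_loss = epoch_loss / nrow(tr),
      valid_loss = vres$loss, valid_auc = vauc))
    if (vauc > best$auc) {
      best <- list(auc = vauc, trainable = trainable, epoch = epoch)
    }
  }

  model[names(best$trainable)] <- best$trainable
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Train several replicates and aggregate their test metrics
#'
#' Runs `n_runs` trainings under consecutive seeds (`seed`, `seed + 1`,
#' ...), evaluates each on the test split, and reports the per-metric mean
#' and sample standard deviation, the aggregation used when reporting
#' benchmark performance as "value (+/- std)".
#'
#' @inheritParams train
#' @return List with `runs` (per-run list of `model`, `history`, `report`)
#'   and `aggregate` (data frame: metric, mean, sd).
#' @export
run_replicates <- function(dataset, vocab, model_config, train_config) {
  n_runs <- train_config$n_runs
  runs <- vector("list", n_runs)
  metrics <- c("auc_roc", "pr_auc", "f1", "precision", "recall")
  values <- matrix(NA_real_, nrow = n_runs, ncol = length(metrics),
                   dimnames = list(NULL, metrics))
  for (r in seq_len(n_runs)) {
    cfg_r <- train_config
    cfg_r$seed <- train_config$seed + r - 1L
    fit <- train(dataset, vocab, model_config, cfg_r)
    report <- evaluate_model(fit$model, dataset, vocab, split = "test")
    values[r, ] <- c(report$auc_roc, report$pr_auc, report$f1,
                     report$precision, report$recall)
    runs[[r]] <- list(model = fit$model, history = fit$history,
                      report = report, seed = cfg_r$seed)
  }
  aggregate <- data.frame(
    metric = metrics,
    mean = colMeans(values),
    sd = if (n_runs > 1L) apply(values, 2L, stats::sd) else 0,
    row.names = NULL)
  list(runs = runs, aggregate = aggregate)
}
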