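# Balanced synthetic SMILES-pair datasets with a planted, symmetric,
# substructure-dependent interaction rule, emulating the statistical shape
# of the public DDI benchmarks (balanced 0/1 labels, varied-length SMILES)
# at desk scale.

#' Generator configuration
#'
#' Molecules are concatenations of SMILES fragments (lexically valid, not
#' chemically bonded -- the classifier consumes strings, not molecules).
#' A pair interacts when one molecule contains a `motif_a` fragment and
#' the other a `motif_b` fragment, in either order, so the planted truth
#' is symmetric in (A, B). With the default (equal) motif sets the rule
#' reads: the pair interacts when both molecules carry a reactive motif
#' (a halogen or a carboxyl group). Equal sets are the default because
#' the pair scorer is additive across the two drugs (an affine predictor
#' over concatenated features), and only then is the planted rule
#' representable by the model it is meant to train; with disjoint motif
#' sets the cross-motif rule is provably not separable by any additive
#' pair score. Labels are balanced exactly, then flipped independently
#' with probability `label_noise`.
#'
#' @param n_pairs Positive even number of pairs (default 2000).
#' @param fragment_alphabet SMILES fragments molecules are built from.
#' @param motif_a,motif_b Fragment subsets defining the interaction rule.
#' @param length_range Integer range of fragments per molecule.
#' @param label_noise Per-label flip probability, in `[0, 0.5]` (0.5
#'   removes all signal and is useful as a sanity floor).
#' @param seed Integer seed.
#' @return A `ddi_gen_config` list.
#' @export
generator_config <- function(n_pairs = 2000L,
                             fragment_alphabet = c("C", "CC", "CO", "N", "O",
                                                   "Cl", "c1ccccc1",
                                                   "C(=O)O", "C(=O)N", "S"),
                             motif_a = c("Cl", "C(=O)O"),
                             motif_b = c("Cl", "C(=O)O"),
                             length_range = c(3L, 12L),
                             label_noise = 0.05,
                             seed = 1L) {
  stopifnot(n_pairs >= 2, n_pairs %% 2 == 0,
            length(fragment_alphabet) >= 1,
            label_noise >= 0, label_noise <= 0.5,
            length(length_range) == 2L, length_range[1L] >= 1,
            length_range[1L] <= length_range[2L])
  if (!all(motif_a %in% fragment_alphabet) ||
      !all(motif_b %in% fragment_alphabet)) {
    stop("motifs must be drawn from the fragment alphabet", call. = FALSE)
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 fragment_alphabet = fragment_alphabet,
                 motif_a = motif_a, motif_b = motif_b,
                 length_range = as.integer(length_range),
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "ddi_gen_config")
}

#' Generate one synthetic molecule
#'
#' Concatenates k fragments, k uniform over the configured length range.
#' Uses the current RNG state, so it is deterministic under a seed set by
#' the caller (as [generate_dataset()] does).
#'
#' @param config A [generator_config()].
#' @return A SMILES string.
#' @export
generate_molecule <- function(config) {
  stopifnot(inherits(config, "ddi_gen_config"))
  if (length(config$fragment_alphabet) == 0L) {
    stop("fragment alphabet is empty", call. = FALSE)
  }
  lo <- config$length_range[1L]
  hi <- config$length_range[2L]
  k <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  frags <- config$fragment_alphabet[
    sample.int(length(config$fragment_alphabet), k, replace = TRUE)]
  paste0(frags, collapse = "")
}

# Planted truth: symmetric cross-motif containment by substring search.
interaction_rule <- function(smiles_a, smiles_b, motif_a, motif_b) {
  has <- function(s, motifs) {
    any(vapply(motifs, function(m) grepl(m, s, fixed = TRUE), logical(1L)))
  }
  (has(smiles_a, motif_a) && has(smiles_b, motif_b)) ||
    (has(smiles_a, motif_b) && has(smiles_b, motif_a))
}

#' Generate a balanced labeled SMILES-pair dataset
#'
#' Rejection-samples molecule pairs until exactly `n_pairs / 2` satisfy
#' the planted interaction rule and `n_pairs / 2` do not, then flips each
#' label independently with probability `label_noise`. The pre-noise rule
#' labels are kept in the `clean_label` column so the planted truth can be
#' re-checked by an independent substring search.
#'
#' @param config A [generator_config()].
#' @param max_attempts Rejection-sampling budget before declaring the rule
#'   unsatisfiable (default 1e6).
#' @return Data frame with columns `smiles_a`, `smiles_b`, `label`,
#'   `clean_label`, carrying `config` as an attribute. Rows are shuffled.
#' @export
generate_dataset <- function(config, max_attempts = 1e6L) {
  stopifnot(inherits(config, "ddi_gen_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)

  n_per_class <- config$n_pairs %/% 2L
  pos <- list(a = character(0), b = character(0))
  neg <- list(a = character(0), b = character(0))
  attempts <- 0L
  max_attempts <- as.integer(max_attempts)
  while ((length(pos$a) < n_per_class || length(neg$a) < n_per_class) &&
         attempts < max_attempts) {
    attempts <- attempts + 1L
    a <- generate_molecule(config)
    b <- generate_molecule(config)
    if (interaction_rule(a, b, config$motif_a, config$motif_b)) {
      if (length(pos$a) < n_per_class) {
        pos$a <- c(pos$a, a)
        pos$b <- c(pos$b, b)
      }
    } else if (length(neg$a) < n_per_class) {
      neg$a <- c(neg$a, a)
      neg$b <- c(neg$b, b)
    }
  }
  if (length(pos$a) < n_per_class || length(neg$a) < n_per_class) {
    stop(sprintf("interaction rule unsatisfiable: %d positives / %d negatives after %d attempts",
                 length(pos$a), length(neg$a), attempts), call. = FALSE)
  }

  clean <- c(rep.int(1L, n_per_class), rep.int(0L, n_per_class))
  flip <- stats::runif(config$n_pairs) < config$label_noise
  dataset <- data.frame(
    smiles_a = c(pos$a, neg$a),
    smiles_b = c(pos$b, neg$b),
    label = ifelse(flip, 1L - clean, clean),
    clean_label = clean,
    stringsAsFactors = FALSE)
  dataset <- dataset[sample.int(nrow(dataset)), , drop = FALSE]
  rownames(dataset) <- NULL
  attr(dataset, "config") <- config
  dataset
}

#' Split sizes under the benchmark scheme
#'
#' 20% of the data is held out for testing; the remainder is split
#' 8:2 into training and validation. Sizes use `round()`.
#'
#' @param n Total number of pairs.
#' @param test_fraction Held-out test fraction (default 0.2).
#' @param valid_fraction Validation fraction of the remainder (default 0.2).
#' @return List with `train`, `valid`, `test` sizes summing to `n`.
#' @examples
#' split_sizes(83040)  # test = 16608
#' @export
split_sizes <- function(n, test_fraction = 0.2, valid_fraction = 0.2) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            valid_fraction > 0, valid_fraction < 1)
  n_test <- round(n * test_fraction)
  n_valid <- round((n - n_test) * valid_fraction)
  n_train <- n - n_test - n_valid
  list(train = n_train, valid = n_valid, test = n_test)
}

#' Assign train/valid/test splits to a pair dataset
#'
#' Shuffles rows under the seed and assigns disjoint, exhaustive splits
#' with the sizes of [split_sizes()].
#'
#' @param dataset A labeled pair data frame.
#' @param test_fraction,valid_fraction See [split_sizes()].
#' @param seed Integer shuffle seed.
#' @return The dataset with an added `split` column
#'   (`"train"`/`"valid"`/`"test"`).
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, valid_fraction = 0.2,
                          seed = 1L) {
  n <- nrow(dataset)
  sizes <- split_sizes(n, test_fraction, valid_fraction)
  if (any(unlist(sizes) == 0L)) {
    stop("dataset too small: a split would be empty", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(n)
  split <- character(n)
  split[idx[seq_len(sizes$train)]] <- "train"
  split[idx[sizes$train + seq_len(sizes$valid)]] <- "valid"
  split[idx[sizes$train + sizes$valid + seq_len(sizes$test)]] <- "test"
  dataset$split <- split
  dataset
}
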