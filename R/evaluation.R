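# Binary-classifier evaluation from first principles: confusion analytics,
# precision/recall/F1, ROC and PR curves with trapezoidal areas, relative
# improvement arithmetic, and Tanimoto fingerprint similarity.

#' Confusion counts at a probability threshold
#'
#' A pair is called positive when its score is strictly greater than the
#' threshold (a score exactly at the threshold is a negative call, so
#' 0.504 is an interaction at 0.5 while 0.500 is not).
#'
#' @param scores Predicted probabilities.
#' @param labels True labels in `{0, 1}`, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A `ddi_confusion` list: `TP`, `FP`, `TN`, `FN`, `threshold`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  pred <- scores > threshold
  structure(list(TP = sum(pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0),
                 FN = sum(!pred & labels == 1),
                 threshold = threshold),
            class = "ddi_confusion")
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any 0/0 is
#' defined as 0.
#'
#' @param cc A `ddi_confusion` (or list with `TP`, `FP`, `FN`).
#' @return List with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cc) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  p <- safe_div(cc$TP, cc$TP + cc$FP)
  r <- safe_div(cc$TP, cc$TP + cc$FN)
  f1 <- safe_div(2 * p * r, p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' False-positive rate
#'
#' `FPR = FP / (FP + TN)`.
#'
#' @param cc A `ddi_confusion` (or list with `FP`, `TN`).
#' @return The false-positive rate.
#' @export
fpr <- function(cc) {
  if (cc$FP + cc$TN == 0) {
    stop("FPR undefined: no true negatives or false positives", call. = FALSE)
  }
  cc$FP / (cc$FP + cc$TN)
}

#' Row-normalized confusion rates
#'
#' Normalizes each true-class row: `TPR + FNR = 1` over true positives,
#' `FPR + TNR = 1` over true negatives.
#'
#' @param cc A `ddi_confusion`.
#' @return List with `TPR`, `FNR`, `FPR`, `TNR`.
#' @export
normalize_confusion <- function(cc) {
  pos <- cc$TP + cc$FN
  neg <- cc$FP + cc$TN
  if (pos == 0 || neg == 0) {
    stop("cannot normalize: an empty true class", call. = FALSE)
  }
  list(TPR = cc$TP / pos, FNR = cc$FN / pos,
       FPR = cc$FP / neg, TNR = cc$TN / neg)
}

# Shared threshold sweep: cumulative TP/FP at each distinct score,
# descending. Ties collapse into one operating point, which makes the
# trapezoidal ROC area equal the Mann-Whitney statistic with ties
# counted 1/2.
sweep_counts <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  list(tp = tp[last_of_tie], fp = fp[last_of_tie],
       P = sum(y == 1), N = sum(y == 0))
}

trapezoid <- function(x, y) {
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' ROC curve and area
#'
#' Sweeps the threshold over all distinct scores and integrates TPR over
#' FPR by the trapezoidal rule. The resulting area equals the concordance
#' probability (Mann-Whitney statistic) with tied scores counted 1/2.
#'
#' @param scores Predicted probabilities or arbitrary real scores.
#' @param labels True labels in `{0, 1}`; both classes must be present.
#' @return List with `fpr`, `tpr` (curve points from (0,0) to (1,1)) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  sw <- sweep_counts(scores, labels)
  if (sw$P == 0 || sw$N == 0) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  fpr <- c(0, sw$fp / sw$N)
  tpr <- c(0, sw$tp / sw$P)
  list(fpr = fpr, tpr = tpr, auc = trapezoid(fpr, tpr))
}

#' Precision-recall curve and area
#'
#' Precision and recall at every distinct-score threshold (descending),
#' integrated over recall by the trapezoidal rule; the curve is anchored
#' at recall 0 with the precision of the strictest threshold.
#'
#' @inheritParams roc_auc
#' @return List with `recall`, `precision` (curve points) and `auc`.
#' @export
pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  sw <- sweep_counts(scores, labels)
  if (sw$P == 0) stop("PR curve requires at least one positive", call. = FALSE)
  rec <- sw$tp / sw$P
  prec <- sw$tp / (sw$tp + sw$fp)
  rec <- c(0, rec)
  prec <- c(prec[1L], prec)
  list(recall = rec, precision = prec, auc = trapezoid(rec, prec))
}

#' Relative improvement in percent
#'
#' `100 * (new - old) / old`; report with [round_half_up()] to one decimal
#' when quoting benchmark gains.
#'
#' @param new_value,old_value Metric values; `old_value` must be > 0.
#' @return Percent improvement (not rounded).
#' @examples
#' round_half_up(relative_improvement(0.997, 0.966), 1)  # 3.2
#' @export
relative_improvement <- function(new_value, old_value) {
  if (any(old_value <= 0)) stop("old_value must be > 0", call. = FALSE)
  100 * (new_value - old_value) / old_value
}

#' Round half away from zero
#'
#' Decimal rounding where halves go up (2.665 -> 2.67), matching how
#' reported percentages are printed, unlike R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Tanimoto similarity of two fingerprint bit sets
#'
#' `|A intersect B| / |A union B|` over the sets of set-bit indices; the
#' similarity of two empty sets is defined as 0.
#'
#' @param fpA,fpB Integer vectors of set-bit indices (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fpA, fpB) {
  a <- unique(fpA)
  b <- unique(fpB)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Hashed n-gram fingerprint of a SMILES string
#'
#' Built-in lexical fingerprint: all n-grams (n = 1..4) of the atom-level
#' symbol sequence are hashed into a fixed-width bit set. Self-contained
#' and adequate for relative similarity of the synthetic molecules; it is
#' not a circular/Morgan fingerprint and makes no claim to match
#' similarities computed with chemistry toolkits.
#'
#' @param smiles A SMILES string.
#' @param n_max Largest n-gram length (default 4).
#' @param n_bits Fingerprint width (default 2048).
#' @return Sorted integer vector of set-bit indices in `0:(n_bits - 1)`.
#' @export
ngram_fingerprint <- function(smiles, n_max = 4L, n_bits = 2048L) {
  symbols <- pretokenize(smiles)
  bits <- integer(0)
  for (n in seq_len(min(n_max, length(symbols)))) {
    grams <- vapply(seq_len(length(symbols) - n + 1L), function(i) {
      paste0(symbols[i:(i + n - 1L)], collapse = "")
    }, character(1L))
    bits <- c(bits, vapply(grams, hash_string, integer(1L),
                           modulus = n_bits))
  }
  sort(unique(bits))
}

hash_string <- function(s, modulus) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% modulus
  as.integer(h)
}

#' Full evaluation report for a model on one split
#'
#' Scores every pair in the chosen split and assembles the confusion
#' counts at the threshold, row-normalized rates, precision/recall/F1,
#' and the ROC and PR curves with their areas.
#'
#' @param model A trained `ddi_model`.
#' @param dataset Labeled pair dataset with a `split` column.
#' @param vocab The model's `ddi_vocab`.
#' @param split Which split to score (default `"test"`).
#' @param threshold Decision threshold (default 0.5).
#' @return A `ddi_eval` list: `n`, `threshold`, `counts`, `rates`,
#'   `precision`, `recall`, `f1`, `roc`, `pr`, `auc_roc`, `pr_auc`.
#' @export
evaluate_model <- function(model, dataset, vocab, split = "test",
                           threshold = 0.5) {
  rows <- split_rows(dataset, split)
  if (nrow(rows) == 0L) {
    stop(sprintf("split \"%s\" is empty", split), call. = FALSE)
  }
  scores <- model_predict(model, rows$smiles_a, rows$smiles_b, vocab)
  report_from_scores(scores, rows$label, threshold)
}

report_from_scores <- function(scores, labels, threshold = 0.5) {
  cc <- confusion(scores, labels, threshold)
  prf <- precision_recall_f1(cc)
  roc <- roc_auc(scores, labels)
  pr <- pr_auc(scores, labels)
  structure(list(n = length(scores), threshold = threshold,
                 counts = cc, rates = normalize_confusion(cc),
                 precision = prf$precision, recall = prf$recall,
                 f1 = prf$f1,
                 roc = roc[c("fpr", "tpr")], pr = pr[c("recall", "precision")],
                 auc_roc = roc$auc, pr_auc = pr$auc),
            class = "ddi_eval")
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat(sprintf("<ddi_eval> n=%d threshold=%.3g\n", x$n, x$threshold))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$counts$TP, x$counts$FP,
              x$counts$TN, x$counts$FN))
  cat(sprintf("  precision=%.3f recall=%.3f F1=%.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  AUC-ROC=%.3f PR-AUC=%.3f\n", x$auc_roc, x$pr_auc))
  invisible(x)
}
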