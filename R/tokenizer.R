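# Atom-level SMILES pre-tokenization + byte-pair-encoding vocabulary.

.SPECIAL_TOKENS <- c(pad = "<pad>", bos = "<bos>", eos = "<eos>", unk = "<unk>")
.PAD_ID <- 0L
.BOS_ID <- 1L
.EOS_ID <- 2L
.UNK_ID <- 3L

.AROMATIC <- c("b", "c", "n", "o", "s", "p")
.BOND_CHARS <- c("-", "=", "#", "$", "/", "\\", ":", ".", "~", "*")

#' Split a SMILES string into atom-level symbols
#'
#' Lexical segmentation of a SMILES string into the units byte-pair encoding
#' operates on: bracket atoms (`[...]`) and the two-letter organic-subset
#' halogens `Cl`/`Br` are kept whole; aromatic atoms, other single-letter
#' atoms, bond characters, branch parentheses, ring-closure digits and
#' `%nn` two-digit ring labels are single symbols. Only lexical validity is
#' checked -- no valence or aromaticity rules.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of symbols whose concatenation equals `smiles`.
#' @examples
#' pretokenize("ClCCl")
#' pretokenize("[nH]1cccc1")
#' @export
pretokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- character(n)  # at most n symbols
  k <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[[j]] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("unbalanced '[' at position %d in \"%s\"", i, smiles),
             call. = FALSE)
      }
      k <- k + 1L
      out[[k]] <- substr(smiles, i, j)
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("unmatched ']' at position %d in \"%s\"", i, smiles),
           call. = FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}", substr(smiles, i + 1L, i + 2L))) {
        stop(sprintf("'%%' at position %d must be followed by two digits", i),
             call. = FALSE)
      }
      k <- k + 1L
      out[[k]] <- substr(smiles, i, i + 2L)
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[[i + 1L]] == "l") {
      k <- k + 1L
      out[[k]] <- "Cl"
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[[i + 1L]] == "r") {
      k <- k + 1L
      out[[k]] <- "Br"
      i <- i + 2L
    } else if (grepl("^[A-Z0-9()]$", ch) || ch %in% .AROMATIC ||
               ch %in% .BOND_CHARS) {
      k <- k + 1L
      out[[k]] <- ch
      i <- i + 1L
    } else {
      stop(sprintf("character \"%s\" at position %d of \"%s\" is outside the SMILES alphabet",
                   ch, i, smiles), call. = FALSE)
    }
  }
  out[seq_len(k)]
}

# IDs of the four special tokens under a vocabulary's own map.
special_ids <- function(vocab) {
  stats::setNames(unname(vocab$token_to_id[vocab$special_tokens]),
                  names(vocab$special_tokens))
}

# Replace every non-overlapping left/right adjacency by the merged token,
# scanning left to right.
apply_merge <- function(tokens, left, right, merged = paste0(left, right)) {
  n <- length(tokens)
  if (n < 2L) return(tokens)
  hits <- which(tokens[-n] == left & tokens[-1L] == right)
  if (length(hits) == 0L) return(tokens)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && tokens[[i]] == left && tokens[[i + 1L]] == right) {
      k <- k + 1L
      out[[k]] <- merged
      i <- i + 2L
    } else {
      k <- k + 1L
      out[[k]] <- tokens[[i]]
      i <- i + 1L
    }
  }
  out[seq_len(k)]
}

new_vocabulary <- function(base_symbols, merges, token_to_id,
                           special_tokens = .SPECIAL_TOKENS) {
  stopifnot(!anyDuplicated(names(token_to_id)), !anyDuplicated(token_to_id))
  structure(
    list(base_symbols = base_symbols,
         merges = merges,
         special_tokens = special_tokens,
         token_to_id = token_to_id),
    class = "ddi_vocab")
}

#' @export
print.ddi_vocab <- function(x, ...) {
  cat(sprintf("<ddi_vocab> %d tokens (%d base symbols, %d merges, %d specials)\n",
              length(x$token_to_id), length(x$base_symbols),
              length(x$merges), length(x$special_tokens)))
  invisible(x)
}

#' Vocabulary size
#' @param vocab A vocabulary from [train_bpe()] or [load_vocab()].
#' @return Integer number of tokens (IDs are `0:(vocab_size(vocab) - 1)`).
#' @export
vocab_size <- function(vocab) length(vocab$token_to_id)

#' Learn a byte-pair-encoding vocabulary from a SMILES corpus
#'
#' Pre-tokenizes every corpus string at the atom level, then greedily merges
#' the most frequent adjacent symbol pair, `n_merges` times. A pair must
#' occur at least twice to be merged; ties are broken by the
#' lexicographically smallest (left, right) pair so training is
#' deterministic. Special tokens take IDs 0--3 (`<pad>`, `<bos>`, `<eos>`,
#' `<unk>`), followed by sorted base symbols, followed by merged tokens in
#' merge order.
#'
#' @param corpus Character vector of SMILES strings.
#' @param n_merges Non-negative integer; maximum number of merges to learn.
#' @return A `ddi_vocab` object.
#' @examples
#' v <- train_bpe(c("CCO", "CCN"), n_merges = 1)
#' v$merges
#' @export
train_bpe <- function(corpus, n_merges) {
  if (length(corpus) == 0L) stop("`corpus` must be non-empty", call. = FALSE)
  stopifnot(is.numeric(n_merges), length(n_merges) == 1L, n_merges >= 0)
  n_merges <- as.integer(n_merges)
  seqs <- lapply(corpus, pretokenize)
  base_symbols <- sort(unique(unlist(seqs)), method = "radix")

  sep <- "\x1f"
  merges <- vector("list", n_merges)
  n_done <- 0L
  for (k in seq_len(n_merges)) {
    keys <- unlist(lapply(seqs, function(s) {
      n <- length(s)
      if (n < 2L) return(character(0))
      paste(s[-n], s[-1L], sep = sep)
    }), use.names = FALSE)
    if (length(keys) == 0L) break
    tab <- table(keys)
    best_count <- max(tab)
    if (best_count < 2L) break
    cand <- sort(names(tab)[tab == best_count], method = "radix")[[1L]]
    pair <- strsplit(cand, sep, fixed = TRUE)[[1L]]
    seqs <- lapply(seqs, apply_merge, left = pair[[1L]], right = pair[[2L]])
    n_done <- n_done + 1L
    merges[[n_done]] <- pair
  }
  merges <- merges[seq_len(n_done)]

  merged_tokens <- vapply(merges, paste0, character(1L), collapse = "")
  tokens <- c(unname(.SPECIAL_TOKENS), base_symbols,
              setdiff(merged_tokens, base_symbols))
  token_to_id <- stats::setNames(seq_along(tokens) - 1L, tokens)
  new_vocabulary(base_symbols, merges, token_to_id)
}

#' Encode a SMILES string as a fixed-length token-ID sequence
#'
#' Applies atom-level pre-tokenization, then the vocabulary's merges in
#' order, maps symbols to IDs (unknown symbols become `<unk>`), wraps the
#' sequence in `<bos>`/`<eos>`, and pads with `<pad>` to `max_len`.
#' Sequences longer than `max_len - 2` content tokens are truncated from
#' the right, keeping a terminal `<eos>`.
#'
#' @param smiles A single SMILES string.
#' @param vocab A `ddi_vocab`.
#' @param max_len Total sequence length (>= 3) including `<bos>`/`<eos>`.
#' @return A `token_seq`: list with integer `ids` and 0/1 `mask`, both of
#'   length `max_len`, and `n_real` (number of mask == 1 positions).
#' @examples
#' v <- train_bpe(c("CCO", "CCN"), n_merges = 1)
#' encode("CCO", v, max_len = 8)
#' @export
encode <- function(smiles, vocab, max_len) {
  stopifnot(inherits(vocab, "ddi_vocab"),
            is.numeric(max_len), length(max_len) == 1L, max_len >= 3)
  max_len <- as.integer(max_len)
  sp <- special_ids(vocab)
  tokens <- pretokenize(smiles)
  for (m in vocab$merges) tokens <- apply_merge(tokens, m[[1L]], m[[2L]])
  ids <- unname(vocab$token_to_id[tokens])
  ids[is.na(ids)] <- sp[["unk"]]
  if (length(ids) > max_len - 2L) ids <- ids[seq_len(max_len - 2L)]
  ids <- c(sp[["bos"]], ids, sp[["eos"]])
  n_real <- length(ids)
  ids <- c(ids, rep.int(sp[["pad"]], max_len - n_real))
  mask <- c(rep.int(1L, n_real), rep.int(0L, max_len - n_real))
  structure(list(ids = as.integer(ids), mask = mask, n_real = n_real),
            class = "token_seq")
}

#' Decode a token sequence back to atom-level symbols
#'
#' Strips special tokens, expands merged tokens, and returns the atom-level
#' symbol sequence. For inputs encoded without any `<unk>` this inverts
#' [encode()] exactly (losslessness).
#'
#' @param seq A `token_seq` from [encode()].
#' @param vocab The vocabulary used to encode.
#' @return Character vector of atom-level symbols.
#' @export
decode <- function(seq, vocab) {
  stopifnot(inherits(seq, "token_seq"), inherits(vocab, "ddi_vocab"))
  sp <- special_ids(vocab)
  ids <- seq$ids[seq$mask == 1L]
  if (any(ids == sp[["unk"]])) {
    stop("sequence contains <unk>; lossless decoding is impossible",
         call. = FALSE)
  }
  ids <- ids[!(ids %in% sp[c("pad", "bos", "eos")])]
  id_to_token <- stats::setNames(names(vocab$token_to_id),
                                 vocab$token_to_id)
  tokens <- unname(id_to_token[as.character(ids)])
  if (length(tokens) == 0L) return(character(0))
  pretokenize(paste0(tokens, collapse = ""))
}

# Encode a vector of SMILES into an ids matrix (max_len x n) plus n_real.
encode_batch <- function(smiles, vocab, max_len) {
  n <- length(smiles)
  ids <- matrix(special_ids(vocab)[["pad"]], nrow = max_len, ncol = n)
  n_real <- integer(n)
  for (j in seq_len(n)) {
    s <- encode(smiles[[j]], vocab, max_len)
    ids[, j] <- s$ids
    n_real[[j]] <- s$n_real
  }
  list(ids = ids, n_real = n_real)
}

#' Save a vocabulary to a JSON file
#'
#' Writes a single JSON bundle holding the special tokens, base symbols,
#' ordered merges and the token-to-ID map. [load_vocab()] restores it
#' exactly.
#'
#' @param vocab A `ddi_vocab`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "ddi_vocab"))
  payload <- list(
    special_tokens = as.list(vocab$special_tokens),
    base_symbols = vocab$base_symbols,
    merges = lapply(vocab$merges, as.character),
    token_to_id = as.list(vocab$token_to_id))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a vocabulary from file
#'
#' Two dialects are accepted: the bundled JSON written by [save_vocab()],
#' or the common pretrained-tokenizer pair of a `vocab.json` token-to-ID
#' map plus a merges text file (one merge per line, "left right", lines
#' starting with `#` ignored) passed via `merges_path`.
#'
#' @param path Path to the bundled JSON (or, with `merges_path`, a plain
#'   token-to-ID JSON map).
#' @param merges_path Optional path to a merges text file.
#' @return A `ddi_vocab`.
#' @export
load_vocab <- function(path, merges_path = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop(sprintf("failed to parse %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (is.null(merges_path)) {
    need <- c("special_tokens", "base_symbols", "merges", "token_to_id")
    missing <- setdiff(need, names(obj))
    if (length(missing) > 0L) {
      stop(sprintf("vocabulary file %s lacks field(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    token_to_id <- unlist(obj$token_to_id)
    storage.mode(token_to_id) <- "integer"
    return(new_vocabulary(
      base_symbols = unlist(obj$base_symbols),
      merges = lapply(obj$merges, unlist),
      token_to_id = token_to_id,
      special_tokens = unlist(obj$special_tokens)))
  }
  # external vocab.json + merges.txt dialect
  token_to_id <- unlist(obj)
  if (!is.numeric(token_to_id) || anyDuplicated(token_to_id)) {
    stop(sprintf("%s is not a token-to-ID map", path), call. = FALSE)
  }
  storage.mode(token_to_id) <- "integer"
  if (!file.exists(merges_path)) {
    stop(sprintf("no such file: %s", merges_path), call. = FALSE)
  }
  lines <- readLines(merges_path, warn = FALSE)
  merges <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1L]]
    if (length(fields) != 2L) {
      stop(sprintf("%s line %d: expected \"left right\", got \"%s\"",
                   merges_path, i, line), call. = FALSE)
    }
    merges[[length(merges) + 1L]] <- fields
  }
  specials <- .SPECIAL_TOKENS
  # accept RoBERTa-style special names when present
  alt <- c(pad = "<pad>", bos = "<s>", eos = "</s>", unk = "<unk>")
  for (role in names(specials)) {
    if (!(specials[[role]] %in% names(token_to_id)) &&
        alt[[role]] %in% names(token_to_id)) {
      specials[[role]] <- alt[[role]]
    }
  }
  absent <- specials[!(specials %in% names(token_to_id))]
  if (length(absent) > 0L) {
    stop(sprintf("%s lacks special token(s): %s", path,
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  merged_tokens <- vapply(merges, paste0, character(1L), collapse = "")
  base_symbols <- setdiff(names(token_to_id), c(specials, merged_tokens))
  new_vocabulary(base_symbols, merges, token_to_id, specials)
}
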