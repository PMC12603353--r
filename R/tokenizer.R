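PAD_TOKEN <- "[PAD]"
UNK_TOKEN <- "[UNK]"
CLS_TOKEN <- "[CLS]"
SEP_TOKEN <- "[SEP]"

#' Build the k-mer vocabulary for LCA tokenization
#'
#' The vocabulary is the four special tokens followed by all `4^k` k-mers over
#' `{A,C,G,T}` in lexicographic order, so token ids are bit-reproducible
#' across runs. Ids are 0-based: `[PAD]` is 0, `[UNK]` 1, `[CLS]` 2,
#' `[SEP]` 3.
#'
#' @param k k-mer size (`k = 6` for the standard model, `k = 1` for the
#'   character-level variant).
#' @return An object of class `lca_vocab`: list with `k`, `tokens`, and the
#'   special-token ids.
#' @export
lca_vocabulary <- function(k = 6L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  bases <- c("A", "C", "G", "T")
  kmers <- bases
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      kmers <- as.vector(t(outer(kmers, bases, paste0)))
    }
  }
  kmers <- sort(kmers)
  tokens <- c(PAD_TOKEN, UNK_TOKEN, CLS_TOKEN, SEP_TOKEN, kmers)
  structure(
    list(k = k, tokens = tokens, size = length(tokens),
         pad_id = 0L, unk_id = 1L, cls_id = 2L, sep_id = 3L),
    class = "lca_vocab"
  )
}

#' Write / read a vocabulary as a token-per-line text file
#' @param vocab an `lca_vocab`.
#' @param path file path.
#' @return `path` (write) or an `lca_vocab` (read).
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  k <- nchar(tokens[length(tokens)])
  v <- lca_vocabulary(k)
  if (!identical(v$tokens, tokens)) {
    stop("vocabulary file does not match the canonical token ordering")
  }
  v
}

#' Tokenize a nucleotide sequence into overlapping (LCA) k-mers
#'
#' Local Context Aware tokenization emits windows `seq[i, i+k)` for
#' `i = 0, shift, 2*shift, ...` while the window fits. Consecutive tokens
#' overlap by `k - shift` bases, preserving local context. Windows containing
#' `N` become the `[UNK]` token so positional structure is preserved.
#'
#' @param seq a single nucleotide sequence.
#' @param k k-mer size.
#' @param shift step between consecutive windows, `1 <= shift <= k`.
#' @return Character vector of tokens (empty when `nchar(seq) < k`).
#' @examples
#' lca_tokenize("AATCGGTA", k = 6, shift = 1)
#' @export
lca_tokenize <- function(seq, k = 6L, shift = 1L) {
  k <- as.integer(k); shift <- as.integer(shift)
  if (shift < 1L || shift > k) {
    stop("`shift` must satisfy 1 <= shift <= k")
  }
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = shift)
  toks <- substring(seq, starts, starts + k - 1L)
  toks[grepl("N", toks, fixed = TRUE)] <- UNK_TOKEN
  toks
}

#' Reconstruct a sequence from overlap-consistent LCA tokens
#'
#' Inverse of [lca_tokenize()] when `(nchar(seq) - k) %% shift == 0` and the
#' sequence contains no `N`: the first token contributes all `k` bases and
#' each subsequent token its trailing `shift` bases. Consecutive tokens must
#' agree on their `k - shift` base overlap.
#'
#' @param tokens character vector of k-mer tokens.
#' @param shift the shift used during tokenization.
#' @return The reconstructed nucleotide string.
#' @export
lca_detokenize <- function(tokens, shift = 1L) {
  if (length(tokens) == 0L) return("")
  shift <- as.integer(shift)
  k <- nchar(tokens[1L])
  if (any(nchar(tokens) != k)) stop("tokens must all have the same length")
  if (length(tokens) > 1L && shift < k) {
    prev_tail <- substring(tokens[-length(tokens)], shift + 1L, k)
    next_head <- substring(tokens[-1L], 1L, k - shift)
    bad <- which(prev_tail != next_head)
    if (length(bad) > 0L) {
      stop(sprintf("overlap mismatch between tokens %d and %d",
                   bad[1L], bad[1L] + 1L))
    }
  }
  paste0(tokens[1L],
         paste(substring(tokens[-1L], k - shift + 1L, k), collapse = ""))
}

#' Encode tokens into a fixed-length id sequence with special-token framing
#'
#' Produces `[CLS] tokens... [SEP]` as 0-based vocabulary ids, truncated to
#' `max_len` with `[SEP]` always retained as the last real token, then padded
#' with `[PAD]` (id 0). The attention mask marks real tokens with 1.
#'
#' @param tokens character vector of k-mer tokens (e.g. from
#'   [lca_tokenize()]).
#' @param vocab an [lca_vocabulary()].
#' @param max_len total encoded length including the two special tokens
#'   (`>= 3`).
#' @return List with `ids` (integer, length `max_len`), `attention_mask`
#'   (0/1 integer), and `n_real_tokens`.
#' @export
encode_tokens <- function(tokens, vocab, max_len = 512L) {
  max_len <- as.integer(max_len)
  if (max_len < 3L) stop("`max_len` must be >= 3")
  ids <- match(tokens, vocab$tokens) - 1L
  ids[is.na(ids)] <- vocab$unk_id
  if (length(ids) > max_len - 2L) {
    ids <- ids[seq_len(max_len - 2L)]
  }
  real <- c(vocab$cls_id, ids, vocab$sep_id)
  n_real <- length(real)
  out_ids <- c(real, rep(vocab$pad_id, max_len - n_real))
  mask <- c(rep(1L, n_real), rep(0L, max_len - n_real))
  list(ids = as.integer(out_ids), attention_mask = mask,
       n_real_tokens = n_real)
}

#' Tokenize and encode a batch of sequences into id/mask matrices
#'
#' @param seqs character vector of nucleotide sequences.
#' @param vocab an [lca_vocabulary()].
#' @param shift LCA shift.
#' @param max_len encoded length (including `[CLS]`/`[SEP]`).
#' @return List with integer matrices `ids` and `mask` (`length(seqs)` rows,
#'   `max_len` columns) and integer vector `n_real`.
#' @export
encode_batch <- function(seqs, vocab, shift = 1L, max_len = 512L) {
  n <- length(seqs)
  ids <- matrix(vocab$pad_id, nrow = n, ncol = max_len)
  mask <- matrix(0L, nrow = n, ncol = max_len)
  n_real <- integer(n)
  for (i in seq_len(n)) {
    enc <- encode_tokens(lca_tokenize(seqs[i], vocab$k, shift), vocab,
                         max_len)
    ids[i, ] <- enc$ids
    mask[i, ] <- enc$attention_mask
    n_real[i] <- enc$n_real_tokens
  }
  list(ids = ids, mask = mask, n_real = n_real)
}
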