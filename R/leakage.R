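# Train/test leakage control: MinHash bottom-k sketching of canonical
# 21-mers, Jaccard -> ANI conversion, FastANI table ingestion, and
# strict/standard holdout construction.

#' 64-bit MurmurHash3 of character strings
#'
#' MurmurHash3 x64 128-bit variant; the first 64-bit word is returned as a
#' fixed-width 16-digit lowercase hex string. R has no native 64-bit integer;
#' lexicographic order on these strings equals unsigned numeric order, so
#' bottom-k selection on them is exact.
#'
#' @param x character vector to hash.
#' @param seed integer hash seed.
#' @return Character vector of 16-digit hex hashes.
#' @export
mm3_hash64 <- function(x, seed = 3L) {
  .mm3_hash64_hex(as.character(x), as.integer(seed))
}

#' Bottom-k MinHash signature of a sequence
#'
#' The sequence's distinct canonical 21-mers are hashed with MurmurHash3
#' (seed 3) and the `size` smallest distinct hash values form the signature.
#' Canonical k-mers make the sketch strand-invariant. A single hash function
#' with bottom-k selection is used (not k independent hash functions).
#'
#' @param seq a nucleotide sequence, or a [contig_set()] row's `seq`.
#' @param id contig id recorded in the signature.
#' @param k k-mer length (default 21).
#' @param size signature size (default 300).
#' @param seed MurmurHash3 seed (default 3).
#' @return Object of class `minhash_signature`: list with `contig_id`, `k`,
#'   `size`, `seed` and `mins` (sorted hex hashes, length `<= size`).
#' @export
minhash_sketch <- function(seq, id = NA_character_, k = 21L, size = 300L,
                           seed = 3L) {
  kmers <- canonical_kmers(seq, k)
  if (length(kmers) == 0L) {
    warning(sprintf("sequence '%s' shorter than k=%d: empty sketch", id, k))
  }
  hashes <- sort(unique(mm3_hash64(kmers, seed)))
  structure(list(contig_id = id, k = as.integer(k), size = as.integer(size),
                 seed = as.integer(seed),
                 mins = utils::head(hashes, size)),
            class = "minhash_signature")
}

#' Sketch every contig in a set
#'
#' @param contigs a [contig_set()].
#' @inheritParams minhash_sketch
#' @return Named list of `minhash_signature` objects.
#' @export
sketch_contigs <- function(contigs, k = 21L, size = 300L, seed = 3L) {
  sigs <- lapply(seq_len(nrow(contigs)), function(i) {
    minhash_sketch(contigs$seq[i], id = contigs$id[i], k = k, size = size,
                   seed = seed)
  })
  stats::setNames(sigs, contigs$id)
}

#' Estimate the Jaccard coefficient of two sketched sequences
#'
#' Merged-sketch estimator: the `size` smallest distinct hashes of the union
#' of both signatures are taken and the fraction present in both signatures
#' is returned. When either sequence had fewer than `size` distinct k-mers
#' its sketch is its complete hash set, and the estimate reduces to the exact
#' Jaccard coefficient.
#'
#' @param a,b `minhash_signature` objects with identical `(k, size, seed)`.
#' @return Estimated Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_estimate <- function(a, b) {
  if (a$k != b$k || a$size != b$size || a$seed != b$seed) {
    stop("signatures were built with different (k, size, seed) parameters")
  }
  u <- sort(unique(c(a$mins, b$mins)))
  if (length(u) == 0L) return(0)
  taken <- utils::head(u, a$size)
  sum(taken %in% a$mins & taken %in% b$mins) / length(taken)
}

#' Convert a Jaccard estimate to an ANI estimate
#'
#' Mash-style conversion `ANI = 1 + (1/k) * ln(2j / (1 + j))`, clipped to
#' `[0, 1]`. A Jaccard of exactly 0 carries no distance information; the
#' result is reported as 0 with attribute `undefined = TRUE`.
#'
#' @param j Jaccard coefficient in `[0, 1]`.
#' @param k the k-mer size the Jaccard was computed over.
#' @return ANI estimate in `[0, 1]` (attribute `undefined` when `j == 0`).
#' @export
ani_from_jaccard <- function(j, k = 21L) {
  if (is.na(j) || j < 0 || j > 1) stop("`j` must lie in [0, 1]")
  if (j == 0) {
    return(structure(0, undefined = TRUE))
  }
  min(1, max(0, 1 + log(2 * j / (1 + j)) / k))
}

#' Parse FastANI default tab-separated output
#'
#' Expected columns: query, reference, ANI (percent), bidirectional fragment
#' mappings, total query fragments. ANI is converted to a fraction and the
#' aligned fraction is mappings / total fragments.
#'
#' @param path FastANI output file.
#' @return `data.frame` with columns `id_a`, `id_b`, `ani_est`,
#'   `aligned_frac`, `source`; zero rows for an empty file.
#' @export
parse_fastani <- function(path) {
  if (!file.exists(path)) stop("FastANI file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      ani_est = numeric(0), aligned_frac = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1L]
    stop(sprintf("malformed FastANI row at line %d: expected 5 columns, got %d",
                 bad, nf[bad]))
  }
  m <- do.call(rbind, fields)
  ani <- suppressWarnings(as.numeric(m[, 3L]))
  frag <- suppressWarnings(as.numeric(m[, 4L]))
  tot <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- which(is.na(ani) | is.na(frag) | is.na(tot) | tot <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("malformed FastANI numeric fields at line %d", bad[1L]))
  }
  data.frame(id_a = m[, 1L], id_b = m[, 2L], ani_est = ani / 100,
             aligned_frac = frag / tot, source = "fastani",
             stringsAsFactors = FALSE)
}

#' Build a leakage-controlled training set (strict or standard holdout)
#'
#' In `strict` mode every training record whose similarity to ANY test
#' record reaches `ani_threshold` is removed; when FastANI output is
#' supplied the full two-part rule applies (ANI >= threshold AND aligned
#' fraction of the training-side record >= `frac_threshold`), while the
#' sketch-based path applies the ANI criterion alone (an aligned fraction is
#' not derivable from a Jaccard sketch) and the report records that. In
#' `standard` mode the training set is returned unchanged.
#'
#' @param train,test labeled [contig_set()]s.
#' @param mode `"strict"` or `"standard"`.
#' @param ani_threshold removal threshold on ANI (inclusive; default 0.80).
#' @param frac_threshold removal threshold on the aligned fraction of the
#'   training record (FastANI path only; default 0.80).
#' @param fastani optional `data.frame` from [parse_fastani()] with the
#'   training record as query (`id_a`) and test record as reference.
#' @param k,size,seed sketch parameters for the sketch-based path.
#' @return List with `train` (filtered [contig_set()]) and `removed`
#'   (`data.frame` of removals: `train_id`, `test_id`, `ani_est`,
#'   `aligned_frac`, `source`).
#' @export
build_holdout <- function(train, test, mode = c("strict", "standard"),
                          ani_threshold = 0.80, frac_threshold = 0.80,
                          fastani = NULL, k = 21L, size = 300L, seed = 3L) {
  mode <- match.arg(mode)
  if (nrow(train) == 0L || nrow(test) == 0L) {
    stop("both train and test sets must be non-empty")
  }
  removed <- data.frame(train_id = character(0), test_id = character(0),
                        ani_est = numeric(0), aligned_frac = numeric(0),
                        source = character(0), stringsAsFactors = FALSE)
  if (mode == "standard") {
    return(list(train = train, removed = removed))
  }
  if (!is.null(fastani)) {
    hits <- fastani[fastani$id_a %in% train$id &
                      fastani$id_b %in% test$id &
                      fastani$ani_est >= ani_threshold &
                      fastani$aligned_frac >= frac_threshold, , drop = FALSE]
    if (nrow(hits) > 0L) {
      removed <- data.frame(train_id = hits$id_a, test_id = hits$id_b,
                            ani_est = hits$ani_est,
                            aligned_frac = hits$aligned_frac,
                            source = "fastani", stringsAsFactors = FALSE)
    }
  } else {
    tr_sigs <- sketch_contigs(train, k = k, size = size, seed = seed)
    te_sigs <- sketch_contigs(test, k = k, size = size, seed = seed)
    for (i in seq_along(tr_sigs)) {
      for (j in seq_along(te_sigs)) {
        jac <- jaccard_estimate(tr_sigs[[i]], te_sigs[[j]])
        ani <- ani_from_jaccard(jac, k = k)
        if (as.numeric(ani) >= ani_threshold) {
          removed <- rbind(removed, data.frame(
            train_id = tr_sigs[[i]]$contig_id,
            test_id = te_sigs[[j]]$contig_id,
            ani_est = as.numeric(ani),
            aligned_frac = NA_real_,
            source = "sketch", stringsAsFactors = FALSE))
        }
      }
    }
  }
  keep <- !(train$id %in% removed$train_id)
  if (!any(keep)) {
    warning("strict holdout removed every training record")
  }
  filtered <- train[keep, , drop = FALSE]
  rownames(filtered) <- NULL
  class(filtered) <- c("contig_set", "data.frame")
  list(train = filtered, removed = removed)
}
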